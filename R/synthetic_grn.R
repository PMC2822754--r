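#' Generate a source regulatory-network topology
#'
#' Directed, weakly connected, acyclic-by-construction graph (edges run
#' from earlier to later nodes in a random order) with preferential
#' attachment on regulator out-degree, producing the heavy-tailed
#' out-degree distribution (a few hub regulators) characteristic of
#' transcriptional networks.  Edges carry a sign (activation by
#' default with probability `activation_prob`), an interaction
#' strength, a half-saturation constant and a Hill coefficient; each
#' gene has a basal expression level.
#'
#' @param n_nodes Number of genes.
#' @param n_edges Number of interactions (>= n_nodes - 1).
#' @param activation_prob Probability that an edge is activating
#'   (default 0.85; a predominantly activating program keeps regulon
#'   responses coherent).
#' @param strength_range Strength range (uniform) of each gene's
#'   primary-regulator edge, on the standardized activity scale where
#'   an edge of strength s yields a regulator-target correlation of
#'   about `s / sqrt(s^2 + 1)` (see [simulate_expression()]); default
#'   `c(5, 9)`.
#' @param extra_strength_range Strength range of the additional
#'   (secondary) regulatory edges; default `c(0.2, 0.6)`, so each gene
#'   has one dominant regulator plus weaker modifiers.
#' @param attachment_offset Initial attractiveness in the preferential
#'   attachment rule (weight = out-degree + offset); smaller values
#'   concentrate regulation into fewer, larger regulons (default
#'   0.15).
#' @param seed Integer seed.
#' @return A `regulatory_network`: list with `nodes`, `edges` (data
#'   frame: `regulator`, `target`, `sign`, `strength`,
#'   `half_saturation`, `hill`), `basal` (named numeric).
#' @export
generate_source_topology <- function(n_nodes, n_edges,
                                     activation_prob = 0.85,
                                     strength_range = c(5, 9),
                                     extra_strength_range = c(0.2, 0.6),
                                     attachment_offset = 0.15,
                                     seed = 1L) {
  if (n_edges < n_nodes - 1L)
    stop("need at least n_nodes - 1 edges for weak connectivity")
  if (n_edges > n_nodes * (n_nodes - 1L) / 2L)
    stop("too many edges for an acyclic simple graph")
  nodes <- sprintf("G%04d", seq_len(n_nodes))
  local_seed(seed, {
    outdeg <- stats::setNames(numeric(n_nodes), nodes)
    reg_of <- vector("list", n_nodes)  # regulators per target index
    # spanning skeleton: each node after the first is regulated by an
    # earlier node chosen preferentially by current out-degree
    for (i in 2:n_nodes) {
      w <- outdeg[seq_len(i - 1L)] + attachment_offset
      r <- sample.int(i - 1L, 1L, prob = w)
      reg_of[[i]] <- r
      outdeg[r] <- outdeg[r] + 1
    }
    n_extra <- n_edges - (n_nodes - 1L)
    added <- 0L
    attempts <- 0L
    while (added < n_extra) {
      attempts <- attempts + 1L
      if (attempts > 50L * n_extra + 1000L)
        stop("could not place the requested number of edges")
      r <- sample.int(n_nodes - 1L, 1L,
                      prob = outdeg[seq_len(n_nodes - 1L)] + attachment_offset)
      tgts <- seq.int(r + 1L, n_nodes)
      tgt <- if (length(tgts) == 1L) tgts else sample(tgts, 1L)
      if (r %in% reg_of[[tgt]]) next
      reg_of[[tgt]] <- c(reg_of[[tgt]], r)
      outdeg[r] <- outdeg[r] + 1
      added <- added + 1L
    }
    targets <- rep(seq_len(n_nodes), lengths(reg_of))
    regulators <- unlist(reg_of)
    m <- length(regulators)
    # the first (spanning) regulator of each target is its primary one
    primary <- !duplicated(targets)
    strength <- ifelse(primary,
                       stats::runif(m, strength_range[1L], strength_range[2L]),
                       stats::runif(m, extra_strength_range[1L],
                                    extra_strength_range[2L]))
    edges <- data.frame(
      regulator = nodes[regulators],
      target = nodes[targets],
      sign = ifelse(stats::runif(m) < activation_prob, 1L, -1L),
      strength = strength,
      half_saturation = stats::runif(m, 0.8, 1.2),
      hill = sample(c(1, 2), m, replace = TRUE, prob = c(0.9, 0.1)),
      stringsAsFactors = FALSE)
    structure(list(nodes = nodes, edges = edges,
                   basal = stats::setNames(stats::rnorm(n_nodes, 0, 5),
                                           nodes)),
              class = "regulatory_network")
  })
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d genes, %d interactions (%.0f%% activating)\n",
              length(x$nodes), nrow(x$edges),
              100 * mean(x$edges$sign == 1L)))
  invisible(x)
}

#' Sample a connected subnetwork by neighbour expansion
#'
#' Starting from a random seed gene, repeatedly adds a random
#' (undirected) graph neighbour of the current set — selected with
#' probability proportional to the strength of its strongest
#' connecting interaction, so that co-regulated modules are sampled
#' coherently rather than severed — until `n_genes` are collected; the
#' induced edge set is retained.  If the reachable component is
#' exhausted, expansion restarts from a fresh seed gene with a
#' warning.
#'
#' @param net A `regulatory_network`.
#' @param n_genes Subnetwork size (default 150).
#' @param seed Integer seed.
#' @return A `regulatory_network` over the sampled genes.
#' @export
sample_subnetwork <- function(net, n_genes = 150L, seed = 1L) {
  if (n_genes > length(net$nodes))
    stop("n_genes exceeds the network size")
  if (n_genes == length(net$nodes)) return(net)
  nbrs <- stats::setNames(rep(list(character()), length(net$nodes)), net$nodes)
  wts <- nbrs
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$regulator[i]; b <- net$edges$target[i]
    s <- net$edges$strength[i]
    nbrs[[a]] <- c(nbrs[[a]], b); wts[[a]] <- c(wts[[a]], s)
    nbrs[[b]] <- c(nbrs[[b]], a); wts[[b]] <- c(wts[[b]], s)
  }
  local_seed(seed, {
    chosen <- sample(net$nodes, 1L)
    frontier <- stats::setNames(unlist(wts[[chosen]]) %||% numeric(),
                                nbrs[[chosen]])
    frontier <- frontier[!names(frontier) %in% chosen]
    while (length(chosen) < n_genes) {
      if (length(frontier) == 0L) {
        warning("component exhausted; restarting from a new seed gene")
        pool <- setdiff(net$nodes, chosen)
        nxt <- sample(pool, 1L)
      } else {
        nxt <- if (length(frontier) == 1L) names(frontier)
               else sample(names(frontier), 1L, prob = frontier)
      }
      chosen <- c(chosen, nxt)
      add <- stats::setNames(unlist(wts[[nxt]]) %||% numeric(), nbrs[[nxt]])
      both <- c(frontier, add)
      both <- tapply(both, names(both), max)     # keep strongest link
      frontier <- both[!names(both) %in% c(chosen, nxt)]
    }
    keep <- net$edges$regulator %in% chosen & net$edges$target %in% chosen
    structure(list(nodes = net$nodes[net$nodes %in% chosen],
                   edges = net$edges[keep, , drop = FALSE],
                   basal = net$basal[net$nodes[net$nodes %in% chosen]]),
              class = "regulatory_network")
  })
}

#' Simulation design for synthetic expression data
#'
#' @param n_samples_per_condition Samples per condition (total samples
#'   is twice this).
#' @param n_time_points Nominal time points per condition; samples are
#'   spread over them cyclically and replicate groups are
#'   condition-by-time blocks.
#' @param bio_noise_sd Biological noise: sd of per-sample perturbation
#'   of each gene's regulatory input (log-expression units).
#' @param exp_noise_sd Experimental noise: sd of measurement noise
#'   added to the latent log-expression.
#' @param condition_effect Named numeric vector of basal shifts applied
#'   to perturbed genes in condition-1 samples.
#' @param seed Integer seed.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_samples_per_condition, n_time_points = 4L,
                              bio_noise_sd = 0.1, exp_noise_sd = 0.1,
                              condition_effect = numeric(), seed = 1L) {
  stopifnot(n_samples_per_condition >= 2L, n_time_points >= 1L,
            is.finite(bio_noise_sd), bio_noise_sd >= 0,
            is.finite(exp_noise_sd), exp_noise_sd >= 0)
  structure(list(n_samples_per_condition = as.integer(n_samples_per_condition),
                 n_time_points = as.integer(n_time_points),
                 bio_noise_sd = bio_noise_sd,
                 exp_noise_sd = exp_noise_sd,
                 condition_effect = condition_effect,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Draw a condition effect for a network
#'
#' Basal shifts for a random fraction of the genes (default 2/3) with
#' predominantly positive sign (up-regulation of the differentiation
#' program; 20% of shifts are negative), emulating the transcriptional
#' response to the induction of differentiation.  Effect magnitudes are expressed in
#' units of each gene's biological standard deviation at a reference
#' noise level (`ref_sd`), so that strongly regulated genes — whose
#' dynamic range is larger — receive proportionally larger absolute
#' shifts and gene selection is not biased towards weakly regulated
#' genes.
#'
#' @param net A `regulatory_network`.
#' @param fraction Fraction of genes perturbed (default 2/3).
#' @param effect_range Magnitude range in per-gene biological-sd
#'   units; default `c(0.8, 1.6)`.
#' @param ref_sd Reference biological noise level at which the per-gene
#'   sd is computed (default 0.3, the cleanest tier).
#' @param seed Integer seed.
#' @return Named numeric vector of basal shifts (latent units).
#' @export
sample_condition_effect <- function(net, fraction = 2 / 3,
                                    effect_range = c(1.0, 1.4),
                                    ref_sd = 0.3, seed = 1L) {
  n <- max(1L, round(fraction * length(net$nodes)))
  # per-gene biological sd multiplier: sqrt(1 + sum of squared incoming
  # strengths) -- own unit noise plus standardized regulatory inputs
  kappa <- vapply(net$nodes, function(g) {
    s <- net$edges$strength[net$edges$target == g]
    sqrt(1 + sum(s^2))
  }, 1.0)
  local_seed(seed, {
    ids <- sample(net$nodes, n)
    u <- stats::runif(n, effect_range[1L], effect_range[2L])
    stats::setNames(u * ref_sd * kappa[ids] *
                      sample(c(-1, 1), n, replace = TRUE,
                             prob = c(0.2, 0.8)), ids)
  })
}

# Hill response of a regulator's latent value: squash to (0,1) with a
# logistic (scale widens the input range treated as responsive), then
# apply the Hill function.  Strictly increasing in x.
hill_response <- function(x, half_saturation, hill, scale = 3) {
  u <- stats::plogis(x / scale)
  u^hill / (half_saturation^hill + u^hill)
}

# Pooled within-condition standard deviation (guards class-shift
# contamination of the scale).
wc_sd <- function(x, cond) {
  sqrt(mean(unlist(lapply(split(x, cond), function(v)
    (v - mean(v))^2))))
}

# Standardized Hill response of a regulator: the regulator's latent
# values are first normalized to their within-condition dynamic range
# across the samples being generated (each target responds over its
# regulator's operating range, as in activity-scaled transfer
# functions), passed through the logistic-Hill transfer, and the
# response is standardized again the same way.  `strength` is thereby
# expressed on the standardized activity scale: an edge's
# signal-to-noise ratio, and the condition shift a target inherits
# from its regulator, are depth- and noise-level-invariant.  Zero when
# the regulator does not vary.
scaled_response <- function(x, half_saturation, hill, cond) {
  s <- wc_sd(x, cond)
  if (!is.finite(s) || s < 1e-12) return(x * 0)
  z <- (x - mean(x)) / s
  h <- hill_response(z, half_saturation, hill, scale = 1.5)
  s2 <- wc_sd(h, cond)
  if (!is.finite(s2) || s2 < 1e-12) return(h * 0)
  (h - mean(h)) / s2
}

#' Simulate an expression dataset from a regulatory network
#'
#' Steady-state Hill-kinetics evaluation: each gene's latent
#' log-expression is its basal level, plus the condition shift (in
#' condition-1 samples), plus `bio_noise_sd` times the sum of a
#' unit-variance per-sample biological perturbation and the signed,
#' strength-weighted standardized Hill responses of its regulators.
#' Interaction strengths are therefore signal-to-noise ratios: an edge
#' of strength s gives a regulator-target correlation of about
#' `s / sqrt(s^2 + 1)` at any network depth and any biological noise
#' level, while `bio_noise_sd` scales all sample-level biological
#' variation (so it dilutes the fixed condition effect, as biological
#' complexity does).  Acyclic networks are evaluated in one topological
#' pass; cyclic ones by damped fixed-point iteration.  Observed values
#' add `exp_noise_sd` measurement noise.  Output standardization is
#' left to the analysis pipeline.
#'
#' @param net A `regulatory_network`.
#' @param design A [simulation_design()].
#' @param name Dataset label.
#' @return An [expression_dataset()] with `replicate_groups` set to
#'   condition-by-time blocks and an attribute `"truth"`: list with
#'   `network`, `responsive` (directly perturbed genes),
#'   `responsive_downstream` (their descendants), `condition_effect`.
#' @export
simulate_expression <- function(net, design, name = "synthetic") {
  genes <- net$nodes
  n_g <- length(genes)
  bad <- setdiff(names(design$condition_effect), genes)
  if (length(bad) > 0L)
    stop("perturbed genes not in network: ", paste(bad, collapse = ", "))
  npc <- design$n_samples_per_condition
  n_s <- 2L * npc
  cond <- rep(c(0L, 1L), each = npc)
  timep <- rep(rep_len(seq_len(design$n_time_points), npc), 2L)
  sample_ids <- sprintf("s%02d_c%d_t%d", seq_len(n_s), cond, timep)
  shift <- stats::setNames(numeric(n_g), genes)
  shift[names(design$condition_effect)] <- design$condition_effect

  parents_idx <- split(seq_len(nrow(net$edges)),
                       factor(net$edges$target, levels = genes))
  plist <- lapply(genes, function(g)
    unique(net$edges$regulator[net$edges$target == g]))
  names(plist) <- genes
  topo <- topological_order(plist)

  local_seed(design$seed, {
    base <- matrix(net$basal, n_g, n_s, dimnames = list(genes, sample_ids))
    base <- base + outer(shift, as.numeric(cond)) +
      design$bio_noise_sd *
        matrix(stats::rnorm(n_g * n_s), n_g, n_s)
    reg_input <- function(latent, g) {
      rows <- parents_idx[[g]]
      if (length(rows) == 0L) return(0)
      contrib <- 0
      for (i in rows) {
        e <- net$edges[i, ]
        contrib <- contrib + e$sign * e$strength *
          scaled_response(latent[e$regulator, ], e$half_saturation,
                          e$hill, cond)
      }
      design$bio_noise_sd * contrib
    }
    if (!is.null(topo)) {
      latent <- base
      for (g in topo)
        latent[g, ] <- base[g, ] + reg_input(latent, g)
    } else {
      latent <- base
      converged <- FALSE
      for (it in seq_len(200L)) {
        nxt <- base
        for (g in genes) nxt[g, ] <- base[g, ] + reg_input(latent, g)
        nxt <- 0.5 * latent + 0.5 * nxt    # damping
        if (max(abs(nxt - latent)) < 1e-8) { latent <- nxt; converged <- TRUE; break }
        latent <- nxt
      }
      if (!converged) {
        drift <- apply(abs(nxt - latent), 1L, max)
        stop("fixed-point iteration did not converge for: ",
             paste(genes[drift > 1e-8], collapse = ", "))
      }
    }
    observed <- latent +
      matrix(stats::rnorm(n_g * n_s, 0, design$exp_noise_sd), n_g, n_s)
    ds <- expression_dataset(observed, cond, name = name,
                             replicate_groups = sprintf("c%d_t%d", cond, timep),
                             time_points = timep)
    responsive <- names(design$condition_effect)
    downstream <- unique(unlist(lapply(genes, function(g)
      if (any(gene_ancestors(plist, g) %in% responsive)) g else NULL)))
    attr(ds, "truth") <- list(network = net,
                              responsive = responsive,
                              responsive_downstream = downstream,
                              condition_effect = design$condition_effect)
    ds
  })
}

#' Default three-tier noise designs
#'
#' Three designs over the same subnetwork that differ in biological and
#' experimental noise, with sample counts 24 / 36 / 32 mimicking the
#' real muscle-differentiation datasets, so that replicate correlation
#' and differentially-expressed-gene counts order them low < mid <
#' high complexity.
#'
#' @param seed Integer seed fanned out to each tier.
#' @return Named list of three [simulation_design()]s (`low`, `mid`,
#'   `high`).
#' @export
default_tiers <- function(seed = 1L) {
  list(
    low = simulation_design(n_samples_per_condition = 12L, n_time_points = 4L,
                            bio_noise_sd = 0.3, exp_noise_sd = 0.05,
                            seed = derive_seed(seed, "tier", "low")),
    mid = simulation_design(n_samples_per_condition = 18L, n_time_points = 6L,
                            bio_noise_sd = 0.75, exp_noise_sd = 0.1,
                            seed = derive_seed(seed, "tier", "mid")),
    high = simulation_design(n_samples_per_condition = 16L, n_time_points = 4L,
                             bio_noise_sd = 1.1, exp_noise_sd = 0.15,
                             seed = derive_seed(seed, "tier", "high")))
}

#' Append unconnected background genes to a network
#'
#' Adds isolated nodes (no regulatory edges, basal level plus noise
#' only) representing the transcriptome outside the process under
#' study: the pool from which uninformative genes are drawn, as on a
#' real array where most probesets are unrelated to the pathway.
#'
#' @param net A `regulatory_network`.
#' @param n_background Number of background genes to append.
#' @param basal_sd Spread of background basal levels (default 5,
#'   matching the regulated genes).
#' @param seed Integer seed.
#' @return The augmented `regulatory_network`.
#' @export
add_background_genes <- function(net, n_background, basal_sd = 5,
                                 seed = 1L) {
  if (n_background < 1L) return(net)
  ids <- sprintf("B%04d", seq_len(n_background))
  if (any(ids %in% net$nodes)) stop("background gene ids collide")
  basal <- local_seed(seed, stats::rnorm(n_background, 0, basal_sd))
  net$nodes <- c(net$nodes, ids)
  net$basal <- c(net$basal, stats::setNames(basal, ids))
  net
}

#' Generate a series of datasets of increasing complexity
#'
#' Samples one subnetwork from the source topology, appends isolated
#' background genes, and simulates one dataset per noise tier from
#' that same gene set (sharing one condition effect over the
#' subnetwork genes), so every dataset carries identical ground truth
#' and the tiers differ only in noise and sample layout.
#'
#' @param net A source `regulatory_network`.
#' @param tiers Named list of [simulation_design()]s with strictly
#'   increasing `bio_noise_sd + exp_noise_sd`.
#' @param n_genes Subnetwork size (default 150).
#' @param n_background Number of unconnected, condition-unresponsive
#'   background genes appended to every dataset (default 250).
#' @param condition_effect Optional shared condition effect; drawn via
#'   [sample_condition_effect()] over the subnetwork when NULL.
#' @param seed Integer seed for subnetwork sampling and the condition
#'   effect.
#' @return Named list of [expression_dataset()]s (one per tier), each
#'   with a `"truth"` attribute; the shared subnetwork is attached as
#'   attribute `"subnetwork"` of the list.
#' @export
make_dataset_series <- function(net, tiers = default_tiers(seed),
                                n_genes = 150L, n_background = 250L,
                                condition_effect = NULL, seed = 1L) {
  if (length(tiers) < 2L) stop("need at least 2 noise tiers")
  total_noise <- vapply(tiers, function(d) d$bio_noise_sd + d$exp_noise_sd, 1.0)
  if (any(diff(total_noise) <= 0))
    stop("tiers must have strictly increasing total noise (bio + exp)")
  sub <- sample_subnetwork(net, n_genes, seed = derive_seed(seed, "subnet"))
  if (is.null(condition_effect))
    condition_effect <- sample_condition_effect(
      sub, seed = derive_seed(seed, "effect"))
  sim_net <- add_background_genes(sub, n_background,
                                  seed = derive_seed(seed, "background"))
  out <- lapply(names(tiers), function(nm) {
    d <- tiers[[nm]]
    d$condition_effect <- condition_effect
    simulate_expression(sim_net, d, name = nm)
  })
  names(out) <- names(tiers)
  attr(out, "subnetwork") <- sub
  out
}

#' Write / read a regulatory network edge list
#'
#' Tab-delimited columns: `regulator`, `target`, `sign`, `strength`,
#' `half_saturation`, `hill`; basal levels in `# basal gene=value`
#' header comments.
#'
#' @param net A `regulatory_network`.
#' @param path File path.
#' @return `path` (write) or a `regulatory_network` (read).
#' @export
write_network <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# basal\t%s\t%.15g", names(net$basal), net$basal), con)
  utils::write.table(net$edges, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  basal_lines <- grep("^# basal\t", lines, value = TRUE)
  parts <- strsplit(basal_lines, "\t", fixed = TRUE)
  basal <- stats::setNames(as.numeric(vapply(parts, `[[`, "", 3L)),
                           vapply(parts, `[[`, "", 2L))
  edges <- utils::read.delim(textConnection(lines[!grepl("^#", lines)]),
                             sep = "\t", stringsAsFactors = FALSE)
  structure(list(nodes = names(basal), edges = edges, basal = basal),
            class = "regulatory_network")
}
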