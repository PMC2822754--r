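#' Geometric simulated-annealing schedule
#'
#' Temperature starts at `t0`, ends at `tn`, with cooling factor
#' `c = (tn / t0)^(1 / maxfc)` so that `t0 * c^maxfc == tn`.  Defaults
#' follow the study settings: initial temperature 10, final 0.001, and
#' 1000 score-function calls for 100-gene panels (1500 once the 50
#' uninformative genes are added).
#'
#' @param t0 Initial temperature (> tn).
#' @param tn Final temperature (> 0).
#' @param maxfc Maximum number of score-function calls.
#' @return An `annealing_schedule`: list with `t0`, `tn`, `maxfc`, `c`.
#' @export
annealing_schedule <- function(t0 = 10, tn = 0.001, maxfc = 1000L) {
  if (!(tn > 0 && t0 > tn)) stop("need 0 < tn < t0")
  if (maxfc < 1L) stop("maxfc must be >= 1")
  structure(list(t0 = t0, tn = tn, maxfc = as.integer(maxfc),
                 c = (tn / t0)^(1 / maxfc)),
            class = "annealing_schedule")
}

# ---- move generation ----

# Uniformly sample one legal instantiation of `operator` on `st`,
# or return NULL (no-move).  `max_parents` caps a child's gene-parent
# count (data-identifiability guard used by the annealer).
# Candidate edges are enumerated without the acyclicity check, then
# sampled without replacement until an acyclic one is found; this is
# uniform over the legal set.
sample_move <- function(st, operator, max_parents = Inf) {
  genes <- st$genes
  n <- length(genes)
  parents <- st$parents
  npar <- vapply(parents, length, 1L)
  if (operator == "add") {
    if (st$constraint == "SNB") return(NULL)
    open_child <- if (st$constraint == "1PB") npar == 0L & max_parents >= 1
                  else npar < max_parents
    cand <- NULL
    if (any(open_child) && n >= 2L) {
      has_edge <- matrix(FALSE, n, n, dimnames = list(genes, genes))
      for (g in genes) has_edge[parents[[g]], g] <- TRUE
      ok <- !has_edge
      diag(ok) <- FALSE
      ok[, !open_child] <- FALSE
      idx <- which(ok)
      if (length(idx) > 0L)
        cand <- cbind(genes[(idx - 1L) %% n + 1L],
                      genes[(idx - 1L) %/% n + 1L])
    }
    if (st$constraint == "NPB") {
      # class -> gene links are searchable in NPB
      closed <- genes[!st$class_parent]
      if (length(closed) > 0L)
        cand <- rbind(cand, cbind(rep(st$class_node, length(closed)), closed))
    }
    while (!is.null(cand) && nrow(cand) > 0L) {
      i <- if (nrow(cand) == 1L) 1L else sample.int(nrow(cand), 1L)
      p <- unname(cand[i, 1L]); ch <- unname(cand[i, 2L])
      if (p == st$class_node) {
        st$class_parent[[ch]] <- TRUE
        return(list(operator = "add", edge = c(parent = p, child = ch),
                    structure = st, affected = ch))
      }
      if (!edge_creates_cycle(parents, p, ch)) {
        st$parents[[ch]] <- c(parents[[ch]], p)
        return(list(operator = "add", edge = c(parent = p, child = ch),
                    structure = st, affected = ch))
      }
      cand <- cand[-i, , drop = FALSE]
    }
    return(NULL)
  }
  if (operator == "remove") {
    cand <- structure_edges(st, include_class = (st$constraint == "NPB"))
    if (nrow(cand) == 0L) return(NULL)
    i <- if (nrow(cand) == 1L) 1L else sample.int(nrow(cand), 1L)
    p <- unname(cand[i, 1L]); ch <- unname(cand[i, 2L])
    if (p == st$class_node) st$class_parent[[ch]] <- FALSE
    else st$parents[[ch]] <- setdiff(st$parents[[ch]], p)
    return(list(operator = "remove", edge = c(parent = p, child = ch),
                structure = st, affected = ch))
  }
  if (operator == "swap") {
    # exchange one link for another, keeping the edge count constant.
    # Under the single-parent constraint the move re-parents a child
    # (replaces its regulator), which pure remove-then-add cannot do
    # once the temperature is low; in unrestricted search it reverses
    # an edge, the classic third operator for repairing edge
    # orientation.
    cand <- structure_edges(st, include_class = FALSE)
    while (nrow(cand) > 0L) {
      i <- if (nrow(cand) == 1L) 1L else sample.int(nrow(cand), 1L)
      p <- unname(cand[i, 1L]); ch <- unname(cand[i, 2L])
      if (st$constraint == "1PB") {
        pruned <- parents
        pruned[[ch]] <- setdiff(pruned[[ch]], p)
        new_par <- setdiff(genes, c(ch, parents[[ch]]))
        while (length(new_par) > 0L) {
          q <- if (length(new_par) == 1L) new_par else sample(new_par, 1L)
          if (!edge_creates_cycle(pruned, q, ch)) {
            st$parents <- pruned
            st$parents[[ch]] <- c(st$parents[[ch]], q)
            return(list(operator = "swap",
                        edge = c(parent = q, child = ch, replaced = p),
                        structure = st, affected = ch))
          }
          new_par <- setdiff(new_par, q)
        }
      } else if (length(parents[[p]]) < max_parents) {
        pruned <- parents
        pruned[[ch]] <- setdiff(pruned[[ch]], p)
        if (!edge_creates_cycle(pruned, ch, p)) {
          st$parents <- pruned
          st$parents[[p]] <- c(st$parents[[p]], ch)
          return(list(operator = "swap",
                      edge = c(parent = ch, child = p, replaced = p),
                      structure = st, affected = c(p, ch)))
        }
      }
      cand <- cand[-i, , drop = FALSE]
    }
    return(NULL)
  }
  stop("unknown operator: ", operator)
}

#' Propose a random structure move
#'
#' A uniformly random legal instantiation of one of the three search
#' operators: `add` inserts an absent legal edge, `remove` deletes a
#' present removable edge, `swap` exchanges a present gene-gene edge
#' for one with a different parent and the same child.
#' The resulting structure always satisfies acyclicity and the active
#' constraint class.  When the operator has no legal instantiation,
#' `NULL` (no-move) is returned.
#'
#' @param st A `network_structure`.
#' @param operator One of `"add"`, `"remove"`, `"swap"`.
#' @param max_parents Optional cap on a gene's number of gene parents.
#' @param seed Optional seed; by default the caller's RNG stream is
#'   used.
#' @return A list with `operator`, `edge` (parent, child),
#'   `structure` (the resulting `network_structure`), or `NULL`.
#' @export
propose_move <- function(st, operator = c("add", "remove", "swap"),
                         max_parents = Inf, seed = NULL) {
  operator <- match.arg(operator)
  validate_structure(st)
  mv <- if (is.null(seed)) sample_move(st, operator, max_parents)
        else local_seed(seed, sample_move(st, operator, max_parents))
  if (!is.null(mv)) validate_structure(mv$structure)
  mv
}

# Metropolis acceptance rule: improving (or equal-score) moves are
# always accepted; worsening moves with probability exp(dscore / t).
# Consumes one uniform draw only for worsening moves.
metropolis_accept <- function(dscore, t) {
  dscore > 0 || stats::runif(1L) < exp(dscore / t)
}

# ---- decomposed family scoring shared by annealer and oracle ----

# Closure computing one gene family's BIC contribution
# (log-likelihood minus per-family penalty) on a fixed dataset.
make_family_scorer <- function(ds) {
  vals <- ds$values
  labs <- ds$class_labels
  idx <- list("0" = which(labs == 0L), "1" = which(labs == 1L))
  logn <- log(length(labs))
  min_state <- min(lengths(idx))
  score1 <- function(g, pa, sub) {
    fam <- fit_lg_family(vals[g, sub], t(vals[pa, sub, drop = FALSE]))
    mu <- rep(fam$intercept, length(sub))
    if (length(pa) > 0L)
      mu <- mu + as.vector(crossprod(vals[pa, sub, drop = FALSE], fam$coef))
    sum(stats::dnorm(vals[g, sub], mu, sqrt(fam$var), log = TRUE))
  }
  list(
    family_score = function(g, pa, class_parent) {
      if (class_parent) {
        ll <- score1(g, pa, idx[["0"]]) + score1(g, pa, idx[["1"]])
        ll - 2 * (length(pa) + 2L) / 2 * logn
      } else {
        score1(g, pa, seq_along(labs)) - (length(pa) + 2L) / 2 * logn
      }
    },
    class_score = {
      p1 <- mean(labs == 1L)
      sum(log(ifelse(labs == 1L, p1, 1 - p1))) - logn / 2
    },
    max_parents_conditioned = min_state - 2L,
    max_parents_free = length(labs) - 2L
  )
}

#' Learn a network structure by simulated annealing
#'
#' Starting from the constraint-class baseline (class-to-gene skeleton
#' for SNB/1PB, empty DAG for NPB), the annealer cycles the three
#' operators (add, remove, swap) in order, scoring each proposal with
#' the decomposed BIC.  Improving moves are always accepted; worsening
#' moves are accepted with probability `exp(dscore / t)`.  The
#' temperature cools geometrically once per operator sweep, the score
#' call counter `fc` increments per proposal scored, and the run ends
#' at `fc >= maxfc`.  The best-scoring structure ever visited is
#' returned.
#'
#' @param ds An [expression_dataset()] over the panel genes
#'   (standardized).
#' @param constraint `"SNB"`, `"1PB"` or `"NPB"`.
#' @param schedule An [annealing_schedule()].
#' @param seed Integer seed driving both proposal choice and acceptance
#'   draws.
#' @param trace Record a per-proposal trace (fc, temperature, operator,
#'   accepted, score)?
#' @return A `scored_structure` for the best structure found; with
#'   `trace = TRUE` the trace data frame is attached as attribute
#'   `"trace"`.
#' @export
anneal <- function(ds, constraint = c("SNB", "1PB", "NPB"),
                   schedule = annealing_schedule(), seed = 1L,
                   trace = FALSE) {
  constraint <- match.arg(constraint)
  genes <- ds$gene_ids
  if (constraint != "SNB" && length(genes) < 2L)
    stop(constraint, " search needs at least 2 genes")
  if (constraint == "SNB")        # fixed skeleton: nothing to search
    return(bic_score(snb_structure(genes), ds))
  st <- if (constraint == "1PB") network_structure(genes, "1PB")
        else network_structure(genes, "NPB")
  scorer <- make_family_scorer(ds)
  local_seed(seed, {
    fam <- vapply(genes, function(g)
      scorer$family_score(g, st$parents[[g]], st$class_parent[[g]]), 1.0)
    oldscore <- sum(fam) + scorer$class_score
    best <- st; bestscore <- oldscore
    t <- schedule$t0
    fc <- 0L
    tr <- if (trace) vector("list", schedule$maxfc) else NULL
    repeat {
      moved_any <- FALSE
      for (op in c("add", "remove", "swap")) {
        if (fc >= schedule$maxfc) break
        # conservative cap: keeps every family identifiable even if a
        # class link is toggled on later
        mv <- sample_move(st, op,
                          max_parents = scorer$max_parents_conditioned)
        if (is.null(mv)) next
        moved_any <- TRUE
        new_fam <- fam
        for (g in mv$affected)
          new_fam[[g]] <- scorer$family_score(
            g, mv$structure$parents[[g]], mv$structure$class_parent[[g]])
        newscore <- sum(new_fam) + scorer$class_score
        fc <- fc + 1L
        dscore <- newscore - oldscore
        accept <- metropolis_accept(dscore, t)
        if (accept) {
          st <- mv$structure
          fam <- new_fam
          oldscore <- newscore
          if (newscore > bestscore) { best <- st; bestscore <- newscore }
        }
        if (trace)
          tr[[fc]] <- data.frame(fc = fc, temperature = t, operator = op,
                                 accepted = accept, score = newscore)
      }
      t <- t * schedule$c
      if (fc >= schedule$maxfc || !moved_any) break
    }
    out <- bic_score(best, ds)
    if (trace) attr(out, "trace") <- do.call(rbind, tr[!vapply(tr, is.null, TRUE)])
    out
  })
}

#' Globally BIC-optimal structure by full enumeration
#'
#' Testing oracle: enumerates node orderings and, per ordering, picks
#' each gene's best parent configuration among its predecessors using
#' the decomposed family scores.  Feasible up to 5 genes for NPB and 7
#' for 1PB.
#'
#' @param ds An [expression_dataset()].
#' @param constraint `"SNB"`, `"1PB"` or `"NPB"`.
#' @return A `scored_structure` for the global optimum.
#' @export
exhaustive_search <- function(ds, constraint = c("SNB", "1PB", "NPB")) {
  constraint <- match.arg(constraint)
  genes <- ds$gene_ids
  n <- length(genes)
  if (constraint == "SNB")
    return(bic_score(snb_structure(genes), ds))
  limit <- if (constraint == "NPB") 5L else 7L
  if (n > limit)
    stop(sprintf("%s search space too large for %d genes (~%s structures); limit %d",
                 constraint, n,
                 format(if (constraint == "NPB") 2^(n * (n - 1)) else n^n,
                        big.mark = ","), limit))
  scorer <- make_family_scorer(ds)
  cap <- if (constraint == "NPB") scorer$max_parents_free
         else scorer$max_parents_conditioned
  # precompute family scores for every (gene, parent set, class flag)
  fam_tab <- lapply(genes, function(g) {
    others <- setdiff(genes, g)
    configs <- list()
    subsets <- if (constraint == "1PB") c(list(character()), as.list(others))
               else unlist(lapply(0:length(others), function(k) {
                 if (k > cap) return(NULL)
                 if (k == 0L) list(character())
                 else utils::combn(others, k, simplify = FALSE)
               }), recursive = FALSE)
    for (pa in subsets) {
      key <- paste(sort(pa), collapse = "|")
      flags <- if (constraint == "1PB") TRUE else c(TRUE, FALSE)
      for (fl in flags) {
        fl_cap <- if (fl) scorer$max_parents_conditioned
                  else scorer$max_parents_free
        if (length(pa) > fl_cap) next
        configs[[paste0(key, if (fl) "+C" else "")]] <-
          list(parents = pa, class_parent = fl,
               score = scorer$family_score(g, pa, fl))
      }
    }
    configs
  })
  names(fam_tab) <- genes
  perms <- permutations_of(seq_len(n))
  best_total <- -Inf; best_choice <- NULL
  for (perm in perms) {
    total <- 0
    choice <- vector("list", n)
    ok <- TRUE
    for (pos in seq_len(n)) {
      g <- genes[perm[pos]]
      preds <- genes[perm[seq_len(pos - 1L)]]
      cfgs <- Filter(function(cf) all(cf$parents %in% preds), fam_tab[[g]])
      if (length(cfgs) == 0L) { ok <- FALSE; break }
      scores <- vapply(cfgs, `[[`, 1.0, "score")
      bi <- which.max(scores)
      total <- total + scores[[bi]]
      choice[[perm[pos]]] <- cfgs[[bi]]
    }
    if (ok && total > best_total) { best_total <- total; best_choice <- choice }
  }
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    pa <- best_choice[[i]]$parents
    if (length(pa) == 0L) NULL else cbind(pa, genes[i])
  }))
  st <- network_structure(
    genes, constraint, gene_edges = edges,
    class_children = genes[vapply(best_choice, `[[`, TRUE, "class_parent")])
  bic_score(st, ds)
}

# All permutations of an integer vector (small n only).
permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(permutations_of(v[-i]), function(p) c(v[i], p)))
  out
}
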