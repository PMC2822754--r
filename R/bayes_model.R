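#' Bayesian network classifier structure
#'
#' A DAG over continuous gene nodes plus one distinguished discrete
#' class node (the differentiation status), tagged with its structural
#' constraint class:
#' \describe{
#'   \item{SNB}{selective naive Bayes: the only edges run from the class
#'     node to genes; every gene has exactly the class as parent.}
#'   \item{1PB}{each gene has the class as parent plus at most one gene
#'     parent.}
#'   \item{NPB}{unrestricted: any acyclic structure; class-to-gene links
#'     are searchable, not forced.}
#' }
#'
#' @param genes Character vector of gene node identifiers.
#' @param constraint One of `"SNB"`, `"1PB"`, `"NPB"`.
#' @param gene_edges Two-column character matrix (or data frame) of
#'   directed gene-gene edges `(parent, child)`; NULL for none.
#' @param class_children For NPB, the genes with a class-to-gene link;
#'   ignored (forced to all genes) for SNB/1PB.  Default: all genes for
#'   SNB/1PB, none for NPB.
#' @return A `network_structure` object.
#' @export
network_structure <- function(genes, constraint = c("SNB", "1PB", "NPB"),
                              gene_edges = NULL, class_children = NULL) {
  constraint <- match.arg(constraint)
  if (anyDuplicated(genes)) stop("duplicate gene node identifiers")
  parents <- stats::setNames(rep(list(character()), length(genes)), genes)
  if (!is.null(gene_edges) && NROW(gene_edges) > 0L) {
    gene_edges <- as.matrix(gene_edges)
    for (i in seq_len(nrow(gene_edges))) {
      p <- unname(gene_edges[i, 1L]); ch <- unname(gene_edges[i, 2L])
      if (!(p %in% genes) || !(ch %in% genes))
        stop("edge endpoint not a gene node: ", p, " -> ", ch)
      if (p == ch) stop("self-loop: ", p)
      if (p %in% parents[[ch]]) stop("duplicate edge: ", p, " -> ", ch)
      parents[[ch]] <- c(parents[[ch]], p)
    }
  }
  class_parent <- if (constraint %in% c("SNB", "1PB"))
    stats::setNames(rep(TRUE, length(genes)), genes)
  else
    stats::setNames(genes %in% (class_children %||% character()), genes)
  st <- structure(list(genes = genes,
                       class_node = "__class__",
                       parents = parents,
                       class_parent = class_parent,
                       constraint = constraint),
                  class = "network_structure")
  validate_structure(st)
  st
}

#' The fixed selective-naive-Bayes skeleton over a gene set
#'
#' @param genes Character vector of gene identifiers.
#' @return A `network_structure` with constraint `"SNB"`.
#' @export
snb_structure <- function(genes) network_structure(genes, "SNB")

#' Validate a network structure against its constraint class
#'
#' Checks acyclicity (via topological sort) and the SNB/1PB/NPB rules.
#' Called by every constructor and on deserialization.
#'
#' @param st A `network_structure`.
#' @return `st`, invisibly; stops on violation.
#' @export
validate_structure <- function(st) {
  if (is.null(topological_order(st$parents)))
    stop("structure contains a directed cycle")
  np <- vapply(st$parents, length, 1L)
  if (st$constraint == "SNB" && any(np > 0L))
    stop("SNB admits no gene-gene edges")
  if (st$constraint == "1PB" && any(np > 1L))
    stop("1PB allows at most one gene parent per gene; violated by: ",
         paste(st$genes[np > 1L], collapse = ", "))
  if (st$constraint %in% c("SNB", "1PB") && !all(st$class_parent))
    stop(st$constraint, " requires the class node as parent of every gene")
  invisible(st)
}

#' @export
print.network_structure <- function(x, ...) {
  cat(sprintf("network_structure [%s]: %d genes, %d gene-gene edges, %d class links\n",
              x$constraint, length(x$genes),
              sum(vapply(x$parents, length, 1L)), sum(x$class_parent)))
  invisible(x)
}

#' Edge list of a structure
#'
#' @param st A `network_structure`.
#' @param include_class Include class-to-gene links (parent
#'   `"__class__"`).
#' @return Two-column character matrix `(parent, child)`.
#' @export
structure_edges <- function(st, include_class = TRUE) {
  gp <- do.call(rbind, lapply(st$genes, function(g) {
    if (length(st$parents[[g]]) == 0L) NULL
    else cbind(parent = st$parents[[g]], child = g)
  }))
  cl <- if (include_class && any(st$class_parent))
    cbind(parent = st$class_node, child = st$genes[st$class_parent])
  else NULL
  out <- rbind(gp, cl)
  if (is.null(out)) out <- matrix(character(), 0L, 2L,
                                  dimnames = list(NULL, c("parent", "child")))
  out
}

#' Serialize / deserialize a structure as a tab-delimited edge list
#'
#' Format: one `parent<TAB>child` line per edge; the class node is named
#' `__class__`.  A header comment records gene set and constraint so the
#' structure round-trips exactly (including isolated genes).
#'
#' @param st A `network_structure`.
#' @param path File path.
#' @return `path` (write) or a validated `network_structure` (read).
#' @export
write_structure <- function(st, path) {
  edges <- structure_edges(st)
  writeLines(c(paste0("# constraint=", st$constraint),
               paste0("# genes=", paste(st$genes, collapse = ",")),
               paste(edges[, 1L], edges[, 2L], sep = "\t")), path)
  invisible(path)
}

#' @rdname write_structure
#' @export
read_structure <- function(path) {
  lines <- readLines(path)
  constraint <- sub("^# constraint=", "",
                    grep("^# constraint=", lines, value = TRUE)[1L])
  genes <- strsplit(sub("^# genes=", "",
                        grep("^# genes=", lines, value = TRUE)[1L]), ",")[[1L]]
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  edges <- if (length(body) > 0L)
    do.call(rbind, strsplit(body, "\t", fixed = TRUE)) else NULL
  is_class <- !is.null(edges) & (if (is.null(edges)) logical() else
    edges[, 1L] == "__class__")
  network_structure(genes, constraint,
                    gene_edges = if (!is.null(edges)) edges[!is_class, ,
                                                            drop = FALSE],
                    class_children = if (!is.null(edges)) edges[is_class, 2L])
}

# ---- internal DAG helpers over the parent-list representation ----

# Kahn topological sort; NULL when the gene-gene graph is cyclic.
topological_order <- function(parents) {
  genes <- names(parents)
  indeg <- vapply(parents, length, 1L)
  children <- stats::setNames(rep(list(character()), length(genes)), genes)
  for (g in genes) for (p in parents[[g]])
    children[[p]] <- c(children[[p]], g)
  queue <- genes[indeg == 0L]
  out <- character(0)
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < length(genes)) NULL else out
}

# All ancestors of `g` in the gene-gene graph (excluding g).
gene_ancestors <- function(parents, g) {
  seen <- character(0)
  frontier <- parents[[g]]
  while (length(frontier) > 0L) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier])), seen)
  }
  seen
}

# Would adding edge p -> ch create a cycle?  Yes iff p is reachable
# from ch, i.e. ch is an ancestor of p (or p == ch).
edge_creates_cycle <- function(parents, p, ch) {
  p == ch || ch %in% gene_ancestors(parents, p)
}

# ---- conditional linear-Gaussian fitting ----

# OLS of y on columns of X (may have 0 columns) with intercept and
# ML (1/n) residual variance; near-singular designs fall back to a
# lambda = 1e-8 ridge with a warning.
fit_lg_family <- function(y, X) {
  D <- cbind(`(Intercept)` = 1, X)
  XtX <- crossprod(D)
  Xty <- crossprod(D, y)
  coefs <- if (ncol(D) == 1L) {
    Xty / XtX[1L, 1L]
  } else if (rcond(XtX) < 1e-10) {
    warning("singular design; ridge fallback (lambda = 1e-8)", call. = FALSE)
    solve(XtX + diag(1e-8, ncol(D)), Xty)
  } else {
    solve(XtX, Xty)
  }
  resid <- y - D %*% coefs
  v <- max(sum(resid^2) / length(y), 1e-12)
  list(intercept = coefs[1L],
       coef = stats::setNames(coefs[-1L], colnames(X)),
       var = v)
}

#' Fit conditional-Gaussian parameters of a structure on a dataset
#'
#' Each gene's family is a linear-Gaussian regression on its continuous
#' (gene) parents, with separate parameters per class state when the
#' class node is a parent of the gene, fitted by maximum likelihood
#' (OLS coefficients, 1/n residual variance).  The class prior is the
#' empirical state frequency.
#'
#' @param st A `network_structure`.
#' @param ds An [expression_dataset()] containing every gene of `st`.
#' @return A `fitted_model`: list with `structure`, `class_prior`
#'   (probability of state 1), `params` (per gene), `n_train`.
#' @export
fit_parameters <- function(st, ds) {
  missing <- setdiff(st$genes, ds$gene_ids)
  if (length(missing) > 0L)
    stop("genes absent from dataset: ", paste(missing, collapse = ", "))
  vals <- ds$values
  labs <- ds$class_labels
  idx_state <- list("0" = which(labs == 0L), "1" = which(labs == 1L))
  params <- lapply(st$genes, function(g) {
    pa <- st$parents[[g]]
    if (st$class_parent[[g]]) {
      fams <- lapply(names(idx_state), function(s) {
        idx <- idx_state[[s]]
        if (length(idx) <= length(pa) + 1L)
          stop(sprintf("gene '%s', state %s: %d samples cannot identify %d parameters",
                       g, s, length(idx), length(pa) + 2L))
        fit_lg_family(vals[g, idx],
                      t(vals[pa, idx, drop = FALSE]))
      })
      names(fams) <- names(idx_state)
      list(parents = pa, by_class = TRUE, families = fams)
    } else {
      if (ncol(vals) <= length(pa) + 1L)
        stop(sprintf("gene '%s': %d samples cannot identify %d parameters",
                     g, ncol(vals), length(pa) + 2L))
      list(parents = pa, by_class = FALSE,
           families = list(all = fit_lg_family(vals[g, ],
                                               t(vals[pa, , drop = FALSE]))))
    }
  })
  names(params) <- st$genes
  structure(list(structure = st,
                 class_prior = mean(labs == 1L),
                 params = params,
                 n_train = length(labs)),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("fitted_model [%s]: %d genes, n_train = %d, P(state 1) = %.3f\n",
              x$structure$constraint, length(x$structure$genes),
              x$n_train, x$class_prior))
  invisible(x)
}

# Family of `gene` for class state s ("0"/"1"); unconditioned genes
# return their single family.
family_for <- function(model, gene, state) {
  pg <- model$params[[gene]]
  if (pg$by_class) pg$families[[as.character(state)]] else pg$families$all
}

# Conditional mean of `gene` for a genes x samples value matrix and a
# per-sample class vector (vectorised over samples).
family_mean <- function(model, gene, values, states) {
  pg <- model$params[[gene]]
  pa <- pg$parents
  contrib <- function(fam, idx) {
    mu <- rep(fam$intercept, length(idx))
    if (length(pa) > 0L)
      mu <- mu + as.vector(crossprod(values[pa, idx, drop = FALSE], fam$coef))
    mu
  }
  mu <- numeric(ncol(values))
  if (pg$by_class) {
    for (s in c(0L, 1L)) {
      idx <- which(states == s)
      if (length(idx) > 0L)
        mu[idx] <- contrib(pg$families[[as.character(s)]], idx)
    }
  } else {
    mu <- contrib(pg$families$all, seq_len(ncol(values)))
  }
  mu
}

# Per-sample log-density contribution of one gene family.
family_logdens <- function(model, gene, values, states) {
  pg <- model$params[[gene]]
  mu <- family_mean(model, gene, values, states)
  ld <- numeric(ncol(values))
  if (pg$by_class) {
    for (s in c(0L, 1L)) {
      idx <- which(states == s)
      if (length(idx) > 0L) {
        fam <- pg$families[[as.character(s)]]
        ld[idx] <- stats::dnorm(values[gene, idx], mu[idx],
                                sqrt(fam$var), log = TRUE)
      }
    }
  } else {
    ld <- stats::dnorm(values[gene, ], mu, sqrt(pg$families$all$var),
                       log = TRUE)
  }
  ld
}

#' Log-likelihood of a dataset under a fitted model
#'
#' Sum over samples of the class-node log-probability plus every gene
#' family's Gaussian log-density given its parents and the observed
#' class state.
#'
#' @param model A `fitted_model`.
#' @param ds An [expression_dataset()] containing all model genes.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(model, ds) {
  st <- model$structure
  missing <- setdiff(st$genes, ds$gene_ids)
  if (length(missing) > 0L)
    stop("genes absent from dataset: ", paste(missing, collapse = ", "))
  prior <- ifelse(ds$class_labels == 1L, model$class_prior,
                  1 - model$class_prior)
  ll <- sum(log(prior))
  for (g in st$genes)
    ll <- ll + sum(family_logdens(model, g, ds$values, ds$class_labels))
  ll
}

#' Number of free parameters of a structure
#'
#' Each gene family conditioned on the class contributes
#' `n_class_states * (n_gene_parents + 2)` parameters (intercept,
#' one coefficient per continuous parent, and a variance, per state);
#' an unconditioned family contributes `n_gene_parents + 2`; the class
#' prior contributes `n_class_states - 1`.
#'
#' @param st A `network_structure`.
#' @param n_class_states Number of class states (default 2).
#' @return Integer parameter count.
#' @export
count_parameters <- function(st, n_class_states = 2L) {
  per_gene <- vapply(st$genes, function(g) {
    fam <- length(st$parents[[g]]) + 2L
    if (st$class_parent[[g]]) n_class_states * fam else fam
  }, 1L)
  sum(per_gene) + (n_class_states - 1L)
}

#' BIC score of a structure on a dataset
#'
#' Fits maximum-likelihood parameters, computes the training
#' log-likelihood, and applies the penalty
#' `bic = log_likelihood - (n_params / 2) * log(n)`.  The score
#' decomposes as a sum of per-family contributions (exposed in
#' `family_scores`), which the annealer exploits for caching.
#'
#' @param st A `network_structure`.
#' @param ds An [expression_dataset()].
#' @return A `scored_structure`: list with `structure`, `model`,
#'   `log_likelihood`, `n_params`, `bic`, `family_scores` (named by gene
#'   plus `"__class__"`).
#' @export
bic_score <- function(st, ds) {
  model <- fit_parameters(st, ds)
  n <- model$n_train
  logn <- log(n)
  fam_scores <- vapply(st$genes, function(g) {
    np <- (length(st$parents[[g]]) + 2L) *
      (if (st$class_parent[[g]]) 2L else 1L)
    sum(family_logdens(model, g, ds$values, ds$class_labels)) -
      np / 2 * logn
  }, 1.0)
  prior <- ifelse(ds$class_labels == 1L, model$class_prior,
                  1 - model$class_prior)
  class_score <- sum(log(prior)) - 1 / 2 * logn
  fam_scores <- c(fam_scores, "__class__" = class_score)
  ll <- log_likelihood(model, ds)
  np_total <- count_parameters(st)
  structure(list(structure = st,
                 model = model,
                 log_likelihood = ll,
                 n_params = np_total,
                 bic = ll - np_total / 2 * logn,
                 family_scores = fam_scores),
            class = "scored_structure")
}

#' @export
print.scored_structure <- function(x, ...) {
  cat(sprintf("scored_structure [%s]: logL = %.3f, %d params, BIC = %.3f\n",
              x$structure$constraint, x$log_likelihood, x$n_params, x$bic))
  invisible(x)
}

#' Predict a gene's expression in one sample
#'
#' Conditional mean of the gene's linear-Gaussian family given its
#' parents' observed values and the observed class state.
#'
#' @param model A `fitted_model`.
#' @param values Named numeric vector of observed gene expression values
#'   (must cover the gene's parents).
#' @param class_state Observed class state (0 or 1).
#' @param gene Gene identifier to predict.
#' @return Predicted expression (scalar).
#' @export
predict_gene <- function(model, values, class_state, gene) {
  if (!(gene %in% model$structure$genes)) stop("unknown gene: ", gene)
  pa <- model$params[[gene]]$parents
  missing <- setdiff(pa, names(values))
  if (length(missing) > 0L)
    stop("unobserved parent(s) of '", gene, "': ",
         paste(missing, collapse = ", "))
  fam <- family_for(model, gene, class_state)
  mu <- fam$intercept
  if (length(pa) > 0L) mu <- mu + sum(fam$coef * values[pa])
  unname(mu)
}

#' Posterior probability of class state 1 given all gene values
#'
#' Bayes posterior proportional to the class prior times the product of
#' every gene family's density at the observed values.
#'
#' @param model A `fitted_model`.
#' @param values Named numeric vector of observed expression values for
#'   every model gene.
#' @return Posterior probability of state 1, in \[0, 1\].
#' @export
predict_class <- function(model, values) {
  genes <- model$structure$genes
  missing <- setdiff(genes, names(values))
  if (length(missing) > 0L)
    stop("unobserved gene(s): ", paste(missing, collapse = ", "))
  vmat <- matrix(values[genes], ncol = 1L, dimnames = list(genes, "s"))
  logpost <- vapply(c(0L, 1L), function(s) {
    prior <- if (s == 1L) model$class_prior else 1 - model$class_prior
    if (prior == 0) return(-Inf)
    lp <- log(prior)
    for (g in genes)
      lp <- lp + family_logdens(model, g, vmat, s)
    lp
  }, 1.0)
  if (all(is.infinite(logpost))) stop("degenerate prior: both states impossible")
  m <- max(logpost)
  w <- exp(logpost - m)
  unname(w[2L] / sum(w))
}

#' Serialize / deserialize a fitted model as JSON
#'
#' Dumps the structure (edges, constraint), the conditional-Gaussian
#' parameters, the class prior and the training sample count, so a
#' model fitted on one dataset can be reloaded and evaluated on
#' another.
#'
#' @param model A `fitted_model`.
#' @param path File path (`.json`).
#' @return `path` (write) or a `fitted_model` (read).
#' @export
write_model <- function(model, path) {
  st <- model$structure
  payload <- list(
    constraint = st$constraint,
    genes = st$genes,
    parents = st$parents,
    class_parent = as.list(st$class_parent),
    class_prior = model$class_prior,
    n_train = model$n_train,
    params = lapply(model$params, function(pg)
      list(parents = pg$parents, by_class = pg$by_class,
           families = lapply(pg$families, function(f)
             list(intercept = f$intercept,
                  coef = as.list(f$coef),
                  var = f$var)))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  genes <- unlist(p$genes)
  edges <- do.call(rbind, unlist(lapply(genes, function(g) {
    pa <- unlist(p$parents[[g]])
    if (length(pa) == 0L) NULL else list(cbind(pa, g))
  }), recursive = FALSE))
  st <- network_structure(genes, p$constraint, gene_edges = edges,
                          class_children = genes[unlist(p$class_parent[genes])])
  params <- lapply(genes, function(g) {
    pg <- p$params[[g]]
    list(parents = unlist(pg$parents) %||% character(),
         by_class = pg$by_class,
         families = lapply(pg$families, function(f)
           list(intercept = f$intercept,
                coef = unlist(f$coef) %||%
                  stats::setNames(numeric(), character()),
                var = f$var)))
  })
  names(params) <- genes
  structure(list(structure = st, class_prior = p$class_prior,
                 params = params, n_train = p$n_train),
            class = "fitted_model")
}
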