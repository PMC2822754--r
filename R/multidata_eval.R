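#' Per-gene prediction error of a fitted model on a dataset
#'
#' For each requested gene, the sum over samples of the squared
#' difference between the model's conditional-mean prediction (given
#' the gene's parents and the observed class state) and the observed
#' value.  The normalized form divides by the sample count (mean
#' squared error per sample) so that datasets of different size are
#' comparable; the raw sum is also returned.
#'
#' @param model A `fitted_model`.
#' @param ds An [expression_dataset()] containing all model genes.
#' @param genes Genes to score (default: all model genes).
#' @return A data frame with columns `gene_id`, `sse` (normalized,
#'   per-sample) and `sse_raw`.
#' @export
per_gene_sse <- function(model, ds, genes = model$structure$genes) {
  missing <- setdiff(genes, ds$gene_ids)
  if (length(missing) > 0L)
    stop("genes absent from dataset '", ds$name, "': ",
         paste(missing, collapse = ", "))
  n <- length(ds$sample_ids)
  raw <- vapply(genes, function(g) {
    mu <- family_mean(model, g, ds$values, ds$class_labels)
    sum((ds$values[g, ] - mu)^2)
  }, 1.0)
  data.frame(gene_id = genes, sse = raw / n, sse_raw = raw,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank genes by a score (ascending; rank 1 = most informative)
#'
#' Stable sort: ties keep the input gene order, which is itself pinned
#' by the panel, so rankings are deterministic.
#'
#' @param scores Named numeric vector (gene id -> score); lower is
#'   better (SSE or variance).
#' @param source Label recording which score family produced the
#'   ranking (e.g. `"trainR_SSE"`).
#' @return A `gene_ranking`: data frame with columns `gene_id`, `rank`,
#'   `score`, and attribute `source`.
#' @export
rank_genes <- function(scores, source = "scores") {
  if (anyNA(scores) || any(!is.finite(scores)))
    stop("scores contain NA/NaN/Inf")
  ord <- order(scores)   # stable
  out <- data.frame(gene_id = names(scores)[ord],
                    rank = seq_along(scores),
                    score = unname(scores[ord]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "source") <- source
  class(out) <- c("gene_ranking", "data.frame")
  out
}

#' Rank position of each gene in a ranking
#'
#' @param ranking A `gene_ranking`.
#' @return Named integer vector gene id -> rank.
#' @export
ranking_positions <- function(ranking) {
  stats::setNames(ranking$rank, ranking$gene_id)
}

#' Cross-validated multi-dataset gene scoring
#'
#' The core training/testing regime: k-fold cross-validation on the
#' single simple dataset (`train`), with each fold's model also
#' evaluated on every independent, more complex dataset in full.  For
#' each fold, a structure is learned by simulated annealing on the
#' k - 1 training folds, maximum-likelihood parameters are fitted, and
#' per-gene prediction error is scored on the held-out fold and on each
#' independent dataset.  Mean and across-fold variance of these scores
#' are aggregated per gene and turned into the four ranking families:
#' `trainR_SSE`, `train_var`, `testR_SSE_<m>`, `testR_var_<m>`.
#'
#' @param train The cross-validation [expression_dataset()] (panel
#'   genes, standardized).
#' @param tests List of independent test [expression_dataset()]s
#'   sharing the training gene identifiers (may be empty).
#' @param folds A `fold_assignment` from [make_folds()]; reused across
#'   constraint classes.
#' @param constraint `"SNB"`, `"1PB"` or `"NPB"`.
#' @param schedule An [annealing_schedule()].
#' @param seed Integer master seed; per-fold annealing seeds are
#'   derived deterministically.
#' @param trace Passed through to [anneal()].
#' @return A `multidata_scores` object: list with
#'   \describe{
#'     \item{score_table}{data frame: `gene_id`, `train_sse`,
#'       `train_var`, `train_sse_raw`, and `test_sse_<name>`,
#'       `test_var_<name>` per independent dataset.}
#'     \item{rankings}{named list of `gene_ranking`s.}
#'     \item{fold_models}{the k `fitted_model`s.}
#'     \item{fold_structures}{the k `scored_structure`s.}
#'     \item{k, constraint}{bookkeeping.}
#'   }
#' @export
multidata_eval <- function(train, tests = list(), folds, constraint = "1PB",
                           schedule = annealing_schedule(), seed = 1L,
                           trace = FALSE) {
  genes <- train$gene_ids
  for (ts in tests) {
    missing <- setdiff(genes, ts$gene_ids)
    if (length(missing) > 0L)
      stop("test dataset '", ts$name, "' is missing genes: ",
           paste(missing, collapse = ", "))
  }
  if (!identical(names(folds$assignment), train$sample_ids))
    stop("fold assignment does not match the training dataset samples")
  k <- folds$k
  test_names <- vapply(tests, `[[`, "", "name")
  if (anyDuplicated(test_names)) stop("independent datasets must have unique names")

  train_sse <- matrix(NA_real_, length(genes), k, dimnames = list(genes, NULL))
  train_sse_raw <- train_sse
  test_sse <- lapply(tests, function(ts)
    matrix(NA_real_, length(genes), k, dimnames = list(genes, NULL)))
  fold_models <- vector("list", k)
  fold_structures <- vector("list", k)

  for (j in seq_len(k)) {
    in_fold <- folds$assignment == j
    tr_ds <- subset_samples(train, !in_fold)
    ho_ds <- subset_samples(train, in_fold)
    scored <- anneal(tr_ds, constraint, schedule,
                     seed = derive_seed(seed, "anneal", j), trace = trace)
    model <- scored$model
    fold_structures[[j]] <- scored
    fold_models[[j]] <- model
    ho <- per_gene_sse(model, ho_ds, genes)
    train_sse[, j] <- ho$sse
    train_sse_raw[, j] <- ho$sse_raw
    for (m in seq_along(tests))
      test_sse[[m]][, j] <- per_gene_sse(model, tests[[m]], genes)$sse
  }

  pop_var <- function(mat) rowMeans((mat - rowMeans(mat))^2)  # k denominator
  tab <- data.frame(gene_id = genes,
                    train_sse = rowMeans(train_sse),
                    train_var = pop_var(train_sse),
                    train_sse_raw = rowMeans(train_sse_raw),
                    row.names = NULL, stringsAsFactors = FALSE)
  rankings <- list(
    trainR_SSE = rank_genes(stats::setNames(tab$train_sse, genes), "trainR_SSE"),
    train_var = rank_genes(stats::setNames(tab$train_var, genes), "train_var"))
  for (m in seq_along(tests)) {
    nm <- test_names[[m]]
    msse <- rowMeans(test_sse[[m]])
    mvar <- pop_var(test_sse[[m]])
    tab[[paste0("test_sse_", nm)]] <- msse
    tab[[paste0("test_var_", nm)]] <- mvar
    rankings[[paste0("testR_SSE_", nm)]] <-
      rank_genes(stats::setNames(msse, genes), paste0("testR_SSE_", nm))
    rankings[[paste0("testR_var_", nm)]] <-
      rank_genes(stats::setNames(mvar, genes), paste0("testR_var_", nm))
  }
  structure(list(score_table = tab,
                 rankings = rankings,
                 fold_models = fold_models,
                 fold_structures = fold_structures,
                 k = k, constraint = constraint,
                 train_name = train$name, test_names = test_names),
            class = "multidata_scores")
}

#' @export
print.multidata_scores <- function(x, ...) {
  cat(sprintf("multidata_scores [%s]: trained on '%s' (k = %d), %d genes, %d independent dataset(s)\n",
              x$constraint, x$train_name, x$k, nrow(x$score_table),
              length(x$test_names)))
  invisible(x)
}

#' Restrict a dataset to a subset of samples
#'
#' @param ds An [expression_dataset()].
#' @param which Logical or integer index over samples.
#' @return The restricted [expression_dataset()].
#' @export
subset_samples <- function(ds, which) {
  ds$values <- ds$values[, which, drop = FALSE]
  ds$sample_ids <- colnames(ds$values)
  ds$class_labels <- ds$class_labels[which]
  if (!is.null(ds$replicate_groups))
    ds$replicate_groups <- ds$replicate_groups[which]
  if (!is.null(ds$time_points))
    ds$time_points <- ds$time_points[which]
  ds
}

#' Write a multidata score table / rankings to tab-delimited files
#'
#' @param scores A `multidata_scores`.
#' @param path Output path for the score table.
#' @param header_comment Optional comment lines.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(scores$score_table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @param rankings Named list of `gene_ranking`s.
#' @export
write_rankings <- function(rankings, path, header_comment = NULL) {
  all <- do.call(rbind, lapply(rankings, function(r) {
    r$source <- attr(r, "source")
    as.data.frame(r)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(all, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Deterministically derive a stage seed from a master seed
#'
#' Polynomial rolling hash of the master seed and stage labels, folded
#' into a positive 31-bit integer, so that every pipeline stage
#' (selection, folds, per-fold annealing, simulation tiers) is
#' independently reproducible from one master seed.
#'
#' @param master Integer master seed.
#' @param ... Stage labels (characters/integers) identifying the stage.
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "/")
  h <- 17
  for (b in utf8ToInt(key))
    h <- (h * 31 + b) %% 2147483647   # stays exact in double precision
  as.integer(h) + 1L
}
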