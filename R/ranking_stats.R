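#' Position p-values against a spiked-in uninformative null
#'
#' Converts a gene ranking into per-gene position p-values by comparing
#' each gene's rank against the empirical null formed by the spiked-in
#' uninformative genes: for a gene at rank r,
#' `p = (1 + #\{null genes at rank <= r\}) / (n_null + 1)`.
#' The add-one form is exact under the empirical null and never
#' returns 0.  P-values depend only on rank positions, so they are
#' invariant to monotone transforms of the underlying scores.
#'
#' @param ranking A `gene_ranking` from [rank_genes()].
#' @param null_ids Identifiers of the uninformative (null) genes; all
#'   must be present in the ranking and at least 10 are required.
#' @return A data frame `gene_id`, `rank`, `position_pvalue`, in rank
#'   order, with attribute `source` copied from the ranking.
#' @export
position_p_values <- function(ranking, null_ids) {
  pos <- ranking_positions(ranking)
  missing <- setdiff(null_ids, names(pos))
  if (length(missing) > 0L)
    stop("null genes absent from ranking: ", paste(missing, collapse = ", "))
  if (length(null_ids) < 10L)
    stop("need at least 10 null genes to calibrate position p-values")
  null_ranks <- sort(pos[null_ids])
  n_null <- length(null_ids)
  p <- (1 + findInterval(ranking$rank, null_ranks)) / (n_null + 1)
  out <- data.frame(gene_id = ranking$gene_id, rank = ranking$rank,
                    position_pvalue = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "source") <- attr(ranking, "source")
  out
}

#' Kolmogorov-Smirnov separation of informative vs uninformative genes
#'
#' Two-sample KS test on the rank positions of the two gene groups
#' within one ranking; measures how well a model separates informative
#' genes (expected near the top) from spiked-in uninformative ones.
#' The exact null distribution is used when both groups have at most 25
#' members, the asymptotic one otherwise.
#'
#' @param ranking A `gene_ranking`.
#' @param informative_ids,uninformative_ids Disjoint gene-id groups,
#'   both present in the ranking.
#' @return List with `D` (KS statistic), `p_value`, and `direction`
#'   (`"informative-better"` when informative ranks are stochastically
#'   smaller, else `"uninformative-better"`).
#' @export
ks_separation <- function(ranking, informative_ids, uninformative_ids) {
  if (length(intersect(informative_ids, uninformative_ids)) > 0L)
    stop("informative and uninformative groups overlap")
  if (length(informative_ids) == 0L || length(uninformative_ids) == 0L)
    stop("both groups must be non-empty")
  pos <- ranking_positions(ranking)
  missing <- setdiff(c(informative_ids, uninformative_ids), names(pos))
  if (length(missing) > 0L)
    stop("genes absent from ranking: ", paste(missing, collapse = ", "))
  a <- pos[informative_ids]
  b <- pos[uninformative_ids]
  exact <- length(a) <= 25L && length(b) <= 25L
  kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(D = unname(kt$statistic),
       p_value = kt$p.value,
       direction = if (mean(a) <= mean(b)) "informative-better"
                   else "uninformative-better")
}

#' Rank improvement / deterioration between two rankings
#'
#' Compares each gene's original rank (e.g. its t-test position in the
#' complex dataset) with its rank under a model-based score (e.g. the
#' prediction error of a model trained on the simpler dataset).  The
#' per-gene shift is `original_rank - model_rank`, so positive values
#' mean improvement (the gene moved up).  Per named group, the mean
#' shift is reported together with a two-sample KS test of the group's
#' shifts against all other genes' shifts.
#'
#' @param original A `gene_ranking` (the reference ranking).
#' @param model_based A `gene_ranking` over the same gene set.
#' @param groups Named list of gene-id vectors (e.g. pathway-related,
#'   top-informative, uninformative).
#' @return A `rank_shift_report`: list with `shifts` (named per-gene
#'   vector) and `groups`, a data frame `group`, `n`, `mean_shift`,
#'   `ks_p`.
#' @export
rank_shift <- function(original, model_based, groups = list()) {
  po <- ranking_positions(original)
  pm <- ranking_positions(model_based)
  if (!setequal(names(po), names(pm)))
    stop("rankings cover different gene sets")
  shifts <- po[names(po)] - pm[names(po)]
  for (nm in names(groups)) {
    missing <- setdiff(groups[[nm]], names(shifts))
    if (length(missing) > 0L)
      stop("group '", nm, "' genes absent from rankings: ",
           paste(missing, collapse = ", "))
  }
  gtab <- do.call(rbind, lapply(names(groups), function(nm) {
    ids <- groups[[nm]]
    inside <- shifts[ids]
    outside <- shifts[setdiff(names(shifts), ids)]
    ks_p <- if (length(outside) > 0L)
      suppressWarnings(stats::ks.test(inside, outside, exact = FALSE))$p.value
    else NA_real_
    data.frame(group = nm, n = length(ids), mean_shift = mean(inside),
               ks_p = ks_p, row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(shifts = shifts, groups = gtab, group_ids = groups,
                 sign_convention = "positive = improvement (rank number decreased)"),
            class = "rank_shift_report")
}

#' @export
print.rank_shift_report <- function(x, ...) {
  cat("rank_shift_report (", x$sign_convention, ")\n", sep = "")
  if (!is.null(x$groups)) print(x$groups)
  invisible(x)
}

#' Write per-gene position p-values or shifts to a tab-delimited file
#'
#' @param report A data frame (position p-values) or
#'   `rank_shift_report`.
#' @param path Output path.
#' @param header_comment Optional comment lines.
#' @return `path`, invisibly.
#' @export
write_ranking_report <- function(report, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  if (inherits(report, "rank_shift_report")) {
    writeLines(paste0("# ", report$sign_convention), con)
    utils::write.table(
      data.frame(gene_id = names(report$shifts), shift = report$shifts,
                 row.names = NULL),
      con, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines("", con)
    utils::write.table(report$groups, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    utils::write.table(report, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
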