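#' Construct an expression dataset
#'
#' The universal container of the pipeline: a genes x samples matrix of
#' continuous (log-scale) expression values together with a binary
#' per-sample class label encoding the differentiation status
#' (0 = undifferentiated, 1 = differentiated).
#'
#' @param values Numeric matrix, genes in rows and samples in columns.
#'   Row names are gene identifiers, column names sample identifiers.
#' @param class_labels Integer vector of 0/1 labels, one per sample
#'   (recycled names are matched against `colnames(values)` when named).
#' @param name Character label for the dataset.
#' @param replicate_groups Optional factor/character vector, one entry per
#'   sample, grouping replicate samples (used by [replicate_correlation()]).
#' @param time_points Optional per-sample time annotation.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `name`, `gene_ids`, `sample_ids`, `values`, `class_labels`,
#'   `replicate_groups`, `time_points`.
#' @export
expression_dataset <- function(values, class_labels, name = "dataset",
                               replicate_groups = NULL, time_points = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene row names and sample column names")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression matrix contains missing or non-finite values")
  if (!is.null(names(class_labels)))
    class_labels <- class_labels[sample_ids]
  class_labels <- as.integer(class_labels)
  if (length(class_labels) != length(sample_ids) || anyNA(class_labels))
    stop("'class_labels' must supply one 0/1 label for every sample")
  if (!all(class_labels %in% c(0L, 1L)))
    stop("'class_labels' must be 0 (undifferentiated) or 1 (differentiated)")
  if (sum(class_labels == 0L) < 2L || sum(class_labels == 1L) < 2L)
    stop("each class state needs at least 2 samples ",
         "(within-class variance is required downstream)")
  if (!is.null(replicate_groups)) {
    if (length(replicate_groups) != length(sample_ids))
      stop("'replicate_groups' must have one entry per sample")
    replicate_groups <- as.character(replicate_groups)
  }
  structure(list(name = name,
                 gene_ids = gene_ids,
                 sample_ids = sample_ids,
                 values = values,
                 class_labels = class_labels,
                 replicate_groups = replicate_groups,
                 time_points = time_points),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset '%s': %d genes x %d samples (%d/%d per class)\n",
              x$name, length(x$gene_ids), length(x$sample_ids),
              sum(x$class_labels == 0L), sum(x$class_labels == 1L)))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Read a tab-delimited expression matrix
#'
#' Expects genes in rows with a `gene_id` first column, one header row of
#' sample identifiers, and a numeric body.  Row and column order of the
#' file is preserved.
#'
#' @param path Path to the tab-delimited file.
#' @param class_map Named vector mapping every sample id to its 0/1 class
#'   state.
#' @param name Dataset label; defaults to the file name.
#' @inheritParams expression_dataset
#' @return An [expression_dataset()].
#' @export
read_expression_matrix <- function(path, class_map, name = basename(path),
                                   replicate_groups = NULL,
                                   time_points = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "#")
  if (ncol(tab) < 2L) stop("expected a gene_id column plus sample columns")
  gene_ids <- tab[[1L]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  body <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                 gene_ids[bad[1L]], colnames(body)[bad[2L]]))
  }
  dimnames(num) <- list(gene_ids, colnames(body))
  missing <- setdiff(colnames(num), names(class_map))
  if (length(missing) > 0L)
    stop("samples missing from class_map: ", paste(missing, collapse = ", "))
  expression_dataset(num, class_map[colnames(num)], name = name,
                     replicate_groups = replicate_groups,
                     time_points = time_points)
}

#' Write an expression dataset to a tab-delimited file
#'
#' @param ds An [expression_dataset()].
#' @param path Output path.
#' @param header_comment Optional character vector of comment lines
#'   (written as `# ...` before the header).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(ds, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  writeLines(paste(c("gene_id", ds$sample_ids), collapse = "\t"), con)
  body <- apply(ds$values, 1L, function(r)
    paste(format(r, trim = TRUE, digits = 15, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(ds$gene_ids, body, sep = "\t"), con)
  invisible(path)
}

#' Read a sample annotation sidecar
#'
#' Tab-delimited with columns `sample_id`, `class` (0/1),
#' `replicate_group`, `time_point`.
#'
#' @param path Path to the annotation file.
#' @return A data frame with one row per sample.
#' @export
read_sample_annotations <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#")
  need <- c("sample_id", "class")
  if (!all(need %in% names(ann)))
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  ann
}

#' Standardize each gene to mean 0 and standard deviation 1
#'
#' Row-wise centring and scaling by the sample standard deviation, the
#' normalisation applied to every dataset before gene selection and
#' modelling.
#'
#' @param ds An [expression_dataset()].
#' @return A standardized [expression_dataset()] of the same shape.
#' @export
standardize <- function(ds) {
  m <- rowMeans(ds$values)
  centred <- ds$values - m
  s <- sqrt(rowSums(centred^2) / (ncol(ds$values) - 1L))
  if (any(s == 0))
    stop("zero-variance gene(s): ",
         paste(ds$gene_ids[s == 0], collapse = ", "))
  ds$values <- centred / s
  ds
}

#' Per-gene two-sample Student's t-test between class states
#'
#' Compares undifferentiated (state 0) against differentiated (state 1)
#' samples for every gene, disregarding time.  The classical
#' pooled-variance form is the default; Welch's unequal-variance form is
#' available via `var_equal = FALSE`.
#'
#' @param ds An [expression_dataset()].
#' @param var_equal Use the pooled-variance (Student) form (default) or
#'   Welch's approximation.
#' @return Named numeric vector of two-sided p-values, one per gene.
#' @export
differential_test <- function(ds, var_equal = TRUE) {
  x0 <- ds$values[, ds$class_labels == 0L, drop = FALSE]
  x1 <- ds$values[, ds$class_labels == 1L, drop = FALSE]
  n0 <- ncol(x0); n1 <- ncol(x1)
  m0 <- rowMeans(x0); m1 <- rowMeans(x1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1L)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  if (var_equal) {
    sp2 <- ((n0 - 1L) * v0 + (n1 - 1L) * v1) / (n0 + n1 - 2L)
    se <- sqrt(sp2 * (1 / n0 + 1 / n1))
    df <- rep(n0 + n1 - 2L, length(se))
  } else {
    se <- sqrt(v0 / n0 + v1 / n1)
    df <- (v0 / n0 + v1 / n1)^2 /
      ((v0 / n0)^2 / (n0 - 1L) + (v1 / n1)^2 / (n1 - 1L))
  }
  tstat <- (m0 - m1) / se
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  # zero pooled variance: identical groups -> no evidence; shifted -> certain
  degenerate <- se == 0
  p[degenerate] <- ifelse(m0[degenerate] == m1[degenerate], 1, 0)
  names(p) <- ds$gene_ids
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values.
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Select an informative + spiked-in uninformative gene panel
#'
#' The `n_top` genes with the smallest t-test p-values form the
#' informative set; `n_random` genes drawn uniformly (without
#' replacement) from the remaining genes whose raw p-value exceeds a
#' quantile threshold form the spiked-in uninformative set used as the
#' null for position p-values.
#'
#' @param ds An [expression_dataset()].
#' @param n_top Number of informative genes (default 100).
#' @param n_random Number of spiked-in uninformative genes (default 50).
#' @param pool_quantile Quantile (of the non-top genes' raw p-values)
#'   above which the uninformative candidates are drawn; default 0.5.
#' @param seed Integer seed for the random draw.
#' @param var_equal Passed to [differential_test()].
#' @return A `gene_panel`: list with `informative_ids`,
#'   `uninformative_ids`, `source_dataset`, `selection_pvalues`.
#' @export
select_gene_panel <- function(ds, n_top = 100L, n_random = 50L,
                              pool_quantile = 0.5, seed = 1L,
                              var_equal = TRUE) {
  if (length(ds$gene_ids) < n_top + n_random)
    stop("dataset has fewer than n_top + n_random genes")
  p <- differential_test(ds, var_equal = var_equal)
  ord <- order(p)                       # stable for ties
  informative <- ds$gene_ids[ord[seq_len(n_top)]]
  rest <- ds$gene_ids[ord[-seq_len(n_top)]]
  thr <- stats::quantile(p[rest], pool_quantile, names = FALSE)
  pool <- rest[p[rest] > thr]
  if (length(pool) < n_random)
    stop(sprintf("uninformative candidate pool (%d) smaller than n_random (%d)",
                 length(pool), n_random))
  uninformative <- local_seed(seed, sample(pool, n_random))
  structure(list(informative_ids = informative,
                 uninformative_ids = uninformative,
                 source_dataset = ds$name,
                 selection_pvalues = p),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("gene_panel from '%s': %d informative + %d uninformative genes\n",
              x$source_dataset, length(x$informative_ids),
              length(x$uninformative_ids)))
  invisible(x)
}

#' Write / read a gene panel file
#'
#' Plain text, one gene id per line, with `# informative` /
#' `# uninformative` section headers.
#'
#' @param panel A `gene_panel`.
#' @param path File path.
#' @return `path` (write) or a `gene_panel` (read).
#' @export
write_gene_panel <- function(panel, path) {
  writeLines(c("# informative", panel$informative_ids,
               "# uninformative", panel$uninformative_ids), path)
  invisible(path)
}

#' @rdname write_gene_panel
#' @export
read_gene_panel <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  section <- cumsum(grepl("^#", lines))
  headers <- trimws(sub("^#+", "", lines[grepl("^#", lines)]))
  ids <- split(lines[!grepl("^#", lines)], section[!grepl("^#", lines)])
  names(ids) <- headers[as.integer(names(ids))]
  structure(list(informative_ids = ids[["informative"]] %||% character(),
                 uninformative_ids = ids[["uninformative"]] %||% character(),
                 source_dataset = basename(path),
                 selection_pvalues = NULL),
            class = "gene_panel")
}

#' Average within-replicate-group correlation
#'
#' Mean Pearson correlation (computed across genes) over all sample
#' pairs that share a replicate group; the pipeline's measurement of
#' dataset noisiness.
#'
#' @param ds An [expression_dataset()].
#' @param replicate_groups Optional grouping vector; defaults to the
#'   dataset's own `replicate_groups`.
#' @return Mean pairwise correlation (scalar).
#' @export
replicate_correlation <- function(ds, replicate_groups = ds$replicate_groups) {
  if (is.null(replicate_groups))
    stop("no replicate grouping available for dataset '", ds$name, "'")
  groups <- split(seq_along(ds$sample_ids), replicate_groups)
  singletons <- vapply(groups, length, 1L) < 2L
  if (all(singletons))
    stop("all replicate groups are singletons")
  if (any(singletons))
    warning(sum(singletons), " singleton replicate group(s) excluded")
  cors <- unlist(lapply(groups[!singletons], function(idx) {
    cm <- stats::cor(ds$values[, idx, drop = FALSE])
    cm[upper.tri(cm)]
  }))
  mean(cors)
}

#' Order datasets by increasing biological complexity
#'
#' Complexity is operationalised as decreasing informativeness: the
#' primary key is the count of BH-significant genes at `alpha`
#' (descending = simpler), ties broken by average replicate correlation
#' (descending = simpler).
#'
#' @param datasets List of [expression_dataset()] objects.
#' @param replicate_groups Optional list of grouping vectors, one per
#'   dataset (defaults to each dataset's own).
#' @param alpha BH significance level for the primary key (default 0.05).
#' @return A data frame, simplest dataset first, with columns `name`,
#'   `n_significant`, `replicate_cor`, and the original index `index`.
#' @export
complexity_order <- function(datasets, replicate_groups = NULL,
                             alpha = 0.05) {
  if (length(datasets) < 2L) stop("need at least 2 datasets")
  stats_df <- do.call(rbind, lapply(seq_along(datasets), function(i) {
    ds <- datasets[[i]]
    groups <- if (is.null(replicate_groups)) ds$replicate_groups
              else replicate_groups[[i]]
    nsig <- sum(bh_adjust(differential_test(ds)) < alpha)
    rc <- if (is.null(groups)) NA_real_
          else replicate_correlation(ds, groups)
    data.frame(name = ds$name, n_significant = nsig, replicate_cor = rc,
               index = i, stringsAsFactors = FALSE)
  }))
  ord <- order(-stats_df$n_significant,
               -ifelse(is.na(stats_df$replicate_cor), -Inf,
                       stats_df$replicate_cor))
  stats_df[ord, , drop = FALSE]
}

#' Assign samples to cross-validation folds
#'
#' Random partition into `k` folds of near-equal size, stratified by
#' class so that every training set contains both states.  The same
#' assignment object is reused across model-complexity classes on a
#' given dataset.
#'
#' @param ds An [expression_dataset()].
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param stratify Stratify by class (default TRUE).
#' @return A `fold_assignment`: list with `dataset`, `k`, `assignment`
#'   (named integer vector of fold indices in 1..k).
#' @export
make_folds <- function(ds, k, seed = 1L, stratify = TRUE) {
  n <- length(ds$sample_ids)
  if (k > n) stop("k exceeds the number of samples")
  if (k < 2L) stop("k must be at least 2")
  assignment <- integer(n)
  if (stratify) {
    slot <- 0L  # rotating fold pointer keeps overall sizes within 1
    order_within <- local_seed(seed, {
      lapply(split(seq_len(n), ds$class_labels), sample)
    })
    for (idx in order_within) {
      assignment[idx] <- (slot + seq_along(idx) - 1L) %% k + 1L
      slot <- (slot + length(idx)) %% k
    }
  } else {
    perm <- local_seed(seed, sample(n))
    assignment[perm] <- (seq_len(n) - 1L) %% k + 1L
  }
  names(assignment) <- ds$sample_ids
  structure(list(dataset = ds$name, k = as.integer(k),
                 assignment = assignment),
            class = "fold_assignment")
}

#' Restrict a dataset to a set of genes
#'
#' @param ds An [expression_dataset()].
#' @param gene_ids Genes to keep, in the given order.
#' @return The restricted [expression_dataset()].
#' @export
subset_genes <- function(ds, gene_ids) {
  missing <- setdiff(gene_ids, ds$gene_ids)
  if (length(missing) > 0L)
    stop("genes absent from '", ds$name, "': ",
         paste(missing, collapse = ", "))
  ds$values <- ds$values[gene_ids, , drop = FALSE]
  ds$gene_ids <- gene_ids
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
local_seed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = env)
    else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  expr
}
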