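#' Build and validate a pipeline run configuration
#'
#' Defaults follow the study settings: panels of 100 informative + 50
#' spiked-in uninformative genes, annealing from temperature 10 down to
#' 0.001 with 1500 score calls for 150-gene panels, and fold counts of
#' about a quarter of the sample count.
#'
#' @param config Named list (or path handled by
#'   [load_run_config()]) with any of: `simulate` (logical; use the
#'   bundled generator), `dataset_paths` / `annotation_paths` (named
#'   character vectors, used when `simulate` is FALSE), `n_genes`
#'   (subnetwork size for simulation), `source_nodes`, `source_edges`
#'   (source topology scale), `n_top`, `n_random`, `folds` (named
#'   integer vector or NULL for samples/4), `constraints`, `t0`, `tn`,
#'   `maxfc`, `seed`, `out_dir`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(config = list()) {
  defaults <- list(simulate = TRUE,
                   dataset_paths = NULL,
                   annotation_paths = NULL,
                   source_nodes = 1330L,
                   source_edges = 2724L,
                   n_genes = 150L,
                   n_background = 250L,
                   n_top = 100L,
                   n_random = 50L,
                   folds = NULL,
                   constraints = c("SNB", "1PB", "NPB"),
                   t0 = 10, tn = 0.001, maxfc = 1500L,
                   seed = NULL,
                   out_dir = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed))
    stop("a master seed is mandatory (no wall-clock seeding)")
  cfg$seed <- as.integer(cfg$seed)
  if (!all(cfg$constraints %in% c("SNB", "1PB", "NPB")))
    stop("constraints must be among SNB, 1PB, NPB")
  if (!cfg$simulate) {
    if (is.null(cfg$dataset_paths))
      stop("dataset_paths required when simulate = FALSE")
    missing <- cfg$dataset_paths[!file.exists(cfg$dataset_paths)]
    if (length(missing) > 0L)
      stop("dataset path(s) not found: ", paste(missing, collapse = ", "))
  }
  annealing_schedule(cfg$t0, cfg$tn, cfg$maxfc)  # validates the triple
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path Path to a YAML configuration file.
#' @export
load_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

# Short stable hash of the scientific configuration (the output
# location does not alter results, so it is excluded) for output-file
# headers.
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  key <- paste(deparse(cfg), collapse = "")
  h <- 17
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

output_header <- function(cfg) {
  sprintf("config_hash=%s seed=%d", config_hash(cfg), cfg$seed)
}

#' Simulate the three-tier dataset series to disk
#'
#' Writes one expression matrix and sample-annotation sidecar per noise
#' tier, the shared subnetwork edge list, and a JSON truth sidecar
#' naming the condition-responsive genes and replicate groups.  Byte
#' identical on reruns with the same configuration.
#'
#' @param cfg A [run_config()] (must include `out_dir`).
#' @return Named list of the simulated [expression_dataset()]s,
#'   invisibly.
#' @export
pipeline_simulate <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  if (is.null(cfg$out_dir)) stop("out_dir required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(cfg$out_dir)) stop("cannot create output dir: ", cfg$out_dir)
  series <- simulate_series(cfg)
  hdr <- output_header(cfg)
  sub <- attr(series, "subnetwork")
  write_network(sub, file.path(cfg$out_dir, "subnetwork.tsv"))
  for (nm in names(series)) {
    ds <- series[[nm]]
    write_expression_matrix(ds, file.path(cfg$out_dir, paste0(nm, ".tsv")),
                            header_comment = hdr)
    ann <- data.frame(sample_id = ds$sample_ids, class = ds$class_labels,
                      replicate_group = ds$replicate_groups,
                      time_point = ds$time_points)
    utils::write.table(ann, file.path(cfg$out_dir, paste0(nm, "_samples.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth <- attr(ds, "truth")
    jsonlite::write_json(
      list(responsive = truth$responsive,
           responsive_downstream = truth$responsive_downstream,
           condition_effect = as.list(truth$condition_effect),
           replicate_groups = ds$replicate_groups),
      file.path(cfg$out_dir, paste0(nm, "_truth.json")),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(series)
}

# Generate the in-memory dataset series for a config.
simulate_series <- function(cfg) {
  net <- generate_source_topology(cfg$source_nodes, cfg$source_edges,
                                  seed = derive_seed(cfg$seed, "topology"))
  make_dataset_series(net, tiers = default_tiers(cfg$seed),
                      n_genes = cfg$n_genes, n_background = cfg$n_background,
                      seed = cfg$seed)
}

load_series <- function(cfg) {
  out <- lapply(names(cfg$dataset_paths), function(nm) {
    ann <- read_sample_annotations(cfg$annotation_paths[[nm]])
    read_expression_matrix(
      cfg$dataset_paths[[nm]],
      class_map = stats::setNames(ann$class, ann$sample_id),
      name = nm,
      replicate_groups = ann$replicate_group,
      time_points = ann$time_point)
  })
  names(out) <- names(cfg$dataset_paths)
  out
}

#' Run the full multi-dataset experiment
#'
#' For every (training dataset x constraint class) combination:
#' standardizes the training data, selects the gene panel, restricts
#' and standardizes all datasets to the panel, lays out folds, runs the
#' cross-validated multi-dataset evaluation, and computes position
#' p-values and KS separation for every ranking.  A rank-improvement
#' analysis compares the simplest training dataset's model-based
#' ranking of the most complex dataset against that dataset's own
#' t-test ranking.  A summary table of mean cross-validation vs
#' independent-test error per cell is always produced; failed cells are
#' marked rather than aborting the run.
#'
#' @param cfg A [run_config()].
#' @param datasets Optional named list of [expression_dataset()]s; by
#'   default simulated (when `cfg$simulate`) or read from
#'   `cfg$dataset_paths`.
#' @return A `pipeline_result`: list with `summary` (data frame),
#'   `cells` (per train x constraint results), `order` (complexity
#'   ordering), `rank_shifts`, `config`.
#' @export
pipeline_run <- function(cfg, datasets = NULL) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  if (is.null(datasets))
    datasets <- if (cfg$simulate) simulate_series(cfg) else load_series(cfg)
  hdr <- output_header(cfg)
  ord <- complexity_order(datasets)
  cells <- list()
  summary_rows <- list()
  for (train_nm in names(datasets)) {
    train_raw <- datasets[[train_nm]]
    panel <- select_gene_panel(standardize(train_raw),
                               n_top = cfg$n_top, n_random = cfg$n_random,
                               seed = derive_seed(cfg$seed, "panel", train_nm))
    panel_genes <- c(panel$informative_ids, panel$uninformative_ids)
    restricted <- lapply(datasets, function(ds)
      standardize(subset_genes(ds, panel_genes)))
    train <- restricted[[train_nm]]
    tests <- restricted[names(restricted) != train_nm]
    k <- if (!is.null(cfg$folds)) cfg$folds[[train_nm]]
         else max(2L, round(length(train$sample_ids) / 4))
    folds <- make_folds(train, k, seed = derive_seed(cfg$seed, "folds", train_nm))
    for (constraint in cfg$constraints) {
      cell_id <- paste(train_nm, constraint, sep = ".")
      res <- tryCatch({
        scores <- multidata_eval(
          train, tests, folds, constraint,
          schedule = annealing_schedule(cfg$t0, cfg$tn, cfg$maxfc),
          seed = derive_seed(cfg$seed, "eval", train_nm, constraint))
        pos_p <- lapply(scores$rankings, position_p_values,
                        null_ids = panel$uninformative_ids)
        ks <- lapply(scores$rankings, ks_separation,
                     informative_ids = panel$informative_ids,
                     uninformative_ids = panel$uninformative_ids)
        list(scores = scores, panel = panel, folds = folds,
             position_pvalues = pos_p, ks = ks, failed = FALSE)
      }, error = function(e) list(failed = TRUE, error = conditionMessage(e)))
      cells[[cell_id]] <- res
      summary_rows[[cell_id]] <- if (res$failed) {
        data.frame(train = train_nm, constraint = constraint,
                   cv_error = NA_real_, test_error = NA_real_,
                   mean_edges = NA_real_, status = "failed")
      } else {
        tab <- res$scores$score_table
        test_cols <- grep("^test_sse_", names(tab), value = TRUE)
        edges <- mean(vapply(res$scores$fold_structures, function(s)
          nrow(structure_edges(s$structure, include_class = FALSE)), 1.0))
        data.frame(train = train_nm, constraint = constraint,
                   cv_error = mean(tab$train_sse),
                   test_error = if (length(test_cols) > 0L)
                     mean(colMeans(tab[test_cols])) else NA_real_,
                   mean_edges = edges, status = "ok")
      }
    }
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL

  # rank improvement: simplest training dataset modelling the most
  # complex one, for the panel selected on the simplest
  rank_shifts <- NULL
  simple_nm <- ord$name[1L]
  complex_nm <- ord$name[nrow(ord)]
  shift_cell <- cells[[paste(simple_nm,
                             if ("1PB" %in% cfg$constraints) "1PB"
                             else cfg$constraints[1L], sep = ".")]]
  if (!is.null(shift_cell) && !shift_cell$failed && simple_nm != complex_nm) {
    panel <- shift_cell$panel
    panel_genes <- c(panel$informative_ids, panel$uninformative_ids)
    complex_std <- standardize(subset_genes(datasets[[complex_nm]], panel_genes))
    original <- rank_genes(differential_test(complex_std),
                           source = paste0("ttest_", complex_nm))
    model_rk <- shift_cell$scores$rankings[[paste0("testR_SSE_", complex_nm)]]
    groups <- list(top_informative = panel$informative_ids,
                   uninformative = panel$uninformative_ids)
    truth <- attr(datasets[[complex_nm]], "truth")
    if (!is.null(truth))
      groups$condition_responsive <-
        intersect(truth$responsive, panel_genes)
    rank_shifts <- rank_shift(original, model_rk, groups)
  }

  result <- structure(list(summary = summary, cells = cells, order = ord,
                           rank_shifts = rank_shifts, config = cfg),
                      class = "pipeline_result")
  if (!is.null(cfg$out_dir)) write_pipeline_result(result, cfg$out_dir, hdr)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$summary)
  invisible(x)
}

write_pipeline_result <- function(result, out_dir, hdr) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(out_dir, "summary.tsv"), "w")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(result$summary, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  con <- file(file.path(out_dir, "complexity_order.tsv"), "w")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(result$order, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  for (cell_id in names(result$cells)) {
    cell <- result$cells[[cell_id]]
    if (cell$failed) next
    write_score_table(cell$scores,
                      file.path(out_dir, paste0(cell_id, "_scores.tsv")),
                      header_comment = hdr)
    write_rankings(cell$scores$rankings,
                   file.path(out_dir, paste0(cell_id, "_rankings.tsv")),
                   header_comment = hdr)
    pos_all <- do.call(rbind, lapply(names(cell$position_pvalues), function(nm) {
      d <- cell$position_pvalues[[nm]]
      d$source <- nm
      d
    }))
    write_ranking_report(pos_all,
                         file.path(out_dir, paste0(cell_id, "_position_pvalues.tsv")),
                         header_comment = hdr)
    ks_tab <- do.call(rbind, lapply(names(cell$ks), function(nm)
      data.frame(source = nm, D = cell$ks[[nm]]$D,
                 p_value = cell$ks[[nm]]$p_value,
                 direction = cell$ks[[nm]]$direction)))
    write_ranking_report(ks_tab,
                         file.path(out_dir, paste0(cell_id, "_ks.tsv")),
                         header_comment = hdr)
  }
  if (!is.null(result$rank_shifts))
    write_ranking_report(result$rank_shifts,
                         file.path(out_dir, "rank_shifts.tsv"),
                         header_comment = hdr)
  invisible(out_dir)
}

#' Desk-scale replication experiment on the synthetic three-tier series
#'
#' Runs the full pipeline (gene selection, cross-validated annealing,
#' independent-dataset scoring, rank-shift analysis) on the bundled
#' three-tier generator with the one-parent classifier, and extracts
#' the quantities the study design is about: the complexity ordering
#' of the tiers, mean cross-validation and independent-test error per
#' training tier, and the rank improvement of condition-responsive vs
#' spiked-in uninformative genes when the simplest tier's models are
#' evaluated on the most complex tier.
#'
#' @param seed Integer master seed.
#' @param maxfc Annealing score-call budget per fold (default 6000;
#'   see the methods vignette for the choice).
#' @param constraint Constraint class to benchmark (default `"1PB"`,
#'   the classifier the study design favours).
#' @return List with `order` (complexity ordering data frame),
#'   `summary` (per-train-tier cv/test errors), `shift_groups` (mean
#'   shifts per gene group), `shifts` (per-gene), `result` (the full
#'   `pipeline_result`).
#' @export
tier_benchmark <- function(seed, maxfc = 6000L, constraint = "1PB") {
  cfg <- run_config(list(seed = seed, constraints = constraint,
                         maxfc = maxfc))
  res <- pipeline_run(cfg)
  list(order = res$order,
       summary = res$summary,
       shift_groups = if (!is.null(res$rank_shifts)) res$rank_shifts$groups,
       shifts = if (!is.null(res$rank_shifts)) res$rank_shifts$shifts,
       result = res)
}
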