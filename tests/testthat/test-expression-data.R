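test_that("expression matrix files round-trip and are validated on read", {
  ds <- toy_dataset(3L, 4L, seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(ds, path)
  back <- read_expression_matrix(
    path, class_map = stats::setNames(ds$class_labels, ds$sample_ids))
  expect_equal(dim(back), c(3L, 4L))
  expect_equal(back$gene_ids, ds$gene_ids)
  expect_equal(back$values, ds$values, tolerance = 1e-12)

  # duplicate gene id is named in the error
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "gA\t1\t2\t3\t4", "gA\t5\t6\t7\t8"), path)
  expect_error(read_expression_matrix(path, c(s1 = 0, s2 = 0, s3 = 1, s4 = 1)),
               "gA")

  # non-numeric cell names its row and column
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "gA\t1\t2\tx\t4", "gB\t5\t6\t7\t8"), path)
  expect_error(read_expression_matrix(path, c(s1 = 0, s2 = 0, s3 = 1, s4 = 1)),
               "gA.*s3")

  # one sample per class violates the within-class-variance invariant
  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2", "gB\t3\t4"), path)
  expect_error(read_expression_matrix(path, c(s1 = 0, s2 = 1)),
               "at least 2 samples")

  # sample missing from the class map
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "gA\t1\t2\t3\t4", "gB\t5\t6\t7\t8"), path)
  expect_error(read_expression_matrix(path, c(s1 = 0, s2 = 0, s3 = 1)), "s4")
})

test_that("standardize gives exact per-gene moments and is idempotent", {
  vals <- rbind(g1 = c(1, 2, 3, 4), g2 = c(5, 5, 7, 7))
  colnames(vals) <- paste0("s", 1:4)
  ds <- expression_dataset(vals, c(0L, 0L, 1L, 1L))
  std <- standardize(ds)
  expect_equal(rowMeans(std$values), c(g1 = 0, g2 = 0), tolerance = 1e-12)
  expect_equal(apply(std$values, 1, sd), c(g1 = 1, g2 = 1), tolerance = 1e-12)
  # closed form: the evenly spaced row 1,2,3,4 maps to symmetric scores
  expect_equal(unname(std$values["g1", ]),
               (c(1, 2, 3, 4) - 2.5) / sd(c(1, 2, 3, 4)))

  # idempotence
  std2 <- standardize(std)
  expect_equal(std2$values, std$values, tolerance = 1e-10)

  # random matrix: all row moments exact within 1e-10
  big <- toy_dataset(150L, 30L, seed = 3)
  bigstd <- standardize(big)
  expect_lt(max(abs(rowMeans(bigstd$values))), 1e-10)
  expect_lt(max(abs(apply(bigstd$values, 1, sd) - 1)), 1e-10)

  # zero-variance gene is a named hard error
  flat <- toy_dataset(2L, 6L, seed = 1)
  flat$values["g02", ] <- 5
  expect_error(standardize(flat), "g02")
})

test_that("differential_test matches t.test and handles degenerate genes", {
  ds <- toy_dataset(20L, 12L, seed = 11)
  p <- differential_test(ds)
  # dual route: classical pooled t.test per gene
  for (g in c("g01", "g07", "g20")) {
    ref <- t.test(ds$values[g, ds$class_labels == 0],
                  ds$values[g, ds$class_labels == 1], var.equal = TRUE)
    expect_equal(unname(p[g]), ref$p.value, tolerance = 1e-12)
  }
  pw <- differential_test(ds, var_equal = FALSE)
  ref <- t.test(ds$values["g03", ds$class_labels == 0],
                ds$values["g03", ds$class_labels == 1])
  expect_equal(unname(pw["g03"]), ref$p.value, tolerance = 1e-12)

  # strong shift with no within-class variance: certain
  ds$values["g01", ] <- rep(c(0, 5), each = 6)
  # balanced gene with equal class means: t = 0, p = 1
  ds$values["g02", ] <- c(-1, 1, -1, 1, -1, 1, 1, -1, 1, -1, 1, -1)
  p2 <- differential_test(ds)
  expect_lt(p2[["g01"]], 1e-6)
  expect_equal(p2[["g02"]], 1)

  # affine invariance per gene (scale-free t statistic)
  shifted <- ds
  shifted$values <- ds$values * 3.7 - 2.2
  expect_equal(differential_test(shifted), differential_test(ds),
               tolerance = 1e-10)
})

test_that("pure-noise p-values are uniform", {
  ds <- toy_dataset(10000L, 10L, seed = 19)
  p <- differential_test(ds)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.04), 0.04)
  p <- withr_seed(5, runif(50))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("gene panel selection recovers planted signal and is seeded", {
  # 100 planted signal genes (2-sd class shift), 1000 nulls, 15/class
  n <- 30L
  withr_seed(23, {
    vals <- matrix(rnorm(1100 * n), 1100, n)
    vals[1:100, 16:30] <- vals[1:100, 16:30] + 2
  })
  rownames(vals) <- sprintf("g%04d", 1:1100)
  colnames(vals) <- sprintf("s%02d", 1:n)
  ds <- expression_dataset(vals, rep(c(0L, 1L), each = 15L))
  panel <- select_gene_panel(ds, n_top = 100L, n_random = 50L, seed = 9)
  expect_gte(sum(panel$informative_ids %in% sprintf("g%04d", 1:100)), 95)
  expect_length(intersect(panel$informative_ids, panel$uninformative_ids), 0)
  expect_length(c(panel$informative_ids, panel$uninformative_ids), 150)

  # determinism
  panel2 <- select_gene_panel(ds, n_top = 100L, n_random = 50L, seed = 9)
  expect_identical(panel$uninformative_ids, panel2$uninformative_ids)

  # candidate pool too small
  small <- toy_dataset(30L, 10L, seed = 2)
  expect_error(select_gene_panel(small, n_top = 25L, n_random = 5L),
               "smaller than n_random|fewer than")

  # panel file round trip
  path <- withr::local_tempfile(fileext = ".txt")
  write_gene_panel(panel, path)
  back <- read_gene_panel(path)
  expect_identical(back$informative_ids, panel$informative_ids)
  expect_identical(back$uninformative_ids, panel$uninformative_ids)
})

test_that("replicate correlation handles exact and degenerate groups", {
  vals <- withr_seed(3, matrix(rnorm(40), 10, 4))
  vals[, 2] <- vals[, 1]            # identical replicate pair
  dimnames(vals) <- list(sprintf("g%02d", 1:10), sprintf("s%d", 1:4))
  ds <- expression_dataset(vals, c(0L, 0L, 1L, 1L),
                           replicate_groups = c("a", "a", "b", "b"))
  pair_b <- cor(vals[, 3], vals[, 4])
  expect_equal(replicate_correlation(ds), mean(c(1, pair_b)), tolerance = 1e-12)

  # anti-proportional standardized columns give -1
  v2 <- vals
  v2[, 4] <- -v2[, 3]
  ds2 <- expression_dataset(v2, c(0L, 0L, 1L, 1L),
                            replicate_groups = c("x", "x", "y", "y"))
  expect_equal(replicate_correlation(ds2), mean(c(1, -1)), tolerance = 1e-12)

  # singleton groups excluded with a warning; all singletons error
  ds3 <- expression_dataset(vals, c(0L, 0L, 1L, 1L),
                            replicate_groups = c("a", "a", "b", "c"))
  expect_warning(rc <- replicate_correlation(ds3), "singleton")
  expect_equal(rc, 1, tolerance = 1e-12)
  ds4 <- expression_dataset(vals, c(0L, 0L, 1L, 1L),
                            replicate_groups = c("a", "b", "c", "d"))
  expect_error(suppressWarnings(replicate_correlation(ds4)), "singleton")
})

test_that("fold layout is stratified, balanced, seeded and exhaustive", {
  ds36 <- toy_dataset(5L, 36L, seed = 4)
  f9 <- make_folds(ds36, 9L, seed = 1)
  expect_equal(as.vector(table(f9$assignment)), rep(4L, 9L))
  ds24 <- toy_dataset(5L, 24L, seed = 4)
  f6 <- make_folds(ds24, 6L, seed = 1)
  expect_equal(as.vector(table(f6$assignment)), rep(4L, 6L))

  # stratification: every fold contains both classes
  for (j in 1:6) {
    cls <- ds24$class_labels[f6$assignment == j]
    expect_setequal(unique(cls), c(0L, 1L))
  }
  # union of folds = all samples, pairwise disjoint (by construction of
  # a single assignment vector); sizes differ by at most 1
  f7 <- make_folds(ds36, 7L, seed = 2)
  expect_length(f7$assignment, 36L)
  expect_lte(diff(range(table(f7$assignment))), 1L)

  # determinism and error cases
  expect_identical(make_folds(ds24, 6L, seed = 5)$assignment,
                   make_folds(ds24, 6L, seed = 5)$assignment)
  expect_error(make_folds(ds24, 25L, seed = 1), "exceeds")
})

test_that("complexity ordering is stable for identical datasets", {
  ds <- toy_dataset(40L, 12L, seed = 8)
  ds$replicate_groups <- rep(c("a", "a", "b", "b", "c", "c"), 2)
  a <- ds; a$name <- "first"
  b <- ds; b$name <- "second"
  ord <- complexity_order(list(a, b))
  expect_equal(ord$name, c("first", "second"))
})
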