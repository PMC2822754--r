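test_that("source topology has the requested scale and hubby out-degrees", {
  net <- generate_source_topology(1330L, 2724L, seed = 2)
  expect_length(net$nodes, 1330L)
  expect_equal(nrow(net$edges), 2724L)
  expect_false(any(net$edges$regulator == net$edges$target))
  expect_false(anyDuplicated(paste(net$edges$regulator, net$edges$target)) > 0)
  expect_true(all(net$edges$strength > 0))

  small <- generate_source_topology(5L, 4L, seed = 3)
  expect_length(small$nodes, 5L)
  expect_equal(nrow(small$edges), 4L)
  expect_error(generate_source_topology(10L, 5L, seed = 1), "n_nodes - 1")

  # out-degree is heavier-tailed than an Erdos-Renyi graph of the same
  # density (matched by multinomial regulator assignment)
  heavier <- withr_seed(11, {
    vapply(1:30, function(i) {
      pa <- generate_source_topology(300L, 600L, seed = i)
      od <- table(factor(pa$edges$regulator, levels = pa$nodes))
      er <- tabulate(sample.int(300L, 600L, replace = TRUE), nbins = 300L)
      k <- function(x) mean((x - mean(x))^4) / stats::var(x)^2
      k(as.numeric(od)) > k(er)
    }, TRUE)
  })
  expect_gte(mean(heavier), 0.9)
})

test_that("subnetwork sampling is induced, seeded, and module-coherent", {
  net <- generate_source_topology(400L, 800L, seed = 5)
  sub <- sample_subnetwork(net, 60L, seed = 7)
  expect_length(sub$nodes, 60L)
  # induced-subgraph oracle: brute-force filter of the full edge list
  manual <- net$edges[net$edges$regulator %in% sub$nodes &
                        net$edges$target %in% sub$nodes, ]
  expect_equal(sub$edges[order(sub$edges$regulator, sub$edges$target), ],
               manual[order(manual$regulator, manual$target), ],
               ignore_attr = TRUE)
  # determinism, and the full network returned unchanged
  sub2 <- sample_subnetwork(net, 60L, seed = 7)
  expect_identical(sub$nodes, sub2$nodes)
  expect_identical(sample_subnetwork(net, 400L, seed = 1), net)
  expect_error(sample_subnetwork(net, 500L), "exceeds")
})

test_that("steady-state simulation honours basal levels, signs, and noise", {
  # no regulators, all noise zero: every sample equals the basal level
  iso <- structure(list(nodes = c("x", "y"),
                        edges = data.frame(regulator = character(),
                                           target = character(), sign = integer(),
                                           strength = numeric(),
                                           half_saturation = numeric(),
                                           hill = numeric()),
                        basal = c(x = 1.5, y = -2)),
                   class = "regulatory_network")
  d0 <- simulate_expression(iso, simulation_design(4L, 2L, 0, 0, seed = 1))
  expect_true(all(d0$values["x", ] == 1.5))
  expect_true(all(d0$values["y", ] == -2))

  # the transfer function is strictly increasing in the regulator
  grid <- seq(-4, 4, length.out = 101L)
  resp <- mdbnc:::hill_response(grid, 1, 1)
  expect_true(all(diff(resp) > 0))
  # and an activating edge yields a positive regulator-target
  # correlation (negative for repression) in simulated data
  edge_net <- function(sign) structure(list(
    nodes = c("r", "t"),
    edges = data.frame(regulator = "r", target = "t", sign = sign,
                       strength = 5, half_saturation = 1, hill = 1),
    basal = c(r = 0, t = 0)), class = "regulatory_network")
  act <- simulate_expression(edge_net(1L), simulation_design(100L, 1L, 0.4, 0, seed = 2))
  rep_ <- simulate_expression(edge_net(-1L), simulation_design(100L, 1L, 0.4, 0, seed = 2))
  expect_gt(cor(act$values["r", ], act$values["t", ]), 0.9)
  expect_lt(cor(rep_$values["r", ], rep_$values["t", ]), -0.9)

  # higher measurement noise lowers replicate correlation
  net <- generate_source_topology(200L, 400L, seed = 9)
  sub <- sample_subnetwork(net, 50L, seed = 9)
  quieter <- vapply(1:10, function(i) {
    lo <- simulate_expression(sub, simulation_design(8L, 4L, 0.3, 0.1, seed = i))
    hi <- simulate_expression(sub, simulation_design(8L, 4L, 0.3, 0.5, seed = i))
    replicate_correlation(lo) > replicate_correlation(hi)
  }, TRUE)
  expect_gte(mean(quieter), 0.9)

  # condition effects shift perturbed genes and are recorded as truth
  eff <- sample_condition_effect(sub, fraction = 0.5, seed = 4)
  d <- simulate_expression(sub, simulation_design(10L, 2L, 0.2, 0.05, eff, seed = 5))
  truth <- attr(d, "truth")
  expect_setequal(truth$responsive, names(eff))
  expect_error(
    simulate_expression(sub, simulation_design(4L, 2L, 0.1, 0.1,
                                               c(nope = 1), seed = 1)),
    "nope")
})

test_that("the three-tier series matches the study layout and ground truth", {
  net <- generate_source_topology(600L, 1200L, seed = 13)
  series <- make_dataset_series(net, default_tiers(13), n_genes = 80L,
                                n_background = 120L, seed = 13)
  expect_named(series, c("low", "mid", "high"))
  expect_equal(vapply(series, function(d) length(d$sample_ids), 1L),
               c(low = 24L, mid = 36L, high = 32L))
  # one shared subnetwork and one shared condition effect
  sub <- attr(series, "subnetwork")
  expect_length(sub$nodes, 80L)
  effs <- lapply(series, function(d) attr(d, "truth")$condition_effect)
  expect_identical(effs$low, effs$mid)
  expect_identical(effs$low, effs$high)
  expect_length(series$low$gene_ids, 200L)

  # complexity ordering recovers the noise tiers
  ord <- complexity_order(series)
  expect_equal(ord$name, c("low", "mid", "high"))

  # misordered tiers are rejected before simulation
  bad <- default_tiers(13)
  bad$mid$bio_noise_sd <- 10
  expect_error(make_dataset_series(net, bad, n_genes = 80L, seed = 13),
               "increasing")
})

test_that("a null condition effect yields nominal false-positive rates", {
  net <- generate_source_topology(500L, 900L, seed = 17)
  sub0 <- sample_subnetwork(net, 40L, seed = 17)
  d <- simulate_expression(add_background_genes(sub0, 360L, seed = 2),
                           simulation_design(16L, 4L, 0.3, 0.1,
                                             condition_effect = numeric(),
                                             seed = 3))
  p <- differential_test(standardize(d))
  # background genes are independent; expect about 5% below 0.05
  bg <- grep("^B", names(p), value = TRUE)
  hits <- sum(p[bg] < 0.05)
  expect_lt(abs(hits / length(bg) - 0.05), 0.035)
})

test_that("network files round-trip", {
  net <- generate_source_topology(30L, 60L, seed = 19)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$basal, net$basal, tolerance = 1e-12)
  expect_equal(back$edges$strength, net$edges$strength, tolerance = 1e-12)
  expect_identical(back$edges$regulator, net$edges$regulator)
})
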