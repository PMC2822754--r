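test_that("structure constructors enforce constraint classes and acyclicity", {
  genes <- c("a", "b", "c")
  expect_error(network_structure(genes, "SNB", gene_edges = rbind(c("a", "b"))),
               "SNB")
  expect_error(network_structure(genes, "1PB",
                                 gene_edges = rbind(c("a", "c"), c("b", "c"))),
               "one gene parent")
  expect_error(network_structure(genes, "NPB",
                                 gene_edges = rbind(c("a", "b"), c("b", "c"),
                                                    c("c", "a"))),
               "cycle")
  expect_error(network_structure(genes, "NPB", gene_edges = rbind(c("a", "a"))),
               "self-loop")
  expect_error(network_structure(genes, "NPB",
                                 gene_edges = rbind(c("a", "b"), c("a", "b"))),
               "duplicate edge")
  st <- network_structure(genes, "1PB", gene_edges = rbind(c("a", "b")))
  expect_true(all(st$class_parent))
  expect_s3_class(validate_structure(st), "network_structure")

  # serialization round trip preserves genes, constraint, and edges
  path <- withr::local_tempfile(fileext = ".tsv")
  write_structure(st, path)
  back <- read_structure(path)
  expect_identical(back$constraint, "1PB")
  expect_identical(back$genes, genes)
  expect_identical(back$parents, st$parents)
  expect_identical(back$class_parent, st$class_parent)
})

test_that("maximum-likelihood fitting matches closed forms", {
  # no gene parents: intercept = state mean, variance = ML (1/n)
  vals <- rbind(g = c(1, 2, 3, 7, 8, 9))
  colnames(vals) <- paste0("s", 1:6)
  ds <- expression_dataset(vals, rep(c(0L, 1L), each = 3L))
  m <- fit_parameters(snb_structure("g"), ds)
  fam0 <- m$params$g$families[["0"]]
  expect_equal(fam0$intercept, 2)
  expect_equal(fam0$var, 2 / 3)
  expect_equal(m$class_prior, 0.5)

  # OLS consistency: child = 2 * parent + 1 + N(0, 0.01)
  n <- 1000L
  withr_seed(31, {
    cls <- rep(c(0L, 1L), each = n / 2L)
    par <- rnorm(n)
    ch <- 2 * par + 1 + rnorm(n, 0, 0.1)
    vals <- rbind(p = par, ch = ch)
    colnames(vals) <- sprintf("s%04d", 1:n)
    ds2 <- expression_dataset(vals, cls)
  })
  st <- network_structure(c("p", "ch"), "1PB", gene_edges = rbind(c("p", "ch")))
  m2 <- fit_parameters(st, ds2)
  for (s in c("0", "1")) {
    fam <- m2$params$ch$families[[s]]
    expect_gt(fam$coef[["p"]], 1.9); expect_lt(fam$coef[["p"]], 2.1)
    expect_gt(fam$intercept, 0.9); expect_lt(fam$intercept, 1.1)
  }

  # empty-edge structure reduces to per-state mean and variance
  ds3 <- toy_dataset(3L, 10L, seed = 2)
  m3 <- fit_parameters(snb_structure(ds3$gene_ids), ds3)
  x0 <- ds3$values["g01", ds3$class_labels == 0L]
  expect_equal(m3$params$g01$families[["0"]]$intercept, mean(x0))
  expect_equal(m3$params$g01$families[["0"]]$var,
               mean((x0 - mean(x0))^2))

  # too few samples for a family is a named error
  tiny <- toy_dataset(3L, 4L, seed = 3)
  st_big <- network_structure(tiny$gene_ids, "NPB",
                              gene_edges = rbind(c("g01", "g03"),
                                                 c("g02", "g03")),
                              class_children = tiny$gene_ids)
  expect_error(fit_parameters(st_big, tiny), "g03.*state")
})

test_that("log-likelihood matches closed form and brute-force oracle", {
  # single sample at every family mean with unit variances:
  # logL = log P(class) - G * log(sqrt(2*pi))
  ds <- chain_dataset(n = 60L, seed = 5)
  st <- network_structure(ds$gene_ids, "1PB",
                          gene_edges = rbind(c("a", "b"), c("b", "c")))
  m <- fit_parameters(st, ds)
  m_unit <- m
  for (g in names(m_unit$params))
    for (s in names(m_unit$params[[g]]$families))
      m_unit$params[[g]]$families[[s]]$var <- 1
  one <- subset_samples(ds, 1:4)
  # place the first sample exactly at each family mean
  for (g in one$gene_ids)
    one$values[g, 1L] <- predict_gene(m_unit, one$values[, 1L],
                                      one$class_labels[1L], g)
  ll1 <- log_likelihood(m_unit, subset_samples(one, 1L:4L))
  # check sample 1's contribution via difference against brute force
  expect_equal(ll1, brute_force_loglik(m_unit, subset_samples(one, 1L:4L)),
               tolerance = 1e-8)

  # full-dataset brute-force equality
  expect_equal(log_likelihood(m, ds), brute_force_loglik(m, ds),
               tolerance = 1e-8)

  # nested-model property: adding an edge never decreases training logL
  for (seed in 1:5) {
    d <- toy_dataset(4L, 30L, seed = seed)
    base <- network_structure(d$gene_ids, "NPB",
                              gene_edges = rbind(c("g01", "g02")),
                              class_children = d$gene_ids)
    bigger <- network_structure(d$gene_ids, "NPB",
                                gene_edges = rbind(c("g01", "g02"),
                                                   c("g03", "g02")),
                                class_children = d$gene_ids)
    ll_base <- log_likelihood(fit_parameters(base, d), d)
    ll_big <- log_likelihood(fit_parameters(bigger, d), d)
    expect_gte(ll_big, ll_base - 1e-8)
  }
})

test_that("BIC decomposes into family scores and counts parameters", {
  ds <- chain_dataset(n = 80L, seed = 9)
  st <- network_structure(ds$gene_ids, "1PB",
                          gene_edges = rbind(c("a", "b"), c("b", "c")))
  sc <- bic_score(st, ds)
  expect_equal(sum(sc$family_scores), sc$bic, tolerance = 1e-8)
  expect_equal(sc$bic,
               sc$log_likelihood - sc$n_params / 2 * log(length(ds$sample_ids)))

  # structures differing by one edge differ only in the affected child
  st2 <- network_structure(ds$gene_ids, "1PB", gene_edges = rbind(c("a", "b")))
  sc2 <- bic_score(st2, ds)
  expect_equal(sc$bic - sc2$bic,
               sc$family_scores[["c"]] - sc2$family_scores[["c"]],
               tolerance = 1e-8)
  same <- setdiff(names(sc$family_scores), "c")
  expect_equal(sc$family_scores[same], sc2$family_scores[same],
               tolerance = 1e-10)

  # parameter-count formula: empty SNB over 150 genes, 2 states
  expect_equal(count_parameters(snb_structure(sprintf("g%03d", 1:150))), 601L)
  # one gene-gene edge adds one coefficient per class state
  expect_equal(count_parameters(st2) - count_parameters(snb_structure(ds$gene_ids)),
               2L)
  # monotone in edge count
  expect_gt(count_parameters(st), count_parameters(st2))
})

test_that("gene prediction equals the conditional mean and a quadrature oracle", {
  ds <- chain_dataset(n = 120L, seed = 13)
  # SNB: prediction is the class-conditional mean
  snb <- fit_parameters(snb_structure(ds$gene_ids), ds)
  expect_equal(predict_gene(snb, ds$values[, 3L], 0L, "a"),
               snb$params$a$families[["0"]]$intercept)

  # pinned linear family: coefficient 2, intercept 1, parent at 0.5
  st <- network_structure(c("p", "ch"), "1PB", gene_edges = rbind(c("p", "ch")))
  m <- list(structure = st, class_prior = 0.5, n_train = 10L,
            params = list(
              p = list(parents = character(), by_class = TRUE,
                       families = list("0" = list(intercept = 0, coef = numeric(), var = 1),
                                       "1" = list(intercept = 0, coef = numeric(), var = 1))),
              ch = list(parents = "p", by_class = TRUE,
                        families = list("0" = list(intercept = 1, coef = c(p = 2), var = 0.5),
                                        "1" = list(intercept = 1, coef = c(p = 2), var = 0.5)))))
  class(m) <- "fitted_model"
  expect_equal(predict_gene(m, c(p = 0.5), 1L, "ch"), 2.0)
  expect_error(predict_gene(m, c(x = 1), 1L, "ch"), "unobserved parent")

  # quadrature oracle: E[gene | parents, class] by grid integration of
  # the gene's conditional density
  fitted <- fit_parameters(network_structure(ds$gene_ids, "1PB",
                                             gene_edges = rbind(c("a", "b"))),
                           ds)
  obs <- ds$values[, 7L]
  cls <- ds$class_labels[7L]
  fam <- fitted$params$b$families[[as.character(cls)]]
  grid <- seq(-15, 15, length.out = 20001L)
  dens <- dnorm(grid, fam$intercept + fam$coef[["a"]] * obs[["a"]],
                sqrt(fam$var))
  oracle <- sum(grid * dens) / sum(dens)
  expect_equal(predict_gene(fitted, obs, cls, "b"), oracle, tolerance = 1e-4)
})

test_that("class posterior matches symmetry, degenerate prior, and enumeration", {
  # symmetric two-state model, sample equidistant from both state means
  vals <- rbind(g = c(-1, -1, -1, 1, 1, 1))
  colnames(vals) <- paste0("s", 1:6)
  ds <- expression_dataset(vals, rep(c(0L, 1L), each = 3L))
  m <- fit_parameters(snb_structure("g"), ds)
  m$params$g$families[["0"]]$var <- 1
  m$params$g$families[["1"]]$var <- 1
  expect_equal(predict_class(m, c(g = 0)), 0.5, tolerance = 1e-12)

  # degenerate prior forces the posterior
  m1 <- m; m1$class_prior <- 1
  expect_equal(predict_class(m1, c(g = -5)), 1)

  # enumeration oracle on a 3-gene model
  ds3 <- chain_dataset(n = 60L, seed = 17)
  fit3 <- fit_parameters(network_structure(ds3$gene_ids, "1PB",
                                           gene_edges = rbind(c("a", "b"),
                                                              c("b", "c"))),
                         ds3)
  obs <- ds3$values[, 11L]
  joint <- vapply(c(0L, 1L), function(s) {
    prior <- if (s == 1L) fit3$class_prior else 1 - fit3$class_prior
    dens <- prior
    for (g in ds3$gene_ids) {
      pg <- fit3$params[[g]]
      fam <- pg$families[[as.character(s)]]
      mu <- fam$intercept + sum(fam$coef * obs[pg$parents])
      dens <- dens * dnorm(obs[[g]], mu, sqrt(fam$var))
    }
    dens
  }, 1.0)
  expect_equal(predict_class(fit3, obs), joint[2] / sum(joint),
               tolerance = 1e-10)
})

test_that("fitted models round-trip through the JSON dump", {
  ds <- chain_dataset(n = 60L, seed = 19)
  st <- network_structure(ds$gene_ids, "1PB",
                          gene_edges = rbind(c("a", "b"), c("b", "c")))
  m <- fit_parameters(st, ds)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_identical(back$structure$parents, m$structure$parents)
  expect_equal(back$class_prior, m$class_prior)
  expect_equal(back$n_train, m$n_train)
  # reloaded model scores data identically
  expect_equal(log_likelihood(back, ds), log_likelihood(m, ds),
               tolerance = 1e-12)
  expect_equal(per_gene_sse(back, ds)$sse, per_gene_sse(m, ds)$sse,
               tolerance = 1e-12)
})
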