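# Small in-code fixtures shared across the suite.

# Random expression dataset: iid standard normal, balanced classes.
toy_dataset <- function(n_genes = 6L, n_samples = 20L, seed = 1L,
                        name = "toy") {
  stopifnot(n_samples %% 2L == 0L)
  vals <- withr_seed(seed, matrix(rnorm(n_genes * n_samples),
                                  n_genes, n_samples))
  rownames(vals) <- sprintf("g%02d", seq_len(n_genes))
  colnames(vals) <- sprintf("s%02d", seq_len(n_samples))
  expression_dataset(vals, rep(c(0L, 1L), each = n_samples / 2L),
                     name = name)
}

# Dataset generated from a known one-parent chain:
# class -> every gene; a -> b -> c; d independent.
chain_dataset <- function(n = 100L, seed = 42L, noise = c(0.5, 0.3, 0.4)) {
  withr_seed(seed, {
    cls <- rep(c(0L, 1L), each = n / 2L)
    a <- 1.0 * cls + rnorm(n, 0, noise[1L])
    b <- 0.8 * a + 0.5 * cls + rnorm(n, 0, noise[2L])
    cc <- -0.7 * b + rnorm(n, 0, noise[3L])
    d <- rnorm(n)
    vals <- rbind(a = a, b = b, c = cc, d = d)
    colnames(vals) <- sprintf("s%03d", seq_len(n))
    expression_dataset(vals, cls, name = "chain")
  })
}

# Run expr with a temporary seed, restoring RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Independent brute-force log-likelihood: naive per-sample product of
# densities, written without reusing the package's family helpers.
brute_force_loglik <- function(model, ds) {
  st <- model$structure
  total <- 0
  for (s in seq_along(ds$sample_ids)) {
    cls <- ds$class_labels[s]
    prior <- if (cls == 1L) model$class_prior else 1 - model$class_prior
    lp <- log(prior)
    for (g in st$genes) {
      pg <- model$params[[g]]
      fam <- if (pg$by_class) pg$families[[as.character(cls)]]
             else pg$families$all
      mu <- fam$intercept
      for (p in pg$parents) mu <- mu + fam$coef[[p]] * ds$values[p, s]
      lp <- lp + dnorm(ds$values[g, s], mu, sqrt(fam$var), log = TRUE)
    }
    total <- total + lp
  }
  total
}
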