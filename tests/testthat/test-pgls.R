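# helpers to build a random regression instance on a random small tree
random_instance <- function(n, k = 2) {
  tr <- random_small_tree(n)
  C <- phylo_vcv(tr)
  X <- cbind(1, matrix(rnorm(n * (k - 1)), n))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(k - 1)))
  beta <- rnorm(k)
  y <- drop(X %*% beta) + drop(crossprod(chol(C), rnorm(n)))
  list(tree = tr, C = C, X = X, y = y)
}

test_that("gls_fit reduces to the sample mean on a star tree", {
  g <- gls_fit(c(1, 2, 3), matrix(1, 3, 1), diag(3))
  expect_equal(unname(g$beta), 2)
  expect_equal(g$sigma2, 2 / 3)
  # closed-form Gaussian likelihood at the ML variance
  expect_equal(g$logLik, -0.5 * (3 * log(2 * pi * 2 / 3) + 0 + 3),
               tolerance = 1e-12)
})

test_that("gls_fit matches the Cholesky-whitening OLS oracle", {
  set.seed(201)
  for (i in 1:20) {
    inst <- random_instance(sample(5:10, 1))
    g <- gls_fit(inst$y, inst$X, inst$C)
    o <- oracle_gls(inst$y, inst$X, inst$C)
    expect_equal(unname(g$beta), o$beta, tolerance = 1e-8)
    expect_equal(unname(g$se), o$se, tolerance = 1e-8)
    expect_equal(g$logLik, o$logLik, tolerance = 1e-8)
  }
})

test_that("gls_fit with identity covariance equals ordinary regression", {
  set.seed(202)
  n <- 30
  x <- rnorm(n)
  y <- 1 + 2 * x + rnorm(n)
  g <- gls_fit(y, cbind(1, x), diag(n))
  lf <- summary(lm(y ~ x))
  expect_equal(unname(g$beta), unname(coef(lf)[, 1]), tolerance = 1e-10)
  expect_equal(unname(g$se), unname(coef(lf)[, 2]), tolerance = 1e-10)
})

test_that("gls_fit rejects singular covariance and rank-deficient designs", {
  C <- matrix(1, 3, 3)
  expect_error(gls_fit(1:3, matrix(1, 3, 1), C), "singular|positive definite")
  X <- cbind(1, c(1, 1, 1))
  expect_error(gls_fit(1:3, X, diag(3)), "rank deficient")
})

test_that("lambda estimation matches an exhaustive fine grid search", {
  set.seed(203)
  for (i in 1:5) {
    tr <- random_small_tree(10)
    C <- phylo_vcv(tr)
    lam_true <- runif(1, 0.2, 0.9)
    y <- drop(crossprod(chol(lambda_transform(C, lam_true)), rnorm(10)))
    X <- matrix(1, 10, 1, dimnames = list(NULL, "(Intercept)"))
    fit <- phylofreq:::.fit_lambda(y, X, C = C)
    o <- oracle_lambda_grid(y, X, C)
    expect_lt(abs(fit$logLik - o$logLik), 1e-6)
    expect_lt(abs(fit$lambda - o$lambda), 1e-3)
  }
})

test_that("a star tree yields a flat profile, lambda 0 and a flag", {
  star <- ape::stree(6, "star")
  star$edge.length <- rep(1, 6)
  d <- data.frame(species = star$tip.label, y = rnorm(6))
  fit <- pgls_fit(d, y ~ 1, star)
  expect_true(fit$profile_flat)
  expect_equal(fit$lambda, 0)
})

test_that("lambda recovery: Brownian traits near 1, iid noise near 0", {
  tr <- sim_yule_tree(250, seed = 7)
  d <- data.frame(species = sort(tr$tip.label))
  d$bm <- sim_trait(tr, lambda = 1, seed = 8)[d$species]
  d$noise <- withr::with_seed(9, rnorm(250))
  expect_gt(phylo_signal(d, bm, tr)$lambda, 0.9)
  expect_lt(phylo_signal(d, noise, tr)$lambda, 0.1)
})

test_that("lambda and likelihood agree with phytools::phylosig", {
  skip_if_not_installed("phytools")
  tr <- sim_yule_tree(120, seed = 31)
  x <- sim_trait(tr, lambda = 0.6, seed = 32)
  d <- data.frame(species = names(x), x = unname(x))
  fit <- phylo_signal(d, x, tr)
  ps <- phytools::phylosig(tr, x[tr$tip.label], method = "lambda")
  expect_equal(fit$lambda, ps$lambda, tolerance = 1e-3)
  expect_equal(fit$logLik, ps$logL, tolerance = 1e-4)
})

test_that("AIC bookkeeping counts coefficients plus sigma^2 and lambda", {
  sim <- sim_study(n_tips = 40, n_trees = 1, seed = 11)
  fit <- pgls_fit(sim$traits, song_peak ~ log10(mass_g), sim$base_tree)
  expect_equal(fit$AIC, 2 * (fit$k + 2) - 2 * fit$logLik)
  td <- tidy(fit)
  expect_equal(td$p.value,
               2 * pt(-abs(td$statistic), df = fit$n - fit$k))
})

test_that("standardized slopes follow beta * sd_x / sd_y and are unit invariant", {
  expect_equal(standardize_coefficient(-2, 1, 4), -0.5)
  expect_equal(standardize_coefficient(0, 3, 2), 0)
  expect_error(standardize_coefficient(1, 1, 0), "positive")

  sim <- sim_study(n_tips = 60, n_trees = 1, seed = 12)
  f1 <- pgls_fit(sim$traits, song_peak ~ log10(mass_g), sim$base_tree)
  tr2 <- sim$traits
  tr2$mass_mg <- tr2$mass_g * 1000 # unit change: x10^3
  f2 <- pgls_fit(tr2, song_peak ~ log10(mass_mg), sim$base_tree)
  expect_equal(tidy(f1)$beta_st[2], tidy(f2)$beta_st[2], tolerance = 1e-4)
})

test_that("degenerate inputs error informatively", {
  tr <- sim_yule_tree(10, seed = 5)
  d <- data.frame(species = sort(tr$tip.label), y = 1)
  expect_error(pgls_fit(d, y ~ 1, tr), "zero variance")
  d2 <- data.frame(species = sort(tr$tip.label)[1:4], y = rnorm(4),
                   x1 = rnorm(4), x2 = rnorm(4), x3 = rnorm(4))
  expect_error(pgls_fit(d2, y ~ x1 + x2 + x3, tr), "at least")
})

test_that("species absent from the tree are dropped with a message", {
  tr <- sim_yule_tree(20, seed = 6)
  d <- data.frame(species = c(sort(tr$tip.label), "ghost"),
                  y = rnorm(21), x = rnorm(21))
  expect_message(fit <- pgls_fit(d, y ~ x, tr), "absent from the tree")
  expect_equal(fit$n, 20)
})
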