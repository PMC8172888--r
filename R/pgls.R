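# Maximum-likelihood PGLS with Pagel's lambda.
#
# The lambda profile is computed from a single symmetric eigendecomposition
# per covariance matrix: with D = diag(diag(C)) and C* = D^{-1/2} C D^{-1/2},
# the lambda-rescaled covariance factors as
#   C(lambda) = D^{1/2} Q (lambda E + (1 - lambda) I) Q' D^{1/2},
# so after scaling by D^{-1/2} and rotating by Q' every lambda reduces to a
# weighted least-squares problem with weights w_i = lambda e_i + (1 - lambda).
# This holds for any valid tree (no ultrametricity assumption).

.pgls_decomp <- function(C) {
  d <- diag(C)
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop_pf("covariance diagonal must be positive (zero-length root-to-tip path?)")
  }
  s <- sqrt(d)
  Cstar <- C / tcrossprod(s)
  eg <- eigen(Cstar, symmetric = TRUE)
  list(
    rot = t(eg$vectors),
    values = pmax(eg$values, 0),
    logdet_d = sum(log(d)),
    s = s,
    taxa = rownames(C)
  )
}

# Profile log-likelihood (sigma^2 profiled out) at one lambda, in the rotated
# coordinate system. With full = TRUE returns the complete fit at that lambda.
.gls_rotated <- function(lambda, yt, Xt, ev, logdet_d,
                         full = FALSE, se_method = "unbiased") {
  n <- length(yt)
  w <- lambda * ev + (1 - lambda)
  if (any(w < 1e-12)) {
    if (!full) return(-Inf)
    stop_pf("covariance is singular at lambda = ", signif(lambda, 4))
  }
  sw <- sqrt(w)
  yw <- yt / sw
  Xw <- Xt / sw
  qrX <- qr(Xw)
  k <- ncol(Xw)
  if (qrX$rank < k) stop_pf("design matrix is rank deficient")
  beta <- qr.coef(qrX, yw)
  rss <- sum((yw - Xw %*% beta)^2)
  sigma2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) + sum(log(w)) + logdet_d + n)
  if (!full) return(ll)
  s2 <- if (identical(se_method, "ml")) sigma2 else rss / (n - k)
  vc <- s2 * solve(crossprod(Xw))
  list(beta = drop(beta), se = sqrt(diag(vc)), sigma2 = sigma2, s2 = s2,
       logLik = ll, vcov = vc)
}

# Optimize lambda in [0, 1]: coarse grid then local refinement around the
# grid optimum. A profile flat to within 1e-8 (star phylogeny) returns
# lambda = 0 with a flag.
#
# The profile likelihood is evaluated from weighted sufficient statistics:
# with rotated variables m = [X~, y~] and per-lambda weights w, every
# entry of [X'C^-1X, X'C^-1y; ., y'C^-1y] is a weighted column sum of the
# elementwise products m_i * m_j, so the whole grid costs one
# (n x features) by (n x lambdas) product plus small k x k solves.
.fit_lambda <- function(y, X, C = NULL, decomp = NULL, lambda = NULL,
                        se_method = "unbiased", grid_step = 0.01,
                        profile = FALSE) {
  n <- length(y)
  k <- ncol(X)
  if (n < k + 2) {
    stop_pf("need at least ", k + 2, " species to fit ", k,
            " coefficients plus sigma^2 and lambda; got ", n)
  }
  dec <- decomp %||% .pgls_decomp(C)
  yt <- drop(dec$rot %*% (y / dec$s))
  Xt <- dec$rot %*% (X / dec$s)
  ev <- dec$values
  if (qr(Xt)$rank < k) stop_pf("design matrix is rank deficient")

  m <- cbind(Xt, yt)
  k1 <- k + 1L
  pair_idx <- which(upper.tri(diag(k1), diag = TRUE), arr.ind = TRUE)
  P <- m[, pair_idx[, 1], drop = FALSE] * m[, pair_idx[, 2], drop = FALSE]
  lin_idx <- pair_idx[, 1] + (pair_idx[, 2] - 1L) * k1
  ll_vec <- function(lams) {
    W <- ev %o% lams + matrix(1 - lams, n, length(lams), byrow = TRUE)
    ok <- colSums(W < 1e-12) == 0
    W[, !ok] <- NA_real_
    S <- crossprod(P, 1 / W)
    logw <- colSums(log(W))
    vapply(seq_along(lams), function(j) {
      if (!ok[j]) return(-Inf)
      Af <- matrix(0, k1, k1)
      Af[lin_idx] <- S[, j]
      Af <- Af + t(Af) - diag(diag(Af), k1)
      A <- Af[seq_len(k), seq_len(k), drop = FALSE]
      b <- Af[seq_len(k), k1]
      beta <- tryCatch(solve(A, b), error = function(e) NULL)
      if (is.null(beta)) return(-Inf)
      rss <- max(Af[k1, k1] - sum(b * beta), 1e-300)
      -0.5 * (n * log(2 * pi * rss / n) + logw[j] + dec$logdet_d + n)
    }, numeric(1))
  }
  obj <- function(l) ll_vec(l)

  profile_flat <- FALSE
  prof <- NULL
  if (is.null(lambda)) {
    grid <- seq(0, 1, by = grid_step)
    ll_grid <- ll_vec(grid)
    if (profile) prof <- tibble::tibble(lambda = grid, logLik = ll_grid)
    if (max(ll_grid) - min(ll_grid) < 1e-8) {
      profile_flat <- TRUE
      lambda_hat <- 0
    } else {
      i <- which.max(ll_grid)
      lo <- grid[max(1L, i - 1L)]
      hi <- grid[min(length(grid), i + 1L)]
      opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-7)
      lambda_hat <- if (opt$objective >= ll_grid[i]) opt$maximum else grid[i]
      # snap to the boundary when the optimum sits against it
      if (lambda_hat < 1e-6) lambda_hat <- 0
      if (lambda_hat > 1 - 1e-6 && ll_grid[length(grid)] >= obj(lambda_hat)) {
        lambda_hat <- 1
      }
    }
  } else {
    if (lambda < 0 || lambda > 1) stop_pf("`lambda` must be in [0, 1]")
    lambda_hat <- lambda
  }

  fit <- .gls_rotated(lambda_hat, yt, Xt, ev, dec$logdet_d,
                      full = TRUE, se_method = se_method)
  names(fit$beta) <- colnames(X)
  names(fit$se) <- colnames(X)
  fitted <- drop(X %*% fit$beta)
  residuals <- y - fitted
  names(fitted) <- names(residuals) <- dec$taxa

  # free parameters: regression coefficients + sigma^2 + lambda
  aic <- 2 * (k + 2) - 2 * fit$logLik
  tval <- fit$beta / fit$se
  pval <- 2 * stats::pt(-abs(tval), df = n - k)

  list(lambda = lambda_hat, beta = fit$beta, se = fit$se,
       statistic = tval, p.value = pval,
       sigma2 = fit$sigma2, logLik = fit$logLik, AIC = aic,
       n = n, k = k, df.residual = n - k,
       fitted = fitted, residuals = residuals,
       profile = prof, profile_flat = profile_flat)
}

#' Generalized least squares with a fixed phylogenetic covariance
#'
#' The fixed-covariance inner solver of the PGLS machinery, exposed for
#' transparency and testing. Estimates
#' \eqn{\hat\beta = (X'C^{-1}X)^{-1} X'C^{-1} y} via Cholesky whitening, the
#' profiled ML variance \eqn{\hat\sigma^2 = e'C^{-1}e/n}, and the full
#' multivariate-normal log-likelihood
#' \eqn{-\tfrac12[n\log(2\pi\hat\sigma^2) + \log|C| + n]}.
#'
#' @param y Numeric response vector.
#' @param X Design matrix (rows aligned with `y` and `C`).
#' @param C Positive-definite covariance matrix.
#' @param se_method `"unbiased"` (default) uses the residual-variance
#'   denominator `n - k` for standard errors, the convention in GLS software;
#'   `"ml"` uses the ML variance (denominator `n`).
#' @return List with `beta`, `se`, `sigma2` (ML), `logLik`, `fitted`,
#'   `residuals`, `n`, `k`.
#' @export
gls_fit <- function(y, X, C, se_method = c("unbiased", "ml")) {
  se_method <- match.arg(se_method)
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || nrow(C) != n || ncol(C) != n) {
    stop_pf("y, X and C must be aligned on the same species order")
  }
  U <- tryCatch(chol(C), error = function(e) {
    stop_pf("covariance matrix is singular or not positive definite ",
            "(reciprocal condition number ~ ", signif(rcond(C), 3), ")")
  })
  yw <- backsolve(U, y, transpose = TRUE)
  Xw <- backsolve(U, X, transpose = TRUE)
  qrX <- qr(Xw)
  k <- ncol(X)
  if (qrX$rank < k) stop_pf("design matrix is rank deficient")
  beta <- drop(qr.coef(qrX, yw))
  rss <- sum((yw - Xw %*% beta)^2)
  sigma2 <- rss / n
  logdet <- 2 * sum(log(diag(U)))
  ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  s2 <- if (se_method == "ml") sigma2 else rss / (n - k)
  se <- sqrt(diag(s2 * solve(crossprod(Xw))))
  names(beta) <- names(se) <- colnames(X)
  fitted <- drop(X %*% beta)
  list(beta = beta, se = se, sigma2 = sigma2, logLik = ll,
       fitted = fitted, residuals = y - fitted, n = n, k = k)
}

#' Fit a PGLS regression with maximum-likelihood Pagel's lambda
#'
#' Fits `formula` on `data` with residual covariance
#' \eqn{\sigma^2 C(\lambda)}, where `C` is the Brownian covariance of `tree`
#' and lambda rescales its off-diagonals. Lambda is estimated by maximizing
#' the profile likelihood over \[0, 1\] (coarse grid plus local refinement)
#' unless fixed via `lambda`. Rows with missing model variables are dropped
#' (row-wise deletion per model); species absent from the tree are dropped
#' with a message. Coefficients are also reported standardized
#' (\eqn{\beta_{st} = \beta \cdot sd(x)/sd(y)}), the scale on which slopes
#' are compared across models.
#'
#' @param data Data frame with one row per species.
#' @param formula Model formula; transforms such as `log10(mass_g)` may be
#'   used inline.
#' @param tree An [ape::phylo] whose tips cover the modelled species.
#' @param species Name of the species-identifier column in `data`.
#' @param lambda Optional fixed lambda in \[0, 1\]; `NULL` (default)
#'   estimates it by ML.
#' @param se_method `"unbiased"` (default) or `"ml"`; see [gls_fit()].
#' @param profile If `TRUE`, store the lambda profile grid in the fit.
#' @param grid_step Grid step for the coarse lambda search.
#' @return An object of class `pgls_fit`; see [tidy.pgls_fit()] and
#'   [glance.pgls_fit()].
#' @examples
#' sim <- sim_study(n_tips = 50, n_trees = 1, seed = 1)
#' fit <- pgls_fit(sim$traits, song_peak ~ log10(mass_g), sim$base_tree)
#' tidy(fit)
#' @export
pgls_fit <- function(data, formula, tree, species = "species",
                     lambda = NULL, se_method = c("unbiased", "ml"),
                     profile = FALSE, grid_step = 0.01) {
  se_method <- match.arg(se_method)
  stopifnot(is.data.frame(data))
  if (!species %in% names(data)) {
    stop_pf("column `", species, "` not found in `data`")
  }
  spp_all <- as.character(data[[species]])
  if (anyDuplicated(spp_all)) stop_pf("species ids must be unique")
  prep <- NULL
  if (inherits(tree, "pgls_prepared_tree")) {
    prep <- tree
    tree <- prep$tree
  }
  validate_phylo(tree)

  df <- as.data.frame(data)
  rownames(df) <- spp_all
  mf <- stats::model.frame(formula, df, na.action = stats::na.omit)
  keep_finite <- apply(as.matrix(mf), 1L, function(r) all(is.finite(r)))
  mf <- mf[keep_finite, , drop = FALSE]
  spp <- rownames(mf)

  off_tree <- setdiff(spp, tree$tip.label)
  if (length(off_tree) > 0) {
    message(length(off_tree), " species absent from the tree dropped (",
            paste(utils::head(off_tree, 3), collapse = ", "),
            if (length(off_tree) > 3) ", ..." else "", ")")
    mf <- mf[setdiff(spp, off_tree), , drop = FALSE]
    spp <- rownames(mf)
  }
  if (length(spp) < 4) stop_pf("fewer than 4 usable species")

  if (!is.null(prep) && length(spp) == length(prep$decomp$taxa) &&
      setequal(spp, prep$decomp$taxa)) {
    # reuse the precomputed decomposition for this tree
    C <- NULL
    dec <- prep$decomp
    mf <- mf[dec$taxa, , drop = FALSE]
  } else {
    tr <- if (length(spp) < length(tree$tip.label)) {
      prune_to_taxa(tree, spp)
    } else {
      tree
    }
    C <- phylo_vcv(tr)
    dec <- NULL
    mf <- mf[rownames(C), , drop = FALSE]
  }
  spp <- rownames(mf)

  y <- stats::model.response(mf)
  if (stats::var(y) == 0) {
    stop_pf("response has zero variance (degenerate trait)")
  }
  X <- stats::model.matrix(attr(mf, "terms"), mf)

  fit <- .fit_lambda(y, X, C = C, decomp = dec, lambda = lambda,
                     se_method = se_method,
                     grid_step = grid_step, profile = profile)

  sd_y <- stats::sd(y)
  sd_x <- apply(X, 2L, stats::sd)
  is_icpt <- colnames(X) == "(Intercept)"
  scale_f <- ifelse(is_icpt, NA_real_, sd_x / sd_y)

  coefs <- tibble::tibble(
    term = colnames(X),
    estimate = unname(fit$beta),
    std.error = unname(fit$se),
    beta_st = unname(fit$beta * scale_f),
    std.error_st = unname(fit$se * scale_f),
    statistic = unname(fit$statistic),
    p.value = unname(fit$p.value)
  )

  structure(
    list(coefficients = coefs, lambda = fit$lambda, sigma2 = fit$sigma2,
         logLik = fit$logLik, AIC = fit$AIC, n = fit$n, k = fit$k,
         df.residual = fit$df.residual, fitted = fit$fitted,
         residuals = fit$residuals, profile = fit$profile,
         profile_flat = fit$profile_flat, sd_y = sd_y,
         formula = formula, species = spp, se_method = se_method),
    class = "pgls_fit"
  )
}

#' Phylogenetic signal of a trait (Pagel's lambda)
#'
#' Maximum-likelihood lambda for a single trait: an intercept-only PGLS fit.
#' Lambda near 1 means trait similarity tracks phylogenetic relatedness under
#' Brownian motion; lambda near 0 means phylogenetic independence.
#'
#' @param data Data frame with one row per species.
#' @param trait Trait column, unquoted; inline transforms such as
#'   `log10(mass_g)` are allowed.
#' @param tree An [ape::phylo] object.
#' @param species Species-id column name.
#' @param profile If `TRUE`, keep the lambda profile (see [autoplot.pgls_fit()]).
#' @param ... Passed to [pgls_fit()].
#' @return A `phylo_signal` object (a `pgls_fit` carrying the trait name).
#' @examples
#' sim <- sim_study(n_tips = 50, n_trees = 1, seed = 1)
#' phylo_signal(sim$traits, log10(mass_g), sim$base_tree)
#' @export
phylo_signal <- function(data, trait, tree, species = "species",
                         profile = FALSE, ...) {
  expr <- rlang::enexpr(trait)
  lab <- rlang::expr_deparse(expr)
  f <- stats::as.formula(paste(lab, "~ 1"), env = parent.frame())
  out <- pgls_fit(data, f, tree, species = species, profile = profile, ...)
  out$trait <- lab
  class(out) <- c("phylo_signal", class(out))
  out
}

#' Standardize a regression slope
#'
#' \eqn{\beta_{st} = \beta \cdot sd(x) / sd(y)}: the slope times the standard
#' deviation of the predictor over the standard deviation of the response,
#' which makes slopes comparable across responses and units. Standard errors
#' standardize with the same factor.
#'
#' @param beta Raw slope.
#' @param sd_x Standard deviation of the predictor (on the modelled scale).
#' @param sd_y Standard deviation of the response; must be positive.
#' @return The standardized slope.
#' @export
standardize_coefficient <- function(beta, sd_x, sd_y) {
  if (any(sd_y <= 0)) stop_pf("`sd_y` must be positive")
  beta * sd_x / sd_y
}
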