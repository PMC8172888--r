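# Hypothesis tests built on averaged PGLS output: comparison of standardized
# allometric slopes between signal classes, the absolute-residual
# heteroscedasticity regression, and within-species measurement
# repeatability.

#' Compare two standardized slopes
#'
#' Tests whether two independently estimated standardized slopes differ,
#' using the difference over the pooled standard error,
#' \eqn{Z = (b_1 - b_2)/\sqrt{se_1^2 + se_2^2}}. With the species counts
#' typical of cross-species allometries (hundreds of species) the normal
#' reference is used by default; a Welch t reference is available when
#' degrees of freedom are supplied.
#'
#' @param b1,b2 Standardized slopes (e.g. AIC-weight-averaged `beta_st`).
#' @param se1,se2 Their standard errors (nonnegative, not both zero).
#' @param method `"normal"` (default) or `"welch"`.
#' @param df1,df2 Residual degrees of freedom for the Welch reference.
#' @return A `slope_comparison` object with the difference, pooled SE,
#'   statistic and two-tailed P.
#' @examples
#' compare_slopes(-0.51, 0.05, -0.38, 0.05)
#' @export
compare_slopes <- function(b1, se1, b2, se2,
                           method = c("normal", "welch"),
                           df1 = Inf, df2 = Inf) {
  method <- match.arg(method)
  if (se1 < 0 || se2 < 0) stop_pf("standard errors must be nonnegative")
  if (se1 == 0 && se2 == 0) stop_pf("both standard errors are zero")
  se <- sqrt(se1^2 + se2^2)
  z <- (b1 - b2) / se
  if (method == "normal") {
    df <- Inf
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    df <- se^4 / (se1^4 / df1 + se2^4 / df2)
    p <- 2 * stats::pt(-abs(z), df = df)
  }
  structure(
    list(difference = b1 - b2, se = se, statistic = z, p.value = p,
         method = method, df = df),
    class = "slope_comparison"
  )
}

#' Regress absolute averaged residuals on a predictor
#'
#' Heteroscedasticity test: takes the per-species weight-averaged residuals
#' of an averaged PGLS fit, their absolute values (large values = larger
#' deviation from the fitted optimum), and regresses them on a predictor
#' with a fresh lambda-PGLS on every tree, averaging the results. Residuals
#' are averaged across trees first and the absolute value taken afterwards.
#'
#' @param avg_fit A `pgls_average` carrying per-species averaged residuals.
#' @param data Data frame with the predictor column (one row per species).
#' @param predictor Predictor expression as a string, e.g.
#'   `"log10(song_duration)"`.
#' @param trees Tree sample over which to run the regression.
#' @param species Species-id column in `data`.
#' @param ... Passed to [pgls_average()].
#' @return A `pgls_average` for `|residual| ~ predictor`.
#' @export
abs_residual_regression <- function(avg_fit, data, predictor, trees,
                                    species = "species", ...) {
  if (!inherits(avg_fit, "pgls_average")) {
    stop_pf("`avg_fit` must be a `pgls_average`")
  }
  res <- avg_fit$residuals
  df <- tibble::tibble(!!species := names(res), .abs_resid = abs(res))
  miss <- setdiff(names(res), as.character(data[[species]]))
  if (length(miss) > 0) {
    stop_pf("species in residuals but not in `data`: ",
            paste(utils::head(miss, 5), collapse = ", "))
  }
  df <- dplyr::left_join(df, data, by = species)
  f <- stats::reformulate(predictor, response = ".abs_resid")
  pgls_average(df, f, trees, species = species, ...)
}

#' Within-group repeatability (intraclass correlation) from one-way ANOVA
#'
#' The consistency of repeated measurements within groups (here, repeated
#' acoustic measurements within species), estimated from a one-way ANOVA
#' with the unbalanced-design correction: with group sizes \eqn{n_i},
#' \eqn{N = \sum n_i}, \eqn{a} groups,
#' \eqn{n_0 = (N - \sum n_i^2/N)/(a - 1)},
#' \eqn{s^2_A = (MS_A - MS_W)/n_0} and \eqn{R = s^2_A/(s^2_A + MS_W)}.
#' Groups with a single measurement are retained (they contribute to the
#' among-group sums of squares). A negative estimate (no among-group
#' variance) is reported as computed, with a flag, rather than truncated.
#'
#' @param data Long-format data frame: one row per measurement.
#' @param value Measurement column (unquoted).
#' @param group Grouping column (unquoted), e.g. species.
#' @return A `repeatability` object with `R`, mean squares, group count and
#'   effective group size `n0`.
#' @examples
#' d <- data.frame(sp = rep(c("A", "B", "C"), each = 2),
#'                 x = c(1, 2, 3, 4, 5, 6))
#' repeatability(d, x, sp)
#' @export
repeatability <- function(data, value, group) {
  val <- rlang::eval_tidy(rlang::enquo(value), data)
  grp <- as.character(rlang::eval_tidy(rlang::enquo(group), data))
  ok <- is.finite(val) & !is.na(grp)
  val <- val[ok]
  grp <- grp[ok]
  sizes <- table(grp)
  a <- length(sizes)
  N <- length(val)
  if (a < 2) stop_pf("need at least 2 groups")
  if (N - a < 1) {
    stop_pf("all groups are singletons; within-group mean square undefined")
  }
  means <- tapply(val, grp, mean)
  grand <- mean(val)
  ss_a <- sum(as.numeric(sizes) * (means - grand)^2)
  ss_w <- sum((val - means[grp])^2)
  df_a <- a - 1
  df_w <- N - a
  ms_a <- ss_a / df_a
  ms_w <- ss_w / df_w
  n0 <- (N - sum(as.numeric(sizes)^2) / N) / df_a
  s2_a <- (ms_a - ms_w) / n0
  R <- s2_a / (s2_a + ms_w)
  structure(
    list(R = R, ms_among = ms_a, ms_within = ms_w, var_among = s2_a,
         n_groups = a, n_total = N, n0 = n0,
         df_among = df_a, df_within = df_w,
         negative = R < 0),
    class = "repeatability"
  )
}
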