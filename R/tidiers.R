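# broom-style tidiers, print methods and ggplot2 autoplots for the fitted
# objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a PGLS fit
#'
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @return Tibble with one row per model term: `estimate`, `std.error`,
#'   standardized `beta_st` and `std.error_st`, `statistic`, `p.value`.
#' @method tidy pgls_fit
#' @export
tidy.pgls_fit <- function(x, ...) x$coefficients

#' @rdname tidy.pgls_fit
#' @method glance pgls_fit
#' @export
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, sigma2 = x$sigma2, logLik = x$logLik, AIC = x$AIC,
    nobs = x$n, df.residual = x$df.residual, profile_flat = x$profile_flat
  )
}

#' Tidy an averaged PGLS fit
#'
#' @param x A `pgls_average`.
#' @param ... Unused.
#' @return Per-term tibble of weight-averaged quantities.
#' @method tidy pgls_average
#' @export
tidy.pgls_average <- function(x, ...) x$terms

#' @rdname tidy.pgls_average
#' @method glance pgls_average
#' @export
glance.pgls_average <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, nobs = x$n, n_trees = x$n_trees,
    df.residual = x$df.residual, se_average = x$se_average
  )
}

#' @method tidy slope_comparison
#' @export
tidy.slope_comparison <- function(x, ...) {
  tibble::tibble(difference = x$difference, std.error = x$se,
                 statistic = x$statistic, p.value = x$p.value,
                 method = x$method)
}

#' @method tidy repeatability
#' @export
tidy.repeatability <- function(x, ...) {
  tibble::tibble(R = x$R, ms_among = x$ms_among, ms_within = x$ms_within,
                 n_groups = x$n_groups, n_total = x$n_total, n0 = x$n0,
                 negative = x$negative)
}

#' @method glance repeatability
#' @export
glance.repeatability <- tidy.repeatability

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit (ML Pagel's lambda)\n")
  cat(sprintf("  lambda = %.4f%s  sigma2 = %.4g  logLik = %.3f  AIC = %.2f  n = %d\n",
              x$lambda, if (isTRUE(x$profile_flat)) " [profile flat]" else "",
              x$sigma2, x$logLik, x$AIC, x$n))
  print(x$coefficients)
  invisible(x)
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat(sprintf("Phylogenetic signal of %s: lambda = %.4f (logLik = %.3f, n = %d)%s\n",
              x$trait, x$lambda, x$logLik, x$n,
              if (isTRUE(x$profile_flat)) " [profile flat]" else ""))
  invisible(x)
}

#' @export
print.pgls_average <- function(x, ...) {
  cat(sprintf("AIC-weight-averaged PGLS over %d trees (lambda = %.4f, n = %d)\n",
              x$n_trees, x$lambda, x$n))
  print(x$terms)
  invisible(x)
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("Slope comparison: difference = %.4f, Z = %.3f, two-tailed P = %.4g (%s)\n",
              x$difference, x$statistic, x$p.value, x$method))
  invisible(x)
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("Repeatability (one-way ANOVA ICC): R = %.4f over %d groups (n0 = %.2f)%s\n",
              x$R, x$n_groups, x$n0,
              if (x$negative) " [negative estimate: no among-group variance]" else ""))
  invisible(x)
}

#' @export
print.allometry_comparison <- function(x, ...) {
  cat("Song allometry:\n"); print(x$song)
  cat("Call allometry:\n"); print(x$call)
  cat(sprintf("Comparison of standardized %s slopes:\n", x$mass_term))
  print(x$comparison)
  invisible(x)
}

#' @export
print.duration_models <- function(x, ...) {
  cat("Full model (with duration):\n"); print(x$full_fit)
  cat("Absolute-residual regression on duration:\n")
  print(x$abs_residual_fit)
  cat("Collinearity report (pairwise PGLS):\n")
  print(x$collinearity)
  invisible(x)
}

#' Plot the lambda likelihood profile or coefficients of a PGLS fit
#'
#' With a stored profile (see `profile = TRUE` in [pgls_fit()]) draws the
#' lambda profile log-likelihood with the ML estimate marked; otherwise a
#' standardized-coefficient dot-and-interval plot.
#'
#' @param object A `pgls_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pgls_fit
#' @export
autoplot.pgls_fit <- function(object, ...) {
  if (!is.null(object$profile)) {
    ggplot2::ggplot(object$profile,
                    ggplot2::aes(x = .data$lambda, y = .data$logLik)) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = object$lambda, linetype = 2) +
      ggplot2::labs(x = expression(lambda), y = "profile log-likelihood")
  } else {
    autoplot_terms(object$coefficients)
  }
}

#' Plot averaged PGLS coefficients
#'
#' Standardized coefficients with approximate 95% intervals from the
#' weight-averaged standard errors.
#'
#' @param object A `pgls_average`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pgls_average
#' @export
autoplot.pgls_average <- function(object, ...) {
  autoplot_terms(object$terms)
}

autoplot_terms <- function(terms) {
  d <- terms[terms$term != "(Intercept)", , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta_st, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$beta_st - 1.96 * .data$std.error_st,
                   xmax = .data$beta_st + 1.96 * .data$std.error_st),
      height = 0.15) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = expression(beta[st]), y = NULL)
}

#' @importFrom rlang .data :=
NULL
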