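# AIC-weighted averaging of per-tree PGLS fits across a sample of
# phylogenies, the device used to propagate phylogenetic uncertainty into
# the reported statistics.

#' Akaike weights
#'
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} with
#' \eqn{\Delta_i = AIC_i - \min(AIC)}. Invariant to adding a constant to all
#' AIC values.
#'
#' @param aic Numeric vector of finite AIC values (one per tree's model).
#' @return Nonnegative weights summing to 1.
#' @examples
#' aic_weights(c(100, 102))
#' @export
aic_weights <- function(aic) {
  if (length(aic) == 0) stop_pf("`aic` is empty")
  if (any(!is.finite(aic))) stop_pf("non-finite AIC value")
  w <- exp(-(aic - min(aic)) / 2)
  w / sum(w)
}

#' Average PGLS fits across trees with Akaike weights
#'
#' Combines per-tree [pgls_fit()] objects sharing the same model and species
#' set into a single averaged result: every reported quantity (coefficients,
#' standard errors, standardized slopes, lambda, per-species residuals) is
#' the AIC-weight-averaged value across trees. P-values are recomputed from
#' the averaged estimate and standard error on a t reference with
#' `n - k` degrees of freedom (they are not averaged directly).
#'
#' @param fits List of `pgls_fit` objects from the same model fitted on
#'   different trees.
#' @param se_average `"weighted"` (default) averages per-tree standard errors
#'   directly; `"unconditional"` adds the between-tree spread of the
#'   estimates, \eqn{\sqrt{\sum_i w_i (se_i^2 + (\beta_i - \bar\beta)^2)}}.
#' @return An object of class `pgls_average`.
#' @export
average_fits <- function(fits, se_average = c("weighted", "unconditional")) {
  se_average <- match.arg(se_average)
  if (length(fits) == 0) stop_pf("`fits` is empty")
  if (!all(vapply(fits, inherits, logical(1), "pgls_fit"))) {
    stop_pf("`fits` must be a list of `pgls_fit` objects")
  }
  terms0 <- fits[[1]]$coefficients$term
  spp0 <- names(fits[[1]]$residuals)
  for (f in fits[-1]) {
    if (!identical(f$coefficients$term, terms0)) {
      stop_pf("fits have mismatched model terms")
    }
    if (!identical(names(f$residuals), spp0)) {
      stop_pf("fits have mismatched species sets")
    }
  }

  aics <- vapply(fits, `[[`, numeric(1), "AIC")
  w <- aic_weights(aics)
  wavg <- function(field) {
    m <- vapply(fits, function(f) f$coefficients[[field]],
                numeric(length(terms0)))
    m <- matrix(m, nrow = length(terms0))
    drop(m %*% w)
  }

  est <- wavg("estimate")
  se_w <- wavg("std.error")
  bst <- wavg("beta_st")
  bst_se_w <- wavg("std.error_st")
  if (se_average == "unconditional") {
    estm <- matrix(vapply(fits, function(f) f$coefficients$estimate,
                          numeric(length(terms0))), nrow = length(terms0))
    sem <- matrix(vapply(fits, function(f) f$coefficients$std.error,
                         numeric(length(terms0))), nrow = length(terms0))
    se <- sqrt(drop((sem^2 + (estm - est)^2) %*% w))
    bstm <- matrix(vapply(fits, function(f) f$coefficients$beta_st,
                          numeric(length(terms0))), nrow = length(terms0))
    bstsem <- matrix(vapply(fits, function(f) f$coefficients$std.error_st,
                            numeric(length(terms0))), nrow = length(terms0))
    bst_se <- sqrt(drop((bstsem^2 + (bstm - bst)^2) %*% w))
  } else {
    se <- se_w
    bst_se <- bst_se_w
  }

  n <- round(sum(w * vapply(fits, `[[`, numeric(1), "n")))
  k <- fits[[1]]$k
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), df = n - k)

  resid_m <- vapply(fits, `[[`, numeric(length(spp0)), "residuals")
  resid_m <- matrix(resid_m, nrow = length(spp0),
                    dimnames = list(spp0, NULL))
  residuals <- drop(resid_m %*% w)

  lambda <- sum(w * vapply(fits, `[[`, numeric(1), "lambda"))

  per_tree <- tibble::tibble(
    tree = seq_along(fits),
    lambda = vapply(fits, `[[`, numeric(1), "lambda"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    AIC = aics,
    weight = w
  )

  structure(
    list(
      terms = tibble::tibble(term = terms0, estimate = est, std.error = se,
                             beta_st = bst, std.error_st = bst_se,
                             statistic = tval, p.value = pval),
      lambda = lambda, weights = w, n_trees = length(fits), n = n, k = k,
      df.residual = n - k, residuals = residuals, per_tree = per_tree,
      se_average = se_average, formula = fits[[1]]$formula
    ),
    class = "pgls_average"
  )
}

#' Fit one PGLS model across a sample of trees and average the results
#'
#' The per-tree unit of analysis is a [pgls_fit()] with its own
#' maximum-likelihood lambda; results are then combined with
#' [average_fits()] using Akaike weights derived from each tree's model AIC.
#'
#' @inheritParams pgls_fit
#' @param trees A `multiPhylo` object, list of trees, or single `phylo`.
#' @param se_average Passed to [average_fits()].
#' @param keep_fits If `TRUE`, attach the list of per-tree fits.
#' @param ... Passed to [pgls_fit()].
#' @return A `pgls_average` object.
#' @examples
#' sim <- sim_study(n_tips = 40, n_trees = 5, seed = 1)
#' avg <- pgls_average(sim$traits, song_peak ~ log10(mass_g) + habitat_forest,
#'                     sim$trees)
#' tidy(avg)
#' @export
pgls_average <- function(data, formula, trees, species = "species",
                         se_average = c("weighted", "unconditional"),
                         keep_fits = FALSE, ...) {
  se_average <- match.arg(se_average)
  trees <- as_tree_list(trees)
  fits <- lapply(trees, function(tr) {
    pgls_fit(data, formula, tr, species = species, ...)
  })
  out <- average_fits(fits, se_average = se_average)
  if (keep_fits) out$fits <- fits
  out
}

# Normalize phylo / multiPhylo / prepared / list input into a plain list
# whose elements pgls_fit() accepts (phylo or pgls_prepared_tree).
as_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) return(list(trees))
  if (inherits(trees, "pgls_prepared_tree")) return(list(trees))
  if (inherits(trees, c("multiPhylo", "pgls_tree_set"))) return(unclass(trees))
  if (is.list(trees) &&
      all(vapply(trees, inherits, logical(1),
                 c("phylo", "pgls_prepared_tree")))) {
    return(trees)
  }
  stop_pf("`trees` must be a phylo, multiPhylo, pgls_tree_set, ",
          "or list of phylo objects")
}

#' Precompute covariance decompositions for a tree sample
#'
#' Computes each tree's Brownian covariance and its symmetric
#' eigendecomposition once, so that several models fitted on the same
#' species set (e.g. signal estimates for many traits, or the song and
#' duration models) can share them. Every function that takes `trees`
#' accepts the result; models whose species set differs from the tree's
#' full tip set fall back to pruning and decomposing on the fly.
#'
#' @param trees `multiPhylo`, list of trees, or single `phylo`.
#' @return A `pgls_tree_set` usable wherever a tree sample is expected.
#' @examples
#' sim <- sim_study(n_tips = 40, n_trees = 5, seed = 1)
#' prep <- pgls_prepare(sim$trees)
#' avg <- pgls_average(sim$traits, song_peak ~ log10(mass_g), prep)
#' @export
pgls_prepare <- function(trees) {
  if (inherits(trees, "pgls_tree_set")) return(trees)
  trees <- as_tree_list(trees)
  out <- lapply(trees, function(tr) {
    if (inherits(tr, "pgls_prepared_tree")) return(tr)
    validate_phylo(tr)
    structure(list(tree = tr, decomp = .pgls_decomp(phylo_vcv(tr))),
              class = "pgls_prepared_tree")
  })
  class(out) <- "pgls_tree_set"
  out
}
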