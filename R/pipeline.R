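# High-level analysis surface: phylogenetic signal of every trait, the
# song/call allometry comparison, and the song-duration models, each
# AIC-weight-averaged across a tree sample.

default_signal_traits <- function() {
  c(
    song_frequency = "song_peak",
    call_frequency = "call_peak",
    song_duration = "log10(song_duration)",
    body_mass = "log10(mass_g)",
    habitat = "habitat_forest"
  )
}

#' Phylogenetic signal of each trait, averaged across trees
#'
#' For every declared trait, fits an intercept-only lambda-PGLS on every
#' tree in the sample and AIC-weight-averages the lambda estimates.
#' Degenerate traits (zero variance, too few species) are reported with a
#' warning and an `NA` row; the run continues for the remaining traits.
#'
#' @param traits Data frame, one row per species.
#' @param trees Tree sample (`multiPhylo`, list, or single `phylo`).
#' @param trait_cols Named character vector of trait expressions; names
#'   label the output rows. Defaults cover the song/call layout produced by
#'   [sim_study()] with log10 transforms for mass and duration.
#' @param species Species-id column name.
#' @param ... Passed to [pgls_fit()].
#' @return Tibble with columns `trait`, `lambda`, `n_species`, `n_trees`.
#' @export
run_signal <- function(traits, trees, trait_cols = default_signal_traits(),
                       species = "species", ...) {
  trees <- pgls_prepare(trees)
  if (is.null(names(trait_cols))) names(trait_cols) <- trait_cols
  rows <- purrr::imap_dfr(trait_cols, function(expr, label) {
    f <- stats::as.formula(paste(expr, "~ 1"))
    res <- tryCatch({
      fits <- lapply(trees, function(tr) {
        pgls_fit(traits, f, tr, species = species, ...)
      })
      avg <- average_fits(fits)
      tibble::tibble(trait = label, lambda = avg$lambda,
                     n_species = avg$n, n_trees = avg$n_trees)
    }, error = function(e) {
      warning("trait `", label, "` skipped: ", conditionMessage(e),
              call. = FALSE)
      tibble::tibble(trait = label, lambda = NA_real_,
                     n_species = NA_integer_, n_trees = length(trees))
    })
    res
  })
  rows
}

#' Song and call allometry of signal frequency, with slope comparison
#'
#' Fits `frequency ~ log10(mass) + habitat` separately for songs and calls
#' on every tree, AIC-weight-averages each model across trees, and compares
#' the standardized body-mass slopes between the two signal classes with a
#' pooled-SE Z test. Species enter each model by row-wise deletion on its
#' own variables, so the song and call models may use different species
#' counts (reported in the result).
#'
#' @param traits Data frame, one row per species.
#' @param trees Tree sample.
#' @param song_col,call_col Peak-frequency columns.
#' @param mass_col,habitat_col Predictor columns.
#' @param log10_mass Model mass on the log10 scale (default `TRUE`).
#' @param log10_frequency Model frequencies on the log10 scale (default
#'   `FALSE`; frequency distributions are typically already bell-shaped on
#'   the raw scale).
#' @param species Species-id column name.
#' @param ... Passed to [pgls_average()].
#' @return An `allometry_comparison`: list with `song` and `call`
#'   (`pgls_average`), `comparison` (`slope_comparison`), and `mass_term`.
#' @export
run_allometry <- function(traits, trees,
                          song_col = "song_peak", call_col = "call_peak",
                          mass_col = "mass_g", habitat_col = "habitat_forest",
                          log10_mass = TRUE, log10_frequency = FALSE,
                          species = "species", ...) {
  trees <- pgls_prepare(trees)
  mass_term <- if (log10_mass) sprintf("log10(%s)", mass_col) else mass_col
  resp <- function(col) {
    if (log10_frequency) sprintf("log10(%s)", col) else col
  }
  f_song <- stats::as.formula(
    paste(resp(song_col), "~", mass_term, "+", habitat_col))
  f_call <- stats::as.formula(
    paste(resp(call_col), "~", mass_term, "+", habitat_col))

  song <- pgls_average(traits, f_song, trees, species = species, ...)
  call <- pgls_average(traits, f_call, trees, species = species, ...)
  message("allometry fitted on ", song$n, " species (song) and ",
          call$n, " species (call)")

  srow <- song$terms[song$terms$term == mass_term, ]
  crow <- call$terms[call$terms$term == mass_term, ]
  cmp <- compare_slopes(srow$beta_st, srow$std.error_st,
                        crow$beta_st, crow$std.error_st)

  structure(
    list(song = song, call = call, comparison = cmp, mass_term = mass_term),
    class = "allometry_comparison"
  )
}

#' Song-duration models: direction, deviation, and collinearity checks
#'
#' Three linked analyses of song duration as a predictor: (i) the full model
#' `frequency ~ log10(mass) + habitat + log10(duration)`, asking whether
#' longer songs shift frequency in a consistent direction; (ii) the
#' absolute-residual regression — residuals of
#' `frequency ~ log10(mass) + habitat` weight-averaged across trees, their
#' absolute values regressed on duration — asking whether longer songs show
#' larger non-directional deviations from the allometric optimum; and
#' (iii) pairwise PGLS regressions among the three predictors as a
#' collinearity report.
#'
#' @inheritParams run_allometry
#' @param duration_col Song-duration column (seconds).
#' @param log10_duration Model duration on the log10 scale (default `TRUE`).
#' @return A `duration_models` list: `full_fit`, `base_fit`,
#'   `abs_residual_fit` (all `pgls_average`), and `collinearity` (tibble of
#'   pairwise standardized slopes).
#' @export
run_duration_models <- function(traits, trees,
                                song_col = "song_peak",
                                mass_col = "mass_g",
                                habitat_col = "habitat_forest",
                                duration_col = "song_duration",
                                log10_mass = TRUE, log10_duration = TRUE,
                                log10_frequency = FALSE,
                                species = "species", ...) {
  trees <- pgls_prepare(trees)
  mass_term <- if (log10_mass) sprintf("log10(%s)", mass_col) else mass_col
  dur_term <- if (log10_duration) {
    sprintf("log10(%s)", duration_col)
  } else {
    duration_col
  }
  resp <- if (log10_frequency) sprintf("log10(%s)", song_col) else song_col

  f_full <- stats::as.formula(
    paste(resp, "~", mass_term, "+", habitat_col, "+", dur_term))
  f_base <- stats::as.formula(paste(resp, "~", mass_term, "+", habitat_col))

  full_fit <- pgls_average(traits, f_full, trees, species = species, ...)
  base_fit <- pgls_average(traits, f_base, trees, species = species, ...)
  abs_fit <- abs_residual_regression(base_fit, traits, dur_term, trees,
                                     species = species, ...)

  pairs <- list(
    c(dur_term, mass_term),
    c(dur_term, habitat_col),
    c(mass_term, habitat_col)
  )
  collin <- purrr::map_dfr(pairs, function(p) {
    f <- stats::as.formula(paste(p[1], "~", p[2]))
    a <- pgls_average(traits, f, trees, species = species, ...)
    row <- a$terms[a$terms$term == p[2], ]
    tibble::tibble(response = p[1], predictor = p[2],
                   beta_st = row$beta_st, p.value = row$p.value,
                   lambda = a$lambda, n = a$n)
  })

  structure(
    list(full_fit = full_fit, base_fit = base_fit,
         abs_residual_fit = abs_fit, collinearity = collin,
         duration_term = dur_term),
    class = "duration_models"
  )
}
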