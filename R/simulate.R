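# Synthetic data with the statistical structure the analysis assumes:
# ultrametric pure-birth trees, pseudo-posterior tree samples obtained by
# branch-length jitter, lambda-structured traits, and noisy repeated
# acoustic measurements per species.

#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Wraps [ape::rphylo()] with extinction rate 0 and rescales the tree to
#' unit root-to-tip depth, so branch lengths are in units of total tree
#' depth and covariance matrices have unit diagonal.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth Speciation rate (only affects node-depth distribution, not
#'   the rescaled depth).
#' @param seed Optional integer seed; the caller's RNG stream is untouched.
#' @return An ultrametric [ape::phylo] with depth 1 and tips
#'   `sp0001, sp0002, ...`.
#' @export
sim_yule_tree <- function(n_tips, birth = 1, seed = NULL) {
  if (n_tips < 2) stop_pf("`n_tips` must be >= 2")
  maybe_with_seed(seed, {
    tr <- ape::rphylo(n_tips, birth = birth, death = 0)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / depth
    tr$tip.label <- sprintf("sp%04d", seq_len(n_tips))
    tr
  })
}

#' Jittered tree sample (pseudo-posterior)
#'
#' Emulates a posterior sample of phylogenies by multiplying every branch
#' length by independent lognormal noise with mean 1 and coefficient of
#' variation `cv`, keeping the topology fixed. `cv = 0` returns identical
#' copies. This is a simplification of real posterior tree samples (which
#' also vary topologically) sufficient to exercise AIC-weighted averaging.
#'
#' @param tree Template [ape::phylo].
#' @param n_trees Number of jittered copies.
#' @param cv Coefficient of variation of the branch-length noise (>= 0).
#' @param seed Optional integer seed.
#' @return A `multiPhylo` of length `n_trees`.
#' @export
jitter_trees <- function(tree, n_trees, cv = 0.2, seed = NULL) {
  validate_phylo(tree)
  if (cv < 0) stop_pf("`cv` must be >= 0")
  maybe_with_seed(seed, {
    out <- lapply(seq_len(n_trees), function(i) {
      tr <- tree
      if (cv > 0) {
        sdlog <- sqrt(log(1 + cv^2))
        f <- stats::rlnorm(length(tr$edge.length),
                           meanlog = -sdlog^2 / 2, sdlog = sdlog)
        tr$edge.length <- tr$edge.length * f
      }
      tr
    })
    class(out) <- "multiPhylo"
    out
  })
}

#' Simulate a lambda-structured trait on a tree
#'
#' One draw from the multivariate normal with covariance
#' \eqn{\sigma^2 \cdot C(\lambda)}, where `C` is the Brownian covariance of
#' the tree and lambda rescales its off-diagonals — the generative model
#' that lambda-PGLS assumes. `lambda = 1` is standard Brownian motion,
#' `lambda = 0` independent tips.
#'
#' @param tree An [ape::phylo].
#' @param lambda Phylogenetic signal of the trait, in \[0, 1\].
#' @param sigma2 Brownian rate (trait variance per unit depth).
#' @param root_mean Trait mean (root state).
#' @param seed Optional integer seed.
#' @return Named numeric vector (alphabetical taxon order).
#' @export
sim_trait <- function(tree, lambda = 1, sigma2 = 1, root_mean = 0,
                      seed = NULL) {
  if (sigma2 <= 0) stop_pf("`sigma2` must be positive")
  C <- sigma2 * lambda_transform(phylo_vcv(tree), lambda)
  U <- chol(C)
  maybe_with_seed(seed, {
    z <- stats::rnorm(nrow(C))
    out <- root_mean + drop(crossprod(U, z))
    names(out) <- rownames(C)
    out
  })
}

#' Simulate a full synthetic comparative study
#'
#' Generates the whole data layout the analysis pipeline consumes: a Yule
#' tree, a jittered tree sample standing in for a posterior of phylogenies,
#' species traits with planted structure, and repeated noisy acoustic
#' measurements per species. Defaults emulate the structure of large
#' song/call datasets: high phylogenetic signal for body mass
#' (`lambda_mass = 0.9`), moderate for song duration (0.45), high for
#' habitat (0.75, generated as a lambda-structured latent trait squashed to
#' \[0, 1\] by a logistic map), a negative frequency-on-log-mass allometry
#' (default raw slope -0.5), no habitat effect, a call subset of ~85% of
#' species, and up to 3 noisy measurements per species and class. Species
#' frequency and duration values in the trait table are the means of the
#' simulated measurements, as they would be in a real study; mass and
#' habitat are exact (sourced from literature rather than measured, in the
#' emulated design).
#'
#' @param n_tips Number of species.
#' @param n_trees Size of the jittered tree sample.
#' @param birth Yule speciation rate.
#' @param jitter_cv Branch-length jitter coefficient of variation.
#' @param lambda_mass,lambda_habitat,lambda_duration Planted phylogenetic
#'   signal of log10 body mass, the latent habitat trait, and log10 song
#'   duration.
#' @param lambda_resid_song,lambda_resid_call Signal of the phylogenetic
#'   residual of song/call frequency around the allometry.
#' @param mass_root,mass_sigma2 Root mean and rate of log10 mass (g).
#' @param duration_root,duration_sigma2 Root mean and rate of log10 song
#'   duration (s).
#' @param habitat_root,habitat_sigma2 Root mean and rate of the latent
#'   habitat trait (logistic-squashed to a proportion).
#' @param intercept_song,intercept_call Allometry intercepts (kHz).
#' @param slope_mass_song,slope_mass_call Frequency-on-log10-mass slopes
#'   (kHz per log10 g).
#' @param slope_habitat Habitat effect on frequency (default 0: null).
#' @param resid_sd_song,resid_sd_call Residual SD of species frequency
#'   around the regression surface (kHz).
#' @param call_fraction Fraction of species with call data.
#' @param n_recordings Measurements per species and class.
#' @param meas_sd_freq Within-species measurement SD of peak frequency
#'   (kHz); default planted so frequency repeatability is ~0.87.
#' @param meas_sd_duration Within-species SD of log10 duration; default
#'   planted so duration repeatability is ~0.7.
#' @param seed Optional integer seed; all outputs are reproducible given it.
#' @return List with `traits` (tibble, one row per species), `trees`
#'   (`multiPhylo` jitter sample), `base_tree`, `measurements` (long
#'   tibble), and `truth` (the planted parameters and true species values).
#' @examples
#' sim <- sim_study(n_tips = 30, n_trees = 3, seed = 42)
#' head(sim$traits)
#' @export
sim_study <- function(n_tips = 591, n_trees = 50, birth = 1,
                      jitter_cv = 0.2,
                      lambda_mass = 0.9, lambda_habitat = 0.75,
                      lambda_duration = 0.45,
                      lambda_resid_song = 0.3, lambda_resid_call = 0.65,
                      mass_root = 1.3, mass_sigma2 = 0.2,
                      duration_root = 0.5, duration_sigma2 = 0.09,
                      habitat_root = 0.2, habitat_sigma2 = 1,
                      intercept_song = 5, intercept_call = 4.5,
                      slope_mass_song = -0.5, slope_mass_call = -0.35,
                      slope_habitat = 0,
                      resid_sd_song = 0.4, resid_sd_call = 0.4,
                      call_fraction = 505 / 591, n_recordings = 3,
                      meas_sd_freq = 0.175, meas_sd_duration = 0.2,
                      seed = NULL) {
  maybe_with_seed(seed, {
    base_tree <- sim_yule_tree(n_tips, birth = birth)
    trees <- jitter_trees(base_tree, n_trees, cv = jitter_cv)
    spp <- sort(base_tree$tip.label)

    log_mass <- sim_trait(base_tree, lambda_mass, mass_sigma2, mass_root)[spp]
    latent_hab <- sim_trait(base_tree, lambda_habitat, habitat_sigma2,
                            habitat_root)[spp]
    habitat <- stats::plogis(latent_hab)
    log_dur <- sim_trait(base_tree, lambda_duration, duration_sigma2,
                         duration_root)[spp]
    res_song <- sim_trait(base_tree, lambda_resid_song, resid_sd_song^2, 0)[spp]
    res_call <- sim_trait(base_tree, lambda_resid_call, resid_sd_call^2, 0)[spp]

    song_true <- intercept_song + slope_mass_song * log_mass +
      slope_habitat * habitat + res_song
    call_true <- intercept_call + slope_mass_call * log_mass +
      slope_habitat * habitat + res_call

    call_spp <- sort(sample(spp, round(call_fraction * n_tips)))

    meas <- function(true_vals, who, cls) {
      purrr::map_dfr(who, function(sp) {
        tibble::tibble(
          species = sp,
          class = cls,
          recording = seq_len(n_recordings),
          peak_freq = true_vals[sp] +
            stats::rnorm(n_recordings, sd = meas_sd_freq),
          duration_s = if (cls == "song") {
            10^(log_dur[sp] + stats::rnorm(n_recordings, sd = meas_sd_duration))
          } else {
            rep(NA_real_, n_recordings)
          }
        )
      })
    }
    measurements <- dplyr::bind_rows(
      meas(song_true, spp, "song"),
      meas(call_true, call_spp, "call")
    )

    summ <- summarize_species(measurements, max_per_class = n_recordings)
    traits <- tibble::tibble(
      species = spp,
      mass_g = 10^log_mass,
      habitat_forest = habitat
    )
    traits <- dplyr::left_join(traits, summ, by = "species")
    traits <- dplyr::select(traits, "species", "song_peak", "call_peak",
                            "song_duration", "mass_g", "habitat_forest")

    list(
      traits = traits,
      trees = trees,
      base_tree = base_tree,
      measurements = measurements,
      truth = list(
        log_mass = log_mass, habitat = habitat, log_duration = log_dur,
        song_peak = song_true, call_peak = call_true, call_species = call_spp,
        lambda = c(mass = lambda_mass, habitat = lambda_habitat,
                   duration = lambda_duration,
                   resid_song = lambda_resid_song,
                   resid_call = lambda_resid_call),
        slope_mass = c(song = slope_mass_song, call = slope_mass_call),
        slope_habitat = slope_habitat,
        seed = seed
      )
    )
  })
}
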