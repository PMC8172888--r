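# Peak-frequency extraction and per-species summaries of repeated acoustic
# measurements.

#' Construct a recording object
#'
#' Holds a mono waveform, its sample rate, and the metadata needed
#' downstream: species id, vocalization class (song or call), and an
#' optional annotated segment delimiting the vocalization within the file.
#'
#' @param wave Numeric vector of samples (normalized amplitude).
#' @param sample_rate Sampling rate in Hz.
#' @param species Species identifier.
#' @param class Vocalization class, `"song"` or `"call"`.
#' @param segment Optional `c(start_s, end_s)` with
#'   `0 <= start < end <= duration`.
#' @return An object of class `recording`.
#' @export
recording <- function(wave, sample_rate, species = NA_character_,
                      class = NA_character_, segment = NULL) {
  wave <- as.numeric(wave)
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop_pf("`sample_rate` must be positive")
  }
  dur <- length(wave) / sample_rate
  if (!is.null(segment)) {
    if (length(segment) != 2 || segment[1] < 0 || segment[2] <= segment[1] ||
        segment[2] > dur + 1e-9) {
      stop_pf("segment must satisfy 0 <= start < end <= duration (",
              signif(dur, 4), " s)")
    }
  }
  structure(list(wave = wave, sample_rate = sample_rate, species = species,
                 class = class, segment = segment),
            class = "recording")
}

#' Peak frequency of a recording
#'
#' The frequency with the highest cumulative sound amplitude: magnitude
#' spectra of successive windowed frames are accumulated over the (segment
#' of the) recording, and the center frequency of the bin with maximal
#' cumulative amplitude inside `band` is returned. Ties (within a relative
#' tolerance of 1e-9) break to the lowest frequency for determinism. The
#' measurement is invariant to global amplitude scaling.
#'
#' @param rec A [recording()] or a numeric waveform (then supply
#'   `sample_rate`).
#' @param window Analysis window length in samples (Hann window).
#' @param overlap Fractional overlap between successive windows.
#' @param band `c(low_hz, high_hz)` search band, within (0, Nyquist\].
#' @param spectrum Accumulate `"magnitude"` (default) or `"power"`.
#' @param sample_rate Sample rate in Hz when `rec` is a bare waveform.
#' @return Peak frequency in Hz.
#' @examples
#' sr <- 44100
#' tone <- sin(2 * pi * 2000 * seq(0, 1, by = 1 / sr))
#' peak_frequency(tone, sample_rate = sr)
#' @export
peak_frequency <- function(rec, window = 1024, overlap = 0.5,
                           band = c(200, 12000),
                           spectrum = c("magnitude", "power"),
                           sample_rate = NULL) {
  spectrum <- match.arg(spectrum)
  if (inherits(rec, "recording")) {
    wave <- rec$wave
    sr <- rec$sample_rate
    if (!is.null(rec$segment)) {
      i0 <- floor(rec$segment[1] * sr) + 1
      i1 <- min(length(wave), ceiling(rec$segment[2] * sr))
      wave <- wave[i0:i1]
    }
  } else {
    wave <- as.numeric(rec)
    sr <- sample_rate
    if (is.null(sr)) stop_pf("supply `sample_rate` for a bare waveform")
  }
  if (length(band) != 2 || band[1] >= band[2]) stop_pf("invalid `band`")
  if (band[1] <= 0 || band[1] >= sr / 2) {
    stop_pf("`band` must lie within (0, Nyquist)")
  }
  band[2] <- min(band[2], sr / 2)
  if (length(wave) < window) {
    stop_pf("segment too short for a ", window, "-sample window (",
            length(wave), " samples)")
  }

  hop <- max(1L, as.integer(round(window * (1 - overlap))))
  starts <- seq.int(1L, length(wave) - window + 1L, by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * seq.int(0L, window - 1L) / window)
  nb <- window %/% 2 + 1L
  acc <- numeric(nb)
  for (s in starts) {
    mag <- Mod(stats::fft(wave[s:(s + window - 1L)] * win))[seq_len(nb)]
    acc <- acc + if (spectrum == "power") mag^2 else mag
  }
  freqs <- (seq_len(nb) - 1L) * sr / window
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel)) stop_pf("no spectral bins inside `band`")
  amps <- acc[sel]
  # lowest bin among (near-)ties, for determinism
  idx <- which(amps >= max(amps) * (1 - 1e-9))[1]
  freqs[sel][idx]
}

#' Duration of the annotated segment of a recording
#'
#' @param rec A [recording()] with a segment annotation; there is no
#'   automatic onset detection.
#' @return Duration in seconds (`end - start`).
#' @export
segment_duration <- function(rec) {
  if (!inherits(rec, "recording")) stop_pf("`rec` must be a recording")
  if (is.null(rec$segment)) {
    stop_pf("recording has no segment annotation")
  }
  rec$segment[2] - rec$segment[1]
}

#' Measure a batch of recordings
#'
#' Applies [peak_frequency()] (and [segment_duration()] where a segment is
#' annotated) to a list of recordings, returning the long-format measurement
#' table consumed by [summarize_species()] and [repeatability()].
#'
#' @param recs List of [recording()] objects.
#' @param ... Passed to [peak_frequency()].
#' @return Tibble with columns `species`, `class`, `recording`, `peak_freq`
#'   (Hz) and `duration_s`.
#' @export
measure_recordings <- function(recs, ...) {
  purrr::imap_dfr(recs, function(r, i) {
    tibble::tibble(
      species = r$species,
      class = r$class,
      recording = i,
      peak_freq = peak_frequency(r, ...),
      duration_s = if (is.null(r$segment)) NA_real_ else segment_duration(r)
    )
  })
}

#' Summarize per-recording measurements to species means
#'
#' Arithmetic means per species and vocalization class, capped at
#' `max_per_class` recordings per species and class (taking the first in
#' input order, mirroring a fixed per-species sampling effort); recordings
#' beyond the cap are dropped with a message.
#'
#' @param measurements Long-format data frame with columns `species`,
#'   `class` (`"song"`/`"call"`), `peak_freq` and optionally `duration_s`.
#' @param max_per_class Per-species, per-class recording cap (default 3).
#' @return Tibble with one row per species: `song_peak`, `call_peak`,
#'   `song_duration`, and recording counts `n_song`, `n_call`.
#' @export
summarize_species <- function(measurements, max_per_class = 3) {
  stopifnot(all(c("species", "class", "peak_freq") %in% names(measurements)))
  m <- dplyr::mutate(
    dplyr::group_by(measurements, .data$species, .data$class),
    .idx = dplyr::row_number()
  )
  n_drop <- sum(m$.idx > max_per_class)
  if (n_drop > 0) {
    message(n_drop, " recordings beyond the per-class cap of ",
            max_per_class, " dropped")
  }
  m <- dplyr::filter(m, .data$.idx <= max_per_class)
  has_dur <- "duration_s" %in% names(m)
  sm <- dplyr::summarise(
    m,
    peak = mean(.data$peak_freq),
    duration = if (has_dur) mean(.data$duration_s, na.rm = TRUE) else NA_real_,
    n = dplyr::n(),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(
    sm,
    id_cols = "species",
    names_from = "class",
    values_from = c("peak", "duration", "n")
  )
  out <- tibble::tibble(
    species = wide$species,
    song_peak = wide[["peak_song"]] %||% rep(NA_real_, nrow(wide)),
    call_peak = wide[["peak_call"]] %||% rep(NA_real_, nrow(wide)),
    song_duration = wide[["duration_song"]] %||% rep(NA_real_, nrow(wide)),
    n_song = wide[["n_song"]] %||% rep(0L, nrow(wide)),
    n_call = wide[["n_call"]] %||% rep(0L, nrow(wide))
  )
  out
}
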