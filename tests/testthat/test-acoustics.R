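sr <- 44100
tone <- function(freq, dur = 1, amp = 1, sr. = sr) {
  amp * sin(2 * pi * freq * seq(0, dur, by = 1 / sr.)[-1])
}
bin_width <- sr / 1024

test_that("peak frequency finds a pure tone within one bin", {
  f <- peak_frequency(tone(2000), sample_rate = sr)
  expect_lt(abs(f - 2000), bin_width)
})

test_that("peak frequency picks the dominant component of a mixture", {
  mix <- tone(1000, amp = 1) + tone(3000, amp = 0.5)
  f <- peak_frequency(mix, sample_rate = sr)
  expect_lt(abs(f - 1000), bin_width)
})

test_that("peak frequency is invariant to global amplitude scaling", {
  x <- tone(2500) + 0.3 * tone(700)
  expect_equal(peak_frequency(x, sample_rate = sr),
               peak_frequency(1000 * x, sample_rate = sr))
  expect_equal(peak_frequency(x, sample_rate = sr),
               peak_frequency(x / 1e6, sample_rate = sr))
})

test_that("exact amplitude ties break to the lowest frequency", {
  # components centred exactly on FFT bins 40 and 80 of a 1024-sample frame:
  # the periodic Hann window confines each to +-1 bin, so the two peaks are
  # equal in exact arithmetic
  srb <- 10240
  n <- 1024 * 8
  tt <- seq_len(n) - 1
  x <- cos(2 * pi * 40 * tt / 1024) + cos(2 * pi * 80 * tt / 1024)
  f <- peak_frequency(x, sample_rate = srb, band = c(100, 5000))
  expect_equal(f, 40 * srb / 1024)

  # all-zero signal: every bin ties at zero; lowest in-band bin returned
  z <- peak_frequency(numeric(5000), sample_rate = sr, band = c(200, 12000))
  expect_equal(z, ceiling(200 / bin_width) * bin_width)
})

test_that("segments delimit the analysis and durations come from annotations", {
  rec <- recording(tone(2000, dur = 3), sr, species = "sp1", class = "song",
                   segment = c(0.5, 2.5))
  expect_equal(segment_duration(rec), 2.0)
  expect_equal(segment_duration(recording(tone(1000, dur = 0.2), sr,
                                          segment = c(0, 0.1))), 0.1)
  expect_error(segment_duration(recording(tone(1000), sr)), "no segment")
  expect_error(recording(tone(1000, dur = 0.5), sr, segment = c(0.2, 1)),
               "segment")
  expect_error(peak_frequency(recording(tone(2000, dur = 1), sr,
                                        segment = c(0, 0.01))),
               "too short")
  expect_error(peak_frequency(tone(2000), sample_rate = sr,
                              band = c(5000, 1000)), "band")
})

test_that("species summaries average per class and cap at 3 recordings", {
  m <- tibble::tibble(
    species = c(rep("sp1", 3), rep("sp2", 5)),
    class = "song",
    recording = c(1:3, 1:5),
    peak_freq = c(2000, 2200, 2400, 100, 200, 300, 9000, 9000),
    duration_s = c(1, 2, 3, rep(1, 5))
  )
  expect_message(s <- summarize_species(m), "cap")
  expect_equal(s$song_peak[s$species == "sp1"], 2200)
  expect_equal(s$song_duration[s$species == "sp1"], 2)
  # sp2: only the first 3 recordings used
  expect_equal(s$song_peak[s$species == "sp2"], 200)
  expect_equal(s$n_song[s$species == "sp2"], 3)

  one <- summarize_species(tibble::tibble(species = "a", class = "call",
                                          recording = 1, peak_freq = 1500))
  expect_equal(one$call_peak, 1500)
})

test_that("measure_recordings produces the long-format measurement table", {
  recs <- list(
    recording(tone(2000), sr, species = "sp1", class = "song",
              segment = c(0, 1)),
    recording(tone(3000), sr, species = "sp1", class = "call"),
    recording(tone(1000), sr, species = "sp2", class = "song",
              segment = c(0.1, 0.9))
  )
  m <- measure_recordings(recs)
  expect_equal(nrow(m), 3)
  expect_lt(abs(m$peak_freq[1] - 2000), bin_width)
  expect_true(is.na(m$duration_s[2]))
  expect_equal(m$duration_s[3], 0.8)
})

test_that("WAV files round-trip through the PCM reader/writer", {
  x <- 0.8 * tone(2000, dur = 0.25)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, path, sample_rate = sr)
  rec <- read_wav(path, species = "sp1", class = "song")
  expect_equal(rec$sample_rate, sr)
  expect_equal(length(rec$wave), length(x))
  expect_lt(max(abs(rec$wave - x)), 1 / 2^14) # 16-bit quantization
  expect_lt(abs(peak_frequency(rec) - 2000), bin_width)
})

test_that("repeated noisy measurements of tones are highly repeatable", {
  set.seed(401)
  freqs <- seq(1000, 4000, length.out = 12)
  m <- purrr::map_dfr(seq_along(freqs), function(i) {
    peaks <- vapply(1:3, function(r) {
      x <- tone(freqs[i]) + rnorm(sr, sd = 0.05)
      peak_frequency(x, sample_rate = sr)
    }, numeric(1))
    tibble::tibble(species = paste0("sp", i), peak = peaks)
  })
  r <- repeatability(m, peak, species)
  expect_gt(r$R, 0.95)
})
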