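test_that("slope comparison follows the pooled-SE Z form", {
  eq <- compare_slopes(-0.4, 0.05, -0.4, 0.08)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p.value, 1)

  cmp <- compare_slopes(-0.51, 0.05, -0.38, 0.05)
  expect_equal(cmp$statistic, -0.13 / sqrt(0.005), tolerance = 1e-10)
  expect_equal(cmp$p.value, 2 * pnorm(-abs(cmp$statistic)), tolerance = 1e-12)

  swap <- compare_slopes(-0.38, 0.05, -0.51, 0.05)
  expect_equal(swap$statistic, -cmp$statistic)
  expect_equal(swap$p.value, cmp$p.value)

  expect_error(compare_slopes(1, 0, 2, 0), "both standard errors")
})

test_that("Welch reference is available and close to normal at large df", {
  a <- compare_slopes(-0.5, 0.05, -0.3, 0.05)
  b <- compare_slopes(-0.5, 0.05, -0.3, 0.05, method = "welch",
                      df1 = 500, df2 = 500)
  expect_equal(a$statistic, b$statistic)
  expect_gt(b$p.value, a$p.value)
  expect_equal(a$p.value, b$p.value, tolerance = 0.03)
})

test_that("repeatability matches hand-worked ANOVA fixtures", {
  perfect <- data.frame(sp = c("A", "A", "B", "B"), x = c(1, 1, 2, 2))
  expect_equal(repeatability(perfect, x, sp)$R, 1)

  d <- data.frame(sp = rep(c("A", "B", "C"), each = 2), x = c(1, 2, 3, 4, 5, 6))
  r <- repeatability(d, x, sp)
  expect_equal(r$ms_among, 8)
  expect_equal(r$ms_within, 0.5)
  expect_equal(r$n0, 2)
  expect_equal(r$R, 3.75 / 4.25, tolerance = 1e-10)

  flip <- data.frame(sp = c("A", "A", "B", "B"), x = c(0, 1, 1, 0))
  rf <- repeatability(flip, x, sp)
  expect_lt(rf$R, 0)
  expect_true(rf$negative)
})

test_that("repeatability equals the aov-based oracle on unbalanced data", {
  set.seed(301)
  for (i in 1:50) {
    a <- sample(3:8, 1)
    sizes <- sample(1:4, a, replace = TRUE)
    if (sum(sizes) - a < 1) sizes[1] <- sizes[1] + 2
    grp <- rep(paste0("g", seq_len(a)), sizes)
    val <- rnorm(a, sd = 2)[as.integer(factor(grp))] + rnorm(length(grp))
    d <- data.frame(g = grp, v = val)
    expect_equal(repeatability(d, v, g)$R, oracle_icc(val, grp),
                 tolerance = 1e-10)
  }
})

test_that("all-singleton groups are rejected", {
  d <- data.frame(sp = c("A", "B", "C"), x = 1:3)
  expect_error(repeatability(d, x, sp), "singleton")
})

test_that("absolute-residual regression recovers planted heteroscedasticity", {
  sim <- sim_study(n_tips = 200, n_trees = 3, seed = 303)
  d <- sim$traits
  # plant residual spread that grows with song duration
  spread <- scale(log10(d$song_duration))[, 1]
  d$song_peak <- withr::with_seed(304, {
    5 - 0.5 * log10(d$mass_g) + rnorm(nrow(d), sd = 0.5 * plogis(3 * spread))
  })
  base <- pgls_average(d, song_peak ~ log10(mass_g) + habitat_forest,
                       sim$trees)
  het <- abs_residual_regression(base, d, "log10(song_duration)", sim$trees)
  expect_gt(tidy(het)$beta_st[2], 0.1)
  expect_lt(tidy(het)$p.value[2], 0.05)
})

test_that("near-constant residual magnitudes yield a near-zero slope", {
  sim <- sim_study(n_tips = 80, n_trees = 2, seed = 305)
  base <- pgls_average(sim$traits, song_peak ~ log10(mass_g) + habitat_forest,
                       sim$trees)
  base$residuals[] <- withr::with_seed(306, {
    sign(rnorm(length(base$residuals))) * (1 + rnorm(length(base$residuals), sd = 1e-7))
  })
  flat <- abs_residual_regression(base, sim$traits, "log10(song_duration)",
                                  sim$trees)
  expect_equal(tidy(flat)$estimate[2], 0, tolerance = 1e-4)
})
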