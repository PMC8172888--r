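test_that("Yule trees are ultrametric with unit depth and requested size", {
  tr <- sim_yule_tree(50, seed = 1)
  expect_equal(length(tr$tip.label), 50)
  expect_true(check_ultrametric(tr, tol = 1e-9))
  expect_equal(max(ape::node.depth.edgelength(tr)), 1, tolerance = 1e-12)

  cherry <- sim_yule_tree(2, seed = 2)
  expect_equal(length(cherry$tip.label), 2)
  expect_equal(unname(diag(phylo_vcv(cherry))), c(1, 1))

  expect_identical(ape::write.tree(sim_yule_tree(20, seed = 3)),
                   ape::write.tree(sim_yule_tree(20, seed = 3)))
  expect_error(sim_yule_tree(1), ">= 2")
})

test_that("tree jitter keeps topology, is seed-deterministic, and is unbiased", {
  tr <- sim_yule_tree(30, seed = 4)
  same <- jitter_trees(tr, 4, cv = 0, seed = 5)
  expect_length(same, 4)
  for (t2 in same) expect_equal(t2$edge.length, tr$edge.length)

  j1 <- jitter_trees(tr, 3, cv = 0.3, seed = 6)
  j2 <- jitter_trees(tr, 3, cv = 0.3, seed = 6)
  expect_equal(j1[[2]]$edge.length, j2[[2]]$edge.length)
  expect_identical(j1[[1]]$edge, tr$edge)

  big <- jitter_trees(tr, 1000, cv = 0.3, seed = 7)
  mean_len <- mean(vapply(big, function(t2) mean(t2$edge.length), numeric(1)))
  expect_equal(mean_len, mean(tr$edge.length), tolerance = 0.02)
})

test_that("lambda-structured traits have the planted moments", {
  # lambda = 0: iid tips with variance sigma2 * depth
  tr <- sim_yule_tree(400, seed = 8)
  x0 <- sim_trait(tr, lambda = 0, sigma2 = 2, root_mean = 5, seed = 9)
  expect_equal(mean(x0), 5, tolerance = 0.2)
  expect_equal(var(x0), 2, tolerance = 0.35)

  # sister-pair covariance scales with lambda * shared depth
  cherry3 <- read_trees(text = "((A:0.4,B:0.4):0.6,C:1);")
  reps <- withr::with_seed(10, {
    t(replicate(3000, sim_trait(cherry3, lambda = 0.5)))
  })
  expect_lt(abs(cov(reps[, "A"], reps[, "B"]) - 0.5 * 0.6), 0.06)
  expect_lt(abs(cov(reps[, "A"], reps[, "C"])), 0.06)
})

test_that("lambda = 1 simulation matches recursive Brownian motion in distribution", {
  tr <- random_small_tree(5)
  n_rep <- 1000
  mv <- withr::with_seed(11, {
    replicate(n_rep, sim_trait(tr, lambda = 1)[1])
  })
  rec <- withr::with_seed(12, {
    replicate(n_rep, oracle_bm_tips(tr)[names(mv[1])])
  })
  ks <- suppressWarnings(ks.test(mv, rec))
  expect_gt(ks$p.value, 0.01)
})

test_that("sim_study emits aligned traits, trees and measurements", {
  sim <- sim_study(n_tips = 40, n_trees = 6, seed = 13)
  expect_equal(nrow(sim$traits), 40)
  expect_length(sim$trees, 6)
  expect_setequal(sim$traits$species, sim$base_tree$tip.label)
  expect_true(all(sim$traits$habitat_forest >= 0 &
                    sim$traits$habitat_forest <= 1))
  expect_true(all(sim$traits$mass_g > 0))
  # call subset smaller than song coverage
  expect_lt(sum(!is.na(sim$traits$call_peak)), 40)
  expect_equal(sum(!is.na(sim$traits$call_peak)), round(40 * 505 / 591))
  # 3 song recordings per species, durations only for songs
  m <- sim$measurements
  expect_equal(sum(m$class == "song"), 40 * 3)
  expect_true(all(is.na(m$duration_s[m$class == "call"])))
  # trait table means equal measurement means
  sp1 <- sim$traits$species[1]
  expect_equal(sim$traits$song_peak[1],
               mean(m$peak_freq[m$species == sp1 & m$class == "song"]))

  sim2 <- sim_study(n_tips = 40, n_trees = 6, seed = 13)
  expect_equal(sim$traits, sim2$traits)
  expect_equal(sim$measurements, sim2$measurements)
})
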