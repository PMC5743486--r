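test_that("simulated trees are ultrametric with the requested depth and tips", {
  tr <- simulate_tree(4, seed = 131)
  expect_equal(ape::Ntip(tr), 4)
  expect_true(is_ultrametric_tol(tr))
  expect_equal(max(node_ages(tr)), 128)
  expect_error(simulate_tree(10, birth = 1, death = 2), "death")

  # pure-birth trees: the gamma statistic is centred on zero
  gammas <- vapply(1:120, function(i) ape::gammaStat(simulate_tree(64, seed = i)),
                   numeric(1))
  expect_lt(abs(mean(gammas)), 2 / sqrt(120) + 0.1)
})

test_that("Brownian tip variance scales with sigma^2 times the root age", {
  tr <- simulate_tree(8, seed = 133)
  tips <- vapply(1:400, function(i)
    evolve_trait(tr, "BM", sigma = 0.3, seed = 1000 + i)[1], numeric(1))
  expect_equal(var(tips), 0.3^2 * 128, tolerance = 0.15 * 0.3^2 * 128)
})

test_that("the two-clade shift plants a bimodal, deeply conserved niche", {
  tr <- simulate_tree(60, seed = 135)
  y <- evolve_trait(tr, "two_clade_shift", sigma = 0.02, delta = 3,
                    split_age = 90, seed = 136)
  sgn <- attr(y, "clade_sign")
  expect_setequal(unique(sgn), c(-1, 0, 1))
  expect_gt(min(y[sgn == 1]), max(y[sgn == 1]) - 2)   # tight around +delta
  expect_gt(mean(y[sgn == 1]) - mean(y[sgn == -1]), 4)
  expect_true(abs(attr(y, "split_age") - 90) < 40)
  expect_error(evolve_trait(tr, "wiggle"), "arg")
})

test_that("every scenario yields a bundle passing the io invariants", {
  for (sc in c("neutral", "filtering_conserved", "overdispersion",
               "dominance_shift", "deep_filtering_late")) {
    b <- suppressMessages(simulate_bundle(
      scenario_config(sc, pool_size = 80, n_community = 40,
                      plots_per_stage = c(3, 3, 4), richness_range = c(8, 14),
                      individuals_range = c(80, 50)), seed = 21))
    expect_s3_class(b, "succession_bundle")
    expect_true(all(rowSums(b$community) > 0))
    expect_true(all(b$community == round(b$community)))
    expect_true(all(colnames(b$community) %in% b$pool_tree$tip.label))
    expect_equal(b$D_comm, t(b$D_comm))
    expect_equal(unname(diag(b$D_comm)), rep(0, ncol(b$community)))
    expect_equal(nrow(b$stages), nrow(b$community))
  }
})

test_that("the default configuration reproduces the study-design magnitudes", {
  b <- simulate_bundle(scenario_config("neutral"), seed = 23)
  expect_equal(nrow(b$community), 27)
  expect_equal(unname(as.vector(table(b$stages$stage))), c(5, 4, 5, 6, 7))
  expect_equal(ncol(b$community), 143)
  expect_equal(ape::Ntip(b$pool_tree), 410)
  expect_equal(max(node_ages(b$pool_tree)), 128)
})

test_that("dominance shift raises evenness across stages at near-constant composition", {
  b <- simulate_bundle(scenario_config("dominance_shift", pool_size = 100,
                                       n_community = 60,
                                       plots_per_stage = c(4, 4, 4, 4, 4),
                                       richness_range = c(30, 30),
                                       individuals_range = c(300, 200)), seed = 25)
  a <- alpha_diversity(b, "abundance")
  ev <- tapply(a$evenness, a$stage, mean)
  expect_true(all(diff(ev) > 0))                    # monotone increase
  # composition identical -> presence-based turnover exactly zero
  p <- pairwise_turnover(b, "presence")
  expect_equal(p$statistic, rep(0, nrow(p)), tolerance = 1e-12)
})

test_that("fixtures are deterministic and byte-identical for a fixed seed", {
  cfg <- scenario_config("neutral", pool_size = 30, n_community = 15,
                         plots_per_stage = c(2, 2), richness_range = c(4, 8),
                         individuals_range = c(40, 30))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_fixture(cfg, seed = 31, dir = d1)
  make_fixture(cfg, seed = 31, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_true(file.exists(file.path(d1, "manifest.json")))
})

test_that("zero filtering strength collapses onto the neutral scenario", {
  # with a flat niche kernel (huge breadth) filtering weights are ~uniform
  cfg_f <- scenario_config("filtering_conserved", pool_size = 60, n_community = 35,
                           plots_per_stage = c(3, 3, 3), niche_breadth = 1e6,
                           richness_range = c(8, 14), individuals_range = c(60, 40))
  cfg_n <- scenario_config("neutral", pool_size = 60, n_community = 35,
                           plots_per_stage = c(3, 3, 3),
                           richness_range = c(8, 14), individuals_range = c(60, 40))
  stat_f <- vapply(1:40, function(i) {
    b <- simulate_bundle(cfg_f, seed = 4000 + i)
    turnover_null_test(b, "presence", scopes = "within", R = 59, seed = i)$ses
  }, numeric(1))
  stat_n <- vapply(1:40, function(i) {
    b <- simulate_bundle(cfg_n, seed = 8000 + i)
    turnover_null_test(b, "presence", scopes = "within", R = 59, seed = i)$ses
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(stat_f, stat_n))
  expect_gt(ks$p.value, 0.01)
})
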