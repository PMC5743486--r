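test_that("threshold grid reproduces the 30-128 Myr design", {
  g <- threshold_grid()
  expect_length(g, 11)
  expect_equal(g, c(seq(30, 120, 10), 128))
  expect_equal(threshold_grid(30, 30, 10), 30)
  expect_error(threshold_grid(50, 30), "min")
})

test_that("restriction at or beyond the root age reproduces the full statistic", {
  tr <- simulate_tree(16, seed = 21)
  comm <- random_community(tr, 4)
  b <- tiny_bundle(tr, comm, c("1", "1", "2", "2"))
  root <- max(node_ages(tr))
  full <- pairwise_turnover(b, "presence")
  restr <- restricted_turnover(b, "presence", threshold = root * 1.001)
  expect_equal(restr$statistic, full$statistic, tolerance = 1e-12)
  expect_equal(attr(restr, "n_retained"), choose(16, 2))
})

test_that("cherry-only restriction flags pairs with no retained cross pair", {
  tree <- balanced4()
  comm <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 2, byrow = TRUE,
                 dimnames = list(c("k", "l"), c("A", "B", "C", "D")))
  b <- tiny_bundle(tree, comm, c("1", "1"))
  suppressMessages(restr <- restricted_turnover(b, "presence", threshold = 1.5))
  expect_false(restr$defined)                        # no cross pair below 1.5
  a <- alpha_diversity(b, "presence")                # within-pair distances kept
  expect_equal(a$delta_w, c(2, 2))
  expect_equal(attr(restr, "n_retained"), 2L)        # the two cherries
})

test_that("restricted statistics match the masked brute-force oracle", {
  set.seed(31)
  tr <- simulate_tree(32, seed = 32)
  tr$tip.label <- paste0("sp", 1:32)
  comm <- random_community(tr, 3)
  b <- tiny_bundle(tr, comm, c("1", "1", "2"))
  D <- cophenetic_matrix(tr)
  for (Tth in quantile(node_ages(tr)[33:63], c(0.2, 0.4, 0.6, 0.8, 1))) {
    for (mode in c("presence", "abundance")) {
      suppressMessages(p <- restricted_turnover(b, mode, threshold = Tth))
      for (r in seq_len(nrow(p))) {
        ck <- comm[p$plot_a[r], ]; cl <- comm[p$plot_b[r], ]
        dw <- mean(c(oracle_restricted_alpha(ck, D, mode, Tth),
                     oracle_restricted_alpha(cl, D, mode, Tth)))
        da <- oracle_restricted_beta(ck, cl, D, mode, Tth)
        want <- if (is.na(da) || is.na(dw)) NA_real_ else 1 - dw / da
        expect_equal(p$statistic[r], want, tolerance = 1e-12)
      }
    }
  }
})

test_that("retained pair sets grow monotonically with the threshold", {
  tr <- simulate_tree(24, seed = 41)
  D <- cophenetic_matrix(tr)
  masks <- lapply(c(20, 50, 90, 130), function(Tth)
    phylosucc:::.retention_mask(D, Tth))
  for (i in 1:3) expect_true(all(masks[[i]] <= masks[[i + 1]]))
})

test_that("partial shuffle permutes only within young clades", {
  tr <- simulate_tree(20, seed = 51)
  ages <- node_ages(tr)
  # below every internal node age: identity always
  young <- min(ages[21:39])
  expect_equal(unname(partial_shuffle(tr, young * 0.5, seed = 1)), 1:20)
  # at or above the root: full permutation support (not identity, bijection)
  p_full <- partial_shuffle(tr, max(ages) * 1.01, seed = 2)
  expect_setequal(p_full, 1:20)

  # permutations never cross clade boundaries
  Tth <- stats::median(ages[21:39])
  part <- clade_partition(tr, Tth)
  clade_of <- rep(NA_integer_, 20)
  for (i in seq_along(part)) clade_of[part[[i]]] <- i
  for (s in 1:20) {
    p <- partial_shuffle(tr, Tth, seed = s)
    moved <- which(p != 1:20)
    expect_true(all(!is.na(clade_of[moved])))
    expect_equal(clade_of[p[moved]], clade_of[moved])
  }
})

test_that("the 4-tip partial shuffle hits all four cherry permutations equally", {
  tree <- balanced4()
  set.seed(61)
  part <- clade_partition(tree, 1.5)
  draws <- replicate(4000, paste(partial_shuffle(tree, 1.5, partition = part),
                                 collapse = ""))
  tab <- table(factor(draws, levels = c("1234", "2134", "1243", "2143")))
  expect_equal(length(tab), 4L)
  gof <- chisq.test(tab, p = rep(0.25, 4))
  expect_gt(gof$p.value, 0.001)
})

test_that("a single root-age threshold reduces the profile to the plain null test", {
  b <- simulate_bundle(scenario_config("neutral", pool_size = 40, n_community = 24,
                                       plots_per_stage = c(3, 3),
                                       richness_range = c(6, 12),
                                       individuals_range = c(60, 40)), seed = 6)
  root <- max(node_ages(b$pool_tree))
  dp <- depth_profile(b, "presence", grid = root * 1.001, scopes = "within",
                      R = 99, seed = 7)
  tt <- turnover_null_test(b, "presence", scopes = "within", R = 99, seed = 7)
  expect_equal(dp$observed, tt$observed, tolerance = 1e-12)
  expect_equal(dp$ses, tt$ses, tolerance = 1e-10)
})
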