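make_env <- function(n, k = 4, seed = 1) {
  set.seed(seed)
  tibble::tibble(plot = sprintf("p%d", 1:n), x = runif(n, 0, 100),
                 y = runif(n, 0, 100),
                 !!!setNames(lapply(1:k, function(i) rnorm(n)), paste0("v", 1:k)))
}

test_that("environmental distances are invariant to variable order and rescaling", {
  env <- make_env(10, 5)
  d1 <- env_distance(env)
  env2 <- env[, c("plot", "x", "y", "v3", "v1", "v5", "v2", "v4")]
  env2$v1 <- env2$v1 * 100 + 7                       # affine rescale is z-scored away
  d2 <- env_distance(env2)
  expect_equal(d1$env_dist, d2$env_dist, tolerance = 1e-9)
  expect_equal(d1$spatial_dist, d2$spatial_dist)
})

test_that("collinear duplicates add no dimensions and preserve the distance structure", {
  env <- make_env(12, 4, seed = 2)
  dup <- env
  dup$v1b <- env$v1; dup$v2b <- env$v2               # perfectly collinear block
  d1 <- env_distance(env, variance_target = 0.999)
  d2 <- env_distance(dup, variance_target = 0.999)
  # rank cannot exceed the deduplicated rank; duplicated axes are upweighted
  # by exactly sqrt(2), so squared distances decompose accordingly
  expect_lte(attr(d2, "n_pcs"), attr(d1, "n_pcs"))
  d12 <- env_distance(env[, c("plot", "x", "y", "v1", "v2")],
                      variance_target = 0.999)
  expect_equal(d2$env_dist^2, d1$env_dist^2 + d12$env_dist^2, tolerance = 1e-9)
  expect_warning(env_distance(dplyr::mutate(env, cst = 5)), "constant")
})

test_that("a six-factor environment needs about six components for 90% variance", {
  cfg <- scenario_config("neutral", pool_size = 40, n_community = 25,
                         plots_per_stage = c(5, 5, 6, 6, 5),
                         richness_range = c(6, 12), individuals_range = c(60, 40),
                         n_env_vars = 11, n_latent = 6, env_noise_sd = 0.35)
  b <- simulate_bundle(cfg, seed = 9)
  d <- env_distance(b$env, variance_target = 0.90)
  expect_true(attr(d, "n_pcs") %in% 5:7)
  expect_gte(attr(d, "variance_explained"), 0.90)
})

test_that("spatial residualization matches closed-form least squares", {
  tr <- simulate_tree(10, seed = 81)
  comm <- random_community(tr, 4)
  b <- tiny_bundle(tr, comm, c("1", "1", "1", "1"))
  pairs <- pairwise_turnover(b, "presence")
  env <- make_env(4, 3, seed = 3)
  env$plot <- rownames(comm)
  d <- env_distance(env)
  res <- residualize_on_space(pairs, d)
  x <- res$spatial_dist; y <- res$statistic
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(attr(res, "slope"), beta, tolerance = 1e-12)
  expect_equal(res$residual, y - (mean(y) - beta * mean(x)) - beta * x,
               tolerance = 1e-12)

  # turnover an exact linear function of space -> residuals vanish
  res2 <- residualize_on_space(dplyr::mutate(pairs,
    statistic = 0.3 + 0.02 * d$spatial_dist, defined = TRUE), d)
  expect_equal(res2$residual, rep(0, 6), tolerance = 1e-10)
})

test_that("permutation regression is exact on deterministic input and calibrated on noise", {
  x <- seq_len(30)
  fit <- perm_regression(x, x, n_perm = 199, seed = 4)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$p_value, 1 / 200)
  expect_equal(fit$slope, 1)

  set.seed(91)
  rejections <- vapply(1:400, function(i) {
    y <- rnorm(25); x <- rnorm(25)
    perm_regression(y, x, n_perm = 99)$p_value <= 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_gt(rate, 0.05 - 1.96 * sqrt(0.05 * 0.95 / 400))
  expect_lt(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 400) + 0.01)

  flat <- perm_regression(rep(1, 10), rnorm(10), n_perm = 99)
  expect_true(is.na(flat$p_value))
})

test_that("a planted linear turnover-environment relationship is recovered", {
  set.seed(101)
  n <- 60
  x <- runif(n, 0, 3)
  y <- 0.1 * x + rnorm(n, 0, 0.5 * sd(0.1 * x))      # noise SD = half signal SD
  fit <- perm_regression(y, x, n_perm = 499, seed = 5)
  expect_lt(abs(fit$slope - 0.1) / 0.1, 0.10)
  expect_lte(fit$p_value, 0.01)
})

test_that("stagewise association flags low-power scopes and finds planted signal", {
  cfg <- scenario_config("deep_filtering_late", pool_size = 120, n_community = 70,
                         plots_per_stage = c(4, 4, 6, 7), richness_range = c(12, 22),
                         individuals_range = c(120, 80))
  b <- simulate_bundle(cfg, seed = 14)
  ea <- stagewise_association(b, "presence", n_perm = 499, seed = 15)
  expect_setequal(ea$scope, c("overall", "within", "between", "1", "2", "3", "4"))
  late <- ea[ea$scope == "4", ]
  expect_lte(late$p_value, 0.05)
  expect_gt(late$slope, 0)
})

test_that("subsampling enumerates k-plot subsets and matches the single-subset case", {
  cfg <- scenario_config("neutral", pool_size = 60, n_community = 35,
                         plots_per_stage = c(4, 7), richness_range = c(8, 15),
                         individuals_range = c(80, 60))
  b <- simulate_bundle(cfg, seed = 16)
  sub <- subsample_association(b, k = 4, mode = "presence", n_perm = 199, seed = 17)
  expect_equal(sub$n_subsets, c(1L, 35L))            # C(4,4), C(7,4)
  full <- stagewise_association(b, "presence", n_perm = 199, seed = 18)
  expect_equal(sub$mean_r_squared[1], full$r_squared[full$scope == "1"],
               tolerance = 1e-9)
})
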