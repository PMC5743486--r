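#' Environmental and spatial distances between plots
#'
#' Builds between-plot environmental distances: strictly positive variables
#' are log-transformed (signed variables such as northness pass through, and
#' are recorded), all variables are z-scored, a PCA is run, and the smallest
#' set of leading components reaching `variance_target` of total variance is
#' retained; distances are Euclidean in that component space. This damps the
#' dominance of the distance matrix by blocks of highly correlated
#' variables. Spatial distances are Euclidean on the `x`, `y` coordinates.
#'
#' @param env Environmental tibble with columns `plot`, `x`, `y` and numeric
#'   variables (see [read_env_table()]).
#' @param variance_target Fraction of variance the retained components must
#'   reach (default 0.90).
#' @return Tibble of class `distance_table`: `plot_a`, `plot_b`, `env_dist`,
#'   `spatial_dist`; attributes `n_pcs`, `variance_explained`,
#'   `logged_vars`, `unlogged_vars`, `dropped_vars`.
#' @export
env_distance <- function(env, variance_target = 0.90) {
  env <- as_tibble(env)
  if (!all(c("plot", "x", "y") %in% names(env)))
    stop_ps("env table needs plot, x, y columns")
  vars <- setdiff(names(env), c("plot", "x", "y"))
  if (length(vars) < 2) stop_ps("need at least 2 environmental variables")
  if (nrow(env) < 3) stop_ps("need at least 3 plots")
  V <- as.matrix(env[, vars])
  if (anyNA(V)) stop_ps("missing values in environmental variables")

  const <- apply(V, 2, function(v) sd(v) == 0)
  if (any(const)) {
    warn_ps("dropping constant variable(s): ", paste(vars[const], collapse = ", "))
    V <- V[, !const, drop = FALSE]; vars_kept <- vars[!const]
  } else vars_kept <- vars
  positive <- apply(V, 2, function(v) all(v > 0))
  V[, positive] <- log(V[, positive, drop = FALSE])
  Z <- scale(V)

  pca <- prcomp(Z, center = FALSE, scale. = FALSE)
  cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  k <- min(which(cum >= variance_target), length(cum))
  scores <- pca$x[, seq_len(k), drop = FALSE]

  ed <- as.matrix(dist(scores))
  sp <- as.matrix(dist(cbind(env$x, env$y)))
  idx <- which(upper.tri(ed), arr.ind = TRUE)
  out <- tibble(
    plot_a = env$plot[idx[, 1]], plot_b = env$plot[idx[, 2]],
    env_dist = ed[idx], spatial_dist = sp[idx]
  )
  class(out) <- c("distance_table", class(out))
  attr(out, "n_pcs") <- k
  attr(out, "variance_explained") <- cum[k]
  attr(out, "logged_vars") <- vars_kept[positive]
  attr(out, "unlogged_vars") <- vars_kept[!positive]
  attr(out, "dropped_vars") <- vars[const]
  out
}

#' Partial out spatial distance from pairwise turnover
#'
#' Ordinary least-squares regression of the pairwise turnover statistic on
#' the between-plot spatial distance; the residuals carry the turnover
#' signal net of spatial covariation and are what gets regressed on
#' environmental distance. If the spatial distances have zero variance the
#' residuals are the centred statistic (with a warning).
#'
#' @param pairs A `pairwise_turnover` tibble.
#' @param distances A `distance_table` from [env_distance()].
#' @return `pairs` joined with `env_dist`, `spatial_dist` and a new
#'   `residual` column; attributes `slope` and `intercept` record the fitted
#'   spatial regression.
#' @export
residualize_on_space <- function(pairs, distances) {
  merged <- .join_pairs(pairs, distances)
  ok <- merged$defined & is.finite(merged$env_dist)
  if (sum(ok) < 3) stop_ps("need at least 3 defined pairs")
  if (sd(merged$spatial_dist[ok]) == 0) {
    warn_ps("zero-variance spatial distances; residuals are centred values")
    merged$residual <- ifelse(ok, merged$statistic - mean(merged$statistic[ok]), NA)
    attr(merged, "slope") <- 0
    attr(merged, "intercept") <- mean(merged$statistic[ok])
    return(merged)
  }
  fit <- lm(statistic ~ spatial_dist, data = merged[ok, ])
  merged$residual <- NA_real_
  merged$residual[ok] <- resid(fit)
  attr(merged, "slope") <- unname(coef(fit)[2])
  attr(merged, "intercept") <- unname(coef(fit)[1])
  merged
}

# join pairwise turnover with a pair-level distance table on unordered pairs
.join_pairs <- function(pairs, distances) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  d <- tibble(.key = key(distances$plot_a, distances$plot_b),
              env_dist = distances$env_dist, spatial_dist = distances$spatial_dist)
  p <- as_tibble(pairs)
  p$.key <- key(p$plot_a, p$plot_b)
  out <- left_join(p, d, by = ".key")
  if (anyNA(out$spatial_dist))
    stop_ps("some plot pairs are missing from the distance table")
  out$.key <- NULL
  out
}

#' Permutation regression of turnover on environmental distance
#'
#' OLS slope and R-squared of `y` on `x`, with significance from
#' randomization: `y` is permuted across pairs `n_perm` times and
#' `p = (r + 1) / (n_perm + 1)` where `r` counts permutations with
#' `|slope| >= |observed|` (two-sided default) or `slope >= observed`
#' (one-sided `"greater"`). Pairwise observations are non-independent, so
#' permutation is at the pair level, mirroring randomization-based linear
#' model tests on distance-derived responses.
#'
#' @param y Numeric response (e.g. residual turnover per pair).
#' @param x Numeric predictor (e.g. environmental distance per pair).
#' @param n_perm Number of permutations (default 5000).
#' @param seed Optional seed.
#' @param alternative `"two.sided"` or `"greater"`.
#' @return Object of class `perm_lm`: list with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`, `n_perm`, `alternative`.
#' @export
perm_regression <- function(y, x, n_perm = 5000, seed = NULL,
                            alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 3) stop_ps("need at least 3 pairs")
  flagged <- sd(x) == 0 || sd(y) == 0
  if (flagged) {
    return(structure(list(slope = if (sd(x) == 0) NA_real_ else 0, intercept = mean(y),
                          r_squared = 0, p_value = NA_real_, n = n, n_perm = n_perm,
                          alternative = alternative, flagged = TRUE), class = "perm_lm"))
  }
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2)
  slope <- sum(xc * yc) / sxx
  r2 <- slope^2 * sxx / sum(yc^2)

  perm_slopes <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sum(xc * yc[sample.int(n)]) / sxx, numeric(1))
  })
  r <- if (alternative == "two.sided") sum(abs(perm_slopes) >= abs(slope))
       else sum(perm_slopes >= slope)
  structure(list(slope = slope, intercept = mean(y) - slope * mean(x),
                 r_squared = r2, p_value = (r + 1) / (n_perm + 1),
                 n = n, n_perm = n_perm, alternative = alternative,
                 flagged = FALSE), class = "perm_lm")
}

#' @export
print.perm_lm <- function(x, ...) {
  cat("<perm_lm> slope =", signif(x$slope, 4), " R2 =", signif(x$r_squared, 3),
      " p =", signif(x$p_value, 3), " (", x$n, "pairs,", x$n_perm, "permutations )\n")
  invisible(x)
}

#' Turnover-environment association per scope
#'
#' For each scope (each stage's within-stage pairs, the pooled within-stage
#' pairs, the between-stage pairs, and all pairs), residualizes turnover on
#' spatial distance within the scope and runs the permutation regression of
#' the residuals on environmental distance.
#'
#' @param bundle A `succession_bundle` with an environmental table.
#' @param mode `"presence"` or `"abundance"`.
#' @param n_perm Permutations per scope.
#' @param seed Optional master seed.
#' @param variance_target Passed to [env_distance()].
#' @param pairs Optional precomputed `pairwise_turnover` (e.g. restricted).
#' @return Tibble of class `env_association`: `scope`, `slope`, `r_squared`,
#'   `p_value`, `n_pairs`, `low_power` (fewer than 3 pairs in scope).
#' @export
stagewise_association <- function(bundle, mode = c("presence", "abundance"),
                                  n_perm = 5000, seed = NULL,
                                  variance_target = 0.90, pairs = NULL) {
  mode <- match.arg(mode)
  if (is.null(bundle$env)) stop_ps("bundle has no environmental table")
  pairs <- pairs %||% pairwise_turnover(bundle, mode)
  distances <- env_distance(bundle$env, variance_target)
  scopes <- c("overall", "within", "between", levels(bundle$stages$stage))
  seeds <- spawn_seeds(seed, length(scopes))

  out <- purrr::map2(scopes, seeds, function(sc, sd_i) {
    sel <- switch(sc,
      overall = rep(TRUE, nrow(pairs)),
      within = pairs$group == "within",
      between = pairs$group == "between",
      pairs$group == "within" & as.character(pairs$stage_a) == sc)
    sub <- pairs[sel, ]
    if (sum(sub$defined) < 3)
      return(tibble(scope = sc, slope = NA_real_, r_squared = NA_real_,
                    p_value = NA_real_, n_pairs = sum(sel), low_power = TRUE))
    res <- residualize_on_space(sub, distances)
    fit <- perm_regression(res$residual, res$env_dist, n_perm, seed = sd_i)
    tibble(scope = sc, slope = fit$slope, r_squared = fit$r_squared,
           p_value = fit$p_value, n_pairs = fit$n,
           low_power = fit$n < 3 + 3)
  }) |> bind_rows()
  class(out) <- c("env_association", class(out))
  attr(out, "n_pcs") <- attr(distances, "n_pcs")
  out
}

#' Sample-size-robust association via plot resampling
#'
#' Re-assesses the within-stage turnover-environment association after
#' equalizing sample sizes: for every stage with at least `k` plots, all
#' `choose(n, k)` subsets of `k` plots are enumerated, the association is
#' re-run on each subset's pairs, and the distribution of subset R-squared
#' values is summarized. Stages with fewer than `k` plots are skipped with a
#' notice.
#'
#' @inheritParams stagewise_association
#' @param k Subset size (default 4, the minimum stage size in the study
#'   design).
#' @param n_perm Permutations per subset regression.
#' @return Tibble of class `subsample_association`: `stage`, `n_plots`,
#'   `n_subsets`, `mean_r_squared`, `mean_slope`, `prop_significant`
#'   (fraction of subsets with p <= 0.05).
#' @export
subsample_association <- function(bundle, k = 4, mode = c("presence", "abundance"),
                                  n_perm = 999, seed = NULL,
                                  variance_target = 0.90) {
  mode <- match.arg(mode)
  if (is.null(bundle$env)) stop_ps("bundle has no environmental table")
  pairs <- pairwise_turnover(bundle, mode)
  distances <- env_distance(bundle$env, variance_target)
  stages <- levels(bundle$stages$stage)
  seeds <- spawn_seeds(seed, length(stages))

  out <- purrr::map2(stages, seeds, function(s, sd_i) {
    plots <- bundle$stages$plot[bundle$stages$stage == s]
    if (length(plots) < k) {
      inform(paste0("stage ", s, " has fewer than ", k, " plots; skipped"))
      return(tibble(stage = s, n_plots = length(plots), n_subsets = 0L,
                    mean_r_squared = NA_real_, mean_slope = NA_real_,
                    prop_significant = NA_real_))
    }
    subsets <- combn(plots, k, simplify = FALSE)
    sub_seeds <- spawn_seeds(sd_i, length(subsets))
    fits <- purrr::map2(subsets, sub_seeds, function(ss, sd_j) {
      sub <- pairs[pairs$plot_a %in% ss & pairs$plot_b %in% ss, ]
      if (sum(sub$defined) < 3) return(NULL)
      res <- residualize_on_space(sub, distances)
      perm_regression(res$residual, res$env_dist, n_perm, seed = sd_j)
    })
    fits <- purrr::compact(fits)
    tibble(stage = s, n_plots = length(plots), n_subsets = length(subsets),
           mean_r_squared = mean(purrr::map_dbl(fits, "r_squared")),
           mean_slope = mean(purrr::map_dbl(fits, "slope")),
           prop_significant = mean(purrr::map_dbl(fits, "p_value") <= 0.05))
  }) |> bind_rows()
  class(out) <- c("subsample_association", class(out))
  out
}
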