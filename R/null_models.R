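#' Tip-shuffling null model over the regional pool ("1p")
#'
#' Draws a uniform random permutation of the pool phylogeny's tip names. The
#' community matrix is untouched, so the randomization preserves plot
#' richness, species turnover between plots, occurrence frequencies, and all
#' abundances; only the mapping of species names onto the phylogeny changes.
#' Equivalently, the rows/columns of the pool cophenetic matrix are permuted.
#'
#' @param tree Pool phylogeny, or a character vector of pool tip names.
#' @param seed Optional integer seed.
#' @return Integer permutation of `seq_along(tips)`, with the tip names as
#'   names: species occupying tip i is assigned the distances of tip
#'   `perm[i]`.
#' @export
shuffle_tips_1p <- function(tree, seed = NULL) {
  tips <- if (inherits(tree, "phylo")) tree$tip.label else tree
  with_seed(seed, {
    p <- sample.int(length(tips))
    names(p) <- tips
    p
  })
}

# Permuted community-species cophenetic matrix: species keep their names,
# their pairwise distances come from the permuted pool positions.
.shuffled_D_comm <- function(D_pool, comm_pos, perm) {
  q <- perm[comm_pos]
  D <- D_pool[q, q]
  dimnames(D) <- list(names(comm_pos), names(comm_pos))
  D
}

#' Null distribution of an arbitrary statistic under tip shuffling
#'
#' Recomputes `stat_fun` for `R` independent tip shuffles of the pool
#' phylogeny. `stat_fun` receives the permuted community cophenetic matrix
#' (species labels preserved) and must return a single number; `NA` returns
#' are counted as undefined replicates.
#'
#' @param bundle A `succession_bundle`.
#' @param stat_fun Function of one argument (the permuted community distance
#'   matrix) returning a scalar.
#' @param R Number of replicates (default 999).
#' @param seed Optional master seed; per-replicate streams are spawned from
#'   it and recorded in the result.
#' @param shuffle `"pool"` shuffles all pool tips (the default, spanning the
#'   full regional pool); `"community"` restricts the shuffle to community
#'   species, for sensitivity analysis.
#' @param perm_fun Optional function `(n) -> integer permutation` replacing
#'   the uniform shuffle (used for clade-restricted partial randomizations).
#' @return Object of class `null_distribution`: list with `replicates`,
#'   `mean`, `sd` (denominator R-1), `ci` (2.5/97.5% type-7 quantiles), `R`,
#'   `seed`.
#' @export
null_distribution <- function(bundle, stat_fun, R = 999, seed = NULL,
                              shuffle = c("pool", "community"),
                              perm_fun = NULL) {
  shuffle <- match.arg(shuffle)
  if (R < 1) stop_ps("R must be >= 1")
  pool_tips <- bundle$pool_tree$tip.label
  universe <- if (shuffle == "pool") pool_tips else colnames(bundle$community)
  comm_pos <- match(colnames(bundle$community), universe)
  names(comm_pos) <- colnames(bundle$community)
  D_pool <- bundle$D_pool[universe, universe]
  perm_fun <- perm_fun %||% sample.int

  reps <- with_seed(seed, {
    vapply(seq_len(R), function(r) {
      perm <- perm_fun(length(universe))
      stat_fun(.shuffled_D_comm(D_pool, comm_pos, perm))
    }, numeric(1))
  })
  n_undef <- sum(!is.finite(reps))
  if (n_undef > R / 2)
    stop_ps("statistic undefined in ", n_undef, "/", R,
            " null replicates; check for degenerate plots or mask")
  new_null_distribution(reps, seed)
}

new_null_distribution <- function(reps, seed = NULL) {
  ok <- reps[is.finite(reps)]
  structure(list(
    replicates = reps,
    mean = mean(ok),
    sd = if (length(ok) > 1) sd(ok) else NA_real_,
    ci = quantile(ok, c(0.025, 0.975), type = 7, names = FALSE),
    R = length(reps),
    n_undefined = sum(!is.finite(reps)),
    seed = seed
  ), class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> R =", x$R, " mean =", signif(x$mean, 4),
      " sd =", signif(x$sd, 4), "\n  95% CI [", signif(x$ci[1], 4), ",",
      signif(x$ci[2], 4), "]\n")
  invisible(x)
}

#' Significance of an observed statistic against a null distribution
#'
#' Rank-based p-values use the add-one convention `p = (r + 1) / (R + 1)`
#' with `r` the number of replicates strictly more extreme than the observed
#' value, so p is never zero and the test is exact when observed and
#' replicates are exchangeable (with continuous statistics, ties have
#' probability zero). The standardized effect size is
#' `SES = (obs - mean_null) / sd_null` (flagged `NA` when `sd_null = 0`).
#' `outside_ci` reports the figure-style convention: observed outside the
#' null 2.5-97.5% quantile interval.
#'
#' @param observed Observed scalar statistic.
#' @param null A `null_distribution`, or a numeric vector of replicates.
#' @return Tibble: `observed`, `null_mean`, `null_sd`, `ses`, `p_low`,
#'   `p_high`, `p_two`, `outside_ci`.
#' @export
significance <- function(observed, null) {
  if (!inherits(null, "null_distribution")) null <- new_null_distribution(null)
  reps <- null$replicates[is.finite(null$replicates)]
  R <- length(reps)
  if (!is.finite(observed) || R < 1) {
    return(tibble(observed = observed, null_mean = null$mean, null_sd = null$sd,
                  ses = NA_real_, p_low = NA_real_, p_high = NA_real_,
                  p_two = NA_real_, outside_ci = NA))
  }
  p_low <- (sum(reps < observed) + 1) / (R + 1)
  p_high <- (sum(reps > observed) + 1) / (R + 1)
  sd0 <- !is.na(null$sd) && null$sd > 0
  tibble(
    observed = observed,
    null_mean = null$mean,
    null_sd = null$sd,
    ses = if (sd0) (observed - null$mean) / null$sd else NA_real_,
    p_low = p_low, p_high = p_high,
    p_two = min(1, 2 * min(p_low, p_high)),
    outside_ci = observed < null$ci[1] | observed > null$ci[2]
  )
}

#' Null-model tests of grouped turnover
#'
#' Runs the tip-shuffling null model for the turnover statistic of one or
#' more scopes (overall, pooled within-stage, pooled between-stage, or a
#' single stage's within-stage turnover) and returns observed value, null
#' mean, 95% CI, SES and p-values per scope.
#'
#' @inheritParams null_distribution
#' @param mode `"presence"` (PIst) or `"abundance"` (Bst).
#' @param scopes Character vector drawn from `"overall"`, `"within"`,
#'   `"between"` and the stage levels; default tests all of them.
#' @param convention `"pairwise"` (mean of pairwise statistics, matching
#'   figure-style summaries) or `"pooled"` (Hardy-Senterre ratio form).
#' @return Tibble of class `turnover_test`: one row per scope with the
#'   columns of [significance()] plus `scope`, `mode`, `R`.
#' @export
turnover_null_test <- function(bundle, mode = c("presence", "abundance"),
                               scopes = NULL, R = 999, seed = NULL,
                               convention = c("pairwise", "pooled"),
                               shuffle = c("pool", "community")) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  shuffle <- match.arg(shuffle)
  scopes <- scopes %||% c("overall", "within", "between", levels(bundle$stages$stage))
  W <- .weight_matrix(bundle, mode)
  stage <- bundle$stages$stage

  seeds <- spawn_seeds(seed, length(scopes))
  out <- purrr::map2(scopes, seeds, function(sc, sd_i) {
    obs <- .scope_stat(W, bundle$D_comm, stage, sc, convention)
    nd <- null_distribution(bundle, function(D) .scope_stat(W, D, stage, sc, convention),
                            R = R, seed = sd_i, shuffle = shuffle)
    mutate(significance(obs, nd), scope = sc, ci_low = nd$ci[1], ci_high = nd$ci[2])
  }) |> bind_rows()
  out <- mutate(out, mode = mode, R = R, .before = 1) |>
    select("scope", dplyr::everything())
  class(out) <- c("turnover_test", class(out))
  out
}

#' Sensitivity of stage-level turnover to the number of plots per stage
#'
#' Simulates `n_runs` data sets under a scenario configuration, computes the
#' per-stage within-stage mean turnover, and correlates it with the number of
#' plots per stage within each run. Under neutral assembly the mean Pearson
#' correlation should be close to zero, showing that turnover levels are not
#' an artefact of unequal stage sizes. Stages must differ in plot count for
#' the correlation to exist; otherwise the run is flagged.
#'
#' @param config A [scenario_config()].
#' @param n_runs Number of simulation runs (default 100).
#' @param mode `"presence"` or `"abundance"`.
#' @param seed Optional master seed.
#' @return List with `correlations` (per-run Pearson r), `mean_r`, `n_runs`,
#'   and `undefined` (count of runs with undefined correlation).
#' @export
plot_count_sensitivity <- function(config, n_runs = 100,
                                   mode = c("presence", "abundance"),
                                   seed = NULL) {
  mode <- match.arg(mode)
  counts <- config$plots_per_stage
  if (length(unique(counts)) < 2) {
    warn_ps("identical plot counts across stages: correlation undefined")
    return(list(correlations = rep(NA_real_, n_runs), mean_r = NA_real_,
                n_runs = n_runs, undefined = n_runs))
  }
  seeds <- spawn_seeds(seed, n_runs)
  rs <- vapply(seeds, function(sd_i) {
    b <- simulate_bundle(config, seed = sd_i)
    W <- .weight_matrix(b, mode)
    per_stage <- vapply(levels(b$stages$stage), function(s)
      .scope_stat(W, b$D_comm, b$stages$stage, s), numeric(1))
    if (sd(per_stage, na.rm = TRUE) == 0) return(NA_real_)
    cor(per_stage, counts, use = "complete.obs")
  }, numeric(1))
  list(correlations = rs, mean_r = mean(rs, na.rm = TRUE),
       n_runs = n_runs, undefined = sum(is.na(rs)))
}
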