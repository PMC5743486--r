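#' Divergence-time threshold grid
#'
#' Arithmetic grid of node-age thresholds (Myr) from `min` by `step`, with
#' `max` appended when it does not fall on the grid. The defaults give the
#' eleven thresholds 30, 40, ..., 120, 128 used to profile turnover from
#' shallow to deep phylogenetic scales.
#'
#' @param min,max Youngest and oldest threshold (Myr); `max` should not
#'   exceed the root age.
#' @param step Grid step (Myr).
#' @return Increasing numeric vector of thresholds.
#' @export
threshold_grid <- function(min = 30, max = 128, step = 10) {
  if (min > max) stop_ps("min must be <= max")
  g <- seq(min, max, by = step)
  if (g[length(g)] < max) g <- c(g, max)
  g
}

# Species-pair retention mask at threshold T: pairs whose MRCA is younger
# than T, i.e. cophenetic distance < 2T on an ultrametric tree. Ties
# (MRCA age exactly T) are excluded by default, configurable to included.
.retention_mask <- function(D, threshold, ties = c("exclude", "include")) {
  ties <- match.arg(ties)
  M <- if (ties == "exclude") (D < 2 * threshold) else (D <= 2 * threshold)
  storage.mode(M) <- "double"
  diag(M) <- 0
  M
}

#' Depth-restricted pairwise turnover
#'
#' Recomputes the turnover statistic using only species pairs whose most
#' recent common ancestor is younger than the given divergence-time
#' threshold; older pairs contribute to neither the within- nor the
#' cross-plot mean distances. Plot pairs with no retained species pair are
#' flagged undefined.
#'
#' @inheritParams pairwise_turnover
#' @param threshold Age threshold (Myr), > 0.
#' @param ties `"exclude"` (MRCA age strictly < threshold, the default) or
#'   `"include"`.
#' @return A `pairwise_turnover` tibble (see [pairwise_turnover()]) with
#'   attributes `threshold` and `n_retained` (number of retained unordered
#'   species pairs in the community).
#' @export
restricted_turnover <- function(bundle, mode = c("presence", "abundance"),
                                threshold, ties = c("exclude", "include")) {
  mode <- match.arg(mode)
  if (threshold <= 0) stop_ps("threshold must be > 0")
  M <- .retention_mask(bundle$D_comm, threshold, ties)
  out <- pairwise_turnover(bundle, mode, mask = M)
  attr(out, "threshold") <- threshold
  attr(out, "n_retained") <- sum(M[upper.tri(M)] > 0)
  out
}

#' Maximal-clade partition at an age threshold
#'
#' Decomposes the tips into the maximal clades whose root node is younger
#' than `threshold`: a node qualifies when its age is below the threshold
#' while its parent's age is not. Every tip falls in exactly one such clade
#' (possibly a singleton, when even its immediate parent is older).
#'
#' @param tree A dated phylogeny.
#' @param threshold Age threshold (Myr).
#' @param ties `"exclude"` (clade age strictly < threshold) or `"include"`.
#' @return List of integer tip-index vectors, one per maximal clade with
#'   at least 2 tips (singletons are fixed points of the shuffle and
#'   omitted).
#' @export
clade_partition <- function(tree, threshold, ties = c("exclude", "include")) {
  ties <- match.arg(ties)
  ntip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  young <- if (ties == "exclude") ages < threshold else ages <= threshold
  root <- ntip + 1L
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  maximal <- which(young & (seq_along(ages) == root | !young[pmax(parent, 1L)]))
  # only internal maximal nodes can hold >1 tip
  maximal <- maximal[maximal > ntip]
  if (!length(maximal)) return(list())
  pp <- ape::prop.part(tree)
  lapply(maximal, function(v) pp[[v - ntip]])
}

#' Clade-restricted partial tip shuffle
#'
#' Permutes tip names independently within each maximal clade younger than
#' the age threshold; tips whose smallest containing clade is older stay
#' fixed. At thresholds at or above the root age this reduces to the full
#' pool-wide shuffle; below the youngest internal node it is the identity.
#'
#' @inheritParams clade_partition
#' @param seed Optional seed.
#' @param partition Optional precomputed [clade_partition()] (avoids
#'   recomputation inside replicate loops).
#' @return Integer permutation of the tip indices, named by tip label.
#' @export
partial_shuffle <- function(tree, threshold, seed = NULL, ties = c("exclude", "include"),
                            partition = NULL) {
  partition <- partition %||% clade_partition(tree, threshold, match.arg(ties))
  ntip <- ape::Ntip(tree)
  with_seed(seed, {
    p <- seq_len(ntip)
    for (tips in partition) p[tips] <- tips[sample.int(length(tips))]
    names(p) <- tree$tip.label
    p
  })
}

#' Turnover profile across phylogenetic depths
#'
#' For each stage and each age threshold, computes the depth-restricted
#' within-stage turnover, its null distribution under the matching
#' clade-restricted partial randomization, and the standardized effect size
#' `SES = (obs - mean_null) / sd_null` with rank-based p-values. Positive
#' significant SES at deep thresholds only indicates clustering confined to
#' old divergences.
#'
#' @inheritParams turnover_null_test
#' @param grid Thresholds (Myr), see [threshold_grid()].
#' @param scopes Scopes to profile; defaults to each stage's within-stage
#'   turnover. `"overall"`, `"within"`, `"between"` are also accepted.
#' @param ties Tie handling for both the pair retention and the clade
#'   partition (see [restricted_turnover()]).
#' @return Tibble of class `depth_profile`: `scope`, `threshold`, `observed`,
#'   `null_mean`, `null_sd`, `ses`, `p_two`, `significant`, `n_retained`.
#' @export
depth_profile <- function(bundle, mode = c("presence", "abundance"),
                          grid = threshold_grid(), scopes = NULL,
                          R = 999, seed = NULL,
                          convention = c("pairwise", "pooled"),
                          ties = c("exclude", "include")) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  ties <- match.arg(ties)
  scopes <- scopes %||% levels(bundle$stages$stage)
  W <- .weight_matrix(bundle, mode)
  stage <- bundle$stages$stage
  seeds <- spawn_seeds(seed, length(grid))

  rows <- purrr::imap(grid, function(th, i) {
    part <- clade_partition(bundle$pool_tree, th, ties)
    pfun <- function(n) partial_shuffle(bundle$pool_tree, th, partition = part)
    M_obs <- .retention_mask(bundle$D_comm, th, ties)
    n_ret <- sum(M_obs[upper.tri(M_obs)] > 0)
    purrr::map(scopes, function(sc) {
      obs <- .scope_stat(W, bundle$D_comm, stage, sc, convention, M = M_obs)
      stat_fun <- function(D) .scope_stat(W, D, stage, sc, convention,
                                          M = .retention_mask(D, th, ties))
      nd <- tryCatch(
        null_distribution(bundle, stat_fun, R = R, seed = seeds[[i]], perm_fun = pfun),
        phylosucc_error = function(e) NULL)
      sig <- if (is.null(nd)) significance(NA_real_, new_null_distribution(NA_real_))
             else significance(obs, nd)
      mutate(sig, scope = sc, threshold = th, n_retained = n_ret)
    }) |> bind_rows()
  }) |> bind_rows()

  out <- rows |>
    mutate(significant = is.finite(.data$p_two) & .data$p_two <= 0.05,
           mode = mode, R = R) |>
    select("scope", "threshold", "observed", "null_mean", "null_sd", "ses",
           "p_low", "p_high", "p_two", "significant", "outside_ci",
           "n_retained", "mode", "R") |>
    arrange(.data$scope, .data$threshold)
  class(out) <- c("depth_profile", class(out))
  out
}
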