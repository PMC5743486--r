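# Core engine. W is a plots x species weight matrix: 0/1 presence, or
# relative abundances f (rows summing to 1). D is the species cophenetic
# matrix (zero diagonal). M, if given, is a 0/1 species-pair retention mask
# (diagonal forced to 0) used for depth-restricted statistics.
#
# Returns list(delta = P x P matrix, den = P x P denominator matrix) where
# diag(delta)[k] is the within-plot mean distance Delta_w(k) and
# delta[k, l] the cross-plot mean distance Delta_a(k, l). Entries with a
# (near-)zero denominator are NA: singleton plots in presence mode, or plot
# pairs whose only cross pairs are same-species (conspecific pairs are always
# excluded — "distinct species").
.delta_matrix <- function(W, D, M = NULL, eps = 1e-12) {
  W <- as.matrix(W)
  if (is.null(M)) {
    num <- W %*% D %*% t(W)
    rs <- rowSums(W)
    den <- tcrossprod(rs) - tcrossprod(W)
  } else {
    diag(M) <- 0
    num <- W %*% (D * M) %*% t(W)
    den <- W %*% M %*% t(W)
  }
  delta <- num / den
  delta[den <= eps] <- NA_real_
  list(delta = delta, den = den)
}

# Pairwise turnover statistic from a delta matrix:
# stat(k,l) = 1 - mean(Delta_w(k), Delta_w(l)) / Delta_a(k,l).
.pairwise_stat <- function(delta) {
  dw <- diag(delta)
  1 - outer(dw, dw, "+") / 2 / delta
}

.weight_matrix <- function(bundle, mode) {
  switch(mode,
    presence = bundle$presence,
    abundance = bundle$abundance,
    stop_ps("mode must be 'presence' or 'abundance'"))
}

#' Within-plot phylogenetic alpha diversity
#'
#' The mean phylogenetic distance between distinct species in a plot
#' (presence mode), or between two individuals of distinct species
#' (abundance mode, weights = relative abundances). Plots with fewer than two
#' species (or all abundance on one species) are undefined and returned as
#' `NA`.
#'
#' @param bundle A `succession_bundle` (see [build_bundle()]).
#' @param mode `"presence"` or `"abundance"`.
#' @return A tibble: `plot`, `stage`, `delta_w` (Myr), `richness`,
#'   `evenness` (Shannon evenness, see [shannon_evenness()]).
#' @export
alpha_diversity <- function(bundle, mode = c("presence", "abundance")) {
  mode <- match.arg(mode)
  W <- .weight_matrix(bundle, mode)
  dm <- .delta_matrix(W, bundle$D_comm)
  tibble(
    plot = rownames(bundle$community),
    stage = bundle$stages$stage,
    delta_w = unname(diag(dm$delta)),
    richness = unname(rowSums(bundle$community > 0)),
    evenness = unname(apply(bundle$community, 1, shannon_evenness))
  )
}

#' Shannon evenness of a count vector
#'
#' `H / ln(S)` where `H` is Shannon entropy over relative abundances of the
#' `S` species with positive counts. A single-species plot has an undefined
#' ratio (`ln 1 = 0`) and is returned as 0 by convention.
#'
#' @param counts Non-negative numeric vector.
#' @return Evenness in `[0, 1]`.
#' @export
shannon_evenness <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop_ps("no positive counts")
  if (length(counts) == 1) return(0)
  f <- counts / sum(counts)
  -sum(f * log(f)) / log(length(f))
}

#' Pairwise phylogenetic turnover between plots
#'
#' For every unordered plot pair computes the within-plot mean distances
#' `Delta_w`, the cross-plot mean distance `Delta_a` (conspecific cross pairs
#' excluded), and the turnover statistic
#' `1 - mean(Delta_w(k), Delta_w(l)) / Delta_a(k, l)`: PIst for presence
#' mode, Bst for abundance mode. Positive values indicate phylogenetic
#' clustering (species within plots more related than species from different
#' plots); negative values overdispersion. Pairs are labelled within-stage or
#' between-stage from the bundle's stage map.
#'
#' @inheritParams alpha_diversity
#' @param D Optional species distance matrix overriding the bundle's cached
#'   cophenetic matrix (used by null models; must carry the same species).
#' @param mask Optional 0/1 species-pair retention mask for depth-restricted
#'   statistics.
#' @return A tibble of class `pairwise_turnover`: `plot_a`, `plot_b`,
#'   `stage_a`, `stage_b`, `group` (`"within"`/`"between"`), `stage_pair`,
#'   `delta_w_a`, `delta_w_b`, `delta_a`, `statistic`, `defined`.
#' @export
pairwise_turnover <- function(bundle, mode = c("presence", "abundance"),
                              D = NULL, mask = NULL) {
  mode <- match.arg(mode)
  W <- .weight_matrix(bundle, mode)
  dm <- .delta_matrix(W, D %||% bundle$D_comm, mask)
  st <- .pairwise_stat(dm$delta)

  plots <- rownames(bundle$community)
  stage <- bundle$stages$stage
  idx <- which(upper.tri(st), arr.ind = TRUE)
  a <- idx[, 1]; b <- idx[, 2]
  out <- tibble(
    plot_a = plots[a], plot_b = plots[b],
    stage_a = stage[a], stage_b = stage[b],
    group = ifelse(stage[a] == stage[b], "within", "between"),
    stage_pair = paste(pmin(as.character(stage[a]), as.character(stage[b])),
                       pmax(as.character(stage[a]), as.character(stage[b])), sep = "-"),
    delta_w_a = unname(diag(dm$delta)[a]),
    delta_w_b = unname(diag(dm$delta)[b]),
    delta_a = unname(dm$delta[idx]),
    statistic = unname(st[idx]),
    defined = is.finite(st[idx])
  )
  n_undef <- sum(!out$defined)
  if (n_undef > 0)
    inform(paste0(n_undef, " undefined plot pair(s) flagged (excluded from group means)"))
  class(out) <- c("pairwise_turnover", class(out))
  attr(out, "mode") <- mode
  out
}

#' Grouped turnover summaries
#'
#' Aggregates pairwise turnover to the requested grouping under two
#' conventions, both reported: `mean_stat` is the arithmetic mean of the
#' defined pairwise statistics with its descriptive standard error
#' (plot pairs are non-independent, so inference belongs to the null model);
#' `pooled_stat` is the Hardy-Senterre ratio form
#' `1 - mean(Delta_w over the group's plots) / mean(Delta_a over the group's
#' pairs)`.
#'
#' @param pairs A `pairwise_turnover` tibble.
#' @param grouping One of `"overall"` (all pairs), `"spatial_temporal"`
#'   (within-pooled vs between-pooled), `"stage"` (within-stage pairs per
#'   stage), `"stage_pair"` (between-stage pairs per stage pair).
#' @return A tibble: `group`, `mean_stat`, `se`, `pooled_stat`, `n_pairs`,
#'   `n_undefined`.
#' @export
grouped_turnover <- function(pairs, grouping = c("overall", "spatial_temporal",
                                                 "stage", "stage_pair")) {
  grouping <- match.arg(grouping)
  key <- switch(grouping,
    overall = rep("overall", nrow(pairs)),
    spatial_temporal = pairs$group,
    stage = ifelse(pairs$group == "within", as.character(pairs$stage_a), NA),
    stage_pair = ifelse(pairs$group == "between", pairs$stage_pair, NA))
  keep <- !is.na(key)
  if (!any(keep)) stop_ps("no pairs fall in the requested grouping")
  p <- pairs[keep, ]
  p$.group <- key[keep]
  p |>
    group_by(.data$.group) |>
    summarise(.groups = "drop",
      mean_stat = mean(.data$statistic[.data$defined]),
      se = if (sum(.data$defined) > 1) sd(.data$statistic[.data$defined]) / sqrt(sum(.data$defined)) else 0,
      pooled_stat = 1 - .pooled_delta_w(.data$plot_a, .data$plot_b, .data$delta_w_a, .data$delta_w_b) /
        mean(.data$delta_a[.data$defined]),
      n_pairs = n(),
      n_undefined = sum(!.data$defined)) |>
    dplyr::rename(group = ".group")
}

# Mean Delta_w over the distinct plots contributing to a group (each plot
# counted once).
.pooled_delta_w <- function(plot_a, plot_b, dw_a, dw_b) {
  dw <- c(setNames(dw_a, plot_a), setNames(dw_b, plot_b))
  dw <- dw[!duplicated(names(dw))]
  mean(dw, na.rm = TRUE)
}

# Fast scalar statistics used inside null-model loops: given the weight
# matrix, a distance matrix and the stage vector, return the grouped
# statistic for a scope without tibble overhead.
# scope: "overall", "within", "between", or a stage level (within that stage).
# convention: "pairwise" (mean of pairwise statistics) or "pooled".
.scope_stat <- function(W, D, stage, scope, convention = "pairwise", M = NULL) {
  dm <- .delta_matrix(W, D, M)
  same <- outer(stage, stage, "==")
  sel <- upper.tri(dm$delta) & switch(scope,
    overall = TRUE,
    within = same,
    between = !same,
    same & outer(stage == scope, stage == scope, "&"))
  if (convention == "pairwise") {
    st <- .pairwise_stat(dm$delta)[sel]
    return(mean(st[is.finite(st)]))
  }
  plots_in <- switch(scope,
    overall = rep(TRUE, nrow(W)), within = rep(TRUE, nrow(W)),
    between = rep(TRUE, nrow(W)), stage == scope)
  da <- dm$delta[sel]
  1 - mean(diag(dm$delta)[plots_in], na.rm = TRUE) / mean(da[is.finite(da)])
}
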