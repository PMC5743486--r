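# Align a named trait vector with the tree, pruning the tree to the species
# with data. Returns list(tree, y).
.align_trait <- function(tree, trait) {
  if (is.null(names(trait))) stop_ps("trait vector must be named by species")
  names(trait) <- normalize_names(names(trait))
  trait <- trait[is.finite(trait)]
  common <- intersect(tree$tip.label, names(trait))
  if (length(common) < 4) stop_ps("trait must cover at least 4 tips")
  drop <- setdiff(tree$tip.label, common)
  if (length(drop)) tree <- ape::drop.tip(tree, drop)
  list(tree = tree, y = trait[tree$tip.label])
}

.solve_ridge <- function(C) {
  tryCatch(solve(C), error = function(e) {
    inform("near-singular phylogenetic covariance; adding ridge 1e-10 * mean(diag)")
    solve(C + diag(1e-10 * mean(diag(C)), nrow(C)))
  })
}

#' Blomberg's K
#'
#' Ratio of the observed mean-squared-error ratio `MSE0/MSE` (ordinary vs
#' phylogenetically corrected, using the GLS ancestral mean and the tree
#' covariance matrix) to its Brownian-motion expectation. `K = 1` is the
#' Brownian expectation, `K > 1` stronger-than-Brownian signal, `K` near 0
#' no signal. Significance comes from tip-label permutations: the variance
#' of phylogenetically independent contrasts is compared to its null
#' distribution (signal gives lower-than-random contrast variance).
#'
#' @param tree Dated phylogeny.
#' @param trait Named numeric vector (names = tip labels); tips without data
#'   are pruned.
#' @param R Number of permutations.
#' @param seed Optional seed.
#' @return Tibble of class `signal_result`: `metric`, `estimate`, `p_value`,
#'   `n_species`, plus `statistic` (observed PIC variance).
#' @export
blomberg_k <- function(tree, trait, R = 999, seed = NULL) {
  al <- .align_trait(tree, trait)
  y <- al$y; tr <- al$tree; n <- length(y)
  if (sd(y) == 0) {
    warn_ps("constant trait: K undefined")
    return(.signal_row("K", NA_real_, NA_real_, n))
  }
  C <- ape::vcv(tr)
  Ci <- .solve_ridge(C)
  one <- rep(1, n)
  a <- as.numeric((one %*% Ci %*% y) / (one %*% Ci %*% one))
  dy <- y - a
  mse0 <- sum(dy^2) / (n - 1)
  mse <- as.numeric(dy %*% Ci %*% dy) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(Ci)) / (n - 1)
  k <- (mse0 / mse) / expected

  obs_v <- var(ape::pic(y, tr))
  null_v <- with_seed(seed, vapply(seq_len(R), function(i) {
    var(ape::pic(setNames(sample(y), names(y)), tr))
  }, numeric(1)))
  p <- (sum(null_v <= obs_v) + 1) / (R + 1)
  .signal_row("K", k, p, n, statistic = obs_v)
}

#' Pagel's lambda
#'
#' Maximum-likelihood estimate of the branch-length transformation `lambda`
#' scaling the off-diagonal elements of the tree covariance matrix under a
#' Gaussian trait model. `lambda = 1` is Brownian motion, `lambda = 0` a
#' star phylogeny (no signal). The estimate is found by bounded 1-D
#' optimization on `[0, lambda_max]` where `lambda_max` keeps the covariance
#' positive definite; significance is a likelihood-ratio test against
#' `lambda = 0` (chi-squared, 1 df).
#'
#' @inheritParams blomberg_k
#' @return Tibble of class `signal_result` with `metric`, `estimate`,
#'   `p_value`, `n_species`, `loglik`, `loglik0`.
#' @export
pagel_lambda <- function(tree, trait) {
  al <- .align_trait(tree, trait)
  y <- al$y; tr <- al$tree; n <- length(y)
  if (sd(y) == 0) {
    warn_ps("constant trait: lambda undefined")
    return(.signal_row("lambda", NA_real_, NA_real_, n))
  }
  C <- ape::vcv(tr)
  offdiag_max <- max(C[upper.tri(C)])
  lambda_max <- if (offdiag_max > 0) max(diag(C)) / offdiag_max else 1

  loglik <- function(lambda) {
    Cl <- lambda * C
    diag(Cl) <- diag(C)
    ch <- tryCatch(chol(Cl), error = function(e) NULL)
    if (is.null(ch)) return(-1e10)
    logdet <- 2 * sum(log(diag(ch)))
    Ci_y <- backsolve(ch, forwardsolve(t(ch), y))
    Ci_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
    a <- sum(Ci_y) / sum(Ci_1)
    dy <- y - a
    Ci_dy <- backsolve(ch, forwardsolve(t(ch), dy))
    s2 <- sum(dy * Ci_dy) / n
    -0.5 * (n * log(2 * pi * s2) + logdet + n)
  }
  opt <- optimize(loglik, c(0, lambda_max), maximum = TRUE, tol = 1e-8)
  ll0 <- loglik(0)
  # the boundary can beat the interior optimum found by optimize()
  cand <- c(opt$maximum, 0, lambda_max)
  lls <- c(opt$objective, ll0, loglik(lambda_max))
  best <- which.max(lls)
  lambda_hat <- cand[best]; ll1 <- lls[best]
  if (!is.finite(ll1) || ll1 <= -1e9)
    stop_ps("lambda likelihood optimization failed (boundary diagnostics: ",
            "ll(0)=", signif(ll0, 6), ", lambda_max=", signif(lambda_max, 4), ")")
  p <- pchisq(2 * max(0, ll1 - ll0), df = 1, lower.tail = FALSE)
  .signal_row("lambda", lambda_hat, p, n, loglik = ll1, loglik0 = ll0)
}

#' Abouheif/Moran's I
#'
#' Moran's I autocorrelation of a trait using the Abouheif phylogenetic
#' proximity: for tips i and j the proximity is the product of
#' `1 / (number of direct descendants)` over the internal nodes on the path
#' between them (diagonal zero), row-normalized. Significance is by tip
#' permutation, one-sided for positive autocorrelation.
#'
#' @inheritParams blomberg_k
#' @return Tibble of class `signal_result`.
#' @export
abouheif_moran <- function(tree, trait, R = 999, seed = NULL) {
  al <- .align_trait(tree, trait)
  y <- al$y; tr <- al$tree; n <- length(y)
  if (sd(y) == 0) {
    warn_ps("constant trait: Moran's I undefined")
    return(.signal_row("moranI", NA_real_, NA_real_, n))
  }
  W <- abouheif_proximity(tr)
  W <- W / rowSums(W)
  moran <- function(v) {
    z <- v - mean(v)
    as.numeric(z %*% W %*% z) / sum(z^2)
  }
  obs <- moran(y)
  null_i <- with_seed(seed, vapply(seq_len(R), function(i) moran(sample(y)), numeric(1)))
  p <- (sum(null_i >= obs) + 1) / (R + 1)
  .signal_row("moranI", obs, p, n)
}

#' Abouheif proximity matrix
#'
#' @param tree A phylogeny.
#' @return Symmetric tips x tips matrix, zero diagonal, entry (i, j) the
#'   product of `1/dd` over internal nodes on the path between i and j
#'   (`dd` = number of direct descendants of the node).
#' @export
abouheif_proximity <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  dd <- tabulate(tree$edge[, 1], nbins = nn)            # direct descendants
  parent <- integer(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  # L[v] = sum of log(1/dd) over internal nodes from root down to v inclusive
  w <- ifelse(dd > 0, -log(dd), 0)
  L <- numeric(nn)
  ord <- .preorder(tree)
  for (v in ord) L[v] <- if (v == root) w[v] else L[parent[v]] + (if (v > ntip) w[v] else 0)
  M <- ape::mrca(tree)
  Lp <- L[parent[seq_len(ntip)]]
  S <- outer(Lp, Lp, "+") - 2 * L[M] + w[M]
  A <- exp(S)
  diag(A) <- 0
  dimnames(A) <- list(tree$tip.label, tree$tip.label)
  A
}

.preorder <- function(tree) {
  # root first, parents before children
  e <- ape::reorder.phylo(tree, "cladewise")$edge
  c(ape::Ntip(tree) + 1L, e[, 2])
}

.signal_row <- function(metric, estimate, p, n, ...) {
  out <- tibble(metric = metric, estimate = estimate, p_value = p,
                n_species = n, ...)
  class(out) <- c("signal_result", class(out))
  out
}

#' Phylogenetic signal for a table of traits
#'
#' Runs the requested signal metrics for every trait column and stacks the
#' results (one row per trait x metric), the layout used to report signal in
#' a panel of functional traits.
#'
#' @param tree Dated phylogeny.
#' @param traits Tibble with a `species` column and one numeric column per
#'   trait (see [read_trait_table()]).
#' @param metrics Subset of `c("K", "lambda", "moranI")`.
#' @param R Permutations for K and Moran's I.
#' @param seed Optional master seed.
#' @return Tibble of class `signal_table`: `trait`, `metric`, `estimate`,
#'   `p_value`, `n_species`.
#' @export
phylo_signal <- function(tree, traits, metrics = c("K", "lambda", "moranI"),
                         R = 999, seed = NULL) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  traits <- as_tibble(traits)
  if (!"species" %in% names(traits)) names(traits)[1] <- "species"
  trait_names <- setdiff(names(traits), "species")
  seeds <- spawn_seeds(seed, length(trait_names))

  out <- purrr::map2(trait_names, seeds, function(tn, sd_i) {
    y <- setNames(traits[[tn]], traits$species)
    rows <- list()
    if ("K" %in% metrics) rows <- c(rows, list(blomberg_k(tree, y, R, sd_i)))
    if ("lambda" %in% metrics) rows <- c(rows, list(pagel_lambda(tree, y)))
    if ("moranI" %in% metrics) rows <- c(rows, list(abouheif_moran(tree, y, R, sd_i)))
    mutate(bind_rows(rows), trait = tn, .before = 1)
  }) |> bind_rows()
  class(out) <- c("signal_table", class(out))
  select(out, "trait", "metric", "estimate", "p_value", "n_species",
         dplyr::any_of(c("loglik", "loglik0", "statistic")))
}
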