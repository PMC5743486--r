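# Shared fixtures and independent brute-force oracles. The oracles enumerate
# species pairs with explicit loops and never touch the package's matrix
# engine.

balanced4 <- function() ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):2);")

star_tree <- function(n = 4) {
  labs <- LETTERS[seq_len(n)]
  ape::read.tree(text = paste0("(", paste0(labs, ":1", collapse = ","), ");"))
}

# build a bundle from explicit pieces without synthetic-data machinery
tiny_bundle <- function(tree, comm, stage_labels, env = NULL, traits = NULL) {
  stages <- tibble::tibble(plot = rownames(comm), stage = stage_labels)
  build_bundle(tree, comm, stages, env, traits)
}

# mean within-plot distance between distinct species / individuals
oracle_alpha <- function(counts, D, mode) {
  sp <- names(counts)[counts > 0]
  if (length(sp) < 2) return(NA_real_)
  if (mode == "presence") {
    tot <- 0; n <- 0
    for (i in sp) for (j in sp) if (i != j) { tot <- tot + D[i, j]; n <- n + 1 }
    return(unname(tot / n))
  }
  f <- counts / sum(counts)
  num <- 0; den <- 0
  for (i in sp) for (j in sp) if (i != j) {
    num <- num + f[i] * f[j] * D[i, j]; den <- den + f[i] * f[j]
  }
  unname(num / den)
}

# mean cross-plot distance, conspecific cross pairs excluded
oracle_beta <- function(counts_k, counts_l, D, mode) {
  sk <- names(counts_k)[counts_k > 0]; sl <- names(counts_l)[counts_l > 0]
  if (mode == "presence") {
    tot <- 0; n <- 0
    for (i in sk) for (j in sl) if (i != j) { tot <- tot + D[i, j]; n <- n + 1 }
    if (n == 0) return(NA_real_)
    return(unname(tot / n))
  }
  fk <- counts_k / sum(counts_k); fl <- counts_l / sum(counts_l)
  num <- 0; den <- 0
  for (i in sk) for (j in sl) if (i != j) {
    num <- num + fk[i] * fl[j] * D[i, j]; den <- den + fk[i] * fl[j]
  }
  if (den == 0) return(NA_real_)
  unname(num / den)
}

oracle_statistic <- function(counts_k, counts_l, D, mode) {
  dw_k <- oracle_alpha(counts_k, D, mode)
  dw_l <- oracle_alpha(counts_l, D, mode)
  da <- oracle_beta(counts_k, counts_l, D, mode)
  1 - mean(c(dw_k, dw_l)) / da
}

# depth-restricted variant: only species pairs with D < 2 * threshold count
oracle_restricted_alpha <- function(counts, D, mode, threshold) {
  D2 <- D
  D2[D >= 2 * threshold] <- NA
  sp <- names(counts)[counts > 0]
  if (mode == "presence") {
    tot <- 0; n <- 0
    for (i in sp) for (j in sp) if (i != j && !is.na(D2[i, j])) {
      tot <- tot + D2[i, j]; n <- n + 1
    }
    if (n == 0) return(NA_real_)
    return(unname(tot / n))
  }
  f <- counts / sum(counts)
  num <- 0; den <- 0
  for (i in sp) for (j in sp) if (i != j && !is.na(D2[i, j])) {
    num <- num + f[i] * f[j] * D2[i, j]; den <- den + f[i] * f[j]
  }
  if (den == 0) return(NA_real_)
  unname(num / den)
}

oracle_restricted_beta <- function(counts_k, counts_l, D, mode, threshold) {
  D2 <- D
  D2[D >= 2 * threshold] <- NA
  sk <- names(counts_k)[counts_k > 0]; sl <- names(counts_l)[counts_l > 0]
  if (mode == "presence") {
    tot <- 0; n <- 0
    for (i in sk) for (j in sl) if (i != j && !is.na(D2[i, j])) {
      tot <- tot + D2[i, j]; n <- n + 1
    }
    if (n == 0) return(NA_real_)
    return(unname(tot / n))
  }
  fk <- counts_k / sum(counts_k); fl <- counts_l / sum(counts_l)
  num <- 0; den <- 0
  for (i in sk) for (j in sl) if (i != j && !is.na(D2[i, j])) {
    num <- num + fk[i] * fl[j] * D2[i, j]; den <- den + fk[i] * fl[j]
  }
  if (den == 0) return(NA_real_)
  unname(num / den)
}

# per-node descendant counts by explicit subtree membership
oracle_node_counts <- function(tree, species) {
  ntip <- ape::Ntip(tree)
  vapply(seq_len(tree$Nnode), function(i) {
    node <- ntip + i
    tips <- ape::extract.clade(tree, node)$tip.label
    sum(species %in% tips)
  }, numeric(1))
}

# random small community matrix over the tips of `tree`
random_community <- function(tree, n_plots, max_count = 5, min_rich = 2) {
  sp <- tree$tip.label
  repeat {
    m <- matrix(sample(0:max_count, n_plots * length(sp), replace = TRUE,
                       prob = c(0.45, rep(0.55 / max_count, max_count))),
                n_plots, length(sp), dimnames = list(sprintf("p%d", seq_len(n_plots)), sp))
    if (all(rowSums(m > 0) >= min_rich) && all(colSums(m) > 0)) return(m)
  }
}
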