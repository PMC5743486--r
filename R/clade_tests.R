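#' Per-node descendant counts for a set of species
#'
#' For every internal node of the phylogeny, counts how many of the given
#' species descend from it. The root count equals the number of species
#' matched to tips.
#'
#' @param tree A phylogeny.
#' @param species Character vector of species (tip labels).
#' @return Tibble: `node` (ape node number), `age` (Myr), `clade_size`
#'   (tips under the node), `count`.
#' @export
node_counts <- function(tree, species) {
  species <- normalize_names(species)
  bad <- setdiff(species, tree$tip.label)
  if (length(bad)) stop_ps("species not in tree: ", paste(bad, collapse = ", "))
  ntip <- ape::Ntip(tree)
  memb <- .clade_membership(tree)
  present <- tree$tip.label %in% species
  tibble(
    node = ntip + seq_len(tree$Nnode),
    age = node_ages(tree)[ntip + seq_len(tree$Nnode)],
    clade_size = as.integer(rowSums(memb)),
    count = as.integer(memb %*% present)
  )
}

# internal nodes x tips 0/1 membership matrix (row i = node ntip + i)
.clade_membership <- function(tree) {
  ntip <- ape::Ntip(tree)
  pp <- ape::prop.part(tree)
  memb <- matrix(0, tree$Nnode, ntip)
  for (i in seq_along(pp)) memb[i, pp[[i]]] <- 1
  memb
}

#' Node-level over/under-representation of clades per plot ("nodesig")
#'
#' Tests, for every internal node of the pool phylogeny and every plot,
#' whether the plot holds more (or fewer) descendant taxa of that node than
#' expected when species names are shuffled across the pool phylogeny. This
#' identifies the clades driving turnover between plots. `p_more` and
#' `p_fewer` use the add-one rank convention. Because the tip shuffle places
#' a plot's n species on n uniformly chosen pool tips, the null count for a
#' clade of size c is exactly hypergeometric(pool size, c, n); the
#' `"hypergeometric"` method uses that closed form, the default
#' `"randomization"` method estimates it by Monte Carlo.
#'
#' @param bundle A `succession_bundle`.
#' @param R Number of randomizations (randomization method).
#' @param seed Optional seed.
#' @param method `"randomization"` or `"hypergeometric"`.
#' @param alpha Significance level for the `direction` flag.
#' @param p_adjust Optional p-value adjustment method passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); default `"none"`, matching the usual
#'   practice of reporting unadjusted node-level tests.
#' @return Tibble of class `nodesig`: `plot`, `node`, `age`, `clade_size`,
#'   `observed`, `null_mean`, `p_more`, `p_fewer`, `direction`
#'   (`"more"`/`"fewer"`/`"ns"`).
#' @export
nodesig <- function(bundle, R = 999, seed = NULL,
                    method = c("randomization", "hypergeometric"),
                    alpha = 0.05, p_adjust = "none") {
  method <- match.arg(method)
  if (method == "randomization" && R < 99) stop_ps("R must be >= 99")
  tree <- bundle$pool_tree
  ntip <- ape::Ntip(tree)
  memb <- .clade_membership(tree)
  X <- bundle$presence[, tree$tip.label[tree$tip.label %in% colnames(bundle$presence)],
                       drop = FALSE]
  # plot occupancy over pool tips
  occ <- matrix(0, nrow(X), ntip, dimnames = list(rownames(X), tree$tip.label))
  occ[, colnames(X)] <- X
  obs <- memb %*% t(occ)                      # nodes x plots
  richness <- colSums(t(occ))

  nnode <- tree$Nnode
  nplot <- nrow(X)
  if (method == "hypergeometric") {
    cs <- rowSums(memb)
    null_mean <- outer(cs, richness) / ntip
    # P(X >= obs) and P(X <= obs) under hypergeometric(ntip, c, n)
    p_more <- matrix(phyper(rep(obs, 1) - 1, m = rep(cs, nplot),
                            n = ntip - rep(cs, nplot),
                            k = rep(richness, each = nnode),
                            lower.tail = FALSE),
                     nnode, nplot)
    p_fewer <- matrix(phyper(rep(obs, 1), m = rep(cs, nplot),
                             n = ntip - rep(cs, nplot),
                             k = rep(richness, each = nnode)),
                      nnode, nplot)
  } else {
    ge <- matrix(0, nnode, nplot)
    le <- matrix(0, nnode, nplot)
    tot <- matrix(0, nnode, nplot)
    with_seed(seed, {
      for (r in seq_len(R)) {
        cnt <- memb[, sample.int(ntip), drop = FALSE] %*% t(occ)
        ge <- ge + (cnt >= obs)
        le <- le + (cnt <= obs)
        tot <- tot + cnt
      }
    })
    null_mean <- tot / R
    p_more <- (ge + 1) / (R + 1)
    p_fewer <- (le + 1) / (R + 1)
  }

  ages <- node_ages(tree)[ntip + seq_len(nnode)]
  out <- tibble(
    plot = rep(rownames(X), each = nnode),
    node = rep(ntip + seq_len(nnode), nplot),
    age = rep(ages, nplot),
    clade_size = rep(as.integer(rowSums(memb)), nplot),
    observed = as.integer(obs),
    null_mean = as.numeric(null_mean),
    p_more = as.numeric(p_more),
    p_fewer = as.numeric(p_fewer)
  )
  if (p_adjust != "none") {
    out$p_more <- stats::p.adjust(out$p_more, method = p_adjust)
    out$p_fewer <- stats::p.adjust(out$p_fewer, method = p_adjust)
  }
  out$direction <- ifelse(out$p_more <= alpha, "more",
                          ifelse(out$p_fewer <= alpha, "fewer", "ns"))
  class(out) <- c("nodesig", class(out))
  attr(out, "method") <- method
  out
}
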