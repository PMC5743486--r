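make_comm <- function(tree, ...) {
  rows <- list(...)
  m <- matrix(0, length(rows), ape::Ntip(tree),
              dimnames = list(names(rows), tree$tip.label))
  for (p in names(rows)) m[p, names(rows[[p]])] <- rows[[p]]
  m
}

test_that("alpha diversity matches hand-computed values on the 4-tip tree", {
  tree <- balanced4()
  comm <- make_comm(tree,
    ab = c(A = 1, B = 1),
    abcd = c(A = 2, B = 2, C = 2, D = 2),
    skew = c(A = 9, B = 1))
  b <- tiny_bundle(tree, comm, c("1", "1", "2"))

  pres <- alpha_diversity(b, "presence")
  expect_equal(pres$delta_w[1], 2)                 # single pair at distance 2
  expect_equal(pres$delta_w[2], 28 / 6)            # (2 + 2 + 4*6)/6
  ab <- alpha_diversity(b, "abundance")
  expect_equal(ab$delta_w[2], 28 / 6)              # equal abundances coincide
  expect_equal(ab$delta_w[3], 2)                   # weights cancel, one pair
})

test_that("singleton plots are flagged undefined, not zero", {
  tree <- balanced4()
  comm <- make_comm(tree, single = c(A = 3), pair = c(A = 1, B = 1))
  b <- tiny_bundle(tree, comm, c("1", "1"))
  expect_true(is.na(alpha_diversity(b, "presence")$delta_w[1]))
  suppressMessages(p <- pairwise_turnover(b, "presence"))
  expect_false(p$defined[1])
})

test_that("pairwise turnover reproduces hand-derived statistics", {
  tree <- balanced4()
  comm <- make_comm(tree, k = c(A = 1, B = 1), l = c(C = 1, D = 1))
  b <- tiny_bundle(tree, comm, c("1", "1"))
  p <- pairwise_turnover(b, "presence")
  expect_equal(p$delta_a, 6)                       # all 4 cross pairs at 6
  expect_equal(p$statistic, 1 - 2 / 6)             # PIst = 2/3

  # identical plots: cross pairs (A,B),(B,A) -> delta_a = delta_w -> 0
  comm2 <- make_comm(tree, k = c(A = 1, B = 1), l = c(A = 1, B = 1))
  p2 <- pairwise_turnover(tiny_bundle(tree, comm2, c("1", "1")), "presence")
  expect_equal(p2$statistic, 0)

  # star tree: no phylogenetic structure anywhere
  st <- star_tree(6)
  comm3 <- make_comm(st, k = c(A = 1, B = 1, C = 1), l = c(D = 1, E = 1, F = 1))
  p3 <- pairwise_turnover(tiny_bundle(st, comm3, c("1", "1")), "presence")
  expect_equal(p3$statistic, 0)
})

test_that("brute-force enumeration reproduces every delta and statistic", {
  set.seed(20)
  for (rep in 1:6) {
    n_sp <- sample(4:8, 1)
    n_pl <- sample(2:4, 1)
    tr <- simulate_tree(n_sp, seed = 100 + rep)
    tr$tip.label <- paste0("sp", seq_len(n_sp))
    comm <- random_community(tr, n_pl)
    b <- tiny_bundle(tr, comm, as.character(rep(1:2, length.out = n_pl)))
    D <- cophenetic_matrix(tr)
    for (mode in c("presence", "abundance")) {
      p <- pairwise_turnover(b, mode)
      for (r in seq_len(nrow(p))) {
        ck <- comm[p$plot_a[r], ]; cl <- comm[p$plot_b[r], ]
        expect_equal(p$delta_w_a[r], oracle_alpha(ck, D, mode), tolerance = 1e-12)
        expect_equal(p$delta_a[r], oracle_beta(ck, cl, D, mode), tolerance = 1e-12)
        expect_equal(p$statistic[r], oracle_statistic(ck, cl, D, mode),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("turnover is scale-invariant and bounded above by one", {
  tr <- simulate_tree(12, seed = 9)
  comm <- random_community(tr, 4)
  b1 <- tiny_bundle(tr, comm, c("1", "1", "2", "2"))
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 7.3
  b2 <- tiny_bundle(tr2, comm, c("1", "1", "2", "2"))
  for (mode in c("presence", "abundance")) {
    p1 <- pairwise_turnover(b1, mode); p2 <- pairwise_turnover(b2, mode)
    expect_equal(p1$statistic, p2$statistic, tolerance = 1e-10)
    expect_true(all(p1$statistic[p1$defined] <= 1))
  }
})

test_that("presence and abundance statistics coincide under equal abundances", {
  tr <- simulate_tree(10, seed = 13)
  comm <- (random_community(tr, 4) > 0) * 3       # equal counts where present
  b <- tiny_bundle(tr, comm, c("1", "1", "2", "2"))
  expect_equal(pairwise_turnover(b, "presence")$statistic,
               pairwise_turnover(b, "abundance")$statistic, tolerance = 1e-12)
})

test_that("grouped summaries follow the stage-map combinatorics", {
  tr <- simulate_tree(16, seed = 17)
  comm <- random_community(tr, 8)
  b <- tiny_bundle(tr, comm, as.character(rep(1:4, each = 2)))
  p <- pairwise_turnover(b, "presence")
  expect_equal(nrow(p), choose(8, 2))
  g <- grouped_turnover(p, "spatial_temporal")
  expect_equal(g$n_pairs[g$group == "within"], 4L)
  expect_equal(g$n_pairs[g$group == "between"], choose(8, 2) - 4L)

  # a one-pair group's mean equals the pairwise value, with zero SE
  gs <- grouped_turnover(p, "stage")
  one <- p[p$group == "within" & p$stage_a == "2", ]
  expect_equal(gs$mean_stat[gs$group == "2"], one$statistic)
  expect_equal(gs$se[gs$group == "2"], 0)

  # pooled convention against direct computation for one stage
  plots <- c("p1", "p2")
  dw <- p$delta_w_a[p$plot_a == "p1" & p$plot_b == "p2"]
  dw2 <- p$delta_w_b[p$plot_a == "p1" & p$plot_b == "p2"]
  da <- p$delta_a[p$plot_a == "p1" & p$plot_b == "p2"]
  expect_equal(gs$pooled_stat[gs$group == "1"], 1 - mean(c(dw, dw2)) / da)
})

test_that("identical composition everywhere gives zero turnover and zero SE", {
  tr <- simulate_tree(8, seed = 19)
  row <- c(2, 0, 3, 1, 0, 4, 1, 2)
  comm <- rbind(p1 = row, p2 = row, p3 = row, p4 = row)
  colnames(comm) <- tr$tip.label
  b <- suppressMessages(tiny_bundle(tr, comm, c("1", "1", "2", "2")))
  p <- pairwise_turnover(b, "abundance")
  expect_equal(p$statistic, rep(0, 6), tolerance = 1e-12)
  g <- grouped_turnover(p, "overall")
  expect_equal(g$mean_stat, 0, tolerance = 1e-12)
  expect_equal(g$se, 0, tolerance = 1e-12)
})

test_that("shannon evenness behaves over its range", {
  expect_equal(shannon_evenness(c(5, 5, 5, 5)), 1)
  h <- -(0.97 * log(0.97) + 3 * 0.01 * log(0.01))
  expect_equal(shannon_evenness(c(97, 1, 1, 1)), h / log(4))
  expect_equal(shannon_evenness(c(0, 7, 0)), 0)    # degenerate single species
  expect_error(shannon_evenness(c(0, 0)), "positive")
})
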