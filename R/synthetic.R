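#' Scenario configuration for the chronosequence generator
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study design the analyses are built for: 27 plots in 5 successional
#' stages (5/4/5/6/7 plots), 143 community species drawn from a 410-species
#' regional pool, a dated pool phylogeny with root age 128 Myr, abundance
#' distributions that become more even in later stages, and (in the
#' filtering scenarios) a single latent environmental gradient that sorts
#' species by a phylogenetically conserved niche trait.
#'
#' Scenarios: `neutral` (uniform lottery assembly), `filtering_conserved`
#' (Gaussian niche filtering in every stage), `overdispersion` (filtering
#' plus a repulsion penalty against co-occurring close relatives),
#' `deep_filtering_late` (neutral in stages 1-3, deep-clade niche filtering
#' in stages 4-5), `dominance_shift` (near-constant composition, evenness
#' increasing across stages).
#'
#' @param scenario Scenario name (see above).
#' @param pool_size Tips in the regional pool phylogeny.
#' @param n_community Species occurring in the plots (community pool).
#' @param plots_per_stage Integer vector of plots per successional stage.
#' @param birth,death Birth-death rates for the pool tree simulation.
#' @param root_age Root age (Myr) the tree is rescaled to.
#' @param niche_model `"two_clade_shift"` (deep niche conservatism: the two
#'   daughter clades of an old node are offset to opposite niche optima) or
#'   `"BM"` (Brownian niche).
#' @param clade_split_age Target age (Myr) of the node carrying the planted
#'   niche split; the nearest internal node is used and its true age
#'   recorded.
#' @param niche_shift Niche offset of the two daughter clades (+/-).
#' @param niche_sd Brownian standard deviation of tip niches around their
#'   clade optimum.
#' @param niche_breadth Gaussian niche-kernel width `w` in
#'   `exp(-(niche - env)^2 / (2 w^2))`.
#' @param gradient_span Plot environments are drawn uniformly on
#'   `[-gradient_span, gradient_span]`.
#' @param repulsion_dist Minimum cophenetic distance (Myr) tolerated between
#'   co-occurring species in the `overdispersion` scenario.
#' @param richness_range Range of per-plot species richness.
#' @param individuals_range Mean individuals per plot in the first and last
#'   stage (interpolated linearly; later stages hold fewer individuals).
#' @param evenness_range Lognormal `sdlog` of abundance weights in the first
#'   and last stage (interpolated; smaller sdlog = more even).
#' @param n_env_vars Number of observed environmental variables.
#' @param n_latent Latent environmental factors behind the observed
#'   variables (1 = the assembly gradient; larger values give a multi-factor
#'   environment for PCA behaviour checks).
#' @param env_noise_sd Noise standard deviation of observed variables.
#' @param spatial_gradient If `TRUE`, the x coordinate is correlated with
#'   the gradient (to exercise spatial partialling); default independent.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("neutral", "filtering_conserved",
                                         "overdispersion", "dominance_shift",
                                         "deep_filtering_late"),
                            pool_size = 410, n_community = 143,
                            plots_per_stage = c(5, 4, 5, 6, 7),
                            birth = 1, death = 0, root_age = 128,
                            niche_model = c("two_clade_shift", "BM"),
                            clade_split_age = 100, niche_shift = 2,
                            niche_sd = 0.5, niche_breadth = 0.8,
                            gradient_span = 2, repulsion_dist = 30,
                            richness_range = c(25, 55),
                            individuals_range = c(400, 150),
                            evenness_range = c(1.5, 0.5),
                            n_env_vars = 10, n_latent = 1,
                            env_noise_sd = 0.5, spatial_gradient = FALSE) {
  scenario <- match.arg(scenario)
  niche_model <- match.arg(niche_model)
  if (any(plots_per_stage < 1)) stop_ps("plots_per_stage must be positive")
  if (pool_size < n_community) stop_ps("pool must be at least as large as the community")
  structure(as.list(environment()), class = "scenario_config")
}

#' Simulate an ultrametric birth-death pool phylogeny
#'
#' Birth-death tree conditioned on the number of tips, rescaled so the root
#' age equals `root_age` Myr.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth,death Speciation and extinction rates; `death < birth`.
#' @param root_age Target root age (Myr).
#' @param seed Optional seed.
#' @return An [ape::phylo] object with tips `s001`, `s002`, ...
#' @export
simulate_tree <- function(n_tips, birth = 1, death = 0, root_age = 128, seed = NULL) {
  if (n_tips < 2) stop_ps("n_tips must be >= 2")
  if (death >= birth) stop_ps("death rate must be below birth rate")
  with_seed(seed, {
    tree <- ape::rphylo(n_tips, birth = birth, death = death)
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * root_age / depth
    tree$tip.label <- sprintf("s%03d", seq_len(n_tips))
    tree
  })
}

#' Evolve a continuous trait on a phylogeny
#'
#' Models: `BM` (Brownian motion, increments proportional to branch length),
#' `lambda` (Brownian motion on the lambda-transformed covariance),
#' `white` (independent Gaussian noise, no signal), `two_clade_shift`
#' (Brownian motion plus opposite offsets `+delta`/`-delta` for the two
#' daughter clades of the internal node nearest `split_age`, planting deep
#' niche conservatism).
#'
#' @param tree A dated phylogeny.
#' @param model One of `"BM"`, `"lambda"`, `"white"`, `"two_clade_shift"`.
#' @param sigma Brownian (or white-noise) standard deviation per unit time
#'   (per tip for `white`).
#' @param lambda Pagel's lambda for the `lambda` model.
#' @param delta Clade offset for `two_clade_shift`.
#' @param split_age Target age of the split node for `two_clade_shift`.
#' @param seed Optional seed.
#' @return Named numeric vector of tip values. For `two_clade_shift` the
#'   attributes `split_node`, `split_age` (actual node age) and
#'   `clade_sign` (named +1/-1/0 per tip) record the planted structure.
#' @export
evolve_trait <- function(tree, model = c("BM", "lambda", "white", "two_clade_shift"),
                         sigma = 1, lambda = 0.5, delta = 2, split_age = 100,
                         seed = NULL) {
  model <- match.arg(model)
  ntip <- ape::Ntip(tree)
  with_seed(seed, switch(model,
    BM = ape::rTraitCont(tree, model = "BM", sigma = sigma),
    white = setNames(rnorm(ntip, 0, sigma), tree$tip.label),
    lambda = {
      C <- ape::vcv(tree)
      Cl <- lambda * C
      diag(Cl) <- diag(C)
      y <- drop(t(chol(sigma^2 * Cl)) %*% rnorm(ntip))
      setNames(y, tree$tip.label)
    },
    two_clade_shift = {
      y <- ape::rTraitCont(tree, model = "BM", sigma = sigma)
      ages <- node_ages(tree)
      internal <- ntip + seq_len(tree$Nnode)
      node <- internal[which.min(abs(ages[internal] - split_age))]
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      sign_vec <- setNames(rep(0, ntip), tree$tip.label)
      for (i in seq_along(kids)) {
        tips <- .descendant_tips(tree, kids[i])
        sign_vec[tips] <- if (i == 1) 1 else -1
        y[tips] <- y[tips] + (if (i == 1) delta else -delta)
      }
      attr(y, "split_node") <- node
      attr(y, "split_age") <- ages[node]
      attr(y, "clade_sign") <- sign_vec
      y
    }))
}

.descendant_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  pp <- ape::prop.part(tree)
  tree$tip.label[pp[[node - ntip]]]
}

#' Assemble staged communities along an environmental gradient
#'
#' Places plots on a one-dimensional latent environmental gradient, derives
#' noisy observed environmental variables and independent x/y coordinates,
#' and fills each plot with species according to the scenario's occupancy
#' model (see [scenario_config()]). Abundances follow a lognormal model
#' whose evenness increases across stages.
#'
#' @param config A `scenario_config`.
#' @param tree Pool phylogeny.
#' @param niche Named niche-trait vector over pool tips (ignored by the
#'   neutral and dominance-shift scenarios).
#' @param seed Optional seed.
#' @return List with `community` (plot x species counts over the community
#'   species), `stages`, `env`, and `community_species`.
#' @export
assemble_communities <- function(config, tree, niche = NULL, seed = NULL) {
  cf <- config
  n_stages <- length(cf$plots_per_stage)
  n_plots <- sum(cf$plots_per_stage)
  plot_ids <- sprintf("P%02d", seq_len(n_plots))
  stage_of <- rep(seq_len(n_stages), cf$plots_per_stage)
  needs_niche <- cf$scenario %in% c("filtering_conserved", "overdispersion",
                                    "deep_filtering_late")
  if (needs_niche && is.null(niche)) stop_ps("scenario needs a niche trait")

  with_seed(seed, {
    comm_species <- sort(sample(tree$tip.label, cf$n_community))
    e <- runif(n_plots, -cf$gradient_span, cf$gradient_span)
    D <- NULL
    if (cf$scenario == "overdispersion") D <- cophenetic_matrix(tree)[comm_species, comm_species]

    sdlog_stage <- seq(cf$evenness_range[1], cf$evenness_range[2], length.out = n_stages)
    indiv_stage <- seq(cf$individuals_range[1], cf$individuals_range[2], length.out = n_stages)
    core <- if (cf$scenario == "dominance_shift")
      sample(comm_species, min(mean(cf$richness_range), cf$n_community)) else NULL

    community <- matrix(0L, n_plots, cf$n_community,
                        dimnames = list(plot_ids, comm_species))
    for (k in seq_len(n_plots)) {
      s <- stage_of[k]
      S_k <- if (!is.null(core)) length(core)
             else sample(seq(cf$richness_range[1], cf$richness_range[2]), 1)
      filt <- switch(cf$scenario,
        neutral = , dominance_shift = FALSE,
        deep_filtering_late = s >= n_stages - 1,
        TRUE)
      if (!is.null(core)) {
        chosen <- core
      } else if (!filt) {
        chosen <- sample(comm_species, S_k)
      } else {
        wts <- exp(-(niche[comm_species] - e[k])^2 / (2 * cf$niche_breadth^2))
        wts <- pmax(wts, 1e-12)
        if (cf$scenario == "overdispersion") {
          chosen <- character(0)
          cand_w <- wts
          while (length(chosen) < S_k && any(cand_w > 0)) {
            pick <- sample(comm_species, 1, prob = cand_w)
            chosen <- c(chosen, pick)
            cand_w[pick] <- 0
            cand_w[D[pick, ] < cf$repulsion_dist & cand_w > 0 &
                     comm_species != pick] <- 0
          }
        } else {
          chosen <- sample(comm_species, S_k, prob = wts)
        }
      }
      n_ind <- max(length(chosen), round(indiv_stage[s] * runif(1, 0.8, 1.2)))
      w <- rlnorm(length(chosen), 0, sdlog_stage[s])
      counts <- drop(rmultinom(1, n_ind - length(chosen), prob = w)) + 1L
      community[k, chosen] <- counts
    }

    # guarantee every community-pool species is observed somewhere (a single
    # individual in a uniformly chosen plot, so tree-independence and the
    # exchangeability behind the exact null test are preserved); the
    # dominance-shift scenario keeps its fixed core composition instead
    if (is.null(core)) {
      for (sp in comm_species[colSums(community) == 0])
        community[sample.int(n_plots, 1), sp] <- 1L
    }

    # observed environment: latent factors (factor 1 = assembly gradient)
    Fmat <- cbind(e, if (cf$n_latent > 1)
      matrix(rnorm(n_plots * (cf$n_latent - 1)), n_plots))
    loadings <- runif(cf$n_env_vars, 0.7, 1) * sample(c(-1, 1), cf$n_env_vars, TRUE)
    fac_of <- 1 + (seq_len(cf$n_env_vars) - 1) %% cf$n_latent
    V <- sapply(seq_len(cf$n_env_vars), function(j)
      loadings[j] * Fmat[, fac_of[j]] + rnorm(n_plots, 0, cf$env_noise_sd))
    colnames(V) <- sprintf("env%02d", seq_len(cf$n_env_vars))
    # half the variables are reported on a strictly positive scale
    pos <- seq(2, cf$n_env_vars, by = 2)
    V[, pos] <- exp(V[, pos] / max(abs(V[, pos])) * 2)
    x <- if (cf$spatial_gradient) 500 + 200 * e + rnorm(n_plots, 0, 50)
         else runif(n_plots, 0, 1000)
    env <- tibble(plot = plot_ids, x = x, y = runif(n_plots, 0, 1000),
                  as_tibble(V))

    list(community = community,
         stages = tibble(plot = plot_ids,
                         stage = factor(stage_of, levels = seq_len(n_stages),
                                        ordered = TRUE)),
         env = env, community_species = comm_species, gradient = e)
  })
}

#' Simulate a complete analysis bundle under a scenario
#'
#' One-call generator: simulates the pool phylogeny, the niche trait (for
#' filtering scenarios), the staged communities with environment, and six
#' Brownian functional traits over the community species, and assembles the
#' validated `succession_bundle`.
#'
#' @param config A [scenario_config()] (or a scenario name, for defaults).
#' @param seed Optional seed (deterministic output for a fixed seed).
#' @return A `succession_bundle` with attributes `scenario`, `config`, and
#'   (for `two_clade_shift` niches) `split_age`.
#' @export
simulate_bundle <- function(config = scenario_config(), seed = NULL) {
  if (is.character(config)) config <- scenario_config(config)
  seeds <- spawn_seeds(seed, 4)
  tree <- simulate_tree(config$pool_size, config$birth, config$death,
                        config$root_age, seed = seeds[[1]])
  niche <- NULL
  if (config$scenario %in% c("filtering_conserved", "overdispersion",
                             "deep_filtering_late")) {
    niche <- if (config$niche_model == "two_clade_shift")
      evolve_trait(tree, "two_clade_shift", sigma = config$niche_sd / sqrt(config$root_age),
                   delta = config$niche_shift, split_age = config$clade_split_age,
                   seed = seeds[[2]])
    else evolve_trait(tree, "BM", sigma = config$niche_sd / sqrt(config$root_age),
                      seed = seeds[[2]])
  }
  parts <- assemble_communities(config, tree, niche, seed = seeds[[3]])

  trait_names <- c("leaf_area", "sla", "leaf_n", "leaf_p", "wood_density", "max_height")
  trait_seeds <- spawn_seeds(seeds[[4]], length(trait_names))
  traits <- purrr::map2(trait_names, trait_seeds, function(tn, sd_i) {
    evolve_trait(tree, "BM", sigma = 1 / sqrt(config$root_age), seed = sd_i)[parts$community_species]
  })
  traits <- tibble(species = parts$community_species, !!!setNames(traits, trait_names))

  bundle <- build_bundle(tree, parts$community, parts$stages, parts$env, traits)
  attr(bundle, "scenario") <- config$scenario
  attr(bundle, "config") <- config
  attr(bundle, "gradient") <- parts$gradient
  if (!is.null(niche) && !is.null(attr(niche, "split_age")))
    attr(bundle, "split_age") <- attr(niche, "split_age")
  bundle
}

#' Write a deterministic on-disk fixture for a scenario
#'
#' Simulates a bundle and writes it as plain-text files (Newick tree + TSV
#' tables) plus a JSON manifest recording the scenario parameters and seed.
#' The same seed always yields byte-identical files.
#'
#' @param config Scenario name or [scenario_config()].
#' @param seed Integer seed (required, for reproducibility).
#' @param dir Output directory.
#' @return The bundle, invisibly; files under `dir`.
#' @export
make_fixture <- function(config, seed, dir) {
  if (is.character(config)) config <- scenario_config(config)
  bundle <- simulate_bundle(config, seed = seed)
  write_bundle(bundle, dir)
  manifest <- c(unclass(config),
                list(seed = seed, split_age = attr(bundle, "split_age")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(bundle)
}
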