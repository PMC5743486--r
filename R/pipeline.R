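#' Run configuration for the full analysis pipeline
#'
#' @param input Either a directory holding an on-disk bundle (see
#'   [read_bundle()]), a `succession_bundle`, or a [scenario_config()] /
#'   scenario name to simulate.
#' @param modes Turnover modes to run (`"presence"`, `"abundance"`).
#' @param R_null Null-model replicates (default 999).
#' @param n_perm Permutations for environment regressions (default 5000).
#' @param grid Depth threshold grid (Myr).
#' @param variance_target PCA variance target for environmental distances.
#' @param k Resampling subset size for [subsample_association()].
#' @param nodesig_R Randomizations for [nodesig()].
#' @param seed Master seed, recorded in the manifest.
#' @return List of class `run_config`.
#' @export
run_config <- function(input, modes = c("presence", "abundance"),
                       R_null = 999, n_perm = 5000, grid = threshold_grid(),
                       variance_target = 0.90, k = 4, nodesig_R = 999,
                       seed = 1L) {
  stopifnot(R_null >= 1, n_perm >= 1, k >= 2, nodesig_R >= 99)
  structure(list(input = input, modes = modes, R_null = R_null,
                 n_perm = n_perm, grid = grid,
                 variance_target = variance_target, k = k,
                 nodesig_R = nodesig_R, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full turnover analysis and write tabular reports
#'
#' Orchestrates the whole analysis sequence on a bundle: per-plot alpha
#' diversity and evenness; overall / within-stage / between-stage turnover
#' with null CIs; per-stage and stage-pair turnover tests; environment
#' associations with spatial partialling and the plot-resampling check;
#' depth profiles under clade-restricted randomizations; nodesig clade
#' enrichment; and phylogenetic signal for the trait table. Each result is
#' written as a TSV under `out_dir`, with a JSON manifest recording seeds
#' and sizes. Undefined/flagged quantities are reported, never silently
#' dropped.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return Named list of result tibbles (invisibly also written to disk).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  bundle <- config$input
  if (is.character(bundle) && length(bundle) == 1 && dir.exists(bundle))
    bundle <- read_bundle(bundle)
  if (is.character(bundle) || inherits(bundle, "scenario_config"))
    bundle <- simulate_bundle(bundle, seed = config$seed)
  stopifnot(inherits(bundle, "succession_bundle"))
  seeds <- spawn_seeds(config$seed, 6)

  results <- list()
  results$alpha_diversity <- purrr::map(config$modes, function(m)
    mutate(alpha_diversity(bundle, m), mode = m)) |> bind_rows()

  results$turnover_summary <- purrr::map(config$modes, function(m)
    turnover_null_test(bundle, m, scopes = c("overall", "within", "between"),
                       R = config$R_null, seed = seeds[[1]])) |> bind_rows()

  results$stage_turnover <- purrr::map(config$modes, function(m) {
    within <- turnover_null_test(bundle, m, scopes = levels(bundle$stages$stage),
                                 R = config$R_null, seed = seeds[[2]])
    pairs <- pairwise_turnover(bundle, m)
    bind_rows(within,
              mutate(grouped_turnover(pairs, "stage_pair"), mode = m,
                     scope = .data$group, observed = .data$mean_stat))
  }) |> bind_rows()

  if (!is.null(bundle$env)) {
    results$env_association <- purrr::map(config$modes, function(m)
      mutate(stagewise_association(bundle, m, n_perm = config$n_perm,
                                   seed = seeds[[3]],
                                   variance_target = config$variance_target),
             mode = m)) |> bind_rows()
    results$subsample_association <- mutate(
      subsample_association(bundle, k = config$k, mode = config$modes[1],
                            n_perm = min(config$n_perm, 999), seed = seeds[[3]],
                            variance_target = config$variance_target),
      mode = config$modes[1])
  }

  results$depth_profile <- depth_profile(bundle, config$modes[1],
                                         grid = config$grid, R = config$R_null,
                                         seed = seeds[[4]])
  results$nodesig <- nodesig(bundle, R = config$nodesig_R, seed = seeds[[5]])
  if (!is.null(bundle$traits))
    results$signal <- phylo_signal(bundle$comm_tree, bundle$traits,
                                   R = config$R_null, seed = seeds[[6]])

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(results))
      utils::write.table(results[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(
      seed = config$seed, R_null = config$R_null, n_perm = config$n_perm,
      grid = config$grid, modes = config$modes,
      scenario = attr(bundle, "scenario"),
      n_plots = nrow(bundle$community), n_species = ncol(bundle$community),
      pool_size = ape::Ntip(bundle$pool_tree),
      package_version = as.character(utils::packageVersion("phylosucc")),
      flagged = list(
        undefined_pairs = sum(!pairwise_turnover(bundle, config$modes[1])$defined),
        undefined_depth_cells = sum(!is.finite(results$depth_profile$ses))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(results)
}
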