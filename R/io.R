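#' Read and validate an ultrametric dated phylogeny
#'
#' Reads a Newick file with branch lengths (interpreted as Myr) and checks the
#' tree is rooted, has unique tip labels, non-negative branch lengths, and is
#' ultrametric (all root-to-tip path lengths equal within a relative
#' tolerance). Node ages (Myr before present, tips at age 0) can then be
#' obtained with [node_ages()].
#'
#' @param path Path to a Newick file.
#' @param force If `TRUE`, accept a non-ultrametric tree with a warning (ages
#'   are then measured from the deepest tip plane).
#' @param tol Relative ultrametricity tolerance, as a fraction of tree depth.
#' @return An [ape::phylo] object with normalized tip labels.
#' @export
read_phylogeny <- function(path, force = FALSE, tol = 1e-6) {
  if (!file.exists(path)) stop_ps("phylogeny file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
    error = function(e) stop_ps("failed to parse Newick in ", path, ": ", conditionMessage(e)))
  if (is.null(tree)) stop_ps("failed to parse Newick in ", path)
  validate_phylogeny(tree, force = force, tol = tol)
}

#' Validate a phylogeny object
#'
#' @param tree An [ape::phylo] object.
#' @inheritParams read_phylogeny
#' @return The tree, with normalized tip labels.
#' @export
validate_phylogeny <- function(tree, force = FALSE, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop_ps("not a phylo object")
  if (is.null(tree$edge.length)) stop_ps("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop_ps("negative branch lengths")
  if (ape::Ntip(tree) < 2) stop_ps("tree must have at least 2 tips")
  # a basal polytomy (e.g. a star tree) is fine when the tip plane defines
  # the root; ape::is.rooted is false for those
  if (!ape::is.rooted(tree) && !is_ultrametric_tol(tree, tol))
    stop_ps("tree must be rooted")
  tree$tip.label <- normalize_names(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) {
    stop_ps("duplicate tip labels: ",
            paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (!is_ultrametric_tol(tree, tol)) {
    if (!force) stop_ps("tree is not ultrametric within relative tolerance ", tol,
                        "; use force = TRUE to accept it")
    warn_ps("tree is not ultrametric; node ages measured from the deepest tip")
  }
  tree
}

#' Ultrametricity check with relative tolerance
#'
#' @inheritParams validate_phylogeny
#' @return Logical.
#' @export
is_ultrametric_tol <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  max(depths) - min(depths) <= tol * max(depths)
}

#' Node ages of a dated phylogeny
#'
#' Ages are measured backwards from the tip plane: a node's age is the tree
#' depth minus its distance from the root, so tips have age 0 and the root has
#' the largest age.
#'
#' @param tree An [ape::phylo] object.
#' @return Numeric vector of length `Ntip + Nnode`, indexed like the tree's
#'   internal node numbering (tips first).
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(ape::Ntip(tree))]) - depth
}

#' Cophenetic (patristic) distance matrix
#'
#' Pairwise sum of branch lengths separating each pair of tips; on an
#' ultrametric dated tree this equals twice the age of the pair's most recent
#' common ancestor.
#'
#' @param tree An [ape::phylo] object.
#' @return Symmetric matrix (Myr) with zero diagonal, tip labels as dimnames.
#' @export
cophenetic_matrix <- function(tree) {
  stats::cophenetic(tree)
}

# ---------------------------------------------------------------------------
# Delimited tables

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop_ps("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "",
                    fileEncoding = "UTF-8")
}

#' Read a plot-by-species community table
#'
#' First column = plot identifier, remaining columns = species, cells =
#' individual counts (non-negative integers). TSV or CSV, auto-detected.
#'
#' @param path File path.
#' @return A matrix (plots x species) of integer counts with dimnames.
#' @export
read_community <- function(path) {
  df <- read_delim_auto(path)
  plots <- normalize_names(df[[1]])
  if (anyDuplicated(plots)) stop_ps("duplicate plot identifiers in community table")
  m <- as.matrix(df[, -1, drop = FALSE])
  colnames(m) <- normalize_names(colnames(df)[-1])
  if (anyDuplicated(colnames(m))) stop_ps("duplicate species identifiers in community table")
  rownames(m) <- plots
  storage.mode(m) <- "double"
  validate_community(m)
}

#' Validate a community count matrix
#' @param m Numeric matrix, plots x species.
#' @return The matrix, integer-valued.
#' @export
validate_community <- function(m) {
  if (anyNA(m)) stop_ps("missing values in community table")
  if (any(m < 0)) stop_ps("negative counts in community table")
  if (any(abs(m - round(m)) > 1e-8)) stop_ps("non-integer counts in community table")
  m <- round(m)
  if (any(rowSums(m) == 0)) {
    stop_ps("plots with zero individuals: ",
            paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  }
  m
}

#' Read a plot-to-successional-stage map
#'
#' Two columns: plot identifier and stage label. Stages are kept as an ordered
#' factor in order of first appearance of sorted unique labels.
#'
#' @param path File path.
#' @return A tibble with columns `plot`, `stage` (ordered factor).
#' @export
read_stage_map <- function(path) {
  df <- read_delim_auto(path)
  if (ncol(df) < 2) stop_ps("stage table needs two columns: plot, stage")
  out <- tibble(plot = normalize_names(df[[1]]),
                stage = factor(df[[2]], levels = sort(unique(df[[2]])), ordered = TRUE))
  if (anyDuplicated(out$plot)) stop_ps("duplicate plot identifiers in stage table")
  out
}

#' Read a plot-level environmental table
#'
#' First column = plot identifier; must contain planar coordinate columns
#' `x` and `y`; remaining columns are environmental variables.
#'
#' @param path File path.
#' @return A tibble with `plot`, `x`, `y` and the environmental variables.
#' @export
read_env_table <- function(path) {
  df <- read_delim_auto(path)
  names(df)[1] <- "plot"
  df$plot <- normalize_names(df$plot)
  if (anyDuplicated(df$plot)) stop_ps("duplicate plot identifiers in environmental table")
  if (!all(c("x", "y") %in% names(df))) stop_ps("environmental table must have x and y coordinate columns")
  if (anyNA(df$x) || anyNA(df$y)) stop_ps("missing coordinates in environmental table")
  as_tibble(df)
}

#' Read a species-by-trait table
#'
#' First column = species identifier; remaining columns are numeric traits.
#'
#' @param path File path.
#' @return A tibble with `species` and one column per trait.
#' @export
read_trait_table <- function(path) {
  df <- read_delim_auto(path)
  names(df)[1] <- "species"
  df$species <- normalize_names(df$species)
  if (anyDuplicated(df$species)) stop_ps("duplicate species identifiers in trait table")
  as_tibble(df)
}

# ---------------------------------------------------------------------------
# Pool filtering and alignment

#' Prune a regional species pool by named exclusion lists
#'
#' Applies exclusion rules supplied as named lists of tip labels (e.g.
#' non-angiosperms, bamboos, cultivated species) and reports how many tips
#' each rule removed. Names absent from the tree raise a warning, not an
#' error.
#'
#' @param tree Pool phylogeny.
#' @param exclude Named list of character vectors of tip labels to drop.
#' @return The pruned tree, with a `removal_report` attribute: a tibble of
#'   rule, n requested, n removed.
#' @export
apply_pool_filters <- function(tree, exclude = list()) {
  if (length(exclude) == 0) {
    attr(tree, "removal_report") <- tibble(rule = character(), n_requested = integer(),
                                           n_removed = integer())
    return(tree)
  }
  if (is.null(names(exclude)) || any(!nzchar(names(exclude))))
    names(exclude) <- paste0("rule", seq_along(exclude))
  report <- vector("list", length(exclude))
  dropped <- character()
  for (i in seq_along(exclude)) {
    want <- normalize_names(exclude[[i]])
    present <- intersect(setdiff(want, dropped), tree$tip.label)
    missing <- setdiff(want, c(tree$tip.label, dropped))
    if (length(missing))
      warn_ps("exclusion names not in tree (rule '", names(exclude)[i], "'): ",
              paste(missing, collapse = ", "))
    dropped <- c(dropped, present)
    report[[i]] <- tibble(rule = names(exclude)[i],
                          n_requested = length(want), n_removed = length(present))
  }
  if (length(dropped) >= ape::Ntip(tree) - 1)
    stop_ps("exclusions would leave fewer than 2 tips")
  out <- ape::drop.tip(tree, dropped)
  attr(out, "removal_report") <- bind_rows(report)
  out
}

#' Assemble the aligned analysis bundle
#'
#' Aligns the five inputs (pool phylogeny, community counts, stage map,
#' environmental table, trait table) by normalized identifiers, prunes the
#' pool tree down to the community species, and caches both cophenetic
#' matrices. Species columns whose total count is zero are dropped with a
#' message. Every community species must be a pool tip; offenders are named
#' in the error.
#'
#' @param pool Pool phylogeny ([ape::phylo]).
#' @param community Plot x species count matrix (see [read_community()]).
#' @param stages Tibble/data.frame with columns `plot`, `stage`.
#' @param env Optional environmental tibble (see [read_env_table()]).
#' @param traits Optional trait tibble (see [read_trait_table()]).
#' @return An object of class `succession_bundle`: a list with elements
#'   `pool_tree`, `comm_tree`, `community` (counts), `presence`, `abundance`
#'   (relative abundances f), `stages`, `env`, `traits`, `D_pool`, `D_comm`.
#' @export
build_bundle <- function(pool, community, stages, env = NULL, traits = NULL) {
  pool <- validate_phylogeny(pool)
  community <- validate_community(community)
  rownames(community) <- normalize_names(rownames(community))
  colnames(community) <- normalize_names(colnames(community))

  zero <- colSums(community) == 0
  if (any(zero)) {
    inform(paste0("dropping ", sum(zero), " species with zero total abundance: ",
                  paste(head(colnames(community)[zero], 5), collapse = ", "),
                  if (sum(zero) > 5) ", ..." else ""))
    community <- community[, !zero, drop = FALSE]
  }

  missing_sp <- setdiff(colnames(community), pool$tip.label)
  if (length(missing_sp))
    stop_ps("community species absent from pool phylogeny: ",
            paste(missing_sp, collapse = ", "))

  stages <- as_tibble(stages)
  names(stages)[1:2] <- c("plot", "stage")
  stages$plot <- normalize_names(stages$plot)
  if (!is.factor(stages$stage))
    stages$stage <- factor(stages$stage, levels = sort(unique(stages$stage)), ordered = TRUE)
  missing_pl <- setdiff(rownames(community), stages$plot)
  if (length(missing_pl))
    stop_ps("plots missing from stage map: ", paste(missing_pl, collapse = ", "))
  stages <- stages[match(rownames(community), stages$plot), ]

  if (!is.null(env)) {
    env <- as_tibble(env)
    names(env)[1] <- "plot"
    env$plot <- normalize_names(env$plot)
    missing_env <- setdiff(rownames(community), env$plot)
    if (length(missing_env))
      stop_ps("plots missing from environmental table: ", paste(missing_env, collapse = ", "))
    env <- env[match(rownames(community), env$plot), ]
  }
  if (!is.null(traits)) {
    traits <- as_tibble(traits)
    names(traits)[1] <- "species"
    traits$species <- normalize_names(traits$species)
    extra <- setdiff(traits$species, pool$tip.label)
    if (length(extra))
      stop_ps("trait species absent from pool phylogeny: ", paste(extra, collapse = ", "))
  }

  comm_tree <- if (length(setdiff(pool$tip.label, colnames(community)))) {
    ape::drop.tip(pool, setdiff(pool$tip.label, colnames(community)))
  } else pool
  D_pool <- cophenetic_matrix(pool)
  D_comm <- D_pool[colnames(community), colnames(community)]

  f <- community / rowSums(community)
  structure(list(
    pool_tree = pool, comm_tree = comm_tree,
    community = community,
    presence = (community > 0) * 1,
    abundance = f,
    stages = stages, env = env, traits = traits,
    D_pool = D_pool, D_comm = D_comm
  ), class = "succession_bundle")
}

#' @export
print.succession_bundle <- function(x, ...) {
  cat("<succession_bundle>\n")
  cat("  pool phylogeny: ", ape::Ntip(x$pool_tree), " tips, root age ",
      round(max(node_ages(x$pool_tree)), 2), " Myr\n", sep = "")
  cat("  community:      ", nrow(x$community), " plots x ", ncol(x$community),
      " species, ", sum(x$community), " individuals\n", sep = "")
  cat("  stages:         ", paste(levels(x$stages$stage), collapse = ", "),
      " (", paste(table(x$stages$stage), collapse = "/"), " plots)\n", sep = "")
  if (!is.null(x$env)) cat("  environment:    ", ncol(x$env) - 3, " variables + x,y\n", sep = "")
  if (!is.null(x$traits)) cat("  traits:         ", ncol(x$traits) - 1, "\n", sep = "")
  invisible(x)
}

#' Read an on-disk bundle directory
#'
#' Expects `tree.nwk`, `community.tsv`, `stages.tsv` and optionally
#' `env.tsv`, `traits.tsv` (the layout written by [write_bundle()]).
#'
#' @param dir Directory path.
#' @return A `succession_bundle`.
#' @export
read_bundle <- function(dir) {
  tree <- read_phylogeny(file.path(dir, "tree.nwk"))
  community <- read_community(file.path(dir, "community.tsv"))
  stages <- read_stage_map(file.path(dir, "stages.tsv"))
  env <- if (file.exists(file.path(dir, "env.tsv"))) read_env_table(file.path(dir, "env.tsv"))
  traits <- if (file.exists(file.path(dir, "traits.tsv"))) read_trait_table(file.path(dir, "traits.tsv"))
  build_bundle(tree, community, stages, env, traits)
}

#' Write a bundle to a directory of plain-text files
#'
#' @param bundle A `succession_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(bundle$pool_tree, file.path(dir, "tree.nwk"))
  write_tsv_matrix(bundle$community, "plot", file.path(dir, "community.tsv"))
  utils::write.table(bundle$stages, file.path(dir, "stages.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$env))
    utils::write.table(bundle$env, file.path(dir, "env.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$traits))
    utils::write.table(bundle$traits, file.path(dir, "traits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

write_tsv_matrix <- function(m, id_name, path) {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
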