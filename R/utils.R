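#' @importFrom rlang .data abort warn inform
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n
#' @importFrom tibble tibble as_tibble
#' @importFrom stats cophenetic quantile sd var cor lm resid coef prcomp
#'   dist optimize pchisq phyper rnorm runif rlnorm rmultinom setNames
#'   complete.cases
#' @importFrom utils combn head
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Spawn `n` sub-seeds from one master seed (recorded in output metadata so
# replicate streams are reconstructible).
spawn_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

# Exact name matching after trimming whitespace and mapping spaces to
# underscores; no fuzzy matching (silent mis-joins are worse than errors).
normalize_names <- function(x) {
  gsub(" ", "_", trimws(as.character(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ps <- function(...) abort(paste0(...), class = "phylosucc_error")
warn_ps <- function(...) warn(paste0(...), class = "phylosucc_warning")
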