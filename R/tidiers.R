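#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @method tidy perm_lm
#' @export
tidy.perm_lm <- function(x, ...) {
  tibble(term = c("(Intercept)", "distance"),
         estimate = c(x$intercept, x$slope),
         p.value = c(NA_real_, x$p_value))
}

#' @method glance perm_lm
#' @export
glance.perm_lm <- function(x, ...) {
  tibble(r.squared = x$r_squared, p.value = x$p_value,
         nobs = x$n, n.permutations = x$n_perm)
}

#' @method tidy null_distribution
#' @export
tidy.null_distribution <- function(x, ...) {
  tibble(null_mean = x$mean, null_sd = x$sd,
         ci_low = x$ci[1], ci_high = x$ci[2],
         R = x$R, n_undefined = x$n_undefined)
}

#' @method glance signal_table
#' @export
glance.signal_table <- function(x, ...) {
  x |>
    group_by(.data$metric) |>
    summarise(n_traits = n(),
              n_significant = sum(.data$p_value <= 0.05, na.rm = TRUE),
              .groups = "drop")
}
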