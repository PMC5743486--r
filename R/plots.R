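#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_hline geom_ribbon
#'   geom_errorbar geom_smooth facet_wrap labs theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot grouped turnover with null envelopes
#'
#' Observed turnover (mean over pairs) per scope with the null-model 95%
#' interval, the figure convention for reading clustering (above the band)
#' and overdispersion (below).
#'
#' @param object A `turnover_test` tibble from [turnover_null_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot turnover_test
#' @export
autoplot.turnover_test <- function(object, ...) {
  ggplot(object, aes(x = .data$scope)) +
    geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                  width = 0.25, colour = "grey60") +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    geom_point(aes(y = .data$observed), size = 2) +
    facet_wrap(~mode) +
    labs(x = NULL, y = "phylogenetic turnover",
         caption = "points: observed; bars: null 95% interval") +
    theme_minimal()
}

#' Plot a depth profile of standardized turnover
#'
#' SES of depth-restricted turnover against the divergence-time threshold,
#' one line per scope, with the +/-1.96 significance band.
#'
#' @param object A `depth_profile` tibble from [depth_profile()].
#' @param smooth Add a loess smoother (span 0.66, degree 1), presentation
#'   only.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot depth_profile
#' @export
autoplot.depth_profile <- function(object, smooth = FALSE, ...) {
  p <- ggplot(object, aes(x = .data$threshold, y = .data$ses,
                          colour = .data$scope, group = .data$scope)) +
    geom_hline(yintercept = c(-1.96, 1.96), linetype = 2, colour = "grey50") +
    geom_point() + geom_line(alpha = 0.5) +
    labs(x = "divergence-time threshold (Myr)",
         y = "standardized turnover (SES)", colour = "stage") +
    theme_minimal()
  if (smooth)
    p <- p + geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         span = 0.66,
                         method.args = list(degree = 1), linewidth = 0.7)
  p
}

#' Plot turnover against environmental distance per stage
#'
#' Spatially-partialled pairwise turnover versus environmental distance for
#' within-stage pairs, facetted by stage.
#'
#' @param bundle A `succession_bundle` with environment data.
#' @param mode `"presence"` or `"abundance"`.
#' @param variance_target Passed to [env_distance()].
#' @return A ggplot object.
#' @export
plot_env_turnover <- function(bundle, mode = "presence", variance_target = 0.90) {
  pairs <- pairwise_turnover(bundle, mode)
  res <- residualize_on_space(pairs[pairs$group == "within", ],
                              env_distance(bundle$env, variance_target))
  ggplot(res, aes(x = .data$env_dist, y = .data$residual)) +
    geom_point(alpha = 0.7) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.6) +
    facet_wrap(~stage_a) +
    labs(x = "environmental distance (PC space)",
         y = "turnover residual (spatial distance partialled)") +
    theme_minimal()
}
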