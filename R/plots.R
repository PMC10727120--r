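#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_hline geom_rect
#'   labs facet_grid theme_minimal geom_ribbon
#' @export
ggplot2::autoplot

#' Plot a cluster test: t series with significant windows shaded
#'
#' @param object an `eeg_cluster_test`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.eeg_cluster_test <- function(object, ...) {
  w <- object$windows
  s <- object$spec
  sigruns <- object$clusters
  p <- ggplot(w, aes(x = .data$window_ms, y = .data$t)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_line() +
    labs(x = "window centre (ms)", y = "fixed-effect t",
         title = sprintf("%s ~ %s (%s tail), %s null",
                         s$outcome, s$predictor, s$tail, s$method),
         subtitle = sprintf("corrected alpha = %.4g (%d tests), %d reps",
                            s$alpha_corrected, s$n_tests, s$reps)) +
    theme_minimal()
  if (nrow(sigruns))
    p <- p + geom_rect(data = sigruns,
                       aes(xmin = .data$start_ms, xmax = .data$end_ms,
                           ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, alpha = 0.15, fill = "red")
  p
}

#' Plot cohort eigenvalue time courses by age wave
#'
#' Mean eigenvalue trajectory per lock and wave with a ribbon of +-1 SE
#' over recordings.
#'
#' @param object a `cohort_dynamics`.
#' @param eigenvalue `"eig1"` or `"eig2"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cohort_dynamics <- function(object, eigenvalue = "eig1", ...) {
  d <- object$eigs |>
    dplyr::group_by(.data$lock, .data$wave, .data$window_ms) |>
    dplyr::summarise(m = mean(.data[[eigenvalue]], na.rm = TRUE),
                     se = sd_or_zero(.data[[eigenvalue]]) /
                       sqrt(sum(is.finite(.data[[eigenvalue]]))),
                     .groups = "drop")
  ggplot(d, aes(x = .data$window_ms, y = .data$m,
                colour = factor(.data$wave), fill = factor(.data$wave))) +
    geom_ribbon(aes(ymin = .data$m - .data$se, ymax = .data$m + .data$se),
                alpha = 0.2, colour = NA) +
    geom_line() +
    facet_grid(. ~ .data$lock, scales = "free_x") +
    labs(x = "window centre (ms)", y = sprintf("%s (modulus)", eigenvalue),
         colour = "wave", fill = "wave") +
    theme_minimal()
}
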