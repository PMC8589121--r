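#' Diagnostic plots
#'
#' Lightweight plotting helpers (ggplot2, if available) for the standard
#' diagnostics: the kernel density estimate of a trained weight
#' distribution, a Levy-driven trajectory, and the incumbent trace of an
#' optimization run. Each returns a ggplot object.
#'
#' @param weights numeric vector of trained plastic weights.
#' @param t KDE bandwidth (variance); default Silverman.
#' @return a ggplot object.
#' @export
plot_weight_density <- function(weights, t = NULL) {
  require_ggplot()
  df <- kde_pdf(weights, t = t)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "synaptic weight", y = "density",
                  title = "Trained weight distribution (Gaussian KDE)")
}

#' @rdname plot_weight_density
#' @param trajectory matrix from \code{\link{simulate_ou_levy}}.
#' @export
plot_trajectory <- function(trajectory) {
  require_ggplot()
  df <- data.frame(step = seq_len(nrow(trajectory)) - 1,
                   x = trajectory[, 1])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$x)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step", y = "value",
                  title = "Heavy-tailed process trajectory")
}

#' @rdname plot_weight_density
#' @param bo a \code{bo_run}.
#' @export
plot_incumbent <- function(bo) {
  require_ggplot()
  df <- data.frame(evaluation = seq_along(bo$incumbent_trace),
                   incumbent = bo$incumbent_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$evaluation,
                                   y = .data$incumbent)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "objective evaluation", y = "incumbent BG index")
}

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
}
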