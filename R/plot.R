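#' Plot a fitted gradient curve
#'
#' ggplot2 figure of the fitted mean (or SD) with its pointwise confidence
#' band along the urbanicity gradient.
#'
#' @param curve A `gradient_curve`.
#' @param what `"mean"` or `"sd"`.
#' @param title Optional title.
#' @return A ggplot object.
#' @export
plot_gradient <- function(curve, what = c("mean", "sd"), title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is needed for plotting", call. = FALSE)
  }
  what <- match.arg(what)
  cols <- if (what == "mean") c("mu_hat", "mu_low", "mu_high") else
    c("sigma_hat", "sigma_low", "sigma_high")
  df <- data.frame(d = curve$d, y = curve[[cols[1]]],
                   lo = curve[[cols[2]]], hi = curve[[cols[3]]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$y)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "urbanicity d (km per sqrt person)",
                  y = if (what == "mean") "fitted mean (z units)" else
                    "fitted SD (z units)",
                  title = title) +
    ggplot2::theme_minimal()
}
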