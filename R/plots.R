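#' Plot a hydropathy profile with called spans
#'
#' Line plot of the windowed hydropathy profile, the upper/lower cutoffs,
#' and the TM segments the profile calls.
#'
#' @param seq amino-acid sequence.
#' @param params [hydro_params()].
#' @return a ggplot object.
#' @export
plot_hydropathy <- function(seq, params = hydro_params()) {
  prof <- hydropathy_profile(seq, params)
  spans <- find_tm_segments(prof, params)
  df <- tibble(position = seq_along(prof), hydropathy = prof)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$hydropathy)) +
    ggplot2::geom_hline(yintercept = params$lower_cutoff,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = params$upper_cutoff,
                        linetype = "dotted", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Residue", y = "Windowed hydropathy") +
    ggplot2::theme_minimal()
  if (nrow(spans) > 0) {
    p <- p + ggplot2::geom_rect(
      data = spans,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue",
      inherit.aes = FALSE
    )
  }
  p
}

#' @describeIn summarize_mtfs TM-count and span-location bar charts.
#' @param object `mtf_summary` object.
#' @exportS3Method ggplot2::autoplot
autoplot.mtf_summary <- function(object, ...) {
  if (is.null(object$tm_count)) {
    abort("Nothing to plot: empty MTF summary.")
  }
  df <- bind_rows(
    mutate(object$tm_count, panel = "TM spans per MTF",
           category = as.character(.data$tm_count)),
    if (!is.null(object$location)) {
      mutate(object$location, panel = paste0("Span location (", .data$group, ")"))
    }
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$category, .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "MTF count") +
    ggplot2::theme_minimal()
}

#' @describeIn tidy.mtf_scan summary plots of a scan result.
#' @param object `mtf_scan` object.
#' @exportS3Method ggplot2::autoplot
autoplot.mtf_scan <- function(object, ...) {
  autoplot(object$summary, ...)
}
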