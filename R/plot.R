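# Genome-track and histogram views of the rIBD scan, with the significance
# cut-offs drawn as horizontal/vertical reference lines.

utils::globalVariables(c("midpoint", "ribd"))

#' Genome track of rIBD scores
#'
#' Plots rIBD against the window midpoint, one panel per chromosome, with
#' the y axis clamped to the score's \[-1, 1\] range and the cut-offs from
#' `summary` drawn as dashed lines.
#'
#' @param records A `ribd_windows` table.
#' @param summary Optional `ribd_summary` supplying cut-off lines.
#' @return A ggplot object.
#' @export
plot_ribd_track <- function(records, summary = NULL) {
  if (nrow(records) == 0) stop("no windows to plot", call. = FALSE)
  df <- data.frame(chrom = factor(records$chrom, levels = unique(records$chrom)),
                   midpoint = (records$start + records$end) / 2,
                   ribd = records$ribd)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = midpoint / 1e6, y = ribd)) +
    ggplot2::geom_point(size = 0.4, colour = "grey30") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70", linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(x = "Position (Mb)", y = "rIBD") +
    ggplot2::theme_bw()
  if (!is.null(summary)) {
    p <- p + ggplot2::geom_hline(yintercept = c(summary$cut_high, summary$cut_low),
                                 colour = "firebrick", linetype = "dashed",
                                 linewidth = 0.4)
  }
  p
}

#' Histogram of the genome-wide rIBD distribution
#'
#' @param records A `ribd_windows` table.
#' @param summary Optional `ribd_summary` supplying cut-off lines.
#' @param bins Number of histogram bins (default 60).
#' @return A ggplot object.
#' @export
plot_ribd_histogram <- function(records, summary = NULL, bins = 60) {
  if (nrow(records) == 0) stop("no windows to plot", call. = FALSE)
  df <- data.frame(ribd = records$ribd)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = ribd)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0,
                            fill = "grey40", colour = "white", linewidth = 0.1) +
    ggplot2::coord_cartesian(xlim = c(-1, 1)) +
    ggplot2::labs(x = "rIBD", y = "Windows") +
    ggplot2::theme_bw()
  if (!is.null(summary)) {
    p <- p + ggplot2::geom_vline(xintercept = c(summary$cut_high, summary$cut_low),
                                 colour = "firebrick", linetype = "dashed",
                                 linewidth = 0.4)
  }
  p
}

#' Save a plot in PNG or SVG format
#'
#' @param plot A ggplot object.
#' @param path Output path (extension chosen by the caller).
#' @param format `"png"` or `"svg"`.
#' @param width,height Size in inches.
#' @return `path`, invisibly.
#' @export
save_ribd_plot <- function(plot, path, format = c("png", "svg"),
                           width = 8, height = 5) {
  format <- match.arg(format)
  if (format == "png") {
    grDevices::png(path, width = width, height = height, units = "in", res = 150)
  } else {
    grDevices::svg(path, width = width, height = height)
  }
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}
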