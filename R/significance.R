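# Genome-wide summary of the rIBD distribution, mean +/- k*SD cut-offs,
# per-tail significant window lists, and merging into regions.

#' Summarize the genome-wide rIBD distribution and derive cut-offs
#'
#' rIBD scores genome-wide approximately follow a normal distribution;
#' windows beyond `mean +/- k * SD` (sample SD, n-1 denominator) are treated
#' as significant.  With the default k = 3 the flagged two-tailed normal
#' mass is about 0.27%.
#'
#' @param records A `ribd_windows` table.
#' @param k Cut-off multiplier in standard deviations (default 3).
#' @param exclude_truncated Drop truncated terminal windows from the summary.
#' @param exclude_zero_evidence Drop windows with no IBD evidence on either
#'   side (`n_ibd_s1 = n_ibd_s2 = 0`).
#' @param by_chrom If `TRUE`, return a list of per-chromosome summaries
#'   instead of one pooled summary.
#' @return A `ribd_summary` list: `mean`, `sd`, `n_windows`, `k`,
#'   `cut_high`, `cut_low`, `tail_mass`.
#' @export
ribd_summary <- function(records, k = 3, exclude_truncated = FALSE,
                         exclude_zero_evidence = FALSE, by_chrom = FALSE) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0)
    stop("k must be a positive number", call. = FALSE)
  keep <- rep(TRUE, nrow(records))
  if (exclude_truncated) keep <- keep & !records$truncated
  if (exclude_zero_evidence)
    keep <- keep & !(records$n_ibd_s1 == 0 & records$n_ibd_s2 == 0)
  rec <- records[keep, , drop = FALSE]
  if (by_chrom) {
    out <- lapply(split(rec, factor(rec$chrom, levels = unique(rec$chrom))),
                  ribd_summary, k = k)
    return(out)
  }
  if (nrow(rec) < 2)
    stop("need at least 2 windows to summarize the rIBD distribution", call. = FALSE)
  m <- mean(rec$ribd)
  s <- stats::sd(rec$ribd)
  structure(list(mean = m, sd = s, n_windows = nrow(rec), k = k,
                 cut_high = m + k * s, cut_low = m - k * s,
                 tail_mass = normal_tail_mass(k)),
            class = "ribd_summary")
}

#' @export
print.ribd_summary <- function(x, ...) {
  cat(sprintf("rIBD distribution over %d windows\n", x$n_windows))
  cat(sprintf("  mean %.4f, SD %.4f\n", x$mean, x$sd))
  cat(sprintf("  cut-offs (mean +/- %g SD): %.4f / %.4f\n",
              x$k, x$cut_high, x$cut_low))
  cat(sprintf("  two-tailed normal mass beyond %g SD: %.3f%%\n",
              x$k, 100 * x$tail_mass))
  invisible(x)
}

#' Two-tailed normal mass beyond k standard deviations
#'
#' `2 * (1 - Phi(k))` for the standard normal CDF Phi: the expected fraction
#' of windows flagged in both tails together if scores were exactly normal.
#' For k = 3 this is 0.0027 (about 0.3%).
#'
#' @param k Positive multiplier in standard deviations.
#' @return Fraction in (0, 1).
#' @export
normal_tail_mass <- function(k) {
  if (any(!is.finite(k) | k <= 0)) stop("k must be positive", call. = FALSE)
  2 * stats::pnorm(k, lower.tail = FALSE)
}

#' Significant windows in each tail
#'
#' Windows with `ribd > cut_high` form the positive list (introgression from
#' source breed 1), windows with `ribd < cut_low` the negative list
#' (source breed 2).  Equality with a cut-off is not significant.
#'
#' @param records A `ribd_windows` table.
#' @param summary A `ribd_summary` computed from the same records.
#' @return List with `positive` and `negative` window tables, each sorted by
#'   position.
#' @export
significant_windows <- function(records, summary) {
  stopifnot(inherits(summary, "ribd_summary"))
  list(positive = records[records$ribd > summary$cut_high, , drop = FALSE],
       negative = records[records$ribd < summary$cut_low, , drop = FALSE])
}

#' Merge significant windows into regions
#'
#' Consecutive significant windows of one sign separated by at most
#' `max_gap_windows` non-significant grid windows are merged into one
#' region spanning the member windows.
#'
#' @param windows Significant windows of a single sign (rows of a
#'   `ribd_windows` table), sorted by position.
#' @param grid The `window_grid` the windows come from.
#' @param max_gap_windows Maximum number of intervening non-significant
#'   windows to bridge (default 0).
#' @param sign `"positive"` or `"negative"`; inferred from the scores when
#'   omitted (an error if the scores are of mixed sign).
#' @return Data frame of regions: `chrom`, `start`, `end`, `sign`,
#'   `n_windows`, `peak_ribd`, `mean_ribd`.
#' @export
merge_regions <- function(windows, grid, max_gap_windows = 0, sign = NULL) {
  stopifnot(inherits(grid, "window_grid"))
  if (max_gap_windows < 0) stop("max_gap_windows must be >= 0", call. = FALSE)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      sign = character(), n_windows = integer(),
                      peak_ribd = numeric(), mean_ribd = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(windows) == 0) return(empty)
  if (is.null(sign)) {
    if (all(windows$ribd > 0)) sign <- "positive"
    else if (all(windows$ribd < 0)) sign <- "negative"
    else stop("windows of mixed sign; merge each tail separately", call. = FALSE)
  }
  sign <- match.arg(sign, c("positive", "negative"))
  idx <- match(paste(windows$chrom, windows$start),
               paste(grid$chrom, grid$start))
  if (anyNA(idx)) stop("window not found on the grid", call. = FALSE)
  ord <- order(idx)
  windows <- windows[ord, , drop = FALSE]
  idx <- idx[ord]
  same_chrom <- windows$chrom[-1] == windows$chrom[-nrow(windows)]
  gap <- diff(idx) - 1
  new_region <- c(TRUE, !(same_chrom & gap <= max_gap_windows))
  group <- cumsum(new_region)
  out <- lapply(split(seq_len(nrow(windows)), group), function(i) {
    w <- windows[i, , drop = FALSE]
    data.frame(chrom = w$chrom[1], start = min(w$start), end = max(w$end),
               sign = sign, n_windows = nrow(w),
               peak_ribd = if (sign == "positive") max(w$ribd) else min(w$ribd),
               mean_ribd = mean(w$ribd), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a significant-region list as annotated TSV
#'
#' BED-compatible first three columns (0-based half-open) followed by sign,
#' window count and scores; the header comments record the summary the
#' cut-offs came from.
#'
#' @param regions Region table from [merge_regions()].
#' @param summary The `ribd_summary` used to call significance.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, summary, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# ribd_significant_regions\tdialect=bed0",
    sprintf("# mean=%s\tsd=%s\tn_windows=%d\tk=%s", num_str(summary$mean),
            num_str(summary$sd), summary$n_windows, num_str(summary$k)),
    sprintf("# cut_high=%s\tcut_low=%s\ttail_mass=%s", num_str(summary$cut_high),
            num_str(summary$cut_low), num_str(summary$tail_mass)),
    paste(c("chrom", "start", "end", "sign", "n_windows",
            "peak_ribd", "mean_ribd"), collapse = "\t")), con)
  if (nrow(regions)) {
    body <- paste(regions$chrom, format_bp(regions$start), format_bp(regions$end),
                  regions$sign, regions$n_windows,
                  num_str(regions$peak_ribd), num_str(regions$mean_ribd),
                  sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}
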