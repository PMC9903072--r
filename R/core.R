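# Window grid construction, per-unit IBD calls, population-level sharing
# fractions and the rIBD score.  All intervals are 0-based half-open.

#' Build the window grid
#'
#' Tiles every chromosome with consecutive non-overlapping windows of
#' `window_size` bp; the final window is truncated to the chromosome length.
#' 10 kbp is the default resolution of the scan.
#'
#' @param layout A `genome_layout`.
#' @param window_size Nominal window size in bp (default 10000).
#' @return A `window_grid` data frame with columns `chrom`, `start`, `end`,
#'   `truncated`, carrying the layout as attribute `layout`.
#' @export
build_window_grid <- function(layout, window_size = 10000) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.numeric(window_size) || length(window_size) != 1 || window_size < 1 ||
      window_size != floor(window_size))
    stop("window_size must be a positive integer", call. = FALSE)
  pieces <- lapply(seq_len(nrow(layout)), function(i) {
    L <- layout$length[i]
    starts <- seq(0, L - 1, by = window_size)
    ends <- pmin(starts + window_size, L)
    data.frame(chrom = layout$chrom[i], start = starts, end = ends,
               truncated = (ends - starts) < window_size,
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  rownames(grid) <- NULL
  structure(grid, class = c("window_grid", "data.frame"),
            layout = layout, window_size = window_size)
}

#' Fraction of a window covered by a segment
#'
#' Both intervals are 0-based half-open; disjoint intervals give 0.
#'
#' @param seg_start,seg_end Segment interval.
#' @param win_start,win_end Window interval (`win_end > win_start`).
#' @return Overlap length divided by window length, in \[0, 1\].
#' @export
window_coverage <- function(seg_start, seg_end, win_start, win_end) {
  stopifnot(all(win_end > win_start))
  ov <- pmin(seg_end, win_end) - pmax(seg_start, win_start)
  pmax(ov, 0) / (win_end - win_start)
}

#' Call per-unit IBD status for every window against one source breed
#'
#' For each admixed unit and window, the intervals of all segments pairing
#' that unit with a `side` haplotype are merged (overlapping tracts counted
#' once) and the unit is called IBD in the window when the merged length
#' covers at least `min_cov` of the (actual, possibly truncated) window.
#'
#' Units: `haplotype` treats the two haplotypes of each admixed individual
#' separately; `individual` calls an individual IBD when either haplotype
#' is; `pairwise` calls each (admixed haplotype, source haplotype) pair
#' separately.
#'
#' @param segments An `ibd_segments` data frame (source-vs-admixed pairs;
#'   others are ignored).
#' @param grid A `window_grid`.
#' @param manifest A `pop_manifest`.
#' @param side `"source1"` or `"source2"`.
#' @param unit `"haplotype"` (default), `"individual"` or `"pairwise"`.
#' @param min_cov Minimum covered fraction to call a window IBD (default 0.5).
#' @return A `window_calls` object: logical matrix `calls` (windows x units)
#'   plus metadata.
#' @export
call_windows <- function(segments, grid, manifest,
                         side = c("source1", "source2"),
                         unit = c("haplotype", "individual", "pairwise"),
                         min_cov = 0.5) {
  side <- match.arg(side)
  unit <- match.arg(unit)
  stopifnot(inherits(grid, "window_grid"), inherits(manifest, "pop_manifest"))
  if (!(min_cov > 0 && min_cov <= 1))
    stop("min_cov must be in (0, 1]", call. = FALSE)
  layout <- attr(grid, "layout")
  if (nrow(segments) && !all(segments$chrom %in% layout$chrom))
    stop("segment chromosome not in the grid's layout", call. = FALSE)

  adm <- role_samples(manifest, "admixed")
  src <- role_samples(manifest, side)
  hap_keys <- function(samples) {
    as.vector(t(outer(samples, 1:2, function(s, h) paste(s, h, sep = "|"))))
  }
  adm_haps <- hap_keys(adm)

  # orient segments as (admixed hap, source hap)
  if (nrow(segments)) {
    role_a <- manifest$role[match(segments$sample_a, manifest$sample)]
    role_b <- manifest$role[match(segments$sample_b, manifest$sample)]
    a_src <- !is.na(role_a) & role_a == side & !is.na(role_b) & role_b == "admixed"
    b_src <- !is.na(role_b) & role_b == side & !is.na(role_a) & role_a == "admixed"
    sel <- a_src | b_src
    adm_key <- ifelse(a_src, paste(segments$sample_b, segments$hap_b, sep = "|"),
                      paste(segments$sample_a, segments$hap_a, sep = "|"))[sel]
    src_key <- ifelse(a_src, paste(segments$sample_a, segments$hap_a, sep = "|"),
                      paste(segments$sample_b, segments$hap_b, sep = "|"))[sel]
    seg <- data.frame(adm = adm_key, src = src_key,
                      chrom = segments$chrom[sel],
                      start = segments$start[sel], end = segments$end[sel],
                      stringsAsFactors = FALSE)
  } else {
    seg <- data.frame(adm = character(), src = character(), chrom = character(),
                      start = numeric(), end = numeric(), stringsAsFactors = FALSE)
  }

  unit_of <- switch(unit,
    haplotype = , individual = seg$adm,
    pairwise = paste(seg$adm, seg$src, sep = "~"))
  units <- switch(unit,
    haplotype = , individual = adm_haps,
    pairwise = as.vector(outer(adm_haps, hap_keys(src),
                               function(a, s) paste(a, s, sep = "~"))))

  calls <- matrix(FALSE, nrow = nrow(grid), ncol = length(units),
                  dimnames = list(NULL, units))
  win_width <- grid$end - grid$start
  for (ch in unique(seg$chrom)) {
    in_ch <- grid$chrom == ch
    if (!any(in_ch)) next
    win_ir <- IRanges::IRanges(start = grid$start[in_ch] + 1, end = grid$end[in_ch])
    sch <- seg[seg$chrom == ch, , drop = FALSE]
    for (u in unique(unit_of[seg$chrom == ch])) {
      su <- sch[unit_of[seg$chrom == ch] == u, , drop = FALSE]
      merged <- IRanges::reduce(IRanges::IRanges(start = su$start + 1, end = su$end))
      hits <- IRanges::findOverlaps(win_ir, merged)
      if (!length(hits)) next
      ov <- IRanges::width(IRanges::pintersect(
        win_ir[S4Vectors::queryHits(hits)], merged[S4Vectors::subjectHits(hits)]))
      covered <- tapply(ov, S4Vectors::queryHits(hits), sum)
      widx <- as.integer(names(covered))
      gidx <- which(in_ch)[widx]
      called <- as.numeric(covered) >= min_cov * win_width[gidx] - 1e-9
      calls[gidx[called], u] <- TRUE
    }
  }

  if (unit == "individual") {
    ind <- matrix(FALSE, nrow = nrow(grid), ncol = length(adm),
                  dimnames = list(NULL, adm))
    for (s in adm) {
      ind[, s] <- calls[, paste(s, 1, sep = "|")] | calls[, paste(s, 2, sep = "|")]
    }
    calls <- ind
    units <- adm
  }

  structure(list(calls = calls, units = units, grid = grid,
                 side = side, unit = unit, min_cov = min_cov),
            class = "window_calls")
}

#' Population-level IBD-sharing fraction per window
#'
#' The fraction of admixed units (haplotypes, individuals, or
#' admixed-by-source haplotype pairs, per the call matrix's unit) called IBD
#' with the source breed, per window.
#'
#' @param calls A `window_calls` object.
#' @return Numeric vector in \[0, 1\], one value per grid window.
#' @export
population_fraction <- function(calls) {
  stopifnot(inherits(calls, "window_calls"))
  rowSums(calls$calls) / ncol(calls$calls)
}

#' Relative IBD scores from the two sharing fractions
#'
#' In `raw` mode the reported fractions are `f1` and `f2` and
#' `rIBD = f1 - f2`.  In `normalized` mode (the default downstream) the
#' fractions are rescaled to sum to 1 per window (`fk / (f1 + f2)`), so an
#' rIBD of 0.5 corresponds to fractions 0.75/0.25; windows with no evidence
#' on either side (`f1 + f2 = 0`) report 0/0 and rIBD 0.
#'
#' @param f1,f2 Per-window sharing fractions with source breed 1 and 2.
#' @param mode `"normalized"` or `"raw"`.
#' @return List with numeric vectors `ibd_s1`, `ibd_s2`, `ribd`.
#' @export
ribd_scores <- function(f1, f2, mode = c("normalized", "raw")) {
  mode <- match.arg(mode)
  if (length(f1) != length(f2))
    stop("f1 and f2 must be on the same window grid", call. = FALSE)
  stopifnot(all(f1 >= 0 & f1 <= 1), all(f2 >= 0 & f2 <= 1))
  if (mode == "raw") {
    list(ibd_s1 = f1, ibd_s2 = f2, ribd = f1 - f2)
  } else {
    tot <- f1 + f2
    s1 <- ifelse(tot > 0, f1 / tot, 0)
    s2 <- ifelse(tot > 0, f2 / tot, 0)
    list(ibd_s1 = s1, ibd_s2 = s2, ribd = s1 - s2)
  }
}

#' Invert an rIBD score under the sum-to-1 constraint
#'
#' With `IBD_S1 + IBD_S2 = 1`, an rIBD score determines both fractions:
#' `IBD_S1 = (1 + rIBD) / 2`, `IBD_S2 = (1 - rIBD) / 2`.  E.g. rIBD 0.5
#' corresponds to sharing fractions 0.75 and 0.25.
#'
#' @param ribd Numeric vector of scores in \[-1, 1\].
#' @return List with `ibd_s1` and `ibd_s2`.
#' @export
invert_ribd <- function(ribd) {
  if (any(abs(ribd) > 1)) stop("rIBD scores must lie in [-1, 1]", call. = FALSE)
  list(ibd_s1 = (1 + ribd) / 2, ibd_s2 = (1 - ribd) / 2)
}

#' Run the full windowed rIBD scan
#'
#' Builds the window grid, calls per-unit IBD status against each source
#' breed, aggregates to population-level sharing fractions and scores
#' `rIBD = IBD_S1 - IBD_S2` per window.
#'
#' @inheritParams call_windows
#' @param layout A `genome_layout`.
#' @param window_size Window size in bp (default 10000).
#' @param mode Score mode, `"normalized"` (default) or `"raw"`; see
#'   [ribd_scores()].
#' @return A `ribd_windows` data frame, one row per window, sorted by layout
#'   order and start, with counts, fractions, `ribd` and a `truncated` flag;
#'   the mode is stored in attribute `score_mode`.
#' @export
compute_ribd <- function(segments, layout, manifest, window_size = 10000,
                         unit = c("haplotype", "individual", "pairwise"),
                         min_cov = 0.5, mode = c("normalized", "raw")) {
  unit <- match.arg(unit)
  mode <- match.arg(mode)
  grid <- build_window_grid(layout, window_size)
  c1 <- call_windows(segments, grid, manifest, "source1", unit, min_cov)
  c2 <- call_windows(segments, grid, manifest, "source2", unit, min_cov)
  n1 <- rowSums(c1$calls); t1 <- ncol(c1$calls)
  n2 <- rowSums(c2$calls); t2 <- ncol(c2$calls)
  sc <- ribd_scores(n1 / t1, n2 / t2, mode)
  structure(data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                       n_ibd_s1 = as.integer(n1), n_total_s1 = t1,
                       n_ibd_s2 = as.integer(n2), n_total_s2 = t2,
                       ibd_s1 = sc$ibd_s1, ibd_s2 = sc$ibd_s2, ribd = sc$ribd,
                       truncated = grid$truncated, stringsAsFactors = FALSE),
            class = c("ribd_windows", "data.frame"),
            score_mode = mode, window_size = window_size)
}
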