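# Synthetic three-breed IBD-segment datasets with known ground-truth local
# ancestry.  Each admixed haplotype is a mosaic of ancestry tracts with
# exponential lengths; each tract is reported IBD with haplotypes of its
# source breed, subject to false-negative (drop) and false-positive
# (spurious) noise.  The expected normalized rIBD of a window with true
# source-1 ancestry fraction p is 2p - 1, which makes recovery testable in
# closed form.

#' Simulation configuration
#'
#' @param n_source1,n_source2,n_admixed Individuals per breed.
#' @param layout A `genome_layout`; default one 1 Mb chromosome `"1"`.
#' @param baseline_p Probability that an ancestry tract derives from source
#'   breed 1, outside any introgressed interval (default 0.5).
#' @param introgressed_intervals `NULL`, or a data frame with columns
#'   `chrom`, `start`, `end` (0-based half-open) and `p_local`: the local
#'   source-1 ancestry probability inside the interval.
#' @param mean_tract_bp Mean ancestry-tract length in bp (exponential;
#'   default 1e5).
#' @param segments_per_tract Number of source haplotypes each tract is
#'   reported IBD with (default 1).
#' @param drop_rate Probability a true segment is omitted (false negatives;
#'   default 0.05).
#' @param spurious_rate Expected spurious wrong-breed segments per admixed
#'   haplotype per Mb (false positives; default 0.1).
#' @param lod_mean Mean of the exponential LOD-score distribution
#'   (default 10).
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return A validated `sim_config` list.
#' @export
simulate_config <- function(n_source1 = 10, n_source2 = 10, n_admixed = 20,
                            layout = genome_layout("1", 1e6),
                            baseline_p = 0.5, introgressed_intervals = NULL,
                            mean_tract_bp = 1e5, segments_per_tract = 1,
                            drop_rate = 0.05, spurious_rate = 0.1,
                            lod_mean = 10, seed = 1) {
  stopifnot(inherits(layout, "genome_layout"))
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || x < 1 || x != floor(x))
      stop(sprintf("%s must be a positive integer", nm), call. = FALSE)
  }
  chk_count(n_source1, "n_source1"); chk_count(n_source2, "n_source2")
  chk_count(n_admixed, "n_admixed"); chk_count(segments_per_tract, "segments_per_tract")
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || x < 0 || x > 1)
      stop(sprintf("%s must be a fraction in [0, 1]", nm), call. = FALSE)
  }
  chk_frac(baseline_p, "baseline_p"); chk_frac(drop_rate, "drop_rate")
  if (!is.numeric(spurious_rate) || spurious_rate < 0)
    stop("spurious_rate must be >= 0", call. = FALSE)
  if (!is.numeric(mean_tract_bp) || mean_tract_bp <= 0)
    stop("mean_tract_bp must be positive", call. = FALSE)
  if (!is.numeric(lod_mean) || lod_mean <= 0)
    stop("lod_mean must be positive", call. = FALSE)
  if (!is.null(introgressed_intervals)) {
    ii <- introgressed_intervals
    stopifnot(is.data.frame(ii),
              all(c("chrom", "start", "end", "p_local") %in% names(ii)))
    ci <- match(ii$chrom, layout$chrom)
    if (anyNA(ci)) stop("introgressed interval on unknown chromosome", call. = FALSE)
    if (any(ii$start < 0 | ii$end > layout$length[ci] | ii$start >= ii$end))
      stop("introgressed interval outside layout", call. = FALSE)
    if (any(ii$p_local < 0 | ii$p_local > 1))
      stop("p_local must be a fraction in [0, 1]", call. = FALSE)
  }
  structure(list(n_source1 = n_source1, n_source2 = n_source2,
                 n_admixed = n_admixed, layout = layout,
                 baseline_p = baseline_p,
                 introgressed_intervals = introgressed_intervals,
                 mean_tract_bp = mean_tract_bp,
                 segments_per_tract = segments_per_tract,
                 drop_rate = drop_rate, spurious_rate = spurious_rate,
                 lod_mean = lod_mean, seed = as.integer(seed)),
            class = "sim_config")
}

# local source-1 ancestry probability at positions x on one chromosome
local_p <- function(config, chrom, x) {
  p <- rep(config$baseline_p, length(x))
  ii <- config$introgressed_intervals
  if (!is.null(ii)) {
    ii <- ii[ii$chrom == chrom, , drop = FALSE]
    for (j in seq_len(nrow(ii))) {
      inside <- x >= ii$start[j] & x < ii$end[j]
      p[inside] <- ii$p_local[j]
    }
  }
  p
}

#' Simulate a three-breed IBD-segment dataset with known ancestry truth
#'
#' Each admixed haplotype's chromosome is partitioned into ancestry tracts
#' with i.i.d. exponential(`mean_tract_bp`) lengths (the last tract is
#' truncated at the chromosome end).  A tract derives from source breed 1
#' with the local probability `p` at its midpoint (`baseline_p` outside
#' introgressed intervals).  Each tract emits `segments_per_tract` IBD
#' segments spanning the tract, each to a uniformly chosen haplotype of the
#' tract's source breed; segments are dropped independently with
#' `drop_rate`.  Spurious segments pairing an admixed haplotype with the
#' wrong source breed are added as a Poisson process with `spurious_rate`
#' per haplotype per Mb, at uniform positions with
#' exponential(`mean_tract_bp`) lengths.  LOD scores are
#' exponential(`lod_mean`).  Draws follow a fixed documented order per
#' chromosome, sample and haplotype, so a config + seed pin the dataset
#' byte for byte.
#'
#' @param config A `sim_config` from [simulate_config()].
#' @return A `sim_dataset` list: `segments` (an `ibd_segments` data frame),
#'   `manifest`, `layout`, `truth` (tract table: `sample`, `hap`, `chrom`,
#'   `start`, `end`, `source`), and `config`.
#' @export
simulate_ibd_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lay <- config$layout
  s1 <- sprintf("S1_%03d", seq_len(config$n_source1))
  s2 <- sprintf("S2_%03d", seq_len(config$n_source2))
  ad <- sprintf("ADM_%03d", seq_len(config$n_admixed))
  manifest <- pop_manifest(c(s1, s2, ad),
                           c(rep("source1", length(s1)),
                             rep("source2", length(s2)),
                             rep("admixed", length(ad))))
  src_pool <- list(`1` = s1, `2` = s2)

  seg_rows <- list()
  truth_rows <- list()
  for (ci in seq_len(nrow(lay))) {
    chrom <- lay$chrom[ci]; L <- lay$length[ci]
    for (s in ad) for (h in 1:2) {
      # tract boundaries: cumulative exponential lengths, truncated at L
      bounds <- 0
      while (bounds[length(bounds)] < L) {
        bounds <- c(bounds, bounds[length(bounds)] +
                      max(1, round(stats::rexp(1, rate = 1 / config$mean_tract_bp))))
      }
      bounds[length(bounds)] <- L
      bounds <- unique(bounds)
      t_start <- bounds[-length(bounds)]
      t_end <- bounds[-1]
      mid <- (t_start + t_end) / 2
      p <- local_p(config, chrom, mid)
      src <- ifelse(stats::runif(length(mid)) < p, 1L, 2L)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        sample = s, hap = h, chrom = chrom,
        start = t_start, end = t_end, source = src, stringsAsFactors = FALSE)
      for (ti in seq_along(t_start)) {
        pool <- src_pool[[src[ti]]]
        for (k in seq_len(config$segments_per_tract)) {
          partner <- pool[sample.int(length(pool), 1)]
          p_hap <- sample.int(2, 1)
          lod <- stats::rexp(1, rate = 1 / config$lod_mean)
          dropped <- stats::runif(1) < config$drop_rate
          if (!dropped) {
            seg_rows[[length(seg_rows) + 1L]] <- data.frame(
              sample_a = s, hap_a = h, sample_b = partner, hap_b = p_hap,
              chrom = chrom, start = t_start[ti], end = t_end[ti],
              lod = lod, stringsAsFactors = FALSE)
          }
        }
      }
      # spurious wrong-breed segments
      n_spur <- stats::rpois(1, config$spurious_rate * L / 1e6)
      if (n_spur > 0) {
        for (k in seq_len(n_spur)) {
          pos <- floor(stats::runif(1, 0, L - 1))
          len <- max(1, round(stats::rexp(1, rate = 1 / config$mean_tract_bp)))
          s_end <- min(pos + len, L)
          mid_k <- (pos + s_end) / 2
          true_src <- src[findInterval(mid_k, t_start)]
          wrong <- if (true_src == 1L) 2L else 1L
          pool <- src_pool[[wrong]]
          partner <- pool[sample.int(length(pool), 1)]
          p_hap <- sample.int(2, 1)
          lod <- stats::rexp(1, rate = 1 / config$lod_mean)
          seg_rows[[length(seg_rows) + 1L]] <- data.frame(
            sample_a = s, hap_a = h, sample_b = partner, hap_b = p_hap,
            chrom = chrom, start = pos, end = s_end,
            lod = lod, stringsAsFactors = FALSE)
        }
      }
    }
  }
  empty_seg <- data.frame(sample_a = character(), hap_a = integer(),
                          sample_b = character(), hap_b = integer(),
                          chrom = character(), start = numeric(),
                          end = numeric(), lod = numeric(),
                          stringsAsFactors = FALSE)
  segments <- if (length(seg_rows)) do.call(rbind, seg_rows) else empty_seg
  rownames(segments) <- NULL
  class(segments) <- c("ibd_segments", "data.frame")
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  structure(list(segments = segments, manifest = manifest, layout = lay,
                 truth = truth, config = config),
            class = "sim_dataset")
}

#' True per-window rIBD from the simulated ancestry mosaic
#'
#' For each grid window, `p` is the base-weighted fraction of admixed
#' haplotype material with source-1 ancestry; the expected normalized rIBD
#' under perfect detection is `2 p - 1`.
#'
#' @param truth Tract table from [simulate_ibd_dataset()].
#' @param grid A `window_grid` on the same layout.
#' @return Data frame `chrom`, `start`, `end`, `true_p`, `true_ribd`.
#' @export
true_window_ribd <- function(truth, grid) {
  stopifnot(inherits(grid, "window_grid"))
  n_hap <- length(unique(paste(truth$sample, truth$hap)))
  s1_bases <- numeric(nrow(grid))
  for (ch in unique(grid$chrom)) {
    in_ch <- which(grid$chrom == ch)
    tr <- truth[truth$chrom == ch & truth$source == 1L, , drop = FALSE]
    if (!nrow(tr)) next
    win_ir <- IRanges::IRanges(start = grid$start[in_ch] + 1, end = grid$end[in_ch])
    tr_ir <- IRanges::IRanges(start = tr$start + 1, end = tr$end)
    hits <- IRanges::findOverlaps(win_ir, tr_ir)
    if (!length(hits)) next
    ov <- IRanges::width(IRanges::pintersect(
      win_ir[S4Vectors::queryHits(hits)], tr_ir[S4Vectors::subjectHits(hits)]))
    tot <- tapply(ov, S4Vectors::queryHits(hits), sum)
    s1_bases[in_ch[as.integer(names(tot))]] <- as.numeric(tot)
  }
  p <- s1_bases / (n_hap * (grid$end - grid$start))
  data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
             true_p = p, true_ribd = 2 * p - 1, stringsAsFactors = FALSE)
}

#' Write a simulated dataset to disk
#'
#' Writes the three pipeline inputs (IBD segments in the 8-column 1-based
#' dialect, manifest, chromosome table) plus the ground truth: a tract table
#' (`<prefix>_truth.tsv`, bed0 coordinates) and the true per-window rIBD at
#' `window_size` resolution (`<prefix>_true_ribd.tsv`).
#'
#' @param dataset A `sim_dataset`.
#' @param prefix Output path prefix.
#' @param window_size Window size for the true-rIBD table (default 10000).
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_sim_dataset <- function(dataset, prefix, window_size = 10000) {
  stopifnot(inherits(dataset, "sim_dataset"))
  paths <- c(ibd = paste0(prefix, "_ibd.tsv"),
             manifest = paste0(prefix, "_manifest.tsv"),
             chromosomes = paste0(prefix, "_chromosomes.tsv"),
             truth = paste0(prefix, "_truth.tsv"),
             true_ribd = paste0(prefix, "_true_ribd.tsv"))
  write_ibd_segments(dataset$segments, paths["ibd"])
  write.table(dataset$manifest, paths["manifest"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(dataset$layout$chrom, format_bp(dataset$layout$length)),
              paths["chromosomes"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  tr <- dataset$truth
  con <- file(paths["truth"], "w")
  writeLines(c("# ribd_ancestry_truth\tdialect=bed0",
               "sample\thap\tchrom\tstart\tend\tsource"), con)
  writeLines(paste(tr$sample, tr$hap, tr$chrom, format_bp(tr$start),
                   format_bp(tr$end), tr$source, sep = "\t"), con)
  close(con)
  grid <- build_window_grid(dataset$layout, window_size)
  tw <- true_window_ribd(dataset$truth, grid)
  con <- file(paths["true_ribd"], "w")
  writeLines(c("# ribd_true_windows\tdialect=bed0",
               "chrom\tstart\tend\ttrue_p\ttrue_ribd"), con)
  writeLines(paste(tw$chrom, format_bp(tw$start), format_bp(tw$end),
                   num_str(tw$true_p), num_str(tw$true_ribd), sep = "\t"), con)
  close(con)
  invisible(paths)
}
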