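# Shared fixture builders: everything is generated in code at test time.

seg_df <- function(sample_a, hap_a, sample_b, hap_b, chrom, start, end, lod = 9) {
  df <- data.frame(sample_a = sample_a, hap_a = hap_a,
                   sample_b = sample_b, hap_b = hap_b,
                   chrom = chrom, start = start, end = end, lod = lod,
                   stringsAsFactors = FALSE)
  class(df) <- c("ibd_segments", "data.frame")
  df
}

empty_segments <- function() {
  seg_df(character(), integer(), character(), integer(),
         character(), numeric(), numeric(), numeric())
}

basic_manifest <- function(n1 = 2, n2 = 2, na = 2) {
  pop_manifest(
    c(sprintf("S1_%d", seq_len(n1)), sprintf("S2_%d", seq_len(n2)),
      sprintf("A%d", seq_len(na))),
    c(rep("source1", n1), rep("source2", n2), rep("admixed", na)))
}

# A window-record table carrying given rIBD scores on a single-chromosome
# grid, with internally consistent fractions and counts.
make_window_records <- function(scores, window_size = 10000, chrom = "1",
                                mode = "normalized") {
  n <- length(scores)
  s1 <- (1 + scores) / 2
  s2 <- (1 - scores) / 2
  df <- data.frame(chrom = chrom,
                   start = (seq_len(n) - 1) * window_size,
                   end = seq_len(n) * window_size,
                   n_ibd_s1 = 5L, n_total_s1 = 10L,
                   n_ibd_s2 = 5L, n_total_s2 = 10L,
                   ibd_s1 = s1, ibd_s2 = s2, ribd = scores,
                   truncated = FALSE, stringsAsFactors = FALSE)
  structure(df, class = c("ribd_windows", "data.frame"),
            score_mode = mode, window_size = window_size)
}

# Random small instance for oracle-equivalence and property tests.
random_instance <- function(seed, n_adm = 3, n_src = 2, n_windows = 20,
                            window_size = 1000, n_seg = 40, n_chrom = 1) {
  set.seed(seed)
  layout <- genome_layout(paste0("chr", seq_len(n_chrom)),
                          rep(n_windows * window_size, n_chrom))
  manifest <- basic_manifest(n_src, n_src, n_adm)
  adm <- role_samples(manifest, "admixed")
  s1 <- role_samples(manifest, "source1")
  s2 <- role_samples(manifest, "source2")
  L <- n_windows * window_size
  rows <- lapply(seq_len(n_seg), function(i) {
    side <- sample(c("source1", "source2"), 1)
    src <- if (side == "source1") sample(s1, 1) else sample(s2, 1)
    a <- sample(adm, 1)
    start <- sample.int(L - 1, 1) - 1
    end <- min(start + sample.int(3 * window_size, 1), L)
    flip <- runif(1) < 0.5  # either column order must be accepted
    if (flip) {
      data.frame(sample_a = src, hap_a = sample.int(2, 1),
                 sample_b = a, hap_b = sample.int(2, 1),
                 chrom = sample(layout$chrom, 1), start = start, end = end,
                 lod = runif(1, 3, 20), stringsAsFactors = FALSE)
    } else {
      data.frame(sample_a = a, hap_a = sample.int(2, 1),
                 sample_b = src, hap_b = sample.int(2, 1),
                 chrom = sample(layout$chrom, 1), start = start, end = end,
                 lod = runif(1, 3, 20), stringsAsFactors = FALSE)
    }
  })
  segments <- do.call(rbind, rows)
  class(segments) <- c("ibd_segments", "data.frame")
  list(segments = segments, layout = layout, manifest = manifest,
       window_size = window_size)
}
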