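# Window grid, per-unit IBD calls, sharing fractions and the rIBD score.

test_that("window grid tiles each chromosome exactly", {
  g <- build_window_grid(genome_layout("c", 25000), 10000)
  expect_equal(g$start, c(0, 10000, 20000))
  expect_equal(g$end, c(10000, 20000, 25000))
  expect_equal(g$truncated, c(FALSE, FALSE, TRUE))

  g1 <- build_window_grid(genome_layout("c", 10000), 10000)
  expect_equal(nrow(g1), 1L)
  expect_equal(c(g1$start, g1$end), c(0, 10000))

  g2 <- build_window_grid(genome_layout("c", 9999), 10000)
  expect_equal(c(g2$start, g2$end, g2$truncated), c(0, 9999, TRUE))

  # tiling invariant on an uneven multi-chromosome layout
  lay <- genome_layout(c("a", "b"), c(123456, 70000))
  g3 <- build_window_grid(lay, 10000)
  for (ch in lay$chrom) {
    w <- g3[g3$chrom == ch, ]
    expect_equal(w$start[1], 0)
    expect_equal(w$end[nrow(w)], lay$length[lay$chrom == ch])
    expect_equal(w$start[-1], w$end[-nrow(w)])  # disjoint and contiguous
    expect_true(all(w$end - w$start > 0 & w$end - w$start <= 10000))
  }
  expect_error(build_window_grid(lay, 0), "positive integer")
})

test_that("window coverage is overlap over window length", {
  expect_equal(window_coverage(1000, 5000, 0, 10000), 0.4)
  expect_equal(window_coverage(0, 10000, 0, 10000), 1.0)
  expect_equal(window_coverage(20000, 30000, 0, 10000), 0.0)
})

test_that("per-haplotype calls merge overlapping tracts before thresholding", {
  layout <- genome_layout("chr1", 10000)
  man <- basic_manifest()
  grid <- build_window_grid(layout, 10000)

  # one full-window segment: only the involved haplotype is called
  seg <- seg_df("A1", 1, "S1_1", 1, "chr1", 0, 10000)
  calls <- call_windows(seg, grid, man, "source1", "haplotype", 0.5)
  expect_true(calls$calls[1, "A1|1"])
  expect_false(calls$calls[1, "A1|2"])
  expect_equal(sum(calls$calls), 1)

  # overlapping tracts from two source haplotypes count once:
  # union of [0,3000) and [2000,6000) is 6000 bases (per-base oracle)
  seg2 <- rbind(seg_df("A1", 1, "S1_1", 1, "chr1", 0, 3000),
                seg_df("A1", 1, "S1_2", 2, "chr1", 2000, 6000))
  class(seg2) <- c("ibd_segments", "data.frame")
  expect_equal(oracle_union_length(c(0, 2000), c(3000, 6000), 10000), 6000)
  expect_true(call_windows(seg2, grid, man, "source1", "haplotype", 0.5)$calls[1, "A1|1"])
  expect_false(call_windows(seg2, grid, man, "source1", "haplotype", 0.7)$calls[1, "A1|1"])
})

test_that("population fraction counts called units over all units", {
  layout <- genome_layout("chr1", 10000)
  man <- basic_manifest(na = 2)  # 4 admixed haplotypes
  grid <- build_window_grid(layout, 10000)
  seg <- rbind(seg_df("A1", 1, "S1_1", 1, "chr1", 0, 10000),
               seg_df("A1", 2, "S1_1", 2, "chr1", 0, 10000),
               seg_df("A2", 1, "S1_2", 1, "chr1", 0, 10000))
  class(seg) <- c("ibd_segments", "data.frame")
  calls <- call_windows(seg, grid, man, "source1", "haplotype", 0.5)
  expect_equal(population_fraction(calls), 0.75)

  empty <- call_windows(empty_segments(), grid, man, "source1", "haplotype", 0.5)
  expect_equal(population_fraction(empty), 0)
})

test_that("rIBD scoring matches the sum-to-1 worked example", {
  # normalized fractions 0.75/0.25 correspond to a score of 0.5
  sc <- ribd_scores(0.75, 0.25, mode = "raw")
  expect_equal(sc$ribd, 0.5)
  expect_equal(ribd_scores(0.5, 0.5, "normalized")$ribd, 0)

  # raw fractions renormalize to sum to 1
  sc2 <- ribd_scores(0.3, 0.2, "normalized")
  expect_equal(sc2$ibd_s1, 0.6)
  expect_equal(sc2$ibd_s2, 0.4)
  expect_equal(sc2$ribd, 0.2)

  # no evidence on either side reports zeros, not NaN
  sc3 <- ribd_scores(c(0, 0.3), c(0, 0.2), "normalized")
  expect_equal(sc3$ribd, c(0, 0.2))
  expect_equal(sc3$ibd_s1 + sc3$ibd_s2, c(0, 1))
})

test_that("inverting a score under the sum-to-1 constraint", {
  inv <- invert_ribd(0.5)
  expect_equal(inv$ibd_s1, 0.75)
  expect_equal(inv$ibd_s2, 0.25)
  expect_equal(invert_ribd(0), list(ibd_s1 = 0.5, ibd_s2 = 0.5))
  expect_equal(invert_ribd(1), list(ibd_s1 = 1, ibd_s2 = 0))
  expect_error(invert_ribd(1.2), "\\[-1, 1\\]")
  # round trip with the forward normalization
  r <- seq(-1, 1, by = 0.25)
  inv <- invert_ribd(r)
  expect_equal(ribd_scores(inv$ibd_s1, inv$ibd_s2, "normalized")$ribd, r)
})

test_that("pipeline handles the degenerate extremes", {
  layout <- genome_layout(c("chr1", "chr2"), c(50000, 25000))
  man <- basic_manifest()
  win0 <- compute_ribd(empty_segments(), layout, man, window_size = 10000)
  expect_equal(nrow(win0), 8L)
  expect_true(all(win0$ribd == 0))

  # every admixed haplotype fully IBD with source1, never source2 -> rIBD 1
  adm <- role_samples(man, "admixed")
  rows <- do.call(rbind, lapply(adm, function(a) rbind(
    seg_df(a, 1, "S1_1", 1, "chr1", 0, 50000),
    seg_df(a, 2, "S1_2", 1, "chr1", 0, 50000),
    seg_df(a, 1, "S1_1", 2, "chr2", 0, 25000),
    seg_df(a, 2, "S1_2", 2, "chr2", 0, 25000))))
  class(rows) <- c("ibd_segments", "data.frame")
  win1 <- compute_ribd(rows, layout, man, window_size = 10000)
  expect_true(all(win1$ribd == 1))
  expect_true(all(win1$ibd_s1 == 1 & win1$ibd_s2 == 0))
})

test_that("pipeline equals the per-base brute-force oracle", {
  for (seed in 1:4) {
    inst <- random_instance(seed, n_adm = 3, n_src = 2, n_windows = 20)
    for (unit in c("haplotype", "individual", "pairwise")) {
      got <- compute_ribd(inst$segments, inst$layout, inst$manifest,
                          window_size = inst$window_size, unit = unit)
      want <- oracle_pipeline(inst$segments, inst$layout, inst$manifest,
                              inst$window_size, unit = unit)
      for (col in names(want)) {
        expect_equal(got[[col]], want[[col]],
                     info = sprintf("seed %d unit %s col %s", seed, unit, col))
      }
    }
  }
  # raw mode and a non-default coverage threshold, multi-chromosome
  inst <- random_instance(9, n_adm = 4, n_src = 3, n_windows = 25, n_chrom = 2)
  got <- compute_ribd(inst$segments, inst$layout, inst$manifest,
                      window_size = inst$window_size, min_cov = 0.3, mode = "raw")
  want <- oracle_pipeline(inst$segments, inst$layout, inst$manifest,
                          inst$window_size, min_cov = 0.3, mode = "raw")
  for (col in names(want)) expect_equal(got[[col]], want[[col]], info = col)
})

test_that("swapping the source labels negates every score", {
  for (seed in c(11, 12)) {
    inst <- random_instance(seed)
    swapped <- inst$manifest
    swapped$role[swapped$role == "source1"] <- "tmp"
    swapped$role[swapped$role == "source2"] <- "source1"
    swapped$role[swapped$role == "tmp"] <- "source2"
    class(swapped) <- class(inst$manifest)
    for (mode in c("normalized", "raw")) {
      a <- compute_ribd(inst$segments, inst$layout, inst$manifest,
                        window_size = inst$window_size, mode = mode)
      b <- compute_ribd(inst$segments, inst$layout, swapped,
                        window_size = inst$window_size, mode = mode)
      expect_equal(b$ribd, -a$ribd)
      expect_equal(b$ibd_s1, a$ibd_s2)
    }
  }
})

test_that("scores are bounded and fractions consistent on random instances", {
  for (seed in 21:24) {
    inst <- random_instance(seed, n_seg = 60)
    win <- compute_ribd(inst$segments, inst$layout, inst$manifest,
                        window_size = inst$window_size)
    expect_true(all(win$ribd >= -1 & win$ribd <= 1))
    expect_true(all(win$ibd_s1 >= 0 & win$ibd_s1 <= 1))
    expect_true(all(win$ibd_s1 + win$ibd_s2 == 0 | abs(win$ibd_s1 + win$ibd_s2 - 1) < 1e-12))
    expect_equal(win$ribd, win$ibd_s1 - win$ibd_s2)
    raw <- compute_ribd(inst$segments, inst$layout, inst$manifest,
                        window_size = inst$window_size, mode = "raw")
    expect_equal(raw$ibd_s1, raw$n_ibd_s1 / raw$n_total_s1)
    expect_equal(raw$ibd_s2, raw$n_ibd_s2 / raw$n_total_s2)
  }
})

test_that("adding a source1 segment never decreases raw-mode scores", {
  for (seed in 31:33) {
    inst <- random_instance(seed)
    base <- compute_ribd(inst$segments, inst$layout, inst$manifest,
                         window_size = inst$window_size, mode = "raw")
    set.seed(seed + 1000)
    L <- sum(inst$layout$length[1])
    extra <- seg_df(sample(role_samples(inst$manifest, "admixed"), 1), sample(2, 1),
                    sample(role_samples(inst$manifest, "source1"), 1), sample(2, 1),
                    inst$layout$chrom[1],
                    start <- sample.int(L - 2000, 1), min(start + 5000, L))
    more <- rbind(inst$segments, extra)
    class(more) <- c("ibd_segments", "data.frame")
    win <- compute_ribd(more, inst$layout, inst$manifest,
                        window_size = inst$window_size, mode = "raw")
    expect_true(all(win$ribd - base$ribd >= 0))
    expect_equal(win$ibd_s2, base$ibd_s2)
  }
})

test_that("chromosomes are scored independently", {
  inst <- random_instance(41, n_chrom = 2, n_windows = 15)
  whole <- compute_ribd(inst$segments, inst$layout, inst$manifest,
                        window_size = inst$window_size)
  for (ch in inst$layout$chrom) {
    sub_layout <- genome_layout(ch, inst$layout$length[inst$layout$chrom == ch])
    sub_seg <- inst$segments[inst$segments$chrom == ch, ]
    class(sub_seg) <- c("ibd_segments", "data.frame")
    part <- compute_ribd(sub_seg, sub_layout, inst$manifest,
                         window_size = inst$window_size)
    whole_ch <- whole[whole$chrom == ch, ]
    rownames(whole_ch) <- NULL
    for (col in names(part)) expect_equal(whole_ch[[col]], part[[col]])
  }
})
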