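# Independent per-base brute-force recomputation of the windowed rIBD scan.
# Deliberately naive: one logical vector per haplotype and base pair, no
# interval library, no sharing of code with the package internals.

oracle_pipeline <- function(segments, layout, manifest, window_size,
                            unit = "haplotype", min_cov = 0.5,
                            mode = "normalized") {
  adm <- manifest$sample[manifest$role == "admixed"]
  out <- NULL
  for (ci in seq_len(nrow(layout))) {
    chrom <- layout$chrom[ci]
    L <- layout$length[ci]
    w_start <- seq(0, L - 1, by = window_size)
    w_end <- pmin(w_start + window_size, L)
    nw <- length(w_start)
    counts <- list()
    for (side in c("source1", "source2")) {
      src <- manifest$sample[manifest$role == side]
      units <- character(0)
      unit_cov <- list()
      register <- function(key) {
        if (is.null(unit_cov[[key]])) unit_cov[[key]] <<- rep(FALSE, L)
        key
      }
      if (unit %in% c("haplotype", "individual")) {
        for (a in adm) for (h in 1:2) register(paste(a, h))
      } else {
        for (a in adm) for (h in 1:2) for (s in src) for (g in 1:2)
          register(paste(a, h, s, g))
      }
      for (i in seq_len(nrow(segments))) {
        if (segments$chrom[i] != chrom) next
        ra <- manifest$role[match(segments$sample_a[i], manifest$sample)]
        rb <- manifest$role[match(segments$sample_b[i], manifest$sample)]
        if (is.na(ra) || is.na(rb)) next
        if (ra == side && rb == "admixed") {
          a <- segments$sample_b[i]; ah <- segments$hap_b[i]
          s <- segments$sample_a[i]; sh <- segments$hap_a[i]
        } else if (rb == side && ra == "admixed") {
          a <- segments$sample_a[i]; ah <- segments$hap_a[i]
          s <- segments$sample_b[i]; sh <- segments$hap_b[i]
        } else next
        key <- if (unit %in% c("haplotype", "individual")) paste(a, ah)
               else paste(a, ah, s, sh)
        # bases covered: 0-based half-open [start, end) -> R indices start+1 .. end
        unit_cov[[key]][(segments$start[i] + 1):segments$end[i]] <- TRUE
      }
      # threshold per unit and window; an individual is called when either
      # of its haplotype-level calls is true
      unit_called <- sapply(names(unit_cov), function(key) {
        vapply(seq_len(nw), function(w) {
          idx <- (w_start[w] + 1):w_end[w]
          sum(unit_cov[[key]][idx]) >= min_cov * length(idx)
        }, logical(1))
      })
      unit_called <- matrix(unit_called, nrow = nw,
                            dimnames = list(NULL, names(unit_cov)))
      if (unit == "individual") {
        unit_called <- sapply(adm, function(a) {
          unit_called[, paste(a, 1)] | unit_called[, paste(a, 2)]
        })
        unit_called <- matrix(unit_called, nrow = nw, dimnames = list(NULL, adm))
      }
      counts[[side]] <- list(n_ibd = as.integer(rowSums(unit_called)),
                             n_total = ncol(unit_called))
    }
    f1 <- counts$source1$n_ibd / counts$source1$n_total
    f2 <- counts$source2$n_ibd / counts$source2$n_total
    if (mode == "raw") {
      s1 <- f1; s2 <- f2
    } else {
      tot <- f1 + f2
      s1 <- ifelse(tot > 0, f1 / tot, 0)
      s2 <- ifelse(tot > 0, f2 / tot, 0)
    }
    out <- rbind(out, data.frame(
      chrom = chrom, start = w_start, end = w_end,
      n_ibd_s1 = counts$source1$n_ibd, n_total_s1 = counts$source1$n_total,
      n_ibd_s2 = counts$source2$n_ibd, n_total_s2 = counts$source2$n_total,
      ibd_s1 = s1, ibd_s2 = s2, ribd = s1 - s2,
      truncated = (w_end - w_start) < window_size, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

# union length of a set of 0-based half-open intervals, counted base by base
oracle_union_length <- function(starts, ends, L) {
  cov <- rep(FALSE, L)
  for (i in seq_along(starts)) cov[(starts[i] + 1):ends[i]] <- TRUE
  sum(cov)
}
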