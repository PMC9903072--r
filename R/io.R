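# Readers and writers for the three inputs (chromosome table, population
# manifest, IBD segment file) and the windowed score tables.  All genomic
# intervals are 0-based half-open internally; conversion to/from the 1-based
# inclusive file dialects happens here and nowhere else.

#' Read a chromosome-length table
#'
#' Two tab-separated columns: chromosome name and length in base pairs.
#' Row order is preserved and defines the output and plotting order.
#'
#' @param path Path to a tab-separated file (transparently gzipped allowed).
#' @return A `genome_layout` data frame with columns `chrom` and `length`.
#' @export
read_chromosome_table <- function(path) {
  rows <- read_tsv_lines(path, n_fields = 2, what = "chromosome table")
  chrom <- vapply(rows$fields, `[`, character(1), 1L)
  len_str <- vapply(rows$fields, `[`, character(1), 2L)
  len <- suppressWarnings(as.numeric(len_str))
  bad <- is.na(len) | len != floor(len) | len <= 0
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("%s line %d: chromosome length '%s' is not a positive integer",
                 path, rows$lineno[i], len_str[i]), call. = FALSE)
  }
  if (anyDuplicated(chrom)) {
    stop(sprintf("%s: duplicate chromosome name '%s'",
                 path, chrom[duplicated(chrom)][1L]), call. = FALSE)
  }
  genome_layout(chrom, len)
}

#' Construct a genome layout
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Positive integer lengths in base pairs, one per chromosome.
#' @return A `genome_layout` data frame; row order is the genome order.
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  stopifnot(length(chrom) == base::length(length))
  if (base::length(chrom) == 0L) stop("layout needs at least one chromosome", call. = FALSE)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique", call. = FALSE)
  if (any(!is.finite(length) | length <= 0 | length != floor(length)))
    stop("chromosome lengths must be positive integers", call. = FALSE)
  structure(data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE),
            class = c("genome_layout", "data.frame"))
}

#' Read a population manifest
#'
#' Two tab-separated columns: sample ID and role.  Roles are matched
#' case-insensitively against `source1`, `source2` and `admixed`; each role
#' must have at least one sample.
#'
#' @param path Path to the manifest file.
#' @return A `pop_manifest` data frame with columns `sample` and `role`.
#' @export
read_population_manifest <- function(path) {
  rows <- read_tsv_lines(path, n_fields = 2, what = "population manifest")
  sample <- vapply(rows$fields, `[`, character(1), 1L)
  role_raw <- vapply(rows$fields, `[`, character(1), 2L)
  role <- tolower(role_raw)
  bad <- !role %in% c("source1", "source2", "admixed")
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("%s line %d: unknown role '%s' (expected source1/source2/admixed)",
                 path, rows$lineno[i], role_raw[i]), call. = FALSE)
  }
  pop_manifest(sample, role)
}

#' Construct a population manifest
#'
#' @param sample Character vector of unique sample IDs.
#' @param role Role per sample: `source1`, `source2` or `admixed`.
#' @return A `pop_manifest` data frame.
#' @export
pop_manifest <- function(sample, role) {
  sample <- as.character(sample)
  role <- tolower(as.character(role))
  stopifnot(length(sample) == length(role))
  if (anyDuplicated(sample))
    stop(sprintf("duplicate sample ID '%s' in manifest",
                 sample[duplicated(sample)][1L]), call. = FALSE)
  if (!all(role %in% c("source1", "source2", "admixed")))
    stop("roles must be source1, source2 or admixed", call. = FALSE)
  for (r in c("source1", "source2", "admixed")) {
    if (!any(role == r))
      stop(sprintf("manifest has no '%s' samples", r), call. = FALSE)
  }
  structure(data.frame(sample = sample, role = role, stringsAsFactors = FALSE),
            class = c("pop_manifest", "data.frame"))
}

#' Samples assigned to one role
#' @param manifest A `pop_manifest`.
#' @param role One of `"source1"`, `"source2"`, `"admixed"`.
#' @return Character vector of sample IDs, in manifest order.
#' @export
role_samples <- function(manifest, role) {
  manifest$sample[manifest$role == role]
}

#' Read pairwise IBD segments (Refined-IBD-style dialect)
#'
#' Eight tab-separated columns: sample A, haplotype A index (1 or 2),
#' sample B, haplotype B index, chromosome, start, end, LOD.  File
#' coordinates are 1-based inclusive; internally segments become 0-based
#' half-open (`start - 1`, `end`).
#'
#' Segments are skipped (and counted in the attached skip report) when their
#' LOD is below `min_lod`, when either sample is absent from the manifest,
#' when both samples belong to a source breed (source-source pairs play no
#' role in the rIBD contrast), when both are admixed, or when shorter than
#' `min_length`.
#'
#' @param path Path to the segment file.
#' @param layout A `genome_layout`; segments must fall inside it.
#' @param manifest A `pop_manifest`.
#' @param min_lod Minimum LOD score to keep a segment (default 3).
#' @param min_length Minimum segment length in bp (default 0, i.e. off).
#' @return An `ibd_segments` data frame with columns `sample_a`, `hap_a`,
#'   `sample_b`, `hap_b`, `chrom`, `start`, `end`, `lod` and a
#'   `skip_report` attribute (named integer vector).
#' @export
read_ibd_segments <- function(path, layout, manifest, min_lod = 3, min_length = 0) {
  stopifnot(inherits(layout, "genome_layout"), inherits(manifest, "pop_manifest"))
  rows <- read_tsv_lines(path, n_fields = 8, what = "IBD segment file")
  n <- length(rows$lineno)
  get <- function(j) vapply(rows$fields, `[`, character(1), j)
  sample_a <- get(1L); sample_b <- get(3L)
  hap_a <- suppressWarnings(as.integer(get(2L)))
  hap_b <- suppressWarnings(as.integer(get(4L)))
  chrom <- get(5L)
  start1 <- suppressWarnings(as.numeric(get(6L)))
  end1 <- suppressWarnings(as.numeric(get(7L)))
  lod <- suppressWarnings(as.numeric(get(8L)))

  fail <- function(i, msg) {
    stop(sprintf("%s line %d: %s", path, rows$lineno[i], msg), call. = FALSE)
  }
  bad_hap <- is.na(hap_a) | is.na(hap_b) | !hap_a %in% 1:2 | !hap_b %in% 1:2
  if (any(bad_hap)) fail(which(bad_hap)[1L], "haplotype index must be 1 or 2")
  bad_num <- is.na(start1) | is.na(end1) | is.na(lod) |
    start1 != floor(start1) | end1 != floor(end1)
  if (any(bad_num)) fail(which(bad_num)[1L], "malformed coordinates or LOD")
  if (any(lod < 0)) fail(which(lod < 0)[1L], "negative LOD score")
  chr_idx <- match(chrom, layout$chrom)
  if (anyNA(chr_idx))
    fail(which(is.na(chr_idx))[1L],
         sprintf("chromosome '%s' not in layout", chrom[which(is.na(chr_idx))[1L]]))
  if (any(start1 < 1)) fail(which(start1 < 1)[1L], "start below 1 (file is 1-based)")
  if (any(start1 > end1)) fail(which(start1 > end1)[1L], "start greater than end")
  over <- end1 > layout$length[chr_idx]
  if (any(over)) fail(which(over)[1L], "segment end beyond chromosome length")
  self <- sample_a == sample_b & hap_a == hap_b
  if (any(self)) fail(which(self)[1L], "segment pairs a haplotype with itself")

  role_a <- manifest$role[match(sample_a, manifest$sample)]
  role_b <- manifest$role[match(sample_b, manifest$sample)]
  is_source <- function(r) !is.na(r) & r %in% c("source1", "source2")

  # classification order: LOD filter, unknown samples, irrelevant pairs, length
  skip_lod <- lod < min_lod
  skip_unknown <- !skip_lod & (is.na(role_a) | is.na(role_b))
  skip_ss <- !skip_lod & !skip_unknown & is_source(role_a) & is_source(role_b)
  skip_aa <- !skip_lod & !skip_unknown &
    !is.na(role_a) & !is.na(role_b) & role_a == "admixed" & role_b == "admixed"
  skip_short <- !skip_lod & !skip_unknown & !skip_ss & !skip_aa &
    (end1 - start1 + 1) < min_length
  keep <- !(skip_lod | skip_unknown | skip_ss | skip_aa | skip_short)

  seg <- data.frame(
    sample_a = sample_a[keep], hap_a = hap_a[keep],
    sample_b = sample_b[keep], hap_b = hap_b[keep],
    chrom = chrom[keep],
    start = start1[keep] - 1, end = end1[keep],
    lod = lod[keep], stringsAsFactors = FALSE)
  report <- c(total = n, accepted = sum(keep),
              low_lod = sum(skip_lod), unknown_sample = sum(skip_unknown),
              source_source = sum(skip_ss), admixed_admixed = sum(skip_aa),
              short = sum(skip_short))
  structure(seg, class = c("ibd_segments", "data.frame"), skip_report = report)
}

#' Skip report of a segment read
#' @param segments An `ibd_segments` object from [read_ibd_segments()].
#' @return Named integer vector of line counts by fate.
#' @export
skip_report <- function(segments) attr(segments, "skip_report")

#' Write IBD segments in the Refined-IBD-style 8-column dialect
#'
#' Inverse of [read_ibd_segments()]: internal 0-based half-open intervals are
#' written as 1-based inclusive coordinates.
#'
#' @param segments Data frame with the `ibd_segments` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ibd_segments <- function(segments, path) {
  out <- data.frame(segments$sample_a, segments$hap_a,
                    segments$sample_b, segments$hap_b,
                    segments$chrom,
                    format_bp(segments$start + 1), format_bp(segments$end),
                    num_str(segments$lod))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

window_table_columns <- c("chrom", "start", "end",
                          "n_ibd_s1", "n_total_s1", "n_ibd_s2", "n_total_s2",
                          "ibd_s1", "ibd_s2", "ribd", "truncated")

#' Write a windowed rIBD score table
#'
#' Tab-separated with a mandatory header; the first line is a comment tag
#' recording the coordinate dialect (and score mode), so that the table can
#' be re-read without off-by-one ambiguity.  `bed0` writes 0-based half-open
#' coordinates (BED-compatible first three columns); `one_based` writes
#' 1-based inclusive coordinates.
#'
#' @param records A `ribd_windows` table from [compute_ribd()], sorted by
#'   layout order and start (the caller's contract).
#' @param path Output path.
#' @param dialect `"bed0"` (default) or `"one_based"`.
#' @return `path`, invisibly.
#' @export
write_window_table <- function(records, path, dialect = c("bed0", "one_based")) {
  dialect <- match.arg(dialect)
  stopifnot(all(window_table_columns %in% names(records)))
  ord <- order(match(records$chrom, unique(records$chrom)), records$start)
  if (!identical(ord, seq_len(nrow(records))))
    stop("window records must be sorted by chromosome order and start", call. = FALSE)
  mode <- attr(records, "score_mode")
  if (is.null(mode)) mode <- "unknown"
  start <- records$start
  end <- records$end
  if (dialect == "one_based") start <- start + 1
  out <- data.frame(records$chrom, format_bp(start), format_bp(end),
                    records$n_ibd_s1, records$n_total_s1,
                    records$n_ibd_s2, records$n_total_s2,
                    num_str(records$ibd_s1), num_str(records$ibd_s2),
                    num_str(records$ribd), as.integer(records$truncated))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ribd_window_table\tdialect=%s\tmode=%s", dialect, mode), con)
  writeLines(paste(window_table_columns, collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
  invisible(path)
}

#' Read a windowed rIBD score table
#'
#' Reads tables produced by [write_window_table()]; the header comment
#' declares the coordinate dialect.  Record invariants are re-validated:
#' `ribd` must lie in \[-1, 1\] and equal `ibd_s1 - ibd_s2` within 1e-9.
#'
#' @param path Path to the table.
#' @return A `ribd_windows` data frame (internal 0-based half-open
#'   coordinates) with the score mode in attribute `score_mode`.
#' @export
read_window_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || !startsWith(lines[1L], "# ribd_window_table"))
    stop(sprintf("%s: missing ribd_window_table header", path), call. = FALSE)
  tag <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  get_tag <- function(key) {
    hit <- grep(paste0("^", key, "="), tag, value = TRUE)
    if (length(hit) != 1L)
      stop(sprintf("%s: header lacks %s tag", path, key), call. = FALSE)
    sub(paste0("^", key, "="), "", hit)
  }
  dialect <- get_tag("dialect")
  if (!dialect %in% c("bed0", "one_based"))
    stop(sprintf("%s: unknown dialect '%s'", path, dialect), call. = FALSE)
  mode <- get_tag("mode")
  header <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, window_table_columns))
    stop(sprintf("%s: unexpected column header", path), call. = FALSE)
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  df <- if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != length(window_table_columns)))
      stop(sprintf("%s: malformed row", path), call. = FALSE)
    m <- do.call(rbind, parts)
    data.frame(chrom = m[, 1],
               start = as.numeric(m[, 2]), end = as.numeric(m[, 3]),
               n_ibd_s1 = as.integer(m[, 4]), n_total_s1 = as.integer(m[, 5]),
               n_ibd_s2 = as.integer(m[, 6]), n_total_s2 = as.integer(m[, 7]),
               ibd_s1 = as.numeric(m[, 8]), ibd_s2 = as.numeric(m[, 9]),
               ribd = as.numeric(m[, 10]), truncated = m[, 11] == "1",
               stringsAsFactors = FALSE)
  } else {
    stop(sprintf("%s: empty window table", path), call. = FALSE)
  }
  if (dialect == "one_based") df$start <- df$start - 1
  if (any(df$ribd < -1 | df$ribd > 1))
    stop(sprintf("%s: rIBD outside [-1, 1]", path), call. = FALSE)
  if (any(df$ibd_s1 < 0 | df$ibd_s1 > 1 | df$ibd_s2 < 0 | df$ibd_s2 > 1))
    stop(sprintf("%s: IBD fraction outside [0, 1]", path), call. = FALSE)
  if (any(abs(df$ribd - (df$ibd_s1 - df$ibd_s2)) > 1e-9))
    stop(sprintf("%s: ribd inconsistent with ibd_s1 - ibd_s2", path), call. = FALSE)
  if (any(df$n_ibd_s1 > df$n_total_s1 | df$n_ibd_s2 > df$n_total_s2 |
          df$n_ibd_s1 < 0 | df$n_ibd_s2 < 0))
    stop(sprintf("%s: inconsistent window counts", path), call. = FALSE)
  structure(df, class = c("ribd_windows", "data.frame"), score_mode = mode)
}

# --- internal helpers --------------------------------------------------------

# Split a tab-separated text file into fields, skipping blanks and comment
# lines, enforcing a strict column count; keeps original line numbers so
# errors can name them.
read_tsv_lines <- function(path, n_fields, what) {
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (!length(lines)) stop(sprintf("%s: empty %s", path, what), call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) != n_fields
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("%s line %d: expected %d tab-separated fields, found %d",
                 path, lineno[i], n_fields, lengths(fields)[i]), call. = FALSE)
  }
  list(fields = fields, lineno = lineno)
}

# Base-pair positions are stored as doubles (they can exceed .Machine$integer.max
# on large genomes); print them without scientific notation.
format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

# Full-precision decimal text so tables round-trip losslessly.
num_str <- function(x) {
  s <- sprintf("%.17g", x)
  sub("^(-?\\d+)\\.0*$", "\\1", s)
}
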