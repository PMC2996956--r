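empty_ssr_frame <- function() {
  data.frame(read_id = character(), start = integer(), end = integer(),
             unit_length = integer(), observed_unit = character(),
             motif_class = character(), repeat_count = integer(),
             span_bp = integer(), is_terminal = logical(),
             library_label = character(), stringsAsFactors = FALSE)
}

#' Find maximal perfect SSR runs in one sequence
#'
#' Scans a read for perfect tandem repeats with primitive units of the
#' requested lengths. Every reported run is maximal: it cannot be extended
#' perfectly by one base in either direction with the same unit. The run
#' detector works per unit length k on the lag-k self-match vector, so a run
#' of `TRUE` of length L marks a period-k stretch of L + k bases; maximal
#' `TRUE` runs map one-to-one onto maximal period-k repeat runs. Runs whose
#' repeat unit is non-primitive are skipped (they are the same physical run
#' seen at a multiple of its true period), which also guarantees the
#' reported `unit_length` is the smallest period of the run. Any `N`
#' terminates extension. Compound and imperfect structures are never merged;
#' see [filter_compound()] to drop adjacent runs.
#'
#' @param sequence Uppercase A/C/G/T/N string (a character scalar or an
#'   [ssr_library] read row can be passed via [scan_library()]).
#' @param read_id Identifier recorded in the output.
#' @param min_units Minimum number of complete repeat units (default 5).
#' @param unit_lengths Unit lengths to scan, subset of 2..6.
#' @param partial_extension If `TRUE` (default) the reported span includes a
#'   perfect partial trailing unit, while `repeat_count` still counts
#'   complete units only.
#' @param library_label Optional label carried into the output.
#' @return `data.frame` of SSR loci sorted by start, with 0-based half-open
#'   `start`/`end`, the `observed_unit` in its phase of occurrence, the
#'   canonical `motif_class`, `repeat_count`, `span_bp`, and an
#'   `is_terminal` placeholder (`NA` until [flag_terminal()]).
#' @examples
#' find_ssrs("GGGATATATATATATGGG")   # one (AT)6 locus at [3, 15)
#' @export
find_ssrs <- function(sequence, read_id = "read", min_units = 5L,
                      unit_lengths = 2:6, partial_extension = TRUE,
                      library_label = NA_character_) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  min_units <- as.integer(min_units)
  if (min_units < 2L) stop("min_units must be >= 2")
  unit_lengths <- as.integer(unit_lengths)
  if (!all(unit_lengths %in% 2:6)) stop("unit_lengths must lie in 2..6")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  is_base <- chars %in% DNA_BASES4
  rows <- list()
  for (k in unit_lengths) {
    if (n < k * min_units) next
    idx <- seq_len(n - k)
    eq <- (chars[idx] == chars[idx + k]) & is_base[idx] & is_base[idx + k]
    r <- rle(eq)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    hits <- which(r$values & r$lengths >= k * (min_units - 1L))
    for (j in hits) {
      s1 <- run_start[j]                     # 1-based first matched position
      span <- r$lengths[j] + k
      rc <- span %/% k
      if (rc < min_units) next
      unit <- paste(chars[s1:(s1 + k - 1L)], collapse = "")
      if (!is_primitive(unit)) next
      start0 <- s1 - 1L
      end0 <- if (partial_extension) start0 + span else start0 + rc * k
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = read_id, start = start0, end = end0,
        unit_length = k, observed_unit = unit,
        motif_class = canonical_motif(unit),
        repeat_count = rc, span_bp = end0 - start0,
        is_terminal = NA, library_label = library_label,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_ssr_frame())
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$unit_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a whole library for SSRs
#'
#' Runs [find_ssrs()] on every read, then flags terminal loci with
#' [flag_terminal()] and (optionally) removes compound runs with
#' [filter_compound()].
#'
#' @inheritParams find_ssrs
#' @param lib An [ssr_library].
#' @param min_flank_bp Minimum flank on both sides for a locus to be
#'   primer-designable; shorter flanks set `is_terminal` (default 20, about
#'   one primer length).
#' @param drop_compound If `TRUE`, apply [filter_compound()] per read.
#' @param max_compound_gap_bp Gap threshold for compound filtering.
#' @return `data.frame` of SSR loci across all reads.
#' @export
scan_library <- function(lib, min_units = 5L, unit_lengths = 2:6,
                         partial_extension = TRUE, min_flank_bp = 20L,
                         drop_compound = FALSE, max_compound_gap_bp = 0L) {
  stopifnot(inherits(lib, "ssr_library"))
  per_read <- lapply(seq_len(lib$n_reads), function(i) {
    row <- lib$reads[i, ]
    loci <- find_ssrs(row$sequence, read_id = row$read_id,
                      min_units = min_units, unit_lengths = unit_lengths,
                      partial_extension = partial_extension,
                      library_label = row$library_label)
    if (nrow(loci) && drop_compound)
      loci <- filter_compound(loci, max_gap_bp = max_compound_gap_bp)
    loci
  })
  loci <- do.call(rbind, c(per_read, list(empty_ssr_frame())))
  rownames(loci) <- NULL
  flag_terminal(loci, lib, min_flank_bp = min_flank_bp)
}

#' Flag terminal SSR loci
#'
#' A locus is terminal when either flank is shorter than `min_flank_bp`;
#' such loci sit too close to a sequencing-read end for primers to be
#' designed in flanking sequence.
#'
#' @param loci SSR `data.frame` from [find_ssrs()]/[scan_library()].
#' @param lib The [ssr_library] the loci came from.
#' @param min_flank_bp Minimum flank length in bp.
#' @return `loci` with `is_terminal` filled in.
#' @export
flag_terminal <- function(loci, lib, min_flank_bp = 20L) {
  stopifnot(inherits(lib, "ssr_library"))
  if (!nrow(loci)) { loci$is_terminal <- logical(0); return(loci) }
  len <- lib$reads$length_bp[match(loci$read_id, lib$reads$read_id)]
  if (anyNA(len))
    stop("loci reference read_ids absent from the library")
  if (any(loci$start < 0L | loci$end > len))
    stop("locus coordinates fall outside the read bounds")
  loci$is_terminal <- loci$start < min_flank_bp |
    (len - loci$end) < min_flank_bp
  loci
}

#' Drop compound repeat structures
#'
#' Removes every locus whose gap to another locus on the same read is at
#' most `max_gap_bp` (default 0: only abutting or overlapping runs count as
#' compound). The removal is symmetric: both members of a compound pair go.
#'
#' @param loci SSR `data.frame` (one or more reads).
#' @param max_gap_bp Maximum gap in bp between spans for two runs to be
#'   considered parts of one compound structure.
#' @return Filtered `data.frame`, original order preserved.
#' @export
filter_compound <- function(loci, max_gap_bp = 0L) {
  if (nrow(loci) < 2L) return(loci)
  drop <- logical(nrow(loci))
  for (ids in split(seq_len(nrow(loci)), loci$read_id)) {
    if (length(ids) < 2L) next
    for (a in ids) for (b in ids) {
      if (a >= b) next
      gap <- max(loci$start[b], loci$start[a]) - min(loci$end[a], loci$end[b])
      if (gap <= max_gap_bp) drop[c(a, b)] <- TRUE
    }
  }
  out <- loci[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

ssr_granges <- function(loci) {
  GenomicRanges::GRanges(
    seqnames = loci$read_id,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = "+",
    type = "microsatellite",
    motif_class = loci$motif_class,
    observed_unit = loci$observed_unit,
    repeat_count = loci$repeat_count,
    is_terminal = loci$is_terminal)
}

#' Write SSR calls as GFF3
#'
#' Coordinates are converted from the internal 0-based half-open convention
#' to GFF3 1-based inclusive. Feature type is `microsatellite`.
#'
#' @param loci SSR `data.frame`.
#' @param path Output `.gff3` path.
#' @return `path`, invisibly.
#' @export
write_ssr_gff3 <- function(loci, path) {
  rtracklayer::export(ssr_granges(loci), path, format = "GFF3")
  invisible(path)
}

#' Write or read the SSR call table (TSV)
#'
#' @param loci SSR `data.frame`.
#' @param path TSV path.
#' @return `path` (write) or the call `data.frame` (read).
#' @export
write_ssr_table <- function(loci, path) {
  write.table(loci, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ssr_table
#' @export
read_ssr_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
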