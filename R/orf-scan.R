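empty_orf_frame <- function() {
  data.frame(read_id = character(), start = integer(), end = integer(),
             strand = character(), frame = integer(), length_nt = integer(),
             stringsAsFactors = FALSE)
}

revcomp_chr <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

orfs_one_strand <- function(sequence, min_orf_nt) {
  n <- nchar(sequence)
  out <- list()
  for (frame in 0:2) {
    starts <- seq.int(frame + 1L, n, by = 3L)
    starts <- starts[starts + 2L <= n]
    if (!length(starts)) next
    codons <- substring(sequence, starts, starts + 2L)
    is_atg <- codons == "ATG"
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    stop_idx <- which(is_stop)
    for (i in which(is_atg)) {
      nxt <- stop_idx[stop_idx > i]
      if (!length(nxt)) next
      j <- nxt[1L]
      len <- (j - i + 1L) * 3L          # stop codon included in the span
      if (len < min_orf_nt) next
      out[[length(out) + 1L]] <- c(start = starts[i] - 1L,
                                   end = starts[j] + 2L, frame = frame,
                                   length_nt = len)
    }
  }
  out
}

#' Find open reading frames in all reading frames
#'
#' An ORF runs from an ATG to the first in-frame stop codon (TAA/TAG/TGA)
#' downstream, stop codon included. Every qualifying ATG yields an ORF, so
#' nested ORFs sharing a stop are all reported. All three frames of each
#' requested strand are scanned; reverse-strand ORFs are reported in
#' forward-strand coordinates. Codons containing `N` match neither start
#' nor stop and are read through.
#'
#' @param sequence Uppercase A/C/G/T/N string.
#' @param read_id Identifier recorded in the output.
#' @param min_orf_nt Minimum ORF length in nucleotides, a multiple of 3
#'   (default 300, i.e. 100 codons — the historical NCBI ORF-finder default).
#' @param strands Strands to scan, subset of `c("+", "-")`.
#' @return `data.frame` with 0-based half-open `start`/`end` (forward
#'   coordinates), `strand`, `frame` (0-2, start position mod 3 on the
#'   ORF's own strand) and `length_nt`.
#' @export
find_orfs <- function(sequence, read_id = "read", min_orf_nt = 300L,
                      strands = c("+", "-")) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  min_orf_nt <- as.integer(min_orf_nt)
  if (min_orf_nt %% 3L != 0L || min_orf_nt < 3L)
    stop("min_orf_nt must be a positive multiple of 3")
  if (!all(strands %in% c("+", "-"))) stop("strands must be '+' and/or '-'")
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  rows <- list()
  if ("+" %in% strands) {
    for (o in orfs_one_strand(sequence, min_orf_nt))
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = read_id, start = unname(o["start"]), end = unname(o["end"]),
        strand = "+", frame = unname(o["frame"]),
        length_nt = unname(o["length_nt"]), stringsAsFactors = FALSE)
  }
  if ("-" %in% strands && n >= 3L) {
    for (o in orfs_one_strand(revcomp_chr(sequence), min_orf_nt))
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = read_id, start = n - unname(o["end"]),
        end = n - unname(o["start"]), strand = "-",
        frame = unname(o["frame"]), length_nt = unname(o["length_nt"]),
        stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_orf_frame())
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a whole library for ORFs
#'
#' @inheritParams find_orfs
#' @param lib An [ssr_library].
#' @return `data.frame` of ORFs across all reads.
#' @export
scan_orfs <- function(lib, min_orf_nt = 300L, strands = c("+", "-")) {
  stopifnot(inherits(lib, "ssr_library"))
  per_read <- lapply(seq_len(lib$n_reads), function(i) {
    find_orfs(lib$reads$sequence[i], read_id = lib$reads$read_id[i],
              min_orf_nt = min_orf_nt, strands = strands)
  })
  out <- do.call(rbind, c(per_read, list(empty_orf_frame())))
  rownames(out) <- NULL
  out
}

#' Classify SSR placement relative to ORFs
#'
#' Each locus is `inside` when its span is contained in a single ORF,
#' `outside` when it is disjoint from the union of all ORF spans on its
#' read, and `bridging` otherwise (it straddles an ORF boundary, including
#' the case where it is covered by the union of several ORFs but by no
#' single one). Bridging loci are conventionally excluded from downstream
#' goodness-of-fit tests.
#'
#' @param loci SSR `data.frame`.
#' @param orfs ORF `data.frame` from [find_orfs()]/[scan_orfs()]; only ORFs
#'   whose `read_id` matches each locus are consulted, so a pooled table is
#'   fine. Classification is invariant to ORF order and duplication.
#' @return `loci` with an `orf_placement` column
#'   (`"inside"`/`"outside"`/`"bridging"`).
#' @export
classify_placement <- function(loci, orfs) {
  needed <- c("read_id", "start", "end")
  if (!all(needed %in% names(orfs)))
    stop("orfs must have columns read_id, start, end")
  placement <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    o <- orfs[orfs$read_id == loci$read_id[i], , drop = FALSE]
    s <- loci$start[i]; e <- loci$end[i]
    if (nrow(o) == 0L) { placement[i] <- "outside"; next }
    contained <- any(o$start <= s & e <= o$end)
    overlaps <- any(o$start < e & s < o$end)
    placement[i] <- if (contained) "inside"
      else if (!overlaps) "outside" else "bridging"
  }
  loci$orf_placement <- placement
  loci
}

#' Write ORFs as GFF3
#'
#' @param orfs ORF `data.frame`.
#' @param path Output `.gff3` path.
#' @return `path`, invisibly.
#' @export
write_orf_gff3 <- function(orfs, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = orfs$read_id,
    ranges = IRanges::IRanges(start = orfs$start + 1L, end = orfs$end),
    strand = orfs$strand,
    type = "ORF", frame = orfs$frame)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
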