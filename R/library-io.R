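#' Construct a sequence library
#'
#' A light container for a read library: a `data.frame` of reads plus a
#' library label ("BAC", "EST", or anything else). Sequences are uppercased;
#' bases outside A/C/G/T/N are rejected.
#'
#' @param read_id Character vector of read identifiers.
#' @param sequence Character vector of nucleotide sequences.
#' @param library_label Single label applied to all reads.
#' @return An object of class `ssr_library`: a list with elements
#'   `reads` (data.frame: read_id, sequence, length_bp, library_label),
#'   `label`, `n_reads`, `total_bases`.
#' @export
ssr_library <- function(read_id, sequence, library_label = "library") {
  if (length(read_id) != length(sequence))
    stop("read_id and sequence must have equal length")
  if (length(sequence) == 0L)
    stop("empty library: no sequence records")
  sequence <- toupper(as.character(sequence))
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad))
    stop("sequences contain letters outside A/C/G/T/N: read ",
         read_id[which(bad)[1L]])
  read_id <- as.character(read_id)
  if (anyDuplicated(read_id)) {
    warning("duplicate read IDs; suffixing duplicates deterministically")
    read_id <- make.unique(read_id, sep = ".dup")
  }
  reads <- data.frame(
    read_id = read_id,
    sequence = sequence,
    length_bp = nchar(sequence),
    library_label = library_label,
    stringsAsFactors = FALSE)
  structure(
    list(reads = reads, label = library_label,
         n_reads = nrow(reads), total_bases = sum(reads$length_bp)),
    class = "ssr_library")
}

#' @export
print.ssr_library <- function(x, ...) {
  cat(sprintf("ssr_library '%s': %d reads, %d bases (mean %.0f bp)\n",
              x$label, x$n_reads, x$total_bases,
              x$total_bases / x$n_reads))
  invisible(x)
}

#' Read a FASTA sequence library
#'
#' Loads a FASTA file into an [ssr_library]. Record IDs are the first
#' whitespace-delimited token of each header; mixed-case sequence is
#' uppercased; record order is preserved.
#'
#' @param path FASTA file path.
#' @param library_label Label for the library (e.g. `"BAC"`, `"EST"`).
#' @return An [ssr_library].
#' @export
read_fasta_library <- function(path, library_label = "library") {
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(seqs) == 0L)
    stop("empty library: no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  ssr_library(ids, as.character(seqs), library_label = library_label)
}

#' Write a library back to FASTA
#'
#' @param lib An [ssr_library].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_library <- function(lib, path) {
  stopifnot(inherits(lib, "ssr_library"))
  x <- Biostrings::DNAStringSet(lib$reads$sequence)
  names(x) <- lib$reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Remove exact-duplicate reads
#'
#' Mirrors redundancy elimination by sequence identity: reads whose full
#' sequence is byte-identical (case-insensitive, and case is already
#' normalised on load) to an earlier read are dropped; the first occurrence
#' is kept. Near-identical reads are not clustered.
#'
#' @param lib An [ssr_library].
#' @return List with `library` (deduplicated [ssr_library]), `n_removed`,
#'   and `removed_ids`.
#' @export
deduplicate <- function(lib) {
  stopifnot(inherits(lib, "ssr_library"))
  dup <- duplicated(lib$reads$sequence)
  kept <- lib$reads[!dup, , drop = FALSE]
  out <- ssr_library(kept$read_id, kept$sequence, library_label = lib$label)
  list(library = out, n_removed = sum(dup),
       removed_ids = lib$reads$read_id[dup])
}
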