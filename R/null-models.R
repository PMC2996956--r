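motif_distribution <- function(class_probs, unit_length, source,
                               n_kmers_counted = NA_integer_) {
  structure(list(unit_length = as.integer(unit_length),
                 class_probs = class_probs, source = source,
                 n_kmers_counted = n_kmers_counted),
            class = "motif_distribution")
}

#' @export
print.motif_distribution <- function(x, ...) {
  cat(sprintf("motif_distribution (%s, unit length %d, %d classes)\n",
              x$source, x$unit_length, length(x$class_probs)))
  print(round(x$class_probs, 4))
  invisible(x)
}

#' Library-composition null distribution of motif classes
#'
#' The null model for motif usage: how often would each rotation class
#' arise if SSR motifs simply mirrored the k-mer composition of the
#' library? Counts every overlapping k-mer of length `unit_length` on the
#' forward strand of every read (k-mers never span reads), discards k-mers
#' containing `N` and non-primitive k-mers, pools counts by rotation class
#' and normalises.
#'
#' @param lib An [ssr_library].
#' @param unit_length Motif length (2 or 3 in the survey; 2..6 accepted).
#' @param exclude_ssr_spans If `TRUE`, mask the spans in `loci` with `N`
#'   before counting, so the background excludes the repeats themselves.
#' @param loci SSR `data.frame`; required when `exclude_ssr_spans = TRUE`.
#' @return A `motif_distribution` with `source = "composition"`.
#' @export
composition_distribution <- function(lib, unit_length,
                                     exclude_ssr_spans = FALSE,
                                     loci = NULL) {
  stopifnot(inherits(lib, "ssr_library"))
  unit_length <- as.integer(unit_length)
  if (unit_length < 2L || unit_length > 6L)
    stop("unit_length must be in 2..6")
  seqs <- lib$reads$sequence
  if (exclude_ssr_spans) {
    if (is.null(loci)) stop("loci required when exclude_ssr_spans = TRUE")
    for (i in seq_len(nrow(loci))) {
      j <- match(loci$read_id[i], lib$reads$read_id)
      substr(seqs[j], loci$start[i] + 1L, loci$end[i]) <-
        strrep("N", loci$span_bp[i])
    }
  }
  counts <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = unit_length))
  classes <- motif_classes(unit_length)
  class_counts <- vapply(seq_len(nrow(classes)), function(i) {
    sum(counts[classes$members[[i]]])
  }, numeric(1))
  names(class_counts) <- classes$canonical
  total <- sum(class_counts)
  if (total == 0)
    stop("degenerate background: no countable primitive k-mers")
  motif_distribution(class_counts / total, unit_length, "composition",
                     n_kmers_counted = as.integer(total))
}

#' Uniform null distribution of motif classes
#'
#' @param unit_length Motif length in 2..6.
#' @return A `motif_distribution` assigning every rotation class equal
#'   probability (`1/6` for dinucleotides, `1/20` for trinucleotides).
#' @export
uniform_distribution <- function(unit_length) {
  classes <- motif_classes(unit_length)
  p <- setNames(rep(1 / nrow(classes), nrow(classes)), classes$canonical)
  motif_distribution(p, unit_length, "uniform")
}

#' Goodness-of-fit of observed SSR motifs to a null distribution
#'
#' Tests per-class SSR locus counts against a [composition_distribution()]
#' or [uniform_distribution()]. Degrees of freedom are the number of
#' rotation classes minus one (5 for dinucleotides, 19 for trinucleotides).
#' Refuses to run below `min_loci` observations, mirroring the exclusion of
#' motif lengths too rare for adequate statistical power.
#'
#' @param loci SSR `data.frame`, all with `unit_length == null$unit_length`.
#' @param null A `motif_distribution`.
#' @param min_loci Minimum number of loci required (default 20).
#' @return An `ssr_chisq`.
#' @export
motif_gof <- function(loci, null, min_loci = 20L) {
  stopifnot(inherits(null, "motif_distribution"))
  loci <- loci[loci$unit_length == null$unit_length, , drop = FALSE]
  if (nrow(loci) < min_loci)
    stop("only ", nrow(loci), " loci of unit length ", null$unit_length,
         "; below min_loci = ", min_loci,
         " (too infrequent for adequate statistical power)")
  observed <- table(factor(loci$motif_class, levels = names(null$class_probs)))
  observed <- as.integer(observed)
  chisq_gof(observed, expected = null$class_probs * sum(observed),
            df = length(observed) - 1L)
}

#' ORF base-fraction background
#'
#' The null model for ORF inclusion: the fraction of library bases lying
#' inside the union of ORF spans (overlapping ORFs merged per read). With
#' `restrict = TRUE` (the default) only reads containing at least one SSR
#' contribute, matching a null built from "the sequences containing
#' identified SSRs".
#'
#' @param lib An [ssr_library].
#' @param orfs ORF `data.frame` from [scan_orfs()].
#' @param loci SSR `data.frame` (used to select SSR-bearing reads).
#' @param restrict Restrict to reads with at least one SSR.
#' @return List: `fraction_in_orf`, `bases_in_orf`, `bases_total`,
#'   `restricted_to_ssr_reads`.
#' @export
orf_background <- function(lib, orfs, loci, restrict = TRUE) {
  stopifnot(inherits(lib, "ssr_library"))
  reads <- lib$reads
  if (restrict) reads <- reads[reads$read_id %in% loci$read_id, , drop = FALSE]
  orfs <- orfs[orfs$read_id %in% reads$read_id, , drop = FALSE]
  bases_in_orf <- 0L
  if (nrow(orfs)) {
    merged <- IRanges::reduce(S4Vectors::split(
      IRanges::IRanges(start = orfs$start + 1L, end = orfs$end),
      factor(orfs$read_id)))
    bases_in_orf <- sum(sum(IRanges::width(merged)))
  }
  bases_total <- sum(reads$length_bp)
  list(fraction_in_orf = if (bases_total) bases_in_orf / bases_total else 0,
       bases_in_orf = as.integer(bases_in_orf),
       bases_total = as.integer(bases_total),
       restricted_to_ssr_reads = restrict)
}

#' Goodness-of-fit of SSR ORF placement to the base-fraction background
#'
#' Tests the observed (inside, outside) split of SSR loci against the split
#' expected if loci fell uniformly over library bases, i.e. expected inside
#' fraction `f = fraction_in_orf`. Bridging loci must already have been
#' removed.
#'
#' @param placements SSR `data.frame` with an `orf_placement` column
#'   containing only `"inside"`/`"outside"`.
#' @param background Result of [orf_background()].
#' @param correct Yates continuity correction (default off).
#' @return An `ssr_chisq` (df = 1).
#' @export
orf_gof <- function(placements, background, correct = FALSE) {
  pl <- placements$orf_placement
  if (any(pl == "bridging"))
    stop("bridging placements must be removed before the GOF test")
  n <- length(pl)
  if (n == 0L) stop("no placements to test")
  f <- background$fraction_in_orf
  observed <- c(inside = sum(pl == "inside"), outside = sum(pl == "outside"))
  chisq_gof(as.integer(observed), expected = c(f * n, (1 - f) * n),
            df = 1L, correct = correct)
}
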