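DNA_BASES4 <- c("A", "C", "G", "T")

check_alphabet <- function(unit) {
  if (length(unit) != 1L || !is.character(unit) || is.na(unit) || nchar(unit) == 0L)
    stop("repeat unit must be a single nonempty character string")
  chars <- strsplit(unit, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), DNA_BASES4)
  if (length(bad))
    stop("repeat unit contains characters outside A/C/G/T: ",
         paste(bad, collapse = ", "))
  chars
}

#' Test whether a repeat unit is primitive
#'
#' A unit is primitive when it is not a whole-number repetition of any
#' shorter string, e.g. `"ACG"` is primitive but `"ACAC"` (period 2) and
#' `"AA"` (period 1) are not. Primitivity is what keeps an `(AT)n` run from
#' being double-reported as a tetranucleotide `(ATAT)n` repeat.
#'
#' @param unit Single uppercase A/C/G/T string.
#' @return `TRUE` iff no proper divisor of `nchar(unit)` is a period of it.
#' @examples
#' is_primitive("ACG")   # TRUE
#' is_primitive("ACAC")  # FALSE
#' @export
is_primitive <- function(unit) {
  chars <- check_alphabet(unit)
  n <- length(chars)
  if (n == 1L) return(TRUE)
  for (p in seq_len(n %/% 2)) {
    if (n %% p == 0L && all(chars == chars[((seq_len(n) - 1L) %% p) + 1L]))
      return(FALSE)
  }
  TRUE
}

rotations <- function(unit) {
  chars <- check_alphabet(unit)
  n <- length(chars)
  vapply(seq_len(n) - 1L, function(k) {
    paste(chars[((seq_len(n) - 1L + k) %% n) + 1L], collapse = "")
  }, character(1))
}

#' Canonical motif of a repeat unit
#'
#' SSR repeat units that are cyclic rotations of each other (`"AG"`, `"GA"`)
#' describe the same repeat run read in a different phase, so motif identity
#' is the rotation-equivalence class. The class representative is the
#' lexicographically smallest rotation, the usual SSR-miner convention.
#' Reverse complements are *not* merged: the survey is strand-specific.
#'
#' @param unit Primitive uppercase A/C/G/T string of length 2-6.
#' @return The canonical (lexicographically minimal) rotation.
#' @examples
#' canonical_motif("GA")   # "AG"
#' canonical_motif("TAT")  # "ATT"
#' @export
canonical_motif <- function(unit) {
  chars <- check_alphabet(unit)
  if (length(chars) < 2L || length(chars) > 6L)
    stop("repeat unit must have length 2-6, got ", length(chars))
  if (!is_primitive(unit))
    stop("repeat unit '", unit, "' is not primitive")
  min(rotations(unit))
}

#' GC fraction of a motif
#'
#' @param motif Uppercase A/C/G/T string.
#' @return Fraction of G or C bases, in `[0, 1]`.
#' @export
gc_fraction <- function(motif) {
  chars <- check_alphabet(motif)
  sum(chars %in% c("G", "C")) / length(chars)
}

#' Enumerate all motif classes of a given unit length
#'
#' Partitions all primitive units of length `unit_length` into
#' cyclic-rotation orbits. For dinucleotides this yields the 6 classes
#' AC, AG, AT, CG, CT, GT; for trinucleotides, 20 classes. These counts fix
#' the degrees of freedom (classes - 1) of motif goodness-of-fit tests.
#'
#' @param unit_length Integer in 2..6.
#' @return `data.frame` sorted by canonical string, with columns
#'   `canonical`, `unit_length`, `n_members`, `gc_fraction`, and a
#'   list-column `members` holding each class's rotations.
#' @examples
#' nrow(motif_classes(2))  # 6
#' nrow(motif_classes(3))  # 20
#' @export
motif_classes <- function(unit_length) {
  unit_length <- as.integer(unit_length)
  if (length(unit_length) != 1L || is.na(unit_length) ||
      unit_length < 2L || unit_length > 6L)
    stop("unit_length must be a single integer in 2..6")
  kmers <- apply(
    do.call(expand.grid, rep(list(DNA_BASES4), unit_length)),
    1L, paste, collapse = "")
  kmers <- kmers[vapply(kmers, is_primitive, logical(1))]
  canon <- vapply(kmers, canonical_motif, character(1))
  members <- split(unname(kmers), canon)
  canonical <- sort(names(members))
  members <- members[canonical]
  df <- data.frame(
    canonical = canonical,
    unit_length = unit_length,
    n_members = lengths(members),
    gc_fraction = vapply(canonical, gc_fraction, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  df$members <- unname(members)
  df
}
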