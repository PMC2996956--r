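# Independent brute-force oracles and fixture builders. These deliberately
# use naive char-by-char logic, not the package's run-length machinery.

random_dna <- function(len, probs = c(0.25, 0.25, 0.25, 0.25),
                       alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE, prob = probs), collapse = "")
}

oracle_is_primitive <- function(unit) {
  n <- nchar(unit)
  for (p in seq_len(n - 1)) {
    if (n %% p != 0) next
    if (strrep(substr(unit, 1, p), n / p) == unit) return(FALSE)
  }
  TRUE
}

# Every (left-maximal start, primitive unit of length 2-6), extended
# char by char to the right; N never matches anything.
oracle_find_ssrs <- function(sequence, min_units = 5, unit_lengths = 2:6,
                             partial = TRUE) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  ok <- function(i) chars[i] %in% c("A", "C", "G", "T")
  rows <- list()
  for (k in unit_lengths) {
    for (s in seq_len(max(0, n - k + 1))) {
      if (!all(vapply(s:(s + k - 1), ok, logical(1)))) next
      unit <- paste(chars[s:(s + k - 1)], collapse = "")
      if (!oracle_is_primitive(unit)) next
      # left-maximality: extension by one base must fail
      if (s > 1 && ok(s - 1) && chars[s - 1] == chars[s - 1 + k]) next
      j <- s + k
      while (j <= n && ok(j) && chars[j] == chars[j - k]) j <- j + 1
      span <- j - s
      rc <- span %/% k
      if (rc < min_units) next
      end0 <- if (partial) s - 1 + span else s - 1 + rc * k
      rows[[length(rows) + 1]] <- data.frame(
        start = s - 1, end = end0, unit_length = k, observed_unit = unit,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(),
                      unit_length = integer(), observed_unit = character()))
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$start, out$unit_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_revcomp <- function(sequence) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", sequence), "")[[1]]),
        collapse = "")
}

# ATG-to-first-stop scan over all (strand, frame, ATG) triples.
oracle_find_orfs <- function(sequence, min_orf_nt = 300,
                             strands = c("+", "-")) {
  n <- nchar(sequence)
  scan_one <- function(s) {
    rows <- list()
    for (i in seq_len(max(0, n - 2))) {
      if (substr(s, i, i + 2) != "ATG") next
      j <- i + 3
      while (j + 2 <= n) {
        cod <- substr(s, j, j + 2)
        if (cod %in% c("TAA", "TAG", "TGA")) break
        j <- j + 3
      }
      if (j + 2 > n) next
      len <- j + 2 - i + 1
      if (len < min_orf_nt) next
      rows[[length(rows) + 1]] <- c(start = i - 1, end = j + 2,
                                    frame = (i - 1) %% 3, length_nt = len)
    }
    rows
  }
  out <- list()
  if ("+" %in% strands) for (o in scan_one(sequence))
    out[[length(out) + 1]] <- data.frame(start = o[["start"]],
      end = o[["end"]], strand = "+", frame = o[["frame"]],
      length_nt = o[["length_nt"]], stringsAsFactors = FALSE)
  if ("-" %in% strands) for (o in scan_one(oracle_revcomp(sequence)))
    out[[length(out) + 1]] <- data.frame(start = n - o[["end"]],
      end = n - o[["start"]], strand = "-", frame = o[["frame"]],
      length_nt = o[["length_nt"]], stringsAsFactors = FALSE)
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      length_nt = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Naive per-position overlapping k-mer counter pooled by rotation class.
oracle_class_counts <- function(sequences, k) {
  classes <- motif_classes(k)
  counts <- setNames(numeric(nrow(classes)), classes$canonical)
  for (s in sequences) {
    chars <- strsplit(s, "")[[1]]
    for (i in seq_len(max(0, length(chars) - k + 1))) {
      kmer <- paste(chars[i:(i + k - 1)], collapse = "")
      if (grepl("[^ACGT]", kmer)) next
      if (!oracle_is_primitive(kmer)) next
      hit <- which(vapply(classes$members, function(m) kmer %in% m,
                          logical(1)))
      counts[hit] <- counts[hit] + 1
    }
  }
  counts
}

# Loci data.frame with given per-class counts, for GOF tests.
make_class_loci <- function(counts, unit_length) {
  data.frame(read_id = "r", start = 0L, end = 0L,
             unit_length = unit_length,
             observed_unit = rep(names(counts), counts),
             motif_class = rep(names(counts), counts),
             repeat_count = 5L, span_bp = 0L, is_terminal = FALSE,
             library_label = "X", stringsAsFactors = FALSE)
}

ssr_key <- function(d) paste(d$read_id, d$start, d$end, d$unit_length,
                             d$observed_unit)
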