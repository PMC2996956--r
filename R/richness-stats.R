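#' Construct a genotype screening table
#'
#' Holds a loci-by-individuals matrix of categorical allele labels (gel
#' band identities, not sizes) together with per-locus metadata: library of
#' origin, canonical motif, unit length, and the repeat number of the
#' reference library sequence. Missing calls are `NA`.
#'
#' @param loci `data.frame` with columns `locus_id`, `library_label`,
#'   `motif_class`, `unit_length`, `reference_repeat_count`.
#' @param individuals Character vector of individual IDs.
#' @param calls Character matrix, `nrow(loci)` x `length(individuals)`.
#' @return Object of class `genotype_table`.
#' @export
genotype_table <- function(loci, individuals, calls) {
  needed <- c("locus_id", "library_label", "motif_class", "unit_length",
              "reference_repeat_count")
  if (!all(needed %in% names(loci)))
    stop("loci must have columns: ", paste(needed, collapse = ", "))
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(loci) || ncol(calls) != length(individuals))
    stop("calls must be |loci| x |individuals|")
  if (anyDuplicated(loci$locus_id)) stop("duplicate locus_id")
  rownames(calls) <- loci$locus_id
  colnames(calls) <- individuals
  structure(list(loci = loci, individuals = individuals,
                 calls = calls),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d loci x %d individuals (%d missing calls)\n",
              nrow(x$loci), length(x$individuals), sum(is.na(x$calls))))
  invisible(x)
}

#' Read/write the genotype TSV dialect
#'
#' One row per locus: `locus_id`, `library_label`, `motif_class`,
#' `unit_length`, `reference_repeat_count`, then one column per individual
#' holding an allele label or `NA`.
#'
#' @param path TSV path.
#' @return A [genotype_table] (read) or `path` invisibly (write).
#' @export
read_genotype_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  meta_cols <- c("locus_id", "library_label", "motif_class", "unit_length",
                 "reference_repeat_count")
  if (!all(meta_cols %in% names(df)))
    stop("genotype TSV must start with columns: ",
         paste(meta_cols, collapse = ", "))
  loci <- df[meta_cols]
  loci$unit_length <- as.integer(loci$unit_length)
  loci$reference_repeat_count <- as.integer(loci$reference_repeat_count)
  ind <- setdiff(names(df), meta_cols)
  calls <- as.matrix(df[ind])
  calls[calls == "NA" | calls == ""] <- NA_character_
  genotype_table(loci, ind, calls)
}

#' @rdname read_genotype_table
#' @param table A [genotype_table].
#' @export
write_genotype_table <- function(table, path) {
  stopifnot(inherits(table, "genotype_table"))
  df <- cbind(table$loci[c("locus_id", "library_label", "motif_class",
                           "unit_length", "reference_repeat_count")],
              as.data.frame(table$calls, stringsAsFactors = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply marker screening filters
#'
#' Drops loci whose screen status is anything but `ok`: loci that failed to
#' amplify entirely, amplified in only one species, or showed a null allele
#' (at least one individual with missing amplification). Retained loci must
#' have complete calls, so downstream richness estimates rest on an equal
#' number of individuals per locus.
#'
#' @param table A [genotype_table].
#' @param screen_log `data.frame` with columns `locus_id` and `status`
#'   (one of `ok`, `failed_all`, `single_species`, `null_allele`), one row
#'   per locus of `table`.
#' @return List: `table` (filtered [genotype_table]) and `report`, a
#'   `data.frame` of per-status counts (`n_screened` through `n_retained`).
#' @export
apply_screening_filters <- function(table, screen_log) {
  stopifnot(inherits(table, "genotype_table"))
  statuses <- c("ok", "failed_all", "single_species", "null_allele")
  if (!all(c("locus_id", "status") %in% names(screen_log)))
    stop("screen_log must have columns locus_id and status")
  if (!all(screen_log$status %in% statuses))
    stop("unknown status values: ",
         paste(setdiff(screen_log$status, statuses), collapse = ", "))
  status <- screen_log$status[match(table$loci$locus_id, screen_log$locus_id)]
  if (anyNA(status))
    stop("screen_log is missing loci: ",
         paste(utils::head(table$loci$locus_id[is.na(status)], 3),
               collapse = ", "))
  keep <- status == "ok"
  if (any(is.na(table$calls[keep, , drop = FALSE])))
    stop("loci marked ok contain missing calls; screen log is inconsistent")
  out <- genotype_table(table$loci[keep, , drop = FALSE], table$individuals,
                        table$calls[keep, , drop = FALSE])
  counts <- table(factor(status, levels = statuses))
  report <- data.frame(
    n_screened = length(status),
    n_failed_all = as.integer(counts["failed_all"]),
    n_single_species = as.integer(counts["single_species"]),
    n_null_allele = as.integer(counts["null_allele"]),
    n_retained = as.integer(counts["ok"]))
  list(table = out, report = report)
}

#' Per-locus allelic richness
#'
#' Richness is the simple count of distinct allele labels observed at a
#' locus across all individuals jointly. A diploid individual's two bands
#' are recorded slash-joined in one cell (`"r+0/r+1"`); cells are split on
#' `/` before counting, and duplicate bands within an individual collapse
#' to one label.
#'
#' @param table A filtered [genotype_table] (no missing calls).
#' @return `data.frame`: `locus_id`, `richness`, `reference_repeat_count`,
#'   `motif_class`, `unit_length`, `library_label`, and `gc_bin` (percent,
#'   trinucleotide loci only, otherwise `NA`).
#' @export
allelic_richness <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  rich <- apply(table$calls, 1L, function(row) {
    length(unique(unlist(strsplit(row[!is.na(row)], "/", fixed = TRUE))))
  })
  out <- data.frame(
    locus_id = table$loci$locus_id,
    richness = as.integer(rich),
    reference_repeat_count = table$loci$reference_repeat_count,
    motif_class = table$loci$motif_class,
    unit_length = table$loci$unit_length,
    library_label = table$loci$library_label,
    stringsAsFactors = FALSE)
  out$gc_bin <- NA_real_
  tri <- out$unit_length == 3L
  if (any(tri))
    out$gc_bin[tri] <- vapply(out$motif_class[tri], gc_bin, numeric(1))
  if ("orf_placement" %in% names(table$loci))
    out$orf_placement <- table$loci$orf_placement
  out
}

#' GC-content bin of a trinucleotide motif
#'
#' Pools trinucleotide motifs by GC content into the four possible
#' categories: 0, 33, 67 or 100 percent.
#'
#' @param motif_class Canonical trinucleotide motif.
#' @return One of 0, 33, 67, 100.
#' @export
gc_bin <- function(motif_class) {
  chars <- check_alphabet(motif_class)
  if (length(chars) != 3L)
    stop("gc_bin is defined for trinucleotide motifs only")
  c(0, 33, 67, 100)[sum(chars %in% c("G", "C")) + 1L]
}

#' Spearman rank correlation of repeat number and richness
#'
#' Tie-corrected Spearman correlation (Pearson on mid-ranks). The two-sided
#' p-value uses the t approximation; for very small samples (n <= 8,
#' no ties needed) an exact permutation enumeration is available.
#'
#' @param x,y Numeric vectors, typically reference repeat counts and
#'   per-locus richness; `length(x) == length(y) >= 3`.
#' @param method `"t"` (default) or `"permutation"` (n <= 8).
#' @return List of class `ssr_correlation`: `rho`, `p.value`, `n`. `rho`
#'   is `NA` with a note when either vector has zero variance.
#' @export
spearman_rho <- function(x, y, method = c("t", "permutation")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(structure(list(rho = NA_real_, p.value = NA_real_, n = length(x),
                          note = "zero variance; correlation undefined"),
                     class = "ssr_correlation"))
  if (method == "permutation") {
    if (length(x) > 8L) stop("exact permutation is limited to n <= 8")
    rho_obs <- stats::cor(rank(x), rank(y))
    perms <- permutations_of(length(y))
    ry <- rank(y); rx <- rank(x)
    rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
    return(structure(list(rho = rho_obs, p.value = p, n = length(x),
                          note = "exact permutation"),
                     class = "ssr_correlation"))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  structure(list(rho = unname(ct$estimate), p.value = ct$p.value,
                 n = length(x), note = "t approximation"),
            class = "ssr_correlation")
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' @export
print.ssr_correlation <- function(x, ...) {
  cat(sprintf("Spearman correlation: rho = %.3f, p = %.4g, n = %d (%s)\n",
              x$rho, x$p.value, x$n, x$note))
  invisible(x)
}

#' Heterogeneity of allelic richness across groups
#'
#' Tie-corrected Kruskal-Wallis test of richness across a grouping of loci
#' (motif class, GC bin, ORF placement, or unit length). Empty groups are
#' dropped with a warning; fewer than two nonempty groups is an error.
#'
#' @param richness `data.frame` from [allelic_richness()].
#' @param group_by Column of `richness` to group on, or a vector of group
#'   labels of matching length.
#' @return List of class `ssr_ranktest` with `statistic` (H), `df`,
#'   `p.value`, `n_per_group`.
#' @export
richness_heterogeneity <- function(richness, group_by) {
  if (is.character(group_by) && length(group_by) == 1L) {
    if (!group_by %in% names(richness))
      stop("no column '", group_by, "' in richness table")
    groups <- richness[[group_by]]
  } else {
    groups <- group_by
  }
  if (length(groups) != nrow(richness))
    stop("grouping length must match the richness table")
  groups <- factor(groups)
  sizes <- table(groups)
  if (any(sizes == 0)) {
    warning("dropping empty group(s): ",
            paste(names(sizes)[sizes == 0], collapse = ", "))
    groups <- droplevels(groups)
    sizes <- table(groups)
  }
  if (nlevels(groups) < 2L)
    stop("need at least 2 nonempty groups")
  if (length(unique(richness$richness)) == 1L) {
    # every observation tied: no heterogeneity by definition
    return(structure(list(statistic = 0, df = nlevels(groups) - 1L,
                          p.value = 1, n_per_group = as.integer(sizes),
                          tie_correction_applied = TRUE,
                          method = "Kruskal-Wallis"),
                     class = "ssr_ranktest"))
  }
  kt <- kruskal.test(richness$richness, groups)
  structure(list(statistic = unname(kt$statistic),
                 df = unname(kt$parameter), p.value = kt$p.value,
                 n_per_group = as.integer(sizes),
                 tie_correction_applied = TRUE,
                 method = "Kruskal-Wallis"),
            class = "ssr_ranktest")
}

#' Cross-tabulate richness by repeat-number bins
#'
#' Pools loci by reference repeat number into the supplied bins and
#' cross-tabulates bin against richness, the layout used to display how
#' allelic richness concentrates in high repeat-number loci.
#'
#' @param richness `data.frame` from [allelic_richness()].
#' @param bins List of inclusive integer intervals `c(lo, hi)`, disjoint
#'   and jointly covering the observed repeat-number range; see
#'   [default_repeat_bins()].
#' @return A `table`, bins x richness values.
#' @export
pool_by_repeat_bins <- function(richness, bins) {
  lo <- vapply(bins, `[`, numeric(1), 1L)
  hi <- vapply(bins, `[`, numeric(1), 2L)
  if (any(lo > hi)) stop("each bin must satisfy lo <= hi")
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  if (any(lo[-1L] <= hi[-length(hi)])) stop("bins must be disjoint")
  labels <- ifelse(is.finite(hi),
                   ifelse(lo == hi, as.character(lo), paste0(lo, "-", hi)),
                   paste0(lo, "+"))
  x <- richness$reference_repeat_count
  bin_idx <- vapply(x, function(v) {
    w <- which(v >= lo & v <= hi)
    if (!length(w)) NA_integer_ else w[1L]
  }, integer(1))
  if (anyNA(bin_idx))
    stop("repeat count(s) outside all bins: ",
         paste(unique(x[is.na(bin_idx)]), collapse = ", "))
  table(bin = factor(labels[bin_idx], levels = labels),
        richness = factor(richness$richness,
                          levels = sort(unique(richness$richness))))
}

#' Default repeat-number bins per library type
#'
#' The genomic (BAC) set pools 5, 6, 7-8, 9-20 and 21-42 repeats; the
#' transcribed (EST) set pools 5, 6, 7, 8 and 9-or-more.
#'
#' @param library `"BAC"` or `"EST"`.
#' @return List of `c(lo, hi)` intervals.
#' @export
default_repeat_bins <- function(library = c("BAC", "EST")) {
  switch(match.arg(library),
         BAC = list(c(5, 5), c(6, 6), c(7, 8), c(9, 20), c(21, 42)),
         EST = list(c(5, 5), c(6, 6), c(7, 7), c(8, 8), c(9, Inf)))
}
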