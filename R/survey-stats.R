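#' Chi-square goodness-of-fit test
#'
#' Pearson chi-square against given expected counts. Exposed because every
#' distributional test in the survey (motif composition, ORF inclusion,
#' cross-library abundance) reduces to it. If any cell has expected count 0
#' with observed > 0 the statistic is reported as `Inf` with a note; cells
#' with expected < 5 trigger a recorded warning, not a failure.
#'
#' @param observed Integer vector of observed counts.
#' @param expected Vector of expected counts (same length and total as
#'   `observed`; rescaled to the observed total if given as probabilities).
#' @param df Degrees of freedom; default `length(observed) - 1`.
#' @param correct Apply the Yates continuity correction (df = 1 designs
#'   only; default off).
#' @return Object of class `ssr_chisq`: list with `statistic`, `df`,
#'   `p.value`, `observed`, `expected`, `low_expected_warning`, `note`.
#' @export
chisq_gof <- function(observed, expected, df = length(observed) - 1L,
                      correct = FALSE) {
  if (length(observed) != length(expected))
    stop("observed and expected must have equal length")
  if (any(observed < 0) || any(expected < 0))
    stop("counts must be nonnegative")
  n <- sum(observed)
  if (n == 0) stop("no observations")
  expected <- expected * n / sum(expected)
  note <- NULL
  zero_bad <- expected == 0 & observed > 0
  if (any(zero_bad)) {
    stat <- Inf
    note <- paste0("expected count 0 with observed > 0 in cell(s) ",
                   paste(which(zero_bad), collapse = ","),
                   "; statistic is infinite")
    p <- 0
  } else {
    keep <- expected > 0
    dev <- abs(observed[keep] - expected[keep])
    if (correct) dev <- pmax(dev - 0.5, 0)
    stat <- sum(dev^2 / expected[keep])
    p <- pchisq(stat, df = df, lower.tail = FALSE)
  }
  structure(list(statistic = stat, df = as.integer(df), p.value = p,
                 observed = observed, expected = expected,
                 low_expected_warning = any(expected < 5),
                 note = note),
            class = "ssr_chisq")
}

#' @export
print.ssr_chisq <- function(x, ...) {
  cat(sprintf("Chi-square GOF: X^2 = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  if (x$low_expected_warning) cat("  (some expected counts < 5)\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Per-library SSR density summary
#'
#' Density and repeat-structure summaries for one library: reads per SSR,
#' kb per SSR, percent of sequenced bases inside SSR spans, mean repeat
#' count, and primer-design accounting (terminal loci, externally supplied
#' unprimeable loci). With zero loci the density fields are `NA` rather
#' than a division error.
#'
#' @param lib An [ssr_library].
#' @param loci SSR `data.frame` from that library.
#' @param n_unprimeable Loci that failed primer design for reasons other
#'   than terminality (supplied externally; default 0).
#' @return One-row `data.frame`.
#' @export
summarize_library <- function(lib, loci, n_unprimeable = 0L) {
  stopifnot(inherits(lib, "ssr_library"))
  if (nrow(loci) && !all(loci$read_id %in% lib$reads$read_id))
    stop("loci reference reads absent from the library")
  n_ssr <- nrow(loci)
  n_terminal <- if (n_ssr) sum(loci$is_terminal %in% TRUE) else 0L
  data.frame(
    library_label = lib$label,
    n_reads = lib$n_reads,
    total_bases = lib$total_bases,
    n_ssr = n_ssr,
    reads_per_ssr = if (n_ssr) lib$n_reads / n_ssr else NA_real_,
    kb_per_ssr = if (n_ssr) lib$total_bases / 1000 / n_ssr else NA_real_,
    pct_ssr_bases = if (n_ssr) 100 * sum(loci$span_bp) / lib$total_bases
                    else NA_real_,
    mean_repeat_count = if (n_ssr) mean(loci$repeat_count) else NA_real_,
    n_terminal = n_terminal,
    n_designable = n_ssr - n_terminal - n_unprimeable,
    stringsAsFactors = FALSE)
}

#' Compare SSR abundance between two libraries
#'
#' Chi-square test of the split of SSR counts between two libraries against
#' the split expected from their sequencing effort ("exposure"), measured
#' either in reads or in bases. Equal densities give expected counts
#' proportional to exposure and a statistic of 0.
#'
#' @param a,b One-row summaries from [summarize_library()].
#' @param exposure `"reads"` or `"bases"`.
#' @param correct Yates continuity correction (default off).
#' @return An `ssr_chisq` (df = 1).
#' @export
compare_abundance <- function(a, b, exposure = c("reads", "bases"),
                              correct = FALSE) {
  exposure <- match.arg(exposure)
  expo <- switch(exposure,
                 reads = c(a$n_reads, b$n_reads),
                 bases = c(a$total_bases, b$total_bases))
  if (any(expo <= 0)) stop("both libraries need nonzero exposure")
  obs <- c(a$n_ssr, b$n_ssr)
  chisq_gof(obs, expected = expo / sum(expo) * sum(obs), df = 1L,
            correct = correct)
}

#' Compare repeat counts between two libraries
#'
#' Two-sided Mann-Whitney U test on per-locus repeat counts. Uses exact
#' enumeration when `n1 * n2 <= 400` and there are no ties, otherwise the
#' tie-corrected normal approximation.
#'
#' @param x_a,x_b Numeric vectors of repeat counts (or SSR `data.frame`s,
#'   from which `repeat_count` is taken).
#' @return List of class `ssr_ranktest`: `statistic` (U for the first
#'   sample), `p.value`, `n_per_group`, `tie_correction_applied`, `method`.
#' @export
compare_repeat_counts <- function(x_a, x_b) {
  if (is.data.frame(x_a)) x_a <- x_a$repeat_count
  if (is.data.frame(x_b)) x_b <- x_b$repeat_count
  if (!length(x_a) || !length(x_b))
    stop("both groups must be nonempty")
  ties <- anyDuplicated(c(x_a, x_b)) > 0L
  exact <- (length(x_a) * length(x_b) <= 400) && !ties
  wt <- suppressWarnings(
    wilcox.test(x_a, x_b, alternative = "two.sided", exact = exact,
                correct = !exact))
  structure(list(statistic = unname(wt$statistic),  # W == U for sample a
                 p.value = wt$p.value,
                 n_per_group = c(length(x_a), length(x_b)),
                 tie_correction_applied = !exact && ties,
                 method = if (exact) "exact" else "normal approximation"),
            class = "ssr_ranktest")
}

#' @export
print.ssr_ranktest <- function(x, ...) {
  lab <- if (!is.null(x$df)) sprintf("H = %.4g, df = %d", x$statistic, x$df)
         else sprintf("U = %.4g", x$statistic)
  cat(sprintf("Rank test (%s): %s, p = %.4g, n = %s\n", x$method, lab,
              x$p.value, paste(x$n_per_group, collapse = "/")))
  invisible(x)
}
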