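#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate a
#' small AT-rich insect read library: ~700 bp reads, 35% GC background,
#' roughly one SSR per twelve reads (the density scale of a genomic BAC-end
#' set), an AT-biased motif spectrum dominated by di- and trinucleotide
#' units, geometric unit-count tails, and a genotype model in which the
#' allele-pool size grows log-linearly with reference repeat number.
#'
#' @param seed Integer seed; fully determines all generator output.
#' @param n_reads Number of reads.
#' @param read_length_mean,read_length_sd Read length distribution (bp).
#' @param base_probs Named A/C/G/T probability vector for background bases.
#' @param ssr_per_read_rate Poisson mean of planted SSRs per read.
#' @param unit_length_probs Named probabilities over planted unit lengths.
#' @param motif_gc_bias Motif-class weight is proportional to
#'   `exp(-motif_gc_bias * gc_fraction)`; 0 gives uniform class weights.
#' @param min_units Minimum planted complete unit count.
#' @param unit_count_geom_p Planted unit count is
#'   `min_units + rgeom(unit_count_geom_p)`.
#' @param orf_density Planted ORFs per kb of read (forward strand).
#' @param orf_codons_min,orf_codons_geom_p Planted ORF length in codons is
#'   `orf_codons_min + rgeom(orf_codons_geom_p)` (plus the stop codon).
#' @param richness_intercept,richness_slope Genotype model: allele-pool
#'   size is `1 + Poisson(exp(intercept + slope * n))` for reference repeat
#'   number `n`, truncated at twice the number of individuals.
#' @param allele_step_weight Geometric decay of allele sampling weight per
#'   repeat-unit step away from the reference length.
#' @param rate_failed_all,rate_single_species,rate_null_allele Injection
#'   rates of screening-failure classes (defaults match a screen in which
#'   288 loci yield 35 total failures, 2 single-species amplifications and
#'   9 null-allele loci).
#' @param library_label Label for the generated library.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_reads = 500L,
                              read_length_mean = 703,
                              read_length_sd = 80,
                              base_probs = c(A = 0.325, C = 0.175,
                                             G = 0.175, T = 0.325),
                              ssr_per_read_rate = 0.08,
                              unit_length_probs = c(`2` = 0.70, `3` = 0.27,
                                                    `4` = 0.03),
                              motif_gc_bias = 2,
                              min_units = 5L,
                              unit_count_geom_p = 0.25,
                              orf_density = 0.15,
                              orf_codons_min = 100L,
                              orf_codons_geom_p = 0.03,
                              richness_intercept = -0.5,
                              richness_slope = 0.15,
                              allele_step_weight = 0.5,
                              rate_failed_all = 35 / 288,
                              rate_single_species = 2 / 288,
                              rate_null_allele = 9 / 288,
                              library_label = "SIM") {
  base_probs <- base_probs[DNA_BASES4]
  if (anyNA(base_probs) || any(base_probs < 0))
    stop("base_probs must be a named nonnegative A/C/G/T vector")
  base_probs <- base_probs / sum(base_probs)
  unit_length_probs <- unit_length_probs / sum(unit_length_probs)
  if (!all(names(unit_length_probs) %in% as.character(2:6)))
    stop("unit_length_probs names must be unit lengths in 2..6")
  rates <- c(rate_failed_all, rate_single_species, rate_null_allele)
  if (any(rates < 0) || sum(rates) >= 1)
    stop("failure-injection rates must be nonnegative and sum to < 1")
  cfg <- list(seed = as.integer(seed), n_reads = as.integer(n_reads),
              read_length_mean = read_length_mean,
              read_length_sd = read_length_sd,
              base_probs = base_probs,
              ssr_per_read_rate = ssr_per_read_rate,
              unit_length_probs = unit_length_probs,
              motif_gc_bias = motif_gc_bias,
              min_units = as.integer(min_units),
              unit_count_geom_p = unit_count_geom_p,
              orf_density = orf_density,
              orf_codons_min = as.integer(orf_codons_min),
              orf_codons_geom_p = orf_codons_geom_p,
              richness_intercept = richness_intercept,
              richness_slope = richness_slope,
              allele_step_weight = allele_step_weight,
              rate_failed_all = rate_failed_all,
              rate_single_species = rate_single_species,
              rate_null_allele = rate_null_allele,
              library_label = library_label)
  # feasibility: expected planted SSR bases must stay below half a read
  mean_units <- min_units + (1 - unit_count_geom_p) / unit_count_geom_p
  mean_k <- sum(as.integer(names(unit_length_probs)) * unit_length_probs)
  if (ssr_per_read_rate * mean_units * mean_k > 0.5 * read_length_mean)
    stop("infeasible packing: expected planted SSR bases exceed half a read")
  structure(cfg, class = "sim_config")
}

sample_motif <- function(cfg, classes_by_k) {
  k <- as.integer(sample(names(cfg$unit_length_probs), 1L,
                         prob = cfg$unit_length_probs))
  classes <- classes_by_k[[as.character(k)]]
  w <- exp(-cfg$motif_gc_bias * classes$gc_fraction) * classes$n_members
  i <- sample.int(nrow(classes), 1L, prob = w)
  members <- classes$members[[i]]
  list(unit_length = k, canonical = classes$canonical[i],
       observed_unit = sample(members, 1L))
}

random_codons <- function(n, base_probs) {
  out <- character(n)
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_len(n)) {
    repeat {
      cod <- paste(sample(DNA_BASES4, 3L, replace = TRUE, prob = base_probs),
                   collapse = "")
      if (!cod %in% stops) break
    }
    out[i] <- cod
  }
  out
}

place_interval <- function(len, width, used, margin = 10L, tries = 200L) {
  lo <- margin
  hi <- len - margin - width            # 0-based start range [lo, hi]
  if (hi < lo) return(NULL)
  for (t in seq_len(tries)) {
    s <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    e <- s + width
    ok <- !any(used$start < e + margin & s - margin < used$end)
    if (ok) return(c(start = s, end = e))
  }
  NULL
}

#' Generate a synthetic read library with planted SSRs and ORFs
#'
#' Background bases are i.i.d. from `base_probs`. ORFs (ATG + stop-free
#' codons + stop, forward strand) and perfect SSR runs are planted at
#' uniform positions, rejecting overlaps between features (10 bp buffer)
#' and read ends. The single base on each side of a planted SSR is forced
#' to differ from the base that would extend the repeat, so planted
#' coordinates are exactly the maximal-run coordinates and coordinate-exact
#' recovery by [find_ssrs()] is a fair test.
#'
#' @param config A [simulation_config()].
#' @return List: `library` (an [ssr_library]) and `truth`, itself a list of
#'   `ssrs` (read_id, start, end, unit_length, observed_unit, motif_class,
#'   unit_count) and `orfs` (read_id, start, end, strand, frame, length_nt).
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  classes_by_k <- lapply(
    setNames(nm = names(config$unit_length_probs)),
    function(k) motif_classes(as.integer(k)))
  ids <- sprintf("%s_read%05d", config$library_label,
                 seq_len(config$n_reads))
  seqs <- character(config$n_reads)
  truth_ssr <- list(); truth_orf <- list()
  for (i in seq_len(config$n_reads)) {
    len <- max(60L, as.integer(round(rnorm(1, config$read_length_mean,
                                           config$read_length_sd))))
    chars <- sample(DNA_BASES4, len, replace = TRUE,
                    prob = config$base_probs)
    used <- data.frame(start = integer(), end = integer())
    # ORFs first: they are longer and harder to place
    n_orf <- rpois(1L, config$orf_density * len / 1000)
    for (j in seq_len(n_orf)) {
      codons <- config$orf_codons_min + rgeom(1L, config$orf_codons_geom_p)
      width <- 3L * (codons + 1L)       # + stop codon
      pos <- place_interval(len, width, used)
      if (is.null(pos)) next
      orf_seq <- c("ATG", random_codons(codons - 1L, config$base_probs),
                   sample(c("TAA", "TAG", "TGA"), 1L))
      chars[(pos["start"] + 1L):pos["end"]] <-
        strsplit(paste(orf_seq, collapse = ""), "")[[1L]]
      used <- rbind(used, data.frame(start = pos["start"], end = pos["end"]))
      truth_orf[[length(truth_orf) + 1L]] <- data.frame(
        read_id = ids[i], start = unname(pos["start"]),
        end = unname(pos["end"]), strand = "+",
        frame = unname(pos["start"]) %% 3L, length_nt = width,
        stringsAsFactors = FALSE)
    }
    n_ssr <- rpois(1L, config$ssr_per_read_rate)
    for (j in seq_len(n_ssr)) {
      m <- sample_motif(config, classes_by_k)
      units <- config$min_units + rgeom(1L, config$unit_count_geom_p)
      width <- units * m$unit_length
      if (width > 0.5 * len) next
      pos <- place_interval(len, width, used)
      if (is.null(pos)) next
      unit_chars <- strsplit(m$observed_unit, "")[[1L]]
      chars[(pos["start"] + 1L):pos["end"]] <-
        rep(unit_chars, units)
      # block single-base extension on both sides
      left_block <- unit_chars[m$unit_length]
      right_block <- unit_chars[1L]
      p <- config$base_probs
      chars[pos["start"]] <- sample(setdiff(DNA_BASES4, left_block), 1L,
        prob = p[setdiff(DNA_BASES4, left_block)])
      chars[pos["end"] + 1L] <- sample(setdiff(DNA_BASES4, right_block), 1L,
        prob = p[setdiff(DNA_BASES4, right_block)])
      used <- rbind(used, data.frame(start = pos["start"], end = pos["end"]))
      truth_ssr[[length(truth_ssr) + 1L]] <- data.frame(
        read_id = ids[i], start = unname(pos["start"]),
        end = unname(pos["end"]), unit_length = m$unit_length,
        observed_unit = m$observed_unit, motif_class = m$canonical,
        unit_count = units, stringsAsFactors = FALSE)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  truth <- list(
    ssrs = if (length(truth_ssr)) do.call(rbind, truth_ssr) else
      data.frame(read_id = character(), start = integer(), end = integer(),
                 unit_length = integer(), observed_unit = character(),
                 motif_class = character(), unit_count = integer()),
    orfs = if (length(truth_orf)) do.call(rbind, truth_orf) else
      empty_orf_frame())
  list(library = ssr_library(ids, seqs,
                             library_label = config$library_label),
       truth = truth)
}

#' Generate a synthetic genotype screen with known richness structure
#'
#' For each input locus with reference repeat number `n`, the latent
#' allele-pool size is `k = 1 + Poisson(exp(a + b * n))`, truncated at
#' twice the number of individuals. Pool alleles are stepwise length
#' variants of the reference (offsets 0, +1, -1, +2, ...), sampled with
#' geometrically decaying weight per step; each diploid individual draws
#' two labels (recorded slash-joined). Screening-failure classes are
#' injected at the configured rates for filter testing: `failed_all` loci
#' are all-missing, `single_species` loci amplify in the first half of the
#' panel only, `null_allele` loci have one missing individual.
#'
#' @param loci SSR `data.frame` (e.g. truth SSRs or [scan_library()] calls)
#'   whose `repeat_count`/`unit_count` column provides the reference repeat
#'   number.
#' @param config A [simulation_config()].
#' @param n_individuals Panel size (default 8; two species of four).
#' @return List: `table` (a [genotype_table]), `screen_log` (locus status
#'   `data.frame` for [apply_screening_filters()]) and `truth`
#'   (per-locus pool size and injected status).
#' @export
generate_genotypes <- function(loci, config, n_individuals = 8L) {
  stopifnot(inherits(config, "sim_config"))
  if (n_individuals < 2L) stop("need at least 2 individuals")
  set.seed(config$seed)
  n_rep <- if ("repeat_count" %in% names(loci)) loci$repeat_count
           else loci$unit_count
  if (is.null(n_rep)) stop("loci must carry repeat_count or unit_count")
  n_loci <- nrow(loci)
  locus_id <- sprintf("%s_%d", loci$read_id, loci$start)
  inds <- sprintf("ind%02d", seq_len(n_individuals))
  calls <- matrix(NA_character_, n_loci, n_individuals)
  pool_size <- integer(n_loci)
  status <- character(n_loci)
  max_pool <- 2L * n_individuals
  for (i in seq_len(n_loci)) {
    lambda <- exp(config$richness_intercept +
                    config$richness_slope * n_rep[i])
    k <- min(1L + rpois(1L, lambda), max_pool)
    pool_size[i] <- k
    offsets <- c(0L, as.vector(rbind(seq_len(k), -seq_len(k))))[seq_len(k)]
    weights <- config$allele_step_weight^abs(offsets)
    labels <- sprintf("r%+d", offsets)
    for (j in seq_len(n_individuals)) {
      pair <- sample(labels, 2L, replace = TRUE, prob = weights)
      calls[i, j] <- paste(sort(unique(pair)), collapse = "/")
    }
    u <- runif(1)
    status[i] <-
      if (u < config$rate_failed_all) "failed_all"
      else if (u < config$rate_failed_all + config$rate_single_species)
        "single_species"
      else if (u < config$rate_failed_all + config$rate_single_species +
                 config$rate_null_allele) "null_allele"
      else "ok"
    if (status[i] == "failed_all") calls[i, ] <- NA_character_
    if (status[i] == "single_species")
      calls[i, seq_len(n_individuals) > n_individuals / 2] <- NA_character_
    if (status[i] == "null_allele")
      calls[i, sample.int(n_individuals, 1L)] <- NA_character_
  }
  meta <- data.frame(
    locus_id = locus_id,
    library_label = if ("library_label" %in% names(loci))
      loci$library_label else config$library_label,
    motif_class = loci$motif_class,
    unit_length = loci$unit_length,
    reference_repeat_count = n_rep,
    stringsAsFactors = FALSE)
  list(table = genotype_table(meta, inds, calls),
       screen_log = data.frame(locus_id = locus_id, status = status,
                               stringsAsFactors = FALSE),
       truth = data.frame(locus_id = locus_id, pool_size = pool_size,
                          status = status, stringsAsFactors = FALSE))
}
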