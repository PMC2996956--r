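toy_table <- function(statuses, n_ind = 8) {
  n <- length(statuses)
  loci <- data.frame(locus_id = paste0("L", seq_len(n)),
                     library_label = "BAC", motif_class = "AT",
                     unit_length = 2L, reference_repeat_count = 6L)
  calls <- matrix("a1/a2", n, n_ind)
  for (i in seq_len(n)) {
    if (statuses[i] == "failed_all") calls[i, ] <- NA
    if (statuses[i] == "single_species") calls[i, (n_ind / 2 + 1):n_ind] <- NA
    if (statuses[i] == "null_allele") calls[i, 1] <- NA
  }
  list(table = genotype_table(loci, paste0("i", seq_len(n_ind)), calls),
       log = data.frame(locus_id = loci$locus_id, status = statuses))
}

test_that("screening filters retain only fully amplified loci", {
  tt <- toy_table(c("ok", "failed_all", "single_species", "null_allele", "ok"))
  res <- apply_screening_filters(tt$table, tt$log)
  expect_equal(nrow(res$table$loci), 2)
  expect_equal(res$report$n_retained, 2)
  expect_equal(with(res$report, n_failed_all + n_single_species +
                      n_null_allele + n_retained), 5)
  expect_false(anyNA(res$table$calls))

  all_ok <- toy_table(rep("ok", 4))
  res2 <- apply_screening_filters(all_ok$table, all_ok$log)
  expect_equal(nrow(res2$table$loci), 4)

  # a locus marked ok but holding missing calls is a consistency error
  bad <- toy_table(c("ok", "ok"))
  bad$table$calls[2, 3] <- NA
  expect_error(apply_screening_filters(bad$table, bad$log), "inconsistent")
  bad_log <- tt$log; bad_log$status[1] <- "mystery"
  expect_error(apply_screening_filters(tt$table, bad_log), "unknown status")
})

test_that("allelic richness counts distinct labels across the panel", {
  loci <- data.frame(locus_id = c("L1", "L2"), library_label = "BAC",
                     motif_class = c("AT", "ACT"),
                     unit_length = c(2L, 3L), reference_repeat_count = 7L)
  calls <- rbind(c("A", "B", "A", "A", "B", "C", "A", "A"),
                 rep("X", 8))
  gt <- genotype_table(loci, paste0("i", 1:8), calls)
  r <- allelic_richness(gt)
  expect_equal(r$richness, c(3L, 1L))
  expect_equal(r$gc_bin, c(NA, 33))

  # slash-joined diploid cells are split before counting
  calls2 <- rbind(c("a/b", "a/c", "a", "a", "a", "a", "a", "a"), rep("x", 8))
  gt2 <- genotype_table(loci, paste0("i", 1:8), calls2)
  expect_equal(allelic_richness(gt2)$richness, c(3L, 1L))
})

test_that("richness saturates at the latent pool size", {
  set.seed(701)
  cfg <- simulation_config(seed = 701, richness_slope = 0.3,
                           rate_failed_all = 0, rate_single_species = 0,
                           rate_null_allele = 0)
  loci <- data.frame(read_id = paste0("r", 1:120), start = 1,
                     motif_class = "AT", unit_length = 2L,
                     repeat_count = sample(5:20, 120, replace = TRUE))
  g <- generate_genotypes(loci, cfg, n_individuals = 8)
  rich <- allelic_richness(g$table)
  by_id <- match(rich$locus_id, g$truth$locus_id)
  expect_true(all(rich$richness <= g$truth$pool_size[by_id]))
  expect_true(all(rich$richness >= 1 & rich$richness <= 16))
})

test_that("spearman_rho handles monotone data, ties, and degenerate input", {
  r <- spearman_rho(1:10, (1:10)^2)
  expect_equal(r$rho, 1)
  expect_lt(r$p.value, 1e-6)

  # tie-corrected rho equals Pearson on mid-ranks computed by hand
  x <- c(5, 6, 6, 7, 9, 9, 9, 12)
  y <- c(2, 1, 3, 3, 4, 2, 6, 5)
  got <- spearman_rho(x, y)
  rx <- rank(x); ry <- rank(y)
  hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got$rho, hand)

  flat <- spearman_rho(rep(3, 5), 1:5)
  expect_true(is.na(flat$rho))
  expect_match(flat$note, "zero variance")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("exact permutation p-value matches enumeration at tiny n", {
  got <- spearman_rho(1:5, c(10, 20, 30, 40, 50), method = "permutation")
  expect_equal(got$rho, 1)
  expect_equal(got$p.value, 2 / factorial(5))   # only the two monotone perms
  expect_error(spearman_rho(1:9, 9:1, method = "permutation"), "n <= 8")
})

test_that("permuted responses are significant at roughly the nominal rate", {
  set.seed(702)
  x <- rep(5:16, each = 10)
  y <- rpois(120, 3) + 1
  hits <- 0; n_rep <- 400
  for (i in 1:n_rep) {
    if (spearman_rho(x, sample(y))$p.value < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.02)
  expect_lte(hits / n_rep, 0.08)
})

test_that("Kruskal-Wallis heterogeneity matches the tie-corrected formula", {
  rich <- data.frame(richness = c(1, 2, 2, 3, 5, 5, 6, 8),
                     motif_class = rep(c("AT", "AC"), each = 4))
  got <- richness_heterogeneity(rich, "motif_class")

  vals <- rich$richness
  r <- rank(vals); n <- length(vals)
  groups <- split(r, rich$motif_class)
  h <- 12 / (n * (n + 1)) *
    sum(vapply(groups, function(g) sum(g)^2 / length(g), numeric(1))) -
    3 * (n + 1)
  ties <- table(vals)
  h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(got$statistic, h)
  expect_equal(got$df, 1)

  same <- richness_heterogeneity(
    data.frame(richness = rep(4, 9), motif_class = rep(c("a", "b", "c"), 3)),
    "motif_class")
  expect_equal(same$statistic, 0)

  expect_error(richness_heterogeneity(
    data.frame(richness = 1:3, motif_class = "AT"), "motif_class"),
    "at least 2")
})

test_that("two-group Kruskal-Wallis equals the squared MW z statistic", {
  set.seed(703)
  a <- rnorm(15); b <- rnorm(12, 0.8)
  rich <- data.frame(richness = c(a, b),
                     motif_class = rep(c("g1", "g2"), c(15, 12)))
  h <- richness_heterogeneity(rich, "motif_class")$statistic
  u <- compare_repeat_counts(a, b)$statistic
  n1 <- 15; n2 <- 12; n <- n1 + n2
  z <- (u - n1 * n2 / 2) / sqrt(n1 * n2 * (n + 1) / 12)
  expect_equal(h, z^2, tolerance = 1e-10)
})

test_that("repeat-number pooling conserves loci across bins", {
  rich <- data.frame(richness = c(2, 3, 4, 2, 6, 1),
                     reference_repeat_count = c(5, 6, 8, 15, 30, 42))
  tab <- pool_by_repeat_bins(rich, default_repeat_bins("BAC"))
  expect_equal(dim(tab)[1], 5)
  expect_equal(sum(tab), 6)
  expect_equal(unname(rowSums(tab)), c(1, 1, 1, 1, 2))

  expect_error(pool_by_repeat_bins(
    data.frame(richness = 1, reference_repeat_count = 50),
    default_repeat_bins("BAC")), "outside all bins")
  expect_error(pool_by_repeat_bins(rich, list(c(5, 8), c(7, 10))), "disjoint")

  # random data, random valid bins: every locus in exactly one bin
  set.seed(704)
  for (i in 1:10) {
    vals <- sample(5:40, 50, replace = TRUE)
    cuts <- sort(sample(6:39, 3))
    bins <- list(c(5, cuts[1]), c(cuts[1] + 1, cuts[2]),
                 c(cuts[2] + 1, cuts[3]), c(cuts[3] + 1, 40))
    tab <- pool_by_repeat_bins(
      data.frame(richness = rep(1, 50), reference_repeat_count = vals), bins)
    expect_equal(sum(tab), 50)
  }
})

test_that("GC bins land on the four trinucleotide categories", {
  expect_equal(gc_bin("AAT"), 0)
  expect_equal(gc_bin("ACG"), 67)
  expect_equal(gc_bin("CCG"), 100)
  expect_equal(gc_bin("ACT"), 33)
  expect_error(gc_bin("AT"), "trinucleotide")
})

test_that("genotype TSV dialect round-trips", {
  tt <- toy_table(c("ok", "ok", "null_allele"))
  path <- tempfile(fileext = ".tsv")
  write_genotype_table(tt$table, path)
  back <- read_genotype_table(path)
  expect_identical(back$loci, tt$table$loci)
  expect_identical(unname(back$calls), unname(tt$table$calls))
})
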