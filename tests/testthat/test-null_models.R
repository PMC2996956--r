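test_that("uniform null assigns equal mass to every class", {
  u2 <- uniform_distribution(2)
  expect_equal(unname(u2$class_probs), rep(1 / 6, 6))
  u3 <- uniform_distribution(3)
  expect_equal(unname(u3$class_probs), rep(0.05, 20))
  for (L in 2:6)
    expect_equal(sum(uniform_distribution(L)$class_probs), 1)
})

test_that("composition distribution reflects library k-mer content", {
  lib <- ssr_library("r1", "ACACACACAC")
  d <- composition_distribution(lib, 2)
  expect_equal(unname(d$class_probs["AC"]), 1)
  expect_equal(sum(d$class_probs), 1)

  # counts equal a naive per-position loop oracle
  set.seed(601)
  seqs <- replicate(20, random_dna(120, probs = c(.4, .2, .15, .25)))
  seqs[3] <- paste0(substr(seqs[3], 1, 50), "N", substr(seqs[3], 52, 120))
  lib2 <- ssr_library(paste0("r", 1:20), seqs)
  for (k in 2:3) {
    d2 <- composition_distribution(lib2, k)
    want <- oracle_class_counts(seqs, k)
    expect_equal(d2$n_kmers_counted, sum(want))
    expect_equal(d2$class_probs, want / sum(want))
  }
})

test_that("composition distribution ignores read order and boundaries", {
  set.seed(602)
  seqs <- replicate(10, random_dna(150))
  lib_a <- ssr_library(paste0("r", 1:10), seqs)
  lib_b <- ssr_library(paste0("r", 1:10), rev(seqs))
  expect_equal(composition_distribution(lib_a, 2)$class_probs,
               composition_distribution(lib_b, 2)$class_probs)
  expect_error(composition_distribution(ssr_library("r1", "NNNNN"), 2),
               "degenerate background")
})

test_that("masking SSR spans removes them from the background", {
  set.seed(605)
  at_run <- strrep("AT", 30)
  lib <- ssr_library("r1", paste0(random_dna(200), at_run))
  loci <- scan_library(lib)
  with_ssr <- composition_distribution(lib, 2)
  masked <- composition_distribution(lib, 2, exclude_ssr_spans = TRUE,
                                     loci = loci)
  expect_gt(with_ssr$class_probs["AT"], masked$class_probs["AT"])
  expect_lt(masked$n_kmers_counted, with_ssr$n_kmers_counted)
})

test_that("motif GOF uses class counts, correct df, and sentinels", {
  u2 <- uniform_distribution(2)
  balanced <- make_class_loci(setNames(rep(10L, 6), names(u2$class_probs)), 2L)
  r <- motif_gof(balanced, u2)
  expect_equal(r$statistic, 0)
  expect_equal(r$df, 5)

  u3 <- uniform_distribution(3)
  tri <- make_class_loci(setNames(rep(3L, 20), names(u3$class_probs)), 3L)
  expect_equal(motif_gof(tri, u3)$df, 19)

  # expected 0 with observed > 0 -> infinite statistic sentinel
  null0 <- uniform_distribution(2)
  null0$class_probs[] <- c(0.5, 0.5, 0, 0, 0, 0)
  skewed <- make_class_loci(setNames(c(10L, 10L, 5L, 0L, 0L, 0L),
                                     names(null0$class_probs)), 2L)
  inf <- motif_gof(skewed, null0)
  expect_identical(inf$statistic, Inf)

  expect_error(motif_gof(balanced[1:10, ], u2, min_loci = 20),
               "statistical power")
})

test_that("composition and uniform nulls disagree on a skewed library", {
  set.seed(603)
  lib <- ssr_library(paste0("r", 1:30),
                     replicate(30, random_dna(400, probs = c(.4, .1, .1, .4))))
  counts <- setNames(c(40L, 10L, 30L, 5L, 10L, 5L),
                     names(uniform_distribution(2)$class_probs))
  loci <- make_class_loci(counts, 2L)
  x_unif <- motif_gof(loci, uniform_distribution(2))$statistic
  x_comp <- motif_gof(loci, composition_distribution(lib, 2))$statistic
  expect_false(isTRUE(all.equal(x_unif, x_comp)))
})

test_that("ORF background is the per-read interval union", {
  lib <- ssr_library(c("r1", "r2"), c(strrep("A", 100), strrep("C", 200)))
  loci <- data.frame(read_id = c("r1", "r2"), start = 0, end = 10)

  none <- orf_background(lib, empty_orfs <- data.frame(
    read_id = character(), start = integer(), end = integer()), loci)
  expect_equal(none$fraction_in_orf, 0)

  full <- orf_background(lib, data.frame(read_id = "r1", start = 0, end = 100),
                         loci[1, ], restrict = TRUE)
  expect_equal(full$fraction_in_orf, 1)

  # overlapping ORFs merge before counting
  orfs <- data.frame(read_id = c("r1", "r1", "r2"),
                     start = c(0, 30, 50), end = c(60, 90, 150))
  bg <- orf_background(lib, orfs, loci, restrict = FALSE)
  expect_equal(bg$bases_in_orf, 90 + 100)     # [0,90) on r1, [50,150) on r2
  expect_equal(bg$bases_total, 300)
  expect_equal(bg$fraction_in_orf, 190 / 300)

  restricted <- orf_background(lib, orfs, loci[1, ], restrict = TRUE)
  expect_equal(restricted$bases_total, 100)
  expect_equal(restricted$bases_in_orf, 90)
})

test_that("ORF GOF matches the hand formula and rejects bridging input", {
  pl <- data.frame(orf_placement = c(rep("inside", 8), rep("outside", 2)))
  bg <- list(fraction_in_orf = 0.5)
  r <- orf_gof(pl, bg)
  expect_equal(r$statistic, 3.6)    # (8-5)^2/5 + (2-5)^2/5
  expect_equal(r$df, 1)

  matched <- orf_gof(pl, list(fraction_in_orf = 0.8))
  expect_equal(matched$statistic, 0)

  expect_error(orf_gof(data.frame(orf_placement = c("inside", "bridging")),
                       bg), "bridging")
  expect_error(orf_gof(pl[0, , drop = FALSE], bg), "no placements")
})

test_that("composition probabilities approach uniformity on uniform bases", {
  set.seed(604)
  lib <- ssr_library(paste0("r", 1:40), replicate(40, random_dna(5000)))
  d <- composition_distribution(lib, 2)
  expect_lt(max(abs(d$class_probs - 1 / 6)), 0.02)
})
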