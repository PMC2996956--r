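---
title: "Methods: mining microsatellites and modelling their diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining microsatellites and modelling their diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrsurvey)
```

This vignette is the package's account of its own methods: what is computed,
under which assumptions, which defaults were genuinely open choices, and what
the synthetic-data tests do and do not establish about real libraries.

## Repeat detection

A simple sequence repeat (SSR) locus is a *maximal perfect run* of a
*primitive* unit of 2–6 bp: the run cannot be extended by one base in either
direction with the same unit, and the unit is not itself a repetition of a
shorter string (`ATAT` is never a reported unit; that run belongs to `AT`).
Primitivity plus maximality imply the reported `unit_length` is the smallest
period of the run: a run with two periods `p < k` and at least two complete
units of `k` also has period `gcd(p, k)` (Fine–Wilf), which would make the
`k`-unit non-primitive. The scanner therefore works per unit length on the
lag-`k` self-match vector and discards non-primitive units; an equivalence
test against a brute-force per-start enumeration guards the implementation.

Tunable parameters:

* `min_units` (default **5** complete units). Thresholds phrased as
  *more than five repeating units* are ambiguous between ≥ 5 and > 5 in
  common SSR-miner usage; the downstream repeat-number bins start at 5, so
  the permissive reading is the default and the threshold is an argument
  everywhere.
* `partial_extension` (default **TRUE**): a perfect partial trailing unit is
  included in the span (`span_bp`), while `repeat_count` counts complete
  units only, keeping repeat numbers integral for binning.
* `min_flank_bp` (default **20 bp**, about one primer length): loci with a
  shorter flank on either side are flagged `is_terminal`, the operational
  definition of "no room to design a primer". Marker screens drop such
  loci; the flag is carried rather than the rows deleted.
* Compound structures: two runs whose gap is ≤ `max_gap_bp` (default **0**,
  i.e. only abutting or overlapping runs) are both removed by
  `filter_compound()`. No interruption threshold is assumed because none is
  standard; anything larger is a user decision.
* `N` bases terminate extension and never participate in k-mer counts.

Coordinates are 0-based half-open internally; GFF3 output converts to
1-based inclusive.

## Motif algebra: rotation classes, not reverse complements

Units that are cyclic rotations of each other describe the same run in a
different phase, so motif identity is the rotation orbit, represented by the
lexicographically smallest rotation. Rotation-only classification yields 6
dinucleotide and 20 trinucleotide classes — hence the goodness-of-fit
degrees of freedom 5 and 19. Merging reverse complements would instead give
4 and 10 classes; the df values of the survey design force the rotation-only
convention, and everything downstream (composition nulls, figures-style
tabulations) is therefore strand-specific. Forward-strand-only k-mer
counting in the composition null is the consistent companion choice.

## ORF scanning

An ORF is an ATG to the first in-frame stop (TAA/TAG/TGA) downstream, stop
codon included, on either strand (reverse-strand ORFs reported in forward
coordinates). Every qualifying ATG yields an ORF, so nested starts sharing a
stop are all reported; containment of an SSR in *any single* ORF makes it
`inside`. The minimum length default is **300 nt** (100 codons), the
historical NCBI ORF-finder default — the original survey names its tool but
not its settings, so the value is configurable rather than baked in. SSRs
disjoint from every ORF are `outside`; anything else — straddling a
boundary, or covered by a union of ORFs but by no single one — is
`bridging` and is excluded from the placement goodness-of-fit test, which
otherwise would double-count partially coding loci.

## Null models

The "expected" motif distribution is deliberately empirical, not Bayesian:
the probability of each motif class is its share of all overlapping,
primitive, `N`-free k-mers in the library (pooled by rotation class). This
asks "would SSR motifs look like this if they simply mirrored base
composition?" — the sharpest null available without a mutation model. A
uniform null over classes is provided as the cruder companion. Options that
were genuinely open:

* `exclude_ssr_spans` (default **FALSE**): whether the repeats themselves
  are masked out of the background. Counting everything follows the plain
  reading of "total frequency within a complete library"; masking is one
  flag away for sensitivity analysis.
* `motif_gof()` refuses to run on fewer than `min_loci = 20` observations,
  mirroring the exclusion of tetra- and pentanucleotide classes as too
  infrequent for adequate power.

The ORF-placement null is the fraction of bases inside the per-read union
of ORF spans, by default restricted to reads that contain at least one SSR
(`restrict = TRUE`), since only those reads could have contributed a locus.

## Statistical tests

Chi-square goodness of fit is computed directly (`chisq_gof()`): the
statistic is `sum((O - E)^2 / E)`, `p` from the upper tail of `chisq(df)`.
The in-package implementation exists because the module contract needs an
infinite-statistic sentinel (expected 0 with observed > 0) and an optional
Yates correction in one-df designs; it is cross-checked against
`chisq.test()` in the test suite. Continuity correction is **off** by
default. Rank tests are delegated to base R: `wilcox.test()` (exact
enumeration when `n1*n2 <= 400` and there are no ties, otherwise the
tie-corrected normal approximation), `kruskal.test()` (tie-corrected;
all-identical values return H = 0 by definition), and
`cor.test(method = "spearman", exact = FALSE)` for the tie-corrected
Spearman coefficient with the t approximation appropriate at the survey's
n ≈ 120. An exact permutation p-value for the Spearman test is available
for n ≤ 8: full enumeration beyond that is combinatorially infeasible
(12! ≈ 4.8 × 10⁸ permutations), and at such sizes the t approximation is
the standard tool anyway.

Cross-library abundance comparisons depend entirely on how sequencing
effort is measured, and reads versus bases give different answers whenever
read lengths differ between libraries; `compare_abundance()` therefore
exposes the exposure measure explicitly (`reads` or `bases`) rather than
fixing one convention silently.

## Screening filters and richness

Genotype screens are categorical band labels (precise sizes are not
assumed scorable on silver-stained gels); a diploid individual's two bands
are stored slash-joined in one cell. Loci are dropped when they failed to
amplify entirely, amplified in only one species, or showed a null allele
(any individual missing), so every retained locus rests on the full panel —
richness is then the count of distinct labels across all individuals
jointly. Trinucleotide motifs pool into GC bins {0, 33, 67, 100}%;
repeat-number pooling uses the survey's bins (5 / 6 / 7–8 / 9–20 / 21–42
for genomic reads; 5 / 6 / 7 / 8 / 9+ for transcribed reads) by default.

## The synthetic-data generator

The generator exists so that every stage has ground truth. Its defaults are
the study conditions it emulates, chosen once:

* reads of mean **703 bp** (sd 80), a typical Sanger-era single-pass read;
* background **35% GC** (A = T = 0.325), a typical AT-rich insect genome;
* **0.08 planted SSRs per read**, the density scale of the genomic
  (BAC-end) library (one SSR per ~12 reads);
* unit lengths 2/3/4 at 70/27/3% (tetranucleotides rare, as observed),
  motif-class weight ∝ `exp(-2 · GC fraction)` (AT-biased spectrum),
  unit counts `5 + Geometric(0.25)` (mean 8);
* **0.15 ORFs per kb**, length `100 + Geometric(0.03)` codons;
* genotype model: latent allele-pool size `1 + Poisson(exp(-0.5 + 0.15 n))`
  for reference repeat number `n`, truncated at twice the panel size;
  alleles are stepwise length variants of the reference sampled with
  geometric weight `0.5^|offset|`; screening failures injected at rates
  35/288, 2/288 and 9/288, the attrition funnel of a realistic 288-locus
  marker screen.

Planted SSRs are placed uniformly with 10 bp buffers, rejecting overlaps,
and the single base flanking each side is forced to differ from the base
that would extend the repeat, so planted coordinates coincide exactly with
maximal-run coordinates and coordinate-exact recovery is a fair test. The
log-linear pool model is a test harness, not a mutation-model claim: it
encodes only "richness increases with repeat length", the qualitative
structure the richness statistics must be able to recover.

What the simulator does **not** emulate — and what passing tests therefore
do not establish about real data: sequencing error and chimeric reads,
imperfect and compound repeats in the background, transcript redundancy in
EST sets beyond exact duplicates, population structure or coalescent
history behind the genotypes, and PCR artefacts other than the three
injected failure classes.

## Numerical and testing choices

Test problem sizes were chosen to make sampling error negligible relative
to the bands asserted: scanner-oracle equivalence on 1,000 random 200-mers
and 100 random 2-kb sequences; coordinate-exact recovery on ≥ 500 planted
loci with the background false-positive rate measured on an equally sized
repeat-free library; type-I error of every test estimated from 2,000 null
replicates and required to lie in [0.035, 0.065] at α = 0.05; positive
repeat-length effects recovered in ≥ 99% of 500 genotype replicates; and
convergence of the composition null to uniformity checked on a 5 Mb
uniform-base library (max class deviation < 0.01). All simulations are
seeded; the generator draws only from R's integer RNG streams, so output is
reproducible across platforms.

## Known limitations

* Duplicate removal is exact full-sequence identity only; near-duplicate
  clustering would need a similarity threshold the survey does not supply.
* Detection is forward-strand and per-read; repeats broken across reads are
  invisible, and no attempt is made to merge calls from overlapping reads.
* The richness analyses treat loci as independent; linked loci on one read
  are not modelled.
* Primer design itself (product size, Tm, self-complementarity) is out of
  scope; only flank feasibility is flagged.
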