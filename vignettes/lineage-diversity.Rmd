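---
title: "Methods: lineage-private alleles, diversity, and core selection in two-lineage SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage-private alleles, diversity, and core selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineagescope)
```

# The setting and the data model

The package targets germplasm collections of a selfing species split into
two deeply diverged lineages (here called L1 and L2), genotyped at thousands
of biallelic SNPs by reduced-representation sequencing, optionally together
with a derived crop panel ("wheat") descended from one of the lineages.
Such panels have three defining statistical features that every method here
leans on:

* **Inbreeding.** Accessions are nearly fully homozygous; residual
  heterozygosity is a quality signal, not biology, which is why both the
  site-level and sample-level QC filters treat excess heterozygosity as an
  artifact.
* **Deep divergence.** A large fraction of alleles segregate in one lineage
  while being entirely absent from the other. These *lineage-private
  alleles* are the package's central diagnostic.
* **Missingness.** GBS call sets have substantial, roughly uniform missing
  data; all estimators therefore use pairwise-complete observations and the
  Euclidean distance rescales by `m / m_obs`.

Genotypes live in a `geno_matrix`: an integer matrix of alternate-allele
dosages (0, 1, 2) with `NA` as a dedicated missing sentinel — missingness is
never encoded as a dosage value. Sites are re-sorted by (chromosome,
position) on construction, ties broken by site id, so positional operations
(painting, BED export) always see genomic order. VCF positions are 1-based
throughout; only BED painting output uses 0-based half-open intervals, each
format's own convention. Heterozygote phase is ignored everywhere: with a
selfing panel the unphased dosage model loses nothing.

# The QC cascade

`qc_pipeline()` applies four stages in a fixed order; each stage's
input/output dimensions are logged.

1. **Site filters** (`filter_sites()`): retain sites with MAF ≥ 0.01,
   missingness ≤ 20%, heterozygosity ≤ 5%. MAF is dosage-weighted (a het
   contributes one allele copy), computed over non-missing calls only.
2. **Allelic-tag screen** (`allelic_tag_test()`): genotype calls at a site
   produced by two collapsed paralogous loci show a characteristic excess of
   joint heterozygous/absent patterns. Per site the 2×2 table
   `[[n_het, n_hom_ref], [n_hom_alt, n_missing]]` is tested with a two-sided
   Fisher exact test (direct hypergeometric enumeration, with the
   conventional `1 + 1e-7` relative tie tolerance so results agree with
   `stats::fisher.test` to numerical precision). A site is removed only when
   the Bonferroni-corrected p-value (denominator = sites entering the test,
   i.e. after stage 1) falls below α = 0.001 **and** the table odds ratio
   `(n_het·n_missing)/(n_hom_ref·n_hom_alt)` exceeds 1 — significant
   *negative* association is not evidence of paralogy and is left alone.
   The table is built from called genotypes because the package consumes
   called data, not raw tag depths; the construction is the documented,
   configurable choice.
3. **Sample filters** (`filter_samples()`): remove samples with > 80%
   missing calls **or** > 5% heterozygosity (either threshold suffices).
4. **Group-private removal** (`drop_group_private_sites()`): drop sites
   whose polymorphism exists only because of one group (e.g. wheat) — the
   site would be monomorphic without it.

One subtlety: the cascade is idempotent only once the sample set is stable.
Removing a sample (stage 3) shifts site statistics, so a second pass can
remove a handful more sites; a true F1 hybrid, heterozygous at every
inter-lineage difference, is *correctly* removed by the 5% sample-het filter
— worth remembering when hybrids of interest may be early-generation.

# Diversity and differentiation

`nei_diversity()` computes per-site gene diversity `h = 1 − Σ f_a²` (for
biallelic data `2f(1−f)`, at most 0.5) and averages it. By default the
average runs over *all* sites with at least one call, monomorphic sites
contributing zero — this keeps indices comparable across groups assayed on
one panel. A `"polymorphic"` mode restricts the mean to segregating sites;
the two modes differ only in scale, and the choice is reported via
`n_sites_used`.

For differentiation the package uses **Hudson's F_ST estimator** with
ratio-of-sums accumulation (per-site numerators and denominators summed
before dividing). The estimator needs only allele frequencies and allele
counts per group, is robust to unequal sample sizes, and — decisive for
testing — has a known expectation under the Balding–Nichols divergence model
used by the simulator: two populations drawn with parameter F have expected
Hudson F_ST equal to F. The panel is inbred, so the allele-call count
`n = 2 × genotypes` overstates the number of independent allele draws; the
resulting bias in the finite-sample correction is of order `(1−F)/n` and is
negligible at the panel sizes used here. Estimates are reported unclamped
with a warning when negative (small true differentiation can yield slightly
negative estimates). The estimator choice (over Weir–Cockerham) is a design
decision: with the divergence model used for validation, Hudson admits exact
parameter-recovery tests.

# Structure

`relationship_matrix()` builds the centered-crossproduct genomic
relationship `A = WW′ / (2 Σ p(1−p))` over polymorphic sites, missing calls
imputed at the site mean (so they are neutral after centering).
`relationship_pca()` eigendecomposes A; *scores* are eigenvectors scaled by
√λ (raw eigenvectors are also returned), and variance explained divides by
the sum of non-negative eigenvalues, since mean-imputation can produce tiny
negative ones. On a two-lineage panel PC1 separates the lineages; PC2/PC3
carry within-lineage structure, which `pc_geo_correlation()` relates to
passport longitude/latitude/altitude with pairwise-complete Pearson
correlations.

Cluster analysis uses `stats::dist` (Euclidean, with its standard
missing-data rescaling `sqrt(m/m_obs · Σ d²)`; a pair with no co-observed
sites is an error naming the pair) and Saitou–Nei neighbor joining via
`ape::nj`. Negative NJ branch lengths — an artifact of noisy distances — are
clamped to zero with the count recorded. Admixture-model fitting is
deliberately out of scope: hybrid evidence in this package comes from PCA
position plus private-allele composition, which is direct and
assumption-free.

# Lineage-private alleles

`find_private_alleles()` declares an allele private to lineage A when its
frequency is exactly 0 in lineage B and strictly inside (0, 1) in A. Two
guards matter:

* **Fixed inter-lineage differences are excluded** (frequency 1 vs 0): they
  say nothing about recent exchange, only about divergence. A switch
  (`include_fixed`) re-admits them for sensitivity analysis.
* **A call floor** (`min_call_fraction = 0.5` per lineage) prevents a site
  genotyped in a handful of samples from producing a spurious "frequency
  exactly 0".

Downstream, everything is counting:

* `lineage_contribution()` sums private-allele copies per sample
  (dosage-weighted: het = 1 copy, hom = 2), yielding
  `pct_L1 = count_L1 / (count_L1 + count_L2)`. Dosage weighting makes an F1
  land at ~50/50; for inbred accessions it coincides with site counting.
* `classify_hybrids()` flags samples whose minor-lineage share reaches
  `minor_fraction_min = 0.10` with ≥ `min_informative = 100` informative
  sites. The threshold sits far above the ~0 of clean pure-lineage samples
  and safely below the tens-of-percent signal of real hybrids; the
  informative-site floor protects against sparse-genotype artifacts (it
  should be scaled down for miniature panels, as the README example does).
* `paint_sample()` orders carried private alleles along each chromosome and
  counts label switches; `clarity = 1 − switches/max(informative−1, 1)`
  separates clean recombinant-inbred mosaics (few long runs, clarity near 1)
  from the interleaved pattern of a fixed hybrid lineage descended from
  multiple intercrossing generations.
* `parentage_match()` scores candidates by percent dosage identity at
  private sites co-genotyped in query and candidate — co-genotyped rather
  than all sites, so missingness does not deflate identities; the
  denominator is reported alongside.
* `group_private_alleles()` finds alleles private to an arbitrary target
  group against background groups and splits them into fixed vs segregating
  within the target — the signature of a young, isolated hybrid lineage is
  many fixed and few segregating group-private alleles.
* `consensus_introgression()` assigns private sites assayed in the derived
  panel: an L1 call needs ≥ `min_carriers = 2` distinct carriers of the
  L1-private allele (one carrier could be a genotyping error), while an L2
  call needs one carrier of an L2-private allele, L2 being the assumed
  donor background; the rules are checked in that order. Summaries count
  *called* sites, not all private sites, per chromosome and genome-wide.

# Core selection

`greedy_m_selection()` treats every observed (site, allele) pair — plus
(trait, category) pairs when phenotypes are supplied — as a class to cover,
and greedily adds the sample covering the most uncovered classes, ties
broken by lexicographic sample id, until every coverable class is covered.
This is a deterministic greedy maximal-coverage surrogate for the "advanced
M (maximization)" strategy of core-selection software whose exact internal
heuristic is not published as pseudocode; as greedy set cover it inherits
the (1 − 1/e) worst-case guarantee, and the tests benchmark it against
random same-size subsets and against exhaustive optima on small panels.
`reduce_core()` formalizes the manual, phenotype-guided reduction of a core
as a reproducible constrained greedy: per-group quotas (e.g. `L1 = 29,
L2 = 11`) and a configurable weight `w_pheno = 5` that favors newly covered
*resistant* trait classes over allele classes. `capture_metrics()` assesses
any subset by the percentage of the panel's segregating sites that still
segregate within it, plus the subset's Nei index.

# The synthetic panel generator

`simulate_panel()` generates the full study setting with ground truth; its
defaults are the package's reference conditions, and all randomness flows
from a single seed (identical seed → bit-identical output, including written
fixture files).

| Parameter | Default | Meaning |
|---|---|---|
| `n_L1`, `n_L2`, `n_wheat` | 60, 60, 20 | group sizes |
| `n_sites`, `n_chromosomes` | 2000, 7 | panel dimensions |
| `divergence_F` | 0.55 | Balding–Nichols divergence between lineages |
| `residual_het` | 0.002 | probability of re-drawing a genotype's second allele |
| `missing_rate` | 0.03 | per-call missing probability |
| `error_rate` | 0 | per-call symmetric dosage-flip probability |
| `n_f1`, `n_ril`, `hybrid_group_size` | 1, 1, 7 | the nine planted hybrids |
| `ril_breakpoints_per_chrom` | 3 | expected RIL ancestry switches |
| `hybrid_prototype_breakpoints_per_chrom` | 25 | hybrid-lineage prototype switches |
| `hybrid_private_fixed/_segregating` | 20, 5 | planted group-private sites |
| `wheat_founder_count` | 4 | L2 haplotypes founding the wheat bottleneck |
| `wheat_introgression_sites/_carriers` | 8, 3 | planted L1 introgressions |
| `l1_cline_F`, `l2_cline_F` | 0.12, 0.06 | within-lineage substructure |

Construction order: ancestral frequencies `Uniform(0.1, 0.9)`; per-lineage
frequencies by Balding–Nichols `Beta(p(1−F)/F, (1−p)(1−F)/F)`; inbred
genotypes (one allele drawn and duplicated, second re-drawn with probability
`residual_het`); the wheat panel by a second Balding–Nichols round around
the allele frequencies of a few sampled L2 founders (a bottleneck, giving
wheat the lowest diversity and placing it closest to L2); planted L1
introgressions at realized L1-private sites, written into a fixed number of
wheat carriers; the F1 by gamete draws from one L1 × one L2 panel parent;
RIL and hybrid-lineage prototypes as homozygous two-state Markov mosaics
over site order with the stated expected switch counts (site order, not
genetic-map distance, because painting operates on site order only); the
hybrid-lineage group as copies of one prototype plus group-exclusive alleles
planted at sites monomorphic in everyone else; genotype errors and
missingness last, so recorded truth stays clean.

Three defaults deserve their rationale:

* **`error_rate = 0`.** The generator emulates a *post-QC filtered* call
  set, and several of the pipeline's exact contracts (consensus calls equal
  the planted sites; painting switches bounded by true breakpoints) are
  properties of the error-free process. The error model exists and is
  exercised by its own tests, but it is a dial for robustness studies, not
  part of the reference conditions. Likewise the exact-recovery checks for
  group-private alleles and consensus introgression run with
  `missing_rate = 0`: a single missing call can delete the only background
  copy of a singleton allele and manufacture a spurious private site.
* **A high-switch hybrid prototype.** The hybrid-lineage group is *not* a
  clean mosaic: descended from one hybridization followed by intercrossing,
  its private alleles interleave. The prototype's expected 25 switches per
  chromosome (vs 3 for the RIL) reproduces exactly the clarity contrast the
  painting statistic is designed to detect.
* **Geography tied to genetic substructure.** Each lineage is optionally
  split into two Balding–Nichols subpopulations (`l1_cline_F`,
  `l2_cline_F`), with L1 subpopulations assigned western/eastern longitudes
  and L2 subpopulations low/high altitudes. A PC-geography correlation can
  only exist if geography covaries with genotype, so planting coordinates
  alone would be inert. The simulator does *not* model continuous
  isolation by distance — the clines are two-level, which inflates
  correlation strength relative to a smooth gradient.

What the simulator does **not** emulate, and hence what passing tests do not
show about real data: linkage disequilibrium beyond hybrid mosaics (sites
are exchangeable within a lineage), reference-bias and ascertainment
effects, depth-dependent genotyping error or the het/missing signature of
collapsed paralogs (the tag-test screen is validated on constructed tables,
not simulated paralogy), wheat-private alleles (simulated wheat derives
entirely from sampled L2 haplotypes, so the group-private removal stage
finds essentially nothing on simulated panels and is validated on
constructed matrices), and asymmetric lineage diversity (the model is
exchangeable in L1/L2, so unlike a real collection the two lineages have
equal expected Nei indices).

# Numerical choices and degenerate inputs

* Frequencies are ratios of integer counts, so "frequency exactly 0/1"
  comparisons in private-allele logic are exact; fractions that feed
  threshold comparisons (missingness) are computed directly as
  `count/total` rather than `1 − complement` to avoid representation error
  at the threshold.
* Exact-test p-values enumerate the hypergeometric support directly; ties
  use the `(1 + 1e-7)` relative tolerance standard for two-sided exact
  tests.
* Zero-call sites carry `NA` statistics and fail (only) the missingness
  filter; empty subsets, missing lineages, overlapping target/background
  groups, and distance pairs with no co-observed sites are errors, not
  silent `NA`s.
* Greedy selection and reduction are fully deterministic: candidates are
  scanned in lexicographic id order, so equal gains resolve to the smallest
  id. Simulation reproducibility relies on a single seeded generator; the
  panel generator sets the R RNG seed from `SimConfig$seed`.
* Eigen-scores use `pmax(λ, 0)` before the square root; asymmetric input to
  the PCA is rejected rather than symmetrized silently beyond 1e-8.

# Problem sizes used in validation

The test-suite reference panel is the simulator default (149 samples × 2000
sites); parameter-recovery checks for F_ST use 100+100 samples × 5000 sites
across ten seeds and three divergence levels; oracle-equivalence checks use
200 random matrices up to 40 × 240 with random missingness; the exact-test
oracle enumerates every 2×2 table with total ≤ 60. These sizes were chosen
so the full suite exercises every recovery property in well under a minute
per property while keeping Monte-Carlo acceptance bands comfortably wider
than the estimators' standard errors at those sizes.

# Known limitations

* Private-allele contribution is a global summary; no HMM-based local
  ancestry, phasing, or dating of hybridization events is attempted.
* The consensus rule resolves the (rare) case of a site with both ≥2
  L1-allele carriers and L2-allele carriers in favor of L1, by rule order;
  the carrier lists in the output let users audit such sites.
* Parentage identity uses co-genotyped private sites only; with very uneven
  missingness the per-candidate denominators differ, which the output
  reports but does not correct for.
* The greedy core is a surrogate for published core-selection software, not
  a clone of it; agreement is at the level of objective (maximize retained
  allele classes), not accession-by-accession output.
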