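---
title: "Identifying and classifying a dominant disease variant: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and classifying a dominant disease variant: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famseg)
```

# The problem

Hereditary gingival fibromatosis (HGF) is a benign, autosomal-dominant
overgrowth of the gingiva. In a single large family, the route from exome
data to a clinical verdict about one missense variant runs through four
quantitative steps, each of which this package implements and tests:

1. **Co-segregation filtering**: among all called variants, keep those whose
   genotypes track the phenotype perfectly under a fully penetrant dominant
   model (every affected member carries the variant, every unaffected member
   is wild-type).
2. **Two-point linkage**: quantify that tracking as a LOD score over
   phase-known meioses.
3. **ACMG/ClinGen classification**: convert the LOD, population absence and
   functional support into coded evidence and combine it into a five-tier
   verdict.
4. **Downstream expression**: a two-group negative-binomial exact test on
   RNA-seq counts with BH correction and gene-set enrichment, and
   delta-delta-Ct quantification of qPCR knockdown experiments.

The package also ships seeded generators for every input (family genotypes,
count matrices, Ct tables) with truth manifests, so the whole chain is
testable offline against known answers.

# The family fixture and its reconstruction

The shipped pedigree (`hgf_pedigree()`) has 25 individuals: two deceased,
ungenotyped generation-I founders and 23 alive genotyped members, of whom 12
are affected heterozygous carriers and 11 unaffected non-carriers; with the
affected founder that makes 13 affected. Published sources fix each member's
sex, affection and genotype but not the full marriage structure, so the
topology here is **one documented reconstruction** (see the header of
`extdata/family_hgf.ped`), chosen to satisfy two hard constraints:

* every carrier must be a descendant of the carrier founder under Mendelian
  transmission; and
* the family must yield exactly **12 phase-known informative meioses**, the
  count implied by the reported LOD of 3.6 (`12 * log10(2) = 3.612`).

Both constraints together force a subtlety: the youngest wild-type child
(IV-4) must be somebody's child, and any placement of her adds a scored
meiosis. The reconstruction resolves this by marrying two carrier first
cousins (III-3 x III-6); their child IV-5 has two carrier parents, so his
meiosis is phase-ambiguous and excluded from linkage scoring — the standard
treatment, and the one `classify_meioses()` applies and reports.

An *obligate carrier* is an ungenotyped individual forced to carry by
Mendelian logic (a carrier child whose other parent is a known non-carrier).
`obligate_carriers()` applies this closure transitively; for deceased
founders, affection status additionally stands proxy for carriage because
penetrance is taken as complete (`resolve_carriers()`).

# Two-point LOD under full penetrance

With non-recombinant and recombinant counts NR and R, the phase-known
two-point LOD is

$$\mathrm{LOD}(\theta) = \log_{10}
\frac{(1-\theta)^{NR}\,\theta^{R}}{0.5^{\,NR+R}},$$

maximized over the recombination fraction $\theta \in [0, 0.5]$ on a grid
(default step 0.001; ties break toward smaller $\theta$). When $R > 0$ the
likelihood at $\theta = 0$ is zero; the implementation returns a `-Inf`
sentinel and excludes it from maximization. Complete co-segregation of the
fixture's causal variant gives NR = 12, R = 0 and a maximum LOD of 3.612 at
$\theta = 0$, reported as 3.6 at the one-decimal headline convention. The
model assumes full penetrance, no phenocopies and a vanishing disease-allele
frequency, the only setting in which dominant segregation counting reduces
to NR/R tallies.

# ACMG evidence and combination

The combining rules are data, not code: `extdata/acmg_rules.json` encodes
the published rule table over counts of evidence items per strength tier
and direction, and `combine_evidence()` fires the first matching rule per
direction, returning `uncertain_significance` on cross-direction conflict
or when nothing fires. PP1 (co-segregation) is strength-scaled from the LOD
by `pp1_strength()`: supporting at LOD >= 0.6, moderate at >= 1.5, strong
strictly above 3. Only the strong cutoff is anchored by the clinical
guideline usage this package follows ("LOD > 3"); the lower tiers follow
common co-segregation practice and are configuration keys. PS3 (functional
support) is asserted input; PM2 (absent from population controls) can be
auto-derived from the population-absence filter. For the fixture: PP1
strong + PS3 strong + PM2 moderate fires the ">=2 strong" rule, verdict
pathogenic.

# The co-segregation filter and its two carrier definitions

`dominant_filter()` checks, per variant, that every genotyped affected
member carries the alternate allele and every genotyped unaffected member
is hom-ref. Two deliberate options:

* **Missing calls** are compatible but counted and flagged by default
  (`strict_missing = TRUE` rejects them), since the behavior of the
  original family-filter script on missing calls is not documented.
* **Carrier definition**: by default an affected member may be het *or*
  hom-alt (hom-alt flagged as atypical). `require_het = TRUE` demands
  heterozygosity — the strict reading of a rare dominant model, and the
  one that matches this family, where every carrier is heterozygous.

The simulation study (`analysis/02_simulation_recovery.R`) shows why the
distinction matters: with 5000 background variants at Beta(0.2, 5) founder
allele frequencies, chance co-segregation events are rare but not absent,
and roughly half of them involve a hom-alt call in an affected member.
The heterozygous mode therefore roughly halves the background
false-positive rate (per-run means are printed by the script) at no cost
in recovery of the planted variant, and it is the mode used for the
planted-recovery acceptance checks.

# The expression stage

## Normalization

CPM is library-size-only (`count / library_size * 1e6`; each sample sums
to $10^6$); FPKM divides CPM by gene length in kb. Gene length is
deliberately kept out of CPM — a length-dependent "CPM" is a category
error even where upstream descriptions blur the two.

## Dispersion estimation

The two-group exact test needs a common negative-binomial dispersion
$\phi$ (variance $\mu + \phi\mu^2$). The estimator is method-of-moments:
counts are scaled to the geometric-mean library size; per gene the pooled
within-group variance $s^2$ and grand mean $m$ give
$\phi_g = \max(0, (s^2 - m)/m^2)$, and $\hat\phi$ is the median of
$\phi_g$ over expressed genes. One correction is essential at this
design's sample sizes: with 4 within-group degrees of freedom, the
*median* of a variance estimate is only `qchisq(0.5, 4)/4 = 0.84` of its
expectation, so the raw median-of-moments underestimates $\phi$ by ~16%
and visibly inflates the downstream false-discovery proportion. The
implementation divides $s^2$ by that chi-square median factor first; in
parameter-recovery simulations the corrected estimator is accurate to a
few percent at $\phi$ = 0.1–0.2, and a test cross-checks its magnitude
against an established qCML estimator. With a single sample per group the
dispersion is inestimable and a documented fallback of 0.1 is returned
with a warning.

## The conditional exact test

Counts are scaled to the geometric-mean library size, rounded, and pooled
within groups. Conditional on the pooled total $t$, the group-A total
follows a distribution proportional to
$\binom{y + r_A - 1}{y}\binom{t - y + r_B - 1}{t - y}$ with
$r_g = n_g/\phi$ — the per-gene mean cancels — computed in log space; the
Poisson limit $\phi = 0$ is a binomial with probability $n_A/(n_A+n_B)$.
The two-sided p doubles the smaller cumulative tail at the observed split,
capped at 1. This is a deliberately simpler construction than the
quantile-adjusted test of the established DE packages: exact numerical
agreement with them is a non-goal; the contract is distributional
(type-I calibration, FDR control, planted-truth recovery), and the
conditional distribution itself is verified against independent
density-product enumeration to 1e-10 for all totals up to 200.

BH correction is the standard step-up (via `stats::p.adjust`);
significance requires FDR < 0.05 and |log2FC| >= 1, with log2FC computed
on group-mean CPM with a prior count of 0.5 per group. Note that BH is
*not* idempotent — re-adjusting adjusted values changes them — so the
tests assert monotonicity and `q >= p` instead. Top-gene lists rank by
fold change with FDR-then-lexical tie-breaks; the heatmap export divides
each row by its mean (rows with zero mean become zeros and are flagged).
Enrichment is the upper-tail hypergeometric over an expressed-gene
universe (CPM >= 1 in >= 2 samples by default), with the enrichment ratio
k/K the DE fraction of the pathway.

## What the planted-truth tests can and cannot show

The generator's defaults encode the study design: 2 patients vs 4
controls, 5000 genes (a scaled-down transcriptome), log-normal baselines
(meanlog 4.5, sdlog 1.3, i.e. a median around 90 counts — per-gene depth
typical of tens of millions of mapped reads over a full transcriptome),
common dispersion 0.15 (a biological CV of ~0.39, appropriate for
cultures from genetically distinct human donors), and a planted signature
of 40 up- and 30 down-regulated genes at |log2FC| = 2. At these
conditions the detection power of *any* exact NB test is limited by
dispersion, not depth: with two patients the attainable sensitivity at
FDR < 0.05 hovers near the 0.5–0.75 range depending on the seed, and the
reference qCML exact test gives the same answer on identical data. The
suite therefore asserts the design-level contract — power >= 0.5 with
observed FDR <= 0.1 — and the published DE tallies themselves (which
require the archived raw reads) are out of desk reach. Passing these
tests shows the machinery is calibrated and recovers strong planted
structure; it does not certify recovery of any particular real dataset's
gene lists, which depend on features (gene-specific dispersion, batch
structure, length biases) the generator deliberately omits.

# qPCR quantification

`ddct()` averages technical replicates on the Ct scale, subtracts the
reference gene (18S rRNA in the emulated design) per sample, then
subtracts the control-group mean delta-Ct; relative expression is
$2^{-\Delta\Delta Ct}$ with amplification efficiency fixed at 2 (no
standard-curve correction). Two consequences used as tests: the control
group's relative expressions have geometric mean exactly 1, and any
per-sample constant Ct shift cancels. Group comparison is Student's
pooled-variance t-test (Welch via flag), with the usual star labels; the
degenerate noise-free case (both groups constant) is given p = 1 or 0 by
convention rather than an error.

# Numerical and design choices, collected

* theta grid step 0.001; `-Inf` sentinel at theta = 0 with recombinants,
  excluded from maximization; headline LOD rounded to one decimal.
* Multi-allelic VCF sites are decomposed per alt allele before filtering;
  indel normalization is assumed done upstream. Coordinates are 1-based.
* Population-absence treats a variant missing from a panel's table as
  frequency 0 there, flagged "unobserved".
* Equalized library scaling uses the geometric mean (no TMM; the emulated
  workflow did not use it); scaled counts are rounded for enumeration.
* Background allele frequencies Beta(0.2, 5): rare-skewed (mean ~0.04),
  configurable.
* The causal variant in family simulations follows the template's realized
  transmission (its carriers are the template's affected members), so the
  default configuration reproduces the study composition — 13 affected,
  23 genotyped — exactly; penetrance < 1 then thins affection among
  carriers, and penetrance 0 decouples the two entirely.
* Problem sizes in the test suite: 100 family replicates at 5000
  background variants for recovery; 20 replicates of 5000 genes for null
  calibration; single seeds for planted-recovery spot checks.

# Known limitations

* Linkage is two-point, phase-known, fully penetrant, single-family;
  no multipoint computation, liability classes or penetrance estimation.
* The ACMG engine scores only the criteria given to it; it does not
  auto-derive the other two dozen criteria from annotations, nor the
  Bayesian point system.
* The DE stage fits one common dispersion; gene-wise shrinkage (and hence
  closer agreement with modern DE packages on real data) is out of scope.
* The qPCR model fixes amplification efficiency at 2.
* The pedigree topology and the WES-subset membership are reconstructions;
  both are documented in the fixture files and neither affects the meiosis
  count the fixtures are built to realize.
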