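---
title: "Rare-variant gene-collapsing burden analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant gene-collapsing burden analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvburden)
```

## The model

Rare variants are individually too infrequent for variant-level association
testing: at a minor allele frequency (MAF) of 0.1%, even a cohort of tens of
thousands of exomes observes a handful of carriers per variant. Gene-level
*collapsing* restores power by aggregating: all variants in a gene that
satisfy a *qualifying model* are reduced to a single per-sample binary
indicator — does this sample carry at least one qualifying variant? — and the
carrier frequency is compared between cases and controls.

For a gene with $a$ case carriers among $n_1$ cases and $c$ control carriers
among $n_2$ controls, the evidence is the 2×2 table
$\{(a, n_1-a), (c, n_2-c)\}$, tested with the two-tailed Fisher exact test
(FET): with margins fixed, the carrier count follows a hypergeometric
distribution, and the two-sided p-value sums the point probabilities of all
tables no more probable than the observed one (the minimum-likelihood
convention of standard exact-test software, `fisher_two_sided()`). Effect
size is the odds ratio, either the cross-product $(ad)/(bc)$ (default) or
the conditional maximum-likelihood estimate under the noncentral
hypergeometric model (`odds_ratio(method = "cmle")`). For the flagship
2×2 table used throughout the test-suite (19/849 cases versus 88/15,640
controls) the two estimators give 4.0456 and 4.0451 — numerically
indistinguishable at two decimals; both are reported because published
tables do not always state which was used.

Significance is Bonferroni-controlled at two levels
(`collapsing_thresholds()`): *genome-wide*, $0.05/G$ for the $G$ tested
genes ($G = 18{,}653$ consensus coding sequence genes gives
$2.68\times10^{-6}$), and *study-wide*, $0.05/(MG)$ after further
correcting for the $M = 7$ non-synonymous models
($3.83\times10^{-7}$). The synonymous negative-control model and the
complementary common-LOF model are diagnostics and deliberately excluded
from $M$.

## The qualifying-model registry

`model_registry()` encodes nine rule sets. Each combines:

* **a frequency criterion**, applied to *every* reference population
  (gnomAD-style per-population AFs) *and* both internal cohorts, folded to
  the minor allele. A variant absent from a reference population counts as
  frequency 0 there (absence is not commonness).
* **effect-class rules**: loss-of-function classes (stop gained,
  frameshift, canonical splice acceptor/donor, start lost, stop lost) are
  always admissible; missense requires a PolyPhen-2 HumVar label of
  possibly/probably damaging where the model says so; synonymous and
  splice-region variants can be rescued by a TraP score ≥ 0.2 (the
  transcript-inferred pathogenicity score for splicing disruption).
* **a zygosity rule**: dominant (any het/hom-alt carrier) or recessive
  (hom-alt, or two distinct heterozygous qualifying variants in the gene —
  a putative compound heterozygote; no phase check is attempted).

The three headline models nest by construction: LOF ⊆ LOF+missense ⊆
LOF+missense+splicing, so per-gene carrier sets can only grow across them —
a property the test suite verifies on every simulated cohort. Three
frequency tiers (MAF ≤ 5%, ≤ 0.1%, ≤ 0.01%) and the recessive model
complete the seven corrected models.

Two registry entries need justification:

* **`common_lof` (MAF > 1%)** is the complement screen: if a gene's rare-LOF
  enrichment were an artifact of the rare-MAF ceiling hiding common LOF
  variation, this model would reveal it. We define "common" as *failing the
  rare ceiling in at least one population* (maximum folded AF > 1%), so
  that the rare and common LOF sets exactly partition the unconstrained LOF
  set — the set-algebra invariant the tests assert. A variant rare in one
  population but common in another is excluded by the rare model, and the
  complement screen is precisely where it should reappear.
* **Missing predictor annotations**: a missense variant with no PolyPhen
  label (or a synonymous variant with no TraP score) when the model requires
  one is conservatively non-qualifying, reported with reason
  `"unannotated"`. This avoids promoting unannotatable variants into burden
  counts.

Which gnomAD populations are required, and the treatment of unannotated
variants, are configuration surfaces (`qualifying_variants()` reads whatever
`gnomad_af_*` columns are present).

## Quality control and coverage harmonization

**Sample gates** (`filter_samples()`): contamination strictly above 8%
excludes a sample; eligibility requires strictly more than 87% of CCDS
covered at 10×; and from each component of the kinship graph (pairs related
up to third degree, as produced by upstream kinship software) a maximal set
of mutually unrelated samples is retained. We solve the maximum independent
set exactly by branch and bound for components up to 25 samples — kinship
components in cohort data are small, and the exact solution is
deterministic and verifiable against brute force — falling back to greedy
highest-degree removal for larger components, with ties always broken by
sample ID.

**Variant QC** (`apply_variant_qc()`) is a pure conjunction of inclusive
thresholds (quality ≥ 30, quality-by-depth ≥ 2, genotype quality ≥ 20,
read-position rank sum ≥ −3, mapping quality ≥ 40, mapping-quality rank sum
> −10, depth ≥ 10, Fisher strand bias ≤ 60 for SNVs / ≤ 200 for indels,
het alternate-allele ratio ≥ 25%, no EVS failure). Rank-sum statistics are
undefined when all reads support one allele; their absence passes the rule,
since absence is not evidence of bias. The conjunction is monotone: relaxing
any single metric can never turn a pass into a fail (property-tested).

**Coverage harmonization** (`harmonize_sites()`): if cases and controls were
captured or sequenced differently, a site can be well covered in one cohort
only, and genotype calls there mimic differential burden. At every site we
test independence of coverage (depth ≥ 10) and case/control status: under
the pooled null the covered-case count is Binomial$(n_1, \hat p)$ with
$\hat p$ the pooled covered fraction, tested two-sided by
minimum-likelihood summation; sites with $p \le 0.01$ are eliminated before
any collapsing. Which cohort is tested against the pooled rate is
configurable (`side`); the exact test is label-symmetric in its decision at
any reasonable $\alpha$. Fully covered sites short-circuit to $p = 1$.

## Inflation diagnostics and the mid-p choice

`genomic_lambda()` is the standard median-based genomic inflation factor:
p-values are mapped to 1-df $\chi^2$ quantiles and the median is divided by
0.4549364, the null $\chi^2_1$ median. `qq_with_bands()` supplies QQ
coordinates with the uniform order-statistic expectation $i/(n+1)$ and
pointwise 95% envelopes from Beta$(i, n-i+1)$ quantiles.

Exact-test p-values, however, are *discrete and conservative*: at the small
carrier counts typical of rare-variant collapsing, the null p-value
distribution has atoms well above the uniform, and the median-based lambda
is systematically deflated — in our null simulations at study scale, raw-p
lambda sits around 0.56–0.83 even though the test is perfectly calibrated.
`inflation_diagnostics()` therefore computes lambda and QQ coordinates from
**mid-p** values (the observed table's point mass counted half) by default,
the standard correction for discreteness in calibration diagnostics; this
restores lambda to 0.89–1.10 on calibrated nulls. The raw two-sided p is
always what significance is judged on; `use_midp = FALSE` reproduces the
uncorrected diagnostic. Genes with no qualifying variant at all (p exactly
1, zero carriers) are dropped from the diagnostic by default
(`tested_only = TRUE`) since their constant p-values carry no calibration
information and their inclusion materially shifts lambda; both modes are
available because published analyses do not always state the choice.

## The synthetic-cohort generator

`simulate_cohort()` generates cohorts with the statistical structure the
collapsing analysis assumes — not sequence reads, not linkage
disequilibrium. Defaults are the calibration-study conditions used
throughout the tests: 849 cases, 15,640 controls, 2,000 genes.

* **Variant density.** Per-gene variant counts are negative binomial
  (mean 75, size 2): genes differ widely in length, and in a cohort of
  ~16k exomes a typical gene harbors on the order of 10²
  distinct coding variants. Real per-gene density is a free parameter of
  the design; these defaults were chosen once as realistic and used for
  all reported calibrations.
* **Frequency spectrum.** Allele frequencies are Beta(0.2, 200): strongly
  rare-skewed with a tail crossing the 1% ceiling, so qualifying models
  see mass on both sides of their MAF bounds. Per-population AFs jitter
  around the drawn value; internal cohort AFs are recomputed from the
  realized genotypes.
* **Null genes.** Carrier probability per variant is ~2·AF, identical in
  cases and controls, so any case/control difference is sampling noise.
* **Enriched genes.** An enrichment declares gene-level carrier
  frequencies; per-sample carrier indicators are drawn Bernoulli at those
  rates, and each implanted carrier receives *its own private qualifying
  variant* for the named model (carrier collapsing makes per-carrier
  multiplicity irrelevant, and private variants keep every implanted
  variant individually rare — a shared variant would trip the internal
  cohort-frequency ceiling). Enriched genes carry no background variants,
  so the declared frequencies are the gene's exact carrier-process
  parameters; implanted carriers are heterozygous except under the
  recessive implant modes (`hom` or `compound_het`).
* **Determinism.** One seeded generator drives all draws; the seed is
  recorded in the output metadata, and a fixed seed reproduces the cohort
  byte for byte.

`make_fixture_from_counts()` is the degenerate case used for validation: it
builds a cohort that collapses to an exact, prespecified 2×2 table, one
private variant per carrier. Its frequency annotations are pinned to zero
(absent from reference populations) rather than derived, because a single
carrier in a miniature cohort already exceeds a rare-MAF ceiling — the
fixture's purpose is to replay printed tables bit-exactly through the whole
pipeline. `simulate_coverage_imbalance()` perturbs per-cohort coverage at
designated sites to exercise harmonization; genotype calls at newly
uncovered cells are cleared, preserving the covered-implies-called
invariant.

What the generator does *not* emulate: read-level error processes, linkage
disequilibrium, population substructure, relatedness, annotation error, or
per-site depth distributions. Passing calibration tests on these cohorts
therefore demonstrates correctness of the statistical machinery under its
own assumptions, not robustness to the confounders real cohorts bring;
those are exactly the failure modes the QC, harmonization and inflation
modules exist to detect.

## Haplotype sharing and CpG hotspots

A recurrent variant can be recurrent for two reasons: descent from a common
ancestor (founder allele, one shared haplotype background) or independent
recurrent mutation (hotspot, many backgrounds). Given *pre-phased*
haplotypes (phasing is upstream; `read_phased_vcf()` ingests phased GT
fields), `filter_phasing_input()` applies the pre-phasing site filters
(drop multiallelic sites and sites missing in > 20% of samples) and
`count_carrier_haplotypes()` groups the haplotypes carrying the focal
alternate allele by exact identity over non-missing flanking sites —
optionally restricted to informative sites (alternate allele present on at
least one haplotype), mirroring manual assignment practice.

Missing data create ambiguity, handled conservatively: completely typed
carrier haplotypes are grouped first; an incomplete haplotype compatible
with exactly one established group joins it (refining the group consensus),
one compatible with none founds a new group, and one compatible with two or
more is counted *inconclusive* rather than inflating the background count.
Incomplete haplotypes are processed in a deterministic order (fewest
missing sites first, then allele pattern), making the count invariant to
sample order.

`is_cpg_transition()` classifies the mutational mechanism behind such
hotspots: spontaneous deamination of 5-methylcytosine at CpG dinucleotides,
i.e. C>T with a 3′ G neighbour on the forward strand, or equivalently G>A
with a 5′ C neighbour (the reverse-strand cytosine of the same CpG). The
classification is strand-consistent under reverse complementation
(property-tested).

## Numerical choices and degenerate inputs

* Exact-test ties are compared with a relative tolerance of $10^{-7}$ when
  summing "no more probable" tables, the convention of standard
  implementations; empty and saturated margins return $p = 1$.
* Odds ratios are `NA` where undefined: zero $bc$ for the cross-product,
  boundary cells driving the CMLE to infinity. The Woolf (log
  cross-product) 95% CI is attached where all four cells are positive.
* Burden results sort by ascending p, ties broken by gene symbol, for
  deterministic output; genes with zero qualifying variants report
  $a = c = 0$, $p = 1$ and keep their place in the universe.
* Samples with missing genotypes at every qualifying site of a gene still
  count in the denominators ($n_1$, $n_2$ are fixed cohort sizes).
* Genotypes are stored sparsely (rare variants leave the matrix ~99.8%
  reference-homozygous); no-calls are flagged in a parallel sparse mask and
  never counted as carriers.

## Problem sizes used in the shipped validation

The calibration suites run at the study conditions (2,000 genes,
849/15,640 samples) once per model, the implanted-OR recovery at 100
replicates of a 6-gene cohort, and the exact-test oracle comparison over
every 2×2 table with total ≤ 60 (~600k tables). These sizes keep the
whole validation within a few minutes on one CPU while leaving the
per-gene counts at realistic magnitudes.

## Known limitations

* Carrier-count FET only: no covariate adjustment (Firth/logistic burden
  regression) and no dispersion/kernel tests (SKAT-type); confounding is
  handled by upstream sample pruning plus the diagnostics here, not by
  modelling.
* The internal-cohort MAF criterion uses the full-cohort allele frequency,
  not leave-one-out frequencies; in miniature cohorts this makes rare
  ceilings unreachable (see the fixture design above).
* The recessive model's compound-heterozygote rule does not check phase;
  two variants on the same haplotype will be miscounted as a carrier.
* Inflation values from published cohorts are not reproducible targets:
  they depend on controlled-access data; the package validates the
  machinery and its null calibration instead.
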