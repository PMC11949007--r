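---
title: "Methods: trio de novo calling and the digenic haploinsufficiency screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio de novo calling and the digenic haploinsufficiency screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioscreen)
```

## Scope and model

`trioscreen` implements a cohort-scale exome workflow for rare disease
studies built around proband–parent trios, with craniosynostosis (premature
cranial suture fusion) as the motivating phenotype. It has four analysis
layers, each exposed as data-frame-in / tibble-out functions:

1. **Cohort QC** — hard genotype and site filters over a multi-sample VCF.
2. **De novo identification and burden** — trio-based de novo variant calls
   and a Poisson mutation-rate burden test per consequence class.
3. **Digenic screen** — an exome-wide search for case-specific pairs of
   haploinsufficient genes each hit by a rare deleterious heterozygous
   variant, with biparental-origin logic, unaffected-carrier exclusion,
   stand-in pathogenicity scoring and tissue-expression filtering.
4. **Cohort reporting** — diagnostic yield, suture distribution and
   multilocus pathogenic variation (MPV) summaries recomputed from counts.

A fifth, first-class component is the **synthetic cohort simulator**, which
generates complete truth-annotated fixtures (VCF + PED + annotation and gene
tables) so every stage is testable without access-restricted patient data.

## Cohort QC

Genotypes are masked to missing when GQ < 20, DP < 20, or the allele balance
(AB, the alt-read fraction computed from AD) falls outside the heterozygote
window or below the alt-homozygote bound. All windows are applied exactly as
strict inequalities: heterozygotes need 0.3 < AB < 0.7 (open), alt
homozygotes need AB > 0.98. The printed homozygote rule can only refer to
alt homozygotes — AB is an alternate-allele fraction — so reference-homozygous
genotypes carry no AB filter at this stage; the separate parental AB < 0.03
bound belongs to de novo calling. AB is computed from AD rather than DP
because DP can include reads the caller internally discarded, which would
bias the fraction toward zero.

After masking, a site is dropped when its missing-genotype rate exceeds 10%,
when its FILTER field is neither `PASS` nor `.`, or when the exact
Hardy–Weinberg test falls below 1e-12. The HWE test is the two-sided exact
test conditional on allele counts, computed with the standard stable
recurrence over heterozygote counts; extreme departures at this threshold
indicate genotyping artifacts (e.g. collapsed paralogs), not biology.

**Design choice (open in the source method): founders only.** HWE is
computed on parents and unrelated controls, excluding probands, because case
genotypes can legitimately depart from equilibrium at disease-associated
sites. Either convention passes the QC-rate checks on simulated data; the
founders-only choice is the conservative one and is fixed here.

Genome-sequenced population controls are commonly filtered at a lower depth
minimum than exome samples; `qc_thresholds(dp_min_controls = 10)` applies
that override per genotype (not per site), since depth is a per-genotype
property.

Missing AD with a called genotype is handled by a dialect flag: `strict`
(default) masks the genotype, `lenient` skips AB-dependent filters for it.

## De novo calling and burden

A candidate de novo call requires, at a QC-passed site: proband heterozygous
with GQ ≥ 60, DP ≥ 20 and AB in the **closed** interval [0.3, 0.7]; both
parents homozygous-reference with GQ ≥ 25, DP ≥ 20 and AB < 0.03; and a
population allele frequency below 0.1%. Note the deliberate asymmetry with
cohort QC: the proband window here is closed, the cohort het window is open;
both are implemented literally. Sites where any trio member's genotype is
missing are skipped for that trio. An optional confirmation table models an
orthogonal second caller or wet-lab validation; by default all calls are
confirmed.

The burden test compares the observed de novo count in a class with its
expectation under a per-gene mutation-rate model:

$$E[X_c] = 2\,N_{\text{trios}} \sum_{g \in G} \mu_{g,c}$$

(two transmitted haplotypes per trio), with the p-value the upper Poisson
tail $P(X \ge x \mid \lambda = E[X_c])$. The tail is evaluated with
`stats::ppois(x - 1, lambda, lower.tail = FALSE)`, which is numerically
stable; tests cross-check it against direct probability-mass summation. With
zero expectation and a positive observation the enrichment is reported as
infinite and the p-value as 0 (below machine floor). The gene set is a
parameter: burden can be computed over the full panel or a subset.

The per-trio count dispersion check is a chi-square goodness of fit against
a Poisson with the sample-mean rate. Bins are pooled from the upper tail
(then the lower end) until each expected bin holds at least 5, and degrees
of freedom are `bins - 2`. With 52 trios at rate ~1.5 this typically yields
4 bins and 2 degrees of freedom; simulation shows the nominal 5% level
rejects within a factor ~2 of nominal, adequate for its screening role. A
cohort with no de novo calls at all is reported as a perfect fit rather than
an error.

Ti/Tv treats A↔G and C↔T as transitions and everything else among
single-base substitutions as transversions; with no transversions the ratio
is undefined and reported as `NA`, never as infinity.

## The digenic screen

The screen's population model is additive haploinsufficiency: two genes,
each intolerant of loss of one functional copy (pLI > 0.9, strict), each
carrying one rare (MAF < 0.5%, strict) heterozygous deleterious variant.
Deleterious means likely gene-disrupting (LGD: frameshift, nonsense, or
splice-site with ADA > 0.9) or deleterious missense (D-mis: DANN > 0.98);
the two classes are disjoint by construction. Genes on sex chromosomes are
excluded. Homozygous-alt genotypes do not qualify — the model is one damaged
allele per gene per haplotype — and an absent population frequency counts as
rare (the unseen-allele convention), with the decision logged.

Two literal-reading choices worth stating plainly:

* Canonical ±1/2 splice dinucleotides are **not** auto-promoted to LGD
  without an ADA score above 0.9. The stated rule is applied as printed; a
  site without a score is not LGD and the event is logged.
* The qualifying thresholds (0.9, 0.5%, 0.98, 0.9) are all strict
  inequalities, so boundary values are excluded.

**Pair enumeration.** For each proband, every unordered pair of qualifying
genes with at least one qualifying variant in each gene becomes a candidate
pair; all supporting variant couples are kept as evidence. For trio probands
the biparental rule restricts evidence to couples drawing one allele from
each parental haplotype: origins {paternal, maternal}, or either combined
with de novo, or {de novo, de novo} — a de novo allele occupies one
haplotype and therefore counts for either side. A variant carried by both
parents (or with an unusable parental genotype) has `unknown` origin and
cannot certify biparental transmission. Proband-only samples are never
restricted: origin is unknowable without parents, and the validation arm of
the design is precisely these samples.

**Exclusion.** A pair (A, B) is removed when any single unaffected
individual — a parent or a population control — carries qualifying variants
in both A and B. Exclusion operates at the gene-pair level rather than
requiring the exact same variants: that is the conservative reading of
"pairs also containing rare deleterious variants in unaffected individuals"
and maximally suppresses false positives. The operation is anti-monotone in
the control set (more controls can only remove more pairs), which is
property-tested.

**Scoring.** External combination-pathogenicity predictors are trained
models outside this package's scope, so the default scorer is an explicit,
transparent stand-in: for the best evidence couple, the mean per-variant
deleterious weight (1.0 for LGD, the DANN rank score for D-mis) multiplied
by the mean pLI of the two genes. It is monotone in both deleteriousness and
constraint and lands in [0, 1]. An externally supplied per-pair score
overrides it verbatim. Confidence zones (`neutral`, `candidate`, `zone99`,
`zone999`) are delimited by three ordered cutoffs, defaulting to 0.5 / 0.7 /
0.85. Four tiers require three boundaries; no published cutoffs exist for
the stand-in scale, so these defaults were chosen once such that the
simulator's planted pairs (weights ≥ 0.95, pLI ≥ 0.93) land in `zone999`
while typical background couples do not, and they are fully configurable.

**Recurrence.** Reported pairs (top zone, unexcluded, both genes brain- or
skeletal-expressed) are grouped across unrelated probands; pairs carried by
two or more probands form the recurrent tier, the rest a singleton tier. No
significance is attached to recurrence counts — at cohort sizes of ~10^2 the
screen is descriptive, matching its source design.

## The synthetic cohort generator

Defaults are the study conditions the package targets: 52 trios, 69
proband-only samples, 1,048 unrelated controls; a mean of 1.5 coding de novo
variants per proband (≈78 expected across the cohort, the scale of the
observed 80); transition probability 0.71 for de novo SNVs
(0.71/0.29 ≈ 2.45 expected Ti/Tv); and a default planting plan of two
case-specific digenic pairs in two trio probands each plus one decoy pair
also planted into controls.

What the generator emulates:

* founder genotypes drawn in Hardy–Weinberg equilibrium from a background
  allele-frequency mixture — a rare stratum from a truncated beta
  concentrated below 0.5% plus a common stratum (5–50%) so both the
  rare-qualification and the exclusion logic are exercised;
* Mendelian transmission into trio probands, so every non-planted proband
  alt allele has a carrier parent;
* per-genotype emission noise: Poisson depth (mean 60), binomial allelic
  depths (alt fraction 0.5 het / 0.002 hom-ref / 0.998 hom-alt), GQ jitter
  with 2% of background genotypes pushed below the GQ filter to exercise
  masking;
* planted truths emitted at fixed high confidence (DP 40, GQ 85, AB 0.5 for
  hets, zero alt reads for reference parents) so that truth remains
  recoverable under the default thresholds — recoverability is the contract
  the acceptance checks rely on;
* background sites in planted-pair genes forced benign (synonymous), so the
  planted signal is the only qualifying signal in those genes and
  planted-truth recovery is exact rather than probabilistic.

What it does **not** emulate: linkage disequilibrium, sequence-context
mutation models, shared haplotypes between relatives beyond single-site
transmission, batch effects, or read-level artifacts. Passing the
planted-truth checks therefore demonstrates the pipeline's logic is correct
under its stated assumptions, not that real-data error modes are handled;
the QC layer addresses those only through the threshold behaviors tested.

All randomness flows through a single seeded generator (`withr::with_seed`);
the gene panel uses the configured seed and the cohort stage seed + 1. File
writers use fixed field ordering and integer formatting, so a configuration
reproduces byte-identical fixtures with matching MD5 manifests.

## Numerical choices and degenerate inputs

* Reported percentages are rounded half-up to one decimal (41/121 → 33.9),
  matching conventional clinical-report arithmetic; base `round()`'s
  banker's rounding would differ at exact boundaries. Percentages are always
  recomputed from counts, never stored.
* The exact HWE test runs the linear recurrence from the modal heterozygote
  count and normalizes, with a `1 + 1e-9` tolerance factor when summing
  configurations "at most as probable" to absorb float ties; it agrees with
  a closed-form log-gamma enumeration to 1e-10 across all tables with up to
  50 diploids.
* Monomorphic sites have exactly one genotype configuration and p = 1; a
  site with zero genotyped founders is untestable and passes the HWE filter
  (it is still subject to the missingness filter).
* AB with zero summed allelic depth is undefined (`NA`), which fails strict
  AB filters and is never silently treated as 0.
* Gene-pair identity uppercases and strips whitespace from symbols; the same
  symbol on two chromosomes is a hard error.
* Empty inputs (empty VCF body, zero qualifying variants, empty control
  sets, empty planting plans) all produce valid empty results, and these
  paths are unit-tested.

## Problem sizes used by the test suite

Unit tests run miniature cohorts (1–8 trios, tens of sites) built in code.
The acceptance suite builds one full-size synthetic cohort — 52 trios, 69
singletons, 1,048 controls, ≈740 sites, ≈940k genotypes — through the
complete file round-trip (write VCF/PED/TSV, re-read, QC, both analyses),
checks the de novo caller against a naive triple-loop oracle on a ≈1,000-site
cohort, verifies burden-test calibration on 2,000 null replicates, and
validates the substitution spectrum on 20,000 draws. These sizes were chosen
as the smallest at which every claim is tested at the study's own scale.

## Known limitations

* The pair scorer is a stand-in, not a trained predictor; its zones order
  pairs sensibly but the absolute cutoffs carry no calibrated probability.
* Indel handling assumes left-aligned, biallelic-after-split records; no
  re-normalization is performed beyond the multiallelic split.
* The burden model takes mutation rates as given; it does not estimate them
  from sequence context.
* Parental phasing of de novo variants and trigenic or higher-order
  combinations are out of scope.
* Recurrence is reported without a significance model; treat the recurrent
  tier as a prioritization, not an inference.
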