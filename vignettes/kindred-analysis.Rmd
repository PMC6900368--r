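---
title: "Kindred analysis of severe hypercholesterolemia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kindred analysis of severe hypercholesterolemia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kindredscope)
```

Familial hypercholesterolemia (FH) is a monogenic disorder of LDL-receptor
mediated lipoprotein clearance. Heterozygotes are hypercholesterolemic
(mean LDL-C around 298 mg/dl); individuals carrying two deleterious
alleles of the same gene — homozygotes or compound heterozygotes — are
far more severely affected (mean around 625 mg/dl) and typically present
in childhood. Pinpointing the causal alleles in a kindred is a small-data,
high-structure problem: a handful of exome candidates, a pedigree with
lipid phenotypes, possibly a structural variant invisible to exome
capture, and a question about which population a mutant haplotype came
from. `kindredscope` implements that analysis as four testable stages
plus a synthetic-data generator that stands in for protected patient
genotypes.

## Variant prioritization

`run_cascade()` applies four rules in a fixed order and keeps an audit
trail of every variant it removes:

1. **Consequence.** Synonymous, intronic, intergenic and UTR calls are
   removed; missense, stop-gain, frameshift, in-frame indel and splicing
   calls survive.
2. **Read depth.** Variants supported by fewer than `min_depth` reads
   (default 20) are removed. The boundary is inclusive — depth exactly 20
   is kept, reading the conventional "low depth support" exclusion as a
   statement about the retained class. Missing depth removes the variant
   but is counted separately, because an unsupported call and a weakly
   supported call are different audit events.
3. **Candidate genes.** Intersection with a curated lipid-gene list,
   supplied as a plain text file. A bundled list covers the canonical FH
   and HDL/TG metabolism genes; real analyses should supply their own
   curation.
4. **Allele frequency.** A variant's frequency is aggregated across the
   configured databases (GnomAD, TOPMED, ExAC by default) by the
   *maximum* observed value — the most conservative choice when deciding
   that something is "common". Variants at or above `maf_cutoff`
   (default 1%) are discarded **unless** the predictor consensus calls
   them potentially damaging, in which case they are retained and
   flagged as exceptions. Variants with no frequency in any database are
   kept: absence from the databases cannot be evidence of commonness.

The predictor consensus (`consensus_scores()`) counts categorical calls
from the usual panel of missense predictors. `D`, `H` and `M` count as
damaging; `T`, `B`, `P`, `N` and `L` as benign (`P`, "possibly
damaging", is deliberately counted benign so the exception rule stays
strict); `U` and missing cells are non-calls and enter neither the
numerator nor the denominator — `U` is an explicit statement that the
predictor could not decide, and treating it as a benign vote would let
an uninformative predictor dilute real damaging evidence. A variant
with *no* scoreable predictor at all (typical for in-frame indels and
frameshifts, which SNV predictors do not score) is treated as
potentially damaging by the exception rule: a variant cannot be
declared benign by instruments that cannot see it. The damaging-fraction
threshold for the exception (default 0.5) and every other knob sit in
`filter_config()`.

Ranking of survivors is by damaging fraction, then meta-score
(MetaSVM by default), then genomic coordinate. Unscoreable variants
rank last among survivors rather than being dropped.

## Cosegregation search

`search_explanations()` asks which inheritance model over the candidate
variants best explains the pedigree's affection pattern. Affection
itself comes from `assign_affection()`: LDL-C at or above a cutoff.
Age- and sex-specific population percentile tables are the clinical
standard but are not redistributable; the default rule is a fixed
190 mg/dl for adults and 160 mg/dl for children (18 years as the
boundary), which reproduces the usual screening thresholds, and a
custom `(age, sex) -> cutoff` function can be plugged in. Missing lipid
panels yield `unknown`, never `unaffected`.

Three model families are enumerated:

* **Dominant single-variant**: carrier if and only if affected.
* **Recessive homozygous**: homozygotes must be affected and affected
  members must carry at least one allele. Heterozygous carriers are an
  *intermediate class* whose phenotype never contradicts the model —
  FH heterozygotes are themselves hypercholesterolemic, so requiring
  them to be unaffected would reject the true model in every FH
  kindred. A recessive model is only proposed when at least one member
  is actually homozygous; with no homozygote the model asserts nothing
  and would otherwise outrank genuine explanations simply by never
  being contradicted.
* **Compound heterozygous** (same-gene pairs): members carrying both
  variants *in trans* form the severe class and must be affected.
  Phase is derived from parental genotypes — one variant demonstrably
  inherited from each parent. If no parental genotypes resolve the
  phase the model is scored but flagged `phase_ambiguous` and ranks
  below phased explanations. Single carriers are the intermediate
  class, as above; an affected member carrying neither variant is the
  model's failure mode.

Models are ranked by: explains-all-affected, phased before ambiguous,
fewer inconsistencies, fewer variants, then model kind — recessive,
then compound, then dominant — then gene label. The kind preference
matters when one gene offers both a dominant and a recessive reading
with equal scores (every carrier affected, homozygotes present): the
recessive reading is preferred because it additionally explains *why*
the homozygotes are the severe cases, which is the clinical question
being asked. All of this is deterministic; permuting input rows or
pedigree members never changes the answer.

## Deletion junction and the multiplex screen

Breakpoint coordinates are 1-based *retained* bases: the last kept base
left of the deletion and the first kept base right of it, tagged with
their genome build (the package performs no liftover). With that
convention `deletion_length()` is `right - left - 1` — the only
convention under which a printed coordinate pair and its printed
deletion size agree — and is translation-invariant.
`characterize_junction()` anchors a junction-spanning read on both
flanks (at least 10 exact bases each side) and reports either a
non-templated insert (bases belonging to neither flank) or a
microhomology (identical flank ends that make the exact breakpoint
ambiguous); the two are mutually exclusive by construction.

`in_silico_pcr()` is deliberately minimal: exact primer matching on
both strands, no mismatch tolerance, no thermodynamics. The screening
assay's logic needs presence or absence of an amplicon, not its
efficiency, and exact matching keeps the oracle trivially checkable by
position arithmetic. Product size is the inclusive span between the
two primers' 5' ends; products above `max_product_bp` (default 1000)
are suppressed, which is also what makes the assay work: on the
wild-type allele the breakpoint-flanking pair spans the whole deleted
interval and is far too long to amplify, so the internal pair reports
the wild-type allele and the flanking pair reports the deletion.
`genotype_from_bands()` reads a lane: both diagnostic bands =
heterozygote, one band = the corresponding homozygote, no band = assay
failure; band sizes match within ±10 bp by default (a gel-resolution
proxy). `screen_cohort()` tallies a set of lanes and lists carriers.

## Population of origin for a phased block

The ancestry stage mirrors standard reference-panel practice. Panel QC
drops multi-allelic sites, sex chromosomes, and sites with overall
MAF below 0.05 ("below" read literally — exactly 0.05 is retained).
`ld_prune()` is the sliding-window pairwise pruner (window 1000 sites,
step 5, r² 0.5 by default); when a pair exceeds the threshold the
*later* site in position order is dropped, a deterministic rule chosen
because the reference tool's internal choice is unspecified.
`pca_project()` runs SVD on centered, binomial-scaled dosages with
per-site mean imputation and projects a query sample onto the panel
loadings.

The block-origin model is a per-site independent allele-frequency
likelihood with additive smoothing. For population $k$ with allele
counts $c$ out of $n_k$ panel chromosomes, an observed allele
contributes $\log\{(c + \alpha)/(n_k + 2\alpha)\}$ with $\alpha = 0.5$
by default; when the panel carries only frequencies, a nominal
$n_k = 100$ chromosomes is assumed. Per-population log-likelihoods are
normalized by a stable softmax with a uniform prior
(`population_posterior()`), yielding the "logistic probability" of
block origin. Site independence is an assumption the pipeline earns by
LD-pruning the panel first. The scored object is the *phased block* —
both haplotypes of the diploid genotype flanking the variant of
interest, summed (`block_logliks()`); the conditional probability of
the observed genotype given population frequencies is the inferential
target, and a single haplotype of realistic block length carries
roughly half the information, measurably degrading recovery. The
per-haplotype likelihood is exposed (`block_loglik()`) for targeted
questions about the variant-bearing haplotype alone. The model choices
— functional form, $\alpha$, the uniform prior — are this package's
own; they are deliberately simple, configurable, and validated by
parameter recovery rather than by appeal to any external
implementation.

`origin_recovery_experiment()` is that validation: per replicate it
simulates a fresh panel and a phased block from one known population
and asks whether the true population tops the posterior. Under the
default calibration grid (6 populations, $F_{ST}$ 0.05, 100-site
blocks, 100 diploids per population, 200 replicates) the test suite
requires at least 90% top-1 recovery and monotone accuracy in block
length. Accuracy rises with block length and with differentiation, and
saturates; at within-continent differentiation ($F_{ST}$ well below
0.05) longer blocks are needed for the same confidence.

## The synthetic generator

`simulate_panel()` uses the Balding-Nichols model: ancestral
frequencies uniform on (0.05, 0.95), population frequencies Beta
around them with one differentiation knob, genotypes binomial. It is
the simplest model with a controllable $F_{ST}$ analogue and is a
*surrogate* for a genotyped diversity panel — it has no LD, no
ascertainment bias, no admixture. Passing recovery tests on it shows
the inference machinery is correct and calibrated under its own
assumptions, not that real panels behave this way.

`simulate_pedigree()` transmits planted founder alleles through one of
two built-in structures: a compound-heterozygous kindred (one allele
entering through each grand-parental branch) and a consanguinity-like
kindred (both parents carriers of the same allele). Transmission is
Mendelian — one allele per parent per locus — and the kindred is
*ascertained through its proband* by rejection sampling: draws are
repeated until subject 1-1 carries the planted genotype, exactly as a
clinical kindred is only studied because its proband presented. The
rejection leaves all other meioses unbiased, which the transmission
tests verify.

`simulate_phenotypes()` assigns LDL-C by deleterious-allele count with
means 130 / 298 / 625 mg/dl for 0 / 1 / 2 alleles — the latter two
being the canonical heterozygous and homozygous FH means, the first an
unremarkable population value — and normal noise (default sd
40 mg/dl, a plausible within-class spread; at that spread a small
fraction of non-carriers can cross the pediatric cutoff, which is
realistic and is why the recovery guarantees are stated for low-noise
settings). HDL-C and triglycerides are drawn from unremarkable ranges
and total cholesterol is constructed so the Friedewald relation
(LDL-C = TC − HDL-C − TG/5, invalid at TG ≥ 400 mg/dl) reproduces the
drawn LDL-C exactly.

`simulate_sequences()` builds wild-type and deleted alleles around a
breakpoint specification (default: a 2,977 bp deletion with a TTCG
junction insert) with the assay's primer sites embedded at offsets
that reproduce the diagnostic product sizes; all sequence background
is random and seed-fixed.

All generators are byte-deterministic under a fixed seed.

## Worked examples and problem sizes

The bundled `inst/extdata` transcriptions of a published kindred
study's tables drive the worked examples: eight candidates per
proband, a compound-heterozygous explanation in kindred 1 that only
appears once the deletion genotypes are added, and a homozygous
frameshift explanation in kindred 2. Read depths and member ages are
not printed in the source tables; the fixtures carry a nominal passing
depth and plausible reconstructed ages, and the depth rule is
exercised by synthetic fixtures instead. The test suite's simulation
sizes — panels of a few hundred sites, 60–200 recovery replicates,
400 transmission draws — are chosen so the full suite runs in well
under a minute while keeping Monte-Carlo bounds at three standard
errors.

## Limitations

* Cosegregation is combinatorial screening, not linkage: no LOD
  scores, no penetrance estimation, no quantitative-trait modeling.
* The origin model ignores residual LD and drift since panel
  collection; it ranks candidate source populations, it does not date
  or place the mutation event.
* In-silico PCR is exact-match by design and will not predict products
  under primer-template mismatch.
* The affection rule's fixed cutoffs are a stand-in for age/sex
  percentile tables; conclusions near the cutoff deserve the real
  tables.
* Synthetic data validate correctness and calibration, not performance
  on real cohorts.
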