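---
title: "Mapping sex-stratified genetic regulation of the glucocorticoid response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping sex-stratified genetic regulation of the glucocorticoid response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Glucocorticoids released during the stress response act through the
glucocorticoid receptor (GR) to reprogram transcription in essentially every
tissue, including peripheral blood. A standard way to probe this system in
humans is a paired stimulation design: blood is drawn at baseline, the
participant receives a GR agonist (dexamethasone), and a second draw a few
hours later captures the immediate transcriptional response. Two questions
follow naturally:

1. Which transcripts respond to GR activation, and does the response differ
   between the sexes?
2. Which common genetic variants modulate the *change* in expression
   (GR-response eQTLs), and are those regulatory effects sex-specific?

`grqtl` implements this analysis end to end — paired differential
expression, cis-eQTL mapping with a permutation-based two-stage
multiple-testing correction, methylation-QTL overlap, MAF-matched
permutation enrichment, and a weighted allele-dosage profile score — plus a
synthetic-data module that generates cohorts with known ground truth so
every stage is testable without any external download.

## Differential GR-response expression

Expression is assumed to be on an already-normalized log2-like scale (as
produced by VSN-type normalization upstream; normalization itself is out of
scope here). Three per-probe least-squares models are available through
`fit_dea()`:

* **combined** — a long-format paired model of expression on a
  post-stimulation indicator, controlling for sex, age, BMI, case status,
  and surrogate covariates. The reported coefficient is the stimulation
  effect.
* **stratified** — the same model within one sex, omitting the sex term.
* **sex_effect** — the per-sample change `post − baseline` regressed on sex
  plus the same covariates.

The paired model is deliberately plain OLS with a per-sample stimulation
indicator and no per-subject term, matching the model formula as commonly
written for this design; `subject_effect = TRUE` adds per-subject fixed
effects as a sensitivity analysis. In simulations the two give essentially
identical stimulation estimates (the design is balanced), while the
subject-effect fit absorbs between-person baseline variance.

The per-sample change can be computed in two dialects (`compute_delta()`):
`difference` (default), which is a log2 fold change because the data are on
a log scale, and `standardized`, which additionally divides by the
per-probe baseline SD. The phrase "standardized to baseline" that floats
around this literature is genuinely ambiguous; both readings are
implemented and the default is the plain difference. Downstream summaries
(`threshold_fc()`) use an FDR threshold of 0.05 and an absolute log2
fold-change threshold of 0.2; reported percentages are rounded half-up
(`round_half_up()`), not banker's-rounded.

Multiple testing is Benjamini–Hochberg within each run (combined and each
stratum separately), so each analysis carries its own 5% FDR.

## cis-eQTL mapping and the two-stage correction

A cis pair is a SNP and a probe on the same chromosome within 1 Mb
(inclusive: a distance of exactly 1,000,000 is in). Covariates are removed
once, up front: `make_phenotype()` regresses each feature on the covariate
design and the residuals are the phenotype for everything that follows.
The scan itself (`scan_cis()`) is then simple regression of the residual on
allele dosage. (The alternative — refitting covariates in every SNP model —
gives identical slopes up to the usual Frisch–Waugh argument when the
covariates are the same; residualizing once is what makes genome-scale
scans tractable, and is what PLINK-style pipelines do.)

Because a cis region contains many correlated SNPs and the study tests many
regions, two corrections are stacked:

1. **SNP-level (within region): Westfall–Young maxT.** For each probe, the
   residual phenotype vector is permuted; the genotypes are never touched,
   so the LD structure is preserved exactly. For every permutation the |t|
   statistic is recomputed for all of the probe's SNPs;
   `empirical p = (1 + #{perm |t| ≥ obs})/(1 + n_perm)` and the
   maxT-adjusted p replaces the per-SNP |t| by the maximum across the
   probe's SNPs, controlling family-wise error within the region. The
   +1/+1 correction keeps p valid (never zero) under finite permutations.
   One shared permutation stream is used per probe across its SNPs, seeded
   by a named child stream of the master seed, so reruns are identical to
   the last digit. With `exhaustive = TRUE` all n! phenotype orders are
   enumerated instead and p values are exact proportions — this is how the
   implementation is checked against brute force at small n.
2. **Probe-level (across regions): BH on tag SNPs.** Testing every SNP–probe
   pair at the probe level would overcount regions with extensive LD, so
   the records are first reduced by greedy LD clumping
   (`clump_and_bin()`): ordered by ascending p (ties broken by position,
   then id), the best remaining SNP becomes a tag and every unassigned SNP
   with dosage r² > 0.2 within 1 Mb joins its bin; distinct tags are
   therefore pairwise correlated at r² ≤ 0.2. BH runs over the
   maxT-adjusted p values of tag records pooled within one analysis, and
   Q < 0.05 defines the significant set.

Two design choices deserve a note. First, clumping here is *global per
analysis* on each SNP's best p across probes, rather than repeated per
probe; this guarantees the tag-bin invariants (tags pairwise r² ≤ 0.2,
members within 1 Mb of their tag) and one bin per SNP, at the cost that a
bin's best SNP for a *secondary* probe may not be the global tag. Second,
the exact tie rule of PLINK's `clump` is not reproduced; ties in p are
broken by genomic position then id, which is deterministic and documented.

The permutation default is 10,000 per probe (`map_cis_qtl()`), a desk-scale
compromise; production analyses of real cohorts use orders of magnitude
more (the design this package targets used 500,000), and the parameter is
config-exposed. One practical interaction to be aware of: the smallest
achievable empirical p is `1/(n_perm + 1)`, so with few permutations and a
large tag family BH simply cannot reach Q < 0.05. The worked analyses in
the tests use 2,000–2,500 permutations against tag families of a few
hundred records, which leaves headroom of roughly an order of magnitude.

Sex-stratified scans run the same machinery per sex;
`interaction_scan()` additionally fits sex × dosage interactions on the
stratified hits. The meQTL scan (`scan_meqtl()`) reuses the cis machinery
on methylation beta values but applies plain BH at 5% FDR over all nominal
tests with no permutation stage, matching how large meQTL scans are
typically corrected.

## Enrichment analyses

`annotate_regions()` assigns each SNP exactly one genomic category by
precedence (promoter > 5′UTR > exon > intron > 3′UTR > downstream > distal
intergenic), and compares category membership between sexes with
per-category two-sided Fisher tests (in/out of category). A full
multi-category contingency test would be an alternative; the per-category
form is what is implemented because each category comparison is typically
reported on its own.

`maf_matched_enrichment()` is the workhorse: the overlap of a target SNP
set (e.g. tag GR-eSNPs of one sex) with an annotation interval set or a
GWAS SNP list is compared against `n_sets` (default 1000) null sets drawn
from a background pool (e.g. baseline tag eSNPs). Null sets are sampled
without replacement within folded-MAF bins of width 0.05, so every null
set's binned MAF histogram equals the target's *exactly*; a pool bin too
small to supply its quota is a hard error, never a silent relaxation. The
bin width is config-exposed since reasonable analyses could match more or
less finely. Fold enrichment is observed/null-mean; empirical p values get
the +1/+1 correction on both tails and BH across labels.

Coordinates follow the two conventions of the file formats: SNP and
feature tables are 1-based (VCF convention), interval sets are BED 0-based
half-open, and the conversion happens in exactly one place — a SNP at
1-based position p is inside `[start, end)` iff `start ≤ p − 1 < end`.

Gene-set overlap (`geneset_overlap_enrichment()`) reports the Jaccard
index and Fisher exact test over a declared universe, with
Haldane–Anscombe correction (flagged) when a zero cell makes the sample
odds ratio degenerate. `overrepresentation_test()` is a generic one-sided
hypergeometric test against user-supplied term→gene maps; nominal p values
are reported with no cross-term correction because ontology terms are
heavily nested.

## The transcriptional sensitivity profile score

For every significant tag GR-eQTL association, the *sensitive allele* is
the allele associated with the larger absolute expression change: the
dosage-counted allele when the coefficient is positive, the other allele
otherwise (`derive_weights()`). The weight is the absolute coefficient,
and an eSNP regulating k transcripts contributes k rows. The score of an
individual is the weighted sum of sensitive-allele dosages divided by the
number of *associations* — the default, because summing per association is
what "including each eQTL association" implies — with a `normalize =
"snps"` switch for per-unique-SNP correction, since the phrase "corrected
for the number of SNPs" admits both readings.

When scoring a cohort genotyped on a different platform,
`substitute_proxies()` replaces unavailable eSNPs by the best available
proxy at r² > 0.6. Allele orientation propagates through the signed LD
correlation when it is known; otherwise it falls back to allele-frequency
matching, and as a last resort keeps the original orientation with a
warning — frequency matching is ambiguous near MAF 0.5 and this caveat is
deliberately loud.

`associate_tsps()` fits logistic (binary status) or ordinary (continuous
symptom) regressions of phenotype on score plus covariates, reporting the
coefficient and a Nagelkerke or partial R²; `associate_tsps_items()` loops
over symptom items with BH across items.

## What the synthetic-data module emulates — and what it does not

`sim_config()` fixes the study conditions: a cohort of 289 individuals
with a 93/196 female/male split by default, two timepoints, MAF restricted
to [0.05, 0.5], three surrogate covariates, and sex-specific delta-acting
genetic effects of 0.5 (females) and 0 (males) expression units per dosage
unit. Noise is Gaussian on the normalized scale with SD 0.3 and the
per-probe stimulation shift has SD 0.3 — values chosen once to give
per-probe stimulation effects and eQTL signal-to-noise in the range such
paired designs typically show, and not revisited.

Genotypes are generated per LD block from a latent equicorrelated Gaussian
whose correlation is calibrated numerically (via the threshold bivariate
normal) so that the *realized dosage r²* matches `ld_r2` after
discretization to {0, 1, 2} at Hardy–Weinberg thresholds. One honest
limitation is intrinsic: r² between variants with different allele
frequencies is bounded above, so blocks whose SNPs span a wide MAF range
realize less than the nominal r² — exactly as in real data. Calibration is
exact at matched MAFs, which is how it is tested.

Features the generator does **not** emulate: recombination-map LD decay
(blocks are equicorrelated), population structure and relatedness,
X/Y chromosomes (the analysis targets autosomes), array batch artifacts
(surrogate covariates are generated, not estimated), multi-locus probes,
and dosage uncertainty (simulated dosages are hard calls; user data may be
fractional). Passing tests therefore demonstrate the statistical machinery
under the stated generative model, not robustness to those real-data
complications.

The annotation fixture (`make_annotation_fixtures()`) lays a 51-bp
interval over each covered SNP with coverage probability
`enriched_fraction` for a designated target subset and
`background_fraction` elsewhere; with ≥ 500 bp SNP spacing no interval
reaches a neighbouring SNP, so the ratio of construction fractions is the
expected downstream fold enrichment — the oracle used to validate the
enrichment stage.

## Numerical choices

* Permutation statistics are compared on |r| (monotone in |t| at fixed n)
  with a 1e-12 tolerance, so exact permutation ties — e.g. two individuals
  with identical genotype vectors — count consistently on both sides.
* Empirical and maxT p values use the +1/+1 correction except in
  exhaustive mode, where they are exact proportions over the full
  permutation group (identity included).
* r² for clumping and proxy search is the squared Pearson correlation of
  dosages; the simulators produce no missing data, and missing dosages in
  user data are a hard error at scoring time.
* Clump ties in p break by (chromosome, position, id); BH is always
  `stats::p.adjust(, "BH")`, checked against a brute-force oracle.
* Degenerate inputs fail loudly: monomorphic SNPs are dropped with a
  message, rank-deficient covariate designs name the collinear columns,
  constant covariates are dropped with a warning, empty q-significant sets
  make the fold-change percentage NaN with a warning, and a constant score
  refuses to be associated with anything.
* All randomness derives from one master seed via named child streams
  (`child_seed()`), so stage-level reruns reproduce pipeline-level
  results bit for bit.

## Problem sizes used by the tests

The test suite and the acceptance script size their simulations to run on
one CPU in a few minutes while keeping every check well-powered: cohorts
of 120–400 individuals (5,000 for the score recovery and the
Hardy–Weinberg checks), 30–120 SNPs in blocks of 5, 15–40 probes, and
2,000–2,500 permutations per probe. The FDR-control study uses 20
replicate cohorts with 5% true effects; the enrichment calibration uses
200 replicates of 99 null sets. These sizes are the package's own choice
of a desk-scale demonstration; all of them are parameters, and nothing in
the implementation depends on them.

## Known limitations

* The global greedy clumping can let a bin's best SNP for a secondary
  probe differ from the bin tag (see above).
* maxT controls family-wise error within a cis region under
  exchangeability of the residual phenotype; strong heteroscedasticity
  across individuals would violate that assumption (as it would for any
  permutation test of this form).
* The meQTL stage tests linear dosage effects on beta values directly;
  logit-scale effects near the boundaries are attenuated on the beta
  scale.
* Proxy allele alignment by frequency matching is unreliable near MAF 0.5
  and is flagged when used.
* `run_pipeline()` demonstrates the full workflow on synthetic data; real
  cohorts enter through the TSV/VCF/BED readers and the same stage
  functions, but upstream normalization, imputation and QC are assumed
  done.
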