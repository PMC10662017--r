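---
title: "Methods: quantifying exogenous microbial reads in tumor RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying exogenous microbial reads in tumor RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumormicro)
```

## The problem

Bulk RNA-seq of a tumor biopsy captures mostly human transcripts, but a
small fraction of reads originates from microbes living in or around the
tumor. Those reads are scientifically valuable — tumor-resident bacteria
and fungi have been associated with outcomes in several cancers — but
they sit at the edge of detectability, where reagent contamination,
index hopping, and batch structure can easily masquerade as biology.
`tumormicro` implements a conservative downstream pipeline for this
setting: it consumes taxonomic classifier output (Kraken2/Bracken
reports or a prebuilt taxon-by-sample count table), removes likely
contaminants in four modular phases, normalizes what survives, and then
only believes an association when it replicates — in significance *and*
direction — in two independent cohorts.

## Count tables and the minimum-read rule

Reports are parsed into a `taxon_count_table`: an integer taxa-by-sample
matrix with a full lineage per taxid and a per-sample count of
human-aligned reads. Per-rank tables use *clade* reads, which makes a
genus-level table consistent with the sum of its species rows and
matches the read-redistribution semantics of Bracken. A taxon
observation needs **more than 5 supporting reads** in a sample to be
believed; the rule is applied per (taxon, sample) entry by default,
which is the conservative reading — a taxon may be credible in one
sample and noise in another. A per-taxon-total mode
(`apply_min_reads(..., scope = "taxon_total")`) is available for users
who prefer cohort-level screening.

## Four contaminant filters

The filters run in a fixed order, and each one logs what it removed so a
run's read-loss accounting can be reconstructed from the
`removal_log.tsv` ledger:

1. **Microbial load.** A sample whose total microbial reads exceed 20%
   of its human reads is discarded as an extreme outlier (strict `>`;
   a sample at exactly 0.20 is kept). Genuine tumor biopsies are
   overwhelmingly human; such samples are better explained by failed
   host depletion or gross contamination.
2. **Small batches.** Samples are batched by the tuple (sequencing
   site, preservation method, flow cell); batches with fewer than 10
   samples are removed because within-batch contaminant statistics are
   meaningless at that size (exactly 10 is kept).
3. **Frequency test.** A reagent contaminant contributes a roughly
   fixed mass of nucleic acid, so its *relative* abundance scales
   inversely with input RNA concentration. For each taxon with at least
   5 samples of positive abundance and concentration, we compare two
   fixed-slope regressions of log abundance on log concentration — the
   contaminant model (slope −1) and the non-contaminant model (slope 0)
   — through the statistic λ = SS₁/(SS₁+SS₀). Significance comes from a
   permutation distribution (concentration labels permuted, 1,000
   draws, seeded) rather than a parametric reference: the permutation
   null is assumption-free and exactly reproducible. The screening
   threshold is p < 0.10 with no multiplicity correction — this is a
   deliberately liberal *screen* whose false positives cost little,
   mirroring the default of the frequency-based method it follows.
   When a cohort column is supplied the test runs within each cohort
   and a taxon is flagged if it screens positive in any of them.
4. **Literature lists.** A deny list of organisms recurrently found in
   sequencing negative controls adds flags; a spare list of taxa with
   strong literature precedence as human commensals removes them.
   Sparing always overrides denial, so a well-documented commensal
   survives even if it also behaves suspiciously. Matching is
   case-insensitive by exact name (against the taxon and its whole
   lineage chain), with an optional genus-prefix mode. The bundled
   lists under `inst/extdata/` are small synthetic stand-ins intended
   to be replaced or edited.

Prevalence-based (negative-control) contaminant testing is deliberately
absent: the data this pipeline targets ship without sequenced blanks.

## Normalization

Counts are transformed to log2 counts-per-million with the canonical
offsets, `log2((count + 0.5) / (library + 1) × 1e6)`, and
per-observation precision weights from a LOESS (span 0.5) mean–variance
trend — the published VOOM procedure, delegated to `limma::voom`. The
supervised normalization step then removes named technical covariates
(sequencing center, preservation method) while preserving named
biological ones (cancer type): per taxon, a weighted least-squares fit
on `[intercept | biological | technical]` one-hot covariates, with the
fitted technical component subtracted, the variance trend refit on the
adjusted values, and the cycle iterated to a 1e-6 max-norm tolerance on
the technical coefficients (cap 50 iterations; in practice 2–3
suffice). Because all covariates here are categorical, the spline
options of probe-level normalization tools are unnecessary; the
iterative two-block regression is the whole method. Covariates constant
within the fitted sample set (e.g. sequencing site inside a one-site
cohort) carry no information and are dropped from the design;
confounded designs (a technical variable aliased 1:1 with a biological
one) are refused with the aliased columns named, because "removing" such
a variable would silently remove the biology too.

Prevalence calls come from rarefied counts: each sample is subsampled
without replacement to the lowest retained library size (a single draw
with a recorded seed, not an average over draws — presence/absence is
reported from one concrete table), and a taxon is *present* when any
read supports it (count ≥ 1). The subsample is drawn in a canonical
taxon order so that reordering rows cannot change the result. With an
explicit depth, samples below it are dropped with a warning; with
`depth = "min"` nothing is dropped by construction.

## Associations and two-cohort concordance

Overall survival is modeled per taxon by a one-covariate Cox
proportional-hazards fit on presence/absence (Efron ties, since
day-resolution times tie frequently), tested by the likelihood ratio
against the null model. Degenerate strata — one-sided presence, no
events, monotone likelihoods — yield null results rather than errors,
because a pan-taxon scan must survive its worst rows. A
multi-threshold variant dichotomizes abundance at each decile and
re-tests, showing whether an association depends on one arbitrary
cutoff. Clinical covariates (age, BMI, hypoxia score, immune-cell
fractions) are tested by Spearman rank correlation with midranks for
ties and the t approximation for p-values. The hypoxia score is the
median-split metagene: +1 per signature gene above its cohort median,
−1 otherwise (ties score −1, by the strict inequality); the gene list
ships as an editable file rather than hard-coded.

P-values are corrected by Benjamini–Hochberg within the narrowest
defensible family — one (cohort, stratum, covariate, rank level) at a
time — so that a dense stratum cannot starve a sparse one of
discoveries. The concordance intersection then keeps results with
q < α in *both* cohorts and the same direction of effect. Under two
independent nulls this squares the per-cohort pass rate, which is why
the intersection suppresses false discoveries far below either
cohort's own FDR; the acceptance suite verifies ≤ 2 concordant hits in
≥ 95% of 100 null replicates at α = 0.05, alongside ≥ 0.7 recall of
planted survival effects (true log HR 1.0, n = 300 per cohort). A
raw-p mode exists for users who read "significant" unadjusted.

## Microbe–gene networks

All microbes are correlated with all genes (Spearman, computed in bulk
as Pearson on midranks) in each cohort. Pairs whose correlation sign
agrees across cohorts are *concordant*; the top and bottom 2.5% of
concordant pairs — ranked by the validation cohort's signed rho, with
ties at a cutoff all included — become network edges. Ranking by the
signed value rather than |rho| follows the "top and bottom" phrasing of
the selection rule; a mean-of-cohorts ranking mode is available.
Degree is the incident edge count; betweenness and closeness are
computed on the unweighted bipartite graph via igraph (closeness per
connected component by default, harmonic centrality as the global
option). The degree distribution diagnostic fits a discrete power-law
exponent by maximum likelihood over degrees ≥ dmin, with dmin chosen by
Kolmogorov–Smirnov minimization, and raises a heavy-tail flag when the
excess kurtosis exceeds 1 and the exponent lies in (1.5, 4). The
matched negative control generates the same analysis from iid standard
normal matrices (100×100 and 100×1,000 per cohort): its concordant
fraction sits at 0.5, its edge count at 5% of concordant pairs, and its
degree histogram is symmetric and light-tailed — whereas a planted hub
microbe (one taxon truly correlated with 200 genes at rho 0.5) tops
degree centrality in ≥ 95% of replicates and produces the heavy tail.
On that two-point fixture the ML exponent occasionally lands just above
4, so the flag is a strong-majority rather than an almost-sure event;
the kurtosis component is unambiguous. Enrichment of the genes linked
to a high-centrality microbe uses the preranked weighted
Kolmogorov–Smirnov running sum (weight exponent 1) with gene-label
permutations, delegated to `fgsea::fgseaSimple`, ranking genes by their
validation-cohort rho against the microbe.

## The synthetic cohort generator

Every stage is testable offline because `generate_cohort()` builds
complete cohorts with known truth: negative-binomial taxon counts
(dispersion 0.5, the overdispersion typical of classifier tables over
lognormal per-taxon means), lognormal input concentrations, planted
1/concentration contaminants with configurable lognormal noise (10%
CV), a multiplicative technical shift (log2 effect 2.0 on half the
taxa in FFPE samples), a biological shift tied to one cancer type,
exponential survival with per-sample hazard scaled by
exp(log HR × presence) for planted taxa and administrative censoring
tuned to ~40% observed events, and a latent-factor hub microbe whose
log abundance is shared with a chosen gene set. A truth ledger records
every planted parameter, so recovery tests never reach into the
generator's internals. `generate_cohort_pair()` draws two cohorts with
independent noise but identical truth — the discovery/validation
design — and the cohort label doubles as the sequencing-site technical
covariate.

What the generator does *not* emulate: phylogenetically structured
abundance correlations between taxa, read-level errors (no FASTQ),
realistic taxon name frequencies, non-proportional hazards, and
informative censoring. Passing tests therefore demonstrate that the
machinery recovers planted structure of the assumed forms at realistic
sizes and noise levels — not that real tumor cohorts satisfy those
forms.

## Numerical choices and problem sizes

Defaults: minimum-read threshold 5 (strict), load ratio 0.20 (strict),
minimum batch size 10, contaminant screen p < 0.10 with 1,000
permutations, concordance α = 0.05 on BH q-values, network tails 2.5%
per side, SNM tolerance 1e-6 with 50-iteration cap, rarefaction depth
"min". Tests and the acceptance script run the study-scale
configurations the properties are stated at — 200 taxa / 30
contaminants / 100 samples for the contaminant screen, 300 samples per
cohort for survival recovery, 100×100 and 100×1,000 matrices for the
network null — and scale replicate counts (50 null-concordance
replicates, 5–20 network replicates) to keep a full run in the low
minutes on one core. Every stochastic step takes an explicit seed, and
an identical configuration and seed reproduce a pipeline run directory
byte for byte; output files embed the configuration hash and seed in
their first line instead of timestamps for exactly that reason.

## Known limitations

The frequency screen needs input concentration metadata and at least 5
positive samples per taxon; taxa below that are never flagged. The
concordance intersection trades recall for precision by design — an
effect present in only one cohort is invisible to it. Survival models
use presence only, not abundance or spatial context, and no
treatment-conditional models are attempted. The power-law diagnostic is
a descriptive fit, not a hypothesis test, and is least reliable on
degree distributions that mix a narrow bulk with a single hub.
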