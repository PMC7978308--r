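---
title: "Methods: cohort genomic profiling of biliary tract carcinoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort genomic profiling of biliary tract carcinoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btcprof)
```

This vignette documents the models, parameter choices and numerical
decisions behind `btcprof`, in the order the pipeline runs them. It states
no empirical result beyond what the test suite and `scripts/acceptance.R`
themselves compute.

## Data model

A cohort is five cross-referenced tables keyed by `sample_id`: somatic
variants (1-based MAF-style coordinates; a `context_channel` code 0–95 is
present exactly for single-base substitutions), copy-number calls,
fusions, clinical records (subtype ICC/ECC/GBC, stage, hepatitis status,
platform WES/TPS, MSI-H and EGFR-IHC flags, germline pathogenic genes)
and therapy outcomes (best RECIST response, PFS2 with a censoring flag,
PFS1). Files are tab-separated UTF-8 with empty-string missing values and
`true`/`false` booleans; `write_cohort()` sorts rows deterministically so
identical cohorts serialize to identical bytes. Validation reports
offending rows and never drops them silently.

## Tumor mutation burden

`compute_tmb()` divides the number of counted mutations by the sequenced
region size in Mb. The default counting rule (nonsynonymous SNVs plus
small indels, synonymous and noncoding excluded) is a convention, not a
biological fact, so it is a parameter; panel assays differ on indels and
the rule can be switched per run. Region sizes are likewise parameters
with package defaults of 38 Mb (exome) and 1.5 Mb (panel) — any real
analysis should supply its assay's actual footprint. An optional VAF
floor is available because depth-dependent filtering is common at panel
depth; it is off by default and variants with missing VAF are never
dropped by it.

Hypermutation calling uses fixed platform thresholds, 9.36 Mut/Mb for
exomes and 16.1 Mut/Mb for panels, boundary inclusive. These constants
are inputs to the package, taken as given rather than re-derived; they
are deliberately not configurable per call so that every stage agrees on
the same definition.

## Mutational signatures

Catalogs are 96 × S matrices over the pyrimidine-centred trinucleotide
channels in COSMIC v3 ordering (six substitution classes, flanks
alphabetical within each). The ordering is a wire format shared with
reference files and the integer channel codes, so it is guarded by an
order-sensitive checksum rather than convention.

**Extraction.** `nmf_decompose()` implements Lee–Seung multiplicative
updates for the generalized Kullback–Leibler divergence — the natural
objective for Poisson-distributed counts. Choices: 50 random restarts by
default with the best objective kept (the likelihood surface is
multimodal); convergence when the relative objective improvement over 10
iterations falls below `tol` (default 1e-6, capped at `max_iter` = 2000);
the objective is re-checked every 10 iterations and any increase raises
an error, making the monotonicity invariant executable. After fitting,
profiles are rescaled to sum to one with the scale moved into exposures,
so exposures are in mutation units. Signatures are ordered by total
exposure for stable output.

**Rank selection.** For each candidate rank, `select_rank()` pools the
profiles of `n_restarts` random-start fits, clusters them into k groups
by partitioning around medoids on cosine dissimilarity, and scores the
rank by mean silhouette width. A rank must also improve the best KL
objective by more than 1% (relative) over the previous rank,
cumulatively: once improvement stalls, all larger ranks are disqualified.
The selected rank is the *largest* eligible rank with silhouette at least
0.9. Simply maximizing silhouette was rejected during design:
under-factorized solutions are themselves highly stable across restarts
(merging two true signatures the same way every time), so the most
stable rank is systematically too small; requiring stability at the
largest rank the data still reward matches how practitioners read these
diagnostics. A structureless catalog falls back to the smallest
candidate through the improvement gate.

**Matching and attribution.** Fitted profiles are matched to a
user-supplied reference catalog by cosine similarity. Per-sample presence
of a target signature (here the aristolochic-acid, SBS22-like,
A:T>T:A-dominant pattern) is decided by `attribute_signature()`: the
sample's counts are re-fitted non-negatively onto a fixed profile basis;
the null hypothesis — the catalog is explainable without the target — is
operationalized by re-fitting the counts *without* the target profile,
resampling `n_null` catalogs of the same size from that target-free
mixture, re-fitting each onto the full basis, and scoring the observed
target fraction against the null fractions (add-one-corrected empirical
p-value, BH adjustment across samples, positive at q < 0.05).

Two design points matter here. First, the null mixture comes from a
dedicated target-free re-fit of the data, not from the non-target
components of the full fit; the latter is depleted of whatever mass the
target profile absorbed and anti-conservative. Second, the pipeline
attributes against the *matched reference profiles*, not the de-novo
fitted ones. De-novo NMF trades overlapping channel mass between factors
(a fitted flat background tends to lose its A:T>T:A content to the
SBS22-like factor), which inflates the false-positive rate of any
presence test built on those profiles; with the reference basis the test
is calibrated, as the acceptance run verifies on pure-null samples.
Extraction therefore answers "which processes are active in this
cohort", and the reference basis answers "which samples carry the target
process" — the division of labour standard signature tooling uses. The
package ships a five-signature *synthetic* toy reference
(`synthetic_reference_signatures()`, also as
`inst/extdata/synthetic_reference_signatures.tsv`) so tests never
download anything; real analyses should point `read_signature_reference()`
at the COSMIC catalog.

Hypermutated samples are excluded from extraction by default (their
substitution spectra are dominated by the hypermutation process), as are
samples with fewer than 20 context substitutions, which carry too little
information for a 96-channel fit; both filters are parameters.

## Association statistics

Pairwise gene tests use the two-sided Fisher exact test with the
"probability mass no larger than observed" rule (the `stats::fisher.test`
convention; documented because two-sided conventions differ). The
reported odds ratio is the sample cross-product ad/bc — infinite or zero
on zero cells, with a Haldane 0.5 correction available by flag — rather
than the conditional MLE, because the cross-product is what the 2 × 2
cells display. BH adjustment is applied across all pairs and a direction
is called only below the FDR cutoff. Group TMB comparisons use the Welch
unequal-variance t-test ("unpaired" leaves the variance assumption open;
Welch is the robust default and the difference is negligible at cohort
sizes); the degenerate both-groups-constant case returns t = 0, p = 1.

## DDR classification

A sample is DDR-mutant iff it carries at least one counted nonsynonymous
variant in a mapped gene. The shipped map has 47 genes over TP53 plus
eight functional families (checkpoint factors, Fanconi anemia, mismatch
repair, homologous recombination, nucleotide and base excision repair,
non-homologous end joining, other); it is an editable, partly
non-canonical reconstruction — the curated list it stands in for is not
public — and the loader only warns when a user map deviates from the
47/8 shape. For the cohort summary, mutants split into "TP53-attributed"
(TP53 is the only pathway hit) and a "non-TP53 pool" (any non-TP53
pathway involvement, with or without TP53). That attribution is the only
reading under which mutants = TP53 + non-TP53 as a clean subtraction,
which is how such cohorts report the split; the finer four-way status is
retained internally.

## Actionability

The knowledge base is an editable YAML of (target, alteration class)
entries with an OncoKB level, an ESCAT tier, an optional locus window on
variant positions, and a drug hint; the shipped file names 19 PAT genes
plus MSI-H and is synthetic in the same sense as the DDR map — tiers are
package defaults to be reconciled against the live databases. A PAT is
any entry at OncoKB ≤ level-3A or ESCAT ≤ tier II-B. Matching semantics:
activating entries match missense and in-frame indels, truncating
entries match nonsense/frameshift/splice, SCNA and fusion entries match
their tables, and MSI-H fires on the clinical flag.

Prioritization needs a total order across two incommensurate scales. The
merged rank IA < L1 < IB < IC < L2 < IIA < IIB < L3A < L3B ≈ IIIA < IV ≈
L4 is the minimal order consistent with MTB practice in which an ESCAT
I-C biomarker (MSI-H, pembrolizumab) outranks an OncoKB level-2
amplification; it is overridable per call. Rule III suppresses EGFR
calls without IHC 2+/3+ overexpression (missing IHC counts as absent,
the conservative reading). Ties break alphabetically so the
recommendation is a deterministic total order.

## Therapy outcomes

Responders are CR/PR; percents round half-up at one decimal (matching
clinical reporting, where 12/46 prints as 26.1%, not R's banker's
rounding). Kaplan-Meier estimation and the log-rank test delegate to the
`survival` package; the median is the smallest time with S(t) ≤ 0.5 and
its confidence interval is Brookmeyer-Crowley on the log-log scale. The
benefit rule is PFS2/PFS1 ≥ 1.3, boundary inclusive. Patients without a
measurable PFS1 are excluded from the benefit denominator; censored PFS2
durations are excluded too by default (a censored PFS2 only bounds the
ratio from below) with the count reported, and can be included by flag.
With no events at all the log-rank statistic is 0 by convention.

## The synthetic cohort generator

`btc_cohort_config()` encodes the study conditions the generator
emulates: 803 patients at subtype proportions 475/164/164 (ICC/ECC/GBC)
and platform proportions 160/643 (WES/panel); log-normal TMB with median
1.23 Mut/Mb and IQR 0.7–2.34 (the log-sd follows from the IQR), with a
4.1% hypermutated tail placed at or above the platform threshold;
driver frequencies led by TP53 53% and KRAS 26%; planted co-occurrence
(TP53:CDKN2A, KRAS:SMAD4, log-odds +1) and exclusivity (TP53:ARID1A −2,
KRAS:LRP1B −1.5); a three-signature mixture (CpG C>T clock-like,
SBS22-like, flat) with 35.8% of ICCs AA-positive; actionable-alteration
frequencies around the prevalences such cohorts report (amplified MET and
ERBB2 at ~5%, IDH1 mutations at 7%, FGFR2/3 fusions at 3%/1% of panel
samples); MSI-H at 10/803; germline pathogenic genes led by PRSS1,
BRCA2, MUTYH; and outcomes with median PFS2 5.0 months, responder
fraction 12/46 and 9/46 unmeasurable PFS1.

Choices the emulated conditions do not pin down, fixed once at design
time: per-sample signature exposures are Dirichlet (concentration
(2, 6, 2) for AA-positive ICCs, (4, 0, 4) with an exact zero on the AA
component otherwise); PFS1 is exponential with median 2.5 months; PFS2
censoring is independent exponential with an expected 20% censored
fraction (the censoring rate is solved from that fraction); treated
patients are PAT carriers sampled at 46/204; driver variant classes are
60/20/20 missense/nonsense/frameshift.

Mechanics worth knowing when reading recovery tests. Gene statuses follow
an Ising-style pairwise model — independent Bernoulli base measures
tilted by exp(θ·x_a·x_b) per pair — sampled exactly by enumerating the
2^m states of each connected pair-graph component; tilting shifts the
marginals, so the generator returns the exact tilted marginals as part
of the truth. Mutation counts are TMB × region size with stochastic
rounding, and are nudged to the planted side of the hypermutation
threshold (ceiling for planted-hypermutated samples, a one-mutation cap
below the cutoff otherwise) so the planted and called flags coincide
deterministically rather than flipping on boundary noise at panel scale.
Genes the knowledge base recognizes by mutation class are planted only
through the actionable-alteration spec, never through the driver
frequencies, so every planted prevalence has a single source; fusions
are planted only on panel samples, which is also the platform on which
the pipeline computes fusion prevalence.

**What the generator does not emulate.** Positions are arbitrary
integers on one chromosome; there is no linkage between TMB and DDR or
AA status (real cohorts report higher TMB in both groups), no
subtype-specific driver frequencies beyond AA being ICC-only, no
germline-somatic correlation, and no signature for the hypermutated
samples' own substitution spectrum. Passing recovery tests therefore
show the estimators are correct under the planted model — not that the
pipeline would reproduce any particular real cohort's biology.

## Problem sizes

The test suite and acceptance script use sizes chosen to make sampling
error small relative to the tolerances while keeping runs comfortable on
one CPU: planted-signature recovery on 150 samples with 50 + Poisson(150)
substitutions each and uniform-simplex exposures; attribution
calibration on 500 pure-null samples with 100 null resamples each; the
Fisher oracle exhaustively over all 46,375 tables with total ≤ 30;
end-to-end recovery on a 2000-sample cohort with every planted
prevalence checked within three binomial standard deviations.

## Known limitations

The NMF rank rule's two constants (1% improvement, 0.9 silhouette) are
diagnostics thresholds, not statistics with error control; for ranks far
beyond the truth the silhouette gate does the work. Attribution p-values
are empirical with `n_null` resolution, so FDR control is approximate at
small `n_null` (the function warns below 100). The shipped DDR map and
PAT knowledge base are reconstructions and must be replaced with curated
versions for any substantive use. The merged OncoKB/ESCAT order encodes
one defensible reading of cross-scale MTB practice; where a tumor board
disagrees, the order is a parameter.
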