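---
title: "Chemoproteomic probe-capture analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemoproteomic probe-capture analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probeCapture)
```

## The analysis problem

Affinity-based chemoproteomics asks which proteins of a complex proteome bind
a small-molecule probe. Flavonol-bearing probes (two quercetin isomers, Q8 and
Q6, differing in the linker attachment position, and a kaempferol probe K8)
are incubated with a microsomal protein fraction, captured on streptavidin
beads — either after oxidative activation of the probe (method O, covalent
capture) or without it (method N, affinity-only capture) — and the retained
proteins are identified and quantified by label-free shotgun proteomics.
Probe-less vehicle controls measure nonspecific bead binding. Every sample is
prepared in triplicate.

`probeCapture` implements the downstream data analysis: from a peptide-level
intensity report to tiered capture-significance calls, probe and method
comparisons, probe-selectivity volcano statistics, annotation-based candidate
screening, and sequence-similarity shortlisting of candidate flavonoid
enzymes such as the sought-after flavonol 8-hydroxylase (F8H).

## Quantification model

Protein abundance in a sample is the **sum of unique peptide intensities**.
Peptides mapping to more than one accession are excluded from every protein's
sum — a strict-uniqueness rule chosen because it is conservative and
insensitive to how redundant database entries are grouped. A protein with no
observed unique peptide in a sample is *missing* there, a state deliberately
distinct from zero: label-free data are left-censored, and absence below the
detection limit carries information that later feeds the absent-in-control
branch of the significance call. Missing values are never imputed.

Columns are normalized on total protein amounts: each sample is rescaled so
its observed total equals the grand mean of column totals. Any common target
preserves within-sample ratios; the grand mean keeps the matrix on the scale
of the raw data and makes the operation idempotent. Proteins are retained
only when quantified by at least two unique peptides (`filterMinPeptides()`,
default `k = 2`); the count is taken as the maximum over samples, so a
protein confidently seen in any one sample is not discarded because it is
sparse elsewhere.

Fold changes are ratios of group means of replicate abundances (a
`groupFun = "median"` switch is provided), and per-protein p-values come from
one-way fixed-effects ANOVA on log2-transformed abundances — intensities are
multiplicative, so the linear model is fit on the log scale (a
`log2Transform = FALSE` switch exists since the transform used by the
original processing software is not documented). With two groups this ANOVA
is exactly the pooled-variance t-test (F = t²), which the test suite checks
numerically. A p-value is undefined when any group has fewer than two
observed values, or when all groups are constant; undefined values propagate
as `NA` flags, never as fabricated numbers.

## The tiered capture call

For each capture assay against its probe-less control, every protein passing
a replicate-reproducibility filter (detected in at least 2 of 3 capture
replicates, the weakest majority rule; configurable) is classified, in order
of precedence:

1. **highly significant, absent from control** — not detected in any control
   replicate (the literal reading of "not present in the negative control";
   the allowed control count is configurable via `maxControlDetected`);
2. **highly significant, enriched** — `log2(r) > 2` *and* `-log10(p) > 2.5`,
   both strict, as printed;
3. **significant** — `p < 0.05`;
4. **detected** — everything else, including proteins whose r or p is
   undefined.

The `-log(p)` cut is read in base 10: `-log10(0.05) ≈ 1.3`, so a 2.5 cut
(p ≈ 0.0032) tightens the p < 0.05 gate, whereas a natural-log reading
(p ≈ 0.082) would weaken it, which would make the rule internally
inconsistent. The classification is a total function — every (r, p,
detection) combination maps to exactly one class — and is monotone: raising
r or lowering p never demotes a protein.

## Probe and method comparisons

Captured-protein sets are compared across probes and methods with exact Venn
region counts (`setOverlap()`, k ≤ 3). When proteins are absent from the
negative controls, the capture/control fold change cannot rank probes against
each other; `probeSelectivity()` therefore contrasts the two capture samples
directly: `lg2_r` is the log2 ratio of mean abundance under probe A vs probe
B, with a two-group p-value from the same ANOVA machinery. Only proteins
highly significant under **both** probes and absent from the controls are
eligible; eligible proteins missing in every replicate of one probe are
reported in a side table ("exclusively captured") instead of being forced
into the volcano with an infinite ratio. No pairwise renormalization is
applied on top of the global total-amount normalization. Swapping the probes
mirrors the volcano exactly (ratios negate, p-values are unchanged).

## Annotation screen and enrichment

Candidates are binned into oxidases (A), methyltransferases (B) and
glycosyltransferases (C) by case-insensitive keyword search over the protein
description and the names of its GO and InterPro terms, with priority
A > B > C on multiple matches and D for everything else. The default keyword
lists (`defaultScreenKeywords()`) name the enzyme families searched for among
flavonoid-pathway candidates and are fully overridable — which vocabulary the
original screen used, and whether term names were searched, is an explicit
interpretation. Cross-assay tables are keyed to a reference proteome through
a homologue map; when transcriptome redundancy maps two local accessions to
one reference protein, the cell with the lower p-value wins. GO
overrepresentation uses the one-sided hypergeometric test with
Benjamini–Hochberg adjustment — the minimal standard method, chosen because
the original analysis names no tool; results are therefore comparable
qualitatively, not numerically. No GO-graph propagation to ancestor terms is
performed.

## Similarity shortlisting

Local alignment of captured proteins against known flavonol hydroxylase
queries uses Smith–Waterman with affine gaps (BLOSUM62, gap open 11, extend
1 — protein BLAST defaults), via `Biostrings::pairwiseAlignment`; the test
suite cross-checks the scores against an independently written quadratic
dynamic-programming oracle. Raw Smith–Waterman scores are *not* calibrated to
BLAST bit scores, so the high/low tier cuts (defaults 500/300) are
configuration, not constants, and `parseBlastTabular()` ingests real BLAST
`-outfmt 6` output (bit scores, E-values carried through, never computed
in-package) as the fidelity route. `crossrefShortlist()` joins alignment hits
with capture calls and ranks by capture-class severity (both
highly-significant branches first, then significant), then score, with
lexicographic accession tie-breaks so the order is total.

## What the synthetic-data generator emulates

Because the study's raw data require a commercial search engine and specific
database versions to reprocess, the package ships a generative model of the
*statistical structure* of such experiments, used by every recovery and
calibration test:

* log-normal base peptide intensity, `meanlog = 14`, `sdlog = 1.0` (natural
  log; a realistic multi-order-of-magnitude LFQ dynamic range), with
  `1 + Poisson(6)` peptides per protein;
* true binders (10% of 500 proteins by default) are shifted down by 3
  natural-log units — capture targets here are low-abundance membrane
  enzymes — and multiplied in capture samples by the enrichment fold (16) ×
  probe affinity (Q8 = 4, Q6 = 1, K8 = 0.25, i.e. 16:4:1 selectivity and a
  4× Q8:Q6 ratio) × method efficiency (1 for O, 0.5 for N);
* multiplicative replicate noise with 20% CV;
* left-censoring through a logistic detection probability on log intensity
  (midpoint 14, slope 8). The midpoint sits between the binder base
  distribution and the abundant background, which mechanistically reproduces
  the central phenomenon of the assay: binders are absent from probe-less
  controls while the nonspecific background is detected everywhere.
  Censoring is the only source of missingness; missing rows are absent from
  the report, never zero.

The detection geometry was chosen structurally: if the midpoint sits inside
the binder base distribution, many binders land in a one-control-replicate
state where the ANOVA p is undefined and the tiered call can only say
"detected"; if it sits inside the binder *capture* distribution, binders fail
the two-peptide filter. The defaults place it between the two and were fixed
once during generator design.

Enrichment folds are free parameters of the generator, not estimates of the
study's real effect sizes, which are unknown. Sequences for similarity tiers
are point-mutated copies of a generated query sequence at 90/60/30% identity,
assigned to binders and non-binders alike so that score tiers exist among
captured and uncaptured proteins. The redundant-database variant duplicates a
configurable fraction of accessions and reports their peptides against both,
exercising the shared-peptide exclusion path.

What the generator does **not** emulate: peptide-level identification error
(the 1% FDR filter is upstream of this pipeline), retention-time or
match-between-runs structure, correlated peptide responses within a protein,
interference/ratio compression, and post-translational modifications. Passing
recovery tests therefore show that the statistical pipeline is correct and
calibrated under its own assumptions, not that those assumptions exhaust real
LFQ data.

## Numerical choices and degenerate inputs

* Normalization tolerance: column totals agree to 1e-9 relative; the
  operation is exactly idempotent up to floating-point rounding.
* Ratio flags: absence in all numerator/denominator samples produces
  `absent_in_numerator` / `absent_in_denominator` flags, never `Inf`/0.
* Zero-variance ANOVA inputs give `NA`, not p = 0.
* Local alignment scores floor at 0 (empty alignment); gap cost of a
  length-L gap is `open + L·extend`.
* Shortlist ties break lexicographically by accession; heatmap redundancy
  collapse breaks p-ties toward the larger fold change.
* All tables are TSV (UTF-8, header row, `NA` for missing) with fixed column
  orders, so reruns can be diffed byte for byte; `runPipeline()` with a fixed
  seed is deterministic end to end.

One observation from the simulations is worth recording: total-amount
normalization introduces a compositional bias in capture samples — the
enriched binders inflate the capture totals, so after normalization the
nonspecific background sits slightly *below* its control level and can reach
nominal ANOVA significance in a binder-rich assay. The bias is directed away
from the enrichment thresholds, so the highly-significant tier is unaffected
(false-discovery proportion stays below 1% in the recovery runs), but counts
of the plain "significant" tier should be interpreted with this in mind.
This mirrors the behaviour of any pipeline that normalizes enriched samples
on total amounts.

## Problem sizes used in validation

Recovery and calibration experiments run the default 500-protein
configuration over 25 seeds (spike-in recovery, null calibration); oracle
comparisons use 100–200 randomized instances per operation (ANOVA, Venn
regions, Smith–Waterman, hypergeometric tail). These sizes give Monte-Carlo
standard errors an order of magnitude below the acceptance margins while
keeping a full run of the suite in the low minutes on one CPU.

## Known limitations

* The per-assay capture calls apply no multiple-testing correction across
  proteins, mirroring the original procedure; the GO enrichment does (BH).
* In-package alignment scores are raw Smith–Waterman, so the 500/300 tier
  cuts only correspond to published bit-score tiers when BLAST output is
  ingested.
* The probe-selectivity eligibility rule (highly significant under both
  probes, absent from controls) cannot be verified against the study's exact
  protein list without reprocessing the deposited raw data; it is a faithful
  implementation of the stated rule, parameterized where the text is silent.
* `oneway.test` underlies the ANOVA; heteroscedastic alternatives (Welch)
  are deliberately not exposed, as the fixed-effects equal-variance form is
  what grouped LFQ ratios assume.

## A minimal session

```{r example, eval = FALSE}
cfg <- pipelineConfig(simulation = simulationConfig(seed = 1),
                      outDir = "capture_run")
bundle <- runPipeline(cfg)
bundle$summary              # per-assay class counts
head(bundle$shortlist$shortlist)  # capture x similarity candidates
```
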