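# probeCapture

Analysis of affinity-based chemoproteomic capture experiments with label-free
quantification (LFQ), built for probe-target deconvolution studies in plant
specialized metabolism: flavonol-bearing probes (quercetin isomers **Q8** and
**Q6**, kaempferol **K8**) are used to fish candidate flavonoid enzymes —
e.g. the unknown flavonol 8-hydroxylase (F8H) of Asteraceae — out of
microsomal proteomes, with probe-less vehicle controls measuring nonspecific
bead binding and capture run with (**O**) or without (**N**) oxidative probe
activation.

The package takes a peptide-level intensity report (as exported downstream of
any search engine) and a sample design, and produces:

* a normalized protein × sample abundance matrix (`CaptureExperiment`, a
  `SummarizedExperiment` with `abundance` and unique-peptide-count assays);
* tiered capture-significance calls per assay;
* probe/method set comparisons (Venn regions) and probe-vs-probe selectivity
  volcano statistics;
* an annotation-keyword candidate screen with GO-term enrichment;
* sequence-similarity shortlists of candidates (in-package Smith–Waterman or
  ingested BLAST tabular output).

A ground-truthed synthetic-data generator with realistic left-censored
missingness makes every stage testable end to end.

## The statistics at the core

Protein abundance is the sum of unique peptide intensities; samples are
normalized on total protein amounts; proteins need ≥ 2 unique peptides. For a
capture assay against its probe-less control, with fold change
*r* = mean(capture)/mean(control) and a one-way ANOVA p-value on log2
abundances, a reproducibly captured protein (≥ 2 of 3 capture replicates) is
called **highly significant** when

* it is not detected in any control replicate, **or**
* log2(*r*) > 2 **and** −log10(*p*) > 2.5 (both strict),

falling back to **significant** (*p* < 0.05) and **detected** otherwise.
When binders are absent from the controls, probes are ranked against each
other instead: the selectivity volcano plots lg2(*r*) of probe-A vs probe-B
capture abundance against −log10(*p*) from the same two-group ANOVA
(equivalent to a pooled t-test). GO overrepresentation is hypergeometric with
Benjamini–Hochberg adjustment; local alignment is Smith–Waterman with affine
gaps (BLOSUM62, 11/1 — protein BLAST defaults).

## Worked example

Simulate the reference experiment (500 proteins, 10% true binders, 16-fold
enrichment, probe affinities Q8:Q6:K8 = 16:4:1, triplicates plus controls)
and run the full pipeline:

```r
library(probeCapture)
cfg <- pipelineConfig(simulation = simulationConfig(seed = 1),
                      outDir = "capture_run")
bundle <- runPipeline(cfg)
bundle$summary
#>            assay not_detected detected significant highly_significant_enriched
#> 1 Rudbeckia.Q8.O            4      233         193                           0
#> 2 Rudbeckia.Q6.O            8      390          37                           0
#> 3 Rudbeckia.K8.O           38      411          15                           0
#>   highly_significant_absent_control highly_significant evaluated
#> 1                                49                 49       479
#> 2                                44                 44       479
#> 3                                15                 15       479
```

Of 479 proteins quantified with ≥ 2 peptides, the strong quercetin probe Q8
captures 49 highly significant proteins (here all through the
absent-in-control branch: the simulated binders are low-abundance enzymes
below detection in the vehicle controls), Q6 captures 44, and the kaempferol
probe K8 only 15 — the probe-affinity ladder the simulation encodes. The Venn
table (`bundle$venn`) shows 44 proteins shared by both quercetin probes and
only 5 exclusive to Q8. The candidate shortlist joins capture calls with
similarity to the flavonol 6-hydroxylase-like query sequence:

```r
head(bundle$shortlist$shortlist[, c("accession", "score", "tier", "capture_class", "rank")])
#>   accession score tier                     capture_class rank
#> 1  PROT0079  1548 high highly_significant_absent_control    1
#> 2  PROT0463  1547 high highly_significant_absent_control    2
#> 3  PROT0085   856 high highly_significant_absent_control    3
#> 4  PROT0329   856 high highly_significant_absent_control    4
#> 5  PROT0485   259  low highly_significant_absent_control    5
#> 6  PROT0471   224  low highly_significant_absent_control    6
```

The two top-ranked entries are the simulated 90%-identity homologs of the
query that were also spiked as binders — the "captured **and**
query-similar" candidates the combined capture/BLAST strategy is designed to
surface. GO enrichment on the captured set recovers the oxidoreductase term
(p = 2.6e-4, BH-adjusted 1.0e-3) as expected for a screen whose binders lean
toward oxidases.

All outputs are also written as TSV files plus a JSON manifest under
`outDir`; identical configuration and seed give a byte-identical bundle.

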