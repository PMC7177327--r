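---
title: "Methods: models, parameters and design choices in perimir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in perimir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perimir)
```

perimir implements the quantitative backbone of a chronic traumatic brain
injury (TBI) microRNA study: how strongly a brain-enriched, neuronal miRNA
(miR-124-3p) is downregulated in the cortex next to a lesion, and what that
implies for its target transcripts. Because the original tissue images and
sequencing data are not deposited anywhere, every stage is paired with a
synthetic-data generator that plants known effects, so the pipeline is
validated by parameter recovery rather than by re-analysis of raw data.
This vignette documents the models, the tunable parameters and the design
decisions, in that order of importance.

## Relative quantification by 2^-ddCt

For each sample the target assay is normalized to an endogenous control
(miR-378 for the miRNA, Gapdh for the mRNA target):
dCt_i = Ct_i(target) − Ct_i(reference). The group contrast is the Livak
estimator ddCt = mean dCt(case) − mean dCt(control), and the fold change
is 2^−ddCt. We use the group-mean formulation (the classical one) rather
than per-sample ratios; the two coincide in expectation and the group-mean
version is the one the common instrument software reports. Per-sample
relative quantities 2^−(dCt_i − mean dCt(control)) are kept for plotting,
so the control group averages 1 on the dCt scale.

Two properties are worth knowing when interpreting results:

* ddCt is invariant to adding a constant to all Ct values of one assay —
  plate-level offsets cancel.
* swapping case and control inverts the fold change exactly.

The synthetic Ct generator plants a fold change by shifting the case-group
dCt center by −log2(FC) and splits Gaussian noise evenly between the two
assays so that sd(dCt) equals the scenario's `ct_sd`. The packaged
scenarios use `ct_sd = 0.3` cycles with n = 6 vs 6 — a typical
between-animal spread for brain qPCR; the source study does not report
per-group Ct variances, so this is a package choice, made once.
Outlier screening uses the two-sided single-pass Grubbs test
(G = max|x−mean|/s against the t-based critical value), matching the
common online calculator convention: one candidate, no recursion.

## Per-cell ISH intensity over perilesional sectors

Chromogenic in situ hybridization produces dark staining where the miRNA
is abundant. The per-cell measure is the background-normalized intensity

> (mean gray of background ROI − mean gray of the cell) / mean gray of background ROI,

which is 0 for an unstained region, positive for stained (darker) cells,
and invariant to global linear rescaling of the image when the background
is measured on the same image. Negative values (cells lighter than
background) are retained and flagged, never clamped.

Cells are detected as connected components of pixels below a fixed gray
threshold, filtered to an area window (default 40–1000 µm²). The original
analysis used a manually adjusted color threshold in ImageJ; we fix an
explicit grayscale threshold so the procedure is deterministic — a
deliberate trade of fidelity-to-manual-steps for reproducibility. The
background ROI in the tissue study was a reference structure (fimbria)
that synthetic scenes do not have, so the default background estimate is
the mean gray over all pixels outside the one-pixel-dilated cell mask;
a caller-supplied background value overrides it.

The analysis window is a 1000-µm-wide sector starting at the lesion edge,
split 2×2 into proximal/distal × deep/superficial quadrants (s1 proximal
deep, s2 proximal superficial, s3 distal deep, s4 distal superficial),
with half-open boundaries and splits at the midpoints by default. The
source figures pair s1/s3 as deep and s2/s4 as superficial but never state
the grid explicitly; the 2×2 midpoint layout is our reading, and both
split coordinates are parameters. The human patchy-loss analysis uses the
same machinery with two windows (inside/outside the patch); window width
is a parameter because the study used 1000 µm sectors in one analysis and
100 µm in another.

Group comparisons follow the study's nonparametric scheme: Kruskal–Wallis
omnibus across groups, pairwise Mann–Whitney U afterwards, Spearman for
correlations. Mann–Whitney p-values are exact (full enumeration, two-sided
p = 2 × min(tail) capped at 1) for combined n ≤ 12 without ties, otherwise
the tie-corrected normal approximation with continuity correction; at
n = 6/6 the approximation tracks the exact p to within about 0.02. No
multiple-testing correction is applied, mirroring the per-test α = 0.05
convention of the study; reports list all raw p-values, and this is a
known caveat.

### What the scene generator emulates — and what it does not

A synthetic scene is a light background (`background_gray`, default 0.9)
with darker disks for stained neurons. Per-cell normalized signal s is a
mean-one lognormal (`signal_noise_sd`, default 0.2 on the log scale)
around a planted mean that is the product of a base level (`signal_mean`,
default 0.25), the group multiplier (`group_scale`) and the layer factor
(`layer_effect` for deep cells), and the painted gray is
`background_gray × (1 − s)`, so downstream intensity recovers s directly.
The mean-one parameterization makes the ratio of layer means equal the
planted `layer_effect` exactly in expectation. Cells are placed by
rejection sampling with a minimum separation of one cell diameter plus
two pixels, so detection faces no overlap ambiguity; pixel noise is mild
Gaussian (sd 0.01 gray levels).

The packaged `cohort2_layers` scenario plants the study's printed 7-day
effects: layer fold change 1.9, sham at 71% and TBI at 47% of the naive
mean, 400 cells per subject, 3 subjects per group, 2 µm/pixel over a
1000 × 1000 µm window.

Passing recovery tests on these scenes shows the measurement chain
(threshold → components → normalized intensity → sectors → contrasts) is
unbiased under the generator's assumptions. It does not show robustness
to what real sections add: overlapping and partially sectioned cells,
nucleus/cytoplasm substructure, staining gradients, RGB color variation,
or glial/neuronal mixtures. Those are explicit non-goals (no watershed
splitting, no color deconvolution, no co-localization).

## Seed-site scanning and DE overlap

The mature miRNA is recovered as the reverse complement of the detection
probe (the packaged probe gives `UAAGGCACGCGGUGAAUGCC`). Canonical site
types follow the TargetScan convention: the 6mer is the reverse complement
of miRNA nt 2–7 (here `UGCCUU`); a 7mer-m8 adds the complement of miRNA
nt 8 on the target's 5′ side; a 7mer-A1 adds an A across from miRNA
position 1; the 8mer has both. Each locus (distinct 6mer start) is
reported once at its strongest type; site starts are 1-based at the
site's 5′-most target nucleotide. Conservation filtering — the "conserved"
part of the original TargetScan run — is not implemented (it needs
cross-species alignments); in the synthetic transcriptome the planted
target set plays that role, which is sufficient because the downstream
counting depends only on set membership.

The transcriptome generator makes the scanner's positive set equal the
planted set *exactly*: non-target UTRs are rejection-sampled until they
contain zero 6mer matches, and each target gets one planted site (8mer,
7mer-m8 or 7mer-A1, chosen at random). The DE table is constructed to
contain exactly the requested numbers of significantly up/downregulated
genes and target overlaps. The packaged `cohort3` scenario plants the
study's printed counts: 1547 predicted targets among 12 000 genes
(300-nt UTRs), 2583/2381 significant genes, 312/311 of them targets.

## Preranked enrichment

The ranked list scores each gene by sign(log2FC) × (−log10 p) — the
study describes ranking "on fold-change and p-values" without a formula,
and this metric uses both monotonically; plain log2FC is available as an
option. Ties break lexicographically by gene id, so the list is
deterministic. The enrichment score is the classic weighted KS running
sum (weight exponent 1 on |score|, configurable): hits advance by their
normalized |score|, misses retreat by 1/(N − N_hits), and the ES is the
signed maximal deviation. When the positive and negative extremes tie in
magnitude exactly, the one attained earlier in the list is reported.
Significance uses gene-set permutation (the only null available to
preranked input): p is the one-sided add-one tail fraction of the ES of
random same-size sets, NES divides by the mean same-sign null magnitude,
and the single-set FDR q is the same-sign tail fraction. In the planted
`cohort3` scenario the downregulated targets carry the most extreme
p-values, so the target set is negatively enriched by construction — the
tests assert sign and significance, not a specific ES value, because the
study's own ranked list is not recoverable.

## Duplex minimum free energy

Binding stability between the miRNA and a target site region is scored by
an intermolecular-only dynamic program: antiparallel duplexes built from
Watson–Crick and G:U pairs, nearest-neighbor stacking energies for
adjacent pairs, affine penalties for one-sided bulges
(`bulge_open + bulge_extend × (len − 1)`) and two-sided internal loops
(`internal_open + internal_extend × (len − 2)`), one initiation cost,
free dangling ends, and no intramolecular structure on either strand
(site regions are capped at 60 nt; the default context is 30 nt centered
on the seed site). If no duplex reaches a negative energy the result is
"no binding" (mfe 0, empty pairing). The reported binding start is the
5′-most paired miRNA nucleotide.

The packaged parameter file carries Xia/Turner-style Watson-Crick stack
values; G:U stacks are in the same style, with the two tandem-wobble
entries kept mildly favorable (−0.3/−0.5) so that every stack is negative
and the model is internally consistent, and unlisted wobble stacks
defaulting to −0.5. The original study used a hybridization tool as a
black box and its appendix MFE table is not reproduced in the text, so
only comparative claims (e.g. stronger sites bind more stably, perfect
complements are optimal) are meaningful here, and those are what the
tests check — including exhaustive-enumeration equivalence of the DP on
short sequences. Loop runs are capped at 10 nt per strand; there is no
temperature dependence, coaxial stacking, partition function or
accessibility correction.

## Numerical and reproducibility choices

* Every generator draws from a stream seeded deterministically from the
  scenario seed plus a stage/subject index (kept below 2^31), so any
  subject or replicate is reproducible in isolation and a single seed
  reproduces a whole run.
* Degenerate inputs error early and explicitly: zero-variance data in
  Grubbs or Spearman, empty images, thresholds outside (0, 1), infeasible
  planted counts, gene sets covering none or all of the ranked list,
  non-RNA characters (DNA FASTA is transliterated T→U with a notice).
* Fully tied data in Kruskal–Wallis is reported as H = 0, p = 1 rather
  than NaN.
* Half-open interval conventions everywhere in sector geometry prevent
  double-assignment at split coordinates.

## Problem sizes

The recovery studies use 200 replicate Ct tables (n = 6 vs 6) per qPCR
claim, 500 replicate pairs (n = 24) for the correlation, 9 scenes of 400
cells (500 × 500 px) for the layered ISH scenario, a 12 000-gene
transcriptome with 300-nt UTRs for the counting claims, and 1000 gene-set
permutations for enrichment — sizes at which the median estimates settle
well inside the stated tolerances while a full run stays comfortably
interactive on a laptop.

## Known limitations

* The sector grid geometry is an interpretation of the published figures;
  both split coordinates are parameters for that reason.
* The ISH generator draws i.i.d. cells given group and layer; it has no
  subject-level random effect, so between-animal variability is not part
  of what recovery tests demonstrate.
* Grubbs screening, like the original workflow, is a single-outlier
  procedure; masked multiple outliers will pass.
* The energy model is a compact stylized table, adequate for comparative
  statements, not for absolute kcal/mol accuracy against full
  nearest-neighbor implementations.
* Raw p-values are reported without multiplicity correction, by design.
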