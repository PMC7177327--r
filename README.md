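# perimir

Quantitative analysis of chronic miR-124-3p downregulation in the
perilesional cortex after traumatic brain injury (TBI) — as a tested,
reusable R pipeline.

After a cortical lesion, the brain-enriched neuronal microRNA miR-124-3p
stays downregulated in the adjacent cortex for months, with consequences
for its target transcripts (among them *Stat3*). Quantifying that involves
four very different measurements, and perimir implements all of them:

* **Per-cell in situ hybridization (ISH) intensity** — cells are detected
  in grayscale section images by thresholding and connected components,
  each cell scored by the background-normalized intensity
  `(bg − cell)/bg`, assigned to one of four perilesional sectors
  (proximal/distal × deep/superficial within a 1-mm window at the lesion
  edge), and contrasted across groups (naive / sham / TBI) with
  Kruskal–Wallis and Mann–Whitney tests.
* **Relative qPCR quantification** — the 2^−ΔΔCt method with an
  endogenous control: ΔCt = Ct(target) − Ct(reference),
  ΔΔCt = mean ΔCt(case) − mean ΔCt(control), fold change = 2^−ΔΔCt,
  plus single-pass two-sided Grubbs outlier screening and Spearman
  miRNA–target correlation.
* **Seed-site target analysis** — canonical miRNA site scanning of
  3′UTRs (6mer < 7mer-A1 < 7mer-m8 < 8mer, TargetScan conventions),
  overlap of the predicted target set with a differential-expression
  table, and preranked gene-set enrichment (weighted KS running sum,
  gene-set permutation p/NES/FDR).
* **Duplex stability** — intermolecular miRNA:target minimum free energy
  by dynamic programming over a packaged nearest-neighbor energy model
  (stacks, affine bulges/internal loops, free dangling ends), reporting
  the MFE and the 5′ miRNA position where optimal pairing starts.

No raw data from the original tissue study is deposited, so the package
ships a first-class synthetic-data module: packaged scenarios plant the
study's printed effect sizes (fold changes 0.13 and 0.40, *Stat3* 6.97,
layer ratio 1.9, group levels 47% and 71%, 1547 targets with a
312/311-gene DE overlap, rank correlation −0.647) and every stage is
validated by recovering what was planted. `vignettes/perimir-methods.Rmd`
documents the models and the design choices.

## Worked example

Simulate a 7-day qPCR experiment (6 TBI vs 6 sham animals, Ct noise 0.3
cycles, planted fold change 0.13) and quantify it:

```r
library(perimir)

ct <- generate_ct_table(scenario("cohort1_7d"), "mir124")
res <- ddct_fold_change(ct, case_group = "TBI", control_group = "sham")
res
#> <perimir_ddct> TBI vs sham: ddCt = 2.934, fold change = 0.1308 (Mann-Whitney p = 0.00216)
```

The estimated ΔΔCt of 2.93 cycles means the TBI group needs ~3 extra PCR
cycles relative to its reference assay, i.e. an ~7.6-fold loss of
miR-124-3p (fold change 0.131 against the planted 0.13); the exact
Mann-Whitney p confirms the group difference. `tidy(res)` returns the
per-sample relative quantities, `glance(res)` the one-row summary, and
`autoplot(res)` the jitter plot.

Target-side, derive the mature miRNA from the detection probe and scan a
UTR:

```r
mir <- mirna_from_probe("GgcAuuCacCgcGugCcuuA")
mir
#> [1] "UAAGGCACGCGGUGAAUGCC"

scan_sites("AAAGUGCCUUAAAA", mir)
#> # A tibble: 1 x 2
#>   start site_type
#>   <int> <chr>
#> 1     4 8mer

duplex_mfe(mir, "AAGCGUGCCUUA")
#> <perimir_duplex> mfe = -17.06 kcal/mol, binding start nt 1
#> 5' UAAGGCACGC 3' (miRNA)
#>    ||||||||||
#> 3' AUUCCGUGCG 5' (target)
```

The UTR carries an 8mer site starting at position 4 (seed match flanked
by the m8 complement and a t1 adenine), and the duplex program pairs the
miRNA 5′ end against this site region at −17.1 kcal/mol.

End-to-end, `run_scenario("cohort2_layers", "out/")` generates section
images for all nine subjects, detects and sectors ~3600 cells, writes
`cells.csv`, `sectors.csv` and `contrasts.json`, and reports each
planted-vs-estimated headline with a pass/fail flag.
`inst/exec/perimir` exposes the same stages as shell subcommands
(`run`, `simulate`, `qpcr`, `targets`, `gsea`, `duplex`, `ish-quant`).

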