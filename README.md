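# progressionscope

Discovery of early-lost tumor-suppressor miRNAs in a staged breast-cancer
progression panel.

Triple-negative breast cancer develops through ordered stages — normal-like
epithelium, hyperplasia, atypical hyperplasia, ductal carcinoma in situ
(DCIS), invasive carcinoma — modelled in vitro by the isogenic MCF10A panel
(P < NeoT < AT1 < DCIS < Ca1d).  `progressionscope` is for analysts asking
which miRNAs change *early* in that progression (the preneoplastic window,
where prevention is possible), which mRNA targets they control, and whether
their loss predicts outcome.  It implements:

* **Trajectory classification** — per-transition log2 fold changes with
  equal-variance Student t-tests on replicates, direction calls at the
  (1.5-fold, p < 0.05) gates, and assignment to four progression groups:
  G1 continuous increase, G2 continuous decrease, G3 early increase then
  plateau, G4 early decrease then plateau; plus a census of alterations
  arising in the preneoplastic transitions.
* **miRNA–mRNA integration** — a differential gene signature between any
  two stages; per-miRNA target-set enrichment by the one-sided Fisher
  exact (upper hypergeometric tail) statistic
  p = P(X ≥ k), X ~ Hypergeom(N, K, n), with Benjamini–Hochberg Q-values
  and the discovery gate Q < 0.25; an inverse-correlation filter on stage
  means; ranked candidate-target lists.
* **Survival stratification** — median split of an expression-linked
  cohort, Kaplan–Meier product-limit curves, median survival
  (smallest t with S(t) ≤ 0.5) and the two-group log-rank test.
* **Methylation trends** — per-stage region means of a 16-CpG promoter
  panel (CpG 1–7, CpG 8–16, all 16) and stage-level correlation between
  average methylation and expression.
* **In-vitro quantification** — 2^−ΔΔCt relative qPCR expression with
  replicate-level significance, the repressed-gene filter, Ki67
  proliferation index (≥ 3 foci = positive), colony counting (> 50
  cells = one colony), and dual-luciferase normalization.
* **A synthetic-data generator** with planted ground truth (trajectory
  groups, a focal regulator with true targets among decoy predictions, an
  exponential-hazard cohort, a calibrated two-block methylation trend,
  and Ct fixtures), so every stage is validated by recovery testing.

## Worked example

One call runs the whole pipeline on the default synthetic study
conditions (561 miRNAs, 2000 mRNAs, 3 replicates over 5 stages, one
planted G2 regulator with 35 true targets, an n = 80 cohort):

```r
library(progressionscope)
report <- run_pipeline(out_dir = "results/demo", seed = 1)
#> [generate] 561 miRNAs, 2000 mRNAs, 22501 predicted edges
#> [trajectory] 63/63 altered early (100.0%); 5 miRNAs in G2/G4
#> [integration] signature P->DCIS: 239 genes; top miRNA mir0226 (Q=4.26e-17), 39 candidates
#> [survival] log-rank chisq=4.06 p=0.0439; medians low=55.31 high=103.6 months
#> [methylation] all-16 vs mir0226 expression: r=-0.900 (p=0.0373)
#> [quantify] 9 of 14 genes significantly repressed
#> [report] written to results/demo/report.json
```

Reading the log: 63 miRNAs fall into the four trajectory groups and all
of them first change in the preneoplastic transitions (the planted
patterns all change early); 5 miRNAs show the decreasing G2/G4 patterns
of tumor-suppressor interest.  The P→DCIS up-signature holds 239 genes;
the planted regulator `mir0226` is the top-enriched miRNA at
Q = 4×10⁻¹⁷ — the only G2/G4 miRNA passing Q < 0.25 — with 39 candidate
targets surviving the signature ∩ prediction ∩ anticorrelation
intersection (its 35 planted targets plus a few decoys).  The
low-expression half of the cohort dies earlier (median 55 vs 104 months,
log-rank p = 0.044), promoter methylation anticorrelates with the
regulator's expression across stages (r = −0.90), and the repressed-gene
filter recovers 9 of the 14 qPCR-assayed genes.

Every stage writes its table under `out_dir` (panels, predictions,
transition stats, calls, signature, enrichment, candidates, KM curves,
region means, fold changes) plus a self-contained `report.json`; the
same config and seed reproduce it byte for byte.

Individual operations work standalone:

```r
km <- km_estimate(c(2, 4, 6, 8), rep(1, 4))
km$surv    # 0.75 0.50 0.25 0.00
km$median  # 4
count_repressed(mimic_qpcr_table())$count  # 9
```

A thin CLI over the same functions ships at `inst/cli/progressionscope`
(subcommands `run`, `generate`, `trajectory`, `survival`, `methylation`,
`quantify`).

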