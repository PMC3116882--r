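# awasig

Blood-transcriptome subtype discovery for subclinical atherosclerosis.

People with low or intermediate Framingham risk scores (FRS) can still carry
a significant burden of subclinical atherosclerosis (high coronary artery
calcium, thickened carotid intima-media). `awasig` implements a complete,
tested pipeline for case-control peripheral-blood microarray cohorts built to
ask whether an expression-defined molecular subtype — the *Associated With
Atherosclerosis* (AWA) profile — tracks that hidden burden:

* **Preprocessing** — log2 transform, quantile normalization, and probe
  filtering by coefficient of variation (CV = σ/μ < 0.03 excluded) and
  detection call (detected at p < 0.01 in ≥ 61 of 119 samples).
* **Differential expression** — per-probe Welch/pooled t tests;
  Storey q-values with spline-smoothed π0 (so the estimated DE fraction is
  1 − π0, and forcing π0 = 1 recovers Benjamini–Hochberg exactly); SAM-style
  permutation FDR with the d statistic d = r/(s + s0) and the
  CV-minimizing fudge factor s0.
* **Subtype discovery** — *multiple random validation*: in each of R
  (default 1,000) repeats, samples are split into 10 stratified folds; for
  every fold an SVM (radial kernel, cost 1, γ = 1/k) is trained on the other
  nine folds using the k = 50 probes with the largest within-training-set
  |t|, and the held-out samples are classified. Each sample receives one
  vote per repeat; the AWA profile is the strict majority vote
  (> R/2 votes).
* **Association** — 2×2 odds ratio (tp·tn)/(fp·fn) with Wald CI,
  sensitivity/specificity, chi-square/Fisher tests, subgroup analyses, and
  FRS-adjusted logistic regression.
* **Structure & validation** — average-linkage hierarchical clustering with
  Pearson-correlation distance (d = 1 − r), dendrogram cutting, per-branch
  phenotype enrichment; cross-study fold-change concordance via gene-symbol
  mapping, paired fold changes, Pearson r over dual-significant genes, and a
  hypergeometric overlap test.
* **Synthetic cohorts** — a generator that plants the assumed structure
  (48/71 cases/controls, 2,057 probes, a latent subtype linked to case
  status at sensitivity 0.60 / specificity 0.76 — implying a crude odds
  ratio (0.60/0.40)/(0.24/0.76) = 4.75 — 20% DE probes, block-correlated
  probe groups, detection p-values, Table-1-style covariates), plus null
  and paired baseline/post-stimulus variants.

## Worked example

```r
library(awasig)

co <- generate_cohort(cohort_spec(seed = 1))
co
#> <synthetic_cohort> 2057 probes x 119 samples (48 cases / 71 controls); 411 DE probes; 46 subtype-positive

filt <- filter_probes(co$expr, analysis_config())
glance(filt$report)
#> # A tibble: 1 × 4
#>   n_input_probes n_removed_cv n_removed_detection n_retained
#> 1           2057            0                   0       2057

de <- welch_t(filt$expr, co$annotation$case_status)
mean(de$p_value < 0.05)
#> [1] 0.052

cfg <- analysis_config(n_repeats = 200, rng_seed = 7)
votes <- multiple_random_validation(filt$expr, co$annotation$case_status, cfg)
asg <- assign_subtypes(votes)
head(asg, 3)
#> # A tibble: 3 × 4
#>   sample_id vote_count vote_fraction   awa
#> 1 S001             190         0.95      1
#> 2 S002              51         0.255     0
#> 3 S003             200         1         1

associate(asg, co$annotation$case_status)
#> # A tibble: 1 × 10
#>      tp    fp    fn    tn odds_ratio ci_low ci_high sensitivity specificity
#> 1    23    17    25    54       2.92   1.33    6.41       0.479       0.761

adjusted_logistic(asg, co$annotation$case_status, co$annotation["frs"])$result
#> # A tibble: 1 × 5
#>   method   odds_ratio ci_low ci_high p_value
#> 1 logistic       2.16  0.883    5.27  0.0915

mean(asg$awa == co$truth$samples$subtype)
#> [1] 0.933
```

Reading the numbers: the generator plants a latent subtype in 46 of 119
samples whose cross-tabulation with case status is exactly (29, 17, 19, 54),
i.e. crude OR 4.85, sensitivity 60%, specificity 76%. The vote-based
assignment recovers the planted subtype for 93% of samples; the ~7% of
misassigned samples attenuate the assignment-vs-case odds ratio (2.92 here)
relative to the latent-truth value, and FRS adjustment shrinks it further —
single-run odds ratios at n = 119 carry a log-scale standard error near
0.5, so they should be read as a regime, not a point value. On the filtered
probes, 5.2% of case-control p-values fall below 0.05 in this draw: the
case-control contrast is the subtype contrast diluted by the imperfect
subtype-phenotype linkage.

All result objects are tibbles (or carry `tidy()`/`glance()` methods), and
`autoplot()` methods cover p-value histograms, vote-fraction profiles,
signature-size sweeps, and concordance scatters.

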