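# epistasurv

SNP–SNP interaction discovery and survival validation for two-arm
pharmacogenetic cohorts.

`epistasurv` is aimed at biostatisticians and translational researchers who
ask: *is there a combination of germline genotypes that predicts which
patients benefit from a targeted drug added to chemotherapy?* The concrete
setting it models is hormone-receptor-positive metastatic breast cancer
treated with paclitaxel plus the anti-VEGF antibody bevacizumab versus
paclitaxel alone, with a panel of angiogenesis-pathway SNPs (VEGF-A
rs833061, VEGFR-2 rs1870377 and rs11133360, IL-8 rs4073 by default; the
panel is user-extensible).

## The method

1. **Responder dichotomization.** Patients are split on progression-free
   survival (PFS): *responders* progression-free ≥ 20 months,
   *non-responders* progressing < 10 months; PFS in the 10–20 month window
   is excluded to sharpen the contrast.
2. **Multifactor dimensionality reduction (MDR).** For every pair (more
   generally k-tuple) of loci, patients are pooled into the 3^k genotype
   cells. A cell is **favorable** when its responder/non-responder ratio
   reaches the sample-wide ratio *T* of the training data:

       cell c favorable  ⇔  r_c / n_c ≥ T,   T = R / N  (training totals)

   which collapses the tuple to one binary attribute. Tuples are ranked by
   stratified k-fold cross-validated **balanced accuracy**
   (sensitivity + specificity)/2, with *T* and the cell map recomputed on
   each training split so nothing leaks into the held-out fold.
3. **Permutation significance.** Responder labels are reshuffled
   (class counts preserved) and the *entire* search is re-run per
   permutation; the upper-tail Monte-Carlo p uses the add-one estimator
   p = (1 + #{null ≥ observed}) / (1 + n_perm), so selection over tuples is
   accounted for in the null.
4. **Survival validation.** Every patient in both arms is annotated with
   the learned favorable/unfavorable profile, then compared by
   Kaplan–Meier (median with Brookmeyer–Crowley log(−log) CI), log-rank,
   and Cox proportional hazards with stepwise backward selection over
   clinical covariates; post-hoc power uses the Schoenfeld approximation
   Φ(√(D·p·(1−p))·|ln HR| − z_{1−α/2}).
5. **Synthetic cohorts.** Because real patient-level data of this kind are
   rarely shareable, a generator plants the assumed structure —
   Hardy–Weinberg genotypes, a 9-cell favorable/unfavorable map on one
   locus pair, exponential PFS/OS whose profile effect exists only in the
   combination arm, administrative censoring — so every stage is testable
   and calibratable.

## Worked example

```r
library(epistasurv)

# a bundled 40-patient synthetic cohort round-trips through the reader
co <- read_patient_table(system.file("extdata", "synthetic_cohort_n40.tsv",
                                     package = "epistasurv"))
co
#> <episurv_cohort> 40 patients, 4-locus panel (rs833061, rs1870377, rs11133360, rs4073)
#>   arms: PTX=12, PTX_BEV=28

# full pipeline on the paper-shaped preset (168 synthetic patients)
report <- run_pipeline(pipeline_config(preset = "paper_like",
                                       n_perm = 1000, seed = 7))
report
#> <analysis_report>
#>   attrition: input=168, hr_positive=168, labeled=130, excluded_window=38, excluded_early_censor=0, arm_ptx_bev=106, arm_ptx=62
#>   model: rs833061 x rs1870377 (test BA 0.735)
#>   permutation p = 0.000999 (1000 perms)
#>   ptx_bev PFS: median fav 22.4 vs unfav 6.7, log-rank p = 8.17e-05
#>   ptx_bev OS: median fav 44.0 vs unfav 21.3, log-rank p = 7.889e-06
#>   ptx PFS: median fav 10.5 vs unfav 7.9, log-rank p = 0.3176
#>   ptx OS: median fav 26.6 vs unfav 27.1, log-rank p = 0.9689

report$model
#> <mdr_model> loci: rs833061 x rs1870377
#>   mean CV test BA 0.7350, CV consistency 8/10, train BA 0.7355
#>   threshold T = 0.9773
#>   favorable:    CC/TT, CC/AT, CT/AT, CT/AA, TT/TT, TT/AA
#>   unfavorable:  CC/AA, CT/TT, TT/AT

report$survival$ptx_bev$pfs$cox_selected
#> <cox_fit> n = 106, events = 104, ties = efron
#>   profile_favorable      HR 0.459 (0.309-0.682)  p = 0.0001168
#>   dropped: adjuvant_cht -> grading_3 -> adjuvant_taxanes -> age_ge_65 -> sites_ge_3
```

Reading the output: the search recovers the planted rs833061 × rs1870377
interaction (cross-validated balanced accuracy 0.735, permutation p ≈
0.001 — the add-one floor for 1000 permutations). In the combination arm
the favorable profile carries a large PFS benefit (median 22.4 vs 6.7
months; adjusted HR 0.459 after backward selection pruned the
independently-drawn clinical covariates), while in the chemo-only arm the
profile shows no effect (log-rank p = 0.32 / 0.97) — exactly the
predictive-not-prognostic structure the generator plants. One small cell
(CC/AT, 8 patients here) flips label relative to the planted map,
illustrating the sampling noise quantified in the methods vignette.

The same run from the shell:

```sh
Rscript inst/cli/epistasurv.R --preset paper_like --n-perm 1000 --seed 7 --out out_dir
# or with your own table:
Rscript inst/cli/epistasurv.R --input cohort.tsv --pfs-low 10 --pfs-high 20 --out out_dir
```

`out_dir` receives `report.json`, the 9-cell profile map, per-arm Cox and
baseline tables, Kaplan–Meier curve TSVs, the permutation null
distribution, and the attrition log; contents are byte-identical for a
fixed seed.

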