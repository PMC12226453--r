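# pirasurv

Discrete-time survival modelling of **progression independent of relapse
activity (PIRA)** from a baseline brain MRI in early multiple sclerosis.

PIRA — disability that accumulates outside of clinical relapses — is the
main route to irreversible disability in MS, and at the time of the first
demyelinating attack almost nothing predicts it well. `pirasurv`
implements, as reusable and fully tested R components, a pipeline that:

1. **labels PIRA events** deterministically from longitudinal EDSS and
   relapse records: a 6-month confirmed disability worsening (EDSS rise of
   ≥1.5 / ≥1.0 / ≥0.5 points over a reference of 0 / (0–5] / >5) occurring
   entirely inside a relapse-free period, with re-baselining of the
   reference after every relapse and a floor at the first 6-month EDSS
   (`detect_pira()`; `pdds_pira()` for patient-reported external cohorts);
2. **fits a discrete-time survival network** on 2-channel (T1-w, T2-FLAIR)
   axial slices: a CNN with an 11-unit sigmoid head whose outputs are
   per-interval conditional hazards `h_j`, so the survivor curve is
   `S(t_k) = prod_{j<=k} (1 - h_j)` and the cumulative PIRA risk is
   `F = 1 - S`; training minimises the discrete survival likelihood with
   Adam, cosine annealing and early stopping, and patient predictions are
   the median over slice curves (`pira_dsn()`, `predict()`,
   `cv_pira_dsn()`, `ensemble_average()`);
3. **evaluates like a survival model**: time-dependent concordance,
   censoring-weighted Brier and integrated Brier scores with their
   non-informative ceiling `p(1-p)`, ROC comparison with Šidák correction,
   best-accuracy threshold selection and exact-binomial classification
   reports (`td_cindex()`, `integrated_brier()`,
   `best_accuracy_threshold()`, `classification_report()`);
4. **augments a classical Cox benchmark** with the network's
   first-interval cumulative risk and reports the gain in Harrell's C
   (`fit_cox()`, `backward_select()`, `augment_with_dl()`);
5. **explains predictions** with signed per-pixel relevance maps
   (gradient × input by exact backprop; pluggable backend), 95th-percentile
   trinary masks and population-average aggregation over a parcellation
   (`attribute()`, `normalize_binarize()`, `population_region_table()`);
6. **simulates everything it needs**: clinical cohorts with injected,
   exactly recoverable PIRA events, and brain phantoms whose discrete-time
   hazard depends on known lesion-count and ventricle-size parameters
   (`simulate_clinical_cohort()`, `simulate_imaging_cohort()`).

The methods vignette (`vignettes/pira-survival-modelling.Rmd`) documents
the model, every tunable parameter, the synthetic generator and the design
decisions.

## Worked example

Label a synthetic clinical cohort, train the survival network on phantom
MRI with a known image-to-hazard link, and evaluate:

```r
library(pirasurv)

## clinical arm: exact labelling of injected events
clin <- simulate_clinical_cohort(100, pira_fraction = 0.22, seed = 1)
labels <- label_cohort(clin$records)
table(labels$event)
#>  0  1
#> 78 22

detect_pira(clin$records[[which(clin$truth$pira)[1]]])
#> PIRA event: onset 4.02 y (ref EDSS 0.5, confirmed 4.52 y)

## imaging arm: strong image-hazard coupling
hp  <- hazard_model_params(alpha = -7, beta_lesion = 0.8, beta_ventricle = 1.5)
coh <- simulate_imaging_cohort(300, hp,
                               phantom_params(image_size = c(64, 64, 12)),
                               n_slices = 8, seed = 11)
fit <- pira_dsn(coh$stacks[1:200], coh$labels[1:200, ],
                config = dsn_config(initial_lr = 1e-3, max_epochs = 15, seed = 5))
fit
#> Discrete-time survival network (backbone 'tiny')
#>   input 64 x 64 x 2, 11 output intervals
#>   trained 13 epochs (best 6), val NLL 1.7118

F_hat <- predict(fit, coh$stacks[201:300], type = "cumrisk")
lab   <- coh$labels[201:300, ]
td_cindex(F_hat, lab$interval, lab$event)
#> [1] 0.667
integrated_brier(1 - F_hat, lab$interval, lab$event)$mean
#> [1] 0.214  (non-informative ceiling at this incidence: 0.249)
```

`td_cindex` is the fraction of comparable patient pairs whose predicted
cumulative risks at the earlier event time are correctly ordered (0.5 =
chance); the integrated Brier score is the censoring-weighted mean squared
error of the survival curve, averaged over the 11 yearly intervals.

A one-call orchestration with artifacts and a reproducibility manifest:

```r
run_pipeline(pipeline_config(n_patients = 60), seed = 1, out_dir = "out")
```

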