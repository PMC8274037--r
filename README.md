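# mtbimeth

Predicting four-month outcomes after pediatric mild traumatic brain injury
(pmTBI) from subacute saliva DNA methylation and clinical features.

Most children recover from a concussion within weeks; a minority report
persistent post-concussion symptoms (PPCS) months later. This package
implements, as a tested and fully reproducible pipeline, an analysis that
asks whether DNA methylation restricted to a depression-associated gene
pathway — measured about one week post-injury — adds predictive value for
two outcomes about four months later: post-concussive symptom burden (PCSI,
higher = worse) and pediatric quality of life (PedsQL, higher = better).
It is written for epigenomics and clinical-outcomes researchers who want to
study or adapt each stage of such an analysis with planted ground truth.

Because the motivating cohort is available only on request, the package
ships a synthetic-cohort generator whose defaults emulate the study
conditions (110 patients, 87 controls, 13 sibling pairs, chip batches, a
buccal/granulocyte cell mixture, five latent methylation components on 223
pathway CpGs, and linear outcome models with known weights), together with
a truth record that every stage's tests are scored against.

## The models at the core

* **Per-CpG mixed model (MWAS).** For each CpG `j`,
  `beta_j = diagnosis + age + sex + BMI + race + buccal + PC2..PC4 + (1 | family)`,
  fitted by REML; Wald t on the predictor of interest with residual degrees
  of freedom `n − p`, Benjamini–Hochberg FDR across probes.
* **Pathway ICA.** The patient M-value matrix over pathway CpGs (genes
  ± 20 kb) is decomposed as `X = A × S` by fixed-point ICA (tanh contrast,
  deflation, best of several seeded restarts by a negentropy proxy); the
  component count is the largest `k` whose half-sample worst-component
  reproducibility exceeds 0.8. Control loadings come from projecting control
  data through the pseudoinverse of `S`.
* **Sparse SVR.** Outcomes are predicted by minimizing
  `Σ_i max(0, |y_i − w·x_i − b| − ε) + λ‖w‖₁`,
  solved exactly as a linear program (C++ simplex). λ is tuned by
  leave-one-out MSE; final predictors are the features whose leave-one-out
  weights differ from zero (one-sample t-test, α = 0.05); the final fit
  re-tunes λ on the selected set. Five feature sets are compared: clinical,
  methylation (global + component loadings), their union, prior clinical,
  and prior BDNF/APOE CpGs.
* **PPCS rule.** Follow-up symptom sums are `log10(x + 1)`-transformed,
  z-scored against the control distribution, and thresholded at z > 1.64;
  predicted scores are evaluated as PPCS classifiers by ROC/AUC.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
synthetic cohort and narrate what they find (each is self-contained;
intermediate results are cached under `scratch/`):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/04_factorize.R
Rscript analysis/05_predict.R
```

Selected output from a run of the sequence:

```
Cohort: 110 patients, 87 controls; 184 families (13 sibling pairs)
PCSI at follow-up  HC 6.5 +/- 6.7 | pmTBI 15.4 +/- 11.1

QC filter chain:
               step   unit n_removed n_retained
       sex_mismatch sample         0        197
 sample_missingness sample         0        197
         pc_outlier sample         1        196
      probe_filters  probe       309       1691
          sd_filter  probe      1460        231
Buccal-fraction recovery: MAE 0.014, r = 0.998

Half-sample consistency by candidate component count:
    2     3     4     5     6     7     8
0.965 0.882 0.665 0.955 0.762 0.453 0.188
Estimated components: 5 (planted: 5)
Matched |r| between recovered and planted sources: 0.968 0.975 0.982 0.986 0.988

Prediction accuracies (train 63 / test 28):
   outcome  model n_features train_r test_r test_auc
   PCSI_EC model1         19   0.694  0.478    0.720
 PedsQL_EC model1         17   0.684  0.280    0.653
 PedsQL_EC model2          6   0.556  0.504    0.453
 PedsQL_EC model3         23   0.844  0.668    0.733
```

Read this as the pipeline's reproduction of the study's qualitative
finding on data where the truth is known: the QC chain removes exactly the
planted decoys, deconvolution recovers the planted cell fractions, the
consistency criterion finds the five planted components, and adding the
methylation components raises the quality-of-life test correlation from
0.28 (clinical only) to 0.67 (combined) while symptom burden remains a
clinical-only prediction — the planted symptom model carries no
methylation effect, and the pipeline correctly declines to find one.
Scripts `03`, `06` and `07` add the MWAS (the planted diagnosis-associated
CpG ranks first at q < 0.05), the PPCS classification (11/91 patients
flagged) and the univariate follow-ups.

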