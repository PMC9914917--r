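# qeegicp

Quantitative-EEG prediction of increased intracranial pressure (IICP) in a
stepwise intracranial-hypertension injury protocol.

After traumatic brain injury, intracranial pressure (ICP) is monitored
invasively through a cranial catheter. A usable non-invasive surrogate
would shorten treatment delays; one candidate signal is the EEG, whose
composition shifts toward faster rhythms (≥ 13 Hz) as ICP rises. This
package is for signal-processing and ML researchers working on that
question: it implements, as tested reusable functions plus a scripted
analysis, the complete chain from raw single-channel EEG to a validated
IICP classifier — and, because animal data of this kind are restricted, a
synthetic cohort generator that emulates the experimental protocol
(5-min baseline at ≈ 12.4 mmHg, then four 6-min balloon-inflation steps
targeting 20/30/40/50 mmHg; EEG at 250 Hz, hemodynamics time-aligned).

## The method

Per subject, the EEG is band-passed 0.5–47 Hz (zero-phase Butterworth),
cut into 2-s epochs with 0.5-s stride, synchronized with epoch-mean
ICP/MAP/HR, and labelled IICP-positive when mean ICP ≥ 25 mmHg; the first
minute of every injury step is excluded. Each epoch yields 20 qEEG
features in the time, frequency and entropy domains, e.g.

- relative band powers from a Welch spectrum, with ratio indices
  `thetapr` = P<sub>θ</sub>/P<sub>tot</sub>,
  `gammapr` = P<sub>γ</sub>/P<sub>tot</sub>,
  `dtabr` = log₁₀((P<sub>δ</sub>+P<sub>θ</sub>)/(P<sub>α</sub>+P<sub>β</sub>)),
- RMS magnitude and per-band standard deviations,
- log energy entropy Σᵢ ln(xᵢ² + ε).

Features are min-max normalized on the derivation subjects and ranked by
diagonal **neighborhood component analysis** (implemented from scratch):
maximize the leave-one-out soft accuracy

&nbsp;&nbsp;&nbsp;&nbsp;F(w) = Σᵢ Σ<sub>j : yⱼ=yᵢ</sub> p<sub>ij</sub> − λ‖w‖²,
&nbsp;&nbsp; p<sub>ij</sub> ∝ exp(−Σ<sub>r</sub> w<sub>r</sub>² |x<sub>ir</sub>−x<sub>jr</sub>| / σ),

by monotone gradient ascent. Features failing a pooled two-sample t-test
(p ≥ 0.05) are discarded and the top 10 by weight are kept. Four
classifiers are trained on the selected features of the 21 derivation
subjects — logistic regression, kernel-density naive Bayes, an RBF SVM
(kernel scale 1.7, box constraint 1) and a 30-tree random-subspace
ensemble — and evaluated on the 9 held-out validation subjects with
accuracy, sensitivity, specificity, precision, F1, MCC and AUC, each with
a cluster-bootstrap 95% CI (subjects resampled, 1000 draws).

## Worked example

The whole analysis is one call; stages are also exposed individually
(`generate_cohort()`, `preprocess_subject()`, `extract_feature_table()`,
`nca_feature_weights()`, `train_model()`, `evaluate_holdout()`, ...).

```r
library(qeegicp)
res <- run_pipeline(run_config(seed = 42L))
#> [qeegicp] simulated cohort of 30 subjects
#> [qeegicp] extracted 89550 epochs x 20 features in 21.1 s
#> [qeegicp] selected 10 features in 34.6 s: line_length, hjorth_mobility,
#>   sd_gamma, magnitude, log_energy_entropy, sef95, sd_beta, rel_beta,
#>   sd_theta, gammapr
#> [qeegicp] trained 4 models on 5985 epochs in 3.7 s
#> [qeegicp] evaluated 26865 validation epochs in 17.7 s

res$evaluation$comparison[, c("model", "accuracy", "sensitivity",
                              "specificity", "precision", "f1", "mcc", "auc")]
#>   model accuracy sensitivity specificity precision    f1   mcc   auc
#> 1    LR    0.815       0.957       0.602     0.783 0.861 0.619 0.921
#> 2    NB    0.813       0.930       0.638     0.794 0.856 0.608 0.902
#> 3   SVM    0.813       0.957       0.596     0.780 0.860 0.615 0.921
#> 4    RF    0.801       0.960       0.563     0.767 0.853 0.592 0.902
```

Reading this: the selection stage found the planted high-frequency
signal (gamma/beta-band SDs and shares rank on top), and every classifier
separates IICP from non-IICP epochs of *unseen subjects* with AUC ≈ 0.9
on this synthetic cohort. Rerunning with
`run_config(profile = flat_spectral_profile(), seed = 42L)` — a cohort
whose EEG carries no ICP information — drives every AUC to ≈ 0.5, the
negative control. Numbers on synthetic cohorts characterize the pipeline,
not any animal's physiology; see the vignette
(`vignettes/qeeg-iicp-pipeline.Rmd`) for the generative model, its
calibration anchors and its limits.

The numbered scripts under `analysis/` run the same stages piecewise
(simulate → features → select → evaluate) and leave their tables under
`results/`.

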