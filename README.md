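# cirrhotex

Texture-based quantification of liver cirrhosis from a single T2-weighted
MR slice.

Cirrhotic liver parenchyma on T2-weighted TSE images is darker and more
homogeneous than healthy parenchyma. `cirrhotex` turns that observation into
a quantitative classifier for radiologists and imaging researchers:

1. **Dynamic gray-level scaling** — the 12-bit intensity range (0–4095) is
   quantized to 64 levels by `out = floor(in / 64)`, concentrating the
   histogram onto a fixed alphabet.
2. **ROI-restricted vessel suppression** — within a user-supplied liver ROI
   (both lobes, one slice), Otsu's method picks the gray level `k*`
   maximizing the between-class variance
   `σ²_b(k) = w₀(k) w₁(k) (μ₀(k) − μ₁(k))²`, and the bright class
   (arteries, portal veins, bile) is discarded.
3. **First-order texture features** of the retained parenchyma: the mean,
   the sample standard deviation, and the Shannon entropy
   `H = −Σᵢ pᵢ log₂ pᵢ` of the 64-bin gray-level histogram (0 ≤ H ≤ 6 bits).
4. **QV classification** — a subject is called abnormal on a feature when
   the feature value is ≤ its quantitative value (QV), the cut-off read
   off the ROC curve's Youden-optimal operating point (published defaults
   2.8 / 0.7 / 0.3 for SD / mean / entropy).

The evaluation layer computes everything needed to report such a
classifier: group summaries with 95% CIs, pooled/Welch t-tests (also from
published summary statistics), ROC curves with the trapezoidal AUC (equal
to the Mann–Whitney estimator), Hanley–McNeil AUC significance,
sensitivity/specificity/accuracy/PPV/NPV, and Cohen's kappa. A seeded
phantom generator produces synthetic T2-like cohorts (elliptical liver,
correlated Gaussian texture, bright vessels) so the whole pipeline can be
validated without clinical data.

## Worked example

```r
library(cirrhotex)

# synthetic 31 + 31 cohort, features extracted in memory
feats <- simulate_cohort_features(n_normal = 31, n_abnormal = 31, seed = 1)
evaluate_cohort(feats, qv = "auto")
```

```
Cohort evaluation: 31 normal vs 31 abnormal subjects (QV auto)

 feature    qv sensitivity specificity accuracy ppv npv kappa auc
      sd 0.712           1           1        1   1   1     1   1
    mean 4.299           1           1        1   1   1     1   1
 entropy 1.546           1           1        1   1   1     1   1

Group means (normal vs abnormal), pooled-t p-values:
  sd       2.367 vs 0.661  (p = 2.86e-64)
  mean     13.600 vs 4.193  (p = 1.55e-90)
  entropy  3.277 vs 1.445  (p = 5.59e-73)
```

The abnormal phantoms are generated darker (lower parenchyma level) and
more homogeneous (smaller texture SD), so all three features separate the
groups completely: every QV (the Youden threshold, e.g. SD ≤ 0.712 ⇒
abnormal) sits between the group distributions, and AUC, kappa and
accuracy are all 1. On clinical data the same report is produced from a
cohort CSV via `extract_features()` + `evaluate_cohort()`, with
`tidy()` / `glance()` for tabular access and `autoplot()` for ROC panels.

The same pipeline runs from the shell:

```sh
inst/cli/cirrhotex simulate --n-normal 31 --n-abnormal 31 --seed 1 --output-dir sim
inst/cli/cirrhotex extract  --cohort sim/cohort.csv --output-dir out
inst/cli/cirrhotex evaluate --features out/features.csv --qv auto --output-dir out
```

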