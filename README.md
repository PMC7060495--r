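# pollendiary

Analysis pipeline for crowdsourced pollen-allergy (hayfever) symptom
diaries. Daily diary entries record a 0–3 severity grade per organ (eyes,
nose, lungs), four specific symptoms per organ, and five medication
categories. The package condenses such entries into the four score
calculations commonly used in aerobiology and allergy research, runs the
surrounding season/filter/pooling analysis, and compares the methods on
detrended daily series. It is aimed at aerobiologists and mHealth
researchers working with diary-style symptom data — and, because the
original diary databases are typically non-public, it ships a synthetic
cohort generator so the whole pipeline is reproducible and testable.

## The scores

For a diary entry with per-organ severity $s_o \in \{0,\dots,3\}$, symptom
flags $f_{o,k} \in \{0,1\}$ and medication flags $m_j$:

- **Combined raw score** (0–25.65):
  $\sum_o \bigl(s_o + \sum_k f_{o,k}\bigr) + M$, where the medication score
  $M \le 4.65$ sums organ-specific weights — eyes: 1 point for drops *or*
  tablets, 0.5 other, 0.3 homeopathic (max 1.8); nose: 1 for drops *or*
  tablets, 0.25 eye drops, 0.5 other, 0.3 homeopathic (max 2.05); lungs:
  0.25 tablets, 0.25 other, 0.3 homeopathic (max 0.8). Symptom part max
  21; overall max 25.65.
- **EMA raw score** (0–12): eyes and nose only, per the European Medicines
  Agency immunotherapy-trial directive; nose = severity + 4 symptoms
  (max 7), eyes = severity + 2 collapsed symptoms (tearing;
  itching/grittiness/redness) (max 5).
- **Symptom load index (SLI)** (0–10): a per-user normalization of either
  raw score onto a 0–10 index, pooled daily (per-user in-season maximum by
  default, or the theoretical maximum).

Around the scores: the pollen season is the 1%–95% window of the
cumulative Annual Pollen Integral (APIn); the analysis pool keeps users
with ≥ 15 in-season entries whose scores correlate significantly and
positively with same-day pollen (two-sided Pearson p < α and r > 0); and
the four daily pooled series are compared by pairwise Pearson correlation
after first differencing, which removes the shared seasonal trend.

## Worked example

```r
library(pollendiary)

cfg <- generator_config(n_users = 300, responder_fraction = 0.7, seed = 1)
res <- run_pipeline(cfg, year = 2018, out_dir = tempfile("run"))

res$window
#>   region  taxon  year start_date end_date    apin start_pct end_pct
#> 1 AT-wien birch  2018 2018-03-14 2018-06-03 10000         1      95

glance(res$filter)
#>   n_users n_passed pass_rate alpha min_entries score_col
#> 1     300      206     0.687  0.05          15 phd_raw

res$contributions
#>   base  pct_eyes pct_nose pct_lungs pct_med
#> 1 phd       25.7     25.5      25.7    23.2
#> 2 ema       44.6     55.4      NA      NA

res$correlations
#> First-differenced pairwise Pearson correlations of score methods:
#>         phd_raw phd_sli ema_raw ema_sli
#> phd_raw   1.000   0.998   0.986   0.982
#> phd_sli   0.998   1.000   0.986   0.985
#> ema_raw   0.986   0.986   1.000   0.998
#> ema_sli   0.982   0.985   0.998   1.000
```

Reading the output: the simulated birch season runs 14 March – 3 June 2018
and integrates to the configured APIn of 10,000 grains·day/m³. Of 300
simulated users, 206 pass the correlation-and-entries filter (the cohort
was 70% responders; the filter recovers them and rejects most
non-responders). Within the pooled combined score, eyes/nose/lungs each
contribute about a quarter and medication 23%; under the eyes-and-nose EMA
score the nose dominates (55%). All six detrended pairwise correlations
among the four calculation methods exceed 0.98 — the choice of calculation
method barely affects the seasonal signal, which is the substantive point
the comparison is built to test.

`plot_score_series(res$series, res$pollen)`, `plot_pollen_season()`,
`autoplot(res$filter)` and `autoplot(res$correlations)` draw the standard
figures; `tidy()`/`glance()` give broom-style views of the filter and
correlation objects.

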