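# atlasfuse

Evaluation pipeline for **multi-atlas automatic segmentation of the brachial
plexus (BP)** with **morphometric atlas selection**. The BP — an organ at
risk in head-and-neck, breast and lung radiotherapy — is nearly invisible on
planning CT, so its contour is usually transferred from pre-segmented
reference datasets (atlases) by deformable registration and label fusion.
Registration degrades as the atlas anatomy departs from the patient's;
`atlasfuse` implements the strategy of selecting atlases by similarity in
**shoulder protraction distance** (the anterior-posterior offset between the
anterior tubercle of C5 and the infraglenoid tubercle) and quantifies what
that selection buys.

The package provides:

* **Morphometry** — `protraction_distance()`, `rank_atlases()`,
  `select_top_k()`.
* **Label fusion** — `staple()`, a binary STAPLE
  (Simultaneous Truth and Performance Level Estimation) EM implementation
  estimating the consensus segmentation `W` together with each input's
  sensitivity `p_j` and specificity `q_j`:
  `W_i = a_i / (a_i + b_i)` with
  `a_i = f1 · Π_j p_j^{D_ij} (1−p_j)^{1−D_ij}`,
  `b_i = (1−f1) · Π_j q_j^{1−D_ij} (1−q_j)^{D_ij}`,
  plus a `majority_vote()` baseline.
* **Overlap metrics** — Dice `2|A∩B|/(|A|+|B|)`, Jaccard `|A∩B|/|A∪B|` and
  inclusion `|A∩B|/|A|` via `dice()`, `jaccard()`, `inclusion()`,
  `score_pair()`.
* **Experiment & statistics** — a leave-one-out, selected-versus-random
  design (`run_selected_arm()`, `run_random_arm()`, `run_loo_experiment()`)
  with Welch t-tests, an equivalence trial (two-sided 90 % CI inside a
  ±10 % margin) and a power-based sample-size helper.
* **Synthetic phantoms** — `generate_database()` and
  `simulate_registration()` build a BP-like phantom atlas database and a
  pluggable registration stand-in whose label-transfer error grows with the
  atlas-patient protraction difference, so the entire pipeline runs and is
  tested without any imaging data. Masks are NIfTI, landmarks JSON.

## Worked example

```r
library(atlasfuse)

cfg <- synthetic_config()           # 12 atlases, 48^3 voxels at 2 mm
res <- run_loo_experiment(config = cfg, seed = 1)

subset(res$summaries, strategy == "selected")
#>    strategy k n_runs dsc_mean dsc_sd ji_mean  ji_sd ini_mean ini_sd
#>    selected 2     12    0.359 0.1244   0.225 0.0933    0.244  0.103
#>    selected 3     12    0.535 0.1134   0.372 0.1051    0.470  0.130
#>    selected 4     12    0.607 0.1000   0.442 0.0992    0.601  0.135
#>    selected 5     12    0.607 0.0995   0.442 0.0979    0.682  0.128
#>    selected 6     12    0.589 0.0914   0.423 0.0876    0.744  0.119
#>    selected 7     12    0.571 0.0835   0.403 0.0775    0.801  0.117
#>    selected 8     12    0.544 0.0763   0.377 0.0705    0.838  0.104
```

Twelve phantom atlases, each patient in turn segmented from its `k` most
protraction-similar neighbours (7 × 12 = 84 runs): the mean Dice coefficient
rises from 0.36 at `k = 2` to 0.61 at `k = 4–5`, then declines as
increasingly dissimilar atlases are admitted — the optimum-`k` behaviour the
selection strategy predicts. Against random combinations:

```r
subset(res$t_tests, index == "dsc")
#>  k index mean_selected mean_random mean_difference     t        p
#>  2   dsc         0.359       0.182          0.1768 4.605 3.84e-04
#>  3   dsc         0.535       0.339          0.1959 5.282 5.15e-05
#>  4   dsc         0.607       0.433          0.1734 5.265 4.85e-05
#>  5   dsc         0.607       0.482          0.1250 3.903 1.16e-03
#>  6   dsc         0.589       0.516          0.0734 2.542 2.20e-02
#>  7   dsc         0.571       0.514          0.0564 2.144 4.83e-02
#>  8   dsc         0.544       0.522          0.0220 0.904 3.79e-01
```

Selection helps at every `k`, and helps most when few atlases are used —
with 8 of 11 candidates in play, selected and random combinations largely
overlap and the difference shrinks. The equivalence trial compares every
selected-arm `k` against the reference (`res$reference_k`, here 5, the `k`
with highest mean DSC):

```r
res$equivalence[["8"]]
#> <equivalence_result> d = 0.0627, 90%-type CI [0.0004, 0.1251],
#>   margin 0.0607 -> not equivalent
```

With only 12 runs per group the CI is wider than the 10 % margin, so
equivalence of 8 and 5 atlases cannot be claimed — and
`sample_size_two_means(sd = 0.12, delta = 0.08)` says 28 runs per group
would be needed to resolve such a difference (power 0.80, α = 0.10).

A command-line wrapper (`inst/cli/atlasfuse`) exposes the same stages:
`simulate`, `measure`, `select`, `fuse`, `score`, `evaluate`,
`equivalence`.

## Scope

Binary single-structure fusion only; NIfTI-1 masks (no DICOM-RT);
registration is a simulated, pluggable stand-in — see the methods vignette
(`vignettes/multiatlas-evaluation.Rmd`) for the model, its calibration and
its limitations.
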