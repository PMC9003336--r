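# intentfuse

Modular Bayesian sensor fusion for intent classification from multimodal
wearable sensor networks.

## The problem

Wearable intent-sensing systems — prosthetic controllers, assistive
robotics — infer what the user wants to do from passive sensors such as
surface electromyography (sEMG, ~1000 Hz) and inertial measurement units
(IMUs, ~60 Hz). In the real world sensors *drop in and out*: devices are
donned and doffed, batteries die, the user moves between sensing
environments. A conventional classifier trained on the concatenated
features of one fixed sensor combination cannot follow that churn.

`intentfuse` implements a **modular method (MM)**: one small
1-nearest-neighbour classifier per sensor, combined at decision level by
Bayes' rule with confusion-matrix weights. For intent class $c$, prior
$P(c)$ and per-sensor predictions $V_s$,

$$P(c \mid V) = \frac{P(c)\,\prod_s P(V_s \mid c)}
                     {\sum_{c'} P(c')\,\prod_s P(V_{s} \mid c')},$$

where $P(V_s \mid c)$ is read from sensor $s$'s confusion matrix,
estimated on a held-out *Probability Learning* half of the training data.
A sensor that disappears simply leaves the product; no other sensor is
retrained. The package also implements the **non-modular baseline (NMM)**
— a single combined k-NN over all sensors' features, with dropped sensors
zero-filled — and the full evaluation harness that compares them:
leave-one-out protocol with participant/activity-balanced split
optimisation, classification-horizon sweep, sensor-count sweep and
simulated-dropout sweep, with Spearman trend statistics, 95% t-intervals
and MM/NMM accuracy ratios.

Because the original laboratory recordings are available only on request,
the package ships a first-class synthetic generator
(`generate_dataset()`): class-conditioned burst-like sEMG envelopes over
broadband carriers and smooth minimum-jerk IMU kinematics, with
heterogeneous sensor informativeness, participant effects and shared
per-trial execution noise. It reproduces the statistical structure the
method assumes, so every stage is testable end to end.

## A worked example

Fuse two sensors' predictions through their estimated confusion matrices:

```r
library(intentfuse)

cm1 <- estimate_confusion(truth      = c(1, 1, 1, 2, 2, 2, 3, 3, 3),
                          prediction = c(1, 1, 2, 2, 2, 3, 3, 3, 3),
                          classes = 1:3, smoothing = 1, sensor_id = "semg01")
cm1
#> <sensor_confusion> semg01 3 classes, smoothing 1, balanced accuracy 0.556
#>     predicted
#> true     1     2     3
#>    1 0.500 0.333 0.167
#>    2 0.167 0.500 0.333
#>    3 0.167 0.167 0.667

cm2 <- estimate_confusion(c(1, 1, 2, 2, 3, 3), c(1, 2, 2, 1, 3, 3),
                          classes = 1:3, smoothing = 1, sensor_id = "imu01")
fuse(c(semg01 = 2, imu01 = 2), list(semg01 = cm1, imu01 = cm2))
#> <fusion_result> decision: 2 from 2 sensors
#>      1      2      3
#> 0.3636 0.5455 0.0909
```

Both sensors vote for class 2; the fused posterior concentrates on it
(0.55) while class 3, which neither sensor confuses with 2, drops to 0.09.

Simulate a small network and measure dropout robustness end to end
(36 trials, 3 intent categories, 8 sensors; ~6 s):

```r
ds <- generate_dataset(trial_design(n_participants = 3, n_activities = 6,
                                    n_trials_per_activity = 2),
                       sensor_network(n_semg = 4, n_imu = 4), seed = 1)
sw <- dropout_sweep(ds, N = c(0, 2, 4, 6), n_combos = 5,
                    n_repetitions = 3, seed = 1)
sw
#> <sweep_result> over n_dropped
#> # A tibble: 8 x 7
#>   variable  value method accuracy lower upper     n
#>   <chr>     <dbl> <chr>     <dbl> <dbl> <dbl> <int>
#> 1 n_dropped     0 mm        0.944 0.944 0.944     3
#> 2 n_dropped     2 mm        0.898 0.854 0.943     3
#> 3 n_dropped     4 mm        0.828 0.710 0.946     3
#> 4 n_dropped     6 mm        0.722 0.495 0.949     3
#> 5 n_dropped     0 nmm       1     1     1         3
#> 6 n_dropped     2 nmm       0.974 0.918 1.03      3
#> 7 n_dropped     4 nmm       0.846 0.549 1.14      3
#> 8 n_dropped     6 nmm       0.563 0.471 0.655     3

accuracy_ratio(sw)
#> <ratio_result> MM/NMM accuracy ratio: mean 1.032, range [0.922, 1.283]
```

With every sensor present the combined classifier is ahead (1.00 vs 0.94);
as sensors drop out it collapses (0.56 at 6 of 8 dropped) while the
modular method degrades gracefully (0.72), and the MM/NMM ratio climbs
from 0.92 to 1.28. `autoplot(sw)` draws the curves with their interval
ribbons; `time_sweep()` and `sensor_count_sweep()` run the other two
experiments; `run_pipeline()` drives everything from a YAML configuration
and writes tab-separated results with full provenance, and
`inst/cli/intentfuse` wraps it for the shell.

## Package layout

| Area | Functions |
| --- | --- |
| Synthetic data | `trial_design()`, `sensor_network()`, `generate_dataset()`, `class_separability()` |
| Conditioning | `filter_spec()`, `bandpass()`, `mvic_normalise()`, `truncate_trials()`, `slide_windows()`, `condition_dataset()` |
| Features | `feature_config()`, `semg_features()`, `imu_features()`, `extract_features()` |
| Classifiers | `knn_fit()`, `windowed_knn_fit()`, `predict_trial()`, `zero_input_predict()`, `combined_features()` |
| Fusion | `estimate_confusion()`, `sensor_accuracy()`, `fuse()`, `decide()` |
| Experiments | `loocv_folds()`, `balanced_split()`, `optimise_split()`, `run_fold()`, `time_sweep()`, `sensor_count_sweep()`, `dropout_sweep()`, `confidence_interval()`, `spearman_rho()`, `accuracy_ratio()` |
| IO / pipeline | `write_dataset()`, `read_dataset()`, `validate_run_config()`, `run_pipeline()` |

Results are tibbles throughout; `tidy()`, `glance()` and `autoplot()`
methods are provided for sweep results, confusion matrices and fusion
results. The methods vignette
(`vignettes/intent-fusion-methods.Rmd`) documents the generative models,
the numerical choices and the design decisions in detail.
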