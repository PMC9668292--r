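# mupop — motor-unit population analysis from multichannel intramuscular EMG

`mupop` is an R package for studying the output of a spinal motor-neuron
(MN) pool as a *population*. It is aimed at computational
neurophysiologists who work with high-density intramuscular EMG: it
simulates ground-truth motor-unit (MU) activity and multichannel EMG,
decomposes the EMG blindly back into MU discharge patterns, quantifies
decomposition accuracy against the known truth, and runs the two
population statistics that such recordings enable — pooled coherence and
directional pooled cross-histograms.

## The models and statistics at its core

**Generation.** A pool of leaky integrate-and-fire neurons receives a
common sinusoidal input plus independent Gaussian noise; per-neuron
constant drives are calibrated so discharge rates sit in the
physiological 11–19 pulses/s range (mean 14.8). Multichannel EMG is the
convolutive mixture

    x_c[k] = Σ_i Σ_l h_ci[l] · s_i[k − l] + n_c[k]

of per-MU, per-channel action-potential templates `h_ci` (Hermite–
Rodriguez waveforms with exponential spatial decay along a 40-electrode,
0.5-mm-pitch array) with the binary pulse trains `s_i`.

**Decomposition.** Convolution-kernel-compensation (CKC) style blind
source separation: the observation is extended with R delayed copies per
channel, whitened, and sources are extracted sequentially from
activity-indexed initializations, refined to a fixed point, gated by
pulse-to-noise ratio (PNR) and discharge count, and deflated so the same
pulse train is not re-identified (at most 150 candidate trains).

**Validation.** Discharges matched one-to-one within ±0.5 ms give

    RoA = TP / (TP + FN + FP),  Sensitivity = TP / (TP + FN),
    Precision = TP / (TP + FP)   (all in %).

**Population statistics.** Cumulative discharge patterns of two disjoint
random MU groups are compared by Welch magnitude-squared coherence
(0.5-s Hanning windows, 1-Hz bins, 25 random allocations per group
size), against the analytic confidence level

    CL = 1 − (1 − α)^(1/(N−1)),   N = number of windows.

Connectivity is probed by pooled forward-recurrence cross-histograms
(1-ms bins): for each reference discharge, the latency to the first
subsequent discharge of every partner MU, split by discharge rate
(faster half R1 → slower half R2 and vice versa), with dip detection,
surrogate controls, and a Kolmogorov–Smirnov comparison of the two
directions over the 10 bins around the dip.

## A worked example

```r
library(mupop)

## 1. simulate a 70-neuron pool receiving 33-Hz common input (20 s)
pool <- simulate_if_pool(if_model_params(), seed = 7)
mean(discharge_rates(pool))
#> [1] 15.22786

## 2. pooled coherence, two disjoint random groups of 35 MUs, 25 draws
coh <- pooled_coherence(pool, group_sizes = 35, n_reps = 25, seed = 7)
coherence_peak(coh, 35)
#> $frequency
#> [1] 33
#> $coherence
#> [1] 0.9655847
#> $significant
#> [1] TRUE
coh$confidence_level
#> [1] 0.07393759

## 3. directional cross-histograms and the post-discharge dip
halves <- split_by_rate(pool)
h12 <- pooled_cross_histogram(halves$R1, halves$R2)
h21 <- pooled_cross_histogram(halves$R2, halves$R1, direction = "R2->R1")
dip <- find_dip(h12)
str(dip)
#> List of 4
#>  $ dip_ms     : num 14.5
#>  $ depth      : num 1698
#>  $ z          : num 42.1
#>  $ significant: logi TRUE
ks_compare(h12, h21, center = dip$dip_ms)$p_value
#> [1] 0.05244755

## 4. synthesize 40-channel EMG from 5 units and decompose it blindly
sub <- spike_train_set(pool$trains[1:5], duration = 20,
                       provenance = "simulated")
tpl <- generate_muap_templates(5, n_channels = 40, seed = 7)
emg <- synthesize_emg(tpl, sub, noise_rms = 10, seed = 7)
dec <- ckc_decompose(preprocess_emg(emg), R = 10, seed = 7)
validate_against_truth(sub, as_spike_train_set(dec, 20), dec)
#>   mu_ref mu_test  TP FP FN RoA sensitivity precision      PNR
#> 1      3       1 276  0  0 100         100       100 24.64687
#> 2      1       2 374  0  0 100         100       100 25.15697
#> 3      2       3 256  0  0 100         100       100 20.65148
#> 4      4       4 279  0  0 100         100       100 27.14003
#> 5      5       5 269  0  0 100         100       100 26.10457
```

Reading the numbers: the pool fires at ~15 pulses/s; the coherence
between the two 35-MU cumulative trains peaks exactly at the 33-Hz
common-input frequency, far above the 0.074 confidence level; the
cross-histogram dips at ~15 ms — half the 30-ms input period — and the
two directions do not differ (KS p > 0.05), as expected for a pool with
common drive but no asymmetric inhibition; and all five MUs embedded in
the noisy 40-channel EMG are recovered with a perfect rate of agreement.

`run_pipeline(pipeline_config(...))` chains all of these stages with one
master seed and writes spike-train, EMG and report files; see the
vignette in `vignettes/` for the models, parameter choices and their
rationale.

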