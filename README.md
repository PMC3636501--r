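# ca3metric

How much of the Euclidean metric of physical space survives in a
self-organized hippocampal map? `ca3metric` simulates a threshold-linear
recurrent model of area CA3 driven by sparse multi-field dentate-gyrus
(DG) place units on a periodic (torus) environment, lets the recurrent
collaterals self-organize through a trace-based Hebbian rule, and then
interrogates the resulting population code with template decoding and
information theory. Its headline quantity is the **metric resolution
index**

    chi = 1 - sigma / w,

where `w` is the width of the Gaussian bump fitted to the
translation-averaged ("reduced") confusion matrix `Q(x - x0)` and `sigma`
is the decoding dispersion at which an idealized reference code — `1/a`
Gaussian bumps of volume `a` and width `sigma`, one on the correct
location — carries exactly the information measured in the full confusion
matrix. `chi = 1` means the code is spatially exact (the apparent bump is
pure averaging artefact); `chi = 0` means the entire bump width is genuine
spatial imprecision. The package also computes percent correct, plug-in
mutual information, the classical non-spatial information bounds
(`I_min`, `I_max` biased/unbiased) and metric content
`lambda = (I - I_min) / (I_max - I_min)`, sigmoid fits of information
versus sample size `I(n) = I_sat / (1 + (n0/n)^b)`, a drift-adjusted
(two-adjacent-bump) reference variant for the input-free attractor
condition, and a 3-D Sammon embedding of the 64 spatial templates with its
stress.

It is intended for computational neuroscientists studying population
codes, attractor dynamics and spatial information, and as a reference
implementation of the metric-resolution analysis for simulated or
suitably binned data.

## Worked example

The `desk` preset is a 1/5-scale replication (4,500 DG / 300 CA3 units,
C_MF = 50, C_RC = 180; learning 10,000 steps, templates 100,000, test
50,000) that runs in about ten minutes on one CPU:

```r
library(ca3metric)
res <- run_experiment(experiment_config("desk", seed = 1))
print(res)
```

```
Experiment result
Experiment config (desk): 4500 DG / 300 CA3, C_MF 50, C_RC 180, learn 10000 / template 100000 / test 50000 steps, seed 1
  DG on: I_full 0.569 1.06 2.03 3.07 3.81 4.42 4.67 4.79 4.82 bits; f_cor 0.0341 0.0634 0.145 0.29 0.468 0.642 0.713 0.743 0.753
  DG off: I_full 0.295 0.406 0.534 0.665 0.731 0.73 0.738 0.731 0.729 bits; f_cor 0.0233 0.0347 0.0482 0.0615 0.0684 0.0737 0.0758 0.0767 0.0767
  chi (on): 0.080 +/- 0.097
  chi (off): 0.095 +/- NA
  Sammon stress: 0.1436
```

Reading the output: with the DG input on, information extracted by the
Euclidean template decoder rises sigmoidally with the size of the decoded
unit sample (0.57 bits for one unit, 4.8 bits for 256, against a 6-bit
ceiling for 64 bins), and percent correct rises from 3% to 75%. Removing
the DG input and letting activity reverberate through the learned
collaterals (15 sweeps: full input, then 1/3, then none) retains far less
position information at this reduced scale — attractor capacity shrinks
with network size. The solved metric resolution with DG on is
`chi ~ 0.08`: the code keeps roughly a tenth of the optimal spatial
resolution, i.e. the decoding dispersion `sigma` is about 0.92 of the
fitted bump width `w`. The per-size table, the fitted bump parameters
(`pc`, `w`, `a`), the reduced matrices and the 3-D embedding are all in
the returned object (`res$chi$on`, `res$analysis$on`, `res$mds`), and
`run_experiment(..., out_dir = "results")` writes them as delimited text
with a JSON manifest.

A command-line wrapper with the same functionality is installed at
`system.file("cli", "ca3metric-cli.R", package = "ca3metric")`.

## Layout

* `R/`, `src/` — model (environment, DG population, CA3 network,
  plasticity; compiled inner loops) and analysis (decoding, confusion
  matrices, information, metric resolution, MDS).
* `vignettes/metric-resolution.Rmd` — the methods notes: model equations,
  parameter meanings and defaults, numerical choices, and what the
  reduced-scale preset does and does not show.
* `tests/testthat/` — unit, property and replication tests.
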