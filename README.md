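# waterPET

Quantitative tumour perfusion from dynamic ¹⁵O-water PET, for imaging
scientists and pharmacodynamics analysts who need absolute tumour blood
flow (mL/g/min) from a short dynamic acquisition with an image-derived
arterial input function — for example to measure the early anti-vascular
effect of an angiogenesis inhibitor before any change in tumour size is
visible.

## The model

The detected activity in a tumour volume of interest (VOI) is modelled
as a one-tissue compartment system with an explicit vascular volume
term:

```
M(t) = V0 · Ca(t) + Me(t),      dMe/dt = K1 · Ca(t) − k2 · Me(t)
```

where `Ca(t)` is the arterial input function (here taken from a
descending-aorta VOI on the dynamic study itself), `K1` (mL/g/min) is
blood perfusion into tissue, `k2` (1/min) the washout rate and `V0` the
vascular volume fraction — kept explicit because tumours are densely
vascularised. The analytic solution is
`M(t) = V0·Ca(t) + K1·(Ca ⊗ e^(−k2 t))(t)`.

Two solvers are provided:

* **Spectral analysis** — the curve is expressed as a non-negative sum
  of exponentials convolved with the input,
  `M(t) = Σᵢ αᵢ (Ca ⊗ e^(−βᵢ t))(t)`, with the rates βᵢ fixed on a grid
  from β = 0 up to a predetermined maximum, so that the αᵢ come from a
  linear non-negative least-squares problem (Lawson–Hanson). Summing
  the spectrum gives perfusion + vascular volume; summing only the
  rates below a vascular cutoff gives the tissue perfusion `K1`.
* **Nonlinear fit** — bounded Levenberg–Marquardt over (K1, k2, V0).

Around the solvers the package implements the full pipeline: 75 %-of-max
FDG tumour VOI with connected-component restriction, rigid
attenuation-image co-registration between the FDG and water studies,
VOI transfer, aorta VOI from the summed early frames, VOI-mean
time-activity curves, gamma-variate input-function fitting, bolus delay
estimation, ¹⁵O decay correction (half-life 122.24 s), SUV corrected
for lean body mass, metabolic response classification (OR / PD / MIXED
/ SD), cohort statistics (one-sided Welch t-test, Pearson correlation
with Fisher-z intervals, z-test of drug troughs against a 50 ng/mL
reference) and a 4-D digital phantom generator used by the test suite.

## Worked example

Simulate a patient study (48³ grid, 10-frame dynamic acquisition,
tumour K1 = 0.9 mL/g/min) and run the full pipeline:

```r
library(waterPET)
sim <- simulatePatient(phantomSpec(), seed = 7)
res <- runPerfusion(sim)
est <- perfusionFromSpectrum(res$spectral)
```

The run logs each stage (VOI voxel counts, registration shift, delay)
to stderr and prints:

```
whole-spectrum perfusion + blood volume: 3.234 mL/g/min
tissue perfusion (K1, spectral):        0.926 mL/g/min
tissue perfusion (K1, nonlinear):       0.903 mL/g/min
washout k2: 0.336 /min   vascular V0: 0.015   delay: -2 s
```

The whole-spectrum sum deliberately includes the vascular-volume
contribution absorbed by the fast exponentials; the tissue-only sum and
the nonlinear `K1` both estimate blood perfusion proper and land within
a few percent of the generating 0.9 mL/g/min at the default noise
level (exactly at zero noise).

Cohort statistics of the packaged seven-patient response table:

```r
st <- runCohortStats(fixtureTable())
```

```
perfusion decreases span 20-85%; SUV reductions 29-67%
metabolic responders 6/7; Welch one-sided p = 0.059
```

A thin command-line wrapper with `simulate`, `perfusion`,
`cohort-stats` and `fixture` subcommands is installed at
`inst/scripts/waterpet.R`.

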