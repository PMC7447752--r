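# memfir

Software simulator of an analog neural-signal analysis system in which both
a four-band FIR filter bank and a single-layer perceptron classifier run as
matrix–vector products on memristor crossbar arrays. The package targets
researchers in neuromorphic/in-memory computing and neural engineering who
want to study how device non-idealities propagate through an analog
epileptic-state detection chain without access to physical hardware.

## The model

An FIR filter bank is a matrix product: at time step *n* the lagged input
row vector multiplies the (K+1)×M coefficient matrix **H**,

    y^m(n) = Σ_{k=0}^{K} x(n−k) h^m(k),   m = 1…M.

A memristor crossbar computes this by physics — row voltages, Ohm's law,
Kirchhoff current summation per column. Conductances are non-negative, so
each signed coefficient is a *differential pair*:

    I^m(n) = Σ_k V(n−k) (G₊^m(k) − G₋^m(k)),

with devices programmable in 2–20 µS. A 120-order filter (121 taps) costs
242 devices, the delta/theta/alpha/beta bank 968, and the 21×3 perceptron
decoder 126. The simulator models programming error (clipped additive
Gaussian per device) and read noise (multiplicative Gaussian per
device-read), a synthetic three-class LFP generator (normal / interictal /
ictal, 4096-sample clips), biomarker extraction (max, min, mean, Σ|·|, Σ·²
per band), perceptron training/inference in the 0.1–0.3 V input window,
and an itemized power model comparing the analog system with a CMOS
baseline.

## Worked example

```r
library(memfir)

clip <- generate_clip("ictal", seed = 7)
clip
#> <memfir_clip> ictal_7: 4096 samples @ 173.6 Hz, label 'ictal'
#>   range [-1.48e+03, 1.58e+03] uV, sd 465 uV

bank <- build_filter_bank()
bank
#> <memfir_bank> 121 taps x 4 filters @ 173.6 Hz (order 120)
#>   delta  0.5-4 Hz
#>   theta  4-8 Hz
#>   alpha  8-12 Hz
#>   beta   12-30 Hz
#>   differential-pair device demand: 968

dm   <- device_model()
pair <- program_pair(map_to_conductance(unclass(bank), dm), dm, seed = 1)
seg  <- segment_clip(clip)[[1]]            # first 600-sample segment
tr   <- to_voltage(seg)                    # scale to the 0.2 V read window
mes  <- filter_signal_crossbar(tr, pair, dm, seed = 2)   # crossbar path
ref  <- apply_bank_reference(tr$volts, bank)             # software oracle
error_stats(ref, mes)
#> <memfir_error_stats>
#>   delta  mu = +8.957e-06, sigma = 0.0007221
#>   theta  mu = +8.397e-06, sigma = 0.0009151
#>   alpha  mu = -6.428e-06, sigma = 0.0005414
#>   beta   mu = +2.513e-05, sigma = 0.0006195
#>   pooled mu = +9.015e-06 (0.00% of peak-to-valley), sigma = 0.000713 (0.35%)

power_report()
#> <memfir_power_report>
#>   per-device read power        0.800 uW
#>   filter-bank energy          138.72 pJ/sample
#>   memristor system:
#>     filter bank                1.387 uW/class
#>     perceptron                 0.200 nW/class
#>     total                      1.387 uW/class
#>   CMOS baseline:
#>     filter front end           352.8 uW/class
#>     decoder                    199.1 uW/class
#>     total                      551.9 uW/class
#>   CMOS / memristor ratio       397.8 x
```

The error statistics say the crossbar-filtered waveforms deviate from the
exact convolution by a standard deviation of ~0.4% of this ictal segment's
peak-to-valley span at the calibrated noise level — small enough that the
downstream classifier barely notices. The power report itemizes why the
analog implementation wins: one read pulse per device per sample at
sub-microwatt device power versus a digitally scaled FIR/classifier
baseline, a ~398× efficiency gap.

A full experiment — 100 clips per class, software (S) and crossbar (M)
datasets, ten training trials for the S.S. / M.S. / M.M. operating modes,
error analysis and the power report — is one call:

```r
manifest <- run_experiment(experiment_config(seed = 1))
manifest
```

A thin CLI over the same functions ships in `inst/scripts/memfir`
(verbs: `synth`, `design`, `map`, `filter`, `decode`, `power`, `run`,
`fixtures`).

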