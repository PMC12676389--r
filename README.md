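# smfretr

Single-molecule FRET (smFRET) trace analysis and membrane nanocluster
statistics for R.

Surface-immobilised receptors carrying a donor/acceptor dye pair report
conformational change as anticorrelated intensity fluctuations in two
camera channels. Getting from a two-channel TIRF movie to a defensible
statement like "the active-state population is 26% ± 3%" requires a long
chain of corrections and filters — channel registration, spot detection and
pairing, local background subtraction, donor-leakage removal,
photobleaching-step detection, per-molecule gamma correction, a
multi-criterion trace selection, histogramming and population fitting —
each of which can silently bias the result. `smfretr` implements that chain
as composable, individually tested functions, together with a synthetic
movie/trace generator with known ground truth so every stage can be
validated end to end. A second, independent branch quantifies immunogold
nanocluster sizes on unroofed membrane sheets and compares conditions.

It is written for single-molecule biophysicists and microscopy-core
analysts who want a scriptable, reproducible alternative to ad hoc
per-lab analysis code.

## The quantities it computes

* **FRET efficiency** per frame: `E = Ia / (Ia + γ·Id)`, with `Ia`, `Id`
  the background- and leakage-corrected acceptor and donor intensities and
  `γ` a per-molecule detection/quantum-yield correction estimated from the
  intensity changes at acceptor photobleaching, `γ = ΔIa / ΔId`.
* **Donor leakage**: `Ia ← Ia_raw − α·Id` with `α = 0.07` by default.
* **Trace selection**: (1) signal-to-noise ratio ≥ 5; (2) single-step
  acceptor photobleaching before donor bleaching; (3) `0.5 ≤ γ ≤ 2.5`;
  (4) anticorrelated donor/acceptor fluctuations; (5) single-step donor
  bleaching, if present; plus acceptor-identity confirmation by a direct
  acceptor-excitation segment.
* **Population histograms**: per-molecule FRET histograms on 30 bins over
  `[−0.25, 1.25]`, each normalised to unit mass, averaged with equal
  molecule weight, and fit to a two-Gaussian model whose area shares give
  the state populations (bootstrap over molecules for uncertainties).
* **Trace idealization**: two-state Gaussian-emission hidden Markov model
  (Baum–Welch + Viterbi) yielding state paths and dwell times.
* **Nanocluster statistics**: single-linkage clustering of gold-particle
  coordinates at a configurable linkage radius; per-condition cluster-size
  frequency and cumulative-probability curves; two-sided Mann–Whitney U
  (exact for small samples) or Kolmogorov–Smirnov comparison.

## Worked example

Simulate a dynamic two-state receptor ensemble (FRET means 0.25/0.85,
0.5 /s switching, equal occupancies, realistic shot + camera noise,
tens-of-seconds photobleaching), run the full correction/QC/analysis
chain, and quantify the active (low-FRET) population:

```r
library(smfretr)

cfg <- sim_config_dynamic(seed = 42)
sim <- simulate_traces(cfg, 120)
cts <- correct_traces(sim$traces)
qc  <- lapply(cts, apply_qc)
s   <- qc_summary(qc)
ens <- fret_ensemble(cts, qc = qc)
fit <- fit_two_gaussian(ens$ensemble)
pf  <- population_fractions(fit, ens$ensemble$per_molecule,
                            n_boot = 200, seed = 1)
```

which prints (via `print(fit)` and a summary line):

```
accepted 55 of 120 molecules (46%)
two-Gaussian population fit
  low : mu 0.252 sigma 0.067 area 0.471 fraction 48.6%
  high: mu 0.846 sigma 0.089 area 0.499 fraction 51.4%
  rss 0.00032 over 30 bins (55 molecules)
active (low-FRET) population: 48.6 +/- 2.4%
```

Read: about half the molecules survive the five selection criteria (the
losses are early/undetected acceptor bleaching, out-of-bounds gamma and
low signal-to-noise — the same funnel a real recording goes through); the
fitted low-FRET mean 0.252 and high-FRET mean 0.846 recover the simulated
state means, and the active population 48.6 ± 2.4% recovers the true 50%
stationary occupancy within its bootstrap uncertainty.

`plot(ens$ensemble, fit = fit)` draws the ensemble histogram with the
fitted components; `plot(cts[[1]], idealize_trace(...))` shows a single
trace with its bleach annotations and state path. Movies work the same
way through `simulate_movie()` and `process_movie()`; gold-particle tables
go through `cluster_size_stats()` and `compare_conditions()`.

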