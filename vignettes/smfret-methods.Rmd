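---
title: "From two-channel movies to state populations: the smfretr methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From two-channel movies to state populations: the smfretr methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`smfretr` turns two-colour single-molecule FRET recordings of
surface-immobilised molecules into conformational-state populations, and
gold-particle coordinate tables into nanocluster-size comparisons. This
vignette explains the models behind each stage, the parameters that
matter, the numerical choices, and what the synthetic-data tests do and do
not demonstrate about real data.

## Signal model and the gamma convention

During donor excitation a molecule in a state with FRET efficiency $E$
emits an expected

$$ I_d = (1 - E)\, I_0, \qquad I_a = \gamma\, E\, I_0 $$

in the donor and acceptor channels, where $I_0$ is the molecule's photon
budget per frame (arbitrary linear camera units) and $\gamma$ absorbs the
donor/acceptor difference in detection efficiency and quantum yield.
Under this convention the ratiometric estimator

$$ E = \frac{I_a}{I_a + \gamma I_d} $$

is exact on noise-free data, the quantity conserved across conformational
transitions is $I_d + I_a/\gamma = I_0$, and the standard
donor-recovery estimator at acceptor photobleaching,
$\hat\gamma = \Delta I_a / \Delta I_d$, is exact as well. A useful
property of that estimator, exploited by `estimate_gamma()`, is that the
state occupancy inside the averaging windows cancels between the acceptor
loss and the donor gain, so window placement relative to conformational
dynamics does not bias $\hat\gamma$.

A fraction $\alpha$ of donor emission (default 0.07) leaks into the
acceptor channel and is subtracted first: $I_a = I_a^{raw} - \alpha I_d$.
No correction is made for direct acceptor excitation during the donor
segment; the recording is assumed to use a single donor-excitation laser
followed by a short direct acceptor-excitation segment whose only role is
to confirm the acceptor's identity.

## What the simulator emulates

`sim_config()` / `simulate_traces()` generate the study conditions the
analysis is designed for:

| parameter | default | meaning |
|---|---|---|
| `frame_period` | 0.1 s | camera exposure per frame |
| `n_frames_donor_exc` | 800 | 80 s donor-excitation segment |
| `n_frames_acceptor_exc` | 10 | 1 s direct acceptor excitation |
| `state_means` | 0.5, 0.9 | FRET level of each state |
| `transition_rates` | none | per-second rate matrix; `NULL` = static mixture |
| `total_intensity` | 1000 | photon budget $I_0$ per frame |
| `donor_bleach_lifetime` | 60 s | exponential single-step bleaching |
| `acceptor_bleach_lifetime` | 40 s | idem; acceptor usually dies first |
| `leakage_alpha` | 0.07 | donor-to-acceptor spectral leakage |
| `gamma_range` | 0.5–2.5 | per-molecule $\gamma$, uniform |
| `background_sigma` | 100 | additive Gaussian noise sd per channel |
| `contaminant_fractions` | 0 | donor-only / acceptor-only / aggregate |

Noise is Poisson shot noise on expected counts plus additive Gaussian
background; the defaults put the median trace signal-to-noise ratio
(defined below) near 8, above the selection cut of 5. Two state regimes
are bundled: the default static mixture (two labelling geometries at
$E \approx 0.5$ and $0.9$ that never interconvert — occupancies are
realised as exact molecule counts so a prepared ensemble has exactly the
requested composition) and `sim_config_dynamic()`, a receptor switching
between an active low-FRET state ($E = 0.25$) and an inactive high-FRET
state ($E = 0.85$) at 0.5 /s (2 s mean dwells), i.e. activation-linked
helix movement read out as a high-to-low FRET transition.

Aggregate contaminants superpose two or three independent dye pairs at one
position (multi-step bleaching, over-bright); donor-only molecules lack
the acceptor entirely (leakage-only acceptor signal, dark under direct
excitation); acceptor-only molecules are dark during donor excitation but
light up under direct excitation.

`simulate_movie()` renders the same photophysics as diffraction-limited
spots (Gaussian PSF, $\sigma = 1.2$ px, integrated over pixels with the
error function, so aperture sums are analytically predictable), applies a
known donor-to-acceptor affine transform, adds Poisson camera noise on a
constant offset plus Gaussian read noise, and emits a fiducial-bead image
pair for registration. `simulate_particle_pattern()` produces clustered
2D point patterns (Gaussian scatter around well-separated centres plus
uniform background singletons) with exact cluster labels.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: sub-frame state averaging at
transitions, triplet blinking, spectral cross-talk beyond single
donor-to-acceptor leakage, stage drift, EMCCD gain stochasticity, and
non-Gaussian camera artefacts. The pipeline's recovery numbers are
statements about this model, not guarantees for any particular microscope.

## Movie processing

Registration detects beads in both fiducial images, matches them by
nearest neighbour after removing the bulk shift, and fits the six affine
parameters by least squares; typical residuals on synthetic beads are well
under 0.1 px. Spot detection smooths lightly (Gaussian, $\sigma = 1$ px),
takes strict local maxima in a 5-pixel square window above a robust
threshold (4 median-absolute-deviations of the smoothed image; on
noise-free images, where the robust spread is zero, a small fraction of
the dynamic range), and refines positions by log-quadratic interpolation
of the peak — exact for a Gaussian profile — with an intensity-centroid
fallback. Both detection images are averages of the first 20
donor-excitation frames: the acceptor channel then shows FRET-sensitized
emission, so both dyes are detected while still photoactive. (The late
direct-excitation segment is *not* used for detection: with
tens-of-seconds bleaching most acceptors are already dark by then. It is
used for identity confirmation.)

Pairing maps acceptor detections into the donor frame and matches greedily
by ascending distance (2 px default cap); donor spots without a partner
are flagged donor-only and excluded. Traces are extracted as circular
aperture sums (7 px diameter default; the aperture holds ≥ 98% of a
$\sigma = 1.2$ px spot) minus a local background: the median pixel value
inside a concentric 35-px-diameter region, excluding the aperture and
pixels near other detected spots, scaled to the aperture area. Spots whose
background region leaves the image are skipped with reason `"edge"`,
overlapping spots with `"crowded"`.

## Trace correction and bleach bookkeeping

Each channel is segmented into a piecewise-constant mean model by
penalized least squares (optimal partitioning with PELT pruning, penalty
$3\sigma^2\log n$, noise $\sigma$ estimated from median absolute
successive differences divided by $\sqrt2$). A candidate step is kept when
its mean change is significant at 3 standard errors of the difference of
the two segment means, $|\Delta| > 3\sigma\sqrt{1/l_1 + 1/l_2}$. The SE
form matters: an absolute cutoff (e.g. $3\sigma$ per frame) erases the
acceptor-bleach step out of a low-FRET state — whose height is only
$\gamma E_{low} I_0$ — and thereby systematically deletes terminal
active-state dwells, biasing recovered active fractions low. The same
logic classifies segments as alive or photobleached: a segment is alive
when its mean exceeds 3 standard errors ($\sigma/\sqrt{l}$) of background,
so a dim but long low-FRET dwell is alive while a trailing background run
is dead.

Conformational transitions and bleaching both produce steps, so the two
must be told apart. A trace is called *dynamic* when the acceptor steps
between two above-background levels **and** the donor moves in the
opposite direction at the same frame — the signature of energy transfer
redistribution. An irreversible acceptor drop without donor compensation
is bleaching. On static traces every persistent downward step is a bleach
step; on dynamic traces, acceptor bleach steps are the downward steps that
land at background, and donor bleach steps are counted in the
acceptor-dark part of the trace, where FRET no longer modulates the donor.
When the acceptor channel shows no detectable step at all (a dim acceptor
bleaching out of the low-FRET state), the donor still reports the event as
a persistent upward step of height $E I_0$ — independent of $\gamma$ —
after which the acceptor sits at background; `correct_trace()` uses this
donor-evidence rescue, which removes the selection bias against
mostly-active molecules that acceptor-only detection would cause.

Derived per-molecule quantities:

* **gamma** — window means (50 frames each side, 3 frames around any step
  excluded) across the acceptor bleach; undefined when the donor does not
  recover or fewer than 10 usable frames remain on a side.
* **signal-to-noise ratio** — mean pre-acceptor-bleach total intensity
  divided by the sd of its high-frequency residual after subtracting a
  5-frame running median. The running-median residual isolates
  frame-to-frame noise from slow dynamics and steps. Noise-free traces
  report a capped sentinel (10^6).
* **anticorrelation** — Pearson correlation of the frame-to-frame
  differences of the two channels over the pre-bleach segment. Dynamic
  molecules show strongly negative values, with magnitude growing with
  $\gamma$ (the acceptor jump is $\gamma \Delta E I_0$); a static molecule
  carries no fluctuation signal and is instead judged on the opposite-sign
  window-mean changes at its acceptor-bleach step.

## The five-criterion selection

`apply_qc()` evaluates, in order: (1) SNR ≥ 5; (2) exactly one acceptor
bleach step, before any donor bleach; (3) $0.5 \le \gamma \le 2.5$;
(4) anticorrelated fluctuations (threshold $r \le -0.3$ for dynamic
traces; bleach-step anticorrelation for static ones and as a fallback);
(5) at most one donor bleach step, evaluated only if the donor bleaches at
all (not-applicable otherwise); plus acceptor-identity confirmation: a
surviving acceptor must light up under direct excitation, while an
acceptor that bleached mid-movie is evidenced by its bleach step itself.
All thresholds are inclusive, so boundary values (SNR = 5.0,
$\gamma = 0.5$ or 2.5) pass. The report records every criterion's outcome
and attributes a rejection to the first failure in the printed order; the
pass/fail decision itself is order-independent. On default synthetic
ensembles roughly half the good molecules survive — losses are dominated
by acceptors that bleach too early, too late or not detectably, the same
funnel real recordings go through — and over 90% of simulated
contaminants are removed.

## Histograms, the two-Gaussian model, and uncertainties

FRET is computed frame-wise over the pre-acceptor-bleach segment only
(3 frames before the step dropped; post-bleach E is undefined). Each
molecule's values are binned into 30 half-open intervals spanning
$[-0.25, 1.25]$ (the last bin closed; width 0.05), normalised by the
molecule's in-range count, and the ensemble histogram is the unweighted
per-bin mean over molecules — every molecule contributes one unit of mass
regardless of trace length. Out-of-range values and molecules without
in-range values are excluded and counted.

The population model is a two-Gaussian fit to the ensemble means at the
bin centres: $w[A_1 N(\mu_1,\sigma_1) + A_2 N(\mu_2,\sigma_2)]$ with $w$
the bin width, bounded parameters ($\mu \in [-0.25, 1.25]$,
$\sigma \in [0.01, 0.5]$, $A \in [0, 2]$), Levenberg–Marquardt least
squares from multiple starting points (a data-driven peak pair plus a
fixed grid), components ordered by mean after fitting. Populations are
reported as **area shares** $A_i/(A_1+A_2)$; a per-molecule mode with a
shared width is available (`shared_sigma = TRUE`). Uncertainties come
from a molecule-level bootstrap: resample molecules with replacement,
re-average, refit initialised at the point estimate, and take the SD of
the refitted fractions (200 replicates by default, seeded). On a
degenerate single-mode histogram the second component collapses to
near-zero area, which is reported rather than treated as an error.

Idealization fits a two-state Gaussian-emission hidden Markov model by
Baum–Welch (initialised by 2-means clustering, emission SDs floored at
0.005) and takes the Viterbi path; dwell times are the run lengths times
the frame period. A trace whose two fitted emission means sit closer than
three emission SDs is declared static and assigned one dwell. A
transparent midpoint-threshold idealizer is available as
`method = "threshold"`. When estimating mean dwell times, drop the first
and last dwell of each trace (both are censored by the observation
window); on default dynamic ensembles the recovered mean dwells land
within about 10% of the simulated 2 s.

Two estimators of the active fraction — mixture areas and idealized state
occupancy — agree within a few percentage points on simulated data, which
is a useful internal consistency check (`test-idealize.R` automates it).

## Nanocluster statistics

Clusters are single-linkage connected components: particles closer than
the linkage radius are linked, and a cluster is any maximal connected set
(singletons allowed). The rule is order- and rigid-motion-invariant, and
monotone: growing the radius can only merge clusters. The radius is a
required, reported parameter (default 30 nm, i.e. three nominal 10 nm
gold-particle diameters); conclusions should be checked across a radius
sweep since the operational definition of "cluster" depends on it.
Cluster sizes are pooled across the images of a condition (per-image
breakdowns retained), summarised as frequency tables and empirical CDFs,
and compared across conditions with a two-sided Mann–Whitney U test —
exact by enumeration of all group assignments when the pooled sample is
small (≤ 12), the normal approximation with tie correction otherwise — or
a Kolmogorov–Smirnov test. Pooling cluster sizes across images treats
clusters, not images, as the unit of replication; per-image summaries
support a pseudoreplication-safe alternative when image-to-image
variation matters.

## Numerical and design choices

* Coordinates are 0-based pixel centres; sub-pixel positions continuous.
* The change-point dynamic program is exact (optimal partitioning; PELT
  pruning does not alter the optimum) and implemented in C++ for speed.
* Bin edges are generated once (`fret_bin_edges()`); boundary values fall
  in the right-closed last bin; values exactly on an interior edge belong
  to the bin on their right.
* All simulation randomness flows from one master seed through stable
  per-molecule sub-streams, so results are independent of generation
  order and reruns are bitwise identical; `run_pipeline()` fans a single
  global seed out to per-stage sub-seeds by stable hashing.
* Degenerate inputs: empty point sets cluster to an empty list; zero
  in-range FRET values exclude the molecule with a count; a zero-variance
  Mann–Whitney comparison reports p = 1 with a flag; traces shorter than
  20 pre-bleach frames fail QC with reason `"short"`.
* Test problem sizes were chosen to exercise each claim at meaningful
  statistical resolution while keeping the default suite fast: 200–800
  molecules for recovery and bias checks, 50-molecule movies, 500 step
  traces against the exhaustive change-point oracle, 1000 null
  repetitions for test calibration.

## Known limitations

The static/dynamic classification can mislabel pathological cases — an
aggregate whose internal acceptor bleach coincides with a donor rise looks
like a transition; such molecules are usually still removed by the donor
multi-step or gamma criteria, but the per-criterion attribution may
differ. Acceptor bleaches out of very short terminal low-FRET dwells can
still be placed a few frames early. The HMM assumes two states with
Gaussian emissions; more states, degenerate-width states, or non-Markovian
kinetics are out of scope. The Mann–Whitney normal approximation is
slightly conservative under heavy ties; the exact mode is automatic only
for small samples.
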