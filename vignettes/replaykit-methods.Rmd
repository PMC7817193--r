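---
title: "Models and methods behind replaykit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind replaykit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`replaykit` analyzes place-cell recordings from a checkpoint-learning task
and ships a generator of synthetic sessions with complete ground truth.
This vignette documents the models, the tunable parameters and their
defaults, what the generator does and does not emulate, and the numerical
and design choices a maintainer should know about. It states no empirical
result that the test suite does not itself compute.

## The task world

The arena is a lattice of square cells (default 5×5, 20 cm cells) with a
start box (S) below, a goal box (G) above, and a peripheral return alleyway.
Two lattice cells are reward checkpoints: C1 (fourth column from the left,
second row from the bottom) and C2 (second from the left, fourth from the
bottom). Sessions have three phases: *pre* (reward at C1; trials run
S–C1, C1–G, return), *learning* (reward moved to C2; trial-and-error
trials run S–C1, C1–G, G–C2, C2–G, return), and *post* (the efficient
strategy S–C2, C2–G, return). The ground-truth learning point is the first
post-phase trial. The six canonical paths are each their own 1D axis;
analysis-side linearization projects positions onto the polyline of the
path identified by landmark-visit segmentation — no generator internals are
used by the analysis functions.

The start and goal anchors sit asymmetrically (12 cm below / 18 cm above
the lattice) so path lengths are distinct except for the physically
identical G–C2/C2–G corridor; exact arena dimensions of the original
apparatus are not public, so these defaults are stand-ins chosen once.

## Synthetic sessions: what is emulated

* **Behavior.** Constant nominal running speed (25 cm/s, lognormal
  per-traversal jitter, sd of log 0.08) along piecewise-linear path
  templates, 50 Hz position samples with 0.5 cm Gaussian tracking noise,
  and immobility pauses (lognormal, median 3 s) at S, visited checkpoints
  and G — the locations where synchronous events occur. The speed estimator
  smooths positions (5-sample boxcar) and differentiates over ±5 samples so
  tracking noise does not read as movement; with a 4 cm/s threshold the
  pauses are correctly classified as immobility.
* **Tuning.** Unit types: stable (Gaussian field, fixed path), context
  (field at a fixed distance before the destination, expressed on every
  analogous path of its group — S-C1/S-C2/G-C2 approach a checkpoint,
  C1-G/C2-G approach the goal), on/off (field gained/lost at the
  reward-replacement boundary), and nonplace (untuned, 1 Hz). Default mix
  0.40/0.30/0.10/0.10/0.10; peaks 8–20 Hz, widths 8–12 cm. Stable/on/off
  units may carry 1–3 fields (multiple place fields are common in real
  CA1). Two deliberate identifiability constraints: the primary field of
  stable/off units lies on a path run in *every* phase (otherwise
  "stability" is unobservable in a phase comparison), and context units
  cycle deterministically through the two correspondence groups at 3:2 so
  that per-path coverage cannot collapse by sampling accident.
* **Spiking.** Inhomogeneous Poisson by thinning on a 2 ms grid (which
  doubles as the refractory period), rate = Gaussian spatial envelope ×
  theta modulation `1 + d·cos(θ − φ)`, depth d = 0.7, theta 8 Hz. Phase
  precession spans 270° across the field, mapped so that — with cycles cut
  at theta troughs — cells whose fields lie behind the animal fire early in
  the cycle and cells with fields ahead fire late: the forward theta sweep.
  Spatially uniform background at 0.15 Hz per unit (sparse CA1-like
  immobility firing; also keeps multiunit-coincidence false detections
  below ~1/min, the detector's null bound).
* **LFP.** 1/f (pink) background at 1,250 Hz, theta added during running,
  and a Hann-windowed ripple-band burst (default 200 Hz) at each scheduled
  event.
* **Replays.** A phase-dependent schedule places events in immobility
  pauses (pre 0.15 / learning 0.35 / post 0.30 events per second of pause).
  Content distributions shift across learning thirds: experienced paths
  dominate pre; G–C2/C2–G dominate the first two thirds of learning; the
  efficient S–C2 becomes the majority in the last third — before the
  behavior switches. Participating units (those with a field on the path)
  emit one or two spikes at times proportional to their field positions,
  compressed 15× (event duration = path length / (speed × compression),
  clamped to 60–400 ms), reversed for reverse replays, jittered by 8 ms.

**Not emulated:** biophysical membrane dynamics, interneurons,
spike-sorting artifacts, electrode drift, multi-day recording, sleep
replay, and the closed-loop SWR-disruption hardware. A green test therefore
establishes that the *analysis* recovers what the *statistical* model of
the data contains — not that the model is a complete account of CA1.

## Analysis methods and numerical choices

* **Rate maps.** 2 cm linearized bins, spike counts and occupancy
  accumulated per trial (so leave-one-out refits are sums of sufficient
  statistics), Gaussian smoothing (sd 2 bins) applied after summing,
  occupancy mask at 0.1 s. Smoothing uses FFT convolution padded to
  composite lengths; round-off negatives are clamped to zero.
* **Place fields.** Contiguous runs above max(20% of the unit's peak,
  0.5 Hz), kept if peak ≥ 2 Hz, extent ≥ 3 bins and ≤ 60 cm. The width cap
  and the 2 Hz floor (rather than 1 Hz) exclude diffuse untuned firing;
  both are configurable and are declared substitutes for unavailable
  protocol details.
* **Joint classification.** Stable: same path, peak positions within 10 cm.
  Context: analogous paths of one group at matching distance-to-destination
  (10 cm tolerance). Per-unit label uses context priority (a context unit
  also produces stable same-path pairs on shared paths).
* **Decoder.** Flat prior, memoryless; rate floor ε = 0.01 Hz; 200 ms bins
  for run decoding, 20 ms for events; log-space evaluation. The error
  metric is linearized distance within the true path, and a cross-path MAP
  is penalized with the full true-path length (conservative). The
  likelihood is not scale-invariant: multiplying all rates by c while
  dividing τ by c changes the exposure term, so no such invariance is
  claimed or tested.
* **Event scoring.** Reprates, the weighted correlation and the MAP
  trajectory criterion use only *occupied* time bins (≥ 1 spike). A
  zero-spike bin's posterior is pure exposure term `exp(−τΣλ)` and
  systematically favors whichever path has the lowest summed rate — in
  practice the long return alleyway — so including such bins corrupts
  content estimates. `decode()` itself retains the prior-driven zero-spike
  behavior.
* **Nulls.** repZ: unit-identity shuffle (tuning rows permuted, event
  re-decoded). rZ: column-cycle shuffle (independent circular shift of each
  time bin's position distribution). Both seeded and reproducible.
* **Sequential events.** `|r| ≥ 0.5`, with direction from the sign of r
  (path axes run start→destination). The threshold is applied to the
  magnitude because forward and reverse events are both retained
  downstream.
* **SWR detection.** 150–250 Hz zero-phase FIR (windowed-sinc), Hilbert
  envelope, smoothed (Gaussian sd 5.3 ms), z-scored on immobility. Events:
  z > 3 sustained for ≥ 20 ms (momentary noise excursions of a Rayleigh
  envelope would otherwise alarm several times per minute), extended to
  z > 0.5, merged across < 50 ms gaps, duration-limited to 20–500 ms.
* **Theta sequences.** Cycles are trough-to-trough (peak reference
  available), 6–10 Hz, durations restricted to 1/12–1/5 s, immobility
  excluded. The quadrant score is computed on a single-cycle window with
  the quadrant center at the cycle midpoint and relative position ±50 cm in
  2 cm bins. A two-cycle display window split at the cycle *boundary* was
  considered and rejected: a sweep that repeats every cycle contributes
  equally to all four quadrants of such a window, making the score
  identically zero — with the midpoint-centered single cycle, an ideal
  forward sweep scores exactly 1 and a position-symmetric posterior exactly
  0. Note the score is *not* invariant under a uniform additive posterior
  offset: the quadrant contrast (numerator) is, but the normalization
  grows, shrinking the score toward zero while preserving its sign.
* **Hierarchical models.** Poisson counts with log-link phase effects and
  non-centered rat intercepts (priors: Normal(0, 1.5) on fixed effects,
  half-Normal(1) on the rat sd); binomial proportions with logit link.
  Sampling is adaptive random-walk Metropolis (Haario covariance
  adaptation) composed with component-wise Metropolis sweeps and two
  model-specific moves: a translation along the likelihood-invariant
  fixed-effect/intercept ridge and a σ-versus-z rescaling (with Jacobian)
  for the funnel. This composition was adopted because plain adaptive RWM
  left split-R̂ near 2 on the ridge; with it, R̂ < 1.05 and ESS in the
  hundreds at the default 4 chains × (800 warmup + 800 draws).
  Non-convergence is flagged and warned, never silent. Multinomial path
  proportions are produced as per-category binomial fits renormalized at
  the summary level — a deliberate simplification over a joint softmax
  model.
* **Posterior overlap.** Common-grid histogram (256 bins over the pooled
  0.1–99.9 percentiles, out-of-range draws clamped to edge bins); the
  decision helper flags overlap < 0.05. Degenerate constant draw sets are
  compared directly.
* **Behavior metrics.** String = lattice-cell sequence with consecutive
  duplicates collapsed; trajectory distance is plain Levenshtein on these
  strings (robust to sampling rate; matches the integer "distance ≥ 2"
  change criterion). The learning curve is a centered 5-trial moving
  average of the exact-efficient-trial indicator with a sustained ≥ 0.5
  criterion; window and threshold are configurable substitutes for
  unavailable protocol details.

## Known limitations

* Every path is its own decoder axis; positions at shared corridor ends
  (e.g. G–C2 vs C2–G) are genuinely ambiguous for the decoder, and the
  conservative cross-path penalty charges the full path length for such
  confusions. Median leave-one-out error is the honest headline number;
  means are inflated by this penalty.
* The represented-path statistic inherits the state-space asymmetry of
  unequal path lengths; false-positive synchronous events (population
  coincidences) tend to decode to the longest path.
* The MCMC models aggregate counts to (rat, phase) sufficient statistics;
  trial-level covariates beyond exposure are out of scope.
* Theta-sequence scores depend on encoder quality; with few traversals the
  per-path score is reported as NA below 20 qualifying cycles rather than
  extrapolated.
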