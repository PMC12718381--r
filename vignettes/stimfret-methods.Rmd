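---
title: "Models and methods behind stimfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stimfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

STIM1 is the ER calcium sensor that switches store-operated calcium entry
on and off. It is too flexible for crystallography or cryo-EM as a
full-length protein, so its resting conformation is studied by
single-molecule FRET (smFRET): donor and acceptor dyes are attached at
engineered cysteines, single molecules are imaged in TIRF, and the
efficiency of energy transfer reports the distance between the two labeled
residues. Ensembles of molecules produce amplitude histograms whose
Gaussian components correspond to conformational states; the fractional
area of the low-FRET component of the 242:242' pair is used as the
probability of the inactive (resting) conformation. `stimfret` implements
that analysis end to end — from two-color intensity trajectories to state
occupancies, FRET-derived distances, transition counts, comparison with
structural models, and disulfide-crosslinking statistics — together with a
synthetic trajectory generator, because raw microscope trajectories for
these experiments are not publicly deposited and every stage of the
pipeline must still be testable.

## FRET efficiency and the gamma correction

Each frame's efficiency is computed as

$$E = \frac{I_A}{I_A + \gamma I_D}$$

after background subtraction, where `gamma` corrects for unequal detection
efficiency and quantum yield between the channels. `gamma` is measured per
molecule from the intensity steps at acceptor photobleaching: when the
acceptor dies, the acceptor channel drops by $\Delta I_A$ and the donor
channel rises by $\Delta I_D$, and $\gamma = \Delta I_A / \Delta I_D$
(`estimate_gamma()`, default 10 frames averaged on each side of the
step). Molecules whose donor does not rise — or that lack a usable
acceptor bleach — receive the ensemble median gamma and are flagged
`ensemble-fallback` in the QC report.

Distances come from the Förster relation $E = 1/[1 + (R/R_0)^6]$ with
$R_0 = 5.8$ nm for this dye pair; `fret_to_distance()` and
`distance_to_fret()` are exact mutual inverses, and E values outside
(0, 1) are rejected rather than extrapolated.

## Photobleach detection and trace QC

Bleach steps are found by least-squares change-point detection
(`detect_steps()`): binary segmentation with an L2 cost, minimum segment
of 4 frames, and a penalty of $3\hat\sigma^2\log n$ where $\hat\sigma$ is
a robust (MAD-based) noise estimate from first differences. A one-pass
local refinement re-optimizes each change point between its neighbours,
which makes the detector agree with an exhaustive least-squares search on
the well-separated steps that photobleaching produces (this agreement is
tested against a brute-force oracle).

Bleach *calling* (`find_bleach_events()`) is stricter than generic step
detection in two ways, both adopted after considering how a false call
propagates: the penalty doubles to $6\hat\sigma^2\log n$, and a downward
step only counts as a bleach if it is the channel's last step and lands on
the channel's minimal segment level (bleaching is irreversible and falls
to background). Without the second guard, a spurious donor step can
masquerade as donor bleaching, the frames after it get used as the
background estimate while they still contain signal, and the molecule's E
collapses to the clip boundary.

`qc_filter()` accepts molecules with exactly one acceptor bleach, at most
one donor bleach, acceptor first, at least `min_pre_frames` (default 10)
frames before the acceptor bleach, and donor/acceptor anticorrelation
(Pearson r below -0.2) over the pre-bleach window. Genuinely static
traces cannot anticorrelate, so the test is waived when the E series'
standard deviation is below `single_state_sd` (default 0.05). Background
is the post-donor-bleach mean when a donor bleach exists, else a policy
constant. All thresholds live in `qc_policy()`; none of them is a claim
about the original instrument's settings, which are not published in
re-usable form.

E values are clipped to [-0.1, 1.1] for storage and histogramming — the
conventional smFRET display range, which keeps noise excursions around 0
and 1 visible — with raw values retained alongside.

## Amplitude histograms and the mixture model

`build_histogram()` bins E over [-0.1, 1.1] with 0.02-wide bins. With the
default per-molecule weighting each molecule contributes total mass 1
regardless of trace length, so long-lived molecules do not dominate the
ensemble; per-frame weighting is available. The density integrates to 1.

`fit_mixture()` — the package's model core — fits
$d(E) = \sum_k w_k\,N(E;\mu_k,\sigma_k)$ to the binned density by
Levenberg-Marquardt nonlinear least squares, matching the field's practice
of fitting curves to the displayed histogram rather than running
frame-level EM (frames within a molecule are strongly correlated, so
frame-level likelihoods badly overstate the information content).
Numerical choices that matter:

* **Restarts and initialization.** 20 restarts per candidate k with
  deterministic sub-seeds; the first starts from detected histogram peaks,
  the rest from random means. Widths start at 0.07, the typical component
  width of these histograms.
* **Weighting.** `weighting = "poisson"` scales residuals by
  $1/\sqrt{\max(d_i, 0.02\,d_{max})}$. Bin counts are Poisson-like
  (variance proportional to density), and without this a dominant peak's
  residuals swamp low-occupancy components — a fit to a 92%/4%/4%
  histogram will happily spend its minor components refining the big peak.
  The unweighted fit remains the default for the general contract.
* **Equal widths.** `equal_widths = TRUE` constrains a common sigma. In
  these data the component width is dominated by sources common to all
  states (per-frame shot noise plus per-molecule calibration scatter), so
  the constraint is correct and greatly improves identifiability of
  overlapping and low-occupancy components.
* **Minimum separation.** Restart solutions whose means lie closer than
  `min_separation` (default 0.1) are kept only if nothing else converges:
  a histogram cannot resolve states closer than about 1.5 component
  widths, and such solutions invariably split one state's peak rather
  than finding two states.
* **Model order.** BIC over `k_range` on a chi-square scale whose
  variance uses the molecule as the independent unit
  (var$_i \approx d_i/(M\cdot$bin width$)$), with a 10-unit improvement
  threshold and ties toward fewer components. In the parameter-recovery
  studies the order is instead fixed to the reference fit's component
  count, mirroring how the reference fits themselves were made; order
  selection is validated separately on one- and two-state ensembles.

Fractional areas are renormalized to sum to 1 and components are sorted
by mean. `occupancy()` reports the designated component's area; the
default is the lowest-mean component (the 242:242' resting state), with
`rule = "highest"` or an explicit index for dye pairs whose resting state
is the high-FRET peak — the rule is always explicit, never inferred.

## Transition counting

`count_transitions()` assigns frames to components using thresholds at
midpoints between adjacent means with a hysteresis band of one s.d. of
the target component, calls a transition when the assignment changes and
persists for at least `min_dwell` frames (default 3), and counts within
the first `window_seconds` (default 5 s) of each trace. Hysteresis makes
counts invariant to noise below the band; dwell filtering makes counts
monotonically non-increasing in the threshold. Against a two-state
Markov simulation the counter reproduces the chain's expected number of
switches (the validation runs with `min_dwell = 1` on noiseless traces so
the closed-form expectation applies exactly).

## The synthetic generator

`simulate_trace()` / `simulate_ensemble()` generate what the analysis
assumes: hidden-Markov switching between states with true per-state FRET
(discrete-frame chain, per-frame switch probability
$1-\exp(-r\,\Delta t)$, exact at the data's resolution); single-step
irreversible acceptor and donor photobleaching with per-frame hazards;
additive Gaussian channel noise; per-molecule gamma drawn log-normal
(median 1, sigma-log 0.2 — strictly positive with mild spread, matching
the premise that gamma must be measured per molecule); and optional
per-molecule jitter of the true state FRET (`fret_jitter_sd`),
representing the static heterogeneity that gives real amplitude
histograms their width.

The validation studies use 500 counts/frame, noise s.d. 20 (the shot-noise
scale of such a signal, giving per-frame E scatter of about 0.03), jitter
0.063 (total component width $\sqrt{0.03^2+0.063^2}\approx 0.07$, the
width of the reference histograms), 100 frames of 0.1 s, acceptor bleach
hazard 0.02/frame and donor 0.005/frame (acceptor dyes bleach faster;
about 55% of molecules survive QC, comparable to real single-molecule
yields). Exposure time and trace length are not published for the
original data; 0.1 s frames are a configurable placeholder and all
time-windowed analyses take seconds, not frames.

What the generator does **not** emulate: dye blinking, spectral crosstalk
and direct acceptor excitation (the analysis corrects with gamma only),
camera physics (EMCCD gain, pixelation), diffusion or stage drift, and
non-Gaussian noise. Passing tests therefore show that the estimators
invert the assumed generative process at realistic sizes and noise — not
that the assumptions hold for any particular instrument.

## Accessible-volume dye clouds

`simulate_dye_cloud()` reimplements dye-position simulation as standard
single-radius accessible-volume (AV1) sampling: candidate dye centers on
a 1 Å grid within `linker_length` (20 Å) of the attachment atom (C-beta
of the labeled residue, falling back to C-alpha — deposited models can be
coarse at side chains); a candidate is allowed if it keeps
`dye_radius + clash_distance` (3.5 + 1 Å) from every heavy atom and has
straight-line clearance of `linker_width/2` (2.25 Å) back to the
attachment. The original analysis names only the software it used, not
its parameters, so these are the field's standard AV conventions, all
exposed as arguments; model-structure agreement is consequently a
qualitative target, not a bit-exact one. The straight-line clearance test
is the usual AV1 simplification (no flexible-path search). A Monte-Carlo
rejection sampler (`sample_dye_cloud_mc()`) shares the accessibility test
but draws candidates uniformly in the linker ball, providing an
independent check of the grid enumeration's allowed-volume fraction.

`interdye_distance()` offers the centroid distance and a FRET-averaged
distance (the distance whose efficiency equals the pair-averaged
efficiency — what a measurement of a flexible dye actually reports; it
weights close approaches more). `compare_distances()` assembles the
smFRET-vs-model table with RMSD, mean signed deviation and Pearson r,
using the dimer prime convention ("242:431'" crosses chains; unprimed
pairs resolve to the closer same-chain pairing, reported).

## Crosslinking statistics

Gel lanes are normalized on the heterodimer band, which contains the same
amount of protein in both antibody channels; the scale
$s = I_{het}^{ch2}/I_{het}^{ch1}$ is recorded. Subunit totals per channel
count monomer + heterodimer + 2 x homodimer; whether the original
accounting double-counted homodimers is not stated, so the homodimer term
is a toggle (`include_homodimers`). Under random dimer assembly the
expected heterodimer amount from subunit totals M and H is
$MH/(M+H)$ dimer units, and crosslinking efficiency is the observed
heterodimer band over that expectation. Efficiencies above 1 falsify the
random-assembly assumption for that lane and are flagged, never clipped.
`simulate_assembly()` provides the Monte-Carlo pairing counterpart of the
closed form, `simulate_crosslink_lane()` a generative lane with known
efficiency, densitometry noise and channel gain mismatch, and
`bootstrap_efficiency()` percentile intervals over replicate lanes.

## Validation problem sizes

The shipped tests and the acceptance script rerun the whole pipeline at
the reference conditions: six generator settings taken from the printed
fits (184-437 molecules each, 10 independent ensembles per condition),
500 traces for gamma recovery, 1,000 molecules for transition counting,
20 randomized obstacle scenes for the AV cross-check, and 10,000-dimer
lanes for crosslink recovery. At these sizes recovered occupancies are
within a couple of percentage points on the seed average; single
ensembles at n~200 molecules scatter with a standard deviation of 3-5
percentage points, which is worth remembering when comparing two real
conditions.

## Known limitations

* Molecules with more than two dyes, blinking, or multi-step bleaching
  are rejected rather than modeled.
* The mixture fit is a histogram fit: it cannot separate states closer
  than ~1.5 component widths, and low-occupancy components (<5%) carry
  large relative uncertainty at realistic molecule counts.
* No kinetic (dwell-time/HMM) inference — transition counting only.
* AV clouds use a single dye radius and straight-line linker clearance;
  no rotamer-library dye models.
* The crosslink efficiency inherits the random-assembly assumption;
  deviations show up as flagged efficiencies, not corrected ones.
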