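---
title: "Modelling peripersonal space from multisensory statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling peripersonal space from multisensory statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Peripersonal space (PPS) is the shell of space immediately around the
body, represented in cortex by multisensory neurons whose visual
receptive fields are anchored to body parts that they also cover
tactilely. `ppsnet` simulates how such a representation — and with it a
hand-centred reference-frame transformation — can *emerge* from the
statistics of multisensory experience, without hard-wired connectivity.

The network is a two-layer Restricted Boltzmann Machine. The lower layer
concatenates unisensory populations:

* a **visual** population (50×50 Gaussian-tuned Poisson units covering
  1.2×1.2 m of trunk-centred space plus 0.3 m safety margins, tuning SD
  three grid spacings ≈ 11 cm),
* a **proprioceptive** population (15×10 units covering the 1.2×0.6 m
  hand workspace, SD one grid spacing ≈ 13 cm) — or shoulder/elbow joint
  angles in the `joint` variant,
* a **tactile** population (30 units, no spatial tuning: all units fire
  at the stimulation gain when the hand is touched),
* optionally a second visual population coding the *hand's* visible
  position (`handvision` variant) and a 1D gaze population of 120 units
  (`gaze` variant).

Given lower-layer counts $u$, the upper (multisensory) layer is
Bernoulli with mean $\mu = \sigma(Wu + b_m)$; given upper-layer states
$m$, the lower layer is Poisson with mean $\lambda = e^{W^\top m + b_u}$
— the standard link functions for Bernoulli and Poisson units, with one
symmetric weight matrix serving both directions. Learning is one-step
contrastive divergence: after encoding a stimulus ($u_0 \to m_0$) and
reconstructing it through a confabulation phase ($u_1 \to m_1$), weights
change by the difference of phase correlations,
$\Delta W = \eta\,(\langle m_0 u_0^\top\rangle - \langle m_1
u_1^\top\rangle)$, a Hebbian/anti-Hebbian rule. Defaults follow the
standard recipe: $\eta = 0.005$, batches of 100, 400 batches per epoch,
100 epochs, weights initialized from a zero-mean Gaussian with SD 0.001,
zero biases.

The **training statistics carry the body constraint**: hand and
stimulus positions are drawn independently and uniformly, each
population's gain is an independent uniform draw on [4, 10], and touch
is delivered exactly when the stimulus comes within 15 cm of the hand
(`sample_constrained()`), which happens on about 4.4% of trials. The
control stream (`sample_unconstrained()`) delivers touch on a random 5%
of trials, independent of geometry, with identical marginals — removing
the statistical regularity while keeping every rate constant.

## Geometry and population-code choices

The trunk sits at the origin; $x$ is medial–lateral, $y$
anterior–posterior. The hand workspace is flush with the trunk
($y \in [0, 0.6]$ m): the hand can be at most 60 cm in front of the
trunk. The visual workspace is $y \in [0, 1.2]$ m. A consequence worth
stating explicitly is that the geometric touch probability is the
overlap integral of a 15 cm disc with these domains, ≈ 4.4% rather than
the no-edge-effect value $\pi r^2/A_v =$ 4.9%.

Preferred positions are regular grids whose *endpoints* coincide with
the margin-extended range, i.e. spacing = span/(n−1). The alternative
span/n convention is exposed through `pps_layout()` but not used: with
endpoints included, the proprioceptive posterior SD at maximal gain
works out to 1.68 cm along the anterior–posterior axis and the visual
one to 0.46 cm, matching independent psychophysical estimates of
proprioceptive and visual localisation precision; the span/n convention
would give a noticeably too-precise proprioceptive code (1.51 cm).

`pps_precision()` implements the optimal-decoder posterior SD in the
dense-grid regime, $\sigma_{post} = \sigma/\sqrt{N}$ with expected total
count $N = g\prod_k \sqrt{2\pi}\sigma_k/\Delta_k$. Because the 15×10
proprioceptive grid is slightly anisotropic, the per-axis SDs differ
(1.62/1.68 cm); the scalar summary is their mean. The analytic value is
cross-checked in the tests against a brute-force discretized posterior
and against the spread of maximum-likelihood decodes of sampled spike
vectors (`decode_ml()`), which in the dense-grid regime coincides with
the activity barycentre — the biologically simple read-out used
everywhere else (`decode_barycentre()`).

## Test-time read-outs

All simulated experiments are pure functions of a checkpoint and a
protocol. The default read-out is mean-field: the up pass uses
$\mu$ directly and the down pass returns $\lambda$, making analyses
deterministic given the checkpoint (sampled modes are retained for
training fidelity and available via arguments). Down-pass means are
clipped at $e^{10}$ with a warning; in practice clipping only engages on
degenerate hand-crafted weights.

* **Evoked tactile activity** (`evoked_tactile_map()`): encode visual +
  proprioceptive inputs, zero the tactile slice, one up pass, mean-mode
  down pass, average the 30 tactile means into a single scalar per
  trial. The default protocol samples 4000 (hand, stimulus) pairs with
  uniform hand-centred offsets up to ±40 cm, at test gain 10 (maximal gain is the
  package default; the gain is a protocol option).
* **Proprioceptive drift** (`drift_experiment()`): proprioceptive input
  fixed at the midline (0, 0.3 m), visual stimulus at lateral offsets,
  tactile drive off or at positive gains; the decoded hand position is
  the barycentre of the reconstructed proprioceptive slice, and drift is
  reported both in metres and as a percentage of the
  visuo-proprioceptive disparity. The RHI protocol additionally places
  the hand-visual population's input at the stimulus location (the
  rubber hand); the IHI protocol silences it (hidden hand).
* **Receptive-field profile** (`rf_profile()`): tactile strength is the
  mean of the 30 incoming tactile weights; the preferred visual distance
  is the anterior–posterior preferred position of the strongest visual
  synapse (ties to the lowest index); visuo-proprioceptive overlap is
  the Pearson correlation between the visual weight map and the
  proprioceptive map bilinearly interpolated onto a grid with the
  visual spacing covering the proprioceptive sheet. The overlap index is
  the excitatory-minus-inhibitory difference of mean overlaps.
* **Third-layer hand tuning** (`rf_peak_hand_correlation()`): with touch
  silenced, each third-layer neuron's visual RF peak is mapped for 100
  hand positions; hand tuning is the mean Pearson correlation of peak
  and hand coordinates along x and y. Peaks that never move count as
  correlation 0 (hand-independent). Peak finding uses a Gaussian
  smoothing of one probe step before the argmax; raw argmax is an
  option.

## Scale presets

The full-scale recipe (≈ 2 h of training) is the `full` preset and the
package default. The `reduced` preset — 40×40 visual grid, 500
multisensory units, 6 epochs × 100 batches — was chosen once so that a
constrained run finishes in minutes on one CPU while still reproducing
the full model's qualitative organisation. The visual grid is the
sensitive knob: with a 30×30 grid the visual tuning curves become so
wide (≈ 19 cm) that the excitatory/inhibitory split of the multisensory
layer drifts to ≈ 40% excitatory instead of the ≈ 55% seen at full
scale; at 40×40 (≈ 14 cm) the split is restored. Both presets are named
configurations: the full recipe is never silently altered.

The test suite trains its fixtures at the reduced preset (constrained
and unconstrained variants) plus a slimmer hand-vision network (30×30
visual grids, 300 multisensory units, 12 epochs — the extra visual
population doubles the lower layer, and the synchronous/asynchronous
separation in the rubber-hand protocol needs the longer schedule more
than the finer grid).

Reduced-scale training reproduces the qualitative phenomena (bimodal
tactile tuning, overlapping vs anti-overlapping receptive fields,
hand-centred evoked activity, all-or-none drift) but *over-integrates*
in the illusion simulations relative to the fully trained large
network: the maximal drift exceeds the ≈ 40% of disparity reported at
full scale. This is a genuine scale effect, not a protocol knob — the
drift magnitude rises during the first epochs of training at every
scale we examined — and is discussed further in the test suite, where
the tolerance bands on drift reflect the full-scale target.

## Numerical and design notes

* Distances in tuning curves are Euclidean and isotropic per axis; no
  wrap-around at workspace edges.
* Gains are continuous uniform on [4, 10]; integer gains are a config
  option only in the sense that any fixed gain can be supplied at test
  time.
* All-zero activity is flagged "undecodable" (`NA` + warning), never
  silently decoded as zero.
* Hand-vision trial categories (25% occluded / 25% dissociated / 50%
  congruent) are mutually exclusive, one categorical draw per trial; the
  generators expose the probabilities so "never dissociated" controls
  are one argument away.
* Streams, training runs and mean-mode analyses are bit-reproducible
  from `(config, seed)`; checkpoints are plain-text TSV bundles
  (`pps_save()`/`pps_load()`).
* Divergence guard: training aborts if the reconstruction error rises
  by more than 50% over five consecutive epochs.
* In the joint/gaze variants the visual uniform range is interpreted in
  eye-centred coordinates (the stated sampling space), and body-centred
  coordinates — used by the touch rule — follow by rotating by the
  negative gaze angle.

## What the synthetic world does and does not capture

The generator reproduces the statistical skeleton the model needs:
independent uniform positions, body-constrained touch, gain variability.
It deliberately omits temporal dynamics (looming stimuli, stroking
rhythms), visual appearance of the hand, 3D space, and any
nonuniformity of real hand-position statistics. Tests passing on these
streams therefore show that the learning mechanism extracts the
programmed regularity; they do not certify behaviour on naturalistic
input distributions.

## Known limitations

* The reduced preset's illusion drift overshoots the full-scale value
  (see above); quantitative drift comparisons need the full preset.
* The barycentre read-out is biased near workspace edges; analyses keep
  probe positions at least ≈ 3σ inside the represented range.
* The three-layer extension is trained greedily (stage 2 never
  back-propagates into stage 1).
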