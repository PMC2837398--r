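---
title: "Emergent looming detection in a model locust visual pathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emergent looming detection in a model locust visual pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgmdsim)
```

## The scientific question

The locust Lobula Giant Movement Detector (LGMD) is a wide-field visual
interneuron that fires most strongly to *looming* stimuli — objects on a
collision course. Its firing rate rises during an approach, peaks when the
object subtends a characteristic **angular threshold** on the retina, and
decays before impact. The time of that peak is linear in the ratio
$l/|v|$ (object half-size over approach speed, in ms), and the threshold is
invariant to speed, shape, texture and approach angle.

A widely used phenomenological account describes the firing rate as a local
multiplication performed by the neuron itself,

$$f(t) \;=\; g\!\left[\,\dot\theta(t-\delta)\,
      e^{-\alpha\,\theta(t-\delta)}\,\right],$$

where $\theta$ is the stimulus' angular size, $\dot\theta$ its angular
speed, $\delta$ a response latency, and $g$ a monotone (exponential)
membrane-to-rate mapping. This "eta model" peaks when
$\theta = 2\arctan(1/\alpha)$, i.e. at a fixed angular size, and its peak
time before collision is $\alpha\, l/|v| - \delta$ — exactly the observed
behaviour.

`lgmdsim` implements the competing hypothesis: none of the neurons computes
$\theta$, $\dot\theta$, or their product. The pathway consists only of leaky
linear-threshold (LT) and leaky integrate-and-fire (I&F) units,

$$\frac{dV}{dt} = -\frac{V}{\tau} + \frac{I}{C}, \qquad \tau = RC,$$

and every nonlinearity is a threshold. The looming selectivity and the
angular threshold *emerge* from the wiring between the retina and the LGMD.

## The network

The simulated compound eye is a uniform 32 x 24 photoreceptor raster
covering 74.65 x 56.25 degrees (2.33 degrees per cell), driven at 100
frames/s by the synthetic stimulus renderer. The layers are:

1. **Photoreceptors** — LT units reading normalised luminance.
2. **Lamina** — LT units driven by a centre-excitation/surround-inhibition
   kernel (centre $+1$, eight neighbours $-1/8$). The kernel is zero-sum:
   uniform fields are rejected and luminance edges enhanced. The border is
   handled by replicating edge values so the visual-field boundary itself
   produces no response.
3. **Medulla on/off transient detectors** — onset cells rectify the increase
   of lamina activity over a delayed copy (`onoff_delay`, default one
   frame), offset cells the decrease. Static scenes are silent after the
   delay.
4. **Directional ensembles** — for each cardinal direction, the onset cell
   at a location is combined with the offset cell at the trailing
   neighbour: the signature of an edge that has just moved in that
   direction. The default combination is the elementwise minimum, a graded
   AND: the ensemble stays silent unless *both* partners are active. The
   offset partner is sampled over a 1–3 cell trailing window
   (`trail_extent`), because an edge moving faster than one cell per frame
   leaves its offset trace several cells behind.
5. **Chiasma fan-in** — each unit of the LGMD's pre-synaptic fan samples the
   *outward-selective* ensembles at offsets $\pm\delta_x$, $\pm\delta_y$
   around its retinotopic position and, by default, responds to the
   coincidence of *opposing* pairs: leftward motion at $-\delta_x$ together
   with rightward motion at $+\delta_x$ (and the vertical analogue). Only an
   object whose boundaries are expanding symmetrically about the unit — an
   object centred there spanning $2\delta$ cells — produces that pattern.
   Lateral excitation spreads the activity to neighbouring fan units.
6. **LGMD** — a single I&F unit integrating the summed fan excitation (gain
   `w_exc` = 0.2) against feed-forward inhibition formed by the *total*
   medulla on/off activity (gain `w_inh`). The inhibition grows with the
   object's perimeter and edge speed, so it overtakes the excitation soon
   after the threshold size is passed and terminates the response.

The angular threshold is therefore a *wiring parameter*:
`angular_threshold_estimate()` returns $2\,\delta_x \cdot 2.33^\circ$
(23.3 degrees for the shipped $\delta_x = \delta_y = 5$, the nearest
representable value to a nominal 25-degree surround field). Nothing in the
dynamics ever represents it explicitly.

```{r threshold}
cfg <- network_config()
angular_threshold_estimate(cfg, camera_geometry())
```

## Design choices that were genuinely open

**Directional coincidence rule.** A thresholded sum of the on/off pair was
the first candidate (with a product variant for sensitivity analysis; both
remain available via `coincidence_rule`). It fails structurally: near the
angular threshold, slow approaches move edges by fractions of a cell per
frame and produce transients of ~0.1–0.2 (in normalised units), while fast
edges produce single-channel transients of ~0.4. No fixed threshold admits
the former pair while rejecting the latter singleton, and a leaky ensemble
lights *all four* directional maps along any moving contrast line, which in
turn lets the fan respond to arbitrary lines rather than to expanding
boundaries. The elementwise minimum is scale-free: it passes a coincident
pair of any strength and passes nothing else.

**Fan-in combination.** Counting "at least 2 of 4 active ensembles" admits
corner pairs (rightward + downward), which any expanding object satisfies
at every size larger than the threshold, with activity growing with edge
speed; the measured consequence was a response peaking near 50 degrees
instead of 23. Requiring *opposing* pairs ties the response to the object's
size. A `fanin_rule = "count"` switch retains the counting variant.

**Sampling tolerances.** The fan samples each ensemble over a $\pm 1$-cell
window around $\pm\delta$ (`fan_sample_extent`): the even-sized raster puts
a centred object half a cell off the unit lattice, and the tolerance also
sets the realised resolution of the threshold, about $\pm 2$ cells of
visual angle ($\approx \pm 5$ degrees).

**Front-end time constants.** Photoreceptor and lamina LT units use
$\tau = 20$ ms against the 10 ms frame period. This low-pass front end
stands in for the temporal filtering of a physical screen/camera chain and
of photoreceptor membranes. It matters for texture invariance: a fine
pattern sweeping across a cell produces luminance flicker near the frame
rate, which the filter suppresses, while the object boundary's step-like
transition passes.

**Feed-forward inhibition timing.** The inhibition acts in the same frame
as the excitation (the alternative of delaying it by a frame changes
nothing qualitative at these time constants).

**DCMD.** Treated as a 1:1 relay of LGMD spikes; the simulation output *is*
the LGMD/DCMD train.

## The stimulus generator

`render_sequence()` produces the three protocols on the photoreceptor
raster, in angular coordinates with area-weighted anti-aliasing (the
physical camera's pixel averaging):

- **Looming**: $\theta(t) = 2\arctan\!\big(l/(|v|\,t)\big)$, $t$ the time
  remaining to collision. Trials start when the object subtends 2 degrees
  (sub-pixel) and stop one frame before collision.
- **Receding**: the same law with the object starting at `start_theta`
  (default at the angular-threshold size) and moving away.
- **Uniform expansion**: $\theta$ grows linearly at `expansion_rate`
  (default 0.05 deg/ms, crossing the threshold mid-sequence).

Shapes: solid square, solid circle, checkerboard-textured square (16 checks
per side) and concentric square bands (3 bands). The textures are
object-fixed and *fine relative to the raster*, as in a physical rig where
screen texture is much finer than an ommatidial acceptance angle; the
optics average them to an intermediate grey over most of the approach.

Trial-to-trial variability has two seeded sources, both emulating a
physical rig: Gaussian sensor noise per cell per frame
(`noise_sigma`, default 2 luminance units of 255), and a sub-cell jitter of
the stimulus centre across repetitions (`align_jitter`, default
$\pm 0.5$ cells) representing camera/screen alignment variability. The
jitter matters for spike-count statistics: without it, every repetition
shares the same sub-cell alignment between stimulus and raster, and
alignment — not physiology — dominates the comparison of mean counts
across approach angles.

## What the simulations show

With the shipped calibration (`network_config()` defaults, also in
`inst/extdata/config_25deg.yaml`):

- the firing rate for a looming solid square rises, peaks before collision
  and decays, and the best-fit eta model (exponential mapping) correlates
  with it at $r \approx 0.97$;
- the time-to-collision of the rate peak is linear in $l/|v|$ over
  5–50 ms with $r > 0.99$, for all four shapes and at approach-angle
  offsets of 0% and 75% of the half-field ($r > 0.9$ there);
- the stimulus angular size at the peak stays within ~3 degrees of the
  23.3-degree wiring threshold across the sweep (square stimulus);
- enlarging $\delta_x,\delta_y$ (25 -> 29 -> 36 degree conditions, shipped
  as config files) flattens the TTC slope;
- mean spike counts are statistically indistinguishable across approach
  angles up to 75% of the field and drop significantly beyond, where the
  stimulus partially leaves the field of view;
- an object expanding at *constant* angular rate still yields a peak near
  the angular threshold, whereas the eta model predicts a monotonically
  decaying rate — the discriminating prediction between the two accounts;
- receding stimuli drive the outward-selective ensembles not at all: the
  model predicts an essentially silent LGMD whose membrane potential is
  deflected below rest by the feed-forward inhibition, more deeply the
  larger `w_inh` (the gains 0.02/0.01/0.005/0.001 are scripted as the
  `fig5` preset).

The last point is a sharper prediction than a merely "diminished" receding
response: with strict directional coincidence there is no excitatory drive
at all, and the graded receding responses sometimes reported would have to
come from imperfect directional selectivity or from other inputs.

A comparison suite of stimulus-driven accounts is included: the second
derivative $\ddot\theta(t)$ (whose peak sits near a *fixed large* angle of
$2\arctan\sqrt3 \approx 120^\circ$, far above the network's threshold — so
it cannot explain threshold invariance), and a multivariate linear mapping
from raw 16 x 14 sub-sampled frames to the rate, which reproduces looming
responses in-sample but collapses on receding stimuli because a linear
functional of luminance cannot encode motion direction.

## Calibration

The free constants the biology does not pin down (layer gains, thresholds,
time constants, `w_inh`) were set by a grid search whose objective was the
invariant *structure*: angular-threshold constancy across the $l/|v|$
sweep, TTC linearity for all shapes and angles, silence on blank input,
and non-degenerate spiking at both sweep extremes. The search is documented
by `calibrate_network()`, a small utility that re-runs the scoring for a
user-supplied grid. Units are arbitrary-but-consistent: luminance is
normalised to [0, 1], membrane resistance is 1 for all layers except the
medulla (gain 2), and the LGMD threshold of 0.15 is ~half the typical
threshold-crossing drive of a mid-speed loom.

## Problem sizes and determinism

Simulations run the 32 x 24 raster at 100 frames/s; a single trial spans
0.3–3 s of simulated time (longer for slower approaches, so the object
always starts sub-pixel). The reference experiments use 3 repetitions per
condition for sweep regressions and 8 for spike-count statistics; all
randomness flows from one top-level seed through `derive_seed()`, and every
result object is a pure function of its specification and that seed.

## Known limitations

- The raster is coarse (2.33 degrees/cell); thresholds are representable
  only in steps of ~4.7 degrees, and sub-cell alignment effects are visible
  in single trials (hence the alignment jitter across repetitions).
- One-frame transients make slow approaches flicker at the directional
  stage; the LGMD membrane integrates across the gaps, but single-trial
  peak times can wobble by a frame or two.
- No spike-frequency adaptation, synaptic plasticity, conductance-based
  dynamics or acute-zone magnification: outside the model's scope.
- The synthetic renderer has ideal geometry and contrast; real-camera
  artefacts beyond Gaussian noise and alignment jitter (vignetting, gain
  control, motion blur) are not emulated, so passing tests speak to the
  network mechanism, not to robustness against such artefacts.
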