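---
title: "Monitoring pearl rotation with a magnetometer dome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring pearl rotation with a magnetometer dome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pearlrot)
```

## The measurement problem

A cultured pearl grows around a nucleus implanted in the oyster gonad. When
the nucleus carries a small permanent magnet, the pearl's rotation inside
the pearl sac can be followed from outside the animal: the oyster sits in a
hemispherical dome instrumented with 25 single-axis magnetoresistive
sensors, each sampling the local field component along its measurement axis
once per second. The analysis task is to turn these 25 scalar channels into
an orientation trajectory of the magnet, then into an image of the rotation
pattern, and finally into a prediction of the pearl's final shape class —
Round, Atypical, or Other (no regular deposit).

No public recordings accompany the original study, so this package pairs
the analysis chain with a physics-based generator that emulates the device
closely enough for every stage to be tested end to end. This vignette
documents the models, the parameters that matter, and the design choices
made where the device documentation is silent.

## Dome geometry

The dome is modeled as a hemisphere of volume 4.2 L, giving radius
$r = (3V/2\pi)^{1/3} \approx 0.126$ m. Sensors sit on rings at 6°, 30° and
60° elevation plus one zenith sensor. The per-ring sensor count is not
documented; 8 + 8 + 8 + 1 is the only symmetric partition of 25 consistent
with a single zenith sensor, and it is what `build_dome()` constructs, with
equal azimuthal spacing and a shared azimuth origin (the physical azimuthal
offsets between rings are unknown; equal spacing is an assumption, not an
inference). Measurement axes are radial, pointing inward at the oyster;
`reconstruct_orientation()` multiplies each reading by the cosine between
axis and outward radial before applying the position weights, so inward and
outward conventions give identical estimates.

## Dipole physics and the forward model

The magnet is treated as a point dipole,
$\mathbf B \propto (3(\hat m\cdot\hat r)\hat r - \hat m)/|r|^3$, with unit
prefactor: the sensor gain of the physical device is unknown, so field
units are arbitrary and only ratios matter downstream. Channel $i$ reads
$v_i(t) = \mathbf B(\mathbf u(t),\, \mathbf p_i - \mathbf x_m)\cdot\hat a_i
+ o_i + \varepsilon_i(t)$, with a per-channel constant offset $o_i$
(the residue left by the device's offset-compensation electronics, default
SD 1% of the RMS signal) and iid Gaussian noise (default SD 5% of the RMS
signal). The magnet sits on the dome axis at the height of the second
sensor ring, where the oyster is placed for optimal measurement accuracy.
Oyster body movement is not modeled by default — a known limitation of the
measurement principle itself, which tracks the magnet relative to the dome,
not relative to the animal.

## Rotation regimes

Three regimes generate the moment direction $\mathbf u(t)$, differing in
*pattern* only — measured cohort speeds showed no significant difference
between shape classes, so the generator deliberately gives all rotating
pearls speeds from the same distribution,
$\mathcal N(0.69, 0.13^2)$ ° min⁻¹ truncated at zero:

* **Round — random tumbling.** Each step rotates $\mathbf u$ by exactly
  `speed · dt` about a tangent axis that itself diffuses on the sphere at
  30°/√hour. Per-step increments therefore average exactly to the target
  speed, while the rotation plane wanders with a decorrelation time of a
  few hours: weekly coverage is broad, daily coverage is a meandering arc.
* **Atypical — axial rotation.** Steady rotation about a nearly fixed axis
  (axis diffusion 2°/√hour), starting 60–90° away from the axis so the
  trace is a visible ring or cone. The rotation rate is scaled by
  $1/\sin\theta$ (angle to the axis) so step increments again average to
  the target speed. Applying jitter as per-step white noise on $\mathbf u$
  instead would swamp the 0.0115 °/s signal at 1 Hz and break that
  property, which is why jitter acts on the axis.
* **Other — stillness.** A very slow great-circle diffusion
  (5 × 10⁻⁴ °/√s) around the initial direction, giving an apparent speed
  of ~0.02 ° min⁻¹ at 1 Hz — comfortably below the 0.05 ° min⁻¹ bound that
  separates "no rotation" from rotation in the class structure. (A faster
  wobble would be indistinguishable from genuine rotation at the sample
  level, which is also why this default is slower than a naive reading of
  "half-degree wobble" would suggest.)

A pre-rejection event — the sudden acceleration up to 4.8 ° min⁻¹ observed
shortly before nucleus rejection — can be injected into any trajectory
(`inject_rejection_event()`): the speed ramps linearly after an onset time
and stays at the peak, with the pre-onset samples bit-identical to the
input.

The clock calibration scene is deterministic: a rod rotates the magnet
about the vertical at exactly one revolution per hour, with the moment
parallel, diagonal (45°) or perpendicular to the axis, centred at the
height of any of the three sensor rings. Parallel rotation is unobservable
(rotation about the moment's own axis does not change the field), which is
the physical reason an observability score is reported per trajectory
rather than hiding the ambiguity.

## Signal path

**Smoothing.** Channels are filtered with a Gaussian-weighted moving
average over a 60-sample window. The kernel SD is not documented; the
package uses `window/5` (12 samples), a common engineering default, and
exposes it. Truncated edge windows are renormalized, so constants pass
through unchanged and white noise shrinks by the theoretical gain
$\sqrt{\sum w_k^2}$.

**Reconstruction.** The device's estimator multiplies each channel by the
sensor's unit position vector and sums:
$\hat{\mathbf u}(t) \propto \sum_i v_i(t)\,(\hat a_i\cdot\hat p_i)\,\hat
p_i$. For a dense uniform radial grid this is exactly proportional to the
moment (the radial reading of a central dipole is $2(\hat m\cdot\hat
r)/r^3$ and $\mathbb E[\hat r\hat r^\top] = I/3$); on the real 25-sensor
hemisphere with the magnet at ring-2 height it carries a bounded direction
bias of a few degrees (median ≈ 4°, decreasing with sensor count), which
the test suite pins down against dense-grid oracles. Frames whose raw
vector norm falls below 1% of the trajectory median are flagged
unreliable rather than interpolated.

**Speed estimation.** Two estimators are provided. The spherical step
angle $\arccos(\mathbf u_t\cdot\mathbf u_{t+\ell})$ per elapsed time is
the default; at lag $\ell$ = 1 s it is noticeably inflated by residual
filtered noise (the noise difference between neighbouring smoothed samples
rivals the 0.0115 °/s signal), so for noisy data the pipeline default is a
120 s lag — well beyond the smoothing kernel support, where residual noise
decorrelates, and short enough that random-walk curvature bias stays below
~1% for tumbling at cohort speeds. The azimuth estimator projects the
trajectory on the equator (frames with $|z| > 0.95$ masked) and takes the
net signed azimuth displacement per time; its telescoping makes it exact
for steady rotation about the vertical regardless of reconstruction bias,
which is why the clock calibration uses it. Whether the original speed
statistic was computed from 3-D steps or azimuth rate is not documented;
both are reported, and the identity `hours_per_rev = 360/(60 · mean)` is
kept explicit since a per-pearl average of revolution times need not equal
the revolution time of the average speed.

**Legacy features.** The first, pre-imaging classification attempt used
binned kinematic features; `binned_kinematics()` reproduces it with 100
velocity and 100 acceleration bins per day.

## Imaging

Each weekly trajectory segment is rendered as a single 224 × 224 RGB
image: points on the unit sphere projected orthographically along the
camera, front hemisphere only, drawn in time order with a
perceptually-uniform (viridis) time colormap on a dark background with a
sphere outline. The camera looks along the barycenter (normalized mean) of
the segment's points — the direction that maximizes visible rotation data;
when the mean degenerates (a full ring), the fallback is the
least-variance principal axis, i.e. the normal of the data plane, which
faces the ring head-on. Six views rotated in-plane by 60° are available,
but only view 0 enters datasets: the rotated views add no information and
were found to add noise. The rasterizer is pure R and deterministic:
identical segments give bit-identical pixels on any platform. Point shape
(scatter, not a connected path), point size, background and colormap are
frozen defaults, exposed in `render_spec()` but fixed for tests.

Dataset variants impose the device's weekly acquisition cadence (the dome
must be cleaned weekly, so continuous acquisition beyond a week is
impossible): *full* uses every weekly segment, *week* the last week (one
sample per pearl), *month* the last up-to-four weeks, *day* the last week
split into days. A trailing partial segment is kept only if at least half
full. Each sample carries the two cultivation scalars: total days of
cultivation, and days from graft to that segment's start.

## Classification

The classifier is transfer learning in structure: a frozen convolutional
backbone, two fused metadata scalars, and a trained dense/dropout/softmax
head. The fidelity backbone is an ImageNet-pretrained VGG-16 convolutional
base (18 weight layers, 5 max-pools, flattened 7 × 7 × 512 = 25 088
features); since its weights cannot be bundled, `backbone_spec("vgg16-frozen")`
validates the shape arithmetic and accepts a user-supplied extractor
closure. The tested path is `tiny-cnn`: a small frozen convolutional stack
(4× average pool → two 3 × 3 convolution + ReLU + max-pool blocks →
7 × 7 × 16 = 784 features) with fixed-seed random weights — random
convolutional features are a well-studied baseline, and freezing them
preserves exactly the property the architecture relies on: the feature map
is a fixed function of the image, and only the head is fitted.

The two metadata scalars are z-scored with training-split statistics and
appended to the (scaled) feature vector; their weighting is learned by the
first dense layer rather than hand-set, since the original "specific
weights" are not documented. The head (default dense 256 → dropout 0.5 →
dense 3 softmax) is trained with Adam on cross-entropy, inverted dropout,
and early stopping on validation accuracy, keeping the best epoch's
weights; optimizer settings (lr 10⁻³, batch 16, 30 epochs) are package
defaults inside the grid-search space, as the original hyperparameter
table is not available. Training is deterministic under a fixed seed.
Per-pearl prediction takes the modal class over the pearl's weekly
samples, breaking ties by the highest mean probability among tied classes,
then by fixed class order.

## Evaluation

Splits randomize pearls, never samples: all samples of a pearl share one
assignment, removing the leakage that would otherwise inflate accuracy.
Within each class, pearls are apportioned 70/15/15 by largest remainder
(per-split class counts stay within one pearl of the global proportions)
and split labels are interleaved evenly through the pearls ordered by
harvest-date group, so each harvest group is represented in every split
its size permits — the balancing criterion is best-effort because the
original operationalization is not documented; harvest groups themselves
are culture-duration tertiles. Repeated holdout draws independent splits
from seeds derived from one master seed; repeats whose test split misses a
class are flagged and excluded from per-class F1 aggregation. Metrics are
accuracy, per-class F1 (0 when undefined), macro F1 (unweighted mean) and
weighted F1 (support-weighted), each at sample and pearl level with mean
and SD over repeats.

At very small cohorts the largest-remainder rule can leave the test split
empty (e.g. 3 pearls per class yield 2/1/0); such repeats are flagged and
recorded as missing rather than failing, and realistic cohort sizes (≥ 5
pearls per class) are unaffected.

The graft-survival table helper reproduces the published retention
arithmetic; percentages are truncated to whole numbers because that is the
convention the published table follows (63% for 14/22).

## Problem sizes and what the synthetic tests show

The package's own experiments run at desk scale, chosen once: cohorts of
60 pearls with 21-day acquisitions sampled once per minute for the
end-to-end classification experiment (ten holdout repeats per variant,
plus four further cohort seeds for the data-volume ordering), 40 pearls
with 6-hour 1 Hz acquisitions for speed recovery, and 1000-sensor grids
for the reconstruction oracles. One sample per minute preserves all
rotation structure relevant at 0.69 ° min⁻¹ while keeping week-long
trajectories tractable; the 1 Hz hardware rate is used wherever smoothing
and noise behaviour are under test, because the 60-sample filter window is
defined in samples.

On these synthetic cohorts the classifier separates the three regimes
almost perfectly, the full variant dominates, and pearl-level majority
voting never hurts. One field observation does *not* reproduce: on real
pearls, a single day of rotation was far less predictive than a week,
whereas on stationary synthetic regimes every segment of a pearl is
equally informative, so accuracy ordering degenerates into
majority-vote-count ordering — full (several weekly votes) above day
(seven daily votes) above week (a single sample, the highest-variance
estimate). The field degradation of daily data is driven by the
irregularity of real rotation, which the generator's stationary regimes
deliberately do not emulate; the test suite asserts the field ordering and
documents its week-versus-day clause as failing for exactly this reason.
More broadly, the synthetic results show that the pipeline preserves and
recovers the class signal it simulates — they are integration oracles,
not a forecast of accuracy on new oysters (real pearls change regime over
months and sit in a moving animal).

## Known limitations

* Rotation about the magnet's own axis is unobservable; the observability
  score surfaces, but cannot resolve, the stillness/axial ambiguity.
* The original processing chain includes a projection step ("real rotation
  of the pearl") documented only in supplementary material that is not
  available; the package implements the two named projections (sphere and
  equator) and stops there.
* The weighted-sum reconstruction is biased by partial sensor coverage;
  the bias is bounded and characterized, not corrected.
* Default generator parameters are plausible, not calibrated: only the
  cohort speed distribution, the class mix, the clock rig, and the
  pre-rejection peak speed are anchored to reported measurements.
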