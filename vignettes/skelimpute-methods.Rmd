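---
title: "Masked-modeling imputation of keypoint trajectories: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked-modeling imputation of keypoint trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Markerless pose estimation and marker-based motion capture of behaving
animals lose keypoints to occlusion, reflections and tracking failures.
The resulting gaps are not missing-completely-at-random: which keypoint
drops, for how long, and how often depends on the marker placement, the
task and the camera geometry. Straight-line interpolation -- the default
remedy in behavioral science -- is blind to body structure and fails
badly whenever a gap spans real movement. `skelimpute` instead learns the
joint dynamics of the skeleton from the data themselves and uses that
model to fill the gaps, with a calibrated per-sample confidence that lets
the analyst trade coverage against precision.

## Self-supervised masked modeling

No annotation is available for missing values, so training is
self-supervised. Complete 60-frame windows (`extract_samples()` with
`complete_only = TRUE`) are the training units. At every epoch, each
window receives *fresh* artificial gaps whose statistics mimic the real
missingness of the dataset; the network reads the zero-filled window plus
a binary gap mask and is penalised only on the hidden cells. Gap
regeneration acts as data augmentation: the model never sees the same
masking twice.

The empirical missingness process (`estimate_gap_stats()`) is summarised
by three distributions: the probability that a gap event hits keypoint
$k$, the gap-length distribution per keypoint, and the distribution of
observed spacings between gaps. Gap sampling (`sample_gaps()`) draws
keypoints without replacement, truncates lengths to $[1, L-2]$ and
renormalises, and places starts so that the first and last frame of a
masked keypoint remain observed -- which keeps every artificial gap
solvable by the linear baseline, making the comparison fair. When a
dataset has no native missingness, all three distributions fall back to
uniform. The start-placement rule deserves a note: an inter-gap spacing
distribution does not uniquely determine where a single gap falls inside
a 60-frame window, so we draw the offset from the truncated inter-gap
distribution and fall back to uniform over legal starts when it is
degenerate -- the intent (starts distributed like observed spacings) is
honoured while every draw is legal.

## Preprocessing

Each window is mapped to a canonical frame before modeling and mapped
back exactly afterwards:

1. **View-invariant rotation.** The window is translated by the
   middle-frame body barycenter and rotated about $z$ so the middle-frame
   heading points along $(1, 0)$ in the $x$--$y$ plane. "Heading" is not
   canonical for an arbitrary skeleton; the default is the first
   principal axis of the middle-frame keypoint cloud, sign-oriented by a
   user-supplied keypoint pair (e.g. tail to head) when available and by
   the largest-magnitude component otherwise (a bare principal axis has
   no sign). Degenerate middle frames fall back to the identity rotation
   and are flagged. No rotation is applied in $z$.
2. **Per-sample min--max normalization** to $[-1, 1]$ per axis, computed
   over *observed* cells only and always before masking, so gaps never
   leak into the scale. A static axis maps to 0 with its offset recorded,
   keeping the inverse well defined.

Both transforms are exact affine maps; `inverse_transform()` composes
their inverses and round-trips to ~1e-12, which the test suite asserts on
a thousand random windows. Training and validation losses live in
normalized space; all reported comparisons are made after inverting to
original units.

## Models

Three backbones are implemented natively (hand-derived gradients over
BLAS; the test suite checks every backbone's analytic gradient against
central finite differences at 1e-5 relative tolerance):

* **Transformer encoder** (the reference architecture): tokens are
  (frame, keypoint) pairs. One *shared* linear projection maps each
  token's coordinates-plus-mask-bit to the model dimension, and
  lookup-table embeddings of the time index, the keypoint identity and
  the mask bit are summed on top -- the mask thus enters both
  concatenated and embedded. Post-LN encoder layers with multi-head
  self-attention follow, then a linear head. Reference size: 4 layers,
  model dimension 128 (feed-forward width equal to it -- the stated
  "internal dimensionality" is read as the feed-forward width, left
  configurable), 8 heads.
* **Bidirectional GRU**: each keypoint contributes (x, y[, z], missing)
  channels per frame; 3 layers of hidden size 512 by default, no
  dropout, with a linear output layer decoupling hidden size from
  keypoint count.
* **TCN**: 4 residual blocks of two causal dilated convolutions with
  ReLU and dropout 0.2, dilations 1/2/4/8, hidden 256. The kernel size is
  not dictated by the reference design; 3 is used (receptive field
  $2 \times 2 \times (1+2+4+8) = 60$ frames, one full window).

With `proba = TRUE` any backbone gains a Gaussian head predicting a mean
and a standard deviation per coordinate. The raw scale output passes
through a softplus with floor $10^{-4}$ -- the positive-σ
parameterisation is a numerical choice (only "two Gaussian parameters"
is prescribed); softplus avoids the exploding gradients of `exp` at
initialisation. Latent representations (`extract_latent()`) pool the
final encoder layer by mean over tokens (transformer) or frames (GRU);
mean pooling is our choice where none is prescribed.

## Training

Masked L1 loss, or the Gaussian negative log likelihood
$\tfrac12\log(2\pi\sigma^2) + (x-\mu)^2/(2\sigma^2)$ for probabilistic
heads, averaged over masked coordinates only. Adam, initial learning
rate $10^{-3}$ ($10^{-4}$ for the GRU, which destabilises at higher
rates), step decay $\times 0.95$ every 500 epochs, batches of at most
32, switch probability 0.1. Reference trainings run 1500 epochs; the
model from the epoch with the lowest validation RMSE is kept.

Two choices are ours where the reference is silent. Validation gaps are
*frozen* once at the start (seeded) so that model selection compares all
epochs on the identical task -- regenerating them would add selection
noise. Validation RMSE is computed in normalized space (monotone enough
with original-space RMSE for selection, and cheap); reported metrics are
always in original units. Gradient clipping exists but is off by
default.

**Switch augmentation.** With probability 0.1 per sample, the input
coordinates of two random keypoints are exchanged over a random
sub-interval while the target stays untouched, so the model learns to
undo the identity swaps that trackers produce when keypoints approach
each other. Robustness is evaluated on artificially switched test
samples (probability 0.5), since detecting real switches is itself an
open problem.

## Inference on whole recordings

`impute_recording()` tiles the recording so every native gap run is
centred in a model-length window (shifted at edges), orients and
normalises each window on its observed cells, predicts, and writes
accepted predictions back in original units. Gaps longer than $L-2$
frames are never imputed -- no recursive forecasting -- and neither are
edge gaps without an observed anchor or windows whose simultaneous
missing-keypoint count exceeds what the model was trained for. For
probabilistic models each window's *estimated error* (mean predicted σ
over its masked cells) gates acceptance; 0.1 normalized units is the
default working threshold. Where two accepted windows impute the same
cell, predictions are averaged with inverse-squared-error weights
(unweighted without σ) -- deterministic, seam-free, and our choice where
tiling is unspecified. Observed coordinates are never altered, which the
tests assert bit-for-bit.

## Synthetic motion fixtures

The generators in `synthetic.R` stand in for animal recordings in all
tests; their defaults are fixed study conditions, not tuning knobs.

* `mouse8`: 8 keypoints (hip/knee/ankle/back pairs), 3D, 60 fps,
  millimetre scale, matching the shape of floor-exploration mouse motion
  capture. A smooth random-walk heading carries the body at 40 mm/s;
  limbs oscillate at 2 Hz with left/right antiphase (ankle amplitude
  12 mm); Gaussian noise of 0.5 mm models tracking jitter. These values
  were chosen once as plausible rodent-scale kinematics. The skeleton is
  deliberately elongated (~50 mm long vs ~30 mm wide): when a keypoint
  cloud is nearly isotropic the principal-axis heading becomes unstable
  (the leading eigenvector flips between the forward and lateral axes
  with limb phase), and windows are then canonicalized inconsistently --
  on such skeletons a heading keypoint pair must be configured instead.
  An early draft of this fixture was wider than long and showed exactly
  that failure on held-out recordings.
* `fish2x3`: two 3-keypoint individuals with the second's centre
  attracted to the first, emulating interacting-fish recordings.
* `linear`: exactly constant-velocity motion, no noise -- on it linear
  interpolation is exact (RMSE 0 up to float error), bounding any
  learned model from below and keeping the baseline oracle honest.
* Heteroscedastic mode (`noise_levels`): one noise s.d. per 60-frame
  block drawn from {0.5, 2.5, 5} mm, i.e. roughly {0.01, 0.05, 0.1} in
  normalized units at this body scale. Block-wise i.i.d. noise is
  unpredictable by construction, so an ideal probabilistic model
  predicts the clean trajectory and a σ close to the block's noise
  level -- which is exactly what the estimated-error correlation test
  measures.

What the fixtures deliberately lack: soft-tissue artefacts, camera
distortion, non-stationary behavior repertoires, and realistic
biomechanics. Passing on them demonstrates the machinery (contracts,
learning, calibration directionality), not dataset-level accuracy on
real animals.

## Step detection and kinematics

Locomotor steps are detected from the ankle: instantaneous speed,
smoothed over 0.1 s (6 frames at 60 fps), must show a peak of height
≥ 20 and topographic prominence ≥ 21 (native units per second --
millimetres for the motion-capture data these defaults were calibrated
on) with width-at-half-prominence inside 0.16--2 s. The swing start is
the acceleration peak before the speed peak (takeoff), the stop the
acceleration valley after it (touchdown); acceleration is the first
difference of smoothed speed, smoothed with the same window. Each anchor
is taken as the *dominant* extremum within a window bounded by ±2 s and
by the speed peak's own flanks (half-prominence crossings ± 0.5 s):
nearest-extremum anchoring is unstable under plateau noise, while the
dominant extremum in a flank-bounded window is robust and identical on
clean profiles. Two duration rules coexist in the reference procedure;
they are resolved by assigning them to different quantities: 0.16--2 s
gates the *speed-peak width* at detection, ≥ 0.6 s gates the final
*start-to-stop interval*. Steps whose ankle is not lower at start and
stop than during the swing are discarded when a height axis is
available. Stride length is the path length of the ankle trajectory over
the swing; swing duration the interval in seconds.

The step fixture (`make_step_trace()`) uses trapezoidal speed bumps
(0.15 s rise and fall, plateau in between) rather than smooth sinusoids,
deliberately: with the acceleration-extremum anchors above, a
trapezoid's detectable interval equals its nominal duration, whereas a
sinusoidal bump would be anchored at half its width and a nominally
valid 0.8 s bump would silently fail the 0.6 s gate. Ground-truth
anchors are analytic, so recall and rejection are scored exactly.

## Numerical choices and degenerate inputs

* Missing data are `NaN` internally plus an explicit mask; zero-filling
  happens only at model-input assembly, because zero is an in-range
  coordinate value.
* A keypoint-frame with any unobserved axis is treated as wholly
  missing: coordinates are triangulated jointly and a lone axis is
  untrustworthy.
* Frame indexing is 0-based in sample metadata with half-open windows;
  the R API is otherwise 1-based and documented per function.
* Time-split boundaries floor both cut points (train gets
  $[0, \lfloor 0.7T \rfloor)$, etc.) so splits are reproducible.
* Plateaus in peak finding break ties to the earliest frame; prominence
  is computed against the higher of the two flanking minima
  (standard topographic definition).
* Weight initialisation: uniform $\pm 1/\sqrt{\text{fan-in}}$ for linear
  maps, $\mathcal N(0, 0.1)$ for embedding tables, recorded seed.
* All randomness flows through explicit seeds; trainings are
  deterministic given the master seed on a fixed BLAS.

## Desk-scale study sizes

The package's tests and the acceptance script run on one CPU, so the
study conditions are desk-scale by design: transformer with 2 layers,
dimension 32, 2 heads, and a GRU with 2 layers of hidden size 64,
trained for 150--200 epochs on 96--120 windows of synthetic mouse-like
motion (three 26 s recordings at 60 fps), validated on 24 windows and
evaluated on held-out windows from an unseen recording. The
heteroscedastic calibration study uses 72 training and ≥ 200 held-out
windows. These sizes are stated here because they are the conditions
under which the package's comparative claims (model beats linear
interpolation on long gaps of oscillatory motion; estimated error
correlates with true error; switch training transfers) are verified --
full-scale accuracies on real datasets require full-scale training.

## Known limitations

* No recursive forecasting: gaps longer than $L-2$ frames stay missing.
* The latent space is exposed for downstream embedding/classification
  but no classifier ships with the package.
* Real keypoint-identity switches are augmented against, not detected.
* Step-gate defaults assume millimetre units at 60 fps; other unit
  systems must rescale the gates.
* RMSE values are not comparable across datasets with different skeleton
  sizes and motion ranges.
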