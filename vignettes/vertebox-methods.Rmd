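---
title: "Verte-Box methods: dual attention, multi-scale convolution and deep supervision for vertebra CT segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verte-Box methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Axial CT slices of the spine are hard to segment automatically for three
reasons: neighboring structures share shape and appearance with vertebrae;
unhealthy vertebrae carry lesions whose bright patches pull a detector away
from the true bone outline; and soft tissues near the spine can match the
bone's gray level almost exactly. `vertebox` implements an encoder–decoder
convolutional network designed around these three failure modes, together
with its full training protocol, evaluation metrics, preprocessing
pipeline, and a phantom generator that reproduces the challenge structure
synthetically so that every part of the package can be exercised without
external data.

## The network

The model is a five-level encoder–decoder with three distinctive parts.

**Multi-scale convolution blocks.** Every encoder and decoder level uses a
block that cascades one 3×3 convolution with two Res2Net modules. A
Res2Net module applies a 1×1 convolution, splits the channels into $S$
equal subsets $X_1 \dots X_S$, and processes them hierarchically:

$$Y_1 = X_1,\qquad Y_2 = f_{3\times 3}(X_2),\qquad
Y_i = f_{3\times 3}(X_i + Y_{i-1}),\; 2 < i \le S,$$

after which $Y_1 \dots Y_S$ are concatenated and mixed by a trailing 1×1
convolution. Each subset sees one more 3×3 convolution than the previous
one, so the output mixes receptive fields from one level of context up to
$S-1$ stacked convolutions — cheap multi-scale perception that helps with
the large variation in vertebra size and the thin transverse/spinous
processes. The split count follows the channel width: $S = 4$ on the first
three encoder levels and last two decoder levels, $S = 6$ on the deepest
two encoder levels and first two decoder levels.

Because the deep widths (e.g. 512, 1024 at base width 64) are not
divisible by 6, the leading 1×1 convolution maps to the largest multiple
of $S$ not exceeding the block width (510, 1020), and the trailing 1×1
restores the block width. An explicitly supplied internal width must be
divisible by $S$; anything else is a configuration error.

**Attention on the central processing unit.** Each of the four skip
connections passes through a channel attention module (CAM): global
average *and* max pooling produce a $2C$ descriptor $z_C$, a two-layer
bottleneck ($W_1 \in \mathbb{R}^{C/4\times 2C}$,
$W_2 \in \mathbb{R}^{C\times C/4}$, ReLU between, sigmoid after) turns it
into per-channel gates in $(0,1)$, and the feature map is rescaled
channel-wise. The bottleneck consumes the full $2C$ descriptor — the
average and max halves are complementary summaries and the $C/4$ width
keeps the gate cheap. The deepest feature passes through a dual attention
module (DAM), the element-wise **sum** of CAM and a position attention
module (PAM). PAM stacks three $H\times W$ descriptors — channel-wise
max, channel-wise mean, and a learned 1×1 projection — convolves them
with a 3×3 kernel and gates every pixel with the sigmoid output,
broadcast over channels. The channel-wise mean (rather than a literal
sum) keeps the descriptor scale independent of $C$; a `pool = "sum"`
switch provides the literal sum for comparison. No normalization layer
precedes the gate sigmoid. With all gate weights and biases zero, both
gates are exactly 0.5 everywhere, so the DAM reduces to the identity map
$0.5X + 0.5X = X$ — a property the test suite checks to machine
precision. Note the corresponding *network*-level neutral configuration
is not the identity: a zeroed CAM on a skip scales it by 0.5, and the
tests compare against exactly that neutral-gate twin.

**A feature box with deep supervision.** Each of the four decoder levels
emits a coarse class-score map through a 1×1 head, bilinearly upsampled
to input resolution. The four coarse maps are concatenated and fused by a
final 1×1 convolution into the fine prediction. Training supervises all
five maps:

$$L = \sum_{i=1}^4 \lambda_i L_i + \lambda_P L_P,$$

with all weights 1 by default, where each term is the soft Dice loss

$$L(y, P) = 1 - \frac{1}{C}\sum_j
\frac{2\sum_i y_{ij}P_{ij} + \varepsilon}
     {\sum_i y_{ij} + \sum_i P_{ij} + \varepsilon}$$

over one-hot ground truth $y$ and softmax probabilities $P$. The
smoothing constant $\varepsilon = 10^{-5}$ resolves the 0/0 case of a
class absent from both maps (the term then contributes no loss).
Auxiliary maps are supervised at full input resolution — heads are
upsampled before the loss — because supervising a head on a map the
network never emits at that scale would decouple it from the final
fusion. At inference only the final fused map is used; labels are the
per-pixel argmax with ties resolved toward the lower class index
(background).

### Architectural conventions

The encoder halves spatial size and doubles width per level
(256→128→64→32→16 pixels, $w$→$16w$ channels at input 256). Level 1
convolves at full resolution without a preceding pooling — otherwise no
full-resolution feature would exist for the last skip connection — so the
four inter-level poolings carry the ladder. Decoder upsampling uses
learnable 2×2 transposed convolutions; the cheap auxiliary heads use
fixed bilinear interpolation. Each convolution is followed by batch
normalization and ReLU (both individually switchable; the smooth,
activation-free configuration is used by the gradient-verification
tests). The two Res2Net modules inside a block have independent
parameters. DAM is applied at the bottleneck only; the decoder features
are left unattended, and the final fusion sees only the four coarse maps,
not the last decoder feature.

## Implementation

No deep-learning framework is available to R here, and the network *is*
the package's subject, so forward and analytic backward passes are
implemented in the package: convolution and 2×2 max pooling as
RcppArmadillo kernels (convolution as a sum of shifted GEMMs, with a
zero-copy fast path for 1×1 kernels), batch normalization in C++, and the
attention modules, Res2Net routing, transposed convolution and bilinear
resampling in vectorized R. Every layer's backward pass is verified
against central finite differences; the composite network is verified the
same way on a smooth (activation-free) configuration, where maxima are
generically unique. On the default ReLU configuration, exact ties at
zero-valued activations make the subgradient ambiguous, so
finite-difference equality is only asserted on the smooth variant.
AdamW (decoupled weight decay 0.01, the optimizer's conventional
default) is implemented directly; the learning rate starts at $10^{-3}$
with mini-batches of 16 and is halved when the validation Dice fails to
exceed its best value for 10 consecutive epochs — "does not rise" is
read as no strict improvement over the running best, the standard
plateau semantics, with an optional floor. Validation Dice is the
slice-averaged DSC of hard final-head predictions, computed in
evaluation mode (running normalization statistics), so repeated
evaluation is bit-deterministic.

## Metrics

DSC $= 2|A\cap B|/(|A|+|B|)$ and IOU $= |A\cap B|/|A\cup B|$, both
defined as 1 for two empty masks, linked by
$\mathrm{DSC} = 2\,\mathrm{IOU}/(1+\mathrm{IOU})$. The robust Hausdorff
distance takes boundary points (foreground pixels with a background
4-neighbor in 2-D, 6-neighbor in 3-D; the image border counts as
background), pools the two directed nearest-point distance sets, and
reports the 95th percentile with linear interpolation between order
statistics (`quantile` type 7) — reproducible bit for bit. The
percentile is taken over the pooled symmetric set because that is the
quantity the per-case tables report; `percentile = 100` recovers the
classical maximum Hausdorff distance, which is also available. Distances
are measured in physical units through per-axis spacings (after 1 mm
isotropic resampling, pixels and millimetres coincide). Per-case scores
are compared across methods with a two-sided paired t-test; identical
per-case differences are rejected as degenerate rather than given
p = NaN. Per-volume evaluation is the default; per-slice values can be
computed by passing slices as cases.

## Preprocessing

Volumes are windowed to HU $[-200, 1200]$ — enclosing soft tissue and
trabecular/cortical bone — and min–max scaled to $[0,1]$ per volume;
both constants are configurable. All scans are resampled to 1 mm
isotropic spacing (trilinear for intensities, nearest for labels; output
extent `round(extent × spacing)`), sliced axially, and resized to
256×256 (bilinear for images, nearest for masks, which therefore stay
strictly binary). Augmentation applies, each with probability ½:
rotation by a uniform angle in ±0.1 rad, horizontal flip (vertical flips
are anatomically implausible for axial slices), centered contrast
scaling by a factor in $[0.8, 1.2]$, and additive Gaussian noise with
σ in $[0, 0.02]$ on the unit intensity scale — the last two touch the
image only. Every augmentation is a pure function of its seed. The
train/validation split is 4:1 by slice count, assigning whole volumes to
the validation side when at least three volumes are present so that
near-identical neighboring slices cannot straddle the split; slices from
held-out test volumes never enter either list.

## The phantom generator

`generate_phantom()` rasterizes a minimal vertebra-like scene on a
256×256 (configurable) grid: a bright body ellipse (semi-axes ≈ 11–15%
and 8–11% of the image side, intensity 0.55–0.70 over a 0.12
background), one to three attached process rectangles (one caudal, two
oblique-lateral), optional gray-matched distractor ellipses drawn only on
background pixels (interference regime, intensity within ±0.05 of the
body), an optional hyper-intense lesion disk inside the body (+0.15–0.25,
included in the truth mask), and additive Gaussian noise (σ 0.005–0.02).
The truth mask is the union of body, processes and lesion; distractors
never enter it, by construction. Foreground occupies roughly 2–15% of
pixels, matching the class imbalance that motivates the Dice loss. The
`mixed` profile allocates 40% easy / 30% interference / 30% lesion
deterministically. Every slice's spec is recorded in a manifest and each
generation is a pure function of its spec, so datasets replay exactly.

What the phantoms deliberately do **not** model: anatomical shape detail,
inter-vertebra similarity along the spine, CT reconstruction artifacts,
or 3-D continuity beyond stacking independent slices. Passing tests on
phantoms therefore demonstrate that the architecture, losses, metrics and
training loop function as specified — not that the trained miniature
would transfer to clinical CT.

## Problem sizes and numerical choices

The test suite and the acceptance script run miniatures chosen as the
smallest configurations that still exercise every architectural element:
base width 8 at 64×64 input (all five levels, both $S$ values, ~4×10⁵
parameters) for training runs, and a single forward/backward at the full
base width 64 / input 256 configuration (~2.8×10⁷ parameters) to assert
the shape ladder and gradient reach. The overfit-capacity check trains
the miniature on 8 fixed mixed-profile phantoms for 300 full-batch
optimizer steps with a constant learning rate (the plateau patience is
set beyond the run length: a capacity check wants the protocol's initial
rate held fixed, and epoch-based patience would otherwise trigger on the
8-slice epochs long before a true plateau); it reaches a training DSC
above 0.95. The generalization demonstration in the acceptance script
trains on 24 phantoms with augmentation and evaluates on 8 held-out
phantoms. Random draws everywhere go through explicit seeds; per-item
seeds are derived from a master seed by integer sampling, and seeded
sections save and restore the caller's RNG state.

Degenerate inputs are handled explicitly rather than silently: empty
masks make the Hausdorff distance an error (a missing value in reports),
zero-variance paired differences are a degeneracy error, non-finite
losses abort training with a diagnostic, and masks are revalidated as
binary after every geometric transform.

## Known limitations

Training at the full 256×256 / base width 64 scale is CPU-bound in this
implementation (a single optimizer step takes on the order of a minute);
the package is built for methodological completeness and desk-scale
experiments, not GPU-scale benchmark replication. The MetaImage reader
covers uncompressed scalar volumes only. Checkpoints store double
precision and are therefore large for the full configuration. The 3-D
extension of the architecture is out of scope; volumes are processed
slice-wise and restacked.
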