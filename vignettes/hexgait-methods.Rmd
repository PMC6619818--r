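---
title: "HexGait: models, parameters and design choices"
author: "HexGait maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HexGait: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

HexGait tracks the leg claws of a freely walking hexapod in high-speed
backlit silhouette video, without any hand-annotated training data, and
derives gait and tremor statistics from the tracks. This vignette explains
the underlying models, every tunable parameter that matters, the synthetic
fixtures the package validates itself against, and the places where the
design was genuinely open and a choice had to be made.

## 1. Silhouette extraction and background models

A backlit arena yields a dark animal on a bright, static background. The
foreground of frame $I$ is

$$ S(x, y) = \big| I(x, y) - B(x, y) \big| > \tau , $$

followed by keeping the largest connected component together with any
component within 5 px of it (dust suppression; the silhouette must be a
single animal for pose estimation). The threshold $\tau$ defaults to Otsu's
method on the 256-bin histogram of the difference image; a fixed intensity
can be supplied instead.

Three background models $B$ are available:

* **auto** — the per-pixel median over every 20th frame (the same sampling
  rate used for training frames). The median is a robust bright estimate
  provided the animal keeps moving; it requires roughly 1.5 body lengths of
  travel across the recording. Below that, the estimate carries grey traces
  of the animal and the result is flagged `stationary`.
* **spliced** — the first and last frames mosaicked along the perpendicular
  bisector of the two body centroids, each pixel taken from the frame whose
  animal is farther away. This is the fallback for short or slow recordings.
* **loaded** — a user-supplied animal-free image.

## 2. Self-generated training set

No human annotation is used anywhere. High-confidence **leg** pixels are
found where the silhouette's medial-axis skeleton meets its (1-px-dilated)
edge set: on a structure a few pixels wide the skeleton runs within a pixel
of the boundary, while on the body it stays deep. Skeleton-near-edge pixels
that are nevertheless deeper than half a leg width (`legWidth/2`, default
2.5 px) are rejected — these occur at narrow body extremities (the head, a
wing tip) which would otherwise poison the positive set.

**Non-leg** pixels are everything the morphology is sure about: the whole
body foreground outside a grey exclusion zone of `legWidth` px around the
harvested leg pixels, plus a 10-px band of background around the
silhouette. The grey zone — the pixels around the legs whose labels are
genuinely uncertain — takes no part in learning. Patch sampling draws the
two negative sources half and half.

This harvest is deliberately high-precision / low-recall: on the synthetic
walkers below, essentially every harvested positive lies on a true leg
midline while only about a quarter of the true leg pixels are harvested.
Learning then generalizes from the midlines to whole legs.

Each selected pixel becomes a $41 \times 41$ grayscale patch (zero-padded
at image borders, intensities scaled to $[0,1]$) labeled $y_i = \pm 1$.
Defaults: 30 000 positives and 30 000 negatives, one training frame in
every 20.

## 3. The boosted classifier with learned convolution kernels

The classifier is gradient boosting with a quadratic (Newton)
approximation under the exponential loss

$$ L(y, \varphi) = e^{-y \varphi}, \qquad
   w_i = e^{-y_i \varphi(x_i)}, \qquad r_i = y_i , $$

over $M$ decision trees of depth $\le 5$. The training set is split once
into $T_1$ (kernel learning; by default $1/6$ of the samples, matching
10 000 of 60 000) and $T_2$ (split search).

At every tree node, 100 candidate kernels are generated: square windows
with side $s$ drawn uniformly from 4–19 px, anchored uniformly at random
inside the patch, with a smoothness factor $\lambda$ drawn from
$\{100, 500, 1000\}$. Each kernel minimizes the regularized weighted least
squares problem

$$ K = \arg\min_K \sum_{i \in T_1} w_i \left( K * x_i - r_i \right)^2
   + \lambda \sum_{m \sim n} \left( K^{(m)} - K^{(n)} \right)^2 , $$

solved exactly through its normal equations with a 4-neighbour
graph-Laplacian penalty. The split threshold is found by exhaustive search
over sorted-response midpoints; leaf values are weighted residual means;
the candidate with the smallest weighted SSE wins, ties broken by the
lowest candidate index. Shrinkage is $\gamma = 0.1$; scores are clipped at
$\pm 30$ before exponentiation.

Prediction maps the boosted score to a leg confidence with the logistic
transform $1 / (1 + e^{-2\varphi})$; the confidence is defined on the
silhouette foreground and 0 elsewhere. The segmentation threshold defaults
to 0.65 (the upper end of the 0.6–0.65 band where the pixel
$F_{0.5}$ peaks).

Design choices worth stating explicitly:

* The per-node kernel fit is capped at `kernelFitMax` (default 1000)
  $T_1$ samples, subsampled at the node; the split search still scores
  every $T_2$ sample. The normal-equation cost grows as $n\,s^4$ and the
  fit is a least-squares estimate whose quality saturates well below a
  thousand samples per node.
* Candidate kernels are generated fresh at every node rather than once per
  boosting round, since each split optimizes its own feature.
* **Self-training** (2 rounds by default): the trained classifier is
  applied back to the training frames; foreground pixels with confidence
  $\ge 0.9$ join the positive pool and $\le 0.1$ the negative pool, patches
  are resampled and the model refit. Augmentation stops early if the pools
  grow by less than 1%.

## 4. Tracking

Per frame, the body pose comes from the silhouette moments: centroid and
principal-axis angle $\theta \in (-90^\circ, 90^\circ]$ measured from the
arena y-axis. The axis is kept temporally continuous (mod 180°), and the
anterior end is the one that on average leads the motion; for an
essentially stationary animal the broader axis half (head + thorax) is
taken as anterior. Claw positions are reported both in arena coordinates
(0-based pixels, x = column, y = row) and in the body-centred frame
(centroid at the origin, anterior along +y).

Leg components are the 8-connected supra-threshold confidence regions of
at least 4 px (a leg tip spans about 3 px), with fragments separated by a
$\le$ 2-px dropout bridged back together. Each component is thinned to a
1-px skeleton; the claw candidate is the skeleton endpoint at maximum
distance from the body centroid, refined to the centroid of the most
distal component pixels around that endpoint (thinning retracts a skeleton
tip by a pixel or two from the physical tip).

Identities initialize at the first frame whose candidate count equals the
leg count with equal numbers on each side of the body axis; side follows
the sign of body-frame x and front/mid/hind the body-frame y rank.
Subsequent frames solve a gated linear assignment: squared body-frame
distance, pairs beyond 20 px forbidden (the gate scales with image width),
solved by an $O(n^3)$ Hungarian implementation. Legs that fail to match
are tried against the leftover tips from their last-seen positions; legs
that still fail are flagged missing. Manual corrections (a CSV of frame,
leg, position or absent-mark) re-run tracking forward from the corrected
frame; displacement spikes completing within 1 ms are filtered before
analysis.

## 5. Gait statistics

All distances are converted to mm with `fovMM / image width`.

* **Swing/stance.** A stride (swing) is a maximal run where the claw's
  *arena-frame* speed — smoothed over 15 ms — exceeds 4 mm/s, with
  hysteresis down to 2 mm/s and a 3-ms minimum. The arena frame is used
  deliberately: during stance the claw is planted (speed near zero),
  whereas in the body-centred frame a stance claw moves backward at the
  full walking speed, which no fixed threshold can separate from swing.
  Gaps of up to 5 frames are interpolated before detection; longer gaps
  split strides.
* **Stride parameters.** Take-off (PEP) and landing (AEP) are the
  body-frame positions at swing start and end; displacement
  $=\lVert AEP - PEP \rVert$, path $=$ summed steps, amplitude $=$ the
  displacement projected on the body axis, period $=$ start-to-start
  interval, stretch $=$ distance from the body centre at the temporal
  midpoint, and stance linearity $=$ RMS deviation of the arena-frame
  stride path from a natural cubic spline through control points sampled
  every 20 ms.
* **Leg parameters.** Movement % (swing frames over tracked frames), mean
  stride period, footprint regularity (mean of the AEP- and PEP-cloud
  standard deviations, cloud SD $=\sqrt{\mathrm{var}(x)+\mathrm{var}(y)}$),
  and the trajectory domain: convex hull area of the body-frame
  trajectory with length/width as extents along the principal axes.
  Footprint regularity, domain length and stride length are also
  normalized by body length; domain overlaps and turn counts by the mean
  number of strides per leg.
* **Gait index.** Per frame: $+1$ if the swinging set is a canonical
  tripod ({L1,R2,L3} or {R1,L2,R3}), $-1$ if it is a diagonal
  tetrapod pair (one left, one right, different segments), $0$ otherwise;
  smoothed with a centred 120-ms moving average and clipped to $[-1,1]$.
* **Body.** Per-frame body length (silhouette extent along the axis),
  centroid velocity, and turning points: Douglas–Peucker simplification
  (5-px tolerance) of the centroid path with a turn wherever adjacent
  segments differ by more than 50°.

## 6. Tremor analysis and effect sizes

Claw traces are reduced to their deviation from a 50-ms moving-average
centreline, per axis. A **shaking event** is a local extremum whose
reversal from the preceding opposite extremum is at least 3 px (about a
leg-tip width; smaller reversals are tracking jitter). A **tremor event**
is any shake inside a maximal run of $\ge 3$ shakes with consecutive gaps
under 100 ms (safely below the ~10-Hz stride rhythm). The tremor
frequency is read off the histogram (10-ms bins) of intervals between
consecutive same-polarity extrema within runs — full periods, so a 20–30 ms
dominant bin means 33–50 Hz ($f = 1000 / \text{interval}$).

Enrichment of the dominant bin is tested with a permutation test: the null
redraws interval sets of equal size uniformly over the observed interval
range (100 000 iterations by default) and the p-value uses the add-one
convention. The uniform null and the deviation-signal construction are
this package's choices; both are stated here because only the test's name
and iteration count are fixed by convention.

Cliff's delta between a test and a control sample,

$$ \delta = \frac{\#\{a_i > b_j\} - \#\{a_i < b_j\}}{n_a n_b} \in [-1, 1], $$

is computed literally for small samples and through the equivalent
rank-sum form for large ones; 95% confidence intervals use the percentile
bootstrap with 10 000 resamples of both groups, clipped to $[-1, 1]$.

## 7. The synthetic walker and what it does (not) show

`renderWalkerVideo()` draws a deterministic dark walker on a bright
background: a two-lobed body (broader head+thorax lobe, longer posterior
lobe; 133 px long by default), six two-segment legs tapering to ~3-px
tips, walking a straight or zigzag path under a scripted tripod (or
tetrapod) schedule at 1 mm per 100-ms cycle (10 mm/s — about 2.3 body
lengths over the default 600 frames at 1000 fps, comfortably above the
1.5-body-length requirement of the automatic background). Anti-aliased
rendering is quantized to 8 bits, giving the blurred leg edges real
recordings show; Gaussian pixel noise (SD 2 counts) is added. Everything
is parameterized (field of view 9–12 mm, 250–1000 fps, contrast levels,
leg count 6/8) and seeded, and the ground truth — per-frame body pose,
per-leg claw positions, swing flags and per-pixel leg masks — is exact by
construction.

Two scripted imperfections emulate the dominant real-world failure modes:
fore-leg retraction episodes (30 frames each) during which the claw is
hidden under the body, and optional claw-path tremor injection for the
tremor pipeline. Neutral stance zones are spread so that adjacent claw
paths stay ~10 px apart at all phases; **touching or crossing legs are
deliberately out of the fixture's scope**, so passing tests say nothing
about recordings where legs overlap (the situation that dominates the
manual-correction workload on real data). The fixture also has rigid
geometry, no limb articulation beyond the two segments, no shadows or
illumination drift, and noise that is white rather than structured —
results on it bound the easy part of the problem, not camera reality.

Validation scale: the package's heavyweight self-check tracks three seeded
default walkers (512×512, 10 mm, 1000 fps, 600 frames, fore-leg
occlusions) end to end and asks for $\ge$ 95% of reported claws within
3 px of truth with $\le$ 8% missing data, and for learned segmentation to
beat the morphological harvest in recall and $F_{0.5}$ on every video.
Those runs train at a reduced scale — one training round, M = 30 boosting
rounds, 2 500 + 2 500 patches, 40 candidate kernels per node and a
400-sample kernel-fit cap — which keeps a full video under a few minutes
on one core. Self-training augmentation pays off when the resampled
training set is large enough to absorb the (noisier) augmented pools; at
this reduced patch budget a second round raises tip-localization variance
rather than accuracy, so the end-to-end check trains a single round and
the augmentation machinery (pool growth, non-decreasing recall) is
validated separately at small scale. The package defaults (2 rounds,
M = 100, 30 000 + 30 000 patches, 100 candidates) remain the recommended
settings for real recordings.

## 8. Numerical details and degenerate inputs

* Singular kernel systems receive a 1e-8 ridge jitter (logged).
* Tied split responses cannot be separated; a node with no valid
  threshold, under 20 $T_2$ samples, or an empty child becomes a leaf.
* An isotropic silhouette keeps the previous frame's axis angle.
* Components whose skeleton has no endpoint (closed loops) yield no claw
  candidate.
* A leg count that never appears cleanly makes initialization fail with
  the closest frame named; arachnid mode takes a manual first-frame
  labeling instead.
* CSV outputs print doubles with 17 significant digits, so read/write
  round trips are bit-exact; missing claws are empty cells.
* Assignment ties resolve deterministically (lowest leg index first);
  all randomness flows from a single pipeline seed.
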