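---
title: "Two-stage contrastive detection of facial tics in video: models and methods"
author: "ticmotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage contrastive detection of facial tics in video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Motor tics — sudden, rapid, recurrent facial movements such as repetitive
eye squeezing or mouth pulling — are the defining symptom of Tourette
syndrome and related tic disorders. Clinical severity instruments score
them by watching video: how many facial areas are affected, how often tics
occur per minute. Scoring is slow, and labeled clinical video is scarce,
while *unlabeled* video of the same patients is plentiful.

`ticmotion` implements a two-stage architecture for this setting:

1. **Stage 1 — self-supervised visual pretraining.** A convolutional
   encoder $F$ is trained on unlabeled face-ROI frames with a contrastive
   prediction task: each frame is augmented into two views forming a
   positive pair, and the normalized temperature-scaled cross-entropy
   (NT-Xent) loss pulls positive pairs together while pushing apart all
   other views in the minibatch. Crucially, every minibatch is a window of
   *continuous frames of a single subject*, so the negatives are the same
   person moments apart: the encoder cannot win by memorizing identity and
   is forced to encode facial *configuration* — eye aperture, mouth shape,
   pose.
2. **Stage 2 — supervised clip classification.** Recordings are cut into
   labeled tic segments and inter-event normal segments from timestamped
   annotations, windowed into non-overlapping 1-second clips, and each clip
   is summarized as a $k \times D$ sequence of frozen-encoder features from
   $k$ randomly sampled frames. A single-layer LSTM with a ReLU/dropout
   head and a softmax output classifies the sequence; training minimizes
   the focal loss to counter class imbalance, and the checkpoint is chosen
   by a watched validation metric (overall accuracy, or the F1 of the tic
   classes). Evaluation is leave-one-subject-out (LOSO) throughout.

## The losses

With $u^\top v / (\lVert u\rVert\,\lVert v\rVert)$ the cosine similarity
$\mathrm{sim}(i,j)$ between projected embeddings, the directed pair loss is

$$\ell(i,j) = -\log
  \frac{\exp(\mathrm{sim}(i,j)/\tau)}
       {\sum_{k \ne i}^{2N} \exp(\mathrm{sim}(i,k)/\tau)},$$

and the batch loss is the mean of the $2N$ directed losses over the $N$
pairs. $\tau$ is the softmax temperature; the package default is 0.5,
exposed in `contrastive_config()`. `ntxent_total_loss()` is the vectorized
implementation; the test suite holds it to within $10^{-6}$ of a literal
double-loop evaluation, and its analytic gradient to within $10^{-5}$ of
finite differences.

Stage 2 uses the focal loss
$L_f = -\alpha_t (1-p_t)^\gamma \log p_t$, with $p_t = p$ for a positive
label and $1-p$ otherwise. At $\gamma = 0,\ \alpha_t = 1$ it is exactly the
cross-entropy; $\gamma > 0$ down-weights easy examples. For the multiclass
task the per-class one-vs-rest terms on the softmax outputs are averaged,
which keeps the total invariant under class re-indexing ($\gamma=2$ and
inverse-class-frequency $\alpha$, normalized to max 1, are the training
defaults; both are exposed in `focal_config()`).

## Architecture and hyperparameters

The full-scale recipe is carried in the configuration defaults:
112×112×3 inputs, a residual convolutional encoder with 512-d output
(`encoder_spec()`), a 512→256 projection MLP (`projection_spec()`),
minibatches of 512 frame pairs, Adam at $3\times10^{-4}$ with cosine
annealing and weight decay $10^{-6}$, early stopping after 10 epochs
without a new validation-loss minimum, subject-level 70/30 train/validation
split; clip length 16 with $k<\mathrm{fps}$, LSTM input 512 / hidden 128 /
dropout 0.8 (`lstm_spec()`, `contrastive_config()`).

Two implementation choices deserve note:

* **Batch normalization.** Every convolution is followed by channel-wise
  batch normalization (batch statistics during training, running statistics
  at inference, so inference is deterministic). The reference encoder
  family is BN-throughout, and BN is what lets the contrastive task operate
  on consecutive video frames at all: within a one-subject window the raw
  inter-frame differences are small, and normalization rescales them to
  O(1) so the pretext task has gradient signal.
* **Numerics.** Convolutions are im2col gathers against a memoised sparse
  matrix (`Matrix`), so forward and backward are dense GEMMs; all backward
  passes (conv, BN, LSTM, losses) are exact and verified against numerical
  differentiation in the tests. The NT-Xent softmax uses a log-sum-exp; the
  focal loss works in log space.

Bilinear interpolation with half-pixel centers is the single resampling
convention used everywhere (ROI crops, augmentation crops, Grad-CAM
upsampling), which makes resized output reproducible to the bit across
runs.

## Preprocessing rules

Face detection is an interface: any function
`(subject, frame) -> face_box`. The synthetic generator supplies its
ground-truth boxes; an external detector (e.g. an MTCNN wrapper) can be
slotted in. The detected box is expanded by 20 % *in width and height*
around its center (`expand_roi()`) — the reference procedure states the
width expansion; we expand both axes so the ROI stays face-shaped, and the
factor is exposed per axis. Stage 1 downsamples the frame stream 3-fold
(first frame of every three; `downsample_3fold()`) because consecutive
frames are redundant; Stage 2 uses no downsampling since it samples $k$
frames per 1-second clip anyway. Clip windowing is left-aligned and
non-overlapping; remainders shorter than one second are discarded
(`window_clips()`). Seconds-to-frames conversion floors the start and
ceils the end of each annotated event so no tic frame is lost. Normal
segments are taken from all inter-event gaps; a guard margin around tic
events is available (`guard_s`, default 0) since the reference procedure
does not mention one.

Augmentation (`augment_pair()`) is random crop (area fraction in
(0.6, 1.0)), then channel-wise color jitter (amplitude 0.4), then additive
Gaussian noise ($\sigma = 5$ intensity units), in that order — noise must
not be color-jittered. The reference pipeline names the three operations
but no parameters; these defaults follow common contrastive-learning
practice and are all exposed in `augment_config()`.

## The synthetic cohort

No clinical video ships with (or can ship with) the package, so
`generate_cohort()` builds procedural cohorts that emulate the structure of
a multi-subject tic-video dataset: per-subject cartoon faces (skin tone,
face/eye/mouth geometry drawn per identity seed), continuous two-harmonic
head sway, spontaneous blinks (~12–20/min, 0.15–0.35 s smooth closures),
slow mouth micro-motion, pixel noise, and a marked Poisson schedule of tic
events — eye tics oscillate the eye aperture at ~4 Hz for 0.4–1.5 s, mouth
tics displace and stretch the mouth. Ground-truth face boxes and VoTT-style
JSON annotations are emitted alongside; frames are rendered lazily and are
a deterministic function of the cohort seed.

Design points:

* **Blinks are deliberate confounds.** A blink closes the eyes but is not a
  tic and is never annotated. A per-frame classifier cannot reliably tell a
  blink from an eye tic; the 1-second temporal window of the LSTM can,
  because a tic squeezes repetitively for most of the clip. Without blinks
  (and sway), consecutive frames of a subject are near-identical and the
  contrastive pretext task is degenerate; with them, the generator produces
  footage that is dynamic in the way real seated-patient video is.
* **The event rate is calibrated to the clip-label mix.** Tic events
  shorter than a second often yield no 1-second clip, so the Poisson rate
  is solved by bisection (simulating the exact windowing arithmetic) until
  the realized clip-label proportions match the configured `class_mix`
  (default 15 % eye / 15 % mouth / 70 % normal, an imbalanced mix of the
  kind clinical clip datasets show).
* **What the cartoons do not model:** photorealistic appearance, head
  rotation in depth, occlusions, multiple people, camera motion, vocal
  tics. A pipeline that passes on this benchmark is demonstrated to be
  correctly wired and able to learn the temporal signature of tics from
  unlabeled + labeled video; nothing here certifies performance on
  clinical footage.

## Desk-scale study conditions

The bundled end-to-end experiment (`run_tic_pipeline()`, also what
`scripts/acceptance.R` runs) uses a 6-subject × 60 s × 25 fps cohort
rendered at 64×64, and scales the architecture down with it: 32×32 encoder
input, channel widths (8, 16, 32), 64-d features, projection 64→32,
minibatches of 48 pairs, 16 epochs at Adam $2\times10^{-3}$ (cosine-annealed),
crop range (0.85, 1.0), LSTM hidden 48 with dropout 0.8, 30 epochs per
LOSO fold. Two desk-scale choices matter. First, NT-Xent optimization
starts on a plateau at the uniform-softmax value $\ln(2N-1)$: a positive
pair only beats the negatives once the encoder is invariant to the
augmentations, and until then the gradient carries almost no pair
information. At a 32-pixel input the package-default crop range (0.6, 1.0)
erases most of the few-pixel structure that distinguishes nearby frames,
and whether the optimizer ever clears the plateau becomes an
initialization lottery; with mild crops (0.85, 1.0) the positives have an
immediate similarity advantage and the plateau clears within a few epochs
on every cohort seed tried. Second, the learning rate ($2\times10^{-3}$)
and epoch count were sized so the cosine schedule still has headroom after
the plateau. Both were selected by watching the Stage-1 pretext validation
loss only; the full-scale defaults in the config objects are the reference
recipe. The whole experiment runs in roughly ten
minutes on one CPU.

## Evaluation

`tic_loso()` trains one classifier per held-out subject; within each fold a
subject-stratified 20 % of the training clips forms the validation split
that drives watch-metric checkpointing, so the held-out subject touches
neither training nor model selection (the test suite probes this by
corrupting the held-out subject and asserting the fold's parameters are
bit-identical). Precision/recall/F1 are macro-averaged by default
(`average = "weighted"` is the alternative); binary ROC AUC uses the
trapezoidal rule and PR AUC the step-wise integral, with the tic class as
positive; a class never predicted contributes precision 0. Cross-fold
aggregation reports mean ± SD over folds.

One caution worth stating: the within-fold validation clips come from
*training* subjects, so validation accuracy rewards memorizing subject
idiosyncrasies and is an unreliable signal for choosing capacity or
regularization — in our experiments a lightly regularized LSTM reached the
highest validation accuracy and the worst held-out-subject accuracy. This
is exactly why the heavy dropout of the reference recipe matters, and why
all headline numbers here are leave-one-subject-out.

Clinical items: the number of tic areas is the count of distinct tic
categories in a subject's predicted labels; tic frequency is the number of
*tic signs* — maximal runs of consecutive tic clips, with an optional
`gap_tolerance` for merging — divided by the video duration in minutes.
For comparing clinician and model item scores the package provides both
t-test forms: `items_ttest()` (two-sample, pooled variance — the form
whose p-values published rating-comparison tables of this kind report) and
`paired_ttest()` (matched subjects; arguably the better model for the
design). Degenerate all-zero differences report t = 0, p = 1 with a flag.

Grad-CAM (`grad_cam()`) explains what the encoder looks at: the gradient of
a scalar target (any weight vector over the feature dimensions, e.g. the
eye-tic-minus-normal mean feature direction) with respect to the final
residual stage's activations is spatially averaged into channel weights,
combined, rectified, bilinearly upsampled to input size and max-normalized.
A target independent of the image yields the all-zero map. Two practical
points: the saliency's native resolution is the final convolutional grid,
so `cam_peak()` reports the attended grid cell's center (an argmax on the
upsampled heatmap would land on a boundary pixel whenever a border cell
dominates, since the clamped bilinear upsampling extends it as a constant
plateau); and because the encoder is fully convolutional up to the pooling
stage, saliency can be — and in the bundled evaluation is — computed at
the cohort's native render resolution, which doubles the grid density over
the training input and localizes attention more sharply.

## Known limitations

* The hand-written networks are CPU-bound R; the full-scale recipe
  (512-pair batches, 112×112 inputs) is expressed in the configuration
  defaults but is not practical to train in this implementation — the
  package's empirical claims are at desk scale.
* The LSTM head places ReLU and dropout on the final hidden state before a
  single fully connected layer sized to the number of classes; the
  reference description fixes the sizes but not the exact head wiring.
* Whether "F1 of the tic category" in the multiclass task means macro-F1
  over the tic classes or F1 of a pooled tic-vs-rest dichotomy is
  ambiguous; the watch metric implements macro over tic classes.
* Multiclass AUCs are not reported (binary only), matching how such
  evaluations are usually tabled.
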