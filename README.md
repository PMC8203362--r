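# ticmotion

Automatic detection and classification of motor facial tics (eye tics,
mouth tics) in video, for researchers working on computer-aided assessment
of Tourette syndrome and other tic disorders — settings where labeled
clinical video is scarce but unlabeled footage of the same patients is
plentiful.

## The method

`ticmotion` implements a two-stage architecture:

**Stage 1 — contrastive visual pretraining.** A convolutional encoder *F*
(a reduced ResNet-style network with batch normalization, 112×112×3 input
and 512-d output at full scale) and a projection MLP *G* are trained on
unlabeled face-ROI frames with the NT-Xent objective. Each frame is
augmented twice (random crop, color jitter, Gaussian noise) to form a
positive pair; for a minibatch of N frames (2N views), the directed pair
loss is

    loss(i, j) = -log[ exp(sim(i,j)/τ) / Σ_{k≠i} exp(sim(i,k)/τ) ]

with `sim` the cosine similarity of projected embeddings and τ the
temperature, and the batch loss is the mean of the 2N directed losses.
Every minibatch consists of *continuous frames of a single subject*, so
negatives are the same person moments apart — the encoder must encode
facial configuration, not identity. Training uses Adam (3·10⁻⁴ full scale)
with cosine-annealed learning rate, weight decay 10⁻⁶, a subject-level
70/30 split and 10-epoch early stopping.

**Stage 2 — LSTM clip classification.** Annotated recordings are cut into
tic and inter-event normal segments, windowed into non-overlapping
1-second clips; k frames per clip (k = 16 < fps) pass through the frozen
encoder to give a k×512 feature sequence, classified by a single-layer
LSTM (hidden 128, dropout 0.8) with a softmax head. Training minimizes the
focal loss `-α_t (1-p_t)^γ log(p_t)` to handle class imbalance, with
checkpoint selection by a watched validation metric (accuracy or tic-class
F1). Evaluation is leave-one-subject-out, reporting accuracy, macro
precision/recall/F1, binary ROC/PR AUCs, confusion matrices, and two
video-scale clinical items: number of tic areas and tic frequency
(tic signs per minute), compared between model and rater by t-test.
Grad-CAM saliency maps show where the encoder looks.

Because clinical tic video cannot be redistributed, the package ships a
procedural generator of synthetic multi-subject cohorts (cartoon faces
with head sway, spontaneous blinks, scheduled eye/mouth tic events,
ground-truth face boxes and VoTT-style JSON annotations) on which the
entire pipeline is exercised and tested end to end.

## Worked example

```r
library(ticmotion)

# a 6-subject synthetic cohort: 60 s per subject at 25 fps, with a target
# clip mix of 15 % eye tics / 15 % mouth tics / 70 % normal
cohort <- generate_cohort(cohort_config(seed = 1))
cohort
#> Synthetic tic cohort: 6 subjects x 60 s at 25 fps (64x64 px)
#>   clip-label mix target eye/mouth/normal = 0.15/0.15/0.7; calibrated rate 23.62 tics/min
#>   121 tic events scheduled; noise sigma 5; seed 1

# the whole two-stage experiment at desk scale: stage-1 contrastive
# pretraining on the downsampled unlabeled frame streams, then frozen-encoder
# feature sequences classified by the LSTM under leave-one-subject-out
pipe <- run_tic_pipeline(seed = 1)
pipe$loso
#> Leave-one-subject-out evaluation (binary task, watch = accuracy)
#>   6 folds, 248 clips; metrics mean (sd) over folds:
#>   accuracy  0.8375 (+/-0.1172)
#>   precision 0.8577 (+/-0.1197)
#>   recall    0.7764 (+/-0.1177)
#>   f1        0.7679 (+/-0.1278)
#>   auc_roc   0.9364 (+/-0.0552)
#>   auc_pr    0.8520 (+/-0.1266)
```

Reading these numbers: the majority class (normal) is 75.4 % of clips, so
0.8375 mean accuracy with macro-F1 0.77 and ROC AUC 0.94 means the tic
clips themselves are being recovered, not just the majority guessed — a
binomial test of the pooled 248 predictions against the 0.754 chance level
gives p = 0.0014. The stages are also inspectable on their own:
`plot(pipe$encoder)` shows the NT-Xent training curve (the long plateau at
ln(2N-1) before pair structure emerges is expected, see the vignette),
`summary(pipe$loso)` adds the per-subject clinical items (tic areas, tic
frequency vs ground truth), and
`grad_cam(pipe$encoder, image, w)` returns the saliency map for any
feature-space direction `w` — with the eye-tic-minus-normal direction, the
map's peak lands inside the face box on every eye-tic frame probed
(25 of 25), localizing on the upper and central face.

The individual steps behind `run_tic_pipeline()` — `generate_cohort()`,
`stage1_frames()`, `tic_pretrain()`, `cohort_clips()`,
`cohort_features()`, `tic_loso()` — are all exported with the same
defaults, so any stage can be swapped or rescaled; all numbers above
regenerate exactly from the stated seed.

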