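# poseaction

Target-specific action classification from multi-person 2D pose
streams.

## The problem

Video recorded during clinical motor assessments (for example of
patients with Parkinson's disease) is untrimmed and messy: several
people share the frame, the camera cuts between rooms, and the person
of interest disappears behind staff for minutes at a time. Given the
per-frame output of any multi-person pose estimator — a bounding box
and 17 COCO keypoints per person — `poseaction` tracks one chosen
target through all of that and classifies what the target is doing in
each annotated interval: **sit**, **sit-to-stand**, **stand**,
**walk**, or **stand-to-sit**.

It is aimed at researchers quantifying human motor behavior from video
who already run a pose detector and need the downstream stages:
identity tracking, featurization, classification and evaluation — plus
a fully synthetic scene simulator so every stage can be validated
without access to clinical recordings.

## Method

**Cascaded tracking.** Detections in consecutive frames are linked
into *tracklets* by one-to-one bipartite matching that maximizes total
box IoU (Hungarian algorithm; matches below an IoU gate are refused).
Occlusions and scene cuts fragment an identity into many tracklets, so
a second stage prunes short or low-quality tracklets, represents each
by its highest-confidence detection, embeds that detection in an
appearance space, and accepts tracklet $T_i$ into the target's track
when the Euclidean affinity to the user-chosen reference tracklet,

$$P_a(T_i, T_{\mathrm{ref}}) = \lVert f_i - f_{\mathrm{ref}} \rVert_2 \le \tau,$$

with L2-normalized embeddings and $\tau = 0.7$ by default.

**Pose-evolution maps.** A clip of the target's track becomes a
$(14C) \times H \times W$ tensor: 17 keypoints are reduced to 14 joints
(eyes and ears merge into one head joint), each joint-frame becomes a
confidence-scaled Gaussian heatmap, and each frame's heatmap is spread
over $C$ color channels by triangular time-encoding weights
$o_j(t)$ (a partition of unity over the clip; channel 1 peaks at the
clip start, channel $C$ at its end). Per joint and channel the weighted
heatmaps are summed over frames and normalized by their spatial
maximum. Time direction is preserved — sit-to-stand and stand-to-sit
differ by a channel reversal.

**Classifier.** A compact CNN — two blocks of two 3×3 convolutions
(widths 128/256, strides 2 and 1, each followed by ReLU, batch
normalization and dropout), global average pooling, and a 5-way softmax
layer — trained with Adam (lr 0.01, batch 70, dropout 0.3) on softmax
cross-entropy. With $C = 3$ the model has 1,084,165 parameters.

**Evaluation.** Confusion matrices (rows = truth), per-class accuracy,
weighted overall accuracy (= trace/total), tracker binary accuracy and
fused-track frame coverage.

The methods vignette (`vignettes/poseaction-methods.Rmd`) documents the
model, all tunable parameters, the simulator's scope, and the numerical
choices.

## Worked example

Simulate a 20-second, 3-actor scene (the target sits, stands up, walks,
sits back down; one occlusion each for the target and a bystander; one
scene cut), track the target, and segment its annotation into clips:

```r
library(poseaction)

actors <- make_actor_specs(3, separation_noise_ratio = 20, seed = 5)
scene <- scenario_config(
  600, actors = actors,
  action_script = list(list("sit", 5), list("sit-to-stand", 1),
                       list("stand", 4), list("walk", 6),
                       list("stand-to-sit", 1), list("sit", 3)),
  occlusion_windows = list(list("actor01", 150, 209),
                           list("actor02", 360, 401)),
  scene_changes = 300L, detection_dropout_prob = 0.02, seed = 11)
scen <- generate_scenario(scene)

tracklets <- build_tracklets(scen$stream, iou_threshold = 0.1)
length(tracklets)
#> [1] 36

ev <- evaluate_tracking(scen, pipeline_config(affinity_threshold = 0.7))
ev$track
#> <track> 529 detections from 12/35 accepted tracklets (ref 5, tau 0.7)
c(accuracy = ev$tracklet_accuracy, coverage = ev$coverage)
#> accuracy coverage
#>        1        1

segment_clips(scen$annotations, fps = 30)[, c("label", "n_frames")]
#>          label n_frames
#> 1          sit      120
#> 2          sit       30
#> 3 sit-to-stand       30
#> 4        stand      120
#> 5         walk      120
#> 6         walk       60
#> 7 stand-to-sit       30
#> 8          sit       90
```

The occlusions and the cut fragment three people into 36 tracklets; the
appearance fusion rejects every bystander tracklet and reassembles the
target (binary accuracy 1.0) covering every visible target frame.

Train the classifier on simulated clips and score held-out ones:

```r
train <- generate_clip_dataset(60, clip_len_frames = 60, seed = 1)
val   <- generate_clip_dataset(15, clip_len_frames = 60, seed = 2)
test  <- generate_clip_dataset(20, clip_len_frames = 60, seed = 3)
Xtr <- featurize_clips(train); Xva <- featurize_clips(val)
Xte <- featurize_clips(test)

model <- build_model(model_config(C = 3, H = 34, W = 60, seed = 1))
model <- train_classifier(model, Xtr, attr(Xtr, "labels"),
                          Xva, attr(Xva, "labels"), verbose = TRUE)
#> epoch 1 loss 0.900159 val_acc 1
cm <- confusion(attr(Xte, "labels"), predict_labels(model, Xte))
weighted_overall_accuracy(cm)
#> [1] 1
```

On these synthetic kinematics the five actions are cleanly separable;
the diagonal confusion matrix and accuracy 1.0 say the representation
preserves what distinguishes them (including time direction, which is
all that separates the two transitions).

A thin command-line front end is installed at
`inst/cli/poseaction` (`simulate`, `track`, `clips`, `featurize`,
`evaluate`, `run-all`).

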