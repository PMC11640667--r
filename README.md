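# caprid

Multi-view individual identification for livestock imagery.

## The problem

Precision livestock management needs to know *which* animal a camera is
looking at. For goats — active animals with convex, wool-covered faces —
a frontal face shot is hard to capture and surprisingly uninformative;
field studies across a herd of visually near-identical white goats found
that the **side body** view identifies individuals best, the top-down
**back body** view comes second, and the face views trail. Better still,
fusing the softmax confidences of several per-view classifiers at the
decision level pushes identification to effectively zero error once three
or more views agree.

`caprid` packages that workflow for anyone building a multi-view
re-identification system: the frame-thinning and dataset-construction
preprocessing, a pluggable per-view classifier contract, the
accuracy-weighted decision fusion, the evaluation suite, and the runtime
acquisition policies that decide *how many* images or views to spend on
each animal. Because herd image collections are rarely shareable, the
package also ships a synthetic multi-view herd generator and a classifier
confidence simulator, so every stage is testable end to end on a laptop.

## The core model

Each view classifier maps an appearance image (a cropped region of
interest, resized to a fixed input size) to a softmax confidence vector
over the N known identities. Given vectors v_i from n distinct views and
per-view weights w_i equal to each single-view model's accuracy, the fused
prediction is the weighted average

    v_avg = ( Σ_{i=1..n} w_i · v_i ) / ( Σ_{i=1..n} w_i )

and the identity is `argmax(v_avg)`, with `max(v_avg)` as its top-1
confidence. Evaluation uses top-1/top-5 accuracy and one-vs-rest macro
precision, recall and F1 over the N classes. At runtime, a confidence
threshold policy (accept at ≥ 0.9; reshoot and vote in [0.7, 0.9);
discard below 0.7) or a sequential cascade (side body first, fusing in
further views only while the fused confidence stays below 0.9) trades
accuracy against acquisition and compute cost.

Upstream, near-duplicate video frames are removed with a 64-bit
difference hash (drop at Hamming distance < 5 to the last retained frame)
and the structural similarity index (drop at SSIM ≥ 0.7), and each
(identity, view) class is balanced to a fixed count by seeded
augmentation (mirror, rotation, translation, brightness) before an 8:2
stratified train/validation split; a fixed per-class test set is drawn
before any augmentation.

## Worked example

```r
library(caprid)

# per-view averages of the published single-view results
single <- single_view_benchmark()
aggregate_accuracy_table(single, "view")[, c("view", "top1", "top5")]
#>   view  top1  top5
#> 1    B 97.92 99.52
#> 2    F 97.55 99.24
#> 3    L 96.37 98.66
#> 4    R 96.41 98.87
#> 5    S 99.10 99.96

# fuse two view confidences, weighted by single-view accuracy
s <- simulate_confidence_vector(
  confidence_sim_config(54, c(S = 0.99, B = 0.98), seed = 1), 7, "S")
b <- simulate_confidence_vector(
  confidence_sim_config(54, c(S = 0.99, B = 0.98), seed = 2), 7, "B")
fused <- fuse_confidences(list(s, b), c(S = 0.99, B = 0.98))
fused
#> confidence_vector (view S+B, N=54): top-1 0007 @ 0.9791

# cascade policy over 2000 simulated episodes
sim <- confidence_sim_config(54, c(S = 0.99, B = 0.98, F = 0.97,
                                   L = 0.96, R = 0.96), seed = 3)
log <- simulate_policy_episodes(2000, sim, policy_config(), seed = 4)
sprintf("cascade accuracy %.4f, mean views %.3f",
        mean(log$correct), mean(log$images_consumed))
#> [1] "cascade accuracy 0.9970, mean views 1.047"
```

The per-view table says the side body view is the most reliable single
cue (99.10% mean top-1 across four backbones) and the left face the
weakest (96.37%). The fused vector shows two agreeing views lifting an
individual's confidence to 0.979. The episode log shows the cascade
keeping near-fused accuracy while consuming barely more than one view per
animal — the point of confidence-gated acquisition.

A full synthetic pipeline run (simulate → dedup → build → train → eval →
fuse → policy → report) is one call:

```r
run_pipeline("my_run", run_config(seed = 1))
```

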