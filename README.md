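# leaftracker

Leaf-level time series from top-view plant images. `leaftracker` takes the
per-frame instance masks any segmentation detector produces for a rosette
plant (*Arabidopsis thaliana* and similar flat, top-down-describable
species) and reconstructs individual **leaf tracks** across timepoints, so
that growth and photosynthesis can be analysed per leaf rather than per
plant. It is aimed at plant phenotyping groups working with
chlorophyll-fluorescence (CF) platforms that export Fv/Fm and ϕPSII
parameter images, but the tracking and evaluation layers are
detector- and trait-agnostic.

## The method in brief

Masks of the same leaf in consecutive frames overlap strongly when the
imaging interval is short relative to growth. Tracking is therefore greedy
intersection-over-union association: with
IoU(A, B) = |A ∩ B| / |A ∪ B|, each tracked leaf's current mask claims
the unclaimed next-frame detection with the highest IoU above a threshold
(0.15 by default), unmatched tracks carry their last mask forward as a
placeholder until the leaf is re-detected, and leftover detections open
new tracks. Track ids thus encode leaf order (emergence order).

Quality is scored the way the field scores it:

- detection — precision P = TP/(TP+FP), recall R = TP/(TP+FN), and the
  F-score 2PR/(P+R), after discarding predictions with confidence < 0.9
  and requiring IoU ≥ 0.15 for a correct detection;
- segmentation — descriptor table (count/mean/SD/min/quartiles/max) of
  matched-pair IoUs;
- tracking — HOTA = √(Σ_c A(c) / (|TP|+|FN|+|FP|)) with
  A(c) = |TPA|/(|TPA|+|FNA|+|FPA|), plus whole-track right/miss verdicts
  (a leaf is "right" when one track follows it end to end with at most 5
  missed detections).

A seeded simulator generates ground-truthed rosette sequences (phyllotactic
ellipse leaves, logistic growth, detection dropout/jitter/false positives,
trait images) so every stage is testable without platform data. See the
methods vignette (`vignettes/leaf-tracking-methods.Rmd`) for the model,
conventions and design choices.

## Worked example

Simulate a 57-frame plant, track its noisy detections, and evaluate:

```r
library(leaftracker)

cfg    <- sim_config(seed = 42, n_frames = 57, n_leaves_final = 15,
                     dropout = 0.05)
sim    <- simulate_rosette(cfg)
dets   <- filter_confidence(sim$detections, min_confidence = 0.9)
tracks <- track_sequence(dets, tracker_config(iou_threshold = 0.15))
tracks
#> <track_set> plant 1: 23 track(s) over 57 frame(s)

hota_score(build_correspondence(tracks, sim$gt_tracks, alpha = 0.5))
#> <leaf_hota> HOTA 0.8220 at alpha 0.50  (TP 464 / FN 61 / FP 36)

classify_tracks(tracks, sim$gt_tracks)
#> <leaf_track_verdict> right 8 / miss 6 / excluded 1 (57.1% right)
```

23 tracks for 15 true leaves: at 5 % dropout, missed detections
occasionally break a track and the re-detected leaf opens a new one —
exactly the failure mode the HOTA association term penalizes (HOTA 0.82
here versus 1.0 on noise-free detections). Per-leaf traits come straight
off the tracks:

```r
traits <- extract_leaf_traits(sim$gt_tracks, sim$trait_stacks$FvFm)
dplyr::filter(traits, track_id == 5, frame_index < 8)
#> # A tibble: 3 × 7
#>   plant_id track_id frame_index trait_name status    area mean_value
#>      <int>    <int>       <int> <chr>      <chr>    <int>      <dbl>
#> 1       42        5           5 FvFm       new          5      0.731
#> 2       42        5           6 FvFm       observed     7      0.740
#> 3       42        5           7 FvFm       observed     8      0.731
```

Leaf 5 emerges at frame 5 and its Fv/Fm is the mean of the normalized
parameter image under its mask at each timepoint; carried entries are
flagged so they can be filtered before analysis. Detection metrics work
from matches or from raw counts:

```r
detection_metrics(294, fp = 26, fn = 10)
#> <leaf_metric_report> P 0.9187, R 0.9671, F 0.9423  (TP 294 / FP 26 / FN 10)
```

All result objects have `tidy()`/`glance()` methods and `autoplot()`
figures; `inst/cli/letra.R` wraps the same functions as a command-line
tool (`simulate`, `track`, `eval-detect`, `eval-track`, `extract`,
`compare`).

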