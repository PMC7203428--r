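# hooploc

Markerless 3D localization of multiple basketball players from synchronized
multi-camera video.

Player positions in competition must be measured without instrumenting the
players, and in basketball the *vertical* coordinate matters — jumps,
rebounds, shot contests. `hooploc` implements a video-based framework that
reconstructs each player's head position in court space (X, Y, Z in metres)
from static cameras mounted high above the court, with no temporal tracking:
every frame is solved independently.

The pipeline:

1. **Head detection (per camera).** Adaptive Gaussian-mixture background
   segmentation with shadow relabeling → morphological opening → blob
   contours and their local tops → circle Hough fitting in a head-radius
   range → HOG features (64×64 window, 1764 features) scored by a
   1764–10–1 multilayer perceptron, gated to a per-camera interest-area
   polygon.
2. **3D reconstruction (across cameras).** Each camera is an 11-parameter
   DLT model. Which detected points belong to the same player is a
   constrained combinatorial assignment: for a candidate point subset of
   size *q* with squared re-projection errors *e_p*,

   score = (Σ_p e_p) / q² − q,

   minimized subject to: one player per point, 2 ≤ q ≤ w points per player
   (at most one per camera), every e_p ≤ τ² (default τ = 25 px), and head
   height within [h_min, h_max]. A constructive greedy heuristic solves one
   player per round — each round is an exact search over the remaining
   feasible subsets — then removes the assigned points. Leftover
   single-view points are localized by fixing Z at a mean head height
   (1.85 m). An exact joint solver (`brute_force_assign()`) is included as
   a test oracle.

A fully seeded synthetic-scene simulator (camera rigs as DLT vectors,
ground-truth players, noisy detections with misses and outliers, and a
frame renderer with ground-truth masks) makes every stage testable with no
external data, and the evaluation module implements the 25-pixel matching
rule, detection-rate triplets, and planar/spatial RMSE.

## Worked example

```r
library(hooploc)

cfg   <- scene_config(n_players = 3, noise_sigma_px = 1,
                      outliers_per_camera = 1, min_separation = 2)
scene <- simulate_scene(cfg, seed = 42)
scene
#> synthetic scene: 3 players, 3 cameras, 12 detections

res <- localize_frame(scene$detections, scene$cameras, loc_config())
res
#> player localizations: 3 optimized, 4 fallback
#> # A tibble: 7 × 7
#>   label method         X      Y     Z n_points score
#>   <int> <chr>      <dbl>  <dbl> <dbl>    <int> <dbl>
#> 1     1 optimized   4.58   8.10  1.70        3 -2.71
#> 2     2 optimized   6.81  13.2   1.94        3 -2.70
#> 3     3 optimized   1.26  10.4   1.86        2 -2.00
#> 4     4 fallback    1.26  10.2   1.85        1 NA
#> 5     5 fallback    6.91   5.75  1.85        1 NA
#> 6     6 fallback   13.2    7.94  1.85        1 NA
#> 7     7 fallback  119.   162.    1.85        1 NA

ev <- evaluate_localizations(cbind(frame_id = 0, tidy(res)),
                             cbind(frame_id = 0, scene$truth))
ev
#> # A tibble: 1 × 4
#>   method        n rmse_xy_m rmse_xyz_m
#>   <chr>     <int>     <dbl>      <dbl>
#> 1 optimized     3   0.00905     0.0111
```

Reading the output: three players were localized by optimization with
centimetre-level RMSE under 1 px detection noise (negative scores near −q
mean geometrically consistent multi-view assignments). One player's third
view carried enough noise that the objective preferred the tighter two-view
fix (score −2.00) and left the third point to the height-prior fallback —
the same choice the exact joint solver makes. The three simulated outlier
points also become fallbacks; the one at (119, 162) m lands far outside the
14 × 15 m court, which is how outliers betray themselves downstream.

`autoplot(res)` draws the court-plane view; `glance(res)` summarizes counts
and total score; `localize_players()` maps the same computation over a
multi-frame detection table.

A command-line surface wraps the same functions
(`inst/cli/hooploc simulate | calibrate | detect | localize | evaluate`),
composing CSV/JSON artifacts; see `?run_cli`.

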