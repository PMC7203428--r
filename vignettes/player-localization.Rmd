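---
title: "Multi-camera 3D localization of basketball players: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-camera 3D localization of basketball players: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hooploc)
```

# The problem

In basketball, player positions during competition must be measured
non-invasively, and the vertical coordinate matters: jumps, rebounds and shot
contests are three-dimensional actions. `hooploc` implements a video-based
framework that localizes multiple players in court space (X, Y, Z in metres)
from synchronized, distortion-corrected views of static cameras mounted high
above the court. The reference point is the player's **head**: it is compact,
approximately circular in the image, high above the floor (so it carries
height information), and far less affected by occlusion and floor reflections
than feet or bounding-box bottoms.

The pipeline has two stages:

1. **Detection** — per camera, find candidate head points in each frame.
2. **Reconstruction** — decide which detected points in different cameras
   belong to the same player (a combinatorial data-association problem) and
   triangulate each player's 3D position.

No temporal information is used: every frame is solved independently, which
makes the method a detector/localizer rather than a tracker.

# Camera model: the direct linear transformation

Each camera $k$ is an 11-parameter DLT mapping world coordinates to pixels:

$$x = \frac{\lambda_1 X + \lambda_4 Y + \lambda_7 Z + \lambda_{10}}
           {\lambda_3 X + \lambda_6 Y + \lambda_9 Z + 1}, \qquad
  y = \frac{\lambda_2 X + \lambda_5 Y + \lambda_8 Z + \lambda_{11}}
           {\lambda_3 X + \lambda_6 Y + \lambda_9 Z + 1}.$$

The twelfth projective parameter is fixed at 1, the standard DLT
normalization; `fit_dlt()` solves the stacked linear system by SVD-backed
least squares with no nonlinear refinement. Eleven unknowns need eleven
equations and each world–image pair supplies two, so at least **six pairs**
per camera are required, and they must not be coplanar: calibration uses
court line intersections plus marks on a vertical bar. A condition-number cap
($10^{10}$) on every stacked system turns near-degenerate geometry
(coplanar calibration points, near-parallel rays) into an explicit error
rather than a silently unstable estimate.

Triangulation (`triangulate()`) solves the same equations for (X, Y, Z)
given observations in at least two cameras, again by least squares, and
reports per-observation Euclidean pixel re-projection errors. With a single
camera the point is only constrained to a ray; `triangulate_fixed_height()`
closes the system by fixing Z to a prior mean head height, leaving a 2×2
linear system in (X, Y).

A note on the re-projection error: the per-point cost is the **sum**
$(x_p - x_l)^2 + (y_p - y_l)^2$, the squared Euclidean pixel distance. A
product of the two squared components would vanish whenever either
coordinate matched by chance, which is geometrically meaningless, so the sum
form is used throughout.

# The assignment problem

Let $m$ detected points (across all cameras, one frame) and $n$ unknown
players. A binary assignment matrix $A_{p,l}$ says point $p$ belongs to
player $l$. Two conflicting objectives are merged into one score per player:
minimize re-projection error, and maximize the number of assigned points
(more consistent views mean better geometry). With $q = \sum_p A_{p,l}$ the
per-player objective is

$$\mathrm{score}(l) \;=\; \frac{\sum_{p} e_p}{q^2} \;-\; q,$$

where $e_p$ is the squared pixel re-projection error of point $p$ in its own
camera after triangulating the assigned subset. With perfect geometry the
score is exactly $-q$, so a three-view player ($-3$) always beats a two-view
player ($-2$); the $1/q^2$ damping keeps the error term from dominating as
views are added.

Constraints:

* each point is used by at most one player;
* each player uses at least 2 and at most $w$ points ($w$ = number of
  cameras), and at most one point per camera;
* every assigned point must re-project within a pixel tolerance
  ($e_p \le \tau^2$, default $\tau = 25$ px — the same tolerance the
  evaluation protocol uses for matching detections);
* the triangulated head height must lie in a plausible band
  $h_{\min} \le Z \le h_{\max}$.

The joint problem over all players is exponential in $m$. The solver is a
**constructive greedy heuristic**: each round enumerates every feasible
subset of the remaining points (this is exact per round — the feasible set
is small because subsets take at most one point per camera), selects the
global minimizer of the score, fixes that player, removes the assigned
points, and repeats until no feasible subset remains. Leftover points —
players seen by a single camera — are localized by the fixed-height
fallback at the prior mean head height. Ties break deterministically:
lowest score, then larger subset, then smallest point-index tuple.

`brute_force_assign()` solves the **joint** problem exactly (dynamic program
over point subsets, guarded to ≤ 12 points). It exists as an independent
oracle: the test suite verifies that each greedy round matches an
independent exhaustive scan, that greedy reproduces the jointly optimal
partition on almost all noise-free scenes, and that its total score stays
within a few percent of the joint optimum under pixel noise.

## Parameter defaults and their units

| parameter | default | meaning |
|---|---|---|
| `tau_px` | 25 px | max re-projection error per assigned point |
| `h_min` | 1.2 m | lowest admissible head height (deep crouch) |
| `h_max` | 3.2 m | highest admissible head height (jump apex) |
| `mean_height` | 1.85 m | fallback prior head height |
| `max_players` | unlimited | optional cap on optimized players per frame |

The height band spans a deep crouch to the apex of a jump for professional
players; the 1.85 m prior is a typical standing head height. These are
deliberate package choices (reasonable for adult elite basketball) exposed
through `loc_config()`.

# The detection stage

Per camera and frame:

1. **Background segmentation.** A per-pixel adaptive mixture of Gaussians
   (default 3 components) models the static scene; components accumulating
   the most stable weight (ratio threshold 0.7, ranked by weight/σ) form the
   background. Pixels not explained by a background component are
   foreground. *Shadow relabeling*: a foreground pixel whose intensity is
   0.45–0.95 of the background mean is a cast shadow (a darkened copy of
   the background) and is relabeled background. The model needs a burn-in
   (`history`, default 120 frames) before masks are emitted; the mixture
   update rate defaults to `1/history` and can be set independently when a
   slow burn-in would otherwise absorb slow-moving players.
2. **Morphological cleaning.** Opening (erosion then dilation, disc kernel)
   removes speckle noise; implemented with EBImage morphology.
3. **Contour maxima.** Blob contours are extracted; the topmost point of a
   contour and its local maxima (local minima of the image y coordinate,
   with 5 px suppression) seed the head search — one contour can enclose
   several touching players, each contributing a local top.
4. **Circle fitting.** Around each seed, a circle Hough search over an
   admissible head radius range scores candidate centres by **angular
   coverage** — the fraction of 10° sectors of the circle containing a
   contour pixel. Raw vote counts reward thick or flat contour runs;
   angular coverage demands an actual arc. Circles below the coverage
   threshold, beyond the seed-distance cap, or centred outside the
   per-camera interest-area polygon are dropped.
5. **Classification.** A HOG descriptor is computed on a square window
   around each candidate centre and scored by a trained MLP; candidates
   below the probability threshold (default 0.5) are rejected — raised
   arms, balls, torso fragments.

## HOG geometry

The descriptor follows the standard Dalal–Triggs layout: 64×64 px window,
8×8 px cells, 9 unsigned orientation bins, 2×2-cell blocks at one-cell
stride with clipped L2 block normalization. That geometry yields
$(8-2+1)^2 \times 4 \times 9 = 1764$ features — exactly the classifier's
input width. A constant patch produces an all-zero descriptor (guarded
normalization).

## The head classifier

A feed-forward MLP with one hidden layer of 10 logistic units
(1764–10–1), trained by mini-batch backpropagation with momentum on a
70/15/15 train/validation/test split, early-stopped on validation
cross-entropy (patience 20 epochs), fully seeded. A *positive* sample means
"head centred in the window": an off-centre head is a negative, because
candidates are circle centres and the decision is about the candidate, not
the neighbourhood. The width of the network (≈ 17 700 weights) makes
quasi-Newton training impractical — the Hessian approximation alone would
need gigabytes — which is why plain backpropagation is the right tool at
this scale.

# The synthetic scene generator

Every stage is testable without external footage. The generator emulates the
acquisition geometry of a real deployment:

* one half court, 14 × 15 m, world origin at the intersection of a lateral
  line (X) with a bottom line (Y), Z up;
* `w = 3` static cameras, mounted 12 m above the floor just outside the
  court perimeter, aimed at the court centre, expressed **directly** as DLT
  parameter vectors by composing pinhole intrinsics with the look-at pose —
  so geometry tests do not depend on the calibration fitter;
* a nominal 1038 × 776 px sensor; the focal length is chosen so the court
  volume fits the frame (a `focal_scale` multiplier emulates longer lenses
  for close-up rendering scenarios);
* player heads uniform over the court with heights uniform in 1.6–2.1 m
  (normal standing posture), optional minimum pairwise separation;
* detections = exact projections + isotropic Gaussian pixel noise (σ
  configurable), per-(player, camera) misdetections with probability
  `miss_prob`, and a configured number of uniform outlier points per camera
  with full provenance records.

The frame renderer draws players as a dark body ellipse (feet to head) plus
a bright shaded head disk whose centre is the exact DLT projection and whose
radius is projection-consistent with a 0.11 m head sphere, over a seeded
static textured background, with optional half-luminance floor shadows; it
emits per-frame ground-truth masks, shadow masks and head centres. The
training-patch generator renders head-centred positives and four negative
families (plain background, off-centre heads, elongated arm blobs, unshaded
free-floating balls, torso-centred windows).

**What the renderer does not emulate** — and hence what passing tests do
*not* show about real footage: real court texture and markings, jersey
colours, player articulation and limb motion, motion blur, interlacing,
illumination drift, specular floor reflections, spectators, and genuine
occlusion geometry (bodies may overlap in the render, but there is no
depth-ordered occlusion model). The detection-rate targets on rendered
scenes are a synthetic analogue of a real deployment's rates, not a
prediction of them.

# Numerical choices

* Least squares everywhere is SVD-based with a condition cap of $10^{10}$;
  beyond it the geometry is reported degenerate (error classes
  `hooploc_degenerate_*`), never silently extrapolated.
* Projection refuses denominators below $10^{-9}$ (points at or behind the
  camera's principal plane).
* A fallback point whose fixed-height 2×2 system is singular is reported
  `unlocalized` rather than guessed.
* Greedy tie-breaks (score, then subset size, then index tuple) make
  `localize_frame()` deterministic for a given input order.
* All generators take explicit seeds and restore the caller's RNG state.

# Problem sizes in the test suite

The suite exercises the full pipeline at sizes chosen to keep a complete
run comfortable on a laptop: rendered sequences use a 519 × 388 px frame
(half the nominal sensor) with a 4× focal multiplier so heads span ~6 px,
30-frame sequences with a 12-frame burn-in, 800 training patches;
oracle-agreement checks use 200 noise-free scenes with 2–4 players ≥ 2 m
apart; noise-recovery checks use several hundred σ = 1 px frames with the
joint exhaustive oracle on every one. `scripts/acceptance.R` recomputes the
same quantities from scratch at the same sizes.

# Known limitations

* No temporal linking: identities are per-frame labels in greedy-round
  order, not trajectories.
* The joint oracle is exponential and intentionally guarded to small point
  counts; the greedy solver is the production path.
* The fallback's planar position inherits the full error of the height
  prior: a player jumping or crouching while seen by one camera is displaced
  along the viewing ray.
* Real-footage accuracy depends on calibration quality and on retraining
  the head classifier on footage-specific patches; the bundled classifier
  pipeline is trained on rendered patches.
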