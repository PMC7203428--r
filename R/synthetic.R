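#' Synthetic multi-camera scene configuration
#'
#' Describes the simulated acquisition: one half of a basketball court
#' (14 x 15 m) observed by static cameras mounted high above the perimeter
#' (12 m, the highest practical mounting height in a gym), players
#' represented by their head points, Gaussian pixel noise on detections,
#' per-(player, camera) misdetections, and uniform outlier points emulating
#' non-head detections.
#'
#' @param court_x,court_y court extent in metres.
#' @param n_players number of players on court.
#' @param n_cameras number of cameras `w` (at least 2 for triangulation).
#' @param camera_height camera mounting height in metres.
#' @param head_height_range range (metres) head heights are sampled from;
#'   covers normal standing posture.
#' @param head_radius player head radius in metres (rendering).
#' @param noise_sigma_px standard deviation of isotropic Gaussian pixel noise
#'   added to each detected head point.
#' @param miss_prob probability that a given (player, camera) pair yields no
#'   detection.
#' @param outliers_per_camera number of spurious (non-head) detections added
#'   per camera, uniform over the frame.
#' @param min_separation minimum pairwise planar distance between players in
#'   metres (0 = unconstrained).
#' @param image_width,image_height nominal sensor resolution in pixels.
#' @param focal_scale multiplier on the automatically chosen focal length.
#'   1 frames the whole court volume; larger values zoom in (players must
#'   then stay near the court centre to remain in frame), giving larger
#'   apparent head sizes as with a longer lens.
#' @param shadows render soft floor shadows (renderer only).
#' @return a `scene_config` list.
#' @export
scene_config <- function(court_x = 14, court_y = 15,
                         n_players = 3, n_cameras = 3,
                         camera_height = 12,
                         head_height_range = c(1.6, 2.1),
                         head_radius = 0.11,
                         noise_sigma_px = 0,
                         miss_prob = 0,
                         outliers_per_camera = 0,
                         min_separation = 0,
                         image_width = 1038, image_height = 776,
                         focal_scale = 1,
                         shadows = FALSE) {
  stopifnot(noise_sigma_px >= 0, miss_prob >= 0, miss_prob <= 1,
            n_players >= 0, n_cameras >= 1,
            head_height_range[1] < head_height_range[2])
  structure(as.list(environment()), class = "scene_config")
}

.lookat_rotation <- function(C, target) {
  f <- target - C
  f <- f / sqrt(sum(f^2))
  r <- c(f[2] * 1 - f[3] * 0, f[3] * 0 - f[1] * 1, f[1] * 0 - f[2] * 0) # f x (0,0,1)
  r <- r / sqrt(sum(r^2))
  d <- c(f[2] * r[3] - f[3] * r[2],  # f x r: image-down axis
         f[3] * r[1] - f[1] * r[3],
         f[1] * r[2] - f[2] * r[1])
  rbind(r, d, f)
}

#' Build a synthetic camera rig as DLT parameter vectors
#'
#' Cameras are placed above the court perimeter at the configured height,
#' oriented at the court centre, and expressed directly as 11-parameter DLT
#' models by composing pinhole intrinsics with the look-at pose and
#' normalizing the projective 3 x 4 matrix so its last entry is 1. The focal
#' length is chosen per camera so that the whole court volume (up to jump
#' height) projects inside the nominal frame. Building cameras from the
#' projective composition (rather than through the calibration fitter) keeps
#' geometry tests independent of the fitter.
#'
#' @param config a [scene_config()].
#' @param seed integer; seeds the small placement jitter. Identical seeds give
#'   bitwise-identical rigs.
#' @return camera tibble with `n_cameras` rows.
#' @export
make_camera_rig <- function(config = scene_config(), seed = 1) {
  w <- config$n_cameras
  cx <- config$court_x / 2
  cy <- config$court_y / 2
  with_seed(seed, {
    ang0 <- runif(1, 0, 2 * pi)
    jit <- runif(w, -0.15, 0.15)
    hjit <- runif(w, -0.3, 0.3)
    radius <- sqrt(cx^2 + cy^2) + 4  # just outside the court perimeter
    target <- c(cx, cy, 1.0)
    rows <- purrr::map(seq_len(w), function(i) {
      th <- ang0 + 2 * pi * (i - 1) / w + jit[i]
      C <- c(cx + radius * cos(th), cy + radius * sin(th),
             config$camera_height + hjit[i])
      R <- .lookat_rotation(C, target)
      # test volume: court corners at floor and jump apex, plus centre
      gx <- c(0, config$court_x)
      gy <- c(0, config$court_y)
      gz <- c(0.0, 3.2)
      Wt <- as.matrix(expand.grid(X = gx, Y = gy, Z = gz))
      Wt <- rbind(Wt, c(cx, cy, 1.8))
      rel <- sweep(Wt, 2, C) %*% t(R)   # camera coords: right, down, forward
      u <- rel[, 1] / rel[, 3]
      v <- rel[, 2] / rel[, 3]
      f <- (config$focal_scale %||% 1) * 0.90 *
        min((config$image_width / 2) / max(abs(u)),
            (config$image_height / 2) / max(abs(v)))
      K <- rbind(c(f, 0, config$image_width / 2),
                 c(0, f, config$image_height / 2),
                 c(0, 0, 1))
      P <- K %*% cbind(R, -R %*% C)
      P <- P / P[3, 4]
      # column-major read-out matches the lambda ordering of the DLT equations
      new_camera(i - 1L, c(P)[1:11])
    })
    dplyr::bind_rows(rows)
  })
}

#' Sample ground-truth player head positions
#'
#' Heads are uniform in X, Y over the court (0.5 m inside the boundary) with
#' Z uniform over the configured head-height range; an optional minimum
#' pairwise planar separation is enforced by rejection sampling.
#'
#' @param config a [scene_config()].
#' @param seed integer RNG seed.
#' @return tibble `label`, `X`, `Y`, `Z`.
#' @export
sample_players <- function(config = scene_config(), seed = 1) {
  n <- config$n_players
  if (n == 0) {
    return(tibble(label = integer(), X = numeric(), Y = numeric(), Z = numeric()))
  }
  margin <- 0.5
  with_seed(seed, {
    if (config$min_separation <= 0) {
      return(tibble(label = seq_len(n),
                    X = runif(n, margin, config$court_x - margin),
                    Y = runif(n, margin, config$court_y - margin),
                    Z = runif(n, config$head_height_range[1],
                              config$head_height_range[2])))
    }
    pts <- matrix(NA_real_, n, 2)
    placed <- 0
    for (attempt in seq_len(200 * n)) {
      cand <- c(runif(1, margin, config$court_x - margin),
                runif(1, margin, config$court_y - margin))
      ok <- placed == 0 || config$min_separation <= 0 ||
        all(sqrt(rowSums(sweep(pts[seq_len(placed), , drop = FALSE], 2, cand)^2)) >=
              config$min_separation)
      if (ok) {
        placed <- placed + 1
        pts[placed, ] <- cand
        if (placed == n) break
      }
    }
    if (placed < n) {
      abort(paste0("could not place ", n, " players with min separation ",
                   config$min_separation, " m"),
            class = "hooploc_packing_error")
    }
    tibble(label = seq_len(n),
           X = pts[, 1], Y = pts[, 2],
           Z = runif(n, config$head_height_range[1], config$head_height_range[2]))
  })
}

#' Simulate noisy multi-camera head detections
#'
#' Emulates the output statistics of the per-camera detection stage: each
#' (player, camera) pair yields the exact projection plus isotropic Gaussian
#' pixel noise with probability `1 - miss_prob`; each camera additionally
#' receives `outliers_per_camera` spurious points uniform over the frame.
#' Provenance (which detection came from which player, or is an outlier) is
#' recorded for evaluation.
#'
#' @param truth tibble `label`, `X`, `Y`, `Z` of ground-truth head positions.
#' @param cameras camera tibble.
#' @param config a [scene_config()].
#' @param seed integer RNG seed.
#' @param frame_id frame index attached to the detections (0-based).
#' @return list with `detections` (tibble `frame_id`, `camera_id`, `x`, `y`,
#'   `score`) and `provenance` (tibble adding `source` = "player"/"outlier"
#'   and the originating `label`, NA for outliers).
#' @export
simulate_detections <- function(truth, cameras, config = scene_config(),
                                seed = 1, frame_id = 0L) {
  with_seed(seed, {
    det <- list()
    prov <- list()
    if (nrow(truth) > 0) {
      proj <- dlt_project(truth[, c("X", "Y", "Z")], cameras)
      keep <- runif(nrow(proj)) >= config$miss_prob
      proj <- proj[keep, , drop = FALSE]
      if (nrow(proj) > 0) {
        det[[1]] <- tibble(frame_id = frame_id,
                           camera_id = proj$camera_id,
                           x = proj$x + rnorm(nrow(proj), 0, config$noise_sigma_px),
                           y = proj$y + rnorm(nrow(proj), 0, config$noise_sigma_px),
                           score = NA_real_)
        prov[[1]] <- tibble(source = "player", label = truth$label[proj$point_id])
      }
    }
    if (config$outliers_per_camera > 0) {
      out <- tidyr::expand_grid(camera_id = cameras$camera_id,
                                i = seq_len(config$outliers_per_camera))
      det[[length(det) + 1]] <- tibble(frame_id = frame_id,
                                       camera_id = out$camera_id,
                                       x = runif(nrow(out), 0, config$image_width),
                                       y = runif(nrow(out), 0, config$image_height),
                                       score = NA_real_)
      prov[[length(prov) + 1]] <- tibble(source = rep("outlier", nrow(out)),
                                         label = rep(NA_integer_, nrow(out)))
    }
    detections <- if (length(det)) dplyr::bind_rows(det) else {
      tibble(frame_id = integer(), camera_id = integer(),
             x = numeric(), y = numeric(), score = numeric())
    }
    provenance <- if (length(prov)) dplyr::bind_rows(prov) else {
      tibble(source = character(), label = integer())
    }
    detections$det_id <- seq_len(nrow(detections)) - 1L
    list(detections = detections,
         provenance = dplyr::bind_cols(detections["det_id"], provenance))
  })
}

#' Simulate a complete scene (rig + players + detections)
#'
#' @inheritParams simulate_detections
#' @param config a [scene_config()].
#' @param seed integer RNG seed driving rig jitter, player placement and
#'   detection noise (three decoupled sub-seeds are derived from it).
#' @return a `synthetic_scene` list: `cameras`, `truth`, `detections`,
#'   `provenance`, `config`.
#' @export
simulate_scene <- function(config = scene_config(), seed = 1, frame_id = 0L) {
  seed <- as.integer(seed)
  cameras <- make_camera_rig(config, seed = seed)
  truth <- sample_players(config, seed = seed + 1L)
  sim <- simulate_detections(truth, cameras, config, seed = seed + 2L,
                             frame_id = frame_id)
  structure(list(cameras = cameras, truth = truth,
                 detections = sim$detections, provenance = sim$provenance,
                 config = config),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("synthetic scene:", nrow(x$truth), "players,",
      nrow(x$cameras), "cameras,", nrow(x$detections), "detections\n")
  invisible(x)
}

# --- renderer ---------------------------------------------------------------

# seeded smooth background texture in [lo, hi]
.background_texture <- function(width, height, seed, lo = 0.35, hi = 0.55) {
  with_seed(seed, {
    coarse <- matrix(runif(ceiling(width / 16) * ceiling(height / 16)),
                     ncol = ceiling(height / 16))
    img <- EBImage::resize(EBImage::Image(coarse), w = width, h = height)
    m <- EBImage::imageData(img)
    lo + (hi - lo) * (m - min(m)) / max(max(m) - min(m), 1e-12)
  })
}

# fill an ellipse into image matrix mat (indexed [x, y]); returns indices set
.fill_ellipse <- function(dim_xy, cx, cy, a, b, theta = 0) {
  x0 <- max(1, floor(cx - a - b)); x1 <- min(dim_xy[1], ceiling(cx + a + b))
  y0 <- max(1, floor(cy - a - b)); y1 <- min(dim_xy[2], ceiling(cy + a + b))
  if (x0 > x1 || y0 > y1) return(matrix(numeric(0), 0, 2))
  gx <- x0:x1; gy <- y0:y1
  dx <- outer(gx - cx, rep(1, length(gy)))
  dy <- outer(rep(1, length(gx)), gy - cy)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  sel <- which((u / a)^2 + (v / b)^2 <= 1, arr.ind = TRUE)
  if (nrow(sel) == 0) return(matrix(numeric(0), 0, 2))
  cbind(gx[sel[, 1]], gy[sel[, 2]])
}

# apparent pixel radius of a world sphere of radius r_w at head position P
.pixel_radius <- function(lam, P, r_w) {
  uv0 <- .dlt_project(lam, matrix(P, 1))
  offs <- rbind(P + c(r_w, 0, 0), P + c(-r_w, 0, 0),
                P + c(0, r_w, 0), P + c(0, -r_w, 0))
  uv <- .dlt_project(lam, offs)
  mean(sqrt((uv[, 1] - uv0[1, 1])^2 + (uv[, 2] - uv0[1, 2])^2))
}

#' Render synthetic image sequences with ground truth
#'
#' Produces, per camera, a grayscale image sequence over a static textured
#' background. Each player is drawn as a dark body ellipse from the feet up
#' to the head plus a bright circular head whose centre is the exact DLT
#' projection of the head point and whose radius is projection-consistent
#' with a sphere of the configured head radius. Optional soft floor shadows
#' darken the background without entering the ground-truth mask. Per frame
#' and camera the true foreground mask, shadow mask and head centres/radii
#' are emitted, so segmentation and detection can be scored exactly.
#'
#' @param trajectory tibble `frame_id`, `label`, `X`, `Y`, `Z` (head points).
#' @param cameras camera tibble (its nominal frame size comes from `config`).
#' @param config a [scene_config()]; `image_width`/`image_height` set the
#'   rendered resolution and `shadows` toggles shadow rendering.
#' @param seed integer; fixes the background texture. Identical seeds give
#'   identical pixel output.
#' @return list with `frames` (list over cameras of lists over frames of
#'   `width x height` matrices in `[0, 1]`), `masks` (same shape, logical
#'   player-pixel masks), `shadow_masks`, and `heads` (tibble `frame_id`,
#'   `camera_id`, `label`, `x`, `y`, `radius_px`).
#' @export
render_frames <- function(trajectory, cameras, config = scene_config(),
                          seed = 1) {
  wpx <- config$image_width; hpx <- config$image_height
  frame_ids <- sort(unique(trajectory$frame_id))
  if (length(frame_ids) == 0) frame_ids <- integer(0)
  out_frames <- list(); out_masks <- list(); out_shadows <- list()
  heads <- list()
  for (ci in seq_len(nrow(cameras))) {
    cam_id <- cameras$camera_id[ci]
    lam <- as.numeric(cameras[ci, LAMBDA_COLS])
    bg <- .background_texture(wpx, hpx, seed = seed * 1000L + ci)
    seq_frames <- list(); seq_masks <- list(); seq_shadows <- list()
    for (fi in seq_along(frame_ids)) {
      fid <- frame_ids[fi]
      img <- bg
      mask <- matrix(FALSE, wpx, hpx)
      shmask <- matrix(FALSE, wpx, hpx)
      players <- trajectory[trajectory$frame_id == fid, , drop = FALSE]
      if (nrow(players) > 0) {
        # shadows first so bodies draw over them
        if (isTRUE(config$shadows)) {
          for (pi in seq_len(nrow(players))) {
            P <- as.numeric(players[pi, c("X", "Y", "Z")])
            sh_c <- .dlt_project(lam, matrix(c(P[1] + 0.45, P[2] + 0.45, 0), 1))
            r_sh <- .pixel_radius(lam, c(P[1], P[2], 0), 0.5)
            idx <- .fill_ellipse(c(wpx, hpx), sh_c[1, 1], sh_c[1, 2],
                                 1.4 * r_sh, 0.8 * r_sh)
            if (nrow(idx)) {
              img[idx] <- img[idx] * 0.5
              shmask[idx] <- TRUE
            }
          }
        }
        for (pi in seq_len(nrow(players))) {
          P <- as.numeric(players[pi, c("X", "Y", "Z")])
          head_uv <- .dlt_project(lam, matrix(P, 1))
          r_px <- .pixel_radius(lam, P, config$head_radius)
          feet_uv <- .dlt_project(lam, matrix(c(P[1], P[2], 0), 1))
          # body ellipse between just below the head and the feet
          bx <- (head_uv[1, 1] + feet_uv[1, 1]) / 2
          by <- (head_uv[1, 2] + feet_uv[1, 2]) / 2
          half_len <- sqrt((head_uv[1, 1] - feet_uv[1, 1])^2 +
                           (head_uv[1, 2] - feet_uv[1, 2])^2) / 2
          theta <- atan2(head_uv[1, 2] - feet_uv[1, 2],
                         head_uv[1, 1] - feet_uv[1, 1])
          half_wid <- max(1.6 * r_px, 2)
          bidx <- .fill_ellipse(c(wpx, hpx), bx, by,
                                max(half_len, 2), half_wid, theta)
          if (nrow(bidx)) {
            img[bidx] <- 0.14 + 0.04 * ((bidx[, 1] + bidx[, 2]) %% 3) / 2
            mask[bidx] <- TRUE
            shmask[bidx] <- FALSE
          }
          hidx <- .fill_ellipse(c(wpx, hpx), head_uv[1, 1], head_uv[1, 2],
                                r_px, r_px)
          if (nrow(hidx)) {
            dd <- sqrt((hidx[, 1] - head_uv[1, 1])^2 +
                       (hidx[, 2] - head_uv[1, 2])^2) / max(r_px, 1)
            img[hidx] <- 0.88 - 0.25 * dd  # shaded bright head disk
            mask[hidx] <- TRUE
            shmask[hidx] <- FALSE
          }
          heads[[length(heads) + 1]] <-
            tibble(frame_id = fid, camera_id = cam_id,
                   label = players$label[pi],
                   x = unname(head_uv[1, 1]), y = unname(head_uv[1, 2]),
                   radius_px = unname(r_px))
        }
      }
      seq_frames[[fi]] <- img
      seq_masks[[fi]] <- mask
      seq_shadows[[fi]] <- shmask
    }
    out_frames[[as.character(cam_id)]] <- seq_frames
    out_masks[[as.character(cam_id)]] <- seq_masks
    out_shadows[[as.character(cam_id)]] <- seq_shadows
  }
  list(frames = out_frames, masks = out_masks, shadow_masks = out_shadows,
       heads = if (length(heads)) dplyr::bind_rows(heads) else
         tibble(frame_id = integer(), camera_id = integer(),
                label = integer(), x = numeric(), y = numeric(),
                radius_px = numeric()))
}

#' Render labeled head / non-head training patches
#'
#' Generates square grayscale patches for classifier training. Positives are
#' a shaded head disk centred in the patch (small jitter) with a dark body
#' ellipse below it, over the same textured background the frame renderer
#' uses. Negatives mix plain background, heads displaced well off centre, a
#' bright elongated blob at an arbitrary angle (a raised arm), and an
#' unshaded free-floating disk with no body below it (a ball). A positive
#' label means "head centred in the patch": an off-centre head is a
#' negative, matching how the classifier is used downstream (candidates are
#' circle centres).
#'
#' @param n_pos,n_neg number of positive / negative patches.
#' @param window patch side in pixels.
#' @param radius_range head radius range in pixels.
#' @param seed RNG seed; output is fully reproducible.
#' @return list with `patches` (list of `window x window` matrices),
#'   `labels` (0/1 vector) and `meta` (tibble with the generator type of
#'   each patch).
#' @export
render_training_patches <- function(n_pos = 500, n_neg = 500, window = 64,
                                    radius_range = c(7, 13), seed = 1) {
  with_seed(seed, {
    mk_bg <- function() {
      coarse <- matrix(runif(36), 6, 6)
      m <- EBImage::imageData(EBImage::resize(EBImage::Image(coarse),
                                              w = window, h = window))
      0.35 + 0.2 * (m - min(m)) / max(max(m) - min(m), 1e-12)
    }
    draw_head <- function(img, cx, cy, r, shaded = TRUE) {
      idx <- .fill_ellipse(c(window, window), cx, cy, r, r)
      if (nrow(idx)) {
        if (shaded) {
          dd <- sqrt((idx[, 1] - cx)^2 + (idx[, 2] - cy)^2) / max(r, 1)
          img[idx] <- 0.88 - 0.25 * dd
        } else {
          img[idx] <- 0.85
        }
      }
      img
    }
    draw_body <- function(img, cx, cy, r) {
      # torso running from the shoulders down past the patch edge, as a
      # standing player renders in a frame
      idx <- .fill_ellipse(c(window, window), cx, cy + r + 4.2 * r,
                           1.7 * r, 4.5 * r)
      if (nrow(idx)) img[idx] <- 0.15 + 0.04 * ((idx[, 1] + idx[, 2]) %% 3) / 2
      img
    }
    patches <- vector("list", n_pos + n_neg)
    labels <- integer(n_pos + n_neg)
    types <- character(n_pos + n_neg)
    ctr <- (window + 1) / 2
    for (i in seq_len(n_pos)) {
      r <- runif(1, radius_range[1], radius_range[2])
      cx <- ctr + runif(1, -2, 2)
      cy <- ctr + runif(1, -2, 2)
      img <- draw_body(mk_bg(), cx, cy, r)
      patches[[i]] <- draw_head(img, cx, cy, r)
      labels[i] <- 1L
      types[i] <- "head"
    }
    neg_types <- rep_len(c("background", "offcenter", "arm", "ball", "torso"),
                         n_neg)
    for (j in seq_len(n_neg)) {
      i <- n_pos + j
      r <- runif(1, radius_range[1], radius_range[2])
      img <- mk_bg()
      img <- switch(neg_types[j],
        background = img,
        offcenter = {
          ang <- runif(1, 0, 2 * pi)
          d <- runif(1, 12, 24)
          cx <- ctr + d * cos(ang); cy <- ctr + d * sin(ang)
          draw_head(draw_body(img, cx, cy, r), cx, cy, r)
        },
        arm = {
          th <- runif(1, 0, pi)
          idx <- .fill_ellipse(c(window, window),
                               ctr + runif(1, -3, 3), ctr + runif(1, -3, 3),
                               3.2 * r, 0.8 * r, th)
          if (nrow(idx)) img[idx] <- 0.8 + 0.05 * runif(nrow(idx))
          img
        },
        ball = draw_head(img, ctr + runif(1, -2, 2), ctr + runif(1, -2, 2),
                         r * runif(1, 0.8, 1.2), shaded = FALSE),
        torso = {
          # patch centred on the shoulders/chest: head visible above centre
          cx <- ctr + runif(1, -3, 3)
          cy <- ctr - runif(1, 2.2, 4.2) * r
          draw_head(draw_body(img, cx, cy, r), cx, cy, r)
        })
      patches[[i]] <- img
      labels[i] <- 0L
      types[i] <- neg_types[j]
    }
    ord <- sample.int(n_pos + n_neg)
    list(patches = patches[ord], labels = labels[ord],
         meta = tibble(type = types[ord], label = labels[ord]))
  })
}
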