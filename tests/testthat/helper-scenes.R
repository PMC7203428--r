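# shared fixtures, built in code

# affine test cameras: cam A maps (X,Y,Z) -> (X,Y); cam B -> (X,Z)
affine_camera_xy <- function(id = 0L) {
  lam <- numeric(11); lam[1] <- 1; lam[5] <- 1
  new_camera(id, lam)
}
affine_camera_xz <- function(id = 1L) {
  lam <- numeric(11); lam[1] <- 1; lam[8] <- 1
  new_camera(id, lam)
}

# non-coplanar calibration points spanning the court volume
calibration_points <- function(n = 6, seed = 42) {
  base <- expand.grid(X = c(1, 13), Y = c(1, 14), Z = c(0, 3))
  if (n <= nrow(base)) return(base[seq_len(n), ])
  extra <- with_seed_test(seed, data.frame(X = runif(n - nrow(base), 0, 14),
                                           Y = runif(n - nrow(base), 0, 15),
                                           Z = runif(n - nrow(base), 0, 3)))
  rbind(base, extra)
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# correspondences for one camera from exact projections
exact_correspondences <- function(camera, points) {
  pj <- dlt_project(points, camera)
  data.frame(camera_id = camera$camera_id[1], points, x = pj$x, y = pj$y)
}

# independent exhaustive scan for the best single-player subset, written
# against the public triangulate()/reprojection_error() API only
oracle_best_subset <- function(detections, cameras, config = loc_config()) {
  m <- nrow(detections)
  best <- NULL
  for (sz in 2:min(nrow(cameras), m)) {
    for (ss in utils::combn(m, sz, simplify = FALSE)) {
      if (anyDuplicated(detections$camera_id[ss])) next
      tri <- tryCatch(triangulate(detections[ss, ], cameras),
                      error = function(e) NULL)
      if (is.null(tri)) next
      e2 <- tri$errors$error_px^2
      if (any(e2 > config$tau_px^2)) next
      if (tri$point$Z < config$h_min || tri$point$Z > config$h_max) next
      sc <- sum(e2) / sz^2 - sz
      if (is.null(best) || sc < best$score - 1e-12 ||
          (abs(sc - best$score) <= 1e-12 && sz > length(best$subset))) {
        best <- list(subset = ss, score = sc, point = tri$point)
      }
    }
  }
  best
}

# expensive rendered-scene fixture (frames + classifier), built once per run
.fixture_env <- new.env(parent = emptyenv())

detection_fixture <- function() {
  if (!is.null(.fixture_env$det)) return(.fixture_env$det)
  cfg <- scene_config(n_players = 2, image_width = 519, image_height = 388,
                      focal_scale = 4, min_separation = 2)
  rig <- make_camera_rig(cfg, seed = 5)
  tr <- tibble::tibble(label = 1:2, X = c(6, 8.5), Y = c(7, 8.2),
                       Z = c(1.75, 1.9))
  traj <- dplyr::bind_rows(lapply(0:29, function(f)
    dplyr::bind_cols(tibble::tibble(frame_id = f),
                     dplyr::mutate(tr, X = X + 0.13 * f * c(1, -1),
                                   Y = Y + 0.06 * f * c(-1, 1)))))
  rend <- render_frames(traj, rig, cfg, seed = 3)
  tp <- render_training_patches(400, 400, radius_range = c(5, 10), seed = 7)
  feats <- t(vapply(tp$patches, compute_hog, numeric(1764)))
  clf <- train_head_classifier(feats, tp$labels,
                               classifier_spec(seed = 11, max_epochs = 80))
  .fixture_env$det <- list(cfg = cfg, rig = rig, rend = rend, clf = clf,
                           patches = tp, features = feats,
                           hough = hough_config(r_min = 4, r_max = 14,
                                                min_area = 40,
                                                vote_frac = 0.5),
                           bg = bg_config(history = 12))
  .fixture_env$det
}
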