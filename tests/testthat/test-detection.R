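# small synthetic streams built directly in code (no renderer) -------------

textured_bg <- function(w = 80, h = 60, seed = 1) {
  with_seed_test(seed, matrix(runif(w * h, 0.35, 0.55), w, h))
}

# bright disk translating over a static textured background
mover_stream <- function(n_frames, bg, r = 6, v = 3, y0 = 30, shadow = FALSE) {
  lapply(seq_len(n_frames), function(t) {
    img <- bg
    cx <- 8 + v * t
    for (dx in -r:r) for (dy in -r:r) {
      if (dx^2 + dy^2 <= r^2) {
        px <- cx + dx; py <- y0 + dy
        if (px >= 1 && px <= nrow(img) && py >= 1 && py <= ncol(img))
          img[px, py] <- 0.95
      }
    }
    if (shadow) {
      for (dx in -r:r) for (dy in -r:r) {
        if (dx^2 + dy^2 <= r^2) {
          px <- cx + dx + 2 * r; py <- y0 + dy
          if (px >= 1 && px <= nrow(img) && py >= 1 && py <= ncol(img))
            img[px, py] <- bg[px, py] * 0.5
        }
      }
    }
    img
  })
}

mover_mask <- function(t, dimxy, r = 6, v = 3, y0 = 30) {
  m <- matrix(FALSE, dimxy[1], dimxy[2])
  cx <- 8 + v * t
  for (dx in -r:r) for (dy in -r:r) {
    if (dx^2 + dy^2 <= r^2) {
      px <- cx + dx; py <- y0 + dy
      if (px >= 1 && px <= dimxy[1] && py >= 1 && py <= dimxy[2])
        m[px, py] <- TRUE
    }
  }
  m
}

test_that("a static scene yields an empty mask after burn-in", {
  bg <- textured_bg()
  frames <- rep(list(bg), 15)
  seg <- segment_foreground(frames, bg_config(history = 10))
  expect_length(seg$masks, 5)
  expect_true(all(vapply(seg$masks, sum, numeric(1)) == 0))
})

test_that("a translating bright disk is segmented almost completely", {
  bg <- textured_bg()
  frames <- mover_stream(16, bg)
  # adaptation slower than burn-in so a slow mover is not absorbed
  seg <- segment_foreground(frames, bg_config(history = 8,
                                              learning_rate = 0.02))
  cov <- fp <- numeric(0)
  for (i in seq_along(seg$masks)) {
    gt <- mover_mask(seg$frame_ids[i], dim(bg))
    mk <- seg$masks[[i]]
    cov <- c(cov, sum(mk & gt) / sum(gt))
    fp <- c(fp, sum(mk & !gt) / sum(!gt))
  }
  expect_gte(mean(cov), 0.90)
  expect_lte(mean(fp), 0.01)
})

test_that("a rendered half-luminance shadow is relabeled background", {
  bg <- textured_bg(seed = 2)
  frames <- mover_stream(16, bg, shadow = TRUE)
  seg <- segment_foreground(frames, bg_config(history = 8))
  for (i in seq_along(seg$masks)) {
    t <- seg$frame_ids[i]
    disk <- mover_mask(t, dim(bg))
    shadow <- mover_mask(t, dim(bg)) * 0
    sh <- mover_mask(t, dim(bg), r = 6, v = 3, y0 = 30)
    # shadow region = disk shifted right by 2r
    shadow_mask <- matrix(FALSE, nrow(bg), ncol(bg))
    shifted <- which(sh, arr.ind = TRUE)
    shifted[, 1] <- shifted[, 1] + 12
    shifted <- shifted[shifted[, 1] <= nrow(bg), , drop = FALSE]
    shadow_mask[shifted] <- TRUE
    shadow_mask <- shadow_mask & !disk
    if (sum(shadow_mask) > 0) {
      expect_lte(sum(seg$masks[[i]] & shadow_mask) / sum(shadow_mask), 0.05)
    }
  }
})

test_that("a too-short stream raises an insufficient-history error", {
  frames <- rep(list(textured_bg()), 5)
  expect_error(segment_foreground(frames, bg_config(history = 10)),
               class = "hooploc_insufficient_history")
})

test_that("morphological opening removes specks, keeps blobs, equals its composition", {
  speck <- matrix(FALSE, 40, 40)
  speck[cbind(c(5, 17, 33), c(8, 22, 35))] <- TRUE
  expect_equal(sum(clean_mask(speck, 3)), 0)

  disk <- mover_mask(4, c(60, 60), r = 12, v = 3, y0 = 30)
  opened <- clean_mask(disk, 3)
  expect_gte(sum(opened & disk) / sum(disk), 0.85)
  expect_equal(sum(opened & !disk), 0)

  kern <- EBImage::makeBrush(3, shape = "disc")
  with_seed_test(6, {
    for (i in 1:20) {
      m <- matrix(runif(900) > 0.6, 30, 30)
      ours <- clean_mask(m, 3)
      ref <- EBImage::imageData(
        EBImage::dilate(EBImage::erode(EBImage::Image(m * 1), kern),
                        kern)) > 0.5
      expect_identical(ours, ref)
    }
  })
})

test_that("the circle search finds a single rendered head exactly once on a clean mask", {
  cfg <- scene_config(n_players = 1, image_width = 519, image_height = 388,
                      focal_scale = 4)
  rig <- make_camera_rig(cfg, seed = 5)[1, ]
  traj <- tibble::tibble(frame_id = 0L, label = 1L, X = 7, Y = 7.5, Z = 1.8)
  rend <- render_frames(traj, rig, cfg, seed = 6)
  mask <- rend$masks[[1]][[1]]        # exact player silhouette
  cand <- extract_head_candidates(mask, rend$frames[[1]][[1]], NULL,
                                  hough_config(r_min = 4, r_max = 14,
                                               min_area = 40,
                                               vote_frac = 0.6))
  gt <- rend$heads
  expect_equal(nrow(cand), 1)
  expect_lt(sqrt((cand$x - gt$x)^2 + (cand$y - gt$y)^2), 2)
  expect_lt(abs(cand$radius_px - gt$radius_px), 2)
})

test_that("circle fitting on segmented masks localizes each head within 2 px", {
  fx <- detection_fixture()
  cam <- fx$rig$camera_id[1]
  frames <- fx$rend$frames[[as.character(cam)]]
  seg <- segment_foreground(frames, fx$bg)
  fid <- seg$frame_ids[6]
  mask <- clean_mask(seg$masks[[6]], 3)
  cand <- extract_head_candidates(mask, frames[[fid]], NULL, fx$hough)
  gt <- fx$rend$heads[fx$rend$heads$frame_id == fid - 1 &
                      fx$rend$heads$camera_id == cam, ]
  for (i in seq_len(nrow(gt))) {
    d <- sqrt((cand$x - gt$x[i])^2 + (cand$y - gt$y[i])^2)
    j <- which.min(d)
    expect_lt(d[j], 2)
    expect_lt(abs(cand$radius_px[j] - gt$radius_px[i]), 2)
  }
})

test_that("two touching players still yield one candidate per head", {
  cfg <- scene_config(n_players = 2, image_width = 519, image_height = 388,
                      focal_scale = 4)
  rig <- make_camera_rig(cfg, seed = 5)[1, ]
  # heads 0.55 m apart: bodies merge into a single blob
  traj <- dplyr::bind_rows(lapply(0:15, function(f)
    tibble::tibble(frame_id = f, label = 1:2,
                   X = c(6.9, 7.45) + 0.1 * f, Y = c(7.5, 7.5),
                   Z = c(1.75, 1.92))))
  rend <- render_frames(traj, rig, cfg, seed = 6)
  seg <- segment_foreground(rend$frames[[1]], bg_config(history = 10))
  found <- 0
  for (i in seq_along(seg$masks)) {
    fid <- seg$frame_ids[i]
    mask <- clean_mask(seg$masks[[i]], 3)
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    cand <- extract_head_candidates(mask, rend$frames[[1]][[fid]], NULL,
                                    hough_config(r_min = 4, r_max = 14,
                                                 min_area = 40,
                                                 vote_frac = 0.5))
    gt <- rend$heads[rend$heads$frame_id == fid - 1, ]
    hit <- vapply(seq_len(nrow(gt)), function(g)
      any(sqrt((cand$x - gt$x[g])^2 + (cand$y - gt$y[g])^2) < 5), logical(1))
    if (all(hit)) found <- found + 1
  }
  expect_gte(found / length(seg$masks), 0.8)
})

test_that("candidates outside the interest area are discarded", {
  fx <- detection_fixture()
  cam <- fx$rig$camera_id[1]
  frames <- fx$rend$frames[[as.character(cam)]]
  seg <- segment_foreground(frames, fx$bg)
  fid <- seg$frame_ids[4]
  mask <- clean_mask(seg$masks[[4]], 3)
  all_cand <- extract_head_candidates(mask, frames[[fid]], NULL, fx$hough)
  expect_gt(nrow(all_cand), 0)
  # a polygon excluding every candidate
  far <- data.frame(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  expect_equal(nrow(extract_head_candidates(mask, frames[[fid]], far,
                                            fx$hough)), 0)
  # a polygon containing them all
  whole <- data.frame(x = c(0, 519, 519, 0), y = c(0, 0, 388, 388))
  inside <- extract_head_candidates(mask, frames[[fid]], whole, fx$hough)
  expect_equal(nrow(inside), nrow(all_cand))
})

test_that("HOG length follows the closed-form block count", {
  expect_equal(hog_length(hog_config()), 1764L)
  expect_equal(hog_length(hog_config(window = 32)), 324L)
  expect_equal(hog_length(hog_config(window = 48)), 900L)
  for (cfg in list(hog_config(), hog_config(window = 32),
                   hog_config(window = 48, cell = 16))) {
    ncell <- cfg$window / cfg$cell
    expected <- (ncell - cfg$block + 1)^2 * cfg$block^2 * cfg$bins
    expect_equal(hog_length(cfg), as.integer(expected))
    p <- with_seed_test(7, matrix(runif(cfg$window^2), cfg$window))
    expect_length(compute_hog(p, cfg), expected)
  }
})

test_that("HOG of a constant patch is identically zero, and entries are non-negative", {
  expect_equal(sum(abs(compute_hog(matrix(0.7, 64, 64)))), 0)
  p <- with_seed_test(8, matrix(runif(64 * 64), 64))
  h <- compute_hog(p)
  expect_true(all(h >= 0))
  expect_true(all(h <= 1))  # each block is L2-normalized after clipping
})

test_that("the MLP separates linearly separable clusters and matches an independent learner", {
  with_seed_test(9, {
    n <- 500
    X <- rbind(matrix(rnorm(n * 20, -1, 0.3), n),
               matrix(rnorm(n * 20, 1, 0.3), n))
    y <- rep(c(0, 1), each = n)
    clf <- train_head_classifier(X, y, classifier_spec(seed = 2,
                                                       max_epochs = 50))
    acc <- clf$metrics$accuracy[clf$metrics$subset == "test"]
    expect_gte(acc, 0.99)
    # independent cross-check: nnet on the same data
    idx <- sample.int(2 * n, 700)
    fit <- nnet::nnet(X[idx, ], y[idx], size = 3, maxit = 100,
                      trace = FALSE)
    pred <- as.integer(predict(fit, X[-idx, ]) >= 0.5)
    expect_gte(mean(pred == y[-idx]), 0.99)
  })
})

test_that("training refuses single-class input", {
  X <- matrix(rnorm(100), 10)
  expect_error(train_head_classifier(X, rep(1, 10)),
               class = "hooploc_degenerate_training")
})

test_that("the classifier reaches high accuracy on rendered patches", {
  fx <- detection_fixture()
  acc <- fx$clf$metrics$accuracy[fx$clf$metrics$subset == "test"]
  expect_gte(acc, 0.95)
})

test_that("classification keeps confident heads and rejects arm blobs", {
  fx <- detection_fixture()
  tp <- fx$patches
  feats <- fx$features
  probs <- predict(fx$clf, feats)
  arm <- tp$meta$type == "arm"
  head <- tp$meta$type == "head"
  expect_lt(mean(probs[arm]), 0.2)   # elongated raised-arm blobs rejected
  expect_gt(mean(probs[head]), 0.8)

  cand <- tibble::tibble(x = 100, y = 100, radius_px = 6,
                         seed_x = 100, seed_y = 98, support = 0.8)
  frame <- fx$rend$frames[[1]][[5]]
  kept <- classify_candidates(cand, frame, fx$clf, threshold = 1.0)
  expect_equal(nrow(kept), 0)  # threshold 1 rejects any finite probability
})

test_that("end-to-end detection meets the synthetic rate targets", {
  fx <- detection_fixture()
  stats <- c(true = 0, fp = 0, miss = 0)
  dists <- numeric(0)
  for (ci in seq_len(nrow(fx$rig))) {
    cam <- fx$rig$camera_id[ci]
    det <- detect_heads(fx$rend$frames[[as.character(cam)]], camera_id = cam,
                        classifier = fx$clf, bg = fx$bg, hough = fx$hough)
    for (f in unique(det$frame_id)) {
      gt <- fx$rend$heads[fx$rend$heads$frame_id == f - 1 &
                          fx$rend$heads$camera_id == cam, ]
      mr <- match_detections(det[det$frame_id == f, ], gt, 25)
      stats <- stats + c(mr$true, mr$false_positive, mr$misdetection)
      dists <- c(dists, mr$pairs$dist_px)
    }
  }
  rates <- 100 * stats / sum(stats)
  expect_gte(rates[["true"]], 90)
  expect_lte(rates[["fp"]], 5)
  expect_lte(sqrt(mean(dists^2)), 3)  # detection pixel RMSE
})
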