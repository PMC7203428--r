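# builds a one-frame detection table from noise-free projections plus
# optional extra points
scene_detections <- function(truth, rig, extra = NULL) {
  pj <- dlt_project(truth[, c("X", "Y", "Z")], rig)
  det <- data.frame(frame_id = 0L, camera_id = pj$camera_id,
                    x = pj$x, y = pj$y, score = NA_real_)
  if (!is.null(extra)) det <- rbind(det, extra)
  det
}

test_that("feasible subsets follow the per-camera counts", {
  # camera counts (2, 1, 1): pairs 2+2+1, triples 2 -> 7 subsets
  rig <- make_camera_rig(scene_config(), seed = 1)
  det <- data.frame(camera_id = c(0L, 0L, 1L, 2L),
                    x = c(100, 200, 150, 160), y = c(100, 120, 110, 130))
  ss <- enumerate_feasible_subsets(det, rig)
  expect_length(ss, 7)
  expect_true(all(lengths(ss) >= 2 & lengths(ss) <= 3))
  expect_true(all(vapply(ss, function(s)
    !anyDuplicated(det$camera_id[s]), logical(1))))

  expect_length(enumerate_feasible_subsets(det[1, ], rig), 0)
  expect_length(enumerate_feasible_subsets(det[1:2, ], rig), 0)  # one camera
  expect_length(enumerate_feasible_subsets(det[3:4, ], rig), 1)
})

test_that("zero-error subsets score -q, and the score identity holds under noise", {
  rig <- make_camera_rig(scene_config(), seed = 2)
  truth <- data.frame(X = 7, Y = 7.5, Z = 1.8)
  det <- scene_detections(truth, rig)
  s2 <- score_subset(c(1L, 2L), det, rig)
  s3 <- score_subset(c(1L, 2L, 3L), det, rig)
  expect_equal(s2$score, -2, tolerance = 1e-9)
  expect_equal(s3$score, -3, tolerance = 1e-9)
  expect_lt(s3$score, s2$score)  # more consistent views beat fewer

  # score == sum(e_p)/q^2 - q for noisy subsets (checked against returned e2)
  with_seed_test(5, {
    for (i in 1:25) {
      nd <- det
      nd$x <- nd$x + rnorm(3, 0, 3)
      nd$y <- nd$y + rnorm(3, 0, 3)
      sc <- score_subset(c(1L, 2L, 3L), nd, rig)
      if (!sc$feasible) next
      expect_equal(sc$score, sum(sc$e2) / 9 - 3, tolerance = 1e-12)
    }
  })
})

test_that("subsets violating the pixel tolerance or height band are infeasible", {
  rig <- make_camera_rig(scene_config(), seed = 2)
  det <- scene_detections(data.frame(X = 7, Y = 7.5, Z = 1.8), rig)
  bad <- det
  bad$x[1] <- bad$x[1] + 120  # far outside tau = 25 px
  sc <- score_subset(c(1L, 2L, 3L), bad, rig)
  expect_false(sc$feasible)

  high <- scene_detections(data.frame(X = 7, Y = 7.5, Z = 4.5), rig)
  sc2 <- score_subset(c(1L, 2L, 3L), high, rig)
  expect_false(sc2$feasible)  # Z above h_max even though geometry is exact
})

test_that("solve_round picks the true player over an outlier and matches the oracle scan", {
  rig <- make_camera_rig(scene_config(), seed = 3)
  truth <- data.frame(X = 3, Y = 4, Z = 1.8)
  det <- scene_detections(truth, rig)
  out_pt <- data.frame(frame_id = 0L, camera_id = 0L,
                       x = det$x[1] + 200, y = det$y[1], score = NA_real_)
  det <- rbind(det, out_pt)
  round <- solve_round(det, rig)
  expect_equal(round$subset, 1:3)
  expect_equal(round$score, -3, tolerance = 1e-9)
  expect_lt(max(abs(round$point - c(3, 4, 1.8))), 1e-6)

  # independent exhaustive scan agrees on noisy instances
  with_seed_test(9, {
    for (i in 1:10) {
      cfg <- scene_config(n_players = 2, noise_sigma_px = 2,
                          outliers_per_camera = 1, min_separation = 2)
      sc <- simulate_scene(cfg, seed = 100 + i)
      r <- solve_round(sc$detections, sc$cameras)
      o <- oracle_best_subset(sc$detections, sc$cameras)
      if (is.null(o)) {
        expect_null(r)
      } else {
        expect_equal(r$score, o$score, tolerance = 1e-9)
      }
    }
  })

  expect_null(solve_round(det[integer(), ], rig))
  two_one_cam <- data.frame(camera_id = c(0L, 0L), x = c(10, 20),
                            y = c(10, 20))
  expect_null(solve_round(two_one_cam, rig))
})

test_that("greedy rounds localize all players then fall back on leftovers", {
  rig <- make_camera_rig(scene_config(), seed = 4)
  truth <- data.frame(X = c(3, 10), Y = c(4, 11), Z = c(1.7, 1.95))
  res <- localize_frame(scene_detections(truth, rig), rig)
  opt <- res$localizations[res$localizations$method == "optimized", ]
  expect_equal(nrow(opt), 2)
  expect_equal(sum(res$localizations$method == "fallback"), 0)
  err <- vapply(seq_len(2), function(i)
    min(sqrt((opt$X - truth$X[i])^2 + (opt$Y - truth$Y[i])^2 +
             (opt$Z - truth$Z[i])^2)), numeric(1))
  expect_lt(max(err), 1e-6)

  # a player seen by one camera only is localized by the height prior
  pj <- dlt_project(data.frame(X = 7, Y = 7, Z = 1.9), rig[1, ])
  single <- data.frame(frame_id = 0L, camera_id = pj$camera_id,
                       x = pj$x, y = pj$y, score = NA_real_)
  res1 <- localize_frame(single, rig, loc_config(mean_height = 1.85))
  expect_equal(res1$localizations$method, "fallback")
  expect_equal(res1$localizations$Z, 1.85)
})

test_that("three optimized players plus three single-camera fallbacks", {
  rig <- make_camera_rig(scene_config(), seed = 6)
  truth <- data.frame(X = c(3, 7, 11), Y = c(3, 8, 12), Z = c(1.7, 1.8, 1.9))
  extra_pj <- dlt_project(data.frame(X = c(2, 7, 12), Y = c(12, 2, 6),
                                     Z = c(1.8, 1.8, 1.8)), rig[1, ])
  extra <- data.frame(frame_id = 0L, camera_id = extra_pj$camera_id,
                      x = extra_pj$x, y = extra_pj$y, score = NA_real_)
  res <- localize_frame(scene_detections(truth, rig, extra), rig)
  expect_equal(sum(res$localizations$method == "optimized"), 3)
  expect_equal(sum(res$localizations$method == "fallback"), 3)
})

test_that("every output satisfies the assignment constraints", {
  with_seed_test(13, {
    for (i in 1:12) {
      cfg <- scene_config(n_players = sample(2:4, 1), noise_sigma_px = 1.5,
                          miss_prob = 0.15, outliers_per_camera = 2,
                          min_separation = 2)
      sc <- simulate_scene(cfg, seed = 500 + i)
      config <- loc_config()
      res <- localize_frame(sc$detections, sc$cameras, config)
      A <- res$assignment
      if (ncol(A) > 0) {
        expect_true(all(rowSums(A) <= 1))                   # one player per point
        expect_true(all(colSums(A) >= 2))                   # >= 2 views
        expect_true(all(colSums(A) <= nrow(sc$cameras)))    # <= w views
        for (l in seq_len(ncol(A))) {                       # one point per camera
          cams <- sc$detections$camera_id[A[, l] == 1]
          expect_false(anyDuplicated(cams) > 0)
        }
      }
      e2 <- res$assigned$e2_px
      opt_rows <- !is.na(res$assigned$assigned_label) &
        res$assigned$assigned_label <= ncol(A)
      expect_true(all(e2[opt_rows] <= config$tau_px^2 + 1e-9))
      opt <- res$localizations[res$localizations$method == "optimized", ]
      expect_true(all(opt$Z >= config$h_min & opt$Z <= config$h_max))
    }
  })
})

test_that("tightening the pixel tolerance never adds optimized players", {
  cfg <- scene_config(n_players = 3, noise_sigma_px = 3,
                      outliers_per_camera = 2, min_separation = 2)
  sc <- simulate_scene(cfg, seed = 77)
  n_opt <- vapply(c(25, 10, 5, 2, 1), function(tau) {
    res <- localize_frame(sc$detections, sc$cameras, loc_config(tau_px = tau))
    sum(res$localizations$method == "optimized")
  }, numeric(1))
  expect_true(all(diff(n_opt) <= 0))
})

test_that("the joint brute force dominates the greedy total and agrees noise-free", {
  cfg <- scene_config(n_players = 2, min_separation = 2)
  sc <- simulate_scene(cfg, seed = 21)
  bf <- brute_force_assign(sc$detections, sc$cameras)
  gr <- localize_frame(sc$detections, sc$cameras)
  # same partition of points into players (label order may differ)
  subsets_of <- function(A) {
    s <- lapply(seq_len(ncol(A)), function(l) which(A[, l] == 1))
    s[order(vapply(s, min, numeric(1)))]
  }
  expect_equal(subsets_of(bf$assignment), subsets_of(gr$assignment))

  with_seed_test(31, {
    for (i in 1:8) {
      cfgn <- scene_config(n_players = 3, noise_sigma_px = 2,
                           outliers_per_camera = 1, min_separation = 2)
      scn <- simulate_scene(cfgn, seed = 900 + i)
      bfn <- brute_force_assign(scn$detections, scn$cameras)
      grn <- localize_frame(scn$detections, scn$cameras)
      greedy_total <- sum(grn$localizations$score[
        grn$localizations$method == "optimized"])
      expect_lte(bfn$total_score, greedy_total + 1e-9)
    }
  })
})

test_that("brute force refuses oversized instances", {
  cfg <- scene_config(n_players = 5, outliers_per_camera = 1)
  sc <- simulate_scene(cfg, seed = 8)  # 15 player points + 3 outliers
  expect_error(brute_force_assign(sc$detections, sc$cameras),
               class = "hooploc_size_error")
})

test_that("multi-frame localization returns a tidy per-frame table", {
  rig <- make_camera_rig(scene_config(), seed = 9)
  t1 <- data.frame(X = c(3, 10), Y = c(4, 11), Z = c(1.7, 1.95))
  d1 <- scene_detections(t1, rig)
  d2 <- d1; d2$frame_id <- 1L
  loc <- localize_players(rbind(d1, d2), rig)
  expect_equal(sort(unique(loc$frame_id)), c(0L, 1L))
  expect_equal(nrow(loc), 4)
  expect_s3_class(loc, "tbl_df")
  expect_equal(nrow(localize_players(d1[integer(), ], rig)), 0)
})
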