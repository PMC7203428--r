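#' Localization constraints and priors
#'
#' Parameters of the constrained assignment of detected head points to
#' players: the pixel tolerance bounding each point's re-projection error,
#' the admissible head-height band, the prior mean head height used by the
#' single-view fallback, and an optional cap on the number of players.
#'
#' @param tau_px maximum admissible re-projection error per assigned point,
#'   in pixels (the constraint is `e_p <= tau_px^2` on squared errors).
#'   Defaults to 25 px, the same tolerance used by the evaluation protocol.
#' @param h_min,h_max admissible head height band in metres; spans a deep
#'   crouch to the apex of a jump.
#' @param mean_height prior mean head height (metres) for the single-view
#'   fallback localization.
#' @param max_players optional cap on optimized localizations per frame
#'   (`Inf` = unlimited; the number of players in the scene is unknown).
#' @return a `loc_config` list.
#' @export
loc_config <- function(tau_px = 25, h_min = 1.2, h_max = 3.2,
                       mean_height = 1.85, max_players = Inf) {
  stopifnot(tau_px > 0, h_min < mean_height, mean_height < h_max)
  structure(list(tau_px = tau_px, h_min = h_min, h_max = h_max,
                 mean_height = mean_height, max_players = max_players),
            class = "loc_config")
}

#' Enumerate feasible point subsets for one player
#'
#' A candidate player is a subset of detected points with at least two points
#' (needed for triangulation), at most one point per camera, and hence at
#' most `w` points in total. Subsets are returned as sorted integer vectors of
#' row indices into `detections`, in a deterministic order (by size, then
#' lexicographically).
#'
#' @param detections data frame with columns `camera_id`, `x`, `y` (one frame).
#' @param cameras camera tibble (defines `w`).
#' @return list of integer vectors (possibly empty).
#' @export
enumerate_feasible_subsets <- function(detections, cameras) {
  m <- nrow(detections)
  if (m < 2) return(list())
  cams <- sort(unique(detections$camera_id))
  by_cam <- lapply(cams, function(k) which(detections$camera_id == k))
  nc <- length(by_cam)
  if (nc < 2) return(list())
  out <- list()
  for (q in 2:min(nc, nrow(cameras))) {
    cam_sets <- utils::combn(nc, q, simplify = FALSE)
    for (cs in cam_sets) {
      grid <- expand.grid(by_cam[cs], KEEP.OUT.ATTRS = FALSE)
      for (r in seq_len(nrow(grid))) {
        out[[length(out) + 1]] <- sort(as.integer(grid[r, ]))
      }
    }
  }
  key <- vapply(out, function(s)
    paste(formatC(s, width = 6, flag = "0"), collapse = "-"), character(1))
  out[order(lengths(out), key)]
}

#' Score one candidate point subset
#'
#' Triangulates the subset and evaluates the merged objective for a single
#' player: \deqn{\mathrm{score} = \frac{\sum_p e_p}{q^2} - q} where `q` is
#' the number of assigned points and `e_p` the squared pixel re-projection
#' error of point `p` in its own camera. The first term favours geometric
#' consistency, the second rewards using more views; with zero error the
#' score is exactly `-q`, so consistent larger subsets always win. The
#' subset is infeasible if any `e_p` exceeds `tau_px^2`, if the triangulated
#' height leaves `[h_min, h_max]`, or if the geometry is degenerate.
#'
#' @param subset integer vector of row indices into `detections`.
#' @param detections data frame `camera_id`, `x`, `y`.
#' @param cameras camera tibble.
#' @param config a [loc_config()].
#' @return list with `feasible` (logical); when feasible also `point`
#'   (numeric X, Y, Z), `score`, and `e2` (squared pixel errors per point).
#' @export
score_subset <- function(subset, detections, cameras, config = loc_config()) {
  q <- length(subset)
  lam <- lapply(detections$camera_id[subset], camera_lambdas, cameras = cameras)
  sol <- tryCatch(
    .triangulate_core(lam, detections$x[subset], detections$y[subset]),
    error = function(e) NULL)
  if (is.null(sol)) return(list(feasible = FALSE, reason = "degenerate"))
  if (any(sol$e2 > config$tau_px^2)) {
    return(list(feasible = FALSE, reason = "pixel_tolerance"))
  }
  if (sol$P[3] < config$h_min || sol$P[3] > config$h_max) {
    return(list(feasible = FALSE, reason = "height"))
  }
  list(feasible = TRUE, point = sol$P,
       score = sum(sol$e2) / q^2 - q, e2 = sol$e2)
}

# deterministic preference order: lowest score, then larger subset,
# then lexicographically smallest index tuple
.better_candidate <- function(a, b) {
  if (is.null(b)) return(TRUE)
  if (a$score != b$score) return(a$score < b$score)
  if (length(a$subset) != length(b$subset)) {
    return(length(a$subset) > length(b$subset))
  }
  d <- a$subset - b$subset
  nz <- which(d != 0)
  length(nz) > 0 && d[nz[1]] < 0
}

#' One greedy round: locate the single best-supported player
#'
#' Exhaustively scores every feasible subset of the remaining detections and
#' returns the global minimizer of the per-player objective (each round is
#' exact); `NULL` when no feasible subset exists. Ties break deterministically
#' toward larger subsets, then smallest index tuple.
#'
#' @inheritParams score_subset
#' @return `NULL`, or list `subset`, `point`, `score`, `e2`.
#' @export
solve_round <- function(detections, cameras, config = loc_config()) {
  subsets <- enumerate_feasible_subsets(detections, cameras)
  best <- NULL
  for (s in subsets) {
    sc <- score_subset(s, detections, cameras, config)
    if (!sc$feasible) next
    cand <- list(subset = s, point = sc$point, score = sc$score, e2 = sc$e2)
    if (.better_candidate(cand, best)) best <- cand
  }
  best
}

#' Localize every player in one frame
#'
#' The constructive greedy solution: repeatedly locate the single
#' best-supported player ([solve_round()]), drop that player's image points,
#' and continue until no feasible subset remains. Every leftover point is
#' then localized by the single-view fallback, fixing Z at the prior mean
#' head height; a leftover point whose fixed-height system is singular is
#' reported unlocalized rather than guessed.
#'
#' @param detections data frame `camera_id`, `x`, `y` for one frame
#'   (optionally `frame_id`, `det_id`, `score`).
#' @param cameras camera tibble.
#' @param config a [loc_config()].
#' @return an object of class `player_localizations`: list with
#'   `localizations` (tibble `label`, `method`, `X`, `Y`, `Z`, `n_points`,
#'   `score`), `assignment` (binary m x n matrix over optimized players),
#'   `assigned` (per-detection tibble with assigned `label` and squared
#'   error), plus the inputs. Supports `tidy()`, `glance()` and
#'   [ggplot2::autoplot()].
#' @export
localize_frame <- function(detections, cameras, config = loc_config()) {
  m <- nrow(detections)
  remaining <- seq_len(m)
  loc <- list()
  assigned_label <- rep(NA_integer_, m)
  assigned_e2 <- rep(NA_real_, m)
  label <- 0L
  while (length(remaining) > 0 && label < config$max_players) {
    round <- solve_round(detections[remaining, , drop = FALSE], cameras, config)
    if (is.null(round)) break
    label <- label + 1L
    idx <- remaining[round$subset]
    assigned_label[idx] <- label
    assigned_e2[idx] <- round$e2
    loc[[label]] <- tibble(label = label, method = "optimized",
                           X = round$point[1], Y = round$point[2],
                           Z = round$point[3],
                           n_points = length(idx), score = round$score)
    remaining <- setdiff(remaining, idx)
  }
  n_opt <- label
  # fallback: each leftover point becomes its own fixed-height localization
  for (idx in remaining) {
    label <- label + 1L
    lam <- camera_lambdas(cameras, detections$camera_id[idx])
    P <- tryCatch(
      .fixed_height_core(lam, detections$x[idx], detections$y[idx],
                         config$mean_height),
      error = function(e) NULL)
    assigned_label[idx] <- label
    loc[[label]] <- if (is.null(P)) {
      tibble(label = label, method = "unlocalized",
             X = NA_real_, Y = NA_real_, Z = NA_real_,
             n_points = 1L, score = NA_real_)
    } else {
      tibble(label = label, method = "fallback",
             X = P[1], Y = P[2], Z = P[3], n_points = 1L, score = NA_real_)
    }
  }
  A <- matrix(0L, m, n_opt)
  if (n_opt > 0) {
    opt <- which(!is.na(assigned_label) & assigned_label <= n_opt)
    A[cbind(opt, assigned_label[opt])] <- 1L
  }
  structure(
    list(localizations = if (length(loc)) dplyr::bind_rows(loc) else
           tibble(label = integer(), method = character(), X = numeric(),
                  Y = numeric(), Z = numeric(), n_points = integer(),
                  score = numeric()),
         assignment = A,
         assigned = dplyr::bind_cols(
           as_tibble(detections),
           tibble(assigned_label = assigned_label, e2_px = assigned_e2)),
         cameras = cameras, config = config),
    class = "player_localizations")
}

#' @export
print.player_localizations <- function(x, ...) {
  n_opt <- sum(x$localizations$method == "optimized")
  n_fb <- sum(x$localizations$method == "fallback")
  cat("player localizations:", n_opt, "optimized,", n_fb, "fallback\n")
  print(x$localizations)
  invisible(x)
}

#' @rdname localize_frame
#' @param x a `player_localizations` object.
#' @param ... unused.
#' @export
tidy.player_localizations <- function(x, ...) x$localizations

#' @rdname localize_frame
#' @export
glance.player_localizations <- function(x, ...) {
  tibble(n_detections = nrow(x$assigned),
         n_optimized = sum(x$localizations$method == "optimized"),
         n_fallback = sum(x$localizations$method == "fallback"),
         n_unlocalized = sum(x$localizations$method == "unlocalized"),
         total_score = sum(x$localizations$score[
           x$localizations$method == "optimized"]))
}

#' Localize players across many frames
#'
#' Data-frame-first wrapper running [localize_frame()] per `frame_id`.
#'
#' @param detections data frame `frame_id`, `camera_id`, `x`, `y`.
#' @param cameras camera tibble.
#' @param config a [loc_config()].
#' @return tibble `frame_id`, `label`, `method`, `X`, `Y`, `Z`, `n_points`,
#'   `score`.
#' @export
localize_players <- function(detections, cameras, config = loc_config()) {
  if (nrow(detections) == 0) {
    return(tibble(frame_id = integer(), label = integer(), method = character(),
                  X = numeric(), Y = numeric(), Z = numeric(),
                  n_points = integer(), score = numeric()))
  }
  detections %>%
    dplyr::group_split(.data$frame_id) %>%
    purrr::map_dfr(function(df) {
      res <- localize_frame(df, cameras, config)
      dplyr::bind_cols(tibble(frame_id = df$frame_id[1]), res$localizations)
    })
}

#' Jointly optimal assignment by exhaustive search (test oracle)
#'
#' Dynamic program over point subsets that finds the globally optimal
#' partition of detections into disjoint feasible players minimizing the sum
#' of per-player scores. Exponential in the number of points; guarded to
#' small instances and intended as an independent oracle against which the
#' greedy heuristic is compared.
#'
#' @inheritParams localize_frame
#' @param max_points refuse instances with more detections than this.
#' @return list with `subsets` (list of index vectors), `total_score`,
#'   `assignment` (m x n binary matrix) and `localizations` tibble.
#' @export
brute_force_assign <- function(detections, cameras, config = loc_config(),
                               max_points = 12L) {
  m <- nrow(detections)
  if (m > max_points) {
    abort(paste0("brute force limited to ", max_points, " points (got ", m, ")"),
          class = "hooploc_size_error")
  }
  subsets <- enumerate_feasible_subsets(detections, cameras)
  feas <- list()
  for (s in subsets) {
    sc <- score_subset(s, detections, cameras, config)
    if (sc$feasible) {
      feas[[length(feas) + 1]] <-
        list(mask = sum(2^(s - 1)),
             subset = s, score = sc$score, point = sc$point, e2 = sc$e2)
    }
  }
  n_masks <- 2^m
  best <- rep(0, n_masks)        # best[mask+1]: optimal cost using points in mask
  choice <- vector("list", n_masks)
  if (m > 0) {
    for (mask in 1:(n_masks - 1)) {
      p <- which(bitwAnd(mask, 2^(0:(m - 1))) != 0)[1]  # lowest set point
      b <- best[bitwAnd(mask, bitwNot(2^(p - 1))) + 1]  # leave p unassigned
      ch <- NULL
      for (f in feas) {
        if (bitwAnd(f$mask, mask) == f$mask && bitwAnd(f$mask, 2^(p - 1)) != 0) {
          v <- f$score + best[bitwAnd(mask, bitwNot(f$mask)) + 1]
          if (v < b - 1e-12) {
            b <- v
            ch <- f
          }
        }
      }
      best[mask + 1] <- b
      choice[mask + 1] <- list(ch)   # [[<- would drop the element when NULL
    }
  }
  # reconstruct
  chosen <- list()
  mask <- n_masks - 1
  while (mask > 0) {
    ch <- choice[[mask + 1]]
    if (is.null(ch)) {
      p <- which(bitwAnd(mask, 2^(0:(m - 1))) != 0)[1]
      mask <- bitwAnd(mask, bitwNot(2^(p - 1)))
    } else {
      chosen[[length(chosen) + 1]] <- ch
      mask <- bitwAnd(mask, bitwNot(ch$mask))
    }
  }
  chosen <- rev(chosen)
  A <- matrix(0L, m, length(chosen))
  locs <- purrr::imap_dfr(chosen, function(ch, l) {
    A[cbind(ch$subset, l)] <<- 1L
    tibble(label = l, method = "optimized",
           X = ch$point[1], Y = ch$point[2], Z = ch$point[3],
           n_points = length(ch$subset), score = ch$score)
  })
  list(subsets = purrr::map(chosen, "subset"),
       total_score = if (m > 0) best[n_masks] else 0,
       assignment = A,
       localizations = locs)
}
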