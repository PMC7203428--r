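#' Background model configuration
#'
#' Parameters of the adaptive per-pixel Gaussian mixture background model
#' used for foreground segmentation, including shadow relabeling. Shadows in
#' gym footage are attached darkened copies of the background; a foreground
#' pixel whose intensity is a moderate fraction of the background mean is
#' relabeled background.
#'
#' @param history number of frames used to form the background model; also
#'   the burn-in before masks are emitted.
#' @param n_components Gaussian components per pixel.
#' @param learning_rate mixture update rate per frame (defaults to
#'   `1/history`).
#' @param match_sigma a pixel matches a component within this many standard
#'   deviations.
#' @param var_init initial component variance (intensity units in `[0,1]`).
#' @param bg_ratio cumulative weight threshold defining the background
#'   components.
#' @param detect_shadows relabel shadow pixels to background.
#' @param shadow_range intensity-ratio band `observed / background mean`
#'   classified as shadow.
#' @return a `bg_config` list.
#' @export
bg_config <- function(history = 120, n_components = 3, learning_rate = NULL,
                      match_sigma = 2.5, var_init = 0.01, bg_ratio = 0.7,
                      detect_shadows = TRUE, shadow_range = c(0.45, 0.95)) {
  structure(list(history = history, n_components = n_components,
                 learning_rate = learning_rate %||% (1 / history),
                 match_sigma = match_sigma, var_init = var_init,
                 bg_ratio = bg_ratio, detect_shadows = detect_shadows,
                 shadow_range = shadow_range),
            class = "bg_config")
}

#' Foreground segmentation by an adaptive Gaussian mixture
#'
#' Maintains, per pixel, a small mixture of Gaussians over intensity.
#' Components carrying most of the weight (up to `bg_ratio` cumulative, most
#' stable first) model the static background; pixels not explained by a
#' background component are foreground. Foreground pixels whose intensity is
#' a `shadow_range` fraction of the background mean are relabeled background
#' (cast shadows). The first `history` frames are burn-in: they update the
#' model but yield no mask.
#'
#' @param frames list of grayscale matrices (`width x height`, values in
#'   `[0, 1]`).
#' @param config a [bg_config()].
#' @return list with `masks` (list of logical matrices for frames
#'   `history+1 ... length(frames)`), `frame_ids` (their 1-based indices into
#'   `frames`) and `background` (background mean image).
#' @export
segment_foreground <- function(frames, config = bg_config()) {
  n <- length(frames)
  if (n < config$history + 1) {
    abort(paste0("need more than history = ", config$history,
                 " frames to form a background model (got ", n, ")"),
          class = "hooploc_insufficient_history")
  }
  dm <- dim(frames[[1]])
  npix <- prod(dm)
  K <- config$n_components
  alpha <- config$learning_rate
  MU <- matrix(0.5, npix, K)
  VAR <- matrix(config$var_init, npix, K)
  W <- matrix(1 / K, npix, K)
  MU[, 1] <- as.vector(frames[[1]])  # seed the first component at frame 1
  W[, 1] <- 0.9
  W <- W / rowSums(W)
  masks <- vector("list", max(0, n - config$history))
  bg_mean <- NULL
  for (t in seq_len(n)) {
    x <- as.vector(frames[[t]])
    D <- abs(x - MU) / sqrt(VAR)       # npix x K standardized distances
    Dm <- D
    Dm[D > config$match_sigma] <- Inf
    mc <- max.col(-Dm, ties.method = "first")    # closest matching component
    has_match <- Dm[cbind(seq_len(npix), mc)] < Inf
    # weight update
    Wn <- (1 - alpha) * W
    mi <- cbind(which(has_match), mc[has_match])
    Wn[mi] <- Wn[mi] + alpha
    # matched mean/variance update
    rho <- alpha * 5   # component adaptation faster than weight drift
    dx <- x[mi[, 1]] - MU[mi]
    MU[mi] <- MU[mi] + rho * dx
    VAR[mi] <- pmax((1 - rho) * VAR[mi] + rho * dx^2, 1e-5)
    # unmatched pixels: replace weakest component
    um <- which(!has_match)
    if (length(um)) {
      weakest <- max.col(-Wn[um, , drop = FALSE], ties.method = "first")
      ui <- cbind(um, weakest)
      MU[ui] <- x[um]
      VAR[ui] <- config$var_init
      Wn[ui] <- 0.05
    }
    W <- Wn / rowSums(Wn)
    if (t > config$history) {
      # background set: components by descending w/sd until cumulative
      # weight reaches bg_ratio (K passes of max.col, vectorized over pixels)
      fitness <- W / sqrt(VAR)
      is_bg <- matrix(FALSE, npix, K)
      cum <- numeric(npix)
      mu_bg <- NULL
      for (r in seq_len(K)) {
        comp <- max.col(fitness, ties.method = "first")
        idx <- cbind(seq_len(npix), comp)
        if (r == 1) mu_bg <- MU[idx]
        sel <- idx[cum < config$bg_ratio, , drop = FALSE]
        is_bg[sel] <- TRUE
        cum <- cum + W[idx]
        fitness[idx] <- -Inf
      }
      fg <- !has_match | !is_bg[cbind(seq_len(npix), mc)]
      if (config$detect_shadows) {
        ratio <- x / pmax(mu_bg, 1e-6)
        shadow <- fg & ratio >= config$shadow_range[1] &
          ratio <= config$shadow_range[2]
        fg <- fg & !shadow
      }
      masks[[t - config$history]] <- matrix(fg, dm[1], dm[2])
      bg_mean <- matrix(mu_bg, dm[1], dm[2])
    }
  }
  list(masks = masks,
       frame_ids = if (n > config$history) (config$history + 1):n else integer(),
       background = bg_mean)
}

#' Morphological noise suppression (opening)
#'
#' Erosion followed by dilation with a disc kernel: removes speckle noise
#' from a binary foreground mask while preserving blobs larger than the
#' kernel.
#'
#' @param mask logical or 0/1 matrix.
#' @param kernel_size odd kernel diameter in pixels.
#' @return logical matrix of the same size.
#' @export
clean_mask <- function(mask, kernel_size = 3) {
  kern <- EBImage::makeBrush(kernel_size, shape = "disc")
  img <- EBImage::Image(mask * 1)
  out <- EBImage::dilate(EBImage::erode(img, kern), kern)
  EBImage::imageData(out) > 0.5
}

#' Circle-search configuration for head fitting
#'
#' @param r_min,r_max admissible head radius range in pixels.
#' @param dist_cap maximum distance between a fitted circle centre and the
#'   contour maximum that seeded it (defaults to `1.5 * r_max`).
#' @param vote_frac minimum fraction of the circle circumference supported by
#'   contour pixels for the circle to be accepted.
#' @param min_area minimum connected-component area (px) considered a player
#'   blob.
#' @param nms_px non-maximum-suppression radius for contour maxima.
#' @return a `hough_config` list.
#' @export
hough_config <- function(r_min = 6, r_max = 20, dist_cap = NULL,
                         vote_frac = 0.35, min_area = 60, nms_px = 5) {
  structure(list(r_min = r_min, r_max = r_max,
                 dist_cap = dist_cap %||% (1.5 * r_max),
                 vote_frac = vote_frac, min_area = min_area, nms_px = nms_px),
            class = "hough_config")
}

# local maxima of a closed contour: points whose image y is a local minimum
# along the curve (y grows downward -> head tops), with pixel-radius NMS
.contour_maxima <- function(contour, nms_px = 5) {
  n <- nrow(contour)
  if (n < 3) return(contour[which.min(contour[, 2]), , drop = FALSE])
  y <- contour[, 2]
  win <- 3
  is_min <- vapply(seq_len(n), function(i) {
    nb <- ((i - win):(i + win) - 1) %% n + 1
    y[i] <= min(y[nb])
  }, logical(1))
  cand <- contour[is_min, , drop = FALSE]
  cand <- cand[order(cand[, 2]), , drop = FALSE]   # highest in image first
  keep <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    if (nrow(keep) == 0 ||
        min(sqrt((keep[, 1] - cand[i, 1])^2 + (keep[, 2] - cand[i, 2])^2)) > nms_px) {
      keep <- rbind(keep, cand[i, ])
    }
  }
  keep
}

# circle Hough vote around one seed point: returns best (cx, cy, r, support)
.hough_circle <- function(edges, seed, config) {
  r_seq <- seq(config$r_min, config$r_max, by = 1)
  near <- edges[sqrt((edges[, 1] - seed[1])^2 + (edges[, 2] - seed[2])^2) <=
                  config$dist_cap + config$r_max + 2, , drop = FALSE]
  if (nrow(near) < 5) return(NULL)
  gx <- seq(floor(seed[1] - config$dist_cap), ceiling(seed[1] + config$dist_cap))
  gy <- seq(floor(seed[2] - config$dist_cap), ceiling(seed[2] + config$dist_cap))
  centers <- as.matrix(expand.grid(x = gx, y = gy))
  centers <- centers[sqrt((centers[, 1] - seed[1])^2 +
                          (centers[, 2] - seed[2])^2) <= config$dist_cap, ,
                     drop = FALSE]
  if (nrow(centers) == 0) return(NULL)
  D <- sqrt(outer(centers[, 1], near[, 1], "-")^2 +
            outer(centers[, 2], near[, 2], "-")^2)
  # score = angular coverage: fraction of 10-degree sectors of the circle
  # containing a contour pixel. Robust against flat contour runs, which give
  # many same-direction votes but little angular spread.
  n_sect <- 36
  coverage <- function(ci, r) {
    e <- which(abs(D[ci, ] - r) <= 1)
    if (!length(e)) return(0)
    ang <- atan2(near[e, 2] - centers[ci, 2], near[e, 1] - centers[ci, 1])
    length(unique(floor((ang %% (2 * pi)) / (2 * pi / n_sect)))) / n_sect
  }
  best <- NULL
  for (r in r_seq) {
    support <- rowSums(abs(D - r) <= 1)
    top <- order(-support)[seq_len(min(3, length(support)))]
    for (ci in top[support[top] > 0]) {
      cov <- coverage(ci, r)
      if (is.null(best) || cov > best$frac + 1e-9 ||
          (abs(cov - best$frac) <= 1e-9 && r > best$r)) {
        best <- list(cx = centers[ci, 1], cy = centers[ci, 2], r = r,
                     frac = cov, support = support[ci])
      }
    }
  }
  if (is.null(best) || best$frac < config$vote_frac) return(NULL)
  best
}

#' Extract head candidates from a cleaned foreground mask
#'
#' Contours of the foreground blobs are extracted; along each contour the
#' topmost point and the local maxima (local minima of the image y
#' coordinate, 5 px suppression) seed a circle search, since one contour can
#' enclose several players and each head produces a local top. Near each
#' seed the best circle in the admissible head-radius range is fitted by
#' Hough voting on contour pixels; circles too weakly supported, too far
#' from their seed, or centred outside the interest-area polygon are
#' discarded.
#'
#' @param mask cleaned binary mask (`width x height`).
#' @param frame matching grayscale frame (used downstream for HOG patches).
#' @param interest_area polygon matrix / data frame with columns `x`, `y`
#'   in pixels, or `NULL` for no gating.
#' @param config a [hough_config()].
#' @return tibble `x`, `y`, `radius_px`, `seed_x`, `seed_y`, `support`
#'   (fraction of circumference covered), one row per candidate.
#' @export
extract_head_candidates <- function(mask, frame, interest_area = NULL,
                                    config = hough_config()) {
  empty <- tibble(x = numeric(), y = numeric(), radius_px = numeric(),
                  seed_x = numeric(), seed_y = numeric(), support = numeric())
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  n_obj <- max(lab)
  if (n_obj == 0) return(empty)
  areas <- tabulate(EBImage::imageData(lab)[EBImage::imageData(lab) > 0], n_obj)
  contours <- EBImage::ocontour(lab)
  out <- list()
  for (oi in seq_len(n_obj)) {
    if (areas[oi] < config$min_area) next
    contour <- contours[[oi]] + 1   # 0-based -> pixel indices
    seeds <- .contour_maxima(contour, config$nms_px)
    for (si in seq_len(nrow(seeds))) {
      circ <- .hough_circle(contour, as.numeric(seeds[si, ]), config)
      if (is.null(circ)) next
      out[[length(out) + 1]] <-
        tibble(x = circ$cx, y = circ$cy, radius_px = circ$r,
               seed_x = seeds[si, 1], seed_y = seeds[si, 2],
               support = circ$frac)
    }
  }
  if (!length(out)) return(empty)
  cand <- dplyr::bind_rows(out)
  # deduplicate circles found from different seeds of the same head
  keep <- rep(TRUE, nrow(cand))
  ord <- order(-cand$support)
  for (i in seq_along(ord)) {
    if (!keep[ord[i]]) next
    later <- ord[-seq_len(i)]
    d <- sqrt((cand$x[later] - cand$x[ord[i]])^2 +
              (cand$y[later] - cand$y[ord[i]])^2)
    keep[later[d < config$r_min]] <- FALSE
  }
  cand <- cand[keep, , drop = FALSE]
  if (!is.null(interest_area)) {
    poly <- as.matrix(as.data.frame(interest_area)[, c("x", "y")])
    cand <- cand[points_in_polygon(cand$x, cand$y, poly), , drop = FALSE]
  }
  cand
}

#' HOG descriptor configuration
#'
#' Standard Dalal-Triggs geometry: a square window divided into square
#' cells, gradient orientations (unsigned, 0-180 degrees) voted into
#' histogram bins per cell, and overlapping blocks of cells normalized
#' independently. The default 64 px window with 8 px cells, 2x2-cell blocks
#' at one-cell stride and 9 bins yields a descriptor of length
#' `(8-1)^2 * 4 * 9 = 1764`.
#'
#' @param window window side in pixels.
#' @param cell cell side in pixels (`window` must be a multiple).
#' @param block block side in cells.
#' @param bins orientation bins over 0-180 degrees.
#' @param clip block-normalization clipping value.
#' @return a `hog_config` list.
#' @export
hog_config <- function(window = 64, cell = 8, block = 2, bins = 9,
                       clip = 0.2) {
  stopifnot(window %% cell == 0)
  structure(list(window = window, cell = cell, block = block, bins = bins,
                 clip = clip),
            class = "hog_config")
}

#' Descriptor length implied by a HOG configuration
#' @param config a [hog_config()].
#' @return integer descriptor length.
#' @export
hog_length <- function(config = hog_config()) {
  ncell <- config$window / config$cell
  nblk <- ncell - config$block + 1
  as.integer(nblk^2 * config$block^2 * config$bins)
}

#' Compute a HOG descriptor for one patch
#'
#' @param patch square grayscale matrix of side `config$window`.
#' @param config a [hog_config()].
#' @return numeric descriptor (length [hog_length()]), all entries
#'   non-negative; identically zero for a constant patch.
#' @export
compute_hog <- function(patch, config = hog_config()) {
  wdw <- config$window
  stopifnot(nrow(patch) == wdw, ncol(patch) == wdw)
  pad <- rbind(patch[1, ], patch, patch[wdw, ])
  pad <- cbind(pad[, 1], pad, pad[, wdw])
  gx <- (pad[3:(wdw + 2), 2:(wdw + 1)] - pad[1:wdw, 2:(wdw + 1)]) / 2
  gy <- (pad[2:(wdw + 1), 3:(wdw + 2)] - pad[2:(wdw + 1), 1:wdw]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi                      # unsigned orientation
  # bilinear vote between adjacent orientation bins
  pos <- ang / pi * config$bins - 0.5
  b0 <- floor(pos)
  w1 <- pos - b0
  b0 <- (b0 %% config$bins) + 1
  b1 <- (b0 %% config$bins) + 1
  ncell <- wdw / config$cell
  cellx <- ceiling(row(patch) / config$cell)
  celly <- ceiling(col(patch) / config$cell)
  cidx <- cellx + (celly - 1) * ncell
  hist <- matrix(0, ncell * ncell, config$bins)
  flat <- c(cidx + (b0 - 1) * ncell * ncell, cidx + (b1 - 1) * ncell * ncell)
  vals <- c(mag * (1 - w1), mag * w1)
  acc <- rowsum(vals, flat)
  hist[as.integer(rownames(acc))] <- acc[, 1]
  nblk <- ncell - config$block + 1
  out <- numeric(hog_length(config))
  len <- config$block^2 * config$bins
  pos_out <- 1
  for (by in seq_len(nblk)) {
    for (bx in seq_len(nblk)) {
      cells <- as.vector(outer(bx:(bx + config$block - 1),
                               (by:(by + config$block - 1) - 1) * ncell, "+"))
      v <- as.vector(t(hist[cells, , drop = FALSE]))
      nrm <- sqrt(sum(v^2))
      if (nrm > 1e-10) {
        v <- pmin(v / nrm, config$clip)
        nrm2 <- sqrt(sum(v^2))
        if (nrm2 > 1e-10) v <- v / nrm2
      } else {
        v <- v * 0
      }
      out[pos_out:(pos_out + len - 1)] <- v
      pos_out <- pos_out + len
    }
  }
  out
}

# square patch centred at (cx, cy) with replication padding at frame borders
hog_patch <- function(frame, cx, cy, window = 64) {
  half <- window / 2
  xs <- pmin(pmax(round(cx) - half + seq_len(window), 1), nrow(frame))
  ys <- pmin(pmax(round(cy) - half + seq_len(window), 1), ncol(frame))
  frame[xs, ys]
}
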