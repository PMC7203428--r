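#' Match detections against ground truth in one camera frame
#'
#' Greedy distance-sorted matching: detection-truth pairs are considered in
#' order of increasing pixel distance and accepted while both sides are
#' unmatched and the distance is below the threshold (25 px by default, the
#' protocol's rule for a true detection). Unmatched detections are false
#' positives; unmatched truths are misdetections. An optimal (minimum total
#' distance) matching is available behind `method = "optimal"` for small
#' instances.
#'
#' @param detected data frame with pixel columns `x`, `y`.
#' @param truth data frame with pixel columns `x`, `y` (ground-truth heads).
#' @param threshold_px matching radius in pixels.
#' @param method `"greedy"` (default) or `"optimal"` (exhaustive, small
#'   inputs only).
#' @return a `match_result` list: counts `true`, `false_positive`,
#'   `misdetection` and a `pairs` tibble (`det`, `truth`, `dist_px`).
#' @export
match_detections <- function(detected, truth, threshold_px = 25,
                             method = c("greedy", "optimal")) {
  method <- match.arg(method)
  stopifnot(threshold_px > 0)
  nd <- nrow(detected)
  nt <- nrow(truth)
  pairs <- tibble(det = integer(), truth = integer(), dist_px = numeric())
  if (nd > 0 && nt > 0) {
    D <- sqrt(outer(detected$x, truth$x, "-")^2 +
              outer(detected$y, truth$y, "-")^2)
    if (method == "greedy") {
      cand <- which(D < threshold_px, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        cand <- cand[order(D[cand]), , drop = FALSE]
        used_d <- logical(nd); used_t <- logical(nt)
        for (i in seq_len(nrow(cand))) {
          di <- unname(cand[i, 1]); ti <- unname(cand[i, 2])
          if (!used_d[di] && !used_t[ti]) {
            used_d[di] <- TRUE; used_t[ti] <- TRUE
            pairs <- dplyr::bind_rows(pairs,
              tibble(det = di, truth = ti, dist_px = D[di, ti]))
          }
        }
      }
    } else {
      if (max(nd, nt) > 10) {
        abort("optimal matching is exhaustive; limited to 10 points per side",
              class = "hooploc_size_error")
      }
      # minimise total matched distance over all one-to-one matchings
      # (pairs beyond the threshold stay unmatched)
      Dc <- D
      Dc[Dc >= threshold_px] <- NA
      best <- NULL
      perms <- function(v) if (length(v) <= 1) list(v) else
        unlist(lapply(seq_along(v), function(i)
          lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
      small <- if (nd <= nt) "d" else "t"
      base <- if (small == "d") seq_len(nd) else seq_len(nt)
      other <- if (small == "d") seq_len(nt) else seq_len(nd)
      for (p in perms(other)) {
        sel <- p[seq_along(base)]
        dd <- if (small == "d") Dc[cbind(base, sel)] else Dc[cbind(sel, base)]
        cost <- sum(dd, na.rm = TRUE) - 1e6 * sum(!is.na(dd))
        if (is.null(best) || cost < best$cost) {
          best <- list(cost = cost,
                       det = if (small == "d") base[!is.na(dd)] else sel[!is.na(dd)],
                       truth = if (small == "d") sel[!is.na(dd)] else base[!is.na(dd)])
        }
      }
      if (!is.null(best) && length(best$det)) {
        pairs <- tibble(det = best$det, truth = best$truth,
                        dist_px = D[cbind(best$det, best$truth)])
      }
    }
  }
  structure(list(true = nrow(pairs),
                 false_positive = nd - nrow(pairs),
                 misdetection = nt - nrow(pairs),
                 pairs = pairs),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("matched:", x$true, " false positives:", x$false_positive,
      " misdetections:", x$misdetection, "\n")
  invisible(x)
}

#' Detection rate triplet
#'
#' True-detection, false-positive and misdetection rates sharing the common
#' denominator `true + false_positive + misdetection`, so the three always
#' sum to 100.
#'
#' @param result a `match_result` (or a list with the three counts).
#' @return tibble `true_pct`, `false_positive_pct`, `misdetection_pct`.
#' @export
detection_rates <- function(result) {
  denom <- result$true + result$false_positive + result$misdetection
  if (denom == 0) {
    abort("no detections and no ground truth: rates undefined",
          class = "hooploc_undefined_rate")
  }
  tibble(true_pct = 100 * result$true / denom,
         false_positive_pct = 100 * result$false_positive / denom,
         misdetection_pct = 100 * result$misdetection / denom)
}

#' Pixel RMSE of matched detections
#'
#' @param result a `match_result`.
#' @return root-mean-square pixel distance over matched pairs.
#' @export
detection_rmse <- function(result) {
  if (nrow(result$pairs) == 0) {
    abort("no matched pairs: pixel RMSE undefined",
          class = "hooploc_undefined_rate")
  }
  sqrt(mean(result$pairs$dist_px^2))
}

#' Localization RMSE in court space
#'
#' Root-mean-squared Euclidean error between estimated and true player
#' positions over the selected axes: `c("X", "Y")` is the planar (court
#' plane) error, `c("X", "Y", "Z")` the spatial error.
#'
#' @param estimates data frame with the coordinate columns in metres.
#' @param truth data frame with the same columns, aligned row-wise with
#'   `estimates` (matched by player provenance upstream).
#' @param axes coordinate columns entering the error.
#' @return RMSE in metres.
#' @export
localization_rmse <- function(estimates, truth, axes = c("X", "Y", "Z")) {
  stopifnot(nrow(estimates) == nrow(truth))
  if (nrow(estimates) == 0) {
    abort("no estimate/truth pairs: RMSE undefined",
          class = "hooploc_undefined_rate")
  }
  E <- as.matrix(estimates[, axes, drop = FALSE])
  TT <- as.matrix(truth[, axes, drop = FALSE])
  sqrt(mean(rowSums((E - TT)^2)))
}

#' Evaluate localizations against ground truth by player provenance
#'
#' Joins estimated player positions to ground truth: optimized localizations
#' are matched to the nearest unclaimed true player (within a generous
#' radius), then planar and spatial RMSE are reported separately for
#' optimized and fallback estimates.
#'
#' @param localizations tibble from [localize_players()] (needs `frame_id`,
#'   `method`, `X`, `Y`, `Z`).
#' @param truth tibble `frame_id`, `label`, `X`, `Y`, `Z`.
#' @param max_match_m maximum planar distance (metres) for pairing an
#'   estimate with a true player.
#' @return tibble with one row per method: `method`, `n`, `rmse_xy_m`,
#'   `rmse_xyz_m`.
#' @export
evaluate_localizations <- function(localizations, truth, max_match_m = 2) {
  loc <- localizations[localizations$method %in% c("optimized", "fallback"), ,
                       drop = FALSE]
  rows <- list()
  for (fid in unique(loc$frame_id)) {
    lf <- loc[loc$frame_id == fid, , drop = FALSE]
    tf <- truth[truth$frame_id == fid, , drop = FALSE]
    if (nrow(tf) == 0) next
    claimed <- logical(nrow(tf))
    for (i in seq_len(nrow(lf))) {
      d <- sqrt((lf$X[i] - tf$X)^2 + (lf$Y[i] - tf$Y)^2)
      d[claimed] <- Inf
      j <- which.min(d)
      if (length(j) && is.finite(d[j]) && d[j] <= max_match_m) {
        claimed[j] <- TRUE
        rows[[length(rows) + 1]] <-
          tibble(method = lf$method[i],
                 eX = lf$X[i], eY = lf$Y[i], eZ = lf$Z[i],
                 tX = tf$X[j], tY = tf$Y[j], tZ = tf$Z[j])
      }
    }
  }
  if (!length(rows)) {
    return(tibble(method = character(), n = integer(),
                  rmse_xy_m = numeric(), rmse_xyz_m = numeric()))
  }
  dplyr::bind_rows(rows) %>%
    dplyr::group_by(.data$method) %>%
    dplyr::summarise(
      n = dplyr::n(),
      rmse_xy_m = sqrt(mean((.data$eX - .data$tX)^2 + (.data$eY - .data$tY)^2)),
      rmse_xyz_m = sqrt(mean((.data$eX - .data$tX)^2 + (.data$eY - .data$tY)^2 +
                             (.data$eZ - .data$tZ)^2)),
      .groups = "drop")
}
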