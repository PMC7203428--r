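#' @importFrom rlang abort .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% mutate filter select bind_rows group_by ungroup arrange
#' @importFrom stats rnorm runif setNames
NULL

LAMBDA_COLS <- paste0("l", 1:11)

#' Construct a camera table
#'
#' A camera is an 11-parameter direct linear transformation (DLT) model
#' mapping court-space metres (X, Y, Z) to image pixels (x, y):
#' \deqn{x = \frac{\lambda_1 X + \lambda_4 Y + \lambda_7 Z + \lambda_{10}}
#'            {\lambda_3 X + \lambda_6 Y + \lambda_9 Z + 1}, \quad
#'       y = \frac{\lambda_2 X + \lambda_5 Y + \lambda_8 Z + \lambda_{11}}
#'            {\lambda_3 X + \lambda_6 Y + \lambda_9 Z + 1}}
#' The twelfth projective parameter is fixed to 1 (the "+1" in the
#' denominator), the usual DLT normalization. Cameras live in a tibble with
#' one row per camera: `camera_id`, `l1` ... `l11`.
#'
#' @param camera_id integer camera index (0-based by convention).
#' @param lambdas numeric vector of exactly 11 DLT parameters.
#' @return a one-row camera tibble.
#' @export
new_camera <- function(camera_id, lambdas) {
  if (length(lambdas) != 11 || !is.numeric(lambdas) || anyNA(lambdas)) {
    abort("a DLT camera has exactly 11 finite parameters",
          class = "hooploc_schema_error")
  }
  out <- tibble(camera_id = as.integer(camera_id))
  out[LAMBDA_COLS] <- as.list(as.numeric(lambdas))
  out
}

# 11-vector of one camera's parameters, by id
camera_lambdas <- function(cameras, id) {
  row <- cameras[cameras$camera_id == id, , drop = FALSE]
  if (nrow(row) != 1) {
    abort(paste0("camera_id ", id, " not found (or duplicated) in camera table"),
          class = "hooploc_schema_error")
  }
  as.numeric(row[1, LAMBDA_COLS])
}

# projection denominators lam3*X + lam6*Y + lam9*Z + 1 for an n x 3 matrix
.dlt_denom <- function(lam, W) {
  W[, 1] * lam[3] + W[, 2] * lam[6] + W[, 3] * lam[9] + 1
}

# core projection: lam 11-vector, W n x 3 world matrix -> n x 2 pixel matrix
.dlt_project <- function(lam, W, eps = 1e-9) {
  den <- .dlt_denom(lam, W)
  if (any(abs(den) < eps)) {
    abort("projection denominator is (near) zero: point degenerate for this camera",
          class = "hooploc_degenerate_projection")
  }
  cbind(x = (W[, 1] * lam[1] + W[, 2] * lam[4] + W[, 3] * lam[7] + lam[10]) / den,
        y = (W[, 1] * lam[2] + W[, 2] * lam[5] + W[, 3] * lam[8] + lam[11]) / den)
}

#' Project world points through DLT cameras
#'
#' @param points data frame with columns `X`, `Y`, `Z` (metres; court frame:
#'   origin at the intersection of a lateral line with a bottom line, Z up).
#' @param cameras camera tibble (see [new_camera()]).
#' @param eps smallest admissible absolute projection denominator.
#' @return tibble with one row per (camera, point): `camera_id`, `point_id`
#'   (row number in `points`), `x`, `y` in pixels (origin top-left, y down).
#' @export
dlt_project <- function(points, cameras, eps = 1e-9) {
  W <- as.matrix(points[, c("X", "Y", "Z")])
  storage.mode(W) <- "double"
  purrr::map_dfr(seq_len(nrow(cameras)), function(i) {
    lam <- as.numeric(cameras[i, LAMBDA_COLS])
    uv <- .dlt_project(lam, W, eps)
    tibble(camera_id = cameras$camera_id[i],
           point_id = seq_len(nrow(W)),
           x = uv[, 1], y = uv[, 2])
  })
}

# DLT design matrix rows for one camera's correspondences.
# Unknown order l1..l11; each point pair contributes
#   x-eq: l1 X + l4 Y + l7 Z + l10 - x (l3 X + l6 Y + l9 Z) = x
#   y-eq: l2 X + l5 Y + l8 Z + l11 - y (l3 X + l6 Y + l9 Z) = y
.dlt_design <- function(X, Y, Z, x, y) {
  n <- length(X)
  A <- matrix(0, 2 * n, 11)
  ix <- seq(1, 2 * n, by = 2)
  iy <- ix + 1
  A[ix, 1] <- X;  A[ix, 4] <- Y;  A[ix, 7] <- Z;  A[ix, 10] <- 1
  A[ix, 3] <- -x * X; A[ix, 6] <- -x * Y; A[ix, 9] <- -x * Z
  A[iy, 2] <- X;  A[iy, 5] <- Y;  A[iy, 8] <- Z;  A[iy, 11] <- 1
  A[iy, 3] <- -y * X; A[iy, 6] <- -y * Y; A[iy, 9] <- -y * Z
  b <- numeric(2 * n)
  b[ix] <- x
  b[iy] <- y
  list(A = A, b = b)
}

# SVD least squares with condition-number guard
.solve_ls <- function(A, b, cond_max = 1e10, what = "system") {
  sv <- svd(A)
  d <- sv$d
  if (d[length(d)] <= 0 || d[1] / d[length(d)] > cond_max) {
    abort(paste0("degenerate ", what, ": condition number exceeds ", cond_max),
          class = "hooploc_degenerate_geometry")
  }
  drop(sv$v %*% ((crossprod(sv$u, b)) / d))
}

#' Calibrate DLT cameras from world-image correspondences
#'
#' Estimates the 11 DLT parameters of each camera by linear least squares on
#' the stacked calibration equations. Eleven unknowns need eleven equations,
#' and each world-image point pair supplies two, so at least six pairs per
#' camera are required; the pairs must not be coplanar (the design matrix must
#' be numerically full rank).
#'
#' @param correspondences data frame with columns `camera_id`, `X`, `Y`, `Z`
#'   (metres) and `x`, `y` (pixels); typically line intersections of the court
#'   markings plus points on a vertical calibration bar.
#' @param cond_max condition-number cap above which the configuration is
#'   declared degenerate.
#' @return an object of class `dlt_fit`: list with `cameras` (camera tibble),
#'   `residuals` (per-correspondence re-projection residuals, pixels) and
#'   per-camera summary statistics. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_dlt <- function(correspondences, cond_max = 1e10) {
  req <- c("camera_id", "X", "Y", "Z", "x", "y")
  if (!all(req %in% names(correspondences))) {
    abort(paste("correspondences need columns:", paste(req, collapse = ", ")),
          class = "hooploc_schema_error")
  }
  ids <- sort(unique(correspondences$camera_id))
  fits <- purrr::map(ids, function(id) {
    cc <- correspondences[correspondences$camera_id == id, , drop = FALSE]
    if (nrow(cc) < 6) {
      abort(paste0("camera ", id, ": ", nrow(cc),
                   " correspondences; a minimum of six point pairs is required ",
                   "(11 unknowns, two equations per pair)"),
            class = "hooploc_insufficient_correspondences")
    }
    dm <- .dlt_design(cc$X, cc$Y, cc$Z, cc$x, cc$y)
    sv <- svd(dm$A)
    if (sv$d[11] <= 0 || sv$d[1] / sv$d[11] > cond_max) {
      abort(paste0("camera ", id, ": degenerate calibration configuration ",
                   "(coplanar/collinear world points?)"),
            class = "hooploc_degenerate_configuration")
    }
    lam <- drop(sv$v %*% (crossprod(sv$u, dm$b) / sv$d))
    uv <- .dlt_project(lam, as.matrix(cc[, c("X", "Y", "Z")]))
    res <- sqrt((uv[, 1] - cc$x)^2 + (uv[, 2] - cc$y)^2)
    list(camera = new_camera(id, lam),
         residual = tibble(camera_id = id, residual_px = res),
         stats = tibble(camera_id = id, n_points = nrow(cc),
                        rms_px = sqrt(mean(res^2)),
                        condition = sv$d[1] / sv$d[11]))
  })
  structure(
    list(cameras = bind_rows(purrr::map(fits, "camera")),
         residuals = bind_rows(purrr::map(fits, "residual")),
         stats = bind_rows(purrr::map(fits, "stats"))),
    class = "dlt_fit")
}

#' @export
print.dlt_fit <- function(x, ...) {
  cat("DLT calibration:", nrow(x$cameras), "camera(s)\n")
  print(x$stats)
  invisible(x)
}

#' @rdname fit_dlt
#' @param x a `dlt_fit` object.
#' @param ... unused.
#' @export
tidy.dlt_fit <- function(x, ...) {
  x$cameras %>%
    tidyr::pivot_longer(dplyr::all_of(LAMBDA_COLS),
                        names_to = "term", values_to = "estimate")
}

#' @rdname fit_dlt
#' @export
glance.dlt_fit <- function(x, ...) x$stats

#' Triangulate a 3D point from two or more camera observations
#'
#' Least-squares solution of the stacked DLT equations in the unknown world
#' point (X, Y, Z). At least two observations from distinct cameras are
#' required (a single view constrains only a ray).
#'
#' @param observations data frame with columns `camera_id`, `x`, `y` — the
#'   pixel coordinates of the same physical point seen in each camera.
#' @param cameras camera tibble.
#' @param cond_max condition-number cap for the stacked 2q x 3 system.
#' @return list with `point` (one-row tibble `X`, `Y`, `Z` in metres) and
#'   `errors` (tibble `camera_id`, `error_px`: Euclidean pixel re-projection
#'   error per observation).
#' @export
triangulate <- function(observations, cameras, cond_max = 1e10) {
  if (length(unique(observations$camera_id)) < 2) {
    abort("triangulation needs observations from at least two distinct cameras",
          class = "hooploc_insufficient_views")
  }
  lam <- lapply(observations$camera_id, camera_lambdas, cameras = cameras)
  sol <- .triangulate_core(lam, observations$x, observations$y, cond_max)
  list(point = tibble(X = sol$P[1], Y = sol$P[2], Z = sol$P[3]),
       errors = tibble(camera_id = observations$camera_id,
                       error_px = sqrt(sol$e2)))
}

# fast core used by the assignment solver: lam_list is a list of 11-vectors
# aligned with pixel vectors x, y. Returns world point + per-obs squared error.
.triangulate_core <- function(lam_list, x, y, cond_max = 1e10) {
  q <- length(lam_list)
  A <- matrix(0, 2 * q, 3)
  b <- numeric(2 * q)
  for (i in seq_len(q)) {
    l <- lam_list[[i]]
    A[2 * i - 1, ] <- c(l[1] - l[3] * x[i], l[4] - l[6] * x[i], l[7] - l[9] * x[i])
    A[2 * i, ]     <- c(l[2] - l[3] * y[i], l[5] - l[6] * y[i], l[8] - l[9] * y[i])
    b[2 * i - 1] <- x[i] - l[10]
    b[2 * i]     <- y[i] - l[11]
  }
  P <- .solve_ls(A, b, cond_max, what = "triangulation geometry")
  e2 <- vapply(seq_len(q), function(i) {
    uv <- .dlt_project(lam_list[[i]], matrix(P, 1))
    (uv[1, 1] - x[i])^2 + (uv[1, 2] - y[i])^2
  }, numeric(1))
  list(P = P, e2 = e2)
}

#' Localize a single-view point at a fixed height
#'
#' With only one camera a head point cannot be triangulated; fixing Z to a
#' prior mean head height turns the two DLT equations of that camera into a
#' 2x2 linear system in (X, Y).
#'
#' @param observation one-row data frame with `camera_id`, `x`, `y`.
#' @param cameras camera tibble.
#' @param Z fixed height in metres (e.g. a mean player head height).
#' @param cond_max condition-number cap for the 2x2 system.
#' @return one-row tibble `X`, `Y`, `Z`.
#' @export
triangulate_fixed_height <- function(observation, cameras, Z, cond_max = 1e10) {
  lam <- camera_lambdas(cameras, observation$camera_id[1])
  P <- .fixed_height_core(lam, observation$x[1], observation$y[1], Z, cond_max)
  tibble(X = P[1], Y = P[2], Z = Z)
}

.fixed_height_core <- function(lam, x, y, Z, cond_max = 1e10) {
  A <- rbind(c(lam[1] - lam[3] * x, lam[4] - lam[6] * x),
             c(lam[2] - lam[3] * y, lam[5] - lam[6] * y))
  b <- c(x - lam[10] - (lam[7] - lam[9] * x) * Z,
         y - lam[11] - (lam[8] - lam[9] * y) * Z)
  XY <- .solve_ls(A, b, cond_max, what = "fixed-height system")
  c(XY[1], XY[2], Z)
}

#' Squared pixel re-projection error
#'
#' (x_p - x_l)^2 + (y_p - y_l)^2: the squared Euclidean pixel distance between
#' an observed image point and the projection of a world point into the same
#' camera. This is the per-point cost entering the assignment objective.
#'
#' @param world data frame with `X`, `Y`, `Z` (one or more rows).
#' @param image data frame with `x`, `y`, aligned row-wise with `world`.
#' @param camera one-row camera tibble (or a camera table plus `camera_id`).
#' @param camera_id which camera to use when `camera` has several rows.
#' @return numeric vector of squared pixel errors.
#' @export
reprojection_error <- function(world, image, camera, camera_id = NULL) {
  lam <- if (nrow(camera) == 1 && is.null(camera_id)) {
    as.numeric(camera[1, LAMBDA_COLS])
  } else {
    camera_lambdas(camera, camera_id)
  }
  uv <- .dlt_project(lam, as.matrix(world[, c("X", "Y", "Z")]))
  (uv[, 1] - image$x)^2 + (uv[, 2] - image$y)^2
}
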