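#' Read and write camera files
#'
#' Cameras are stored as a JSON array of objects
#' `{"camera_id": int, "lambdas": [11 numbers]}` at full double precision,
#' so a save/load round trip is lossless.
#'
#' @param cameras camera tibble.
#' @param path file path.
#' @return `load_cameras()` returns a camera tibble; `save_cameras()`
#'   returns `path` invisibly.
#' @export
save_cameras <- function(cameras, path) {
  recs <- purrr::map(seq_len(nrow(cameras)), function(i) {
    list(camera_id = cameras$camera_id[i],
         lambdas = as.numeric(cameras[i, LAMBDA_COLS]))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_cameras
#' @export
load_cameras <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  ids <- purrr::map_int(recs, function(r) as.integer(r$camera_id %||% NA))
  if (anyNA(ids) || anyDuplicated(ids)) {
    abort("camera file: missing or duplicate camera_id",
          class = "hooploc_schema_error")
  }
  dplyr::bind_rows(purrr::map(recs, function(r) {
    lam <- unlist(r$lambdas)
    if (length(lam) != 11) {
      abort(paste0("camera ", r$camera_id, ": expected 11 lambdas, got ",
                   length(lam)),
            class = "hooploc_schema_error")
    }
    new_camera(r$camera_id, lam)
  }))
}

#' Read and write interest-area polygons
#'
#' JSON array of `{"camera_id": int, "vertices": [[x, y], ...]}` with at
#' least three vertices per polygon.
#'
#' @param areas named list (by camera_id) of polygon matrices / data frames
#'   with columns `x`, `y`.
#' @param path file path.
#' @return `load_interest_areas()` returns a named list of tibbles keyed by
#'   camera id.
#' @export
save_interest_areas <- function(areas, path) {
  recs <- purrr::imap(areas, function(poly, id) {
    p <- as.data.frame(poly)
    list(camera_id = as.integer(id),
         vertices = purrr::map(seq_len(nrow(p)), function(i)
           c(p$x[i], p$y[i])))
  })
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_interest_areas
#' @export
load_interest_areas <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list()
  for (r in recs) {
    v <- do.call(rbind, purrr::map(r$vertices, unlist))
    if (is.null(v) || nrow(v) < 3) {
      abort("interest area polygons need at least 3 vertices",
            class = "hooploc_schema_error")
    }
    out[[as.character(r$camera_id)]] <- tibble(x = v[, 1], y = v[, 2])
  }
  out
}

# deterministic, locale-independent CSV writers (C numeric format, header row)
.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

.read_csv <- function(path, required) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "hooploc_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(required %in% names(df))) {
    abort(paste0(basename(path), ": missing columns ",
                 paste(setdiff(required, names(df)), collapse = ", ")),
          class = "hooploc_schema_error")
  }
  tibble::as_tibble(df)
}

#' Tabular artifact readers and writers
#'
#' All tabular artifacts are headered CSV: correspondences
#' (`camera_id,X,Y,Z,x,y`; metres and pixels), detections
#' (`frame_id,camera_id,x,y,score`), localizations
#' (`frame_id,label,method,X,Y,Z,n_points,score`) and ground truth
#' (`frame_id,label,X,Y,Z`).
#'
#' @param df data frame to write.
#' @param path file path.
#' @name hooploc_csv
NULL

#' @rdname hooploc_csv
#' @export
read_correspondences <- function(path)
  .read_csv(path, c("camera_id", "X", "Y", "Z", "x", "y"))

#' @rdname hooploc_csv
#' @export
write_detections <- function(df, path)
  .write_csv(df[, intersect(c("frame_id", "camera_id", "x", "y", "score"),
                            names(df))], path)

#' @rdname hooploc_csv
#' @export
read_detections <- function(path)
  .read_csv(path, c("frame_id", "camera_id", "x", "y"))

#' @rdname hooploc_csv
#' @export
write_localizations <- function(df, path)
  .write_csv(df[, c("frame_id", "label", "method", "X", "Y", "Z",
                    "n_points", "score")], path)

#' @rdname hooploc_csv
#' @export
read_localizations <- function(path)
  .read_csv(path, c("frame_id", "label", "method", "X", "Y", "Z"))

#' @rdname hooploc_csv
#' @export
write_truth <- function(df, path)
  .write_csv(df[, c("frame_id", "label", "X", "Y", "Z")], path)

#' @rdname hooploc_csv
#' @export
read_truth <- function(path)
  .read_csv(path, c("frame_id", "label", "X", "Y", "Z"))

#' Load a YAML run configuration
#'
#' Recognized keys: `tau_px`, `h_min`, `h_max`, `mean_height`,
#' `max_players` (forwarded to [loc_config()]) and `seed`.
#'
#' @param path YAML file.
#' @return list with elements `loc` (a [loc_config()]) and `seed`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  keys <- intersect(names(y), c("tau_px", "h_min", "h_max",
                                "mean_height", "max_players"))
  list(loc = do.call(loc_config, y[keys]),
       seed = y$seed %||% 1L)
}
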