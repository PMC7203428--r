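`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a local RNG state: seeds deterministically, restores the
# caller's .Random.seed afterwards so simulators never perturb user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# point-in-polygon gate; poly is a data frame / matrix with columns x, y
points_in_polygon <- function(x, y, poly) {
  if (length(x) == 0) return(logical(0))
  bnd <- list(x = c(poly[, 1], poly[1, 1]), y = c(poly[, 2], poly[1, 2]))
  mgcv::in.out(cbind(bnd$x, bnd$y), cbind(x, y))
}
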