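# Internal helpers: seeded RNG hygiene, validation errors, numerics.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded package
#' operations never disturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed and a set of tags
#'
#' Deterministic rolling-hash derivation so that every stage of a study run
#' (per mass, observer, session, structural image) gets an independent,
#' reproducible seed from one master seed. Result is always in [1, 2^31 - 2].
#'
#' @param master integer master seed.
#' @param ... character or integer tags identifying the stage.
#' @return integer seed.
#' @export
derive_seed <- function(master, ...) {
  tags <- unlist(lapply(list(...), as.character))
  h <- as.numeric(master) %% 2147483647
  for (tag in tags) {
    for (cp in utf8ToInt(tag)) {
      h <- (h * 31 + cp) %% 2147483647
    }
    h <- (h * 131 + 7) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

# Validation error with the offending field recorded, so callers and tests
# can assert on which constraint fired.
stop_validation <- function(field, msg) {
  stop(structure(
    class = c("dscrepro_validation_error", "error", "condition"),
    list(message = sprintf("[%s] %s", field, msg), call = sys.call(-1),
         field = field)
  ))
}

is_validation_error <- function(e) inherits(e, "dscrepro_validation_error")

# Trapezoidal integral of y over (possibly nonuniform) time grid t.
# y may be a vector or a matrix with time along rows (one column per voxel).
trapz_time <- function(y, t) {
  nt <- length(t)
  dt <- diff(t)
  if (is.matrix(y)) {
    stopifnot(nrow(y) == nt)
    colSums((y[-1, , drop = FALSE] + y[-nt, , drop = FALSE]) * (dt / 2))
  } else {
    stopifnot(length(y) == nt)
    sum((y[-1] + y[-nt]) * (dt / 2))
  }
}

# Cumulative trapezoidal integral from t[1]; same shape as input.
cumtrapz_time <- function(y, t) {
  nt <- length(t)
  dt <- diff(t)
  if (is.matrix(y)) {
    inc <- (y[-1, , drop = FALSE] + y[-nt, , drop = FALSE]) * (dt / 2)
    rbind(0, apply(inc, 2, cumsum))
  } else {
    c(0, cumsum((y[-1] + y[-nt]) * (dt / 2)))
  }
}

# Voxel-center coordinates (mm) along one axis: centers at (i - 0.5) * vs.
axis_centers_mm <- function(n, vs) (seq_len(n) - 0.5) * vs

# mm coordinates of every voxel center as an n x 3 matrix, column-major order.
grid_centers_mm <- function(grid_shape, voxel_size_mm) {
  xs <- axis_centers_mm(grid_shape[1], voxel_size_mm[1])
  ys <- axis_centers_mm(grid_shape[2], voxel_size_mm[2])
  zs <- axis_centers_mm(grid_shape[3], voxel_size_mm[3])
  cbind(
    x = rep(xs, times = grid_shape[2] * grid_shape[3]),
    y = rep(rep(ys, each = grid_shape[1]), times = grid_shape[3]),
    z = rep(zs, each = grid_shape[1] * grid_shape[2])
  )
}

# Sample (n-1)-denominator SD that returns 0 (not NA) for a single value.
sample_sd <- function(x) if (length(x) < 2) 0 else stats::sd(x)
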