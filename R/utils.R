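# internal geometry helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps * 100) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula; `axis` need not be unit length.
#'
#' @param axis numeric length-3 rotation axis.
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @return a 3x3 rotation matrix.
#' @keywords internal
rotation_about <- function(axis, angle_deg) {
  u <- unitize(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# angle between two vectors in degrees, in [0, 180]
angle_between <- function(a, b) {
  ca <- sum(unitize(a) * unitize(b))
  rad2deg(acos(max(-1, min(1, ca))))
}

# draw k integer seeds below 2^31 from a named stream
derive_seeds <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, k)
}

# evaluate fn with a local RNG state
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
}
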