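#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package internals
#' do not disturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' @keywords internal
stop_invalid <- function(...) stop(..., call. = FALSE)

# Population (divisor n) standard deviation; returns 0 for constant input.
#' @keywords internal
pop_sd <- function(x) {
  n <- length(x)
  if (n < 1L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# Z-score with divisor-n sd; constant vectors map to all zeros.
#' @keywords internal
pop_zscore <- function(x) {
  s <- pop_sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Rotation about the vertical (z) axis
#'
#' Returns the 3x3 matrix that rotates row-vector coordinates by `theta`
#' radians about z, in the right-multiplication convention used throughout
#' the package (`pose %*% R`).
#'
#' @param theta Yaw angle in radians.
#' @return A 3x3 rotation matrix.
#' @export
yaw_matrix <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), nrow = 3, byrow = TRUE)
}

# Check that R is a proper rotation (orthogonal, det +1).
#' @keywords internal
is_rotation <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

# Yaw angle encoded in a rotation matrix built by yaw_matrix().
#' @keywords internal
yaw_of <- function(R) atan2(R[1, 2], R[1, 1])
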