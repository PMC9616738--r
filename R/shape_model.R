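# Statistical shape model: generalized Procrustes alignment of annotated
# 3D poses followed by probabilistic PCA. The model is the prior used by the
# robust pose fitter: mean pose, orthonormal eigenposes, eigenvalues, and an
# isotropic residual noise variance.

# Orthogonal Procrustes: rotation R (right multiplication, optionally
# yaw-only) and translation t minimizing ||X - M %*% R - t||_F^2.
# Returns list(R, t). M and X are Np x 3 with matching rows.
#' @keywords internal
rigid_procrustes <- function(M, X, rotation = c("full", "yaw")) {
  rotation <- match.arg(rotation)
  cm <- colMeans(M); cx <- colMeans(X)
  Mt <- sweep(M, 2, cm); Xt <- sweep(X, 2, cx)
  S <- crossprod(Mt, Xt)                      # 3x3; maximize tr(R' S)
  if (rotation == "yaw") {
    R <- yaw_matrix(atan2(S[1, 2] - S[2, 1], S[1, 1] + S[2, 2]))
  } else {
    sv <- svd(S)
    d <- sign(det(sv$u %*% t(sv$v)))
    R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  }
  list(R = R, t = cx - as.vector(cm %*% R))
}

#' Generalized Procrustes alignment (scale fixed at 1)
#'
#' Iteratively rotates and translates every pose onto the running mean pose,
#' with the scale parameter fixed to 1, until the mean pose stabilizes.
#' The reference frame is anchored at the first pose.
#'
#' @param poses A [pose_set()] (all poses must be complete).
#' @param tol Convergence tolerance on the root-mean-square change of the
#'   mean pose between iterations (default `1e-8`).
#' @param max_iter Maximum number of sweeps (default 50).
#' @param rotation `"full"` (classical superimposition, default) or
#'   `"yaw"`: align only about the vertical axis, keeping gravity-
#'   referenced deformations such as body arch in shape space. The
#'   pipeline trains its model with `"yaw"` to match the yaw-only pose
#'   fitter.
#' @return A list with `aligned` (a `pose_set`), `mean` (the converged
#'   `Np x 3` mean pose), and `iterations`.
#' @export
procrustes_align <- function(poses, tol = 1e-8, max_iter = 50L,
                             rotation = c("full", "yaw")) {
  rotation <- match.arg(rotation)
  ps <- if (inherits(poses, "pose_set")) poses else pose_set(poses)
  if (any(!ps$valid)) stop_invalid("procrustes_align requires complete poses")
  n <- n_poses(ps)
  if (n < 2L) stop_invalid("need at least 2 poses to align")
  arr <- ps$poses
  sizes <- vapply(seq_len(n), function(i) {
    p <- arr[i, , ]; sum(sweep(p, 2, colMeans(p))^2)
  }, numeric(1))
  if (all(sizes < 1e-24)) stop_invalid("degenerate input: all poses have zero spread")
  # centre each pose at the origin; anchor orientation at pose 1
  for (i in seq_len(n)) arr[i, , ] <- sweep(arr[i, , ], 2, colMeans(arr[i, , ]))
  mean_pose <- arr[1, , ]
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      rt <- rigid_procrustes(arr[i, , ], mean_pose, rotation = rotation)
      arr[i, , ] <- arr[i, , ] %*% rt$R
    }
    new_mean <- apply(arr, c(2, 3), mean)
    delta <- sqrt(mean((new_mean - mean_pose)^2))
    mean_pose <- new_mean
    if (delta < tol || iter >= max_iter) break
  }
  dimnames(mean_pose) <- list(ps$landmarks, c("x", "y", "z"))
  list(aligned = pose_set(arr, ps$landmarks), mean = mean_pose,
       iterations = iter)
}

#' Train the statistical shape model by probabilistic PCA
#'
#' Fits PPCA to Procrustes-aligned poses flattened landmark-major
#' (x, y, z interleaved per landmark). The retained eigenposes are the top
#' sample-covariance eigenvectors, the eigenvalues are their variances, and
#' the residual noise variance is the maximum-likelihood estimate: the mean
#' of the discarded eigenvalues.
#'
#' @param aligned A `pose_set` of aligned poses (see [procrustes_align()]),
#'   or the list returned by `procrustes_align`.
#' @param n_eigenposes Number of eigenposes to retain. `NULL` (default)
#'   keeps the smallest count explaining at least 95% of total variance,
#'   with a floor of 3 so the first three behavioural scores always exist.
#' @return An object of class `ssm` with fields `mean` (Np x 3), `eigenposes`
#'   (K x Np x 3 array), `eigenvalues`, `sigma2`, `total_var`,
#'   `n_eigenposes`, `landmarks`.
#' @export
train_ssm <- function(aligned, n_eigenposes = NULL) {
  if (is.list(aligned) && !inherits(aligned, "pose_set") &&
      !is.null(aligned$aligned)) aligned <- aligned$aligned
  ps <- aligned
  n <- n_poses(ps); np <- length(ps$landmarks); d <- 3L * np
  if (!is.null(n_eigenposes) && n_eigenposes >= d)
    stop_invalid("n_eigenposes must be < 3 * number of landmarks (", d, ")")
  Xf <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) Xf[i, ] <- flatten_pose(ps$poses[i, , ])
  mu <- colMeans(Xf)
  if (is.null(n_eigenposes)) {
    ev0 <- eigen(stats::cov(Xf), symmetric = TRUE)
    frac <- cumsum(ev0$values) / sum(ev0$values)
    n_eigenposes <- max(3L, which(frac >= 0.95)[1])
    ev <- ev0
  } else {
    ev <- eigen(stats::cov(Xf), symmetric = TRUE)
  }
  if (n <= n_eigenposes)
    stop_invalid("need more poses (", n, ") than eigenposes (", n_eigenposes, ")")
  k <- as.integer(n_eigenposes)
  lambda <- ev$values[seq_len(k)]
  sigma2 <- max(mean(ev$values[(k + 1L):d]), 0)
  P <- array(NA_real_, dim = c(k, np, 3L))
  for (i in seq_len(k)) P[i, , ] <- unflatten_pose(ev$vectors[, i], ps$landmarks)
  # PCA signs are arbitrary; fix a deterministic orientation so downstream
  # semantics (body arch raises the nose, bends point leftward) are stable:
  # orient by the nose's vertical loading when it is substantial, otherwise
  # by the largest-magnitude loading
  nose_i <- match("nose", ps$landmarks)
  for (i in seq_len(k)) {
    v <- P[i, , ]
    s <- 0
    if (!is.na(nose_i) && abs(v[nose_i, 3]) > 0.1 * max(abs(v)))
      s <- sign(v[nose_i, 3])
    if (s == 0) s <- sign(v[which.max(abs(v))])
    if (s < 0) P[i, , ] <- -v
  }
  structure(list(mean = unflatten_pose(mu, ps$landmarks),
                 eigenposes = P,
                 eigenvalues = lambda,
                 sigma2 = sigma2,
                 total_var = sum(ev$values),
                 n_eigenposes = k,
                 landmarks = ps$landmarks),
            class = "ssm")
}

#' @export
print.ssm <- function(x, ...) {
  cat(sprintf("<ssm> %d landmarks, %d eigenposes; sigma2 = %.4g\n",
              length(x$landmarks), x$n_eigenposes, x$sigma2))
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * explained_variance(x)), collapse = " "), "\n")
  invisible(x)
}

#' Synthesize a pose from the shape model
#'
#' Builds the pose `(mean + sum_i b_i P_i) %*% R + T` where `T` replicates
#' the translation vector `t` across landmarks.
#'
#' @param model An `ssm`.
#' @param b Shape-score vector (length `n_eigenposes`; shorter vectors are
#'   zero-padded).
#' @param R 3x3 proper rotation matrix (default identity), or a single yaw
#'   angle in radians.
#' @param t Translation 3-vector (default origin).
#' @return An `Np x 3` pose matrix.
#' @export
synthesize_pose <- function(model, b = numeric(0), R = diag(3), t = c(0, 0, 0)) {
  stopifnot(inherits(model, "ssm"))
  if (length(R) == 1L) R <- yaw_matrix(R)
  if (!is_rotation(R)) stop_invalid("R is not a proper rotation matrix")
  k <- model$n_eigenposes
  if (length(b) > k) stop_invalid("length(b) exceeds n_eigenposes")
  b <- c(b, rep(0, k - length(b)))
  shape <- model$mean
  for (i in seq_len(k)) if (b[i] != 0) shape <- shape + b[i] * model$eigenposes[i, , ]
  out <- shape %*% R + matrix(t, nrow(shape), 3, byrow = TRUE)
  dimnames(out) <- list(model$landmarks, c("x", "y", "z"))
  out
}

#' Per-eigenpose explained variance fractions
#'
#' Each retained eigenvalue divided by the total training variance
#' (retained eigenvalues plus the residual mass `(3 Np - K) * sigma2`).
#'
#' @param model An `ssm`.
#' @return Numeric vector of fractions, non-increasing, summing to at most 1.
#' @export
explained_variance <- function(model) {
  stopifnot(inherits(model, "ssm"))
  model$eigenvalues / model$total_var
}

#' Write / read a shape model as JSON
#'
#' Plain-text serialization used by the pipeline; exact to double precision.
#'
#' @param model An `ssm`.
#' @param path File path.
#' @return `read_ssm` returns an `ssm`; `write_ssm` returns `path` invisibly.
#' @export
write_ssm <- function(model, path) {
  stopifnot(inherits(model, "ssm"))
  obj <- list(landmarks = model$landmarks,
              mean = as.vector(model$mean),
              eigenposes = lapply(seq_len(model$n_eigenposes),
                                  function(i) as.vector(model$eigenposes[i, , ])),
              eigenvalues = model$eigenvalues,
              sigma2 = model$sigma2,
              total_var = model$total_var)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ssm
#' @export
read_ssm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  np <- length(obj$landmarks); k <- length(obj$eigenvalues)
  P <- array(NA_real_, dim = c(k, np, 3L))
  for (i in seq_len(k))
    P[i, , ] <- matrix(if (is.list(obj$eigenposes)) obj$eigenposes[[i]]
                       else obj$eigenposes[i, ], np, 3)
  structure(list(mean = matrix(obj$mean, np, 3,
                               dimnames = list(obj$landmarks, c("x", "y", "z"))),
                 eigenposes = P,
                 eigenvalues = obj$eigenvalues,
                 sigma2 = obj$sigma2,
                 total_var = obj$total_var,
                 n_eigenposes = k,
                 landmarks = obj$landmarks),
            class = "ssm")
}
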