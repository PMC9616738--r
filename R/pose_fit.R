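# Robust per-frame pose fitting: minimize the regularized shape-model cost
#   C(b, R, T) = sigma^-2 ||X - (mean + sum_i b_i P_i) R - T||_F^2
#                + alpha * sum_i b_i^2 / lambda_i
# over the valid landmarks by alternating exact minimization in (R, t)
# (rigid Procrustes) and in b (closed-form ridge), followed by an iterative
# chi-square outlier-removal loop and model-based in-fill of all landmarks.

#' Fit the shape model to a (partially observed) 3D pose
#'
#' Alternating minimization of the regularized cost: given `b`, the rigid
#' parameters are the Procrustes optimum; given `(R, t)`, the scores solve a
#' ridge system with per-mode penalty `alpha / lambda_i`. Iterates until the
#' cost changes by less than `tol` (default `1e-8`) or `max_iter` is
#' reached. Both half-steps are exact, so the cost is non-increasing.
#'
#' @param X `Np x 3` observed pose, `NA` rows allowed.
#' @param model An `ssm`.
#' @param alpha Regularization weight (default 0.01).
#' @param valid Optional logical mask of usable landmarks (default: rows
#'   with finite coordinates).
#' @param rotation `"yaw"` (default) restricts `R` to rotations about the
#'   vertical axis so up/down deformations stay in shape space; `"full"`
#'   allows any proper rotation.
#' @param tol,max_iter Convergence controls.
#' @param init Optional list with starting `R` and `t`.
#' @return An object of class `pose_fit`: `b`, `R`, `t`, `yaw`, `cost`,
#'   `data_term`, `per_landmark` (data-term contribution of each valid
#'   landmark, `NA` elsewhere), `valid`, `iterations`, `converged`.
#' @export
fit_pose <- function(X, model, alpha = 0.01, valid = NULL,
                     rotation = c("yaw", "full"), tol = 1e-8,
                     max_iter = 100L, init = NULL) {
  rotation <- match.arg(rotation)
  stopifnot(inherits(model, "ssm"))
  if (alpha <= 0) stop_invalid("invalid-argument: alpha must be positive")
  np <- length(model$landmarks)
  X <- as.matrix(X)
  if (nrow(X) != np) stop_invalid("pose must have ", np, " rows")
  if (is.null(valid)) valid <- stats::complete.cases(X)
  valid <- valid & stats::complete.cases(X)
  if (sum(valid) < 4L) stop_invalid("underdetermined-pose: fewer than 4 valid landmarks")
  k <- model$n_eigenposes
  lam <- model$eigenvalues
  s2i <- 1 / model$sigma2
  Xv <- X[valid, , drop = FALSE]
  mu_v <- model$mean[valid, , drop = FALSE]
  # K x (3 nv) matrix of flattened valid-landmark eigenposes
  Pv <- matrix(NA_real_, k, 3 * sum(valid))
  for (i in seq_len(k)) Pv[i, ] <- flatten_pose(model$eigenposes[i, valid, ])
  G <- tcrossprod(Pv)                                  # Gram matrix on valid rows
  ridge <- diag(alpha / lam, k) / s2i                  # scaled into the data term
  b <- rep(0, k)
  shape_v <- mu_v
  if (is.null(init)) {
    rt <- rigid_procrustes(shape_v, Xv, rotation)
  } else {
    rt <- init
  }
  cost_of <- function(b, R, t, shape_v) {
    resid <- Xv - shape_v %*% R - matrix(t, nrow(Xv), 3, byrow = TRUE)
    s2i * sum(resid^2) + alpha * sum(b^2 / lam)
  }
  cost <- cost_of(b, rt$R, rt$t, shape_v)
  iter <- 0L; converged <- FALSE
  repeat {
    iter <- iter + 1L
    # b-step: back-rotate data into shape space, solve the ridge system
    Y <- sweep(Xv, 2, rt$t) %*% t(rt$R) - mu_v
    g <- Pv %*% flatten_pose(Y)
    b <- as.vector(solve(G + ridge, g))
    shape_v <- mu_v + unflatten_pose(as.vector(crossprod(Pv, b)),
                                     model$landmarks[valid])
    # rigid step
    rt <- rigid_procrustes(shape_v, Xv, rotation)
    new_cost <- cost_of(b, rt$R, rt$t, shape_v)
    if (abs(cost - new_cost) < tol) { cost <- new_cost; converged <- TRUE; break }
    cost <- new_cost
    if (iter >= max_iter) break
  }
  resid <- Xv - shape_v %*% rt$R - matrix(rt$t, nrow(Xv), 3, byrow = TRUE)
  per_lm <- rep(NA_real_, np)
  per_lm[valid] <- s2i * rowSums(resid^2)
  names(per_lm) <- model$landmarks
  structure(list(b = b, R = rt$R, t = rt$t, yaw = yaw_of(rt$R),
                 cost = cost, data_term = s2i * sum(resid^2),
                 per_landmark = per_lm, valid = valid,
                 iterations = iter, converged = converged),
            class = "pose_fit")
}

#' @export
print.pose_fit <- function(x, ...) {
  cat(sprintf("<pose_fit> cost %.4g (data %.4g), %d/%d landmarks, %d iter%s\n",
              x$cost, x$data_term, sum(x$valid), length(x$valid), x$iterations,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Chi-square outlier rejection and model-based in-fill
#'
#' Implements the robust correction loop: while the fitted cost exceeds the
#' inverse chi-square CDF at `chi2_prob` with `3 * Np` degrees of freedom
#' (`Np` = current number of valid landmarks), the valid landmark with the
#' largest data-term contribution is removed, `Np` decremented and the pose
#' refitted. Removal stops at a floor of `np_floor` landmarks; if the cost
#' is still above threshold there, the frame is flagged low-confidence. The
#' corrected pose is the model synthesis at the converged parameters, which
#' fills in missing and rejected landmarks.
#'
#' @param X `Np x 3` observed pose (NAs allowed).
#' @param model An `ssm`.
#' @param chi2_prob Chi-square probability level (default 0.99).
#' @param alpha,rotation,tol,max_iter Passed to [fit_pose()].
#' @param np_floor Minimum number of landmarks kept (default 6).
#' @return A `pose_fit` with additional fields `corrected` (full `Np x 3`
#'   synthesized pose), `inliers` (logical mask of retained landmarks),
#'   `removed` (names in removal order), `threshold`, `low_confidence`.
#' @export
reject_outliers_and_fill <- function(X, model, chi2_prob = 0.99, alpha = 0.01,
                                     rotation = "yaw", tol = 1e-8,
                                     max_iter = 100L, np_floor = 6L) {
  if (chi2_prob <= 0 || chi2_prob >= 1)
    stop_invalid("chi2_prob must be in (0, 1)")
  fit <- fit_pose(X, model, alpha = alpha, rotation = rotation,
                  tol = tol, max_iter = max_iter)
  removed <- character(0)
  repeat {
    np_valid <- sum(fit$valid)
    threshold <- stats::qchisq(chi2_prob, df = 3 * np_valid)
    if (fit$cost <= threshold || np_valid <= np_floor) break
    worst <- which.max(fit$per_landmark)
    removed <- c(removed, model$landmarks[worst])
    new_valid <- fit$valid
    new_valid[worst] <- FALSE
    fit <- fit_pose(X, model, alpha = alpha, valid = new_valid,
                    rotation = rotation, tol = tol, max_iter = max_iter)
  }
  np_valid <- sum(fit$valid)
  threshold <- stats::qchisq(chi2_prob, df = 3 * np_valid)
  fit$corrected <- synthesize_pose(model, fit$b, fit$R, fit$t)
  fit$inliers <- fit$valid
  fit$removed <- removed
  fit$threshold <- threshold
  fit$low_confidence <- fit$cost > threshold
  fit
}

#' Reconstruct a corrected 3D pose series from multi-view observations
#'
#' Per frame: DLT triangulation, robust model fit with outlier rejection,
#' and model-based in-fill, yielding a complete 11-landmark series plus fit
#' diagnostics. Frames with fewer than 4 triangulated landmarks are imputed
#' from the model prior (`b = 0`) at the last known rigid parameters and
#' flagged.
#'
#' @param observations2d Landmark observation table (see [triangulate()]).
#' @param cameras List of `camera_model`s.
#' @param model An `ssm`.
#' @param epochs Epoch window matrix (start_s, end_s); each frame is
#'   assigned to the epoch containing its timestamp.
#' @param frame_rate Frames per second (default 15).
#' @param frame_times Optional timestamps (s) for the sorted unique frames;
#'   defaults to `(frame - 1) / frame_rate`, which is only correct for
#'   gap-free recordings.
#' @param chi2_prob,alpha,rotation,np_floor Fitting controls (see
#'   [reject_outliers_and_fill()]).
#' @return A list of class `reconstruction`: `poses` (T x Np x 3 corrected
#'   array), `fits` (per-frame data frame: frame, epoch, time_s, b1..bK,
#'   yaw, tx, ty, tz, cost, np_used, low_confidence, imputed), `inliers`
#'   (T x Np logical), `triangulated` (the raw `triangulated_series`).
#' @export
reconstruct_series <- function(observations2d, cameras, model, epochs = NULL,
                               frame_rate = 15, chi2_prob = 0.99,
                               alpha = 0.01, rotation = "yaw", np_floor = 6L,
                               frame_times = NULL) {
  tri <- triangulate(observations2d, cameras, model$landmarks)
  nT <- length(tri$frames); np <- length(model$landmarks)
  k <- model$n_eigenposes
  poses <- array(NA_real_, dim = c(nT, np, 3L),
                 dimnames = list(NULL, model$landmarks, c("x", "y", "z")))
  inliers <- matrix(FALSE, nT, np, dimnames = list(NULL, model$landmarks))
  fits <- data.frame(frame = tri$frames)
  bmat <- matrix(NA_real_, nT, k)
  yaw <- numeric(nT); tmat <- matrix(NA_real_, nT, 3)
  cost <- numeric(nT); np_used <- integer(nT)
  lowc <- logical(nT); imput <- logical(nT)
  last_rt <- list(R = diag(3), t = c(0, 0, 0))
  for (i in seq_len(nT)) {
    Xi <- tri$coords[i, , ]
    if (sum(tri$valid[i, ]) < 4L) {
      # all-(or nearly-)missing frame: impute from the model prior
      bmat[i, ] <- 0
      yaw[i] <- yaw_of(last_rt$R); tmat[i, ] <- last_rt$t
      poses[i, , ] <- synthesize_pose(model, rep(0, k), last_rt$R, last_rt$t)
      cost[i] <- NA_real_; np_used[i] <- sum(tri$valid[i, ])
      lowc[i] <- TRUE; imput[i] <- TRUE
      next
    }
    fit <- reject_outliers_and_fill(Xi, model, chi2_prob = chi2_prob,
                                    alpha = alpha, rotation = rotation,
                                    np_floor = np_floor)
    poses[i, , ] <- fit$corrected
    inliers[i, ] <- fit$inliers
    bmat[i, ] <- fit$b
    yaw[i] <- fit$yaw; tmat[i, ] <- fit$t
    cost[i] <- fit$cost; np_used[i] <- sum(fit$valid)
    lowc[i] <- fit$low_confidence
    last_rt <- list(R = fit$R, t = fit$t)
  }
  time_s <- if (is.null(frame_times)) (fits$frame - 1) / frame_rate else {
    if (length(frame_times) != nT)
      stop_invalid("frame_times must have one entry per frame")
    frame_times
  }
  epoch <- if (is.null(epochs)) rep(1L, nT) else {
    ep <- rep(NA_integer_, nT)
    for (e in seq_len(nrow(epochs)))
      ep[time_s >= epochs[e, 1] - 1e-9 & time_s < epochs[e, 2] - 1e-9] <- e
    ep
  }
  colnames(bmat) <- paste0("b", seq_len(k))
  fits <- cbind(fits, data.frame(epoch = epoch, time_s = time_s), bmat,
                data.frame(yaw = yaw, tx = tmat[, 1], ty = tmat[, 2],
                           tz = tmat[, 3], cost = cost, np_used = np_used,
                           low_confidence = lowc, imputed = imput))
  structure(list(poses = poses, fits = fits, inliers = inliers,
                 triangulated = tri, model = model, frame_rate = frame_rate,
                 epochs = epochs),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("<reconstruction> %d frames; %.1f%% landmarks inlying; %.1f%% frames flagged\n",
              nrow(x$fits), 100 * mean(x$inliers),
              100 * mean(x$fits$low_confidence)))
  invisible(x)
}
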