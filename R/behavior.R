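# Behavioural state variables: six postures (head elevation, head
# left-right, body arch, body left-right, body lunge, rearing), their six
# temporal derivatives, locomotion and overall motion; all z-scored per
# session before any coupling analysis.

#' @keywords internal
posture_vars <- function() c("Hel", "Hlr", "Bar", "Blr", "Blu", "Re")
#' @keywords internal
movement_vars <- function() c("dHel", "dHlr", "dBar", "dBlr", "dBlu", "dRe", "Lc", "OM")
#' @keywords internal
state_vars <- function() c(posture_vars(), movement_vars())

#' Compute posture variables from fitted poses
#'
#' Head elevation (`Hel`, degrees) is the elevation of the neck-to-nose
#' vector above the horizontal plane. Head left-right (`Hlr`, degrees) is
#' the signed horizontal angle between the body midline (tail base to neck)
#' and the neck-to-nose vector, positive leftward (counter-clockwise seen
#' from above). Body arch, left-right and lunge (`Bar`, `Blr`, `Blu`) are
#' the first three shape scores; rearing (`Re`) is the vertical translation.
#'
#' @param fits Data frame with columns `b1`, `b2`, `b3`, `tz` (one row per
#'   frame), e.g. the fit table from [reconstruct_series()].
#' @param poses `T x Np x 3` array of corrected poses.
#' @return Data frame of the six posture series; frames where nose and neck
#'   coincide yield `NA` angles.
#' @export
compute_postures <- function(fits, poses) {
  lm <- dimnames(poses)[[2]]
  nose <- poses[, match("nose", lm), , drop = TRUE]
  neck <- poses[, match("neck", lm), , drop = TRUE]
  tail <- poses[, match("tail_base", lm), , drop = TRUE]
  if (is.null(dim(nose))) { nose <- matrix(nose, 1); neck <- matrix(neck, 1); tail <- matrix(tail, 1) }
  h <- nose - neck                       # neck -> nose
  m <- neck - tail                       # midline: tail base -> neck
  hn <- sqrt(rowSums(h^2))
  hel <- ifelse(hn < 1e-9, NA_real_, asin(pmin(pmax(h[, 3] / hn, -1), 1)) * 180 / pi)
  cross_z <- m[, 1] * h[, 2] - m[, 2] * h[, 1]
  dot_xy <- m[, 1] * h[, 1] + m[, 2] * h[, 2]
  hlr <- ifelse(hn < 1e-9 | (abs(cross_z) < 1e-12 & abs(dot_xy) < 1e-12),
                NA_real_, atan2(cross_z, dot_xy) * 180 / pi)
  data.frame(Hel = hel, Hlr = hlr, Bar = fits$b1, Blr = fits$b2,
             Blu = fits$b3, Re = fits$tz)
}

#' Compute movement variables
#'
#' Temporal derivatives of the six postures (forward difference between
#' consecutive frames times the frame rate, masked at epoch starts),
#' locomotion (`Lc`: planar displacement of the body centre per frame step)
#' and overall motion (`OM`: summed 3D landmark displacement per frame
#' step).
#'
#' @param postures Data frame from [compute_postures()].
#' @param fits Fit table with `tx`, `ty` (body-centre translation).
#' @param poses `T x Np x 3` corrected pose array.
#' @param epoch Integer epoch index per frame.
#' @return Data frame of the eight movement series (`NA` at epoch starts).
#' @export
compute_movements <- function(postures, fits, poses, epoch) {
  n <- nrow(postures)
  first <- c(TRUE, epoch[-1] != epoch[-n])
  fr_diff <- function(x) {
    d <- c(NA_real_, diff(x))
    d[first] <- NA_real_
    d
  }
  fr <- attr(postures, "frame_rate")
  if (is.null(fr)) fr <- 15
  dv <- lapply(postures[posture_vars()], function(x) fr_diff(x) * fr)
  names(dv) <- paste0("d", posture_vars())
  lc <- sqrt(fr_diff(fits$tx)^2 + fr_diff(fits$ty)^2)
  disp <- array(NA_real_, dim = dim(poses))
  disp[-1, , ] <- poses[-1, , , drop = FALSE] - poses[-n, , , drop = FALSE]
  om <- rowSums(sqrt(apply(disp^2, c(1, 2), sum)))
  om[first] <- NA_real_
  out <- as.data.frame(dv)
  out$Lc <- lc
  out$OM <- om
  out
}

# Full state (postures + movements) for a fit table, pose array and epochs.
#' @keywords internal
compute_state <- function(fits, poses, epochs, frame_rate) {
  post <- compute_postures(fits, poses)
  attr(post, "frame_rate") <- frame_rate
  mov <- compute_movements(post, fits, poses, fits$epoch)
  data_ <- cbind(data.frame(frame = fits$frame, epoch = fits$epoch,
                            time_s = fits$time_s), post, mov)
  structure(list(data = data_, epochs = epochs, frame_rate = frame_rate,
                 zscored = FALSE, flags = character(0)),
            class = "behavioral_state")
}

#' Assemble a behavioural state object
#'
#' @param fits Per-frame fit table (`frame`, `epoch`, `time_s`, `b1..b3`,
#'   `tx`, `ty`, `tz`).
#' @param poses Corrected `T x Np x 3` pose array.
#' @param epochs Epoch window matrix (start_s, end_s).
#' @param frame_rate Frames per second.
#' @return An un-z-scored `behavioral_state`.
#' @export
behavioral_state <- function(fits, poses, epochs, frame_rate = 15) {
  compute_state(fits, poses, epochs, frame_rate)
}

#' Z-score the behavioural state
#'
#' Each variable is standardized over its unmasked frames (session-wide).
#' Zero-variance variables are zero-filled and flagged. Idempotent.
#'
#' @param state A `behavioral_state`.
#' @return The z-scored state (`zscored = TRUE`); flagged constant
#'   variables are listed in `$flags`.
#' @export
zscore_state <- function(state) {
  stopifnot(inherits(state, "behavioral_state"))
  flags <- character(0)
  for (v in state_vars()) {
    x <- state$data[[v]]
    ok <- !is.na(x)
    if (sum(ok) < 2L) stop_invalid("variable ", v, " has fewer than 2 unmasked frames")
    s <- stats::sd(x[ok])
    if (!is.finite(s) || s == 0) {
      state$data[[v]][ok] <- 0
      flags <- c(flags, v)
    } else {
      state$data[[v]][ok] <- (x[ok] - mean(x[ok])) / s
    }
  }
  state$zscored <- TRUE
  state$flags <- unique(c(state$flags, flags))
  state
}

#' @export
print.behavioral_state <- function(x, ...) {
  cat(sprintf("<behavioral_state> %d frames, %d epochs, z-scored: %s\n",
              nrow(x$data), nrow(x$epochs), x$zscored))
  invisible(x)
}

#' Pairwise mutual-information matrix of the state variables
#'
#' Quantile-discretizes every variable and estimates bias-corrected MI for
#' every pair (quadratic extrapolation, see [mutual_information()]);
#' diagonal entries are the bias-corrected entropies.
#'
#' @param state A z-scored `behavioral_state`.
#' @param n_quantiles Discretization levels (default 5).
#' @param seed Seed for the subsampling partitions of the bias correction.
#' @return Symmetric 14x14 matrix (bits).
#' @export
variable_mi_matrix <- function(state, n_quantiles = 5, seed = 1L) {
  stopifnot(inherits(state, "behavioral_state"))
  if (n_quantiles < 2) stop_invalid("n_quantiles must be >= 2")
  vars <- state_vars()
  labs <- lapply(vars, function(v) {
    x <- state$data[[v]]
    lab <- rep(NA_integer_, length(x))
    lab[!is.na(x)] <- quantile_discretize(x[!is.na(x)], n_quantiles)
    lab
  })
  names(labs) <- vars
  k <- length(vars)
  M <- matrix(0, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) {
    xi <- labs[[i]]
    M[i, i] <- corrected_entropy(xi[!is.na(xi)], seed = seed)
    if (i < k) for (j in (i + 1):k) {
      ok <- !is.na(xi) & !is.na(labs[[j]])
      mi <- mutual_information(xi[ok], labs[[j]][ok], seed = seed)
      M[i, j] <- M[j, i] <- mi$mi_corrected
    }
  }
  M
}

#' Hierarchical clustering of the behavioural variables
#'
#' Converts the MI matrix into the dissimilarity `1 - MI / max(off-diag MI)`
#' (negative bias-corrected MI clipped to zero first) and builds a weighted
#' pair-group (WPGMA) agglomerative tree, cut at two clusters (the coarse
#' postures-vs-movements level) and at a finer configurable level.
#'
#' @param mi_matrix Symmetric MI matrix from [variable_mi_matrix()].
#' @param k_fine Number of clusters for the fine cut (default 5).
#' @return List with `tree` (an `hclust`), `cut2`, `cut_fine` (named
#'   membership vectors) and the `distance` matrix used.
#' @export
cluster_variables <- function(mi_matrix, k_fine = 5) {
  if (!isTRUE(all.equal(mi_matrix, t(mi_matrix), tolerance = 1e-8)))
    stop_invalid("schema-error: MI matrix must be symmetric")
  M <- pmax(mi_matrix, 0)
  off <- M; diag(off) <- NA
  mx <- max(off, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) mx <- 1
  D <- 1 - M / mx
  diag(D) <- 0
  tree <- stats::hclust(stats::as.dist(D), method = "mcquitty")
  list(tree = tree,
       cut2 = stats::cutree(tree, k = 2),
       cut_fine = stats::cutree(tree, k = min(k_fine, nrow(M))),
       distance = D)
}
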