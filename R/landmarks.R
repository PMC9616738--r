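#' Canonical body landmark set
#'
#' The eleven landmarks tracked on the mouse body and the implanted
#' head stage. All pose matrices in the package are 11x3 with rows in this
#' order (x forward, y left, z up, units of centimetres in the arena frame).
#'
#' @return Character vector of the 11 landmark names.
#' @export
landmark_names <- function() {
  c("nose", "ear_left", "ear_right", "headstage", "neck",
    "body_centre", "flank_left", "flank_right",
    "hip_left", "hip_right", "tail_base")
}

#' @keywords internal
n_landmarks <- function() 11L

# Flatten an Np x 3 pose landmark-major: (x1, y1, z1, x2, y2, z2, ...).
#' @keywords internal
flatten_pose <- function(pose) as.vector(t(pose))

# Inverse of flatten_pose().
#' @keywords internal
unflatten_pose <- function(v, landmarks = landmark_names()) {
  m <- matrix(v, ncol = 3, byrow = TRUE)
  rownames(m) <- landmarks
  colnames(m) <- c("x", "y", "z")
  m
}

#' Assemble a pose set
#'
#' A pose set is the training container for the shape model: `n` poses of
#' `Np` landmarks with an optional validity mask.
#'
#' @param poses A numeric array `n x Np x 3`, or a list of `Np x 3` matrices.
#' @param landmarks Landmark names (length `Np`).
#' @param valid Optional logical `n x Np` validity mask (default all valid).
#' @return An object of class `pose_set`.
#' @export
pose_set <- function(poses, landmarks = landmark_names(), valid = NULL) {
  if (is.list(poses)) {
    arr <- array(NA_real_, dim = c(length(poses), nrow(poses[[1]]), 3L))
    for (i in seq_along(poses)) arr[i, , ] <- poses[[i]]
    poses <- arr
  }
  stopifnot(length(dim(poses)) == 3L, dim(poses)[3] == 3L)
  if (dim(poses)[2] != length(landmarks))
    stop_invalid("landmark count mismatch: poses have ", dim(poses)[2],
                 " landmarks, names give ", length(landmarks))
  if (is.null(valid)) valid <- matrix(TRUE, dim(poses)[1], dim(poses)[2])
  structure(list(poses = poses, landmarks = landmarks, valid = valid),
            class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("<pose_set> %d poses x %d landmarks (%.1f%% valid)\n",
              dim(x$poses)[1], dim(x$poses)[2], 100 * mean(x$valid)))
  invisible(x)
}

#' @keywords internal
n_poses <- function(ps) dim(ps$poses)[1]
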