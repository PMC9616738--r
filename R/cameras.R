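# Pinhole camera models (3x4 projection matrices, arena cm -> pixels) and
# the default four-view rig used by the synthetic generator.

#' Pinhole camera model
#'
#' @param id Camera identifier (integer or string).
#' @param P 3x4 projection matrix mapping homogeneous world coordinates
#'   (arena units) to homogeneous pixel coordinates.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(id, P) {
  P <- as.matrix(P)
  if (!all(dim(P) == c(3L, 4L))) stop_invalid("P must be 3x4")
  if (qr(P)$rank < 3L) stop_invalid("invalid-camera: projection matrix is rank-deficient")
  structure(list(id = id, P = P), class = "camera_model")
}

#' Project 3D points through a camera
#'
#' @param camera A `camera_model`.
#' @param X `n x 3` matrix of world coordinates.
#' @return `n x 2` matrix of pixel coordinates.
#' @export
project_points <- function(camera, X) {
  X <- rbind(t(as.matrix(X)), 1)            # 4 x n homogeneous
  h <- camera$P %*% X
  t(h[1:2, , drop = FALSE] / rep(h[3, ], each = 2))
}

#' Default four-camera rig
#'
#' Four cameras at azimuths 0/90/180/270 degrees and a common elevation,
#' all aimed at the arena centre. Geometry is a generic overhead-oblique
#' multi-view arrangement, not a calibration of any particular set-up.
#'
#' @param n_cameras Number of views (default 4).
#' @param center Arena centre (cm), default `c(15, 15, 0)` for a 30x30 arena.
#' @param distance Camera distance from the centre (cm).
#' @param elevation_deg Elevation angle above the horizontal plane.
#' @param focal_px Focal length in pixels.
#' @param image_px Image size `c(width, height)` in pixels.
#' @return List of `camera_model`s.
#' @export
default_camera_rig <- function(n_cameras = 4L, center = c(15, 15, 0),
                               distance = 70, elevation_deg = 30,
                               focal_px = 1500, image_px = c(1280, 1024)) {
  if (n_cameras < 2L) stop_invalid("need at least 2 cameras")
  az <- 2 * pi * (seq_len(n_cameras) - 1L) / n_cameras
  el <- elevation_deg * pi / 180
  K <- matrix(c(focal_px, 0, image_px[1] / 2,
                0, focal_px, image_px[2] / 2,
                0, 0, 1), 3, 3, byrow = TRUE)
  lapply(seq_len(n_cameras), function(i) {
    C <- center + distance * c(cos(az[i]) * cos(el), sin(az[i]) * cos(el), sin(el))
    zc <- center - C; zc <- zc / sqrt(sum(zc^2))         # optical axis
    up <- c(0, 0, 1)
    xc <- c(zc[2] * up[3] - zc[3] * up[2],
            zc[3] * up[1] - zc[1] * up[3],
            zc[1] * up[2] - zc[2] * up[1])
    xc <- xc / sqrt(sum(xc^2))
    yc <- c(zc[2] * xc[3] - zc[3] * xc[2],
            zc[3] * xc[1] - zc[1] * xc[3],
            zc[1] * xc[2] - zc[2] * xc[1])
    Rc <- rbind(xc, yc, zc)                              # world -> camera
    camera_model(i, K %*% cbind(Rc, -Rc %*% C))
  })
}

#' Serialize / load camera calibration as JSON
#'
#' @param cameras List of `camera_model`s.
#' @param path File path.
#' @return `read_cameras` returns the list of cameras.
#' @export
write_cameras <- function(cameras, path) {
  obj <- lapply(cameras, function(cm) list(id = cm$id, P = as.vector(cm$P)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cameras
#' @export
read_cameras <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(obj)) {
    lapply(seq_len(nrow(obj)), function(i)
      camera_model(obj$id[i], matrix(unlist(obj$P[i]), 3, 4)))
  } else {
    lapply(obj, function(o) camera_model(o$id, matrix(unlist(o$P), 3, 4)))
  }
}

#' Triangulate multi-view landmark observations
#'
#' Linear least-squares (direct linear transform) triangulation of each
#' landmark in each frame from all cameras that observed it. Landmarks seen
#' by fewer than two views are flagged missing.
#'
#' @param observations2d Data frame with columns `frame`, `camera`,
#'   `landmark`, `x`, `y` (and optionally `confidence`).
#' @param cameras List of `camera_model`s whose `id`s match the `camera`
#'   column.
#' @param landmarks Landmark name order for the output (default
#'   [landmark_names()]).
#' @return A list of class `triangulated_series`: `coords` (T x Np x 3
#'   array, `NA` where missing), `valid` (T x Np logical), `residual_px`
#'   (T x Np mean reprojection residual), `frames` (frame indices).
#' @export
triangulate <- function(observations2d, cameras, landmarks = landmark_names()) {
  obs <- observations2d
  need <- c("frame", "camera", "landmark", "x", "y")
  if (!all(need %in% names(obs)))
    stop_invalid("schema-error: observations need columns ",
                 paste(need, collapse = ", "))
  if (nrow(obs) == 0L) stop_invalid("empty-input: no observations")
  if (!all(obs$landmark %in% landmarks))
    stop_invalid("schema-error: unknown landmark names: ",
                 paste(setdiff(unique(obs$landmark), landmarks), collapse = ", "))
  cam_ids <- vapply(cameras, function(cm) as.character(cm$id), character(1))
  Ps <- lapply(cameras, `[[`, "P")
  names(Ps) <- cam_ids
  frames <- sort(unique(obs$frame))
  np <- length(landmarks)
  coords <- array(NA_real_, dim = c(length(frames), np, 3L),
                  dimnames = list(NULL, landmarks, c("x", "y", "z")))
  valid <- matrix(FALSE, length(frames), np, dimnames = list(NULL, landmarks))
  resid <- matrix(NA_real_, length(frames), np, dimnames = list(NULL, landmarks))
  fidx <- match(obs$frame, frames)
  lidx <- match(obs$landmark, landmarks)
  key <- split(seq_len(nrow(obs)), list(fi = fidx, li = lidx), drop = TRUE)
  for (kk in names(key)) {
    rows <- key[[kk]]
    if (length(rows) < 2L) next
    ij <- as.integer(strsplit(kk, ".", fixed = TRUE)[[1]])
    A <- matrix(0, 2L * length(rows), 4L)
    for (r in seq_along(rows)) {
      o <- rows[r]
      P <- Ps[[as.character(obs$camera[o])]]
      if (is.null(P)) stop_invalid("schema-error: unknown camera id ", obs$camera[o])
      A[2L * r - 1L, ] <- obs$x[o] * P[3, ] - P[1, ]
      A[2L * r, ]      <- obs$y[o] * P[3, ] - P[2, ]
    }
    v <- svd(A, nu = 0)$v[, 4L]
    if (abs(v[4]) < 1e-12) next
    Xw <- v[1:3] / v[4]
    coords[ij[1], ij[2], ] <- Xw
    valid[ij[1], ij[2]] <- TRUE
    # mean pixel reprojection error across contributing views
    errs <- vapply(rows, function(o) {
      uv <- project_points(list(P = Ps[[as.character(obs$camera[o])]]),
                           matrix(Xw, 1, 3))
      sqrt((uv[1] - obs$x[o])^2 + (uv[2] - obs$y[o])^2)
    }, numeric(1))
    resid[ij[1], ij[2]] <- mean(errs)
  }
  structure(list(coords = coords, valid = valid, residual_px = resid,
                 frames = frames, landmarks = landmarks),
            class = "triangulated_series")
}

#' @export
print.triangulated_series <- function(x, ...) {
  cat(sprintf("<triangulated_series> %d frames x %d landmarks (%.1f%% valid)\n",
              length(x$frames), length(x$landmarks), 100 * mean(x$valid)))
  invisible(x)
}
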