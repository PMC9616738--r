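# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# canonical ground-truth model
fx_model <- function() fixture("model", canonical_shape_model)

# a mid-length session's kinematics + ground-truth behaviour (seed 31)
fx_kin <- function() fixture("kin", function() generate_kinematics(900, seed = 31))
fx_state <- function() fixture("state", function() behavior_from_kinematics(fx_kin()))

# random proper rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# nonlinear least-squares triangulation oracle: minimizes summed squared
# pixel reprojection error with optim(), started from the DLT solution
triangulate_oracle <- function(obs_rows, cameras) {
  Ps <- lapply(cameras, `[[`, "P")
  names(Ps) <- vapply(cameras, function(cm) as.character(cm$id), character(1))
  err <- function(X) {
    sum(vapply(seq_len(nrow(obs_rows)), function(i) {
      P <- Ps[[as.character(obs_rows$camera[i])]]
      h <- P %*% c(X, 1)
      (h[1] / h[3] - obs_rows$x[i])^2 + (h[2] / h[3] - obs_rows$y[i])^2
    }, numeric(1)))
  }
  dlt <- triangulate(cbind(obs_rows, landmark = "nose", frame = 1),
                     cameras, landmarks = "nose")
  start <- dlt$coords[1, 1, ]
  stats::optim(start, err, method = "BFGS")$par
}

# exhaustive maximum-modularity bipartition for small graphs
best_bipartition_q <- function(A) {
  n <- nrow(A)
  best <- 0
  for (m in 0:(2^(n - 1) - 1)) {
    s <- as.integer(intToBits(m))[1:n]
    best <- max(best, pose2thal:::partition_modularity(A, s))
  }
  best
}
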