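# Generalized Procrustes alignment and the probabilistic-PCA shape model.

test_that("aligning rigid copies of one pose recovers it, with scale preserved", {
  set.seed(1)
  m <- fx_model()
  base <- synthesize_pose(m, c(1, -0.5, 0.3, 0.2))
  arr <- array(NA_real_, dim = c(8, 11, 3))
  for (i in 1:8)
    arr[i, , ] <- base %*% random_rotation() +
      matrix(runif(3, -10, 10), 11, 3, byrow = TRUE)
  ga <- procrustes_align(pose_set(arr))
  # all aligned poses identical to each other
  for (i in 2:8)
    expect_lt(max(abs(ga$aligned$poses[i, , ] - ga$aligned$poses[1, , ])), 1e-8)
  # mean equals the pose up to a rigid transform: centred sizes match
  cs <- function(p) sum(sweep(p, 2, colMeans(p))^2)
  expect_equal(cs(ga$mean), cs(base), tolerance = 1e-10)
  # doubling coordinates doubles the mean (scale fixed at 1, not normalized)
  ga2 <- procrustes_align(pose_set(2 * arr))
  expect_equal(cs(ga2$mean), 4 * cs(ga$mean), tolerance = 1e-10)
})

test_that("alignment never increases the Procrustes sum of squares", {
  set.seed(2)
  m <- fx_model()
  arr <- array(NA_real_, dim = c(20, 11, 3))
  for (i in 1:20) {
    b <- rnorm(4, 0, sqrt(m$eigenvalues))
    arr[i, , ] <- synthesize_pose(m, b, random_rotation(), runif(3, -5, 5)) +
      matrix(rnorm(33, 0, 0.2), 11, 3)
  }
  # re-run the sweeps manually, tracking total SS against the running mean
  ps <- pose_set(arr)
  for (i in 1:20) arr[i, , ] <- sweep(arr[i, , ], 2, colMeans(arr[i, , ]))
  mean_pose <- arr[1, , ]
  ss_prev <- Inf
  for (it in 1:6) {
    for (i in 1:20) {
      rt <- pose2thal:::rigid_procrustes(arr[i, , ], mean_pose)
      arr[i, , ] <- arr[i, , ] %*% rt$R
    }
    mean_pose <- apply(arr, c(2, 3), mean)
    ss <- sum(vapply(1:20, function(i) sum((arr[i, , ] - mean_pose)^2), 1))
    expect_lte(ss, ss_prev + 1e-10)
    ss_prev <- ss
  }
})

test_that("degenerate all-identical-point poses are rejected", {
  arr <- array(0, dim = c(3, 11, 3))
  expect_error(procrustes_align(pose_set(arr)), "degenerate")
})

test_that("PPCA recovers a noiseless rank-3 model exactly", {
  set.seed(3)
  m <- fx_model()
  arr <- array(NA_real_, dim = c(60, 11, 3))
  B <- matrix(rnorm(60 * 3), 60, 3) %*% diag(sqrt(m$eigenvalues[1:3]))
  for (i in 1:60) arr[i, , ] <- synthesize_pose(m, c(B[i, ], 0))
  fit <- train_ssm(pose_set(arr), 3)
  expect_lt(fit$sigma2, 1e-12)
  # recovered eigenposes span the generating subspace
  P_true <- t(sapply(1:3, function(i) as.vector(t(m$eigenposes[i, , ]))))
  P_fit <- t(sapply(1:3, function(i) as.vector(t(fit$eigenposes[i, , ]))))
  proj <- P_fit %*% t(P_true)        # 3x3; should be orthogonal
  expect_lt(max(abs(crossprod(proj) - diag(3))), 1e-6)
})

test_that("eigenposes are orthonormal and eigenvalues sorted", {
  set.seed(4)
  ps <- sample_training_poses(fx_model(), 120, seed = 4)
  fit <- train_ssm(procrustes_align(ps, rotation = "yaw"), 5)
  P <- t(sapply(1:5, function(i) as.vector(t(fit$eigenposes[i, , ]))))
  expect_lt(max(abs(tcrossprod(P) - diag(5))), 1e-8)
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  expect_gte(fit$sigma2, 0)
})

test_that("generative recovery: eigenvalue fractions and noise at N = 350", {
  m <- fx_model()
  ps <- sample_training_poses(m, 350, seed = 5)
  t0 <- Sys.time()
  fit <- train_ssm(procrustes_align(ps, rotation = "yaw"), 4)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_lt(max(abs(fit$eigenvalues / m$eigenvalues - 1)), 0.25)
  expect_lt(abs(fit$sigma2 / m$sigma2 - 1), 0.35)
  frac_fit <- explained_variance(fit)
  frac_true <- m$eigenvalues / m$total_var
  expect_lt(max(abs(frac_fit - frac_true)), 0.03)
})

test_that("explained variance fractions behave at the extremes", {
  set.seed(6)
  # rank-1 noiseless data: first fraction ~ 1
  m <- fx_model()
  arr <- array(NA_real_, dim = c(40, 11, 3))
  for (i in 1:40) arr[i, , ] <- synthesize_pose(m, c(rnorm(1, 0, 2), 0, 0, 0))
  fit <- train_ssm(pose_set(arr), 2)
  expect_gt(explained_variance(fit)[1], 0.999)
  ev <- explained_variance(fit)
  expect_true(all(diff(ev) <= 1e-12) && sum(ev) <= 1 + 1e-12)
})

test_that("synthesize_pose matches the generative equation", {
  m <- fx_model()
  expect_equal(synthesize_pose(m), m$mean, ignore_attr = TRUE)
  # linearity along one eigenpose, pre-rotation
  s <- 0.7
  d1 <- synthesize_pose(m, c(s, 0, 0, 0)) - m$mean
  d2 <- synthesize_pose(m, c(2 * s, 0, 0, 0)) - m$mean
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  expect_error(synthesize_pose(m, c(1, 0, 0, 0), R = diag(c(1, 1, -1))),
               "rotation")
})

test_that("shape scores are equivariant to rigid transforms of the data", {
  set.seed(7)
  m <- fx_model()
  X <- synthesize_pose(m, c(1.1, -0.4, 0.2, 0.1), yaw_matrix(0.4), c(3, 4, 1))
  f1 <- fit_pose(X, m)
  R <- yaw_matrix(1.1); tt <- c(-5, 2, 0.5)
  f2 <- fit_pose(X %*% R + matrix(tt, 11, 3, byrow = TRUE), m)
  expect_equal(f1$b, f2$b, tolerance = 1e-6)
  expect_equal(f2$t, as.vector(f1$t %*% R) + tt, tolerance = 1e-6)
})

test_that("model JSON serialization round-trips exactly", {
  m <- fx_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_ssm(m, path)
  m2 <- read_ssm(path)
  expect_equal(m2$mean, m$mean, tolerance = 1e-15)
  expect_equal(m2$eigenposes, m$eigenposes, tolerance = 1e-15)
  expect_equal(m2$eigenvalues, m$eigenvalues)
  expect_equal(m2$sigma2, m$sigma2)
})

test_that("full 3D superimposition absorbs pitch-like shape variance", {
  # yaw-only alignment preserves the arch eigenvalue; full rotation
  # deflates it by rotating part of the pitch deformation away
  m <- fx_model()
  ps <- sample_training_poses(m, 150, seed = 8)
  lam_yaw <- train_ssm(procrustes_align(ps, rotation = "yaw"), 4)$eigenvalues[1]
  lam_full <- train_ssm(procrustes_align(ps, rotation = "full"), 4)$eigenvalues[1]
  expect_lt(abs(lam_yaw / m$eigenvalues[1] - 1), 0.3)
  expect_lt(lam_full, 0.75 * lam_yaw)
})
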