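# Behavioural state variables: angle conventions, movement conventions,
# z-scoring, and the variable-grouping analysis.

make_fits <- function(n, b = NULL, t = NULL, epoch = NULL) {
  data.frame(frame = seq_len(n), epoch = epoch %||% rep(1L, n),
             time_s = (seq_len(n) - 1) / 15,
             b1 = b[, 1] %||% 0, b2 = b[, 2] %||% 0, b3 = b[, 3] %||% 0,
             tx = t[, 1] %||% 0, ty = t[, 2] %||% 0, tz = t[, 3] %||% 0)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("head elevation follows the stated geometry", {
  m <- fx_model()
  pose <- m$mean
  # nose directly above the neck
  pose["nose", ] <- pose["neck", ] + c(0, 0, 2)
  arr <- array(pose, dim = c(1, 11, 3), dimnames = list(NULL, m$landmarks, NULL))
  p <- compute_postures(data.frame(b1 = 0, b2 = 0, b3 = 0, tz = 0), arr)
  expect_equal(p$Hel, 90)
  # nose level with the neck
  pose["nose", ] <- pose["neck", ] + c(2, 0, 0)
  arr <- array(pose, dim = c(1, 11, 3), dimnames = list(NULL, m$landmarks, NULL))
  p <- compute_postures(data.frame(b1 = 0, b2 = 0, b3 = 0, tz = 0), arr)
  expect_equal(p$Hel, 0)
  # nose collinear with the midline in the plane: no head turn
  mid <- pose["neck", 1:2] - pose["tail_base", 1:2]
  pose["nose", ] <- pose["neck", ] + c(2 * mid / sqrt(sum(mid^2)), 0.5)
  arr <- array(pose, dim = c(1, 11, 3), dimnames = list(NULL, m$landmarks, NULL))
  p <- compute_postures(data.frame(b1 = 0, b2 = 0, b3 = 0, tz = 0), arr)
  expect_equal(p$Hlr, 0, tolerance = 1e-10)
  # leftward (counter-clockwise, +y) nose displacement is positive
  pose["nose", ] <- pose["neck", ] + c(1, 1, 0)
  arr <- array(pose, dim = c(1, 11, 3), dimnames = list(NULL, m$landmarks, NULL))
  p <- compute_postures(data.frame(b1 = 0, b2 = 0, b3 = 0, tz = 0), arr)
  expect_gt(p$Hlr, 0)
})

test_that("shape scores pass through and poses along eigenpose 1 read back as Bar", {
  m <- fx_model()
  s <- seq(-1, 1, length.out = 30)
  arr <- array(NA_real_, dim = c(30, 11, 3))
  for (i in 1:30) arr[i, , ] <- synthesize_pose(m, c(s[i], 0, 0, 0))
  dimnames(arr) <- list(NULL, m$landmarks, c("x", "y", "z"))
  fits <- make_fits(30, b = cbind(s, 0, 0), t = cbind(0, 0, 0))
  p <- compute_postures(fits, arr)
  expect_equal(p$Bar, s)
  expect_equal(p$Re, rep(0, 30))
})

test_that("movement conventions: rigid x-translation and dissociations", {
  m <- fx_model()
  n <- 20; v <- 6; fr <- 15
  arr <- array(NA_real_, dim = c(n, 11, 3))
  tx <- (seq_len(n) - 1) * v / fr
  for (i in 1:n) arr[i, , ] <- synthesize_pose(m, t = c(tx[i], 0, 0))
  dimnames(arr) <- list(NULL, m$landmarks, c("x", "y", "z"))
  fits <- make_fits(n, b = cbind(0, 0, 0), t = cbind(tx, 0, 0))
  post <- compute_postures(fits, arr)
  attr(post, "frame_rate") <- fr
  mov <- compute_movements(post, fits, arr, fits$epoch)
  expect_equal(mov$Lc[-1], rep(v / fr, n - 1))
  expect_equal(mov$OM[-1], rep(11 * v / fr, n - 1), tolerance = 1e-10)
  expect_true(is.na(mov$Lc[1]) && is.na(mov$OM[1]))
  expect_true(all(abs(mov$dHel[-1]) < 1e-9))
  # head-only pitch: OM > 0 with Lc = 0
  arr2 <- arr
  for (i in 1:n) {
    arr2[i, , ] <- synthesize_pose(m, c(0.1 * i, 0, 0, 0))
  }
  fits2 <- make_fits(n, b = cbind(0.1 * seq_len(n), 0, 0), t = cbind(0, 0, 0))
  post2 <- compute_postures(fits2, arr2)
  attr(post2, "frame_rate") <- fr
  mov2 <- compute_movements(post2, fits2, arr2, fits2$epoch)
  expect_true(all(mov2$OM[-1] > 0))
  expect_true(all(mov2$Lc[-1] < 1e-12))
  expect_true(all(abs(mov2$dHel[-1]) > 0))
})

test_that("postures are invariant to global yaw and horizontal translation", {
  kin <- fx_kin()
  idx <- 1:120
  arr <- kin$pose3d_true[idx, , ]
  fits <- data.frame(frame = idx, epoch = kin$epoch[idx],
                     time_s = kin$time_s[idx],
                     b1 = kin$b_true[idx, 1], b2 = kin$b_true[idx, 2],
                     b3 = kin$b_true[idx, 3],
                     tx = kin$t_true[idx, 1], ty = kin$t_true[idx, 2],
                     tz = kin$t_true[idx, 3])
  p1 <- compute_postures(fits, arr)
  R <- yaw_matrix(0.8)
  arr2 <- arr
  for (i in seq_along(idx))
    arr2[i, , ] <- arr[i, , ] %*% R + matrix(c(4, -7, 0), 11, 3, byrow = TRUE)
  p2 <- compute_postures(fits, arr2)
  expect_equal(p1$Hel, p2$Hel, tolerance = 1e-8)
  expect_equal(p1$Hlr, p2$Hlr, tolerance = 1e-8)
})

test_that("z-scoring standardizes, flags constants, and is idempotent", {
  st <- behavior_from_kinematics(fx_kin(), zscore = FALSE)
  z1 <- zscore_state(st)
  for (v in c("Hel", "Bar", "OM")) {
    x <- z1$data[[v]]
    expect_lt(abs(mean(x, na.rm = TRUE)), 1e-9)
    expect_lt(abs(sd(x, na.rm = TRUE) - 1), 1e-9)
  }
  z2 <- zscore_state(z1)
  expect_equal(z2$data$Bar, z1$data$Bar, tolerance = 1e-9)
  # constant variable is zero-filled and flagged
  st$data$Re <- 1.7
  zc <- zscore_state(st)
  expect_true("Re" %in% zc$flags)
  expect_true(all(zc$data$Re[!is.na(zc$data$Re)] == 0))
})

test_that("derivatives are masked at every epoch start", {
  st <- fx_state()
  first <- !duplicated(st$data$epoch)
  for (v in c("dHel", "dBar", "Lc", "OM"))
    expect_true(all(is.na(st$data[[v]][first])))
})

test_that("OM and Lc are non-negative and OM = 0 implies Lc = 0", {
  st <- behavior_from_kinematics(fx_kin(), zscore = FALSE)
  ok <- !is.na(st$data$OM)
  expect_true(all(st$data$OM[ok] >= 0))
  expect_true(all(st$data$Lc[!is.na(st$data$Lc)] >= 0))
  still <- which(ok & st$data$OM < 1e-12)
  if (length(still)) expect_true(all(st$data$Lc[still] < 1e-12))
})

test_that("MI matrix is symmetric with entropy diagonal and expected structure", {
  st <- fx_state()
  M <- fixture("mi_matrix", function() variable_mi_matrix(st, 5, seed = 1))
  expect_equal(M, t(M))
  # diagonal: bias-corrected entropy of a 5-level quantile variable
  expect_true(all(abs(diag(M) - log2(5)) < 0.05))
  # planted structure: within-pair links beat independent-looking pairs
  expect_gt(M["Hel", "Bar"], M["Hel", "Lc"])
  expect_gt(M["Lc", "OM"], M["Bar", "Lc"])
})

test_that("variable clustering separates postures from movements", {
  st <- fx_state()
  M <- fixture("mi_matrix", function() variable_mi_matrix(st, 5, seed = 1))
  cl <- cluster_variables(M)
  expect_equal(nrow(cl$tree$merge), 13)  # 13 merges for 14 variables
  g <- cl$cut2
  post <- c("Hel", "Hlr", "Bar", "Blr", "Blu", "Re")
  expect_length(unique(g[post]), 1)
  expect_length(unique(g[setdiff(names(g), post)]), 1)
  expect_false(g[["Hel"]] == g[["OM"]])
})

test_that("clustering recovers planted two-block structure exactly", {
  set.seed(44)
  n <- 4000
  a <- rnorm(n); b <- rnorm(n)
  X <- cbind(v1 = a, v2 = a + rnorm(n, 0, 0.3), v3 = a + rnorm(n, 0, 0.3),
             w1 = b, w2 = b + rnorm(n, 0, 0.3), w3 = b + rnorm(n, 0, 0.3))
  k <- ncol(X)
  M <- matrix(0, k, k, dimnames = list(colnames(X), colnames(X)))
  labs <- apply(X, 2, quantile_discretize, n_bins = 5)
  for (i in 1:k) for (j in 1:k) {
    M[i, j] <- if (i == j) corrected_entropy(labs[, i])
    else mutual_information(labs[, i], labs[, j])$mi_corrected
  }
  M <- (M + t(M)) / 2
  g <- cluster_variables(M)$cut2
  expect_length(unique(g[1:3]), 1)
  expect_length(unique(g[4:6]), 1)
  expect_false(g[[1]] == g[[4]])
})
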