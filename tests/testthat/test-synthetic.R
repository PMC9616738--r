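# Synthetic session generator: kinematics, multi-view projection with
# corruption bookkeeping, and tuned Poisson spike trains.

test_that("epoch structure follows the recording protocol", {
  kin <- fx_kin()
  lens <- kin$epochs[, 2] - kin$epochs[, 1]
  expect_true(all(lens >= 15 - 1e-9 & lens <= 24 + 1e-9))
  gaps <- kin$epochs[-1, 1] - kin$epochs[-nrow(kin$epochs), 2]
  expect_true(all(gaps >= 30 - 1e-9 & gaps <= 40 + 1e-9))
})

test_that("ground-truth poses equal the shape-model synthesis exactly", {
  kin <- fx_kin()
  idx <- c(1, 50, 400)
  for (i in idx) {
    expect_equal(kin$pose3d_true[i, , ],
                 synthesize_pose(kin$model, kin$b_true[i, ],
                                 yaw_matrix(kin$yaw_true[i]), kin$t_true[i, ]),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  for (j in seq_len(ncol(kin$b_true)))
    expect_true(all(abs(kin$b_true[, j]) <=
                      3 * sqrt(kin$model$eigenvalues[j]) + 1e-9))
})

test_that("zero dynamics variance produces a perfectly still animal", {
  mp <- motif_params(sd_b_frac = rep(0, 4), rear_rate = 0, loco_rate = 0,
                     idle_speed_sd = 0, yaw_sd = 0, yaw_sd_loco = 0,
                     z_sd = 0, act_rate = 0, sd_turn_frac = 0,
                     sd_log_energy = 0)
  kin <- generate_kinematics(60, seed = 3, motifs = mp)
  expect_lt(max(abs(diff(kin$t_true))), 1e-12)
  expect_lt(max(abs(kin$b_true)), 1e-12)
  st <- behavior_from_kinematics(kin, zscore = FALSE)
  mov <- st$data[c("dHel", "dBar", "Lc", "OM")]
  expect_lt(max(abs(as.matrix(mov)), na.rm = TRUE), 1e-9)
})

test_that("same seed reproduces the session bit-identically", {
  k1 <- generate_kinematics(120, seed = 9)
  k2 <- generate_kinematics(120, seed = 9)
  expect_identical(k1$b_true, k2$b_true)
  expect_identical(k1$pose3d_true, k2$pose3d_true)
  p1 <- project_landmarks(k1, noise_sd_px = 2, outlier_rate = 0.1,
                          missing_rate = 0.1, seed = 4)
  p2 <- project_landmarks(k2, noise_sd_px = 2, outlier_rate = 0.1,
                          missing_rate = 0.1, seed = 4)
  expect_identical(p1$observations, p2$observations)
  expect_identical(p1$corruption, p2$corruption)
})

test_that("locomotion bouts advance the body centre by speed over frame rate", {
  mp <- motif_params(sd_b_frac = rep(0, 4), rear_rate = 0, loco_rate = 0.3,
                     loco_dur = 3, idle_speed_sd = 0, yaw_sd = 0,
                     yaw_sd_loco = 0, z_sd = 0, act_rate = 0,
                     sd_turn_frac = 0, sd_log_energy = 0, loco_speed = 6)
  kin <- generate_kinematics(80, seed = 11, motifs = mp)
  step <- sqrt(rowSums(diff(kin$t_true[, 1:2])^2))
  same_epoch <- diff(kin$epoch) == 0
  moving <- kin$locomoting[-1] & same_epoch & step > 1e-9
  # away from walls the displacement is exactly v / frame_rate
  interior <- kin$t_true[-1, 1] > 1 & kin$t_true[-1, 1] < 29 &
    kin$t_true[-1, 2] > 1 & kin$t_true[-1, 2] < 29
  expect_gt(sum(moving & interior), 10)
  expect_equal(step[moving & interior],
               rep(6 / 15, sum(moving & interior)), tolerance = 1e-9)
})

test_that("corruption bookkeeping matches what was injected", {
  kin <- generate_kinematics(60, seed = 5)
  pr <- project_landmarks(kin, noise_sd_px = 1, outlier_rate = 0.08,
                          missing_rate = 0.07, seed = 6)
  clean <- project_landmarks(kin, noise_sd_px = 0, outlier_rate = 0,
                             missing_rate = 0, seed = 6)
  # missing entries are exactly the rows absent from the observation table
  key <- function(d) paste(d$frame, d$camera, d$landmark)
  missing_logged <- key(pr$corruption[pr$corruption$type == "missing", ])
  absent <- setdiff(key(clean$observations), key(pr$observations))
  expect_setequal(missing_logged, absent)
  # logged outliers are displaced by at least 20x the noise SD
  out <- pr$corruption[pr$corruption$type == "outlier", ]
  m <- merge(merge(out, pr$observations), clean$observations,
             by = c("frame", "camera", "landmark"),
             suffixes = c("", "_clean"))
  disp <- sqrt((m$x - m$x_clean)^2 + (m$y - m$y_clean)^2)
  expect_true(all(disp >= 20 * 1))
})

test_that("outlier fraction falls in the binomial 99% interval", {
  kin <- generate_kinematics(120, seed = 7)
  pr <- project_landmarks(kin, noise_sd_px = 2, outlier_rate = 0.1,
                          missing_rate = 0, seed = 8)
  n_entries <- length(kin$frame) * 11 * 4
  n_out <- sum(pr$corruption$type == "outlier")
  ci <- qbinom(c(0.005, 0.995), n_entries, 0.1)
  expect_gte(n_out, ci[1])
  expect_lte(n_out, ci[2])
})

test_that("homogeneous Poisson spikes have the right mean and Fano factor", {
  kin <- fx_kin()
  st <- fx_state()
  tun <- tuning_spec(baseline_log_hz = log(5), beta_ud = 0, beta_om = 0)
  spk <- generate_spikes(st, tun, bin_s = 0.67, seed = 12)
  counts <- spk$counts[, 1]
  expect_equal(mean(counts), 5 * 0.67, tolerance = 0.05)
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.1)
  # total spike count conserved between times and counts
  expect_equal(nrow(spk$spikes), sum(counts))
  expect_true(all(spk$spikes$time_s >= kin$epochs[1, 1]))
})

test_that("motion-tuned spikes correlate with overall motion", {
  st <- fixture("state_long", function()
    behavior_from_kinematics(generate_kinematics(2400, seed = 41)))
  tun <- tuning_spec(beta_ud = 0, beta_om = 0.6)
  spk <- generate_spikes(st, tun, bin_s = 0.67, seed = 13)
  bb <- pose2thal:::bin_frames(st, 0.67)
  om <- pose2thal:::aggregate_to_bins(st$data$OM, bb)
  ok <- !is.na(om)
  expect_gt(sum(ok), 500)
  ct <- suppressWarnings(cor.test(spk$counts[ok, 1], om[ok],
                                  method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("log-linear regression recovers the planted tuning coefficients", {
  st <- fixture("state_long", function()
    behavior_from_kinematics(generate_kinematics(2400, seed = 41)))
  tun <- tuning_spec(baseline_log_hz = log(6), beta_ud = 0.5, beta_om = 0.4)
  spk <- generate_spikes(st, tun, bin_s = 0.25, seed = 14)
  bb <- pose2thal:::bin_frames(st, 0.25)
  ud <- pose2thal:::aggregate_to_bins(st$data$Bar, bb)
  om <- pose2thal:::aggregate_to_bins(st$data$OM, bb)
  ok <- !is.na(ud) & !is.na(om)
  fit <- glm(spk$counts[ok, 1] ~ ud[ok] + om[ok], family = poisson())
  expect_lt(abs(coef(fit)[2] - 0.5) / 0.5, 0.2)
  expect_lt(abs(coef(fit)[3] - 0.4) / 0.4, 0.2)
})

test_that("excessive log-rate is rejected", {
  st <- fx_state()
  expect_error(generate_spikes(st, tuning_spec(baseline_log_hz = 25),
                               seed = 1), "invalid-tuning")
})
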