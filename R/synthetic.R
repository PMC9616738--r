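# Synthetic session generator. Emulates the statistical structure the
# analysis assumes: articulated 11-landmark kinematics at 15 Hz organised in
# 15-24 s recording epochs, four-view pinhole projections corrupted by pixel
# noise / outliers / missing detections, and Poisson spike trains whose
# log-rate is linear in an up/down posture score and overall motion.

#' Canonical mouse shape model
#'
#' A hand-constructed shape model used as ground truth by the synthetic
#' generator: an 11-landmark mean pose (cm) plus four orthonormal
#' deformation modes — body arch (pitch-up/rear of the front body), lateral
#' bend, fore-aft lunge/extension, and a head-only lateral sweep (the head
#' turns on the neck independently of the body bend, so head and body
#' left-right angles are related but not redundant). Rigid components
#' (translations and infinitesimal yaw) are projected out of each mode so
#' shape scores do not trade off against the rigid pose parameters.
#'
#' @param eigenvalues Variances (cm^2) of the four modes.
#' @param sigma2 Isotropic residual variance (cm^2).
#' @return An `ssm`.
#' @export
canonical_shape_model <- function(eigenvalues = c(2.0, 0.9, 0.45, 0.35),
                                  sigma2 = 0.01) {
  lm <- landmark_names()
  mean_pose <- matrix(c(
     4.5,  0.0, 1.2,   # nose
     3.2,  1.0, 2.0,   # ear_left
     3.2, -1.0, 2.0,   # ear_right
     3.0,  0.0, 2.8,   # headstage
     2.2,  0.0, 2.0,   # neck
     0.0,  0.0, 1.8,   # body_centre
     0.0,  1.4, 1.2,   # flank_left
     0.0, -1.4, 1.2,   # flank_right
    -2.0,  1.1, 1.3,   # hip_left
    -2.0, -1.1, 1.3,   # hip_right
    -3.5,  0.0, 1.0),  # tail_base
    ncol = 3, byrow = TRUE, dimnames = list(lm, c("x", "y", "z")))
  mean_pose <- sweep(mean_pose, 2, colMeans(mean_pose))
  arch <- matrix(c(
    -1.0, 0,  1.6,  -0.6, 0, 1.2,  -0.6, 0, 1.2,  -0.5, 0, 1.0,
    -0.3, 0,  0.7,   0.0, 0, 0.2,   0.0, 0, 0.0,   0.0, 0, 0.0,
     0.3, 0, -0.2,   0.3, 0, -0.2,  0.5, 0, -0.3),
    ncol = 3, byrow = TRUE)
  bend <- matrix(c(
    0,  1.5, 0,  0,  1.2, 0,  0,  1.2, 0,  0,  1.0, 0,
    0,  0.6, 0,  0,  0.0, 0,  0,  0.1, 0,  0,  0.1, 0,
    0, -0.6, 0,  0, -0.6, 0,  0, -1.2, 0),
    ncol = 3, byrow = TRUE)
  lunge <- matrix(c(
     1.2, 0, 0,   0.8, 0, 0,   0.8, 0, 0,   0.7, 0, 0.1,
     0.5, 0, 0,   0.0, 0, 0,   0.0, 0, -0.1, 0.0, 0, -0.1,
    -0.5, 0, 0,  -0.5, 0, 0,  -1.0, 0, 0),
    ncol = 3, byrow = TRUE)
  head_sweep <- matrix(c(
    0, 1.5, 0,  0, 1.0, 0,  0, 1.0, 0,  0, 0.8, 0,
    0, 0.3, 0,  0, 0.0, 0,  0, 0.0, 0,  0, 0.0, 0,
    0, 0.0, 0,  0, 0.0, 0,  0, 0.0, 0),
    ncol = 3, byrow = TRUE)
  # basis of rigid displacement fields: tx, ty, tz and infinitesimal yaw
  np <- nrow(mean_pose)
  rigid <- cbind(flatten_pose(matrix(rep(c(1, 0, 0), np), ncol = 3, byrow = TRUE)),
                 flatten_pose(matrix(rep(c(0, 1, 0), np), ncol = 3, byrow = TRUE)),
                 flatten_pose(matrix(rep(c(0, 0, 1), np), ncol = 3, byrow = TRUE)),
                 flatten_pose(cbind(-mean_pose[, 2], mean_pose[, 1], 0)))
  Qr <- qr.Q(qr(rigid))
  modes <- cbind(flatten_pose(arch), flatten_pose(bend), flatten_pose(lunge),
                 flatten_pose(head_sweep))
  modes <- modes - Qr %*% crossprod(Qr, modes)          # remove rigid content
  modes <- qr.Q(qr(modes))                              # orthonormalize
  # fix signs: arch raises the nose; bend and head sweep move it left;
  # lunge pushes it forward
  nose_i <- which(lm == "nose")
  sgn <- c(sign(modes[(nose_i - 1) * 3 + 3, 1]),
           sign(modes[(nose_i - 1) * 3 + 2, 2]),
           sign(modes[(nose_i - 1) * 3 + 1, 3]),
           sign(modes[(nose_i - 1) * 3 + 2, 4]))
  modes <- sweep(modes, 2, ifelse(sgn == 0, 1, sgn), `*`)
  k <- length(eigenvalues)
  P <- array(NA_real_, dim = c(k, np, 3L))
  for (i in seq_len(k)) P[i, , ] <- unflatten_pose(modes[, i], lm)
  structure(list(mean = mean_pose, eigenposes = P,
                 eigenvalues = eigenvalues, sigma2 = sigma2,
                 total_var = sum(eigenvalues) + (3 * np - k) * sigma2,
                 n_eigenposes = as.integer(k), landmarks = lm),
            class = "ssm")
}

#' Behavioural motif parameters
#'
#' Parameters of the kinematic generator: first-order mean-reverting
#' (Ornstein-Uhlenbeck) shape-score dynamics with bout-gated drive, heading
#' random walk, bout-gated planar locomotion, and a rearing gate that raises
#' the body-frame vertical translation while driving the arch score. The
#' defaults give slow dynamics whose power is concentrated below ~2 Hz.
#'
#' @param tau_b OU time constants (s) for the three shape scores.
#' @param sd_b_frac Stationary score SD as a fraction of `sqrt(lambda_i)`.
#' @param rear_rate,rear_dur Rearing bout onset rate (1/s) and mean duration (s).
#' @param rear_b1,rear_b3 Bout targets for scores 1 and 3, in units of
#'   `sqrt(lambda)`.
#' @param rear_z Rearing rise of the vertical translation (cm).
#' @param tau_z OU time constant (s) of the vertical translation.
#' @param z_sd Stationary SD (cm) of vertical translation jitter.
#' @param loco_rate,loco_dur Locomotion bout onset rate (1/s) and mean duration (s).
#' @param loco_speed Bout speed (cm/s).
#' @param idle_speed_sd SD (cm/s) of residual planar drift outside bouts.
#' @param yaw_sd,yaw_sd_loco Heading diffusion (rad/sqrt(s)) outside/inside
#'   locomotion bouts.
#' @param act_rate,act_dur Activity-state onset rate (1/s) and mean active
#'   duration (s); `act_rate = 0` keeps the animal permanently active.
#'   Rearing occurs only while active; quiet periods park the up/down
#'   postures near a crouched rest configuration. Together with the rearing
#'   gate this is the slow up/down latent that couples head elevation, body
#'   arch, lunge and rearing to each other.
#' @param quiet_b1,quiet_b3 Rest-posture targets (units of `sqrt(lambda)`)
#'   while quiet.
#' @param quiet_b2 Magnitude of the lateral-bend target while quiet
#'   (resting mice curl); the side is drawn at random per quiet episode.
#' @param quiet_b4 Head-sweep target magnitude while quiet (head tucked to
#'   the curl side).
#' @param quiet_damp Multiplier on the slow turn-latent innovation while
#'   quiet (sustained bends happen mostly during exploration).
#' @param quiet_damp_fast Multiplier on all fast innovation SDs (shape
#'   scores, heading, planar jitter, vertical jitter) while quiet: a
#'   resting animal barely moves, which is what couples the movement
#'   variables to each other beyond the shared motion-energy latent.
#' @param rear_b2_gain Same multiplier during rearing (the body straightens
#'   when upright); these two gains tie the left/right posture amplitude to
#'   the up/down state without coupling it to motion energy.
#' @param tau_turn,sd_turn_frac Time constant (s) and stationary SD (in
#'   `sqrt(lambda_2)` units) of the slow turn latent that drives the
#'   lateral-bend score.
#' @param tau_energy,sd_log_energy Time constant (s) and log-SD of the
#'   motion-energy latent: a log-normal OU process, independent of posture,
#'   that multiplies all fast innovation SDs (and scales locomotion speed),
#'   so movement variables co-vary with each other but not with postures.
#' @return A list of class `motif_params`.
#' @export
motif_params <- function(tau_b = c(0.45, 0.6, 0.5, 0.7),
                         sd_b_frac = c(0.35, 0.3, 0.35, 0.6),
                         rear_rate = 0.2, rear_dur = 3,
                         rear_b1 = 2.2, rear_b3 = -1.2,
                         rear_z = 2.5, tau_z = 0.5, z_sd = 0.25,
                         loco_rate = 0.15, loco_dur = 2.0,
                         loco_speed = 8, idle_speed_sd = 0.8,
                         yaw_sd = 0.5, yaw_sd_loco = 1.2,
                         act_rate = 1 / 8, act_dur = 7,
                         quiet_b1 = -1.2, quiet_b3 = 0.6, quiet_b2 = 2.2,
                         quiet_b4 = 2.2,
                         quiet_damp = 0.1, quiet_damp_fast = 0.5,
                         rear_b2_gain = 0.05,
                         tau_turn = 2, sd_turn_frac = 0.4,
                         tau_energy = 4, sd_log_energy = 1.5) {
  structure(as.list(environment()), class = "motif_params")
}

# Sample epoch windows: lengths uniform in len_range, gaps in gap_range.
#' @keywords internal
sample_epochs <- function(duration_s, len_range = c(15, 24),
                          gap_range = c(30, 40)) {
  eps <- list(); t0 <- 0
  while (t0 + len_range[1] <= duration_s) {
    len <- stats::runif(1, len_range[1], len_range[2])
    len <- min(len, duration_s - t0)
    if (len < len_range[1]) break
    eps[[length(eps) + 1L]] <- c(t0, t0 + len)
    t0 <- t0 + len + stats::runif(1, gap_range[1], gap_range[2])
  }
  if (length(eps) == 0L) stop_invalid("duration too short for a single epoch")
  do.call(rbind, eps)
}

# Two-state (off/on) bout gate simulated at frame resolution.
#' @keywords internal
sim_gate <- function(n, dt, rate, dur) {
  if (rate <= 0 || dur <= 0) return(rep(FALSE, n))
  p_on <- min(rate * dt, 1); p_off <- min(dt / dur, 1)
  g <- logical(n); state <- FALSE
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    state <- if (state) u[i] >= p_off else u[i] < p_on
    g[i] <- state
  }
  g
}

#' Generate ground-truth kinematics
#'
#' Simulates epoch-structured articulated kinematics: shape scores follow
#' mean-reverting dynamics with rearing-gated drive, the heading performs a
#' (bout-accelerated) random walk, locomotion bouts translate the body in
#' the horizontal plane at a set speed, and rearing raises the vertical
#' translation. The 3D pose of every frame is synthesized exactly from the
#' shape model at the ground-truth `(b, yaw, t)`.
#'
#' @param duration_s Total session duration (s); recording epochs of 15-24 s
#'   separated by 30-40 s gaps are carved out of it.
#' @param frame_rate Frames per second (default 15).
#' @param model Ground-truth `ssm` (default [canonical_shape_model()]).
#' @param motifs A [motif_params()] list.
#' @param seed Integer seed.
#' @param arena Arena extent `c(xmax, ymax)` in cm; trajectories reflect at
#'   the walls.
#' @param epoch_len_range,epoch_gap_range Epoch length / gap ranges (s).
#' @return An object of class `kinematics` with `epochs` (matrix of
#'   start/end s), `frame`, `epoch`, `time_s`, `b_true` (T x K),
#'   `yaw_true`, `t_true` (T x 3), `pose3d_true` (T x Np x 3 array),
#'   `frame_rate`, `model`.
#' @export
generate_kinematics <- function(duration_s, frame_rate = 15,
                                model = canonical_shape_model(),
                                motifs = motif_params(), seed = 1L,
                                arena = c(30, 30),
                                epoch_len_range = c(15, 24),
                                epoch_gap_range = c(30, 40)) {
  if (duration_s <= 0 || frame_rate <= 0)
    stop_invalid("invalid-argument: duration_s and frame_rate must be positive")
  if (model$n_eigenposes < 3L)
    stop_invalid("invalid-argument: model needs at least 3 eigenposes")
  mp <- motifs
  with_seed(seed, {
    epochs <- sample_epochs(duration_s, epoch_len_range, epoch_gap_range)
    dt <- 1 / frame_rate
    k <- model$n_eigenposes
    lam <- model$eigenvalues
    out <- list()
    for (e in seq_len(nrow(epochs))) {
      n <- max(2L, floor((epochs[e, 2] - epochs[e, 1]) * frame_rate))
      act <- if (mp$act_rate > 0) sim_gate(n, dt, mp$act_rate, mp$act_dur)
             else rep(TRUE, n)
      rear <- sim_gate(n, dt, mp$rear_rate, mp$rear_dur) & act
      loco <- sim_gate(n, dt, mp$loco_rate, mp$loco_dur) & !rear
      # motion-energy latent: log-normal OU, independent of posture states
      energy <- rep(1, n)
      if (mp$sd_log_energy > 0) {
        aE <- exp(-dt / mp$tau_energy)
        le <- numeric(n)
        le[1] <- stats::rnorm(1, 0, mp$sd_log_energy)
        iE <- mp$sd_log_energy * sqrt(1 - aE^2)
        for (i in seq_len(n)[-1]) le[i] <- aE * le[i - 1] + stats::rnorm(1, 0, iE)
        energy <- exp(le - mp$sd_log_energy^2 / 2)
      }
      # slow turn latent: OU whose innovation is gated by the up/down state;
      # quiet episodes pull it toward a curled rest bend with a random side
      turn <- numeric(n); head_side_b <- numeric(n)
      aL <- exp(-dt / mp$tau_turn)
      iL <- mp$sd_turn_frac * sqrt(lam[2]) * sqrt(1 - aL^2)
      turn[1] <- stats::rnorm(1, 0, mp$sd_turn_frac * sqrt(lam[2]))
      curl_side <- 0; head_side <- 0
      for (i in seq_len(n)[-1]) {
        if (!act[i]) {
          if (curl_side == 0) {
            curl_side <- sample(c(-1, 1), 1)
            head_side <- sample(c(-1, 1), 1)
          }
        } else curl_side <- head_side <- 0
        gL <- if (!act[i]) mp$quiet_damp else if (rear[i]) mp$rear_b2_gain else 1
        targL <- if (!act[i]) curl_side * mp$quiet_b2 * sqrt(lam[2]) else 0
        turn[i] <- targL + aL * (turn[i - 1] - targL) +
          stats::rnorm(1, 0, iL * gL * energy[i])
        head_side_b[i] <- head_side
      }
      # shape scores: OU toward state targets (up/down latent for scores 1
      # and 3, the turn latent for score 2, head tucked to the curl side
      # for score 4); fast innovations scale with the motion-energy latent
      b <- matrix(0, n, k)
      sd_frac <- rep(mp$sd_b_frac, length.out = k)
      tau <- rep(mp$tau_b, length.out = k)
      sd_st <- sd_frac * sqrt(lam[seq_len(k)])
      b[1, ] <- stats::rnorm(k, 0, sd_st)
      innov0 <- sd_st * sqrt(pmax(0, 1 - exp(-2 * dt / tau)))
      a <- exp(-dt / tau)
      for (i in seq_len(n)[-1]) {
        targ <- rep(0, k)
        gain <- rep(1, k)
        if (!act[i]) {
          targ[1] <- mp$quiet_b1 * sqrt(lam[1])
          targ[3] <- mp$quiet_b3 * sqrt(lam[3])
          gain <- gain * mp$quiet_damp_fast
          if (k >= 4) targ[4] <- head_side_b[i] * mp$quiet_b4 * sqrt(lam[4])
        } else if (rear[i]) {
          targ[1] <- mp$rear_b1 * sqrt(lam[1])
          targ[3] <- mp$rear_b3 * sqrt(lam[3])
          if (k >= 4) gain[4] <- mp$rear_b2_gain
        }
        targ[2] <- turn[i]
        b[i, ] <- targ + a * (b[i - 1, ] - targ) +
          stats::rnorm(k, 0, innov0 * gain * energy[i])
      }
      for (i in seq_len(k)) b[, i] <- pmin(pmax(b[, i], -3 * sqrt(lam[i])), 3 * sqrt(lam[i]))
      # heading random walk and planar position; step noise scales with the
      # energy latent, bout speed is the set parameter
      yaw_step <- ifelse(loco, mp$yaw_sd_loco, mp$yaw_sd) * energy *
        ifelse(act, 1, mp$quiet_damp_fast) * sqrt(dt)
      yaw <- cumsum(c(stats::runif(1, -pi, pi), stats::rnorm(n - 1, 0, yaw_step[-1])))
      speed <- ifelse(loco, mp$loco_speed, 0)
      jit <- if (mp$idle_speed_sd > 0)
        matrix(stats::rnorm(2 * n, 0, mp$idle_speed_sd * dt), n, 2) * energy *
          ifelse(act, 1, mp$quiet_damp_fast)
      else matrix(0, n, 2)
      xy <- matrix(0, n, 2)
      xy[1, ] <- stats::runif(2, arena * 0.25, arena * 0.75)
      for (i in seq_len(n)[-1]) {
        step <- speed[i] * dt * c(cos(yaw[i]), sin(yaw[i])) + jit[i, ]
        p <- xy[i - 1, ] + step
        # reflect at walls
        for (d in 1:2) {
          if (p[d] < 0) p[d] <- -p[d]
          if (p[d] > arena[d]) p[d] <- 2 * arena[d] - p[d]
        }
        xy[i, ] <- p
      }
      # vertical translation: OU toward rearing-gated target
      tz <- numeric(n)
      az <- exp(-dt / mp$tau_z)
      z_innov <- mp$z_sd * sqrt(max(0, 1 - az^2))
      tz[1] <- 0
      b1_hi <- mp$rear_b1 * sqrt(lam[1])
      for (i in seq_len(n)[-1]) {
        # body centre rises with the (positive) arch score: rearing lifts it
        ztarg <- mp$rear_z * max(0, b[i, 1]) / b1_hi
        tz[i] <- ztarg + az * (tz[i - 1] - ztarg) +
          stats::rnorm(1, 0, z_innov * energy[i] *
                         if (act[i]) 1 else mp$quiet_damp_fast)
      }
      out[[e]] <- list(b = b, yaw = yaw, t = cbind(xy, tz),
                       time = epochs[e, 1] + (seq_len(n) - 1L) * dt,
                       epoch = rep(e, n), rear = rear, loco = loco)
    }
    b_true <- do.call(rbind, lapply(out, `[[`, "b"))
    yaw_true <- unlist(lapply(out, `[[`, "yaw"))
    t_true <- do.call(rbind, lapply(out, `[[`, "t"))
    colnames(t_true) <- c("x", "y", "z")
    time_s <- unlist(lapply(out, `[[`, "time"))
    epoch <- unlist(lapply(out, `[[`, "epoch"))
    nT <- length(time_s)
    pose <- array(NA_real_, dim = c(nT, length(model$landmarks), 3L),
                  dimnames = list(NULL, model$landmarks, c("x", "y", "z")))
    for (i in seq_len(nT))
      pose[i, , ] <- synthesize_pose(model, b_true[i, ], yaw_matrix(yaw_true[i]),
                                     t_true[i, ])
    structure(list(epochs = epochs, frame = seq_len(nT), epoch = epoch,
                   time_s = time_s, b_true = b_true, yaw_true = yaw_true,
                   t_true = t_true, pose3d_true = pose,
                   rearing = unlist(lapply(out, `[[`, "rear")),
                   locomoting = unlist(lapply(out, `[[`, "loco")),
                   frame_rate = frame_rate, model = model),
              class = "kinematics")
  })
}

#' @export
print.kinematics <- function(x, ...) {
  cat(sprintf("<kinematics> %d frames in %d epochs @ %g Hz\n",
              length(x$frame), nrow(x$epochs), x$frame_rate))
  invisible(x)
}

#' Project ground-truth landmarks into noisy multi-view observations
#'
#' Each landmark visible to a camera is projected through the pinhole model
#' and perturbed with isotropic Gaussian pixel noise. A fraction of entries
#' is replaced by large-displacement outliers (at least 20x the noise SD,
#' or 20 px when noiseless) and another fraction is dropped as missing. The
#' injected corruption is logged exactly for test oracles.
#'
#' @param kinematics A [generate_kinematics()] result.
#' @param cameras List of `camera_model`s (default [default_camera_rig()]).
#' @param noise_sd_px Gaussian pixel noise SD.
#' @param outlier_rate,missing_rate Corruption probabilities in `[0, 1)`
#'   applied independently per (frame, camera, landmark).
#' @param seed Integer seed.
#' @return List with `observations` (data frame: frame, camera, landmark,
#'   x, y, confidence) and `corruption` (data frame: frame, camera,
#'   landmark, type in "outlier"/"missing").
#' @export
project_landmarks <- function(kinematics, cameras = default_camera_rig(),
                              noise_sd_px = 2, outlier_rate = 0,
                              missing_rate = 0, seed = 1L) {
  if (length(cameras) < 2L) stop_invalid("need at least 2 cameras")
  if (outlier_rate < 0 || outlier_rate >= 1 || missing_rate < 0 || missing_rate > 1)
    stop_invalid("corruption rates must be in [0, 1]")
  lm <- kinematics$model$landmarks
  nT <- length(kinematics$frame); np <- length(lm)
  with_seed(seed, {
    obs_list <- vector("list", length(cameras))
    cor_list <- list()
    for (ci in seq_along(cameras)) {
      uv <- matrix(NA_real_, nT * np, 2)
      for (i in seq_len(nT)) {
        uv[((i - 1) * np + 1):(i * np), ] <-
          project_points(cameras[[ci]], kinematics$pose3d_true[i, , ])
      }
      df <- data.frame(frame = rep(kinematics$frame, each = np),
                       camera = cameras[[ci]]$id,
                       landmark = rep(lm, nT),
                       x = uv[, 1], y = uv[, 2],
                       confidence = stats::runif(nT * np, 0.85, 1))
      u <- stats::runif(nrow(df))
      miss <- u < missing_rate
      outl <- !miss & (u < missing_rate + outlier_rate * (1 - missing_rate))
      if (any(outl)) {
        mag <- pmax(20 * noise_sd_px, 20) * stats::runif(sum(outl), 1, 5)
        ang <- stats::runif(sum(outl), 0, 2 * pi)
        df$x[outl] <- df$x[outl] + mag * cos(ang)
        df$y[outl] <- df$y[outl] + mag * sin(ang)
      }
      keep <- !miss
      if (noise_sd_px > 0) {
        df$x[!outl] <- df$x[!outl] + stats::rnorm(sum(!outl), 0, noise_sd_px)
        df$y[!outl] <- df$y[!outl] + stats::rnorm(sum(!outl), 0, noise_sd_px)
      }
      if (any(miss | outl)) {
        cor_list[[length(cor_list) + 1L]] <-
          data.frame(frame = df$frame[miss | outl],
                     camera = cameras[[ci]]$id,
                     landmark = df$landmark[miss | outl],
                     type = ifelse(miss[miss | outl], "missing", "outlier"))
      }
      obs_list[[ci]] <- df[keep, , drop = FALSE]
    }
    observations <- do.call(rbind, obs_list)
    observations <- observations[order(observations$frame, observations$camera), ]
    rownames(observations) <- NULL
    corruption <- if (length(cor_list)) do.call(rbind, cor_list) else
      data.frame(frame = integer(0), camera = integer(0),
                 landmark = character(0), type = character(0))
    list(observations = observations, corruption = corruption)
  })
}

#' Unit tuning specification
#'
#' Log-linear tuning of each unit: `rate = exp(baseline + beta_ud * UD +
#' beta_om * OM)` spikes/s, where UD is the z-scored up/down posture score
#' (body arch by default) and OM the z-scored overall motion. A positive
#' `beta_ud` makes a look-up unit, negative a look-down unit. `lag_s`
#' optionally delays the dependence on behaviour.
#'
#' @param baseline_log_hz Baseline log firing rate (log spikes/s).
#' @param beta_ud,beta_om Tuning coefficients (per z-unit).
#' @param lag_s Coupling lag in seconds (positive: spikes follow behaviour).
#' @return A one-row data frame; rbind rows to describe a population.
#' @export
tuning_spec <- function(baseline_log_hz = log(5), beta_ud = 0.5,
                        beta_om = 0.5, lag_s = 0) {
  data.frame(baseline_log_hz = baseline_log_hz, beta_ud = beta_ud,
             beta_om = beta_om, lag_s = lag_s)
}

#' Default mixed look-up / look-down population
#'
#' Half the units have `beta_ud = +beta_ud`, half `-beta_ud`; all are
#' positively motion-modulated.
#'
#' @param n_units Population size.
#' @param beta_ud,beta_om Coefficient magnitudes.
#' @param baseline_hz Baseline rate (spikes/s).
#' @return Tuning data frame with a `unit` column and `ud_sign`.
#' @export
default_tuning <- function(n_units, beta_ud = 0.5, beta_om = 0.5,
                           baseline_hz = 5) {
  sgn <- rep(c(1, -1), length.out = n_units)
  df <- tuning_spec(log(baseline_hz), beta_ud * sgn, beta_om, 0)
  df <- df[rep(1, n_units), ]
  df$beta_ud <- beta_ud * sgn
  df$unit <- seq_len(n_units)
  df$ud_sign <- sgn
  rownames(df) <- NULL
  df[, c("unit", "baseline_log_hz", "beta_ud", "beta_om", "lag_s", "ud_sign")]
}

#' Generate Poisson spike trains tuned to behaviour
#'
#' Counts in bins of `bin_s` within each epoch are inhomogeneous Poisson
#' with rate `exp(baseline + beta_ud * UD + beta_om * OM)` (spikes/s, so the
#' per-bin mean is rate x `bin_s`); spike times are scattered uniformly
#' within their bin. UD and OM are taken from the z-scored behavioural
#' state; an optional per-unit lag shifts the behavioural drive.
#'
#' @param behavior A z-scored [behavioral_state] (see [zscore_state()]).
#' @param tuning Tuning data frame (one row per unit, see [tuning_spec()]).
#' @param bin_s Rate discretization bin (s), default 1/frame_rate for a
#'   drive that follows behaviour at frame resolution.
#' @param seed Integer seed.
#' @param ud_variable Name of the up/down drive variable (default "Bar").
#' @return List with `spikes` (data frame: unit, time_s), `counts`
#'   (bins x units matrix), `bins` (data frame: epoch, t_start, t_mid) and
#'   `rate_hz` (bins x units).
#' @export
generate_spikes <- function(behavior, tuning, bin_s = NULL, seed = 1L,
                            ud_variable = "Bar") {
  st <- behavior
  if (!inherits(st, "behavioral_state")) stop_invalid("behavior must be a behavioral_state")
  if (!isTRUE(st$zscored)) stop_invalid("behavior must be z-scored")
  if (is.null(bin_s)) bin_s <- 1 / st$frame_rate
  if (bin_s <= 0) stop_invalid("invalid-argument: bin_s must be positive")
  ud <- st$data[[ud_variable]]; om <- st$data$OM
  om[is.na(om)] <- 0; ud[is.na(ud)] <- 0
  with_seed(seed, {
    bins <- bin_frames(st, bin_s)
    spikes <- list(); counts <- matrix(0L, nrow(bins$table), nrow(tuning))
    rates <- matrix(NA_real_, nrow(bins$table), nrow(tuning))
    for (u in seq_len(nrow(tuning))) {
      tu <- tuning[u, ]
      lag_frames <- round(tu$lag_s * st$frame_rate)
      udl <- shift_within_epochs(ud, st$data$epoch, lag_frames)
      oml <- shift_within_epochs(om, st$data$epoch, lag_frames)
      ud_b <- aggregate_to_bins(udl, bins)
      om_b <- aggregate_to_bins(oml, bins)
      log_rate <- tu$baseline_log_hz + tu$beta_ud * ud_b + tu$beta_om * om_b
      if (any(log_rate > 20, na.rm = TRUE))
        stop_invalid("invalid-tuning: log-rate exceeds 20")
      rate <- exp(log_rate); rate[is.na(rate)] <- exp(tu$baseline_log_hz)
      n <- stats::rpois(length(rate), rate * bin_s)
      counts[, u] <- n
      rates[, u] <- rate
      tot <- sum(n)
      if (tot > 0) {
        t0 <- rep(bins$table$t_start, n)
        spikes[[u]] <- data.frame(unit = u,
                                  time_s = sort(t0 + stats::runif(tot, 0, bin_s)))
      }
    }
    spk <- if (length(spikes)) do.call(rbind, Filter(Negate(is.null), spikes)) else
      data.frame(unit = integer(0), time_s = numeric(0))
    rownames(spk) <- NULL
    list(spikes = spk, counts = counts, bins = bins$table, rate_hz = rates)
  })
}

# Shift a frame series by `k` frames within each epoch (positive k delays),
# padding with the epoch mean so edge bins keep a finite, diluted drive.
#' @keywords internal
shift_within_epochs <- function(x, epoch, k) {
  if (k == 0) return(x)
  out <- x
  for (e in unique(epoch)) {
    idx <- which(epoch == e)
    v <- x[idx]; n <- length(v); m <- mean(v, na.rm = TRUE)
    if (k > 0) out[idx] <- c(rep(m, min(k, n)), v[seq_len(max(0, n - k))])
    else out[idx] <- c(v[(min(-k, n) + 1):n], rep(m, min(-k, n)))
  }
  out
}

# Bin layout for a behavioral_state: bins of bin_s within each epoch,
# trailing partial bins dropped. Returns the bin table and the frame->bin map.
#' @keywords internal
bin_frames <- function(st, bin_s) {
  tab <- list(); map <- rep(NA_integer_, nrow(st$data))
  nb0 <- 0L
  for (e in seq_len(nrow(st$epochs))) {
    idx <- which(st$data$epoch == e)
    if (!length(idx)) next
    t0 <- st$epochs[e, 1]
    dur <- st$epochs[e, 2] - t0
    nb <- floor(dur / bin_s + 1e-9)
    if (nb < 1L) next
    rel <- st$data$time_s[idx] - t0
    bi <- floor(rel / bin_s) + 1L
    ok <- bi >= 1L & bi <= nb
    map[idx[ok]] <- nb0 + bi[ok]
    tab[[length(tab) + 1L]] <- data.frame(
      epoch = e, bin = seq_len(nb),
      t_start = t0 + (seq_len(nb) - 1L) * bin_s,
      t_mid = t0 + (seq_len(nb) - 0.5) * bin_s)
    nb0 <- nb0 + nb
  }
  list(table = do.call(rbind, tab), frame_bin = map)
}

# Mean of a frame-level series within each bin (NA frames ignored).
#' @keywords internal
aggregate_to_bins <- function(x, bins) {
  out <- rep(NA_real_, nrow(bins$table))
  ok <- !is.na(bins$frame_bin) & !is.na(x)
  if (any(ok)) {
    s <- tapply(x[ok], bins$frame_bin[ok], mean)
    out[as.integer(names(s))] <- as.vector(s)
  }
  out
}

#' Simulate a complete synthetic session
#'
#' Convenience wrapper: kinematics, ground-truth behavioural state (from the
#' true poses and fits), multi-view observations with corruption log, and
#' tuned spike trains.
#'
#' @param duration_s Session duration (s).
#' @param n_units Number of units.
#' @param seed Integer seed.
#' @param model Ground-truth shape model.
#' @param motifs Motif parameters.
#' @param cameras Camera rig.
#' @param noise_sd_px,outlier_rate,missing_rate Observation corruption.
#' @param tuning Optional tuning data frame (default [default_tuning()]).
#' @param spike_bin_s Rate discretization for spike generation (default one
#'   frame).
#' @return A list of class `synthetic_session`.
#' @export
simulate_session <- function(duration_s = 600, n_units = 20, seed = 1L,
                             model = canonical_shape_model(),
                             motifs = motif_params(),
                             cameras = default_camera_rig(),
                             noise_sd_px = 2, outlier_rate = 0.05,
                             missing_rate = 0.05, tuning = NULL,
                             spike_bin_s = NULL) {
  kin <- generate_kinematics(duration_s, model = model, motifs = motifs,
                             seed = seed)
  behavior <- behavior_from_kinematics(kin)
  proj <- project_landmarks(kin, cameras, noise_sd_px, outlier_rate,
                            missing_rate, seed = seed + 1000L)
  if (is.null(tuning)) tuning <- default_tuning(n_units)
  spk <- generate_spikes(behavior, tuning, bin_s = spike_bin_s,
                         seed = seed + 2000L)
  structure(list(kinematics = kin, behavior = behavior,
                 observations2d = proj$observations,
                 corruption = proj$corruption, cameras = cameras,
                 tuning = tuning, spikes = spk$spikes,
                 spike_counts = spk$counts, spike_bins = spk$bins,
                 seed = seed),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> %d frames, %d units, %d epochs, seed %d\n",
              length(x$kinematics$frame), nrow(x$tuning),
              nrow(x$kinematics$epochs), x$seed))
  invisible(x)
}

#' Ground-truth behavioural state of a kinematics object
#'
#' Computes the 14 behavioural state variables directly from the generator's
#' true poses and pose parameters, bypassing reconstruction.
#'
#' @param kin A [generate_kinematics()] result.
#' @param zscore Z-score the state (default TRUE).
#' @return A `behavioral_state`.
#' @export
behavior_from_kinematics <- function(kin, zscore = TRUE) {
  fits <- data.frame(frame = kin$frame, epoch = kin$epoch, time_s = kin$time_s,
                     b1 = kin$b_true[, 1], b2 = kin$b_true[, 2],
                     b3 = kin$b_true[, 3], yaw = kin$yaw_true,
                     tx = kin$t_true[, 1], ty = kin$t_true[, 2],
                     tz = kin$t_true[, 3])
  st <- compute_state(fits, kin$pose3d_true, kin$epochs, kin$frame_rate)
  if (zscore) zscore_state(st) else st
}
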