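# End-to-end orchestration: simulate -> train-ssm -> reconstruct ->
# behaviour -> couple -> classify, with uniform CSV/JSON artifacts and a
# single seed policy. The thin command-line wrapper in inst/cli calls
# these functions; the package API is the primary interface.

#' Pipeline configuration
#'
#' Collects the pipeline constants with their standard defaults: 15 Hz
#' frames, 0.67 s information/prediction bins, 0.0667 s correlogram bins,
#' regularization alpha 0.01, chi-square probability 0.99, 5 quantile
#' levels, 1000 permutations, 100 coherence shifts.
#'
#' @param ... Overrides of the defaults.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(frame_rate = 15, bin_s = 0.67, cc_bin_s = 0.0667,
              alpha = 0.01, chi2_prob = 0.99, n_quantiles = 5L,
              n_perm = 1000L, n_shifts = 100L, np_floor = 6L,
              rotation = "yaw", seed = 1L, condition = "dark",
              duration_s = 600, n_units = 20L, n_ssm_poses = 350L,
              noise_sd_px = 2, outlier_rate = 0.05, missing_rate = 0.05)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop_invalid("unknown config fields: ",
                                    paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (any(unlist(cfg[c("frame_rate", "bin_s", "cc_bin_s", "alpha")]) <= 0))
    stop_invalid("durations and rates must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Sample an annotated training pose set from a shape model
#'
#' Draws poses with normal shape scores (variance `lambda_i`) plus
#' isotropic residual noise, mimicking a manually annotated training set.
#'
#' @param model An `ssm`.
#' @param n Number of poses (default 350).
#' @param seed Integer seed.
#' @return A `pose_set`.
#' @export
sample_training_poses <- function(model, n = 350L, seed = 1L) {
  with_seed(seed, {
    np <- length(model$landmarks)
    arr <- array(NA_real_, dim = c(n, np, 3L))
    for (i in seq_len(n)) {
      b <- stats::rnorm(model$n_eigenposes, 0, sqrt(model$eigenvalues))
      yaw <- stats::runif(1, -pi, pi)
      pose <- synthesize_pose(model, b, yaw_matrix(yaw), stats::runif(3, -5, 5))
      arr[i, , ] <- pose + matrix(stats::rnorm(np * 3, 0, sqrt(model$sigma2)),
                                  np, 3)
    }
    pose_set(arr, model$landmarks)
  })
}

#' Validate pipeline input files
#'
#' Schema checks for the on-disk session format: landmark observations CSV
#' (frame, camera, landmark, x, y, confidence; exactly the 11 canonical
#' landmark names), calibration JSON (rank-3 3x4 matrices), spikes CSV
#' (unit, time_s) and epochs CSV (start_s, end_s; positive, non-overlapping
#' windows). Report-only: never throws on content errors.
#'
#' @param paths Named list/vector with any of `landmarks`, `calibration`,
#'   `spikes`, `epochs`.
#' @return Data frame with columns `file`, `check`, `pass`, `message`.
#' @export
validate_inputs <- function(paths) {
  res <- list()
  add <- function(file, check, pass, message = "") {
    res[[length(res) + 1L]] <<- data.frame(file = file, check = check,
                                           pass = pass, message = message)
  }
  if (!is.null(paths$landmarks)) {
    f <- paths$landmarks
    if (!file.exists(f)) add(f, "exists", FALSE, "file not found")
    else {
      d <- utils::read.csv(f)
      need <- c("frame", "camera", "landmark", "x", "y")
      miss <- setdiff(need, names(d))
      add(f, "columns", length(miss) == 0,
          if (length(miss)) paste("missing:", paste(miss, collapse = ", ")) else "")
      if (!length(miss)) {
        extra <- setdiff(unique(d$landmark), landmark_names())
        lack <- setdiff(landmark_names(), unique(d$landmark))
        add(f, "landmark-set", length(extra) == 0 && length(lack) == 0,
            if (length(extra) || length(lack)) "landmark set mismatch" else "")
        add(f, "coordinates-finite", all(is.finite(d$x) & is.finite(d$y)), "")
      }
    }
  }
  if (!is.null(paths$calibration)) {
    f <- paths$calibration
    if (!file.exists(f)) add(f, "exists", FALSE, "file not found")
    else {
      ok <- TRUE; msg <- ""
      cams <- tryCatch(read_cameras(f), error = function(e) {
        ok <<- FALSE; msg <<- conditionMessage(e); NULL
      })
      add(f, "camera-matrices", ok, msg)
      if (ok) add(f, "n-cameras", length(cams) >= 2,
                  if (length(cams) < 2) "fewer than 2 cameras" else "")
    }
  }
  if (!is.null(paths$spikes)) {
    f <- paths$spikes
    if (!file.exists(f)) add(f, "exists", FALSE, "file not found")
    else {
      d <- utils::read.csv(f)
      add(f, "columns", all(c("unit", "time_s") %in% names(d)), "")
    }
  }
  if (!is.null(paths$epochs)) {
    f <- paths$epochs
    if (!file.exists(f)) add(f, "exists", FALSE, "file not found")
    else {
      d <- utils::read.csv(f)
      okc <- all(c("start_s", "end_s") %in% names(d))
      add(f, "columns", okc, "")
      if (okc) {
        ord <- order(d$start_s)
        pos <- all(d$end_s > d$start_s)
        ovl <- nrow(d) > 1 &&
          any(d$start_s[ord][-1] < d$end_s[ord][-nrow(d)] - 1e-9)
        add(f, "windows-positive", pos, "")
        add(f, "non-overlapping", !ovl, if (ovl) "epochs overlap" else "")
      }
    }
  }
  do.call(rbind, res)
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Simulates a session, trains the shape model on a sampled annotation set,
#' reconstructs poses from the corrupted observations, derives and z-scores
#' the behavioural state, runs the coupling suite (correlograms with
#' permutation nulls, mutual information, encoding models) for every unit,
#' and classifies units into look-up/look-down communities. All artifacts
#' are written as CSV/JSON under `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @return A list of class `session_report` with the main result tables.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  cfg <- config
  t_start <- Sys.time()
  session <- simulate_session(duration_s = cfg$duration_s,
                              n_units = cfg$n_units, seed = cfg$seed,
                              noise_sd_px = cfg$noise_sd_px,
                              outlier_rate = cfg$outlier_rate,
                              missing_rate = cfg$missing_rate)
  truth_model <- session$kinematics$model
  train <- sample_training_poses(truth_model, cfg$n_ssm_poses,
                                 seed = cfg$seed + 1L)
  # eigenpose count: smallest explaining >= 95% variance (floor of 3); the
  # first three scores are exported as Bar/Blr/Blu regardless
  model <- train_ssm(procrustes_align(train, rotation = cfg$rotation),
                     n_eigenposes = NULL)
  recon <- reconstruct_series(session$observations2d, session$cameras, model,
                              epochs = session$kinematics$epochs,
                              frame_rate = cfg$frame_rate,
                              chi2_prob = cfg$chi2_prob, alpha = cfg$alpha,
                              rotation = cfg$rotation,
                              np_floor = cfg$np_floor,
                              frame_times = session$kinematics$time_s)
  state <- zscore_state(behavioral_state(recon$fits, recon$poses,
                                         session$kinematics$epochs,
                                         cfg$frame_rate))
  mi_mat <- variable_mi_matrix(state, cfg$n_quantiles, seed = cfg$seed)
  var_clust <- cluster_variables(mi_mat)
  bins_mi <- bin_spikes(session$spikes, session$kinematics$epochs,
                        cfg$bin_s, behavior = state)
  bins_cc <- bin_spikes(session$spikes, session$kinematics$epochs,
                        cfg$cc_bin_s, behavior = state)
  n_units <- ncol(bins_mi$counts)
  coupling <- vector("list", n_units)
  hists <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    cc_bar <- crosscorr_significance(bins_cc, "Bar", n_perm = cfg$n_perm,
                                     unit = u, seed = cfg$seed + u)
    cc_om <- crosscorr_significance(bins_cc, "OM", n_perm = cfg$n_perm,
                                    unit = u, seed = cfg$seed + u)
    cnt <- bins_mi$counts[, u]
    bar_lab <- quantile_discretize(ifelse(is.na(bins_mi$table$Bar), 0,
                                          bins_mi$table$Bar), cfg$n_quantiles)
    om_lab <- quantile_discretize(ifelse(is.na(bins_mi$table$OM), 0,
                                         bins_mi$table$OM), cfg$n_quantiles)
    pmi <- pairwise_mi(cnt, bar_lab, om_lab, seed = cfg$seed + u)
    ok <- !is.na(bins_mi$table$Bar) & !is.na(bins_mi$table$OM)
    enc <- fit_predictive_model(cbind(Bar = bins_mi$table$Bar,
                                      OM = bins_mi$table$OM)[ok, ],
                                cnt[ok], "encode",
                                epoch = bins_mi$epoch[ok],
                                seed = cfg$seed + u)
    coupling[[u]] <- data.frame(
      unit = u,
      cc_bar_peak = cc_bar$peak_cc, cc_bar_lag_s = cc_bar$peak_lag_s,
      cc_bar_sig = cc_bar$significant,
      cc_om_peak = cc_om$peak_cc, cc_om_lag_s = cc_om$peak_lag_s,
      cc_om_sig = cc_om$significant,
      mi2_bits = pmi$mi2$mi_corrected,
      mi1_bits = pmi$mi1_control$mi_corrected,
      encode_acc = enc$accuracy)
    hists[[u]] <- bivariate_rate_histogram(cnt[ok], bins_mi$table$Bar[ok],
                                           bins_mi$table$OM[ok], cfg$bin_s,
                                           n_bins = cfg$n_quantiles)
  }
  coupling <- do.call(rbind, coupling)
  graph <- build_adjacency(hists)
  partition <- newman_communities(graph)
  semantic <- label_communities(partition, hists)
  units_out <- data.frame(unit = seq_len(n_units),
                          community = partition$labels,
                          semantic_label = semantic,
                          modularity = partition$modularity)
  report <- structure(list(config = cfg, coupling = coupling,
                           units = units_out, mi_matrix = mi_mat,
                           variable_clusters = var_clust,
                           reconstruction = recon, state = state,
                           session = session,
                           elapsed_s = as.numeric(difftime(Sys.time(), t_start,
                                                           units = "secs"))),
                      class = "session_report")
  if (!is.null(out_dir)) write_session_report(report, out_dir)
  report
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report> %d units, %d frames; %d/%d units CC-significant (Bar), modularity %.3f\n",
              nrow(x$units), nrow(x$reconstruction$fits),
              sum(x$coupling$cc_bar_sig), nrow(x$coupling),
              x$units$modularity[1]))
  invisible(x)
}

#' Write session artifacts to disk
#'
#' @param report A `session_report`.
#' @param out_dir Target directory.
#' @return `out_dir` invisibly.
#' @export
write_session_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) utils::write.csv(d, file.path(out_dir, f), row.names = FALSE)
  sess <- report$session
  w(sess$observations2d, "landmarks.csv")
  write_cameras(sess$cameras, file.path(out_dir, "calibration.json"))
  w(sess$spikes, "spikes.csv")
  w(data.frame(start_s = sess$kinematics$epochs[, 1],
               end_s = sess$kinematics$epochs[, 2]), "epochs.csv")
  w(report$reconstruction$fits, "fits.csv")
  poses <- report$reconstruction$poses
  long <- data.frame(frame = rep(report$reconstruction$fits$frame,
                                 each = dim(poses)[2]),
                     landmark = rep(dimnames(poses)[[2]], dim(poses)[1]),
                     x = as.vector(t(poses[, , 1])),
                     y = as.vector(t(poses[, , 2])),
                     z = as.vector(t(poses[, , 3])),
                     inlier = as.vector(t(report$reconstruction$inliers)))
  w(long, "poses.csv")
  w(report$state$data, "behavior.csv")
  w(as.data.frame(report$mi_matrix), "mi_matrix.csv")
  w(report$coupling, "coupling.csv")
  w(report$units, "units.csv")
  jsonlite::write_json(list(config = unclass(report$config),
                            elapsed_s = report$elapsed_s,
                            r_version = as.character(getRversion())),
                       file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
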