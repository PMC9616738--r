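# Spike binning and permutation-null cross-correlograms. Correlograms are
# computed per recording epoch on within-epoch standardized series and
# averaged across epochs weighted by epoch length; the null permutes the
# order of the count epochs while the behavioural series stays in place.

#' Bin spike times within recording epochs
#'
#' Counts per `bin_s` bin inside each epoch (trailing partial bins are
#' dropped); behavioural covariates, if supplied, are averaged over the
#' frames falling in each bin. Spikes outside every epoch are ignored and
#' counted in the `dropped_spikes` attribute.
#'
#' @param spike_times Numeric vector of spike times (s), or a data frame
#'   with `unit` and `time_s` columns (then a count matrix is returned).
#' @param epochs Matrix of non-overlapping epoch windows (start_s, end_s).
#' @param bin_s Bin duration in seconds (0.67 for information/prediction
#'   analyses, 0.0667 for correlograms).
#' @param behavior Optional z-scored `behavioral_state` whose variables are
#'   aggregated to the same bins.
#' @return An object of class `binned_counts`: `table` (data frame: epoch,
#'   bin, t_start, t_mid, count or one column per unit, plus covariate
#'   columns), `bin_s`, `epoch` (bin epoch index), `counts` (matrix bins x
#'   units).
#' @export
bin_spikes <- function(spike_times, epochs, bin_s, behavior = NULL) {
  if (bin_s <= 0) stop_invalid("invalid-argument: bin_s must be positive")
  epochs <- as.matrix(epochs)
  if (nrow(epochs) > 1) {
    o <- order(epochs[, 1])
    if (any(epochs[o, 1][-1] < epochs[o, 2][-nrow(epochs)] - 1e-9))
      stop_invalid("epochs overlap")
  }
  if (is.data.frame(spike_times)) {
    units <- sort(unique(spike_times$unit))
    times_by_unit <- split(spike_times$time_s, factor(spike_times$unit, levels = units))
  } else {
    units <- 1L
    times_by_unit <- list(spike_times)
  }
  edges <- list(); meta <- list()
  for (e in seq_len(nrow(epochs))) {
    nb <- floor((epochs[e, 2] - epochs[e, 1]) / bin_s + 1e-9)
    if (nb < 1L) next
    meta[[length(meta) + 1L]] <- data.frame(
      epoch = e, bin = seq_len(nb),
      t_start = epochs[e, 1] + (seq_len(nb) - 1) * bin_s,
      t_mid = epochs[e, 1] + (seq_len(nb) - 0.5) * bin_s)
  }
  tab <- do.call(rbind, meta)
  counts <- matrix(0L, nrow(tab), length(units))
  colnames(counts) <- paste0("u", units)
  dropped <- 0L
  for (u in seq_along(units)) {
    ts <- times_by_unit[[u]]
    inside <- rep(FALSE, length(ts))
    for (e in seq_len(nrow(epochs))) {
      sel <- ts >= epochs[e, 1] & ts < epochs[e, 2]
      inside <- inside | sel
      if (!any(sel)) next
      bi <- floor((ts[sel] - epochs[e, 1]) / bin_s) + 1L
      rows <- which(tab$epoch == e)
      ok <- bi <= length(rows)
      cc <- tabulate(bi[ok], nbins = length(rows))
      counts[rows, u] <- counts[rows, u] + cc
    }
    dropped <- dropped + sum(!inside)
  }
  if (!is.null(behavior)) {
    stopifnot(inherits(behavior, "behavioral_state"))
    bl <- bin_frames(behavior, bin_s)
    if (nrow(bl$table) != nrow(tab) ||
        any(abs(bl$table$t_start - tab$t_start) > 1e-6))
      stop_invalid("behavior epochs do not match spike epochs")
    for (v in state_vars())
      tab[[v]] <- aggregate_to_bins(behavior$data[[v]], bl)
  }
  structure(list(table = tab, counts = counts, bin_s = bin_s,
                 epoch = tab$epoch, units = units,
                 dropped_spikes = dropped),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf("<binned_counts> %d bins x %d units @ %.4g s (%d spikes outside epochs)\n",
              nrow(x$table), ncol(x$counts), x$bin_s, x$dropped_spikes))
  invisible(x)
}

# Lagged cross-correlation of two equal-length epoch segments, both
# standardized within the segment (divisor-n), normalized by the segment
# length so |cc| <= 1 and self-correlation at lag 0 is exactly 1.
#' @keywords internal
epoch_cc <- function(a, b, n_lags) {
  n <- length(a)
  za <- pop_zscore(a); zb <- pop_zscore(b)
  out <- numeric(2L * n_lags + 1L)
  for (l in -n_lags:n_lags) {
    if (l >= 0) {
      idx <- seq_len(n - l)
      out[l + n_lags + 1L] <- sum(za[idx + l] * zb[idx]) / n
    } else {
      idx <- seq_len(n + l)
      out[l + n_lags + 1L] <- sum(za[idx] * zb[idx - l]) / n
    }
  }
  out
}

#' Cross-correlogram between binned counts and a behavioural variable
#'
#' Mean-removed, within-epoch standardized cross-correlation at lags up to
#' `max_lag_s`, computed per epoch and averaged across epochs weighted by
#' epoch length. Positive lags mean spiking follows behaviour. Epochs
#' shorter than twice the maximal lag are excluded.
#'
#' @param binned A `binned_counts` (single unit, or pass `unit`).
#' @param variable Name of a covariate column in `binned$table`, or a
#'   numeric vector aligned to the bins.
#' @param max_lag_s Maximal lag (s), default 2.
#' @param unit Column of the count matrix to use (default 1).
#' @return List with `lag_s`, `cc`, and `excluded_epochs`.
#' @export
cross_correlation <- function(binned, variable, max_lag_s = 2, unit = 1L) {
  stopifnot(inherits(binned, "binned_counts"))
  v <- if (is.character(variable)) binned$table[[variable]] else variable
  if (is.null(v) || length(v) != nrow(binned$table))
    stop_invalid("variable not aligned with bins")
  counts <- binned$counts[, unit]
  n_lags <- round(max_lag_s / binned$bin_s)
  acc <- numeric(2L * n_lags + 1L); wsum <- 0; excl <- integer(0)
  for (e in unique(binned$epoch)) {
    idx <- which(binned$epoch == e)
    if (length(idx) < 2L * n_lags + 1L) { excl <- c(excl, e); next }
    vv <- v[idx]
    if (anyNA(vv)) vv[is.na(vv)] <- mean(vv, na.rm = TRUE)
    acc <- acc + length(idx) * epoch_cc(counts[idx], vv, n_lags)
    wsum <- wsum + length(idx)
  }
  if (wsum == 0) stop_invalid("no epoch long enough for max_lag_s")
  list(lag_s = (-n_lags:n_lags) * binned$bin_s, cc = acc / wsum,
       excluded_epochs = excl)
}

# Pairwise epoch correlogram stack: curve for count-epoch j against
# behaviour-epoch e, truncating both to the shorter length. Returns an
# array [n_pairs = E^2, n_lags] plus the pair weights (overlap lengths).
#' @keywords internal
pairwise_epoch_cc <- function(counts, v, epoch_idx, n_lags) {
  eps <- unique(epoch_idx)
  E <- length(eps)
  L <- 2L * n_lags + 1L
  curves <- array(NA_real_, dim = c(E, E, L))
  w <- matrix(0, E, E)
  seg_c <- lapply(eps, function(e) counts[epoch_idx == e])
  seg_v <- lapply(eps, function(e) {
    x <- v[epoch_idx == e]
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  })
  for (j in seq_len(E)) for (e in seq_len(E)) {
    m <- min(length(seg_c[[j]]), length(seg_v[[e]]))
    if (m < L) next
    curves[j, e, ] <- epoch_cc(seg_c[[j]][seq_len(m)], seg_v[[e]][seq_len(m)], n_lags)
    w[j, e] <- m
  }
  list(curves = curves, w = w, epochs = eps)
}

#' Permutation-null significance of a cross-correlogram
#'
#' The null distribution is built by randomly permuting the order of the
#' count epochs while the behavioural series stays in place, recomputing
#' the full lag curve for each of `n_perm` permutations. The observed curve
#' is significant if any lag falls outside its `[(1-ci_level), ci_level]`
#' null band (default `[0.0005, 0.9995]`). A quantile this extreme cannot
#' be resolved from 1000 values at a single lag, so the band is estimated
#' by studentizing each lag with its null mean and SD and pooling the
#' standardized values across the (exchangeable) lags; the per-lag band is
#' `mean + q * sd` with `q` the pooled standardized quantiles.
#'
#' @inheritParams cross_correlation
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param ci_level Upper quantile of the per-lag null band (default 0.9995).
#' @return An object of class `crosscorr_result`: `lag_s`, `cc`, `null_lo`,
#'   `null_hi`, `significant`, `peak_lag_s`, `peak_cc`, `n_perm`.
#' @export
crosscorr_significance <- function(binned, variable, n_perm = 1000L,
                                   max_lag_s = 2, unit = 1L, seed = 1L,
                                   ci_level = 0.9995) {
  stopifnot(inherits(binned, "binned_counts"))
  v <- if (is.character(variable)) binned$table[[variable]] else variable
  counts <- binned$counts[, unit]
  n_lags <- round(max_lag_s / binned$bin_s)
  L <- 2L * n_lags + 1L
  # keep only epochs long enough for the full lag range
  keep <- names(which(table(binned$epoch) >= L))
  sel <- binned$epoch %in% as.integer(keep)
  epoch_idx <- binned$epoch[sel]
  E <- length(unique(epoch_idx))
  if (E < 10L) stop_invalid("need at least 10 usable epochs for the permutation null")
  pc <- pairwise_epoch_cc(counts[sel], v[sel], epoch_idx, n_lags)
  obs <- numeric(L); wsum <- 0
  for (e in seq_len(E)) {
    if (pc$w[e, e] == 0) next
    obs <- obs + pc$w[e, e] * pc$curves[e, e, ]
    wsum <- wsum + pc$w[e, e]
  }
  obs <- obs / wsum
  perms <- with_seed(seed, t(replicate(n_perm, sample.int(E))))
  null <- matrix(NA_real_, n_perm, L)
  for (p in seq_len(n_perm)) {
    pr <- perms[p, ]
    acc <- numeric(L); ws <- 0
    for (e in seq_len(E)) {
      wje <- pc$w[pr[e], e]
      if (wje == 0) next
      acc <- acc + wje * pc$curves[pr[e], e, ]
      ws <- ws + wje
    }
    null[p, ] <- acc / ws
  }
  m_l <- colMeans(null)
  s_l <- sqrt(colMeans(null^2) - m_l^2)
  s_l[s_l == 0] <- Inf
  z_pool <- sweep(sweep(null, 2, m_l), 2, s_l, `/`)
  qz <- stats::quantile(z_pool, c(1 - ci_level, ci_level), names = FALSE)
  lo <- m_l + qz[1] * s_l
  hi <- m_l + qz[2] * s_l
  sig <- any(obs < lo | obs > hi)
  pk <- which.max(abs(obs))
  lag_s <- (-n_lags:n_lags) * binned$bin_s
  structure(list(lag_s = lag_s, cc = obs, null_lo = lo, null_hi = hi,
                 significant = sig, peak_lag_s = lag_s[pk], peak_cc = obs[pk],
                 n_perm = n_perm, n_epochs = E),
            class = "crosscorr_result")
}

#' @export
print.crosscorr_result <- function(x, ...) {
  cat(sprintf("<crosscorr_result> peak %.3f at %+.3f s; %ssignificant (%d perms, %d epochs)\n",
              x$peak_cc, x$peak_lag_s, if (x$significant) "" else "not ",
              x$n_perm, x$n_epochs))
  invisible(x)
}

#' Batched permutation-null cross-correlograms
#'
#' Identical computation to [crosscorr_significance()] vectorized across
#' many units that share the same behavioural series and equal-length
#' epochs (the calibration setting). Null curves are materialized for
#' blocks of `block_units` units at a time so memory stays bounded.
#'
#' @param counts_matrix `units x bins` integer matrix.
#' @param v Behavioural series over bins.
#' @param epoch_idx Epoch index per bin; all epochs must have equal length.
#' @param n_perm,seed,ci_level,bin_s,max_lag_s As in
#'   [crosscorr_significance()].
#' @param block_units Units processed per internal block (default 250).
#' @return List with `cc` (units x lags observed curves), `significant`
#'   (logical per unit), `peak_lag_s`, `lag_s`, `null_lo`, `null_hi`.
#' @export
crosscorr_significance_batch <- function(counts_matrix, v, epoch_idx,
                                         bin_s, n_perm = 1000L, max_lag_s = 2,
                                         seed = 1L, ci_level = 0.9995,
                                         block_units = 250L) {
  n_lags <- round(max_lag_s / bin_s)
  L <- 2L * n_lags + 1L
  eps <- unique(epoch_idx)
  E <- length(eps)
  if (E < 10L) stop_invalid("need at least 10 epochs")
  lens <- vapply(eps, function(e) sum(epoch_idx == e), integer(1))
  if (length(unique(lens)) != 1L)
    stop_invalid("batch path requires equal-length epochs")
  n <- lens[1]
  if (n < L) stop_invalid("epochs shorter than the lag range")
  U <- nrow(counts_matrix)
  # within-epoch standardization
  Z <- matrix(NA_real_, U, length(epoch_idx))
  Vz <- numeric(length(epoch_idx))
  for (e in eps) {
    idx <- which(epoch_idx == e)
    seg <- counts_matrix[, idx, drop = FALSE]
    mu <- rowMeans(seg)
    sd_ <- sqrt(rowMeans(seg^2) - mu^2)
    sd_[sd_ == 0] <- Inf
    Z[, idx] <- (seg - mu) / sd_
    Vz[idx] <- pop_zscore(v[idx])
  }
  # lag-shifted copies of each behaviour epoch: n x L with zero padding
  shifted <- lapply(seq_len(E), function(e) {
    idx <- which(epoch_idx == eps[e])
    zb <- Vz[idx]
    S <- matrix(0, n, L)
    for (l in -n_lags:n_lags) {
      col <- l + n_lags + 1L
      if (l >= 0) S[(l + 1):n, col] <- zb[seq_len(n - l)]
      else S[seq_len(n + l), col] <- zb[(1 - l):n]
    }
    S
  })
  # pairwise curves: for pair (j, e), Z_j %*% shifted_e / n  -> U x L
  curves <- vector("list", E * E)
  for (j in seq_len(E)) {
    idxj <- which(epoch_idx == eps[j])
    Zj <- Z[, idxj, drop = FALSE]
    for (e in seq_len(E)) {
      curves[[(j - 1L) * E + e]] <- (Zj %*% shifted[[e]]) / n
    }
  }
  obs <- Reduce(`+`, lapply(seq_len(E), function(e) curves[[(e - 1L) * E + e]])) / E
  perms <- with_seed(seed, t(replicate(n_perm, sample.int(E))))
  lo <- hi <- matrix(NA_real_, U, L)
  for (ublock in split(seq_len(U), ceiling(seq_len(U) / block_units))) {
    nb <- length(ublock)
    null_arr <- array(NA_real_, dim = c(n_perm, nb, L))
    for (p in seq_len(n_perm)) {
      pr <- perms[p, ]
      acc <- curves[[(pr[1] - 1L) * E + 1L]][ublock, , drop = FALSE]
      for (e in 2:E)
        acc <- acc + curves[[(pr[e] - 1L) * E + e]][ublock, , drop = FALSE]
      null_arr[p, , ] <- acc / E
    }
    flat <- matrix(null_arr, n_perm, nb * L)
    m_ul <- matrix(colMeans(flat), nb, L)
    s_ul <- matrix(sqrt(pmax(colMeans(flat^2) - colMeans(flat)^2, 0)), nb, L)
    s_ul[s_ul == 0] <- Inf
    for (j in seq_len(nb)) {
      zs <- sweep(sweep(null_arr[, j, ], 2, m_ul[j, ]), 2, s_ul[j, ], `/`)
      qz <- stats::quantile(zs, c(1 - ci_level, ci_level), names = FALSE)
      lo[ublock[j], ] <- m_ul[j, ] + qz[1] * s_ul[j, ]
      hi[ublock[j], ] <- m_ul[j, ] + qz[2] * s_ul[j, ]
    }
  }
  sig <- rowSums(obs < lo | obs > hi) > 0
  lag_s <- (-n_lags:n_lags) * bin_s
  pk <- apply(abs(obs), 1, which.max)
  list(cc = obs, significant = sig, peak_lag_s = lag_s[pk], lag_s = lag_s,
       null_lo = lo, null_hi = hi)
}

#' Tuning-curve stability between two conditions
#'
#' Per-unit Pearson correlation between concatenated cross-correlogram
#' curves measured in two conditions (e.g. dark and light), against a null
#' built by randomly re-pairing units across conditions.
#'
#' @param cc_condition1,cc_condition2 `units x values` matrices of
#'   concatenated correlogram curves (same unit order in both).
#' @param n_shuffles Number of random re-pairings (default 10000).
#' @param seed Integer seed.
#' @return List with `rho_cc` (per-unit correlations), `observed_mean`,
#'   `null_mean` (shuffle means), `p_value` (fraction of shuffles with mean
#'   at least the observed).
#' @export
compare_tuning <- function(cc_condition1, cc_condition2, n_shuffles = 10000L,
                           seed = 1L) {
  A <- as.matrix(cc_condition1); B <- as.matrix(cc_condition2)
  if (nrow(A) != nrow(B) || ncol(A) != ncol(B))
    stop_invalid("condition matrices must match")
  if (nrow(A) < 5L) stop_invalid("need at least 5 shared units")
  n <- nrow(A)
  Cfull <- stats::cor(t(A), t(B))          # C[i, j] = cor(unit_i cond1, unit_j cond2)
  rho <- diag(Cfull)
  null <- with_seed(seed, vapply(seq_len(n_shuffles), function(s) {
    pr <- sample.int(n)
    mean(Cfull[cbind(seq_len(n), pr)])
  }, numeric(1)))
  list(rho_cc = rho, observed_mean = mean(rho), null_mean = null,
       p_value = mean(null >= mean(rho)))
}
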