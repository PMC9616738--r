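# Magnitude-squared coherence between frame-rate spike counts and
# behavioural variables: Welch cross-spectra within each epoch, coherence
# per epoch, averaged across epochs; the null band comes from circular
# random shifts of the behavioural series within epochs.

# Welch auto-/cross-spectra of one epoch segment pair (Hann window, 50%
# overlap). Returns accumulated Pxx, Pyy, Pxy (complex) and segment count.
#' @keywords internal
welch_spectra <- function(x, y, nfft) {
  n <- length(x)
  step <- nfft %/% 2L
  starts <- seq(1L, n - nfft + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nfft) / (nfft + 1)))  # Hann
  nf <- nfft %/% 2L + 1L
  pxx <- pyy <- numeric(nf); pxy <- complex(nf)
  for (s in starts) {
    xs <- (x[s:(s + nfft - 1L)] - mean(x[s:(s + nfft - 1L)])) * w
    ys <- (y[s:(s + nfft - 1L)] - mean(y[s:(s + nfft - 1L)])) * w
    fx <- stats::fft(xs)[seq_len(nf)]
    fy <- stats::fft(ys)[seq_len(nf)]
    pxx <- pxx + Mod(fx)^2
    pyy <- pyy + Mod(fy)^2
    pxy <- pxy + fx * Conj(fy)
  }
  list(pxx = pxx, pyy = pyy, pxy = pxy, n_seg = length(starts))
}

# MSC of one epoch from Welch-averaged spectra.
#' @keywords internal
epoch_msc <- function(x, y, nfft) {
  sp <- welch_spectra(x, y, nfft)
  msc <- Mod(sp$pxy)^2 / (sp$pxx * sp$pyy)
  msc[sp$pxx == 0 | sp$pyy == 0] <- NA_real_
  msc
}

#' Magnitude-squared coherence with a shift-control null band
#'
#' Welch-style MSC (Hann window, 50% overlap) between binned counts and a
#' behavioural variable, computed per epoch and averaged across epochs,
#' from 0 to the Nyquist frequency of the bin rate. The null band is the
#' mean plus/minus two standard deviations of the MSC recomputed after
#' circular random shifts of the behavioural series within each epoch.
#'
#' @param binned A `binned_counts` at frame resolution (e.g. 1/15 s bins).
#' @param variable Covariate column name or aligned numeric vector.
#' @param n_shifts Number of random shifts for the null (default 100).
#' @param seed Integer seed.
#' @param nfft Welch segment length in bins (default 64).
#' @param unit Count column (default 1).
#' @param min_epoch_s Epochs shorter than this are excluded (default 8 s).
#' @return List with `freq_hz`, `msc`, `null_mean`, `null_sd`, `null_hi`
#'   (`mean + 2 sd`), `n_epochs`.
#' @export
magnitude_squared_coherence <- function(binned, variable, n_shifts = 100L,
                                        seed = 1L, nfft = 64L, unit = 1L,
                                        min_epoch_s = 8) {
  stopifnot(inherits(binned, "binned_counts"))
  v <- if (is.character(variable)) binned$table[[variable]] else variable
  counts <- binned$counts[, unit]
  fs <- 1 / binned$bin_s
  min_bins <- max(nfft, ceiling(min_epoch_s * fs))
  eps <- unique(binned$epoch)
  segs <- list()
  for (e in eps) {
    idx <- which(binned$epoch == e)
    if (length(idx) < min_bins) next
    vv <- v[idx]
    if (anyNA(vv)) vv[is.na(vv)] <- mean(vv, na.rm = TRUE)
    segs[[length(segs) + 1L]] <- list(c = counts[idx], v = vv)
  }
  if (!length(segs)) stop_invalid("no epoch of at least ", min_epoch_s, " s")
  nf <- nfft %/% 2L + 1L
  avg_msc <- function(shift_fn) {
    acc <- numeric(nf); m <- 0L
    for (sg in segs) {
      msc <- epoch_msc(sg$c, shift_fn(sg$v), nfft)
      if (anyNA(msc)) msc[is.na(msc)] <- 0
      acc <- acc + msc; m <- m + 1L
    }
    acc / m
  }
  obs <- avg_msc(identity)
  null_mat <- with_seed(seed, {
    vapply(seq_len(n_shifts), function(s) {
      avg_msc(function(z) {
        k <- sample.int(length(z) - 1L, 1L)
        c(z[(k + 1L):length(z)], z[seq_len(k)])
      })
    }, numeric(nf))
  })
  null_mean <- rowMeans(null_mat)
  null_sd <- apply(null_mat, 1, stats::sd)
  list(freq_hz = (seq_len(nf) - 1L) * fs / nfft, msc = obs,
       null_mean = null_mean, null_sd = null_sd,
       null_hi = null_mean + 2 * null_sd, n_epochs = length(segs))
}
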