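#' Estimate a spectro-temporal receptive field by reverse correlation
#'
#' For rippled-noise or white stimuli (approximately uncorrelated across
#' frequency channels), the STRF weight at (channel f, lag tau) is the
#' lag-tau cross-correlation of the mean-subtracted rate with channel f,
#' normalized by the channel variance.
#'
#' @param stim_spectrogram Channel x time matrix (stimulus power per bin).
#' @param rate Firing-rate time series on the same bin grid.
#' @param n_lags Number of non-negative lags (bins).
#' @param freqs Channel center frequencies in Hz (default log-spaced
#'   0.5-16 kHz).
#' @param bin_rate Bins per second (for the lag grid).
#' @return Object of class `STRF`: `w` (channel x lag), `freqs`, `lags` (s).
#' @export
estimate_strf <- function(stim_spectrogram, rate, n_lags = 15,
                          freqs = NULL, bin_rate = 20) {
  stim <- as.matrix(stim_spectrogram)
  n <- ncol(stim)
  stopifnot(length(rate) == n)
  if (is.null(freqs)) {
    freqs <- 2^seq(log2(500), log2(16000), length.out = nrow(stim))
  }
  r <- rate - mean(rate)
  w <- matrix(0, nrow(stim), n_lags)
  for (f in seq_len(nrow(stim))) {
    v <- stats::var(stim[f, ])
    if (v == 0) {
      warning("zero-variance stimulus channel ", f, "; weights set to 0")
      next
    }
    sf <- stim[f, ] - mean(stim[f, ])
    for (l in seq_len(n_lags)) {
      lag <- l - 1L
      idx <- (1 + lag):n
      w[f, l] <- mean(r[idx] * sf[idx - lag]) / v
    }
  }
  structure(list(w = w, freqs = freqs,
                 lags = (seq_len(n_lags) - 1) / bin_rate),
            class = "STRF")
}

#' Best frequency from an STRF
#'
#' Rank-1 decomposition of the STRF matrix; the first-principal-component
#' spectral tuning vector is sign-aligned so its maximum-magnitude
#' coefficient is positive, and BF is the center of mass of its positive
#' part on the log-frequency axis, mapped back to Hz.
#'
#' @param strf An [estimate_strf()] result.
#' @return BF in Hz, or `NA` (with a warning) for an all-zero STRF.
#' @export
best_frequency <- function(strf) {
  w <- strf$w
  if (all(w == 0)) {
    warning("all-zero STRF: best frequency undefined")
    return(NA_real_)
  }
  sv <- svd(w)
  u1 <- sv$u[, 1]
  u1 <- u1 * sign(u1[which.max(abs(u1))])
  pos <- pmax(u1, 0)
  lf <- log2(strf$freqs)
  2^(sum(lf * pos) / sum(pos))
}

#' Single-trial response reliability (SNR)
#'
#' Split-half estimator: trials of one stimulus are randomly halved, the
#' two half-PSTHs correlated, and the correlation Spearman-Brown corrected
#' (`2r/(1+r)`); the mean over random splits, floored at 0, is returned.
#' Deterministic given the seed.
#'
#' @param per_trial_responses Trial x time matrix (>= 4 trials).
#' @param n_splits Number of random splits (default 50).
#' @param seed Seed for the splits.
#' @return SNR in `[0, 1]` (0 for constant responses, with a warning). The
#'   unfloored split-half mean — which is the right quantity for null
#'   calibration, since flooring induces a positive bias — is attached as
#'   attribute `"raw"`.
#' @export
response_snr <- function(per_trial_responses, n_splits = 50, seed = 1) {
  m <- as.matrix(per_trial_responses)
  stopifnot(nrow(m) >= 4)
  if (stats::sd(as.vector(m)) == 0) {
    warning("constant responses: SNR set to 0")
    return(structure(0, raw = 0))
  }
  n <- nrow(m)
  h <- n %/% 2
  vals <- with_seed(seed, vapply(seq_len(n_splits), function(i) {
    a <- sample.int(n, h)
    p1 <- colMeans(m[a, , drop = FALSE])
    p2 <- colMeans(m[-a, , drop = FALSE])
    if (stats::sd(p1) == 0 || stats::sd(p2) == 0) return(NA_real_)
    r <- stats::cor(p1, p2)
    if (r <= -0.999) return(NA_real_)  # degenerate split
    2 * r / (1 + r)
  }, numeric(1)))
  raw <- mean(vals, na.rm = TRUE)
  structure(max(raw, 0), raw = raw)
}
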