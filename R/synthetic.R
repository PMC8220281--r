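#' Construct a multichannel recording segment
#'
#' A recording segment is the package's container for a short multichannel
#' recording: a channels-by-samples numeric matrix plus its sampling rate
#' and labels.  All downstream stages (filtering, embedded point cloud,
#' per-channel ordinal partition networks) consume this class.
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param channel_ids optional character vector of channel labels.
#' @param subject subject label.
#' @param condition condition label (e.g. "awake", "propofol",
#'   "synthetic-rich").
#' @return an object of class `recording_segment`.
#' @export
recording_segment <- function(data, fs, channel_ids = NULL,
                              subject = "unknown", condition = "unknown") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (any(!is.finite(data))) stop("`data` contains non-finite entries")
  if (nrow(data) < 1L || ncol(data) < 2L)
    stop("need at least 1 channel and 2 samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_ids) != nrow(data))
    stop("channel_ids length must equal the number of channels")
  structure(
    list(data = data, fs = fs, channel_ids = as.character(channel_ids),
         subject = subject, condition = condition),
    class = "recording_segment")
}

#' @export
print.recording_segment <- function(x, ...) {
  cat(sprintf(
    "<recording_segment> %d channels x %d samples @ %g Hz (%.3g s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  subject: %s   condition: %s\n", x$subject, x$condition))
  invisible(x)
}

#' @export
dim.recording_segment <- function(x) dim(x$data)

#' Generate a sinusoid
#'
#' @param freq frequency in Hz; must lie strictly below the Nyquist rate.
#' @param fs sampling rate in Hz.
#' @param n number of samples.
#' @param amplitude,phase amplitude and phase (radians).
#' @return numeric vector of length `n`.
#' @export
gen_sine <- function(freq, fs, n, amplitude = 1, phase = 0) {
  if (freq <= 0 || freq >= fs / 2)
    stop(sprintf("freq must satisfy 0 < freq < fs/2 = %g Hz (got %g)",
                 fs / 2, freq))
  if (n < 1L) stop("n must be >= 1")
  t <- seq_len(n) - 1L
  amplitude * sin(2 * pi * freq * t / fs + phase)
}

#' Generate a logistic-map orbit
#'
#' Iterates `x[t+1] = r * x[t] * (1 - x[t])`.  At `r = 4` the map is fully
#' chaotic with largest Lyapunov exponent `log(2)` nats/step, making it the
#' standard fixture for Lyapunov-estimator validation.
#'
#' @param r map rate, `0 < r <= 4`.
#' @param x0 initial condition in (0, 1).
#' @param n orbit length.
#' @return numeric vector of length `n` starting at `x0`.
#' @export
gen_logistic <- function(r, x0, n) {
  if (r <= 0 || r > 4) stop("r must satisfy 0 < r <= 4")
  if (x0 <= 0 || x0 >= 1) stop("x0 must lie strictly in (0, 1)")
  if (n < 1L) stop("n must be >= 1")
  if (r == 4 && x0 %in% c(0.5))
    warning("degenerate orbit: x0 maps into the fixed point at 0 under r = 4")
  x <- numeric(n)
  x[1] <- x0
  if (n > 1L) for (t in seq_len(n - 1L)) x[t + 1L] <- r * x[t] * (1 - x[t])
  x
}

#' Generate a first-order autoregressive series
#'
#' `x[t+1] = phi * x[t] + e[t]` with Gaussian innovations of standard
#' deviation `sigma`, started at `x0`.
#'
#' @param phi AR coefficient, `|phi| < 1` (stationarity).
#' @param sigma innovation standard deviation.
#' @param n series length.
#' @param seed integer seed; the same seed reproduces the series exactly.
#' @param x0 starting value.
#' @return numeric vector of length `n`.
#' @export
gen_ar1 <- function(phi, sigma, n, seed = NULL, x0 = 0) {
  if (abs(phi) >= 1) stop("|phi| must be < 1 (non-stationary otherwise)")
  if (n < 1L) stop("n must be >= 1")
  eps <- with_seed(seed, rnorm(n, mean = 0, sd = sigma))
  x <- numeric(n)
  x[1] <- phi * x0 + eps[1]
  if (n > 1L) for (t in seq_len(n - 1L)) x[t + 1L] <- phi * x[t] + eps[t + 1L]
  x
}

#' Generate a noisy circle point cloud
#'
#' `n` angle-uniform points on a circle plus isotropic Gaussian noise; the
#' canonical fixture carrying exactly one one-dimensional homology class.
#'
#' @param n number of points (>= 3).
#' @param radius circle radius (> 0).
#' @param noise standard deviation of isotropic Gaussian jitter.
#' @param seed integer seed.
#' @return an `n` x 2 numeric matrix.
#' @export
gen_circle_cloud <- function(n, radius = 1, noise = 0, seed = NULL) {
  if (n < 3L) stop("n must be >= 3")
  if (radius <= 0) stop("radius must be > 0")
  if (noise < 0) stop("noise must be >= 0")
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  pts <- cbind(x = radius * cos(theta), y = radius * sin(theta))
  if (noise > 0) pts <- pts + with_seed(seed, matrix(rnorm(2L * n, sd = noise), ncol = 2L))
  pts
}

#' Generate a synthetic multichannel regime segment
#'
#' Produces surrogate multichannel segments in one of three dynamical
#' regimes ordered by dynamical richness, emulating the qualitative
#' contrast between awake-like and deeply sedated cortical activity:
#'
#' * `rich`: every channel is an independent (weakly coupled) chaotic
#'   source summed with an equal-variance independent broadband source --
#'   a large micro-state repertoire, high permutation entropy, weakly
#'   predictable transitions, positive Lyapunov exponent.
#' * `poor`: one shared slow (2 Hz) oscillation projected to all channels
#'   with per-channel gains -- a low-entropy, highly deterministic,
#'   nearly rank-one regime.
#' * `intermediate`: half of the channels carry the rich-type signal and
#'   half the poor-type shared oscillation (partial penetration of the
#'   sedated mode across the array), so channel-aggregated measures land
#'   between the two extremes.
#'
#' Independent low-frequency-weighted (AR(1), phi = 0.95) noise of
#' relative scale `noise_scale` is added to every channel in every
#' regime.  The regimes are defined operationally by the fraction of
#' broadband-chaotic channels (1, 1/2, 0) -- a strict entropy ordering
#' rich > intermediate > poor; no biophysical realism is claimed.
#'
#' @param regime one of "rich", "intermediate", "poor".
#' @param n_channels number of channels.
#' @param duration_s segment duration in seconds; `duration_s * fs` must be
#'   a whole number of samples.
#' @param fs sampling rate in Hz.
#' @param coupling in \[0, 1\]: mean-field coupling strength between the
#'   chaotic sources (rich/intermediate regimes).
#' @param noise_scale standard deviation of the independent per-channel
#'   AR(1) noise relative to the unit-variance signal components.
#' @param seed integer seed; same seed, same segment, bit for bit.
#' @return a [recording_segment] with condition label
#'   `"synthetic-<regime>"`.
#' @export
gen_regime <- function(regime = c("rich", "intermediate", "poor"),
                       n_channels = 16, duration_s = 10, fs = 250,
                       coupling = 0.05, noise_scale = 0.1, seed = 1) {
  regime <- match.arg(regime)
  n <- duration_s * fs
  if (abs(n - round(n)) > 1e-9)
    stop("duration_s * fs must be an integer number of samples")
  n <- as.integer(round(n))
  if (n_channels < 1L) stop("n_channels must be >= 1")
  if (coupling < 0 || coupling > 1) stop("coupling must lie in [0, 1]")
  if (noise_scale < 0) stop("noise_scale must be >= 0")

  # fraction of channels carrying the broadband-chaotic (awake-like)
  # signal; the remainder carry the shared slow oscillation
  rich_frac <- switch(regime, rich = 1, intermediate = 0.5, poor = 0)
  C <- n_channels
  n_rich <- round(rich_frac * C)
  is_rich <- seq_len(C) <= n_rich  # first channels rich-type, rest poor-type

  data <- with_seed(seed, {
    out <- matrix(0, nrow = C, ncol = n)

    if (n_rich > 0L) {
      # weakly mean-field-coupled logistic maps, one per rich channel,
      # burn-in discarded; centred and scaled to unit variance
      # (arcsine-law SD of the r = 4 logistic map is sqrt(1/8))
      burn <- 100L
      x <- runif(n_rich, 0.05, 0.95)
      chaos <- matrix(0, nrow = n_rich, ncol = n)
      for (t in seq_len(burn + n)) {
        fx <- 4 * x * (1 - x)
        x <- (1 - coupling) * fx + coupling * mean(fx)
        x <- pmin(pmax(x, 1e-12), 1 - 1e-12)  # guard numerical escape
        if (t > burn) chaos[, t - burn] <- x
      }
      chaos <- (chaos - 0.5) / sqrt(1 / 8)
      # equal-variance independent broadband component (AR(1), phi = 0.3):
      # awake-like channels are chaos embedded in broadband activity, not
      # a bare deterministic map
      for (c in seq_len(n_rich)) {
        e <- rnorm(n)
        b <- numeric(n)
        b[1] <- e[1]
        for (t in seq_len(n - 1L)) b[t + 1L] <- 0.3 * b[t] + e[t + 1L]
        out[c, ] <- (chaos[c, ] + b * sqrt(1 - 0.3^2)) / sqrt(2)
      }
    }

    if (n_rich < C) {
      phase <- runif(1, 0, 2 * pi)
      shared <- sqrt(2) * sin(2 * pi * 2 * (seq_len(n) - 1L) / fs + phase)
      gains <- runif(C - n_rich, 0.5, 1.5)
      out[!is_rich, ] <- gains %o% shared
    }

    if (noise_scale > 0) {
      # AR(1) with phi = 0.95: 1/f-like low-frequency-weighted noise,
      # scaled to unit marginal SD before applying noise_scale
      phi <- 0.95
      for (c in seq_len(C)) {
        e <- rnorm(n)
        z <- numeric(n)
        z[1] <- e[1]
        for (t in seq_len(n - 1L)) z[t + 1L] <- phi * z[t] + e[t + 1L]
        out[c, ] <- out[c, ] + noise_scale * z * sqrt(1 - phi^2)
      }
    }
    out
  })

  recording_segment(data, fs = fs, subject = sprintf("synthetic-seed%d", seed),
                    condition = paste0("synthetic-", regime))
}
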