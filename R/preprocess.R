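# Signal conditioning: zero-phase FIR band limiting, mains notches with
# harmonics, edge trimming and global z-scoring.

# Apply a linear-phase FIR kernel forwards and backwards (zero net phase).
# Implemented in the frequency domain: double application multiplies the
# spectrum by |H(f)|^2, which is real, so no phase is introduced.  The
# series is odd-reflection padded by the kernel length at both ends to
# suppress wrap-around transients before the circular convolution.
fir_filtfilt <- function(x, h) {
  n <- length(x)
  L <- length(h)
  if (n <= 3L * L)
    stop(sprintf(
      "series too short for zero-phase filtering: length %d, need > %d (3 x filter length %d)",
      n, 3L * L, L))
  pad <- L
  left <- 2 * x[1] - x[seq(pad + 1L, 2L, by = -1L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad, by = -1L)]
  xp <- c(left, x, right)
  np <- length(xp)
  nfft <- nextn(np + 2L * L, 2)
  H <- fft(c(h, rep(0, nfft - L)))
  X <- fft(c(xp, rep(0, nfft - np)))
  # |H(f)|^2 is real and non-negative: the equivalent two-pass kernel is
  # symmetric about lag zero, so the output is already delay-free
  y <- Re(fft(X * Mod(H)^2, inverse = TRUE)) / nfft
  y[(pad + 1L):(pad + n)]
}

# Windowed-sinc FIR order for a given transition width (Hamming: ~3.3/tw).
fir_order <- function(fs, transition_hz) {
  n <- ceiling(3.3 * fs / transition_hz)
  if (n %% 2L == 1L) n <- n + 1L  # even order -> odd length, type-I FIR
  n
}

#' Band-limit and notch-filter a recording segment
#'
#' Applies, in order: a high-pass stage, a low-pass FIR, and band-stop
#' notches at the mains frequency and all harmonics up to `notch_max`.
#' All FIR filters are windowed-sinc (Hamming) designs applied forwards
#' and backwards, so the net phase response is zero.  Very low high-pass
#' edges (< 1 Hz) cannot be realized by an FIR short enough for
#' ten-second segments; in that case the high-pass stage is per-channel
#' mean removal, and the path taken is recorded in the
#' `"highpass_path"` attribute of the result.
#'
#' @param seg a [recording_segment].
#' @param hp high-pass edge in Hz (0 disables).
#' @param lp low-pass edge in Hz; must lie below Nyquist.
#' @param notch_base mains frequency in Hz (0 disables notching).
#' @param notch_max highest harmonic to notch, inclusive.
#' @param notch_halfwidth_hz half-width of each notch stop band.
#' @return the filtered [recording_segment], same shape as the input.
#' @export
apply_filters <- function(seg, hp = 0.1, lp = 200, notch_base = 50,
                          notch_max = 250, notch_halfwidth_hz = 2) {
  stopifnot(inherits(seg, "recording_segment"))
  fs <- seg$fs
  nyq <- fs / 2
  if (lp >= nyq) stop(sprintf("low-pass edge %g Hz must lie below Nyquist (%g Hz)", lp, nyq))
  if (hp < 0 || hp >= lp) stop("need 0 <= hp < lp")
  x <- seg$data
  n <- ncol(x)

  hp_path <- "none"
  if (hp > 0) {
    if (hp < 1) {
      # FIR high-pass at sub-hertz edges needs tens of seconds of data;
      # remove the DC component per channel instead
      x <- x - rowMeans(x)
      hp_path <- "mean-removal"
    } else {
      tw <- max(0.25 * hp, 2)
      h <- signal::fir1(fir_order(fs, tw), hp / nyq, type = "high")
      x <- t(apply(x, 1L, fir_filtfilt, h = h))
      hp_path <- "fir"
    }
  }

  tw_lp <- max(0.25 * lp, 2)
  h_lp <- signal::fir1(fir_order(fs, tw_lp), lp / nyq, type = "low")
  if (n <= 3L * length(h_lp))
    stop(sprintf("segment too short for the low-pass filter: %d samples, need > %d",
                 n, 3L * length(h_lp)))
  x <- t(apply(x, 1L, fir_filtfilt, h = h_lp))

  if (notch_base > 0) {
    freqs <- seq(notch_base, notch_max, by = notch_base)
    freqs <- freqs[freqs + notch_halfwidth_hz < nyq]
    if (length(freqs)) {
      h_notch <- lapply(freqs, function(f0) {
        band <- c(f0 - notch_halfwidth_hz, f0 + notch_halfwidth_hz) / nyq
        signal::fir1(fir_order(fs, notch_halfwidth_hz), band, type = "stop")
      })
      lens <- vapply(h_notch, length, integer(1))
      if (n <= 3L * max(lens))
        stop(sprintf("segment too short for the notch filters: %d samples, need > %d",
                     n, 3L * max(lens)))
      for (h in h_notch) x <- t(apply(x, 1L, fir_filtfilt, h = h))
    }
  }

  out <- recording_segment(x, fs = fs, channel_ids = seg$channel_ids,
                           subject = seg$subject, condition = seg$condition)
  attr(out, "highpass_path") <- hp_path
  out
}

#' Trim filter transients from both ends of a segment
#'
#' @param seg a [recording_segment].
#' @param trim_ms duration removed from each end, in milliseconds.
#' @return the trimmed segment; `T' = T - 2 * round(trim_ms * fs / 1000)`.
#' @export
trim_edges <- function(seg, trim_ms = 50) {
  stopifnot(inherits(seg, "recording_segment"))
  if (trim_ms < 0) stop("trim_ms must be >= 0")
  k <- round(trim_ms * seg$fs / 1000)
  n <- ncol(seg$data)
  if (2 * k >= n)
    stop(sprintf("trimming 2 x %d samples would exhaust the %d-sample segment", k, n))
  if (k == 0) return(seg)
  recording_segment(seg$data[, (k + 1L):(n - k), drop = FALSE], fs = seg$fs,
                    channel_ids = seg$channel_ids, subject = seg$subject,
                    condition = seg$condition)
}

#' Z-score a segment as a set
#'
#' One mean and one standard deviation are computed over the entire
#' channels-by-samples matrix and applied globally, preserving the
#' relative amplitudes between channels (per-channel scaling would
#' destroy exactly the between-channel structure the embedded point
#' cloud analyses).
#'
#' @param seg a [recording_segment].
#' @return the globally standardized segment.
#' @export
zscore_global <- function(seg) {
  stopifnot(inherits(seg, "recording_segment"))
  mu <- mean(seg$data)
  sigma <- sd(as.vector(seg$data))
  if (!is.finite(sigma) || sigma <= 0)
    stop("segment is constant: pooled standard deviation is zero")
  recording_segment((seg$data - mu) / sigma, fs = seg$fs,
                    channel_ids = seg$channel_ids, subject = seg$subject,
                    condition = seg$condition)
}

#' Read / write recording segments as delimited text
#'
#' The on-disk format is plain text: a comment header line
#' `# fs=<Hz> subject=<label> condition=<label>` followed by a
#' channels-by-samples table whose first column holds the channel ids.
#'
#' @param seg a [recording_segment].
#' @param path file path.
#' @return `read_segment` returns a [recording_segment];
#'   `write_segment` returns `path` invisibly.
#' @export
write_segment <- function(seg, path) {
  stopifnot(inherits(seg, "recording_segment"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g subject=%s condition=%s",
                     seg$fs, seg$subject, seg$condition), con)
  df <- data.frame(channel = seg$channel_ids, seg$data,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = ",", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_segment
#' @export
read_segment <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#"))
    stop("missing metadata header line ('# fs=... subject=... condition=...')")
  kv <- regmatches(header, gregexpr("[a-z]+=[^ ]+", header))[[1]]
  meta <- setNames(sub("^[a-z]+=", "", kv), sub("=.*$", "", kv))
  if (!"fs" %in% names(meta)) stop("header does not declare fs")
  df <- read.table(path, sep = ",", skip = 1L, header = FALSE,
                   stringsAsFactors = FALSE)
  data <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(data) <- NULL
  grab <- function(key) if (key %in% names(meta)) meta[[key]] else "unknown"
  recording_segment(data, fs = as.numeric(meta[["fs"]]),
                    channel_ids = df[[1L]],
                    subject = grab("subject"), condition = grab("condition"))
}
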