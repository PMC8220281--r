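# Embedded point cloud: per-timepoint channel vectors, state-space
# velocity, pairwise dissimilarities and landmark subsampling.

#' Build the embedded point cloud of a segment
#'
#' Each time point of a (z-scored) segment becomes one point in
#' C-dimensional channel space; the cloud preserves recording order and
#' traces the system's trajectory through its state space.
#'
#' @param seg a [recording_segment], normally after [zscore_global()].
#' @param metric dissimilarity convention carried by the cloud:
#'   `"cosine"` (default, as used for the Rips filtration) or
#'   `"euclidean"`.
#' @return an object of class `point_cloud`: a `T x C` matrix of points
#'   (rows are time points) plus the metric label.
#' @export
build_epc <- function(seg, metric = c("cosine", "euclidean")) {
  stopifnot(inherits(seg, "recording_segment"))
  metric <- match.arg(metric)
  if (metric == "cosine" && nrow(seg$data) < 2L)
    stop("cosine dissimilarity is degenerate for fewer than 2 channels")
  structure(list(points = t(seg$data), metric = metric),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points in %d dimensions (%s metric)\n",
              nrow(x$points), ncol(x$points), x$metric))
  invisible(x)
}

#' State-space velocity of an embedded trajectory
#'
#' Cosine dissimilarity between temporally consecutive state vectors,
#' `v[t] = 1 - cos(p_t, p_{t+1})`, a sampling-rate-proportional
#' "velocity" of the system through channel space.  Zero-norm states make
#' the cosine undefined; those entries are returned as `NA` and their
#' indices reported in the `"undefined_at"` attribute.
#'
#' @param cloud a `point_cloud`.
#' @return numeric vector of length `T - 1` in \[0, 2\], with the mean
#'   velocity in the `"average_velocity"` attribute.
#' @export
state_velocity <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  p <- cloud$points
  if (nrow(p) < 2L) stop("need at least two time points")
  nrm <- sqrt(rowSums(p^2))
  num <- rowSums(p[-nrow(p), , drop = FALSE] * p[-1L, , drop = FALSE])
  den <- nrm[-length(nrm)] * nrm[-1L]
  v <- ifelse(den > 0, 1 - num / den, NA_real_)
  v <- pmin(pmax(v, 0), 2)
  bad <- which(is.na(v))
  if (length(bad))
    warning(sprintf("velocity undefined at %d transition(s) with a zero-norm state",
                    length(bad)))
  structure(v, average_velocity = mean(v, na.rm = TRUE),
            undefined_at = bad)
}

#' Pairwise dissimilarity matrix of a point cloud
#'
#' Cosine dissimilarity (`1 - cosine similarity`, range \[0, 2\]) or
#' Euclidean distance between all pairs of points: the input to the
#' Vietoris-Rips filtration.
#'
#' @param cloud a `point_cloud`.
#' @return a symmetric zero-diagonal matrix of class
#'   `dissimilarity_matrix` with a `"metric"` attribute.
#' @export
pairwise_dissimilarity <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  p <- cloud$points
  if (cloud$metric == "cosine") {
    nrm <- sqrt(rowSums(p^2))
    bad <- which(nrm == 0)
    if (length(bad))
      stop(sprintf("zero-norm point(s) at index: %s (cosine undefined)",
                   paste(head(bad, 10L), collapse = ", ")))
    pn <- p / nrm
    d <- 1 - tcrossprod(pn)
    d <- pmin(pmax(d, 0), 2)
  } else {
    d <- as.matrix(dist(p))
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  structure(d, metric = cloud$metric, class = c("dissimilarity_matrix", "matrix"))
}

#' Maxmin landmark selection
#'
#' Greedy maxmin subsampling: starting from a seeded random point, each
#' new landmark is the point farthest from the current landmark set.
#' Landmarks cover the cloud evenly and keep Rips filtrations of long
#' segments tractable.
#'
#' @param dm a dissimilarity matrix (any square symmetric matrix).
#' @param k number of landmarks.
#' @param seed integer seed for the starting point.
#' @return integer vector of `k` landmark indices.
#' @export
maxmin_landmarks <- function(dm, k, seed = 1) {
  dm <- unclass(dm)
  n <- nrow(dm)
  if (k >= n) return(seq_len(n))
  if (k < 1L) stop("k must be >= 1")
  idx <- integer(k)
  idx[1] <- with_seed(seed, sample.int(n, 1L))
  mind <- dm[, idx[1]]
  if (k > 1L) for (i in 2:k) {
    idx[i] <- which.max(mind)
    mind <- pmin(mind, dm[, idx[i]])
  }
  sort(idx)
}
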