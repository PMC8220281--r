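# Vietoris-Rips persistent homology (dimensions 0 and 1), Betti curves
# and scalar persistence summaries.

#' Vietoris-Rips persistence of a dissimilarity matrix
#'
#' Computes the persistent homology of the Vietoris-Rips filtration in
#' dimensions 0 (connected components) and 1 (cycles).  H0 intervals come
#' from union-find over edges sorted by length; H1 intervals from GF(2)
#' column reduction of the triangle boundary matrix.  Ties in the
#' filtration are broken lexicographically by vertex index, so the output
#' is deterministic.
#'
#' Cycles still alive at the truncation radius are reported with
#' `death = max_radius` and `truncated = TRUE` rather than dropped; each
#' connected component at the truncation radius contributes one infinite
#' H0 interval (`death = Inf`).
#'
#' @param dm a [pairwise_dissimilarity()] matrix, or any symmetric
#'   non-negative matrix with zero diagonal.
#' @param max_radius truncation radius of the filtration.  Default: the
#'   radius at which the cloud first becomes a single component plus 10%,
#'   capped at 2 for the cosine metric (cycles of interest close before
#'   full connectivity; truncation bounds cost).
#' @param max_points guard against accidentally feeding full-length
#'   clouds whose filtration would be intractable; raise deliberately for
#'   larger inputs.
#' @return an object of class `persistence_diagram`: a data frame of
#'   intervals (`dim`, `birth`, `death`, `truncated`) sorted by
#'   (dim, birth), plus the truncation radius and point count.
#' @export
rips_persistence <- function(dm, max_radius = NULL, max_points = 512L) {
  metric <- attr(dm, "metric") %||% "unknown"
  dm <- unclass(as.matrix(dm))
  n <- nrow(dm)
  if (n != ncol(dm)) stop("dissimilarity matrix must be square")
  if (max(abs(dm - t(dm))) > 1e-8) stop("dissimilarity matrix must be symmetric")
  if (any(diag(dm) != 0)) stop("dissimilarity matrix must have a zero diagonal")
  if (any(dm < 0)) stop("dissimilarities must be non-negative")
  if (n > max_points)
    stop(sprintf(paste0(
      "%d points exceeds the guard of %d: the Rips filtration cost grows ",
      "steeply with point count; subsample (see maxmin_landmarks) or ",
      "raise max_points deliberately"), n, max_points))

  if (is.null(max_radius)) {
    r_conn <- mst_connectivity_radius(dm)
    max_radius <- 1.1 * r_conn
    if (identical(metric, "cosine")) max_radius <- min(max_radius, 2)
  }
  if (max_radius <= 0) stop("max_radius must be > 0")

  off <- dm[upper.tri(dm)]
  if (length(off) && max_radius < min(off))
    warning("max_radius below the smallest dissimilarity: all points remain isolated")

  res <- .rips_ph_cpp(dm, max_radius)

  n_h0 <- length(res$h0_death) + res$n_components
  h0 <- data.frame(dim = rep(0L, n_h0), birth = rep(0, n_h0),
                   death = c(sort(res$h0_death), rep(Inf, res$n_components)),
                   truncated = rep(FALSE, n_h0))
  n_h1 <- length(res$h1_birth)
  h1 <- data.frame(dim = rep(1L, n_h1), birth = res$h1_birth,
                   death = res$h1_death, truncated = rep(FALSE, n_h1))
  if (length(res$h1_inf_birth)) {
    # cycles still open at the truncation radius: death is censored at
    # max_radius (so death >= birth here, with equality possible for a
    # class born exactly at the truncation boundary) and flagged
    k <- length(res$h1_inf_birth)
    extra <- data.frame(dim = rep(1L, k), birth = res$h1_inf_birth,
                        death = rep(max_radius, k), truncated = rep(TRUE, k))
    h1 <- rbind(h1, extra)
  }
  h1 <- h1[order(h1$birth, h1$death), , drop = FALSE]
  intervals <- rbind(h0, h1)
  rownames(intervals) <- NULL
  structure(list(intervals = intervals, max_radius = max_radius,
                 n_points = n, metric = metric),
            class = "persistence_diagram")
}

# Radius at which the cloud first becomes one component = the largest
# edge of the minimum spanning tree (Prim's algorithm on the dense matrix).
mst_connectivity_radius <- function(dm) {
  n <- nrow(dm)
  if (n < 2L) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  mind <- dm[, 1L]
  r <- 0
  for (step in seq_len(n - 1L)) {
    mind[in_tree] <- Inf
    j <- which.min(mind)
    r <- max(r, mind[j])
    in_tree[j] <- TRUE
    mind <- pmin(mind, dm[, j])
  }
  r
}

#' @export
print.persistence_diagram <- function(x, ...) {
  iv <- x$intervals
  n1 <- sum(iv$dim == 1L)
  cat(sprintf(
    "<persistence_diagram> %d points, max radius %.4g (%s metric)\n",
    x$n_points, x$max_radius, x$metric))
  cat(sprintf("  H0: %d intervals (%d infinite)   H1: %d intervals (%d truncated)\n",
              sum(iv$dim == 0L), sum(iv$dim == 0L & is.infinite(iv$death)),
              n1, sum(iv$truncated)))
  invisible(x)
}

#' @param x a `persistence_diagram`.
#' @param ... passed to [graphics::plot()].
#' @rdname rips_persistence
#' @export
plot.persistence_diagram <- function(x, ...) {
  iv <- x$intervals
  iv$death[is.infinite(iv$death)] <- x$max_radius
  plot(iv$birth, iv$death, col = ifelse(iv$dim == 0L, "grey40", "firebrick"),
       pch = ifelse(iv$truncated, 2L, 19L),
       xlab = "birth radius", ylab = "death radius",
       xlim = c(0, x$max_radius), ylim = c(0, x$max_radius), ...)
  abline(0, 1, lty = 2)
  legend("bottomright", legend = c("H0", "H1"), col = c("grey40", "firebrick"),
         pch = 19, bty = "n")
  invisible(x)
}

#' Betti curve of a persistence diagram
#'
#' Counts, at every grid radius, the features of one homology dimension
#' alive there: `counts[g] = #\{intervals with birth <= g < death\}`.
#' Curves computed on a shared grid can be averaged across segments.
#'
#' @param diag a `persistence_diagram`.
#' @param dim homology dimension, 0 or 1.
#' @param grid strictly increasing vector of radii.
#' @return an object of class `betti_curve` (data frame with `radius`,
#'   `count`).
#' @export
betti_curve <- function(diag, dim = 1L, grid) {
  stopifnot(inherits(diag, "persistence_diagram"))
  if (length(grid) == 0L) stop("grid must be non-empty")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  iv <- diag$intervals[diag$intervals$dim == dim, , drop = FALSE]
  counts <- vapply(grid, function(g) sum(iv$birth <= g & g < iv$death),
                   integer(1))
  structure(data.frame(radius = grid, count = counts),
            homology_dim = dim, class = c("betti_curve", "data.frame"))
}

#' @export
plot.betti_curve <- function(x, ...) {
  plot(x$radius, x$count, type = "s", xlab = "filtration radius",
       ylab = sprintf("Betti-%d", attr(x, "homology_dim")), ...)
  invisible(x)
}

#' Scalar persistence summaries of the H1 cycles
#'
#' The three cycle summaries used to compare conditions: the maximum
#' persistence of the longest-lived cycle, the total number of cycles
#' over the whole filtration, and the maximum number of cycles alive at
#' any single radius (the peak of the H1 Betti curve on `grid`).
#'
#' @param diag a `persistence_diagram` computed with H1.
#' @param grid radii on which the Betti-curve peak is evaluated; default
#'   100 points spanning the filtration.
#' @return named list: `max_persistence`, `n_cycles`, `max_cycles`.
#' @export
tda_summaries <- function(diag, grid = NULL) {
  stopifnot(inherits(diag, "persistence_diagram"))
  if (is.null(grid))
    grid <- seq(0, diag$max_radius, length.out = 100L)
  h1 <- diag$intervals[diag$intervals$dim == 1L, , drop = FALSE]
  if (nrow(h1) == 0L)
    return(list(max_persistence = 0, n_cycles = 0L, max_cycles = 0L))
  list(max_persistence = max(h1$death - h1$birth),
       n_cycles = nrow(h1),
       max_cycles = max(betti_curve(diag, 1L, grid)$count))
}

#' Export a persistence diagram as CSV
#'
#' Writes the interval table (`dim`, `birth`, `death`, `truncated`).
#'
#' @param diag a `persistence_diagram`.
#' @param path output file.
#' @export
write_persistence_csv <- function(diag, path) {
  stopifnot(inherits(diag, "persistence_diagram"))
  write.table(diag$intervals, path, sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
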