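# Embedded point cloud, dissimilarities, Rips persistence and Betti curves.

euclid_dm <- function(pts) {
  structure(as.matrix(dist(pts)), metric = "euclidean")
}

test_that("build_epc transposes a segment into ordered state vectors", {
  m <- matrix(1:15, nrow = 3)
  seg <- recording_segment(m, fs = 10)
  cloud <- build_epc(zscore_global(seg))
  expect_equal(dim(cloud$points), c(5L, 3L))
  z <- zscore_global(seg)
  expect_equal(build_epc(z)$points[2, ], z$data[, 2])
  one <- recording_segment(matrix(rnorm(10), nrow = 1), fs = 10)
  expect_error(build_epc(one), "2 channels")
})

test_that("state velocity is the cosine dissimilarity of consecutive states", {
  pts <- rbind(c(1, 0), c(2, 0),   # parallel: 0
               c(0, 3),            # orthogonal: 1
               c(0, -1))           # antiparallel: 2
  cloud <- structure(list(points = pts, metric = "cosine"),
                     class = "point_cloud")
  v <- state_velocity(cloud)
  expect_equal(as.numeric(v), c(0, 1, 2), tolerance = 1e-12)
  expect_equal(attr(v, "average_velocity"), 1, tolerance = 1e-12)
  withz <- structure(list(points = rbind(c(1, 0), c(0, 0), c(0, 1)),
                          metric = "cosine"), class = "point_cloud")
  expect_warning(vz <- state_velocity(withz), "zero-norm")
  expect_equal(attr(vz, "undefined_at"), c(1L, 2L))
})

test_that("pairwise cosine dissimilarity meets its bounds and degeneracies", {
  cloud <- structure(list(points = rbind(c(1, 0), c(0, 1)), metric = "cosine"),
                     class = "point_cloud")
  dm <- pairwise_dissimilarity(cloud)
  expect_equal(dm[1, 2], 1)
  rnd <- structure(list(points = matrix(rnorm(40), ncol = 4),
                        metric = "cosine"), class = "point_cloud")
  dmr <- pairwise_dissimilarity(rnd)
  expect_true(all(dmr <= 2 + 1e-12) && all(dmr >= 0))
  expect_equal(diag(dmr), rep(0, 10))
  copies <- structure(list(points = matrix(rep(c(1, 2, 3), 5), ncol = 3,
                                           byrow = TRUE), metric = "cosine"),
                      class = "point_cloud")
  expect_equal(max(pairwise_dissimilarity(copies)), 0, tolerance = 1e-12)
  zero <- structure(list(points = rbind(c(0, 0), c(1, 1)), metric = "cosine"),
                    class = "point_cloud")
  expect_error(pairwise_dissimilarity(zero), "zero-norm")
})

test_that("rips_persistence handles elementary configurations exactly", {
  # two points at distance 1
  dm2 <- matrix(c(0, 1, 1, 0), 2)
  pd2 <- rips_persistence(dm2, max_radius = 2)
  h0 <- pd2$intervals[pd2$intervals$dim == 0, ]
  expect_equal(sort(h0$death), c(1, Inf))
  expect_equal(sum(pd2$intervals$dim == 1), 0L)

  # three points, pairwise distances 1, 2, 3: H0 deaths are the two
  # merge radii found by union-find over sorted edges
  dm3 <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3)
  pd3 <- rips_persistence(dm3, max_radius = 4)
  h0 <- pd3$intervals[pd3$intervals$dim == 0, ]
  expect_equal(sort(h0$death), c(1, 2, Inf))

  # unit square: exactly one cycle, born 1, filled at sqrt(2)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  pdsq <- rips_persistence(euclid_dm(sq), max_radius = 2)
  h1 <- pdsq$intervals[pdsq$intervals$dim == 1, ]
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$birth, 1, tolerance = 1e-9)
  expect_equal(h1$death, sqrt(2), tolerance = 1e-9)
})

test_that("H0 interval count is conserved and duplicates leave H1 alone", {
  set.seed(31)
  for (rep in 1:20) {
    pts <- matrix(rnorm(2 * sample(5:12, 1)), ncol = 2)
    r <- stats::quantile(dist(pts), 0.5)
    pd <- rips_persistence(euclid_dm(pts), max_radius = r)
    h0 <- pd$intervals[pd$intervals$dim == 0, ]
    finite <- sum(is.finite(h0$death))
    comps <- sum(is.infinite(h0$death))
    expect_equal(finite + comps, nrow(pts))

    dup <- rbind(pts, pts[1, ])
    pd_dup <- rips_persistence(euclid_dm(dup), max_radius = r)
    expect_equal(pd_dup$intervals[pd_dup$intervals$dim == 1, c("birth", "death")],
                 pd$intervals[pd$intervals$dim == 1, c("birth", "death")],
                 ignore_attr = TRUE)
  }
})

test_that("a sub-minimum radius isolates every point with a warning", {
  pts <- matrix(rnorm(10), ncol = 2)
  expect_warning(pd <- rips_persistence(euclid_dm(pts),
                                        max_radius = min(dist(pts)) / 2),
                 "isolated")
  expect_equal(sum(is.infinite(pd$intervals$death)), 5)
})

test_that("the point-count guard triggers with a clear diagnostic", {
  big <- matrix(0, 600, 600)
  expect_error(rips_persistence(big, max_radius = 1), "guard")
})

test_that("betti curves count alive intervals and match direct recounting", {
  pd <- structure(list(
    intervals = data.frame(dim = c(0L, 1L, 1L), birth = c(0, 0.1, 0.2),
                           death = c(Inf, 0.9, 0.5),
                           truncated = FALSE),
    max_radius = 1, n_points = 3, metric = "euclidean"),
    class = "persistence_diagram")
  expect_equal(betti_curve(pd, 1L, 0.3)$count, 2L)
  expect_equal(betti_curve(pd, 1L, 0.7)$count, 1L)
  expect_equal(betti_curve(pd, 1L, 0.95)$count, 0L)
  expect_error(betti_curve(pd, 1L, numeric(0)), "non-empty")
  expect_error(betti_curve(pd, 1L, c(0.5, 0.2)), "increasing")

  # consistency with interval-wise recounting on a real diagram
  pts <- gen_circle_cloud(30, noise = 0.05, seed = 2)
  pdc <- rips_persistence(euclid_dm(pts), max_radius = 2)
  grid <- seq(0.01, 2, length.out = 50)
  bc <- betti_curve(pdc, 1L, grid)
  iv <- pdc$intervals[pdc$intervals$dim == 1L, ]
  direct <- vapply(grid, function(g) sum(iv$birth <= g & g < iv$death),
                   integer(1))
  expect_equal(bc$count, direct)
  expect_true(all(bc$count[grid >= max(iv$death)] == 0))
})

test_that("tda_summaries reduces a diagram to the three cycle statistics", {
  pd <- structure(list(
    intervals = data.frame(dim = c(1L, 1L), birth = c(0.2, 0.1),
                           death = c(0.5, 0.9), truncated = FALSE),
    max_radius = 1, n_points = 10, metric = "euclidean"),
    class = "persistence_diagram")
  s <- tda_summaries(pd, grid = seq(0.05, 1, by = 0.05))
  expect_equal(s$max_persistence, 0.8)
  expect_equal(s$n_cycles, 2L)
  expect_equal(s$max_cycles, 2L)  # both alive on (0.2, 0.5)
  empty <- pd
  empty$intervals <- empty$intervals[0, ]
  expect_equal(tda_summaries(empty),
               list(max_persistence = 0, n_cycles = 0L, max_cycles = 0L))
})

test_that("maxmin landmarks cover the cloud and are seed-stable", {
  pts <- gen_circle_cloud(200, noise = 0.02, seed = 8)
  dm <- as.matrix(dist(pts))
  li <- maxmin_landmarks(dm, 25, seed = 1)
  expect_length(unique(li), 25L)
  expect_identical(li, maxmin_landmarks(dm, 25, seed = 1))
  # every point is close to some landmark relative to the cloud diameter
  expect_lt(max(apply(dm[, li], 1, min)), max(dm) / 4)
})
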