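# Pipeline orchestration, nonparametric group tests, aggregation and the
# morphospace embedding.

small_config <- function(...) {
  pipeline_config(tda_landmarks = 50L, lyap_max_points = 400L,
                  infomap_restarts = 2L, trim_ms = 0, ...)
}

test_that("run_pipeline produces one OPN row per channel and one TDA row per segment", {
  segs <- lapply(1:3, function(s)
    gen_regime("intermediate", n_channels = 4, duration_s = 2, fs = 250,
               seed = s))
  tab <- run_pipeline(segs, small_config())
  expect_s3_class(tab, "measure_table")
  expect_equal(nrow(tab$opn_rows), 12L)
  expect_equal(nrow(tab$tda_rows), 3L)
  expect_null(tab$failures)
  needed <- c("n_nodes", "n_edges", "det", "deg", "perm_entropy",
              "modularity_q", "lyapunov")
  expect_true(all(needed %in% names(tab$opn_rows)))
  expect_false(anyNA(tab$opn_rows[, needed]))
})

test_that("an identical rerun reproduces every number and the provenance hash", {
  segs <- lapply(1:2, function(s)
    gen_regime("poor", n_channels = 3, duration_s = 2, fs = 250, seed = s))
  t1 <- run_pipeline(segs, small_config())
  t2 <- run_pipeline(segs, small_config())
  expect_identical(t1$opn_rows, t2$opn_rows)
  expect_identical(t1$tda_rows, t2$tda_rows)
  expect_identical(t1$provenance$config_hash, t2$provenance$config_hash)
})

test_that("per-item failures are recorded without aborting the run", {
  good <- gen_regime("poor", n_channels = 3, duration_s = 2, fs = 250,
                     seed = 1)
  flat <- good
  flat$data[2, ] <- 0  # constant channel: tau selection must fail
  tab <- run_pipeline(list(good, flat), small_config())
  expect_equal(nrow(tab$opn_rows), 5L)
  expect_false(is.null(tab$failures))
  expect_true(any(grepl("opn-ch2", tab$failures$stage)))
})

test_that("kruskal_wallis matches the hand-computed fixture and contracts", {
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4)))
  expect_equal(kw$statistic, 2.4, tolerance = 1e-10)
  expect_warning(kw0 <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2))),
                 "identical")
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_value, 1)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "at least one")
  # rank-based: invariant under strictly monotone transforms
  g <- list(rexp(8), rexp(8) + 0.3, rexp(8) * 2)
  h1 <- kruskal_wallis(g)$statistic
  h2 <- kruskal_wallis(lapply(g, function(v) exp(v)))$statistic
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("mann_whitney_posthoc tests every pair with the right U identities", {
  r <- mann_whitney_posthoc(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(r$U, 0)  # complete separation
  self <- mann_whitney_posthoc(rep(c(1, 2, 3), 2),
                               rep(c("x", "y"), each = 3))
  expect_equal(self$U, 9 / 2)
  expect_gt(self$p_value, 0.9)
  # U_a + U_b = n_a * n_b on random data
  set.seed(5)
  for (rep in 1:10) {
    a <- rnorm(sample(5:25, 1))
    b <- rnorm(sample(5:25, 1), mean = 0.4)
    vals <- c(a, b)
    labs <- rep(c("A", "B"), c(length(a), length(b)))
    u_ab <- mann_whitney_posthoc(vals, labs)$U
    u_ba <- mann_whitney_posthoc(c(b, a),
                                 rep(c("B", "A"), c(length(b), length(a))))$U
    expect_equal(u_ab + u_ba, length(a) * length(b))
  }
})

test_that("exact and normal-approximation U tests agree closely at n = 15", {
  set.seed(6)
  for (rep in 1:5) {
    a <- rnorm(15)
    b <- rnorm(15, mean = 0.5)
    p_exact <- wilcox.test(a, b, exact = TRUE)$p.value
    p_norm <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                           correct = TRUE)$p.value)
    expect_lt(abs(p_exact - p_norm), 0.01)
  }
})

test_that("aggregation reports sample SD and respects balanced nesting", {
  df <- data.frame(condition = "c1", subject = "s1", value = c(1, 2, 3))
  agg <- aggregate_measures(df, level = "condition", measures = "value")
  expect_equal(agg$mean, 2)
  expect_equal(agg$sd, 1)  # sample SD
  one <- aggregate_measures(data.frame(condition = "c", value = 5),
                            level = "condition", measures = "value")
  expect_equal(one$sd, 0)
  expect_equal(one$n, 1L)
  # balanced subjects: subject-then-condition equals direct condition means
  bal <- expand.grid(subject = c("s1", "s2"), condition = c("A", "B"),
                     rep = 1:3)
  set.seed(2)
  bal$value <- rnorm(nrow(bal))
  direct <- aggregate_measures(bal, "condition", "value")
  bysub <- aggregate(value ~ subject + condition, bal, mean)
  nested <- aggregate_measures(bysub, "condition", "value")
  expect_equal(direct$mean[order(direct$group)],
               nested$mean[order(nested$group)], tolerance = 1e-12)
})

test_that("the morphospace embedding honours its contracts", {
  set.seed(3)
  feats <- c("n_nodes", "n_edges", "det", "deg", "modularity_q")
  mk <- function(center, n, label) {
    df <- as.data.frame(matrix(rnorm(n * 5, mean = center, sd = 0.3),
                               ncol = 5))
    names(df) <- feats
    df$condition <- label
    df
  }
  sil <- replicate(10, {
    df <- rbind(mk(0, 8, "poor"), mk(3, 8, "rich"))
    emb <- morphospace_embed(df)
    d <- as.matrix(dist(emb[, c("dim1", "dim2")]))
    same <- outer(df$condition, df$condition, "==")
    diag(same) <- NA
    a <- rowMeans(ifelse(same, d, NA), na.rm = TRUE)
    b <- rowMeans(ifelse(!same, d, NA), na.rm = TRUE)
    mean((b - a) / pmax(a, b))
  })
  expect_true(all(sil > 0))

  df <- mk(0, 6, "x")
  df2 <- rbind(df, df[1, ])  # duplicated row
  emb <- morphospace_embed(df2)
  dup_dist <- sqrt(sum((emb[1, 1:2] - emb[7, 1:2])^2))
  expect_lt(dup_dist, 0.01 * max(dist(emb[, 1:2])))
  expect_identical(morphospace_embed(df2), morphospace_embed(df2))
  expect_error(morphospace_embed(df[1:2, ]), "at least 3")
  expect_error(morphospace_embed(df[, 1:3]), "missing feature")
})
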