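# Ordinal symbolization, network construction and parameter selection.

test_that("select_tau finds the first autocorrelation zero crossing", {
  expect_equal(select_tau(gen_sine(10, 1000, 1000)), 25L)  # quarter period
  expect_error(select_tau(rep(1, 100)), "constant")
  expect_warning(tau <- select_tau(seq_len(200) + 0.0, max_lag = 10), "cap")
  expect_equal(tau, 10L)
})

test_that("ordinal symbols follow the argsort convention with stable ties", {
  s <- ordinal_symbols(c(1, 3, 2, 4), d = 3, tau = 1)
  expect_equal(s$symbols, c("0.2.1", "1.0.2"))
  expect_equal(s$n_windows, 2L)
  inc <- ordinal_symbols(1:30, d = 4, tau = 2)
  expect_true(all(inc$symbols == "0.1.2.3"))
  expect_equal(inc$n_windows, 30L - 3L * 2L)
  # tie between positions 0 and 1 resolves toward the earlier position
  expect_equal(ordinal_symbols(c(2, 2, 1), d = 3, tau = 1)$symbols, "2.0.1")
  expect_error(ordinal_symbols(1:5, d = 3, tau = 3), "too short")
})

test_that("build_opn counts nodes, transitions and self-loops exactly", {
  sym <- structure(list(symbols = c("A", "B", "A", "B"), d = 2L, tau = 1L,
                        n_windows = 4L), class = "ordinal_symbols")
  net <- build_opn(sym)
  expect_equal(net$N, 2L)
  expect_equal(sort(net$nodes$weight), c(2L, 2L))
  ab <- net$edges[net$edges$from == "A" & net$edges$to == "B", "count"]
  ba <- net$edges[net$edges$from == "B" & net$edges$to == "A", "count"]
  expect_equal(ab, 2L)
  expect_equal(ba, 1L)

  same <- structure(list(symbols = rep("X", 7), d = 2L, tau = 1L,
                         n_windows = 7L), class = "ordinal_symbols")
  net1 <- build_opn(same)
  expect_equal(net1$N, 1L)
  expect_equal(net1$nodes$weight, 7L)
  expect_equal(net1$edges$count, 6L)  # one self-loop
  expect_equal(opn_counts(net1), list(n_nodes = 1L, n_edges = 1L))

  seq5 <- structure(list(symbols = rep(c("a", "b", "c", "d", "e"), 4),
                         d = 3L, tau = 1L, n_windows = 20L),
                    class = "ordinal_symbols")
  cycle <- build_opn(seq5)
  expect_equal(opn_counts(cycle), list(n_nodes = 5L, n_edges = 5L))
  outdeg <- table(cycle$edges$from)
  expect_true(all(outdeg == 1L))

  abcac <- structure(list(symbols = c("A", "B", "C", "A", "C"), d = 2L,
                          tau = 1L, n_windows = 5L),
                     class = "ordinal_symbols")
  expect_equal(opn_counts(build_opn(abcac)), list(n_nodes = 3L, n_edges = 4L))
})

test_that("node weights and edge counts are conserved on random series", {
  for (seed in 1:8) {
    x <- gen_ar1(0.5, 1, 400, seed = seed)
    d <- sample(3:5, 1)
    tau <- sample(1:4, 1)
    net <- build_opn(ordinal_symbols(x, d, tau))
    nw <- length(x) - (d - 1) * tau
    expect_equal(sum(net$nodes$weight), nw)
    expect_equal(sum(net$edges$count), nw - 1L)
    expect_lte(net$N, min(nw, factorial(d)))
  }
})

test_that("periodic input with coprime lag yields a single directed cycle", {
  # period-7 base whose seven phase-windows map to distinct symbols
  base <- c(-0.94, -0.51, 0.29, 1.63, -1.19, 1.59, 1.78)
  x <- rep(base, 40)
  net <- build_opn(ordinal_symbols(x, d = 4, tau = 2))  # gcd(2, 7) = 1
  expect_equal(net$N, 7L)
  outdeg <- table(factor(net$edges$from, levels = net$nodes$symbol))
  expect_true(all(outdeg == 1L))
  expect_equal(nrow(net$edges), net$N)  # one cycle through all nodes
})

test_that("degree-variance dimension selection matches brute force", {
  x <- gen_sine(5, 250, 1500)
  tau <- select_tau(x)
  cands <- 3:8
  vars <- vapply(cands, function(d) {
    net <- build_opn(ordinal_symbols(x, d, tau))
    outd <- table(factor(net$edges$from, levels = net$nodes$symbol))
    ind <- table(factor(net$edges$to, levels = net$nodes$symbol))
    var(as.numeric(outd) + as.numeric(ind))
  }, numeric(1))
  expect_equal(select_dim(x, tau, cands), cands[which.max(vars)])
  expect_error(select_dim(x, tau, integer(0)), "candidate")
  expect_error(select_dim(x, 400, 6), "no embedding windows")
})

test_that("the opn fitting front end is deterministic and self-describing", {
  x <- gen_regime("rich", n_channels = 1, duration_s = 2, fs = 250,
                  seed = 3)$data[1, ]
  n1 <- opn(x, d = 5, tau = "auto")
  n2 <- opn(x, d = 5, tau = "auto")
  expect_identical(n1, n2)
  expect_equal(n1$d, 5L)
  expect_equal(n1$n_windows, length(x) - 4L * n1$tau)
  s <- summary(n1, modularity = FALSE)
  expect_s3_class(s, "summary.opn")
  expect_equal(s$n_nodes, n1$N)
  # predict returns a proper distribution; simulate walks the graph
  W <- predict(n1)
  expect_true(all(abs(rowSums(W)[rowSums(W) > 0] - 1) < 1e-12))
  path <- simulate(n1, nsim = 50, seed = 2)
  expect_true(all(path %in% n1$nodes$symbol))
  expect_identical(path, simulate(n1, nsim = 50, seed = 2))
})

test_that("opn export writes GraphML and edge-list CSV", {
  net <- opn(gen_sine(5, 250, 1000), d = 4, tau = "auto")
  gml <- tempfile(fileext = ".graphml")
  write_opn_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), net$N)
  expect_equal(igraph::ecount(g), nrow(net$edges))
  csv <- tempfile(fileext = ".csv")
  write_opn_csv(net, csv)
  el <- read.csv(csv)
  expect_equal(nrow(el), nrow(net$edges))
  expect_equal(sum(el$count), sum(net$edges$count))
  unlink(c(gml, csv, sub("\\.csv$", "_nodes.csv", csv)))
})
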