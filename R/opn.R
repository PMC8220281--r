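# Ordinal partition networks: delay embedding, permutation symbolization,
# weighted directed transition graphs, and the tau/d selection heuristics.

#' Embedding lag from the autocorrelation zero crossing
#'
#' Returns the smallest lag at which the (biased, divide-by-n) sample
#' autocorrelation of the mean-removed series first drops to or below
#' zero -- the standard heuristic for decorrelating the coordinates of a
#' delay embedding.  For a sinusoid this is a quarter period.
#'
#' @param x univariate numeric series (length >= 10, non-constant).
#' @param max_lag cap on the search; if no crossing occurs before the cap
#'   the cap itself is returned with a warning.
#' @return integer lag in samples.
#' @export
select_tau <- function(x, max_lag = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10L) stop("series too short (need >= 10 samples)")
  if (sd(x) == 0) stop("constant series: autocorrelation undefined")
  if (is.null(max_lag)) max_lag <- min(n - 2L, 1000L)
  ac <- c(1, acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[-1L])
  hit <- which(ac[-1L] <= 0)
  if (length(hit) == 0L) {
    warning(sprintf("no autocorrelation zero crossing up to lag %d; using the cap",
                    max_lag))
    return(as.integer(max_lag))
  }
  # the sign change happens between lags l-1 and l; return the lag nearest
  # the interpolated crossing (a quarter period lands on it exactly for a
  # sinusoid instead of one sample past it)
  l <- hit[1L]
  frac <- ac[l] / (ac[l] - ac[l + 1L])
  max(1L, as.integer(round(l - 1L + frac)))
}

#' Ordinal (permutation) symbolization of a series
#'
#' Delay-embeds the series with dimension `d` and lag `tau` and maps each
#' window `(x_i, x_{i+tau}, ..., x_{i+(d-1)tau})` to its argsort
#' permutation: the sequence of window positions listing the values in
#' ascending order.  Equal values are broken toward the earlier window
#' position (stable sort), which makes the symbolization deterministic on
#' flat or quantized stretches.
#'
#' @param x univariate numeric series.
#' @param d embedding dimension (>= 2).
#' @param tau embedding lag in samples (>= 1).
#' @return an object of class `ordinal_symbols`: the symbol sequence
#'   (encoded as dot-separated 0-based position strings, e.g. `"0.2.1"`),
#'   `d`, `tau` and `n_windows = length(x) - (d-1) * tau`.
#' @export
ordinal_symbols <- function(x, d, tau) {
  x <- as.numeric(x)
  n <- length(x)
  if (d < 2L) stop("d must be >= 2")
  if (tau < 1L) stop("tau must be >= 1")
  nw <- n - (d - 1L) * tau
  if (nw < 1L)
    stop(sprintf("series of length %d too short for d=%d, tau=%d (need > %d)",
                 n, d, tau, (d - 1L) * tau))
  idx <- outer(seq_len(nw), (0:(d - 1L)) * tau, `+`)
  win <- matrix(x[idx], nrow = nw)
  sym <- apply(win, 1L, function(w)
    paste(order(w, method = "radix") - 1L, collapse = "."))
  structure(list(symbols = sym, d = as.integer(d), tau = as.integer(tau),
                 n_windows = nw),
            class = "ordinal_symbols")
}

#' @export
print.ordinal_symbols <- function(x, ...) {
  cat(sprintf("<ordinal_symbols> %d windows, d=%d, tau=%d, %d distinct symbols\n",
              x$n_windows, x$d, x$tau, length(unique(x$symbols))))
  invisible(x)
}

#' Build an ordinal partition network from a symbol sequence
#'
#' Nodes are the distinct permutation symbols, weighted by visit count;
#' a directed edge a -> b counts the occurrences of the consecutive pair
#' (a, b), self-loops included.
#'
#' @param sym an [ordinal_symbols()] object.
#' @param self_loops keep self-transitions (default TRUE; consecutive
#'   overlapping windows commonly repeat a symbol).
#' @return an object of class `opn`; see [opn()].
#' @export
build_opn <- function(sym, self_loops = TRUE) {
  stopifnot(inherits(sym, "ordinal_symbols"))
  s <- sym$symbols
  if (length(s) < 2L) stop("need at least 2 windows to build transitions")
  node_w <- table(s)
  from <- s[-length(s)]
  to <- s[-1L]
  if (!self_loops) {
    keep <- from != to
    from <- from[keep]
    to <- to[keep]
  }
  key <- paste(from, to, sep = ">")
  ew <- table(key)
  parts <- strsplit(names(ew), ">", fixed = TRUE)
  edges <- data.frame(from = vapply(parts, `[`, "", 1L),
                      to = vapply(parts, `[`, "", 2L),
                      count = as.integer(ew), stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(symbol = names(node_w), weight = as.integer(node_w),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$symbol), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, N = nrow(nodes),
                 d = sym$d, tau = sym$tau, n_windows = sym$n_windows,
                 self_loops = self_loops),
            class = "opn")
}

#' Fit an ordinal partition network to a univariate series
#'
#' The one-stop constructor: selects the embedding lag (autocorrelation
#' zero crossing) and dimension (degree-distribution variance maximum)
#' when asked, symbolizes the series, and builds the weighted directed
#' state-transition network.
#'
#' @param x univariate numeric series.
#' @param d embedding dimension, or `"auto"` to maximize the variance of
#'   the total-degree distribution over `candidates`.
#' @param tau embedding lag, or `"auto"` for [select_tau()].
#' @param candidates candidate dimensions tried when `d = "auto"`.
#' @param self_loops keep self-transitions.
#' @return an object of class `opn` with components `nodes`
#'   (symbol, visit weight), `edges` (from, to, count), `N` (node count),
#'   the embedding parameters and `n_windows`.
#' @seealso [determinism()], [degeneracy()], [permutation_entropy()],
#'   [map_partition()], [summary.opn()]
#' @export
opn <- function(x, d = "auto", tau = "auto", candidates = 3:7,
                self_loops = TRUE) {
  x <- as.numeric(x)
  if (identical(tau, "auto")) tau <- select_tau(x)
  tau <- as.integer(tau)
  if (identical(d, "auto")) d <- select_dim(x, tau, candidates,
                                            self_loops = self_loops)
  d <- as.integer(d)
  net <- build_opn(ordinal_symbols(x, d, tau), self_loops = self_loops)
  net
}

#' Embedding dimension by degree-distribution variance
#'
#' Builds one network per candidate dimension and returns the candidate
#' maximizing the variance of the total-degree distribution (distinct
#' in- plus out-neighbour edges per node).  A dimension so large that
#' every window is unique yields a path graph with near-constant degrees
#' and near-zero variance, so it is never preferred on structured input.
#' Ties go to the smallest candidate.
#'
#' @param x univariate numeric series.
#' @param tau embedding lag.
#' @param candidates integer vector of dimensions to try; all must
#'   satisfy `(d-1) * tau < length(x)`.
#' @param self_loops passed to [build_opn()].
#' @return the selected dimension (integer).
#' @export
select_dim <- function(x, tau, candidates = 3:7, self_loops = TRUE) {
  if (length(candidates) == 0L) stop("no candidate dimensions supplied")
  bad <- candidates[(candidates - 1L) * tau >= length(x)]
  if (length(bad))
    stop(sprintf("candidate d=%s leaves no embedding windows at tau=%d",
                 paste(bad, collapse = ","), tau))
  vars <- vapply(candidates, function(d) {
    net <- build_opn(ordinal_symbols(x, d, tau), self_loops = self_loops)
    var(node_total_degree(net))
  }, numeric(1))
  as.integer(candidates[which.max(vars)])  # which.max takes the first tie
}

# Distinct-edge total degree per node (self-loop counts once in each
# direction, the igraph convention for total degree being in + out).
node_total_degree <- function(net) {
  outd <- table(factor(net$edges$from, levels = net$nodes$symbol))
  ind <- table(factor(net$edges$to, levels = net$nodes$symbol))
  as.numeric(outd) + as.numeric(ind)
}

#' Node and distinct-edge counts of an ordinal partition network
#'
#' The number of nodes measures the repertoire of ordinal micro-states
#' visited; the number of distinct directed edges counts the unique
#' transitions observed.
#'
#' @param net an `opn`.
#' @return named list `n_nodes`, `n_edges`.
#' @export
opn_counts <- function(net) {
  stopifnot(inherits(net, "opn"))
  list(n_nodes = net$N, n_edges = nrow(net$edges))
}

# Per-node normalized out-transition distributions as a dense N x N
# matrix (rows: source nodes; all-zero rows for terminal nodes).
opn_out_distributions <- function(net) {
  syms <- net$nodes$symbol
  W <- matrix(0, net$N, net$N, dimnames = list(syms, syms))
  W[cbind(match(net$edges$from, syms), match(net$edges$to, syms))] <-
    net$edges$count
  rs <- rowSums(W)
  has_out <- rs > 0
  W[has_out, ] <- W[has_out, , drop = FALSE] / rs[has_out]
  attr(W, "has_out") <- has_out
  W
}

#' @export
print.opn <- function(x, ...) {
  cat(sprintf(
    "<opn> %d nodes, %d edges (d=%d, tau=%d, %d windows%s)\n",
    x$N, nrow(x$edges), x$d, x$tau, x$n_windows,
    if (x$self_loops) ", self-loops kept" else ", self-loops dropped"))
  invisible(x)
}

#' Summarize an ordinal partition network
#'
#' Computes the scalar state-transition measures of the network:
#' node/edge counts, determinism, degeneracy, permutation entropy, and
#' (optionally) map-equation modularity.
#'
#' @param object an `opn`.
#' @param modularity also run [map_partition()] and report Q (slower).
#' @param seed seed for the partition search.
#' @param ... unused.
#' @export
summary.opn <- function(object, modularity = TRUE, seed = 1L, ...) {
  out <- list(
    n_nodes = object$N,
    n_edges = nrow(object$edges),
    d = object$d, tau = object$tau, n_windows = object$n_windows,
    det = suppressWarnings(determinism(object)),
    deg = suppressWarnings(degeneracy(object)),
    perm_entropy = permutation_entropy(object))
  if (modularity && object$N >= 2L) {
    part <- map_partition(object, seed = seed)
    out$n_communities <- part$n_communities
    out$modularity_q <- modularity_q(object, part)
  }
  structure(out, class = "summary.opn")
}

#' @export
print.summary.opn <- function(x, ...) {
  cat(sprintf("<opn summary> d=%d tau=%d windows=%d\n", x$d, x$tau, x$n_windows))
  cat(sprintf("  nodes %d  edges %d  det %.4f  deg %.4f  PE %.4f bits\n",
              x$n_nodes, x$n_edges, x$det, x$deg, x$perm_entropy))
  if (!is.null(x$modularity_q))
    cat(sprintf("  communities %d  modularity Q %.4f\n",
                x$n_communities, x$modularity_q))
  invisible(x)
}

#' Next-symbol transition distribution
#'
#' @param object an `opn`.
#' @param symbol current symbol (a node label); if `NULL`, the full
#'   out-transition matrix is returned.
#' @param ... unused.
#' @return named probability vector over successor symbols, or the full
#'   row-stochastic matrix.
#' @export
predict.opn <- function(object, symbol = NULL, ...) {
  W <- opn_out_distributions(object)
  if (is.null(symbol)) return(W)
  if (!symbol %in% rownames(W)) stop("unknown symbol: ", symbol)
  W[symbol, ]
}

#' Simulate a symbolic trajectory from a fitted network
#'
#' Random walk over the out-transition distributions, started at a
#' visit-weight-random node; terminal nodes (no out-edges) end the walk
#' early.
#'
#' @param object an `opn`.
#' @param nsim walk length.
#' @param seed integer seed.
#' @param ... unused.
#' @return character vector of symbols (length <= nsim).
#' @export
simulate.opn <- function(object, nsim = 100L, seed = 1L, ...) {
  W <- opn_out_distributions(object)
  has_out <- attr(W, "has_out")
  syms <- object$nodes$symbol
  with_seed(seed, {
    path <- character(nsim)
    cur <- sample(syms, 1L, prob = object$nodes$weight)
    for (i in seq_len(nsim)) {
      path[i] <- cur
      k <- match(cur, syms)
      if (!has_out[k]) return(path[seq_len(i)])
      cur <- sample(syms, 1L, prob = W[k, ])
    }
    path
  })
}

#' Convert an ordinal partition network to an igraph graph
#'
#' @param net an `opn`.
#' @return a weighted directed `igraph` graph with node attribute
#'   `weight` (visit counts) and edge attribute `count`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "opn"))
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = net$nodes[, c("symbol", "weight")])
  igraph::E(g)$weight <- net$edges$count
  g
}

#' @export
plot.opn <- function(x, ...) {
  g <- as_igraph(x)
  plot(g, vertex.size = 3 + 10 * igraph::V(g)$weight / max(igraph::V(g)$weight),
       edge.arrow.size = 0.2, vertex.label = NA, ...)
  invisible(x)
}

#' Export an ordinal partition network
#'
#' `write_opn_graphml` writes GraphML (via igraph); `write_opn_csv`
#' writes a weighted edge list (`source_symbol`, `target_symbol`,
#' `count`) and a node table (`symbol`, `weight`).
#'
#' @param net an `opn`.
#' @param path output file (for CSV, the edge list; the node table goes
#'   to `<path>` with suffix `_nodes.csv`).
#' @export
write_opn_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname write_opn_graphml
#' @export
write_opn_csv <- function(net, path) {
  el <- net$edges
  names(el) <- c("source_symbol", "target_symbol", "count")
  write.table(el, path, sep = ",", row.names = FALSE, quote = FALSE)
  npath <- sub("\\.csv$", "_nodes.csv", path)
  if (npath == path) npath <- paste0(path, "_nodes.csv")
  write.table(net$nodes, npath, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
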