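# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately share no code with the package internals: the
# persistence oracle reduces the full dense boundary matrix over GF(2)
# after explicit simplex enumeration, and the map-equation oracle
# enumerates every set partition.

# ---- persistence: full boundary-matrix reduction --------------------------

# All simplices up to dimension 2 with filtration value = diameter,
# sorted by (value, dim, lexicographic vertex tuple), then the textbook
# column reduction of the full boundary matrix.  Returns intervals per
# dimension; essential classes have death = Inf.
oracle_rips <- function(dm, max_radius = Inf) {
  n <- nrow(dm)
  simplices <- list()
  for (i in seq_len(n)) simplices[[length(simplices) + 1L]] <-
    list(v = i, val = 0, dim = 0L)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (dm[i, j] <= max_radius)
      simplices[[length(simplices) + 1L]] <-
        list(v = c(i, j), val = dm[i, j], dim = 1L)
  }
  if (n >= 3L) for (i in seq_len(n - 2L)) for (j in (i + 1L):(n - 1L)) {
    for (k in (j + 1L):n) {
      val <- max(dm[i, j], dm[i, k], dm[j, k])
      if (val <= max_radius)
        simplices[[length(simplices) + 1L]] <-
          list(v = c(i, j, k), val = val, dim = 2L)
    }
  }
  vals <- vapply(simplices, `[[`, numeric(1), "val")
  dims <- vapply(simplices, `[[`, integer(1), "dim")
  vpad <- t(vapply(simplices, function(s) c(s$v, rep(0L, 3L - length(s$v))),
                   integer(3)))
  ord <- order(vals, dims, vpad[, 1L], vpad[, 2L], vpad[, 3L])
  simplices <- simplices[ord]
  ns <- length(simplices)
  pos <- new.env(hash = TRUE)
  for (s in seq_len(ns))
    assign(paste(simplices[[s]]$v, collapse = ","), s, envir = pos)

  # boundary columns as sorted integer index vectors
  cols <- vector("list", ns)
  for (s in seq_len(ns)) {
    sp <- simplices[[s]]
    if (sp$dim == 0L) { cols[[s]] <- integer(0); next }
    faces <- lapply(seq_along(sp$v), function(drop_i) sp$v[-drop_i])
    cols[[s]] <- sort(vapply(faces, function(f)
      get(paste(f, collapse = ","), envir = pos), integer(1)))
  }

  low_owner <- integer(ns)  # 0 = free
  pairs <- matrix(0L, nrow = 0L, ncol = 2L)
  for (s in seq_len(ns)) {
    col <- cols[[s]]
    while (length(col)) {
      lw <- col[length(col)]
      o <- low_owner[lw]
      if (o == 0L) break
      # symmetric difference over GF(2)
      oc <- cols[[o]]
      col <- sort(c(setdiff(col, oc), setdiff(oc, col)))
    }
    cols[[s]] <- col
    if (length(col)) {
      low_owner[col[length(col)]] <- s
      pairs <- rbind(pairs, c(col[length(col)], s))
    }
  }

  paired <- c(pairs[, 1L], pairs[, 2L])
  intervals <- data.frame(dim = integer(0), birth = numeric(0),
                          death = numeric(0))
  if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
    b <- simplices[[pairs[r, 1L]]]
    d <- simplices[[pairs[r, 2L]]]
    if (d$val > b$val)
      intervals <- rbind(intervals,
                         data.frame(dim = b$dim, birth = b$val, death = d$val))
  }
  for (s in setdiff(which(low_owner == 0L & lengths(cols) == 0L), paired)) {
    sp <- simplices[[s]]
    if (sp$dim <= 1L)
      intervals <- rbind(intervals,
                         data.frame(dim = sp$dim, birth = sp$val, death = Inf))
  }
  intervals[order(intervals$dim, intervals$birth, intervals$death), ,
            drop = FALSE]
}

# Canonical sorted interval table from a package persistence_diagram,
# mapping truncated deaths back to Inf for comparison with the oracle.
diagram_canonical <- function(pd) {
  iv <- pd$intervals
  iv$death[iv$truncated] <- Inf
  iv <- iv[, c("dim", "birth", "death")]
  iv <- iv[order(iv$dim, iv$birth, iv$death), , drop = FALSE]
  rownames(iv) <- NULL
  iv
}

# ---- map equation: exhaustive set-partition enumeration -------------------

# All set partitions of n labelled elements (restricted growth strings).
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(assign, next_label) {
    i <- length(assign) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    for (lab in seq_len(next_label))
      rec(c(assign, lab), max(next_label, lab + 1L))
  }
  rec(integer(0), 1L)
  out
}

# Global minimum of the map-equation codelength by exhaustive search.
oracle_best_partition <- function(net, teleport = 0.15) {
  parts <- all_set_partitions(net$N)
  Ls <- vapply(parts, function(p) opntda::map_codelength(net, p, teleport),
               numeric(1))
  best <- which.min(Ls)
  list(membership = parts[[best]], codelength = Ls[best])
}

# ---- misc fixtures --------------------------------------------------------

# Build an `opn` object directly from edge counts (bypassing a series),
# for worked-example fixtures.
opn_from_edges <- function(edges, weights = NULL) {
  syms <- sort(unique(c(edges$from, edges$to)))
  if (is.null(weights)) weights <- rep(1L, length(syms))
  nodes <- data.frame(symbol = syms, weight = weights,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, N = nrow(nodes),
                 d = NA_integer_, tau = NA_integer_,
                 n_windows = sum(weights), self_loops = TRUE),
            class = "opn")
}

# Directed cycle on p symbolic nodes with given per-edge count.
cycle_opn <- function(p, count = 1L) {
  syms <- sprintf("s%02d", seq_len(p))
  edges <- data.frame(from = syms, to = syms[c(2:p, 1L)], count = count,
                      stringsAsFactors = FALSE)
  opn_from_edges(edges, weights = rep(count, p))
}

# Reference Shannon entropy in bits from a vector of counts.
shannon_entropy_ref <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Two directed 4-cycles (edge count 4) joined by one edge each way
# (count 1): the planted two-community fixture.
planted_two_cycles <- function() {
  opn_from_edges(rbind(
    data.frame(from = c("a1", "a2", "a3", "a4"),
               to = c("a2", "a3", "a4", "a1"), count = 4L,
               stringsAsFactors = FALSE),
    data.frame(from = c("b1", "b2", "b3", "b4"),
               to = c("b2", "b3", "b4", "b1"), count = 4L,
               stringsAsFactors = FALSE),
    data.frame(from = c("a1", "b1"), to = c("b1", "a1"), count = 1L,
               stringsAsFactors = FALSE)))
}

# Two disjoint directed 4-cycles with equal edge counts.
disjoint_two_cycles <- function() {
  opn_from_edges(rbind(
    data.frame(from = c("a1", "a2", "a3", "a4"),
               to = c("a2", "a3", "a4", "a1"), count = 2L,
               stringsAsFactors = FALSE),
    data.frame(from = c("b1", "b2", "b3", "b4"),
               to = c("b2", "b3", "b4", "b1"), count = 2L,
               stringsAsFactors = FALSE)))
}
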