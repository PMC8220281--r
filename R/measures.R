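# Scalar dynamical measures of ordinal partition networks and raw series:
# determinism, degeneracy, permutation entropy, map-equation community
# structure with modularity, and the largest Lyapunov exponent.

#' Determinism of a state-transition network
#'
#' `Det(X) = (log2(N) - <H(W_i_out)>) / log2(N)`, where `H(W_i_out)` is
#' the Shannon entropy (bits) of node i's normalized out-transition
#' distribution and `<.>` the unweighted mean over nodes that have
#' out-edges (terminal nodes have no defined future and are excluded;
#' their count is reported in the `"n_terminal"` attribute).  Det is 1
#' when every state has a unique successor and 0 when every state's
#' future is uniform over all N states.
#'
#' @param net an `opn` (or any object with the same structure).
#' @param weighted average node entropies by visit weight instead of
#'   uniformly (off by default; the uniform mean is the maximum-entropy
#'   convention of the effective-information framework).
#' @return determinism in \[0, 1\]; `NA` with a warning when `N = 1`
#'   (log2 1 = 0 makes the ratio undefined).
#' @export
determinism <- function(net, weighted = FALSE) {
  stopifnot(inherits(net, "opn"))
  if (net$N < 2L) {
    warning("determinism undefined for a single-node network (log2 N = 0)")
    return(NA_real_)
  }
  W <- opn_out_distributions(net)
  has_out <- attr(W, "has_out")
  H <- apply(W[has_out, , drop = FALSE], 1L, shannon_bits)
  avgH <- if (weighted) {
    wts <- net$nodes$weight[has_out]
    sum(H * wts) / sum(wts)
  } else mean(H)
  out <- (log2(net$N) - avgH) / log2(net$N)
  structure(out, n_terminal = sum(!has_out))
}

#' Degeneracy of a state-transition network
#'
#' `Deg(X) = (log2(N) - H(<W_i_out>)) / log2(N)`, where `<W_i_out>` is
#' the elementwise (unweighted) mean of the out-transition distributions
#' over nodes with out-edges -- itself a distribution over the N target
#' states.  Deg is 0 when the averaged future is uniform over all states
#' and approaches 1 as all states funnel into one shared future.
#'
#' @inheritParams determinism
#' @return degeneracy in \[0, 1\]; `NA` with a warning when `N = 1`.
#' @export
degeneracy <- function(net, weighted = FALSE) {
  stopifnot(inherits(net, "opn"))
  if (net$N < 2L) {
    warning("degeneracy undefined for a single-node network (log2 N = 0)")
    return(NA_real_)
  }
  W <- opn_out_distributions(net)
  has_out <- attr(W, "has_out")
  avgW <- if (weighted) {
    wts <- net$nodes$weight[has_out]
    colSums(W[has_out, , drop = FALSE] * wts) / sum(wts)
  } else colMeans(W[has_out, , drop = FALSE])
  out <- (log2(net$N) - shannon_bits(avgW)) / log2(net$N)
  structure(out, n_terminal = sum(!has_out))
}

#' Permutation entropy
#'
#' Shannon entropy, in bits, of the relative frequencies of the distinct
#' ordinal symbols of a series -- unnormalized, so the ceiling is
#' `log2(min(n_windows, d!))`.
#'
#' @param x an [ordinal_symbols()] sequence, an [opn()] (node visit
#'   weights), or a raw numeric series (then `d` and `tau` are required).
#' @param d,tau embedding parameters when `x` is a raw series.
#' @return entropy in bits.
#' @export
permutation_entropy <- function(x, d = NULL, tau = NULL) {
  w <- if (inherits(x, "ordinal_symbols")) {
    table(x$symbols)
  } else if (inherits(x, "opn")) {
    x$nodes$weight
  } else {
    if (is.null(d) || is.null(tau))
      stop("supply d and tau to symbolize a raw series")
    table(ordinal_symbols(as.numeric(x), d, tau)$symbols)
  }
  shannon_bits(as.numeric(w))
}

# ---------------------------------------------------------------------------
# Map-equation (Infomap-style) community detection
# ---------------------------------------------------------------------------

# Node visit rates and the smoothed transition matrix for a random walker
# with uniform teleportation (probability `teleport`); dangling nodes
# teleport uniformly.  Returns list(p, Tm).
opn_walker <- function(net, teleport = 0.15, tol = 1e-12, max_iter = 10000L) {
  W <- opn_out_distributions(net)
  has_out <- attr(W, "has_out")
  N <- net$N
  Tm <- (1 - teleport) * W + teleport / N
  if (any(!has_out)) Tm[!has_out, ] <- 1 / N
  p <- rep(1 / N, N)
  for (i in seq_len(max_iter)) {
    p_new <- as.vector(p %*% Tm)
    if (max(abs(p_new - p)) < tol) { p <- p_new; break }
    p <- p_new
  }
  list(p = p, Tm = Tm)
}

#' Two-level map-equation codelength of a partition
#'
#' Average description length, in bits, of a teleporting random walk on
#' the network under a two-level Huffman coding indexed by the module
#' partition: `L = q * H(Q) + sum_m p_m * H(P_m)` with module entry/exit
#' rates computed from the stationary visit rates.
#'
#' @param net an `opn`.
#' @param membership integer vector of module labels, one per node (in
#'   `net$nodes$symbol` order).
#' @param teleport teleportation probability of the walker.
#' @param walker optional precomputed [opn_walker] result (internal use).
#' @return codelength in bits.
#' @export
map_codelength <- function(net, membership, teleport = 0.15, walker = NULL) {
  stopifnot(inherits(net, "opn"))
  if (length(membership) != net$N)
    stop("membership must assign every node exactly once")
  wk <- walker %||% opn_walker(net, teleport)
  p <- wk$p
  Tm <- wk$Tm
  mods <- sort(unique(membership))
  q_m <- numeric(length(mods))
  inner <- 0
  for (k in seq_along(mods)) {
    in_m <- membership == mods[k]
    # exit probability of module m
    q_m[k] <- sum(p[in_m] * rowSums(Tm[in_m, !in_m, drop = FALSE]))
    pm <- q_m[k] + sum(p[in_m])
    if (pm > 0)
      inner <- inner + pm * plogp(c(q_m[k], p[in_m]) / pm)
  }
  q <- sum(q_m)
  index_len <- if (q > 0) q * plogp(q_m / q) else 0
  index_len + inner
}

#' Map-equation community detection
#'
#' Finds the node partition minimizing the two-level map equation for a
#' teleporting random walker on the weighted directed network: modules
#' are sets of states the walk tends to get stuck in (metastable
#' attractor regions of the state-transition graph).  The search is
#' repeated greedy node moves (each node tried in every neighbouring
#' module and in a module of its own, best improvement taken) from
#' seeded shuffled orders, followed by greedy module merges; the best of
#' `n_restarts` restarts is returned.  Deterministic given `seed`.
#'
#' @param net an `opn` with `N >= 2`.
#' @param seed integer seed controlling the restart shuffles.
#' @param n_restarts number of restarts.
#' @param teleport teleportation probability (handles dangling nodes and
#'   reducible graphs).
#' @return an object of class `map_partition`: `membership` (named
#'   integer vector, labels `1..n_communities`), `n_communities`,
#'   `codelength` (bits), `teleport`, `seed`.
#' @export
map_partition <- function(net, seed = 1L, n_restarts = 8L, teleport = 0.15) {
  stopifnot(inherits(net, "opn"))
  if (net$N < 2L) stop("map partition needs at least 2 nodes")
  wk <- opn_walker(net, teleport)
  N <- net$N
  p <- wk$p
  Fm <- wk$Tm * p  # flow matrix: F[i, j] = p_i T_ij
  plp <- function(x) {
    x <- x[x > 0]
    sum(x * log2(x))
  }
  const_term <- -plp(p)  # -sum_i p_i log2 p_i, partition-independent

  # Codelength from per-module exit flows q_m and visit sums s_m:
  # L = plp(q) - 2 sum plp(q_m) - sum plp(p_i) + sum plp(q_m + s_m)
  L_from <- function(q_m, s_m) {
    plp(sum(q_m)) - 2 * plp(q_m) + const_term + plp(q_m + s_m)
  }

  # undirected neighbour lists for candidate moves
  syms <- net$nodes$symbol
  ef <- match(net$edges$from, syms)
  et <- match(net$edges$to, syms)
  nbr <- vector("list", N)
  for (i in seq_along(ef)) {
    if (ef[i] != et[i]) {
      nbr[[ef[i]]] <- c(nbr[[ef[i]]], et[i])
      nbr[[et[i]]] <- c(nbr[[et[i]]], ef[i])
    }
  }
  nbr <- lapply(nbr, unique)

  one_run <- function(order_idx) {
    memb <- seq_len(N)
    s_m <- p                 # per-module visit sums (indexed by label)
    int_m <- diag(Fm)        # per-module internal flow
    q_m <- s_m - int_m       # per-module exit flow
    cnt_m <- rep(1L, N)      # member counts; the activity mask
    best_L <- L_from(q_m[cnt_m > 0L], s_m[cnt_m > 0L])

    module_stats <- function(v, m) {
      # flow between node v and module m, excluding v itself
      in_m <- memb == m
      in_m[v] <- FALSE
      c(out = sum(Fm[v, in_m]), inn = sum(Fm[in_m, v]))
    }

    repeat {
      improved <- FALSE
      for (v in order_idx) {
        a <- memb[v]
        cand <- unique(memb[nbr[[v]]])
        if (sum(memb == a) > 1L) cand <- c(cand, N + 1L)  # split off
        cand <- setdiff(cand, a)
        if (length(cand) == 0L) next
        fa <- module_stats(v, a)
        fvv <- Fm[v, v]
        sa_new <- s_m[a] - p[v]
        int_a_new <- int_m[a] - fa["out"] - fa["inn"] - fvv
        qa_new <- sa_new - int_a_new
        base_old <- -2 * plp(c(q_m[a])) + plp(c(q_m[a] + s_m[a]))
        q_tot <- sum(q_m[cnt_m > 0L])
        best_delta <- -1e-12
        best_m <- NA_integer_
        best_new <- NULL
        for (m in cand) {
          if (m > N) { fb <- c(out = 0, inn = 0); sb <- 0; int_b <- 0; qb <- 0 }
          else { fb <- module_stats(v, m); sb <- s_m[m]; int_b <- int_m[m]; qb <- q_m[m] }
          sb_new <- sb + p[v]
          int_b_new <- int_b + fb["out"] + fb["inn"] + fvv
          qb_new <- sb_new - int_b_new
          q_tot_new <- q_tot - q_m[a] - qb + qa_new + qb_new
          delta <- (plp(q_tot_new) - plp(q_tot)) +
            (-2 * plp(c(qa_new, qb_new)) + plp(c(qa_new + sa_new, qb_new + sb_new))) -
            base_old - (-2 * plp(c(qb)) + plp(c(qb + sb)))
          if (delta < best_delta) {
            best_delta <- delta
            best_m <- m
            best_new <- list(sb_new = sb_new, int_b_new = int_b_new,
                             qb_new = qb_new)
          }
        }
        if (!is.na(best_m)) {
          m <- if (best_m > N) {
            free <- which(cnt_m == 0L)
            if (length(free)) free[1L] else {
              s_m <- c(s_m, 0); int_m <- c(int_m, 0); q_m <- c(q_m, 0)
              cnt_m <- c(cnt_m, 0L); length(s_m)
            }
          } else best_m
          cnt_m[a] <- cnt_m[a] - 1L
          if (cnt_m[a] == 0L) { sa_new <- 0; int_a_new <- 0; qa_new <- 0 }
          cnt_m[m] <- cnt_m[m] + 1L
          s_m[a] <- sa_new; int_m[a] <- int_a_new; q_m[a] <- qa_new
          s_m[m] <- best_new$sb_new; int_m[m] <- best_new$int_b_new
          q_m[m] <- best_new$qb_new
          memb[v] <- m
          best_L <- best_L + best_delta
          improved <- TRUE
        }
      }

      # greedy pairwise merges on the module-aggregated flow matrix
      mods <- which(cnt_m > 0L)
      if (length(mods) > 1L) {
        gf <- factor(memb, levels = mods)
        MF <- rowsum(t(rowsum(Fm, gf)), gf)  # module-by-module flows
        k <- length(mods)
        for (ai in seq_len(k - 1L)) for (bi in (ai + 1L):k) {
          a <- mods[ai]; b <- mods[bi]
          if (cnt_m[a] == 0L || cnt_m[b] == 0L) next
          s_new <- s_m[a] + s_m[b]
          int_new <- int_m[a] + int_m[b] + MF[ai, bi] + MF[bi, ai]
          q_new <- s_new - int_new
          q_tot <- sum(q_m[cnt_m > 0L])
          q_tot_new <- q_tot - q_m[a] - q_m[b] + q_new
          delta <- (plp(q_tot_new) - plp(q_tot)) +
            (-2 * plp(c(q_new)) + plp(c(q_new + s_new))) -
            (-2 * plp(c(q_m[a], q_m[b])) +
               plp(c(q_m[a] + s_m[a], q_m[b] + s_m[b])))
          if (delta < -1e-12) {
            memb[memb == b] <- a
            s_m[a] <- s_new; int_m[a] <- int_new; q_m[a] <- q_new
            s_m[b] <- 0; int_m[b] <- 0; q_m[b] <- 0
            cnt_m[a] <- cnt_m[a] + cnt_m[b]; cnt_m[b] <- 0L
            # MF rows/cols for a absorb b's flows
            MF[ai, ] <- MF[ai, ] + MF[bi, ]
            MF[, ai] <- MF[, ai] + MF[, bi]
            MF[bi, ] <- 0; MF[, bi] <- 0
            best_L <- best_L + delta
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    list(memb = memb, L = best_L)
  }

  runs <- with_seed(seed, lapply(seq_len(n_restarts), function(r)
    one_run(sample.int(N))))
  Ls <- vapply(runs, `[[`, numeric(1), "L")
  best <- runs[[which.min(Ls)]]
  memb <- as.integer(factor(best$memb, levels = unique(best$memb)))
  names(memb) <- syms
  # the incremental L accumulates rounding; report the directly evaluated
  # codelength of the final partition
  L_final <- map_codelength(net, memb, teleport, walker = wk)
  structure(list(membership = memb,
                 n_communities = length(unique(memb)),
                 codelength = L_final, teleport = teleport, seed = seed),
            class = "map_partition")
}

#' @export
print.map_partition <- function(x, ...) {
  cat(sprintf("<map_partition> %d communities, codelength %.4f bits\n",
              x$n_communities, x$codelength))
  invisible(x)
}

#' Directed weighted Newman modularity of a partition
#'
#' `Q = sum_ij (A_ij / m - k_i_out * k_j_in / m^2) * delta(c_i, c_j)` on
#' the edge counts of the network.
#'
#' @param net an `opn`.
#' @param partition a [map_partition()] object, or a membership vector
#'   over `net$nodes$symbol`.
#' @return modularity Q (<= 1).
#' @export
modularity_q <- function(net, partition) {
  stopifnot(inherits(net, "opn"))
  memb <- if (inherits(partition, "map_partition")) partition$membership
          else partition
  if (length(memb) != net$N)
    stop("partition does not match the network's nodes")
  if (!is.null(names(memb))) {
    if (!setequal(names(memb), net$nodes$symbol))
      stop("partition does not match the network's nodes")
    memb <- memb[net$nodes$symbol]
  }
  syms <- net$nodes$symbol
  w <- net$edges$count
  m <- sum(w)
  ci <- memb[match(net$edges$from, syms)]
  cj <- memb[match(net$edges$to, syms)]
  e_in <- sum(w[ci == cj]) / m
  kout <- vapply(split(w, factor(memb[match(net$edges$from, syms)],
                                 levels = sort(unique(memb)))), sum, numeric(1))
  kin <- vapply(split(w, factor(memb[match(net$edges$to, syms)],
                                levels = sort(unique(memb)))), sum, numeric(1))
  e_in - sum((kout / m) * (kin / m))
}

# ---------------------------------------------------------------------------
# Largest Lyapunov exponent (Rosenstein et al. style)
# ---------------------------------------------------------------------------

#' Largest Lyapunov exponent by nearest-neighbour divergence
#'
#' Rosenstein-style estimator: delay-embed the series, pair each point
#' with its nearest neighbour outside a Theiler exclusion window, track
#' the log distance of each pair forward in time, average over pairs,
#' and fit the slope of the mean log-divergence curve over `fit_range`
#' steps by least squares.  Positive slopes indicate exponential
#' divergence of nearby trajectories (chaos); flat curves indicate
#' regular dynamics.  The default fit window covers the first five steps:
#' for short, noisy segments the divergence curve saturates at the
#' attractor scale within a handful of steps, and including the
#' saturated tail biases the slope toward zero.
#'
#' @param x univariate numeric series (length >= 1000 recommended).
#' @param fs sampling rate (Hz); kept for provenance, the estimate is
#'   returned per sample.
#' @param m embedding dimension.
#' @param lag embedding lag in samples; default [select_tau()].
#' @param theiler temporal exclusion half-width for neighbour search;
#'   default `lag * (m - 1)`.
#' @param fit_range steps of the divergence curve used for the slope fit.
#' @param max_points cap on the number of embedded points used (the
#'   neighbour search is quadratic); longer series are truncated.
#' @return the slope in nats per sample, with the divergence curve in
#'   the `"divergence"` attribute.
#' @export
lyapunov_largest <- function(x, fs = NULL, m = 5L, lag = NULL,
                             theiler = NULL, fit_range = 1:5,
                             max_points = 2500L) {
  x <- as.numeric(x)
  if (length(x) < 100L) stop("series too short for a divergence estimate")
  if (sd(x) == 0) stop("constant series: divergence undefined")
  if (is.null(lag)) lag <- select_tau(x)
  lag <- as.integer(lag)
  if (is.null(theiler)) theiler <- lag * (m - 1L)
  n_steps <- max(fit_range)
  nw <- length(x) - (m - 1L) * lag
  if (nw <= n_steps + theiler + 2L)
    stop("series too short for the requested embedding and horizon")
  if (nw > max_points) {
    x <- x[seq_len(max_points + (m - 1L) * lag)]
    nw <- max_points
  }
  idx <- outer(seq_len(nw), (0:(m - 1L)) * lag, `+`)
  emb <- matrix(x[idx], nrow = nw)
  curve <- .lyap_divergence_cpp(emb, as.integer(theiler), as.integer(n_steps))
  steps <- 0:n_steps
  use <- steps %in% fit_range & !is.na(curve)
  if (sum(use) < 2L) stop("no valid neighbour pairs for the slope fit")
  slope <- unname(coef(lm(curve[use] ~ steps[use]))[2L])
  structure(slope, divergence = data.frame(step = steps, mean_log_dist = curve),
            m = m, lag = lag, theiler = theiler)
}
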