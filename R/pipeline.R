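# Pipeline orchestration over many segments/channels, nonparametric group
# comparisons, condition summaries, and the morphospace embedding.

#' Pipeline configuration
#'
#' Collects every free parameter of the analysis in one list so that a
#' run is fully described by (segments, config).
#'
#' @param filters apply [apply_filters()] (`TRUE` for field recordings
#'   with line noise; synthetic surrogates need none).
#' @param hp,lp,notch_base,notch_max FIR band edges, see
#'   [apply_filters()].
#' @param trim_ms edge trim per side, ms.
#' @param d embedding dimension: an integer, or `"auto"` to use the mode
#'   over per-channel degree-variance selections (shared across all
#'   channels, as required for aggregation).
#' @param candidates candidate dimensions for `d = "auto"`.
#' @param self_loops keep OPN self-transitions.
#' @param tda_landmarks landmark count for the Rips filtration; `0`
#'   disables landmarking (full cloud, subject to the guard).
#' @param tda_metric `"cosine"` or `"euclidean"`.
#' @param tda_grid_n Betti-curve grid resolution.
#' @param lyap_m,lyap_fit,lyap_max_points Lyapunov estimator controls.
#' @param infomap_seed,infomap_restarts partition search controls.
#' @param seed base seed for landmark selection.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(filters = FALSE, hp = 0.1, lp = 200,
                            notch_base = 50, notch_max = 250,
                            trim_ms = 50, d = 5L, candidates = 3:7,
                            self_loops = TRUE, tda_landmarks = 100L,
                            tda_metric = "cosine", tda_grid_n = 100L,
                            lyap_m = 5L, lyap_fit = 1:5,
                            lyap_max_points = 1000L, infomap_seed = 1L,
                            infomap_restarts = 4L, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Run the full dual-embedding pipeline
#'
#' For each segment: optional filtering, edge trimming, global
#' z-scoring; the embedded point cloud with landmarked Rips persistence
#' and its three cycle summaries (one row per segment); then, per
#' channel: lag selection, shared-dimension ordinal partition network,
#' determinism, degeneracy, permutation entropy, map-equation modularity
#' and the largest Lyapunov exponent (one row per channel).  Failures in
#' any item are caught, recorded in the failure manifest, and the run
#' continues.
#'
#' @param segments list of [recording_segment]s with a common sampling
#'   rate.
#' @param config a [pipeline_config()].
#' @return an object of class `measure_table`: `opn_rows` (per channel),
#'   `tda_rows` (per segment), `failures`, and `provenance` (config,
#'   hash, package version).
#' @export
run_pipeline <- function(segments, config = pipeline_config()) {
  if (length(segments) == 0L) stop("no segments supplied")
  fss <- vapply(segments, function(s) s$fs, numeric(1))
  if (length(unique(fss)) != 1L) stop("segments have inconsistent sampling rates")

  opn_rows <- list()
  tda_rows <- list()
  failures <- list()
  d_shared <- config$d

  prepped <- vector("list", length(segments))
  for (si in seq_along(segments)) {
    seg <- segments[[si]]
    res <- tryCatch({
      if (isTRUE(config$filters))
        seg <- apply_filters(seg, hp = config$hp, lp = config$lp,
                             notch_base = config$notch_base,
                             notch_max = config$notch_max)
      if (config$trim_ms > 0) seg <- trim_edges(seg, config$trim_ms)
      zscore_global(seg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(segment = si, stage = "preprocess",
                   message = conditionMessage(res))
      prepped[si] <- list(NULL)
    } else prepped[[si]] <- res
  }

  # shared embedding dimension: mode of per-channel selections
  if (identical(d_shared, "auto")) {
    sels <- integer(0)
    for (seg in prepped) {
      if (is.null(seg)) next
      for (c in seq_len(nrow(seg$data))) {
        x <- seg$data[c, ]
        sel <- tryCatch(select_dim(x, select_tau(x), config$candidates,
                                   self_loops = config$self_loops),
                        error = function(e) NA_integer_)
        sels <- c(sels, sel)
      }
    }
    sels <- sels[!is.na(sels)]
    if (length(sels) == 0L) stop("dimension selection failed on every channel")
    tab <- table(sels)
    d_shared <- as.integer(names(tab)[which.max(tab)])
  }
  d_shared <- as.integer(d_shared)

  for (si in seq_along(prepped)) {
    seg <- prepped[[si]]
    if (is.null(seg)) next

    tda <- tryCatch({
      cloud <- build_epc(seg, metric = config$tda_metric)
      dm <- pairwise_dissimilarity(cloud)
      if (config$tda_landmarks > 0L && config$tda_landmarks < nrow(dm)) {
        lm_idx <- maxmin_landmarks(dm, config$tda_landmarks,
                                   seed = config$seed + si)
        dm_sub <- dm[lm_idx, lm_idx]
        attr(dm_sub, "metric") <- attr(dm, "metric")
        dm <- dm_sub
      }
      pd <- rips_persistence(dm)
      s <- tda_summaries(pd, grid = seq(0, pd$max_radius,
                                        length.out = config$tda_grid_n))
      v <- state_velocity(cloud)
      data.frame(segment = si, subject = seg$subject,
                 condition = seg$condition,
                 max_persistence = s$max_persistence,
                 n_cycles = s$n_cycles, max_cycles = s$max_cycles,
                 avg_velocity = attr(v, "average_velocity"),
                 n_landmarks = nrow(dm))
    }, error = function(e) e)
    if (inherits(tda, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(segment = si, stage = "tda", message = conditionMessage(tda))
    } else tda_rows[[length(tda_rows) + 1L]] <- tda

    for (c in seq_len(nrow(seg$data))) {
      row <- tryCatch({
        x <- seg$data[c, ]
        tau <- select_tau(x)
        net <- build_opn(ordinal_symbols(x, d_shared, tau),
                         self_loops = config$self_loops)
        part <- if (net$N >= 2L)
          map_partition(net, seed = config$infomap_seed,
                        n_restarts = config$infomap_restarts) else NULL
        lam <- lyapunov_largest(x, fs = seg$fs, m = config$lyap_m, lag = tau,
                                fit_range = config$lyap_fit,
                                max_points = config$lyap_max_points)
        data.frame(segment = si, channel = seg$channel_ids[c],
                   subject = seg$subject, condition = seg$condition,
                   d = d_shared, tau = tau,
                   n_nodes = net$N, n_edges = nrow(net$edges),
                   det = as.numeric(suppressWarnings(determinism(net))),
                   deg = as.numeric(suppressWarnings(degeneracy(net))),
                   perm_entropy = permutation_entropy(net),
                   modularity_q = if (is.null(part)) NA_real_
                                  else modularity_q(net, part),
                   n_communities = if (is.null(part)) NA_integer_
                                   else part$n_communities,
                   lyapunov = as.numeric(lam))
      }, error = function(e) e)
      if (inherits(row, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(segment = si, stage = sprintf("opn-ch%d", c),
                     message = conditionMessage(row))
      } else opn_rows[[length(opn_rows) + 1L]] <- row
    }
  }

  out <- list(
    opn_rows = if (length(opn_rows)) do.call(rbind, opn_rows) else NULL,
    tda_rows = if (length(tda_rows)) do.call(rbind, tda_rows) else NULL,
    failures = if (length(failures)) do.call(rbind, failures) else NULL,
    provenance = list(config = config, d_shared = d_shared,
                      config_hash = config_hash(config),
                      n_segments = length(segments),
                      package_version = as.character(utils::packageVersion("opntda"))))
  class(out) <- "measure_table"
  out
}

#' @export
print.measure_table <- function(x, ...) {
  cat(sprintf("<measure_table> %d OPN rows, %d TDA rows, %d failures\n",
              if (is.null(x$opn_rows)) 0L else nrow(x$opn_rows),
              if (is.null(x$tda_rows)) 0L else nrow(x$tda_rows),
              if (is.null(x$failures)) 0L else nrow(x$failures)))
  cat(sprintf("  shared d = %d, config %s\n", x$provenance$d_shared,
              x$provenance$config_hash))
  invisible(x)
}

#' Kruskal-Wallis rank analysis of variance
#'
#' Rank-based H with tie correction; p from the chi-squared
#' approximation with k - 1 degrees of freedom (delegates to
#' [stats::kruskal.test()]).
#'
#' @param groups list of numeric samples, one per group (>= 2 groups,
#'   each non-empty).
#' @return data frame with `test`, `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("every group must contain at least one observation")
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1L) {
    warning("all observations identical: H = 0, p = 1")
    return(data.frame(test = "kruskal_wallis", statistic = 0,
                      df = length(groups) - 1L, p_value = 1))
  }
  kt <- kruskal.test(groups)
  data.frame(test = "kruskal_wallis",
             statistic = unname(kt$statistic),
             df = unname(kt$parameter), p_value = kt$p.value)
}

#' Pairwise Mann-Whitney U post hoc tests
#'
#' Two-sided U test for every unordered pair of groups; the exact null
#' distribution is used for small tie-free samples (both n <= 20),
#' otherwise the normal approximation with tie correction (delegates to
#' [stats::wilcox.test()]).  Empty groups are skipped with a note.
#'
#' @param values numeric vector of observations.
#' @param labels group label per observation.
#' @return data frame with one row per pair: `group_a`, `group_b`,
#'   `U` (statistic for group a), `p_value`, `exact`.
#' @export
mann_whitney_posthoc <- function(values, labels) {
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) < 2L) stop("need at least 2 groups")
  rows <- list()
  for (pair in combn(lv, 2L, simplify = FALSE)) {
    a <- values[labels == pair[1L]]
    b <- values[labels == pair[2L]]
    if (length(a) == 0L || length(b) == 0L) {
      message(sprintf("skipping pair %s vs %s: empty group", pair[1L], pair[2L]))
      next
    }
    exact <- length(a) <= 20L && length(b) <= 20L && !any(duplicated(c(a, b)))
    wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
    rows[[length(rows) + 1L]] <-
      data.frame(group_a = pair[1L], group_b = pair[2L],
                 U = unname(wt$statistic), p_value = wt$p.value,
                 exact = exact)
  }
  do.call(rbind, rows)
}

#' Aggregate a measure table to summary rows
#'
#' Group means and sample standard deviations per measure at the chosen
#' level; groups of a single row report SD 0 and are flagged by `n = 1`.
#'
#' @param table a `measure_table` or a plain data frame of rows.
#' @param level grouping column: `"channel"`, `"subject"` or
#'   `"condition"`.
#' @param measures measure columns to summarize; default: all numeric
#'   measure columns present.
#' @return data frame with one row per (group, measure): `level`,
#'   `group`, `measure`, `mean`, `sd`, `n`.
#' @export
aggregate_measures <- function(table, level = "condition", measures = NULL) {
  df <- if (inherits(table, "measure_table")) table$opn_rows else table
  if (is.null(df) || nrow(df) == 0L) stop("no rows to aggregate")
  if (!level %in% names(df)) stop(sprintf("level column '%s' not present", level))
  if (is.null(measures)) {
    skip <- c("segment", "d", "tau", "n_communities")
    measures <- setdiff(names(df)[vapply(df, is.numeric, logical(1))], skip)
  }
  rows <- list()
  for (g in unique(df[[level]])) {
    sub <- df[df[[level]] == g, , drop = FALSE]
    for (msr in measures) {
      v <- sub[[msr]]
      miss <- sum(is.na(v))
      v <- v[!is.na(v)]
      if (length(v) == 0L) {
        message(sprintf("group %s has no finite values for %s; excluded", g, msr))
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(level = level, group = g, measure = msr,
                   mean = mean(v), sd = if (length(v) > 1L) sd(v) else 0,
                   n = length(v), n_missing = miss)
    }
  }
  do.call(rbind, rows)
}

#' Morphospace embedding of OPN measures
#'
#' Embeds each analyzed channel as a point in the five-dimensional
#' feature space of its state-transition measures and projects to two
#' dimensions for visualization by classical multidimensional scaling of
#' standardized Euclidean feature distances.  The resulting axes carry
#' no intrinsic meaning; only relative distances between points do.  The
#' projection is deterministic; `seed` is accepted for interface
#' stability.
#'
#' @param table a `measure_table` or data frame with the feature columns.
#' @param features feature columns; default the five OPN measures.
#' @param seed accepted for reproducibility contracts (the MDS embedding
#'   is deterministic and ignores it).
#' @return data frame with `dim1`, `dim2` plus any `condition` /
#'   `subject` / `channel` columns of the input.
#' @export
morphospace_embed <- function(table,
                              features = c("n_nodes", "n_edges", "det",
                                           "deg", "modularity_q"),
                              seed = 1L) {
  df <- if (inherits(table, "measure_table")) table$opn_rows else table
  if (is.null(df) || nrow(df) < 3L) stop("need at least 3 rows to embed")
  missing_f <- setdiff(features, names(df))
  if (length(missing_f))
    stop("missing feature column(s): ", paste(missing_f, collapse = ", "))
  X <- scale(as.matrix(df[, features]))
  X[is.nan(X)] <- 0  # constant features carry no information
  coords <- cmdscale(dist(X), k = 2L)
  out <- data.frame(dim1 = coords[, 1L], dim2 = coords[, 2L])
  for (col in intersect(c("condition", "subject", "channel", "segment"),
                        names(df)))
    out[[col]] <- df[[col]]
  out
}
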