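# Turning benchmark scores into headline artifacts: best-over-k final
# scores, tie-aware rankings, average-rank and cross-entropy Monte Carlo
# consensus orders, and k-means clustering of metric performance profiles.

#' Score tensor: benchmark scores indexed by metric, measure, experiment, k
#'
#' Validates and classes a long-format data frame of benchmark scores
#' \eqn{S_{dpek}} with columns `metric` (d), `performance` (p), `experiment`
#' (e), `k` and `score`. Every experiment must carry the complete
#' metric x performance x k grid (the k grid may differ between
#' experiments), and all scores must lie in `[0, 1]`.
#'
#' @param x A data frame with the five columns above.
#' @return `x` with class `"score_tensor"` prepended.
#' @seealso [best_over_k()], [run_benchmark()]
#' @export
score_tensor <- function(x) {
  needed <- c("metric", "performance", "experiment", "k", "score")
  if (!is.data.frame(x) || !all(needed %in% names(x)))
    stop("a score tensor needs columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  x <- as.data.frame(x)[, needed]
  if (any(is.na(x$score)) || any(x$score < 0 | x$score > 1))
    stop("scores must lie in [0, 1] with no missing values", call. = FALSE)
  for (e in unique(x$experiment)) {
    sub <- x[x$experiment == e, ]
    grid <- expand.grid(metric = unique(sub$metric),
                        performance = unique(sub$performance),
                        k = unique(sub$k), stringsAsFactors = FALSE)
    key_have <- paste(sub$metric, sub$performance, sub$k, sep = "\r")
    key_want <- paste(grid$metric, grid$performance, grid$k, sep = "\r")
    missing <- setdiff(key_want, key_have)
    if (length(missing) > 0)
      stop("incomplete score tensor for experiment '", e, "': missing ",
           length(missing), " cell(s), e.g. ",
           paste(utils::head(gsub("\r", "/", missing), 3L), collapse = "; "),
           call. = FALSE)
    if (anyDuplicated(key_have))
      stop("duplicated score-tensor cells in experiment '", e, "'",
           call. = FALSE)
  }
  if (!inherits(x, "score_tensor")) class(x) <- c("score_tensor", class(x))
  x
}

#' Best-over-k final scores
#'
#' The final score of a metric for a given performance measure and
#' experiment is the best (maximum) score across all evaluated neighborhood
#' sizes: \eqn{S_{dpe} = \max_k S_{dpek}}. Called with only a tensor, the
#' maximum is taken for every (metric, performance, experiment) cell; with
#' `metric`, `performance` and `experiment` given, the single scalar is
#' returned.
#'
#' @param tensor A [score_tensor()].
#' @param metric,performance,experiment Optional single ids selecting one
#'   cell.
#' @return A data frame with columns `metric`, `performance`, `experiment`,
#'   `score` (class `"best_scores"`), or a scalar in single-cell mode.
#' @export
best_over_k <- function(tensor, metric = NULL, performance = NULL,
                        experiment = NULL) {
  tensor <- score_tensor(tensor)
  single <- !is.null(metric) || !is.null(performance) || !is.null(experiment)
  if (single) {
    if (is.null(metric) || is.null(performance) || is.null(experiment))
      stop("supply all of 'metric', 'performance' and 'experiment', or none",
           call. = FALSE)
    sub <- tensor[tensor$metric == metric &
                  tensor$performance == performance &
                  tensor$experiment == experiment, ]
    if (nrow(sub) == 0L)
      stop("no scores for cell (", metric, ", ", performance, ", ",
           experiment, ")", call. = FALSE)
    return(max(sub$score))
  }
  agg <- stats::aggregate(score ~ metric + performance + experiment,
                          data = tensor, FUN = max)
  agg <- agg[order(agg$experiment, agg$performance, agg$metric), ]
  rownames(agg) <- NULL
  class(agg) <- c("best_scores", class(agg))
  agg
}

#' Performance-profile matrix of best scores
#'
#' Reshapes best-over-k scores into a matrix with one row per metric and one
#' column per (experiment, performance) combination — the profile each
#' metric exposes to ranking and clustering.
#'
#' @param best A `"best_scores"` data frame from [best_over_k()], or a
#'   [score_tensor()] (reduced with [best_over_k()] first).
#' @return A numeric matrix, metrics x (experiment_performance) columns.
#' @export
profile_matrix <- function(best) {
  if (inherits(best, "score_tensor")) best <- best_over_k(best)
  stopifnot(all(c("metric", "performance", "experiment", "score") %in%
                  names(best)))
  cols <- paste(best$experiment, best$performance, sep = "_")
  m <- tapply(best$score,
              list(factor(best$metric, levels = unique(best$metric)),
                   factor(cols, levels = unique(cols))),
              FUN = identity)
  storage.mode(m) <- "double"
  if (any(is.na(m)))
    stop("incomplete best-score table: missing metric/column cells",
         call. = FALSE)
  m
}

#' Tie-aware ranking of final scores
#'
#' Ranks items by descending score (rank 1 = best). Ties are resolved by
#' `policy`: `"average"` assigns tied items their fractional mean rank (so
#' ranks always sum to `m(m+1)/2`), `"min"` the shared best (competition)
#' rank, and `"ordinal"` distinct ranks in order of appearance.
#'
#' @param scores A named numeric vector (higher = better). `NA`/`NaN`
#'   scores are rejected.
#' @param policy `"average"` (default), `"min"` or `"ordinal"`.
#' @return A named numeric vector of ranks with attribute `policy`.
#' @examples
#' rank_with_ties(c(a = 0.9, b = 0.8, c = 0.8, d = 0.1))  # 1, 2.5, 2.5, 4
#' @export
rank_with_ties <- function(scores, policy = c("average", "min", "ordinal")) {
  policy <- match.arg(policy)
  if (length(scores) < 1L)
    stop("need at least one item to rank", call. = FALSE)
  if (any(is.na(scores)))
    stop("scores contain NA/NaN", call. = FALSE)
  method <- c(average = "average", min = "min", ordinal = "first")[[policy]]
  r <- rank(-scores, ties.method = method)
  structure(as.numeric(r), names = names(scores), policy = policy)
}

#' Average rank across experiments
#'
#' The arithmetic mean of each item's rank over a collection of rankings on
#' the same item set (one ranking per experiment x performance-measure
#' combination in the benchmark).
#'
#' @param rankings A list of named rank vectors (see [rank_with_ties()]).
#' @return A named numeric vector of mean ranks (lower = better).
#' @export
average_rank <- function(rankings) {
  if (length(rankings) < 1L)
    stop("need at least one ranking", call. = FALSE)
  items <- names(rankings[[1L]])
  for (r in rankings)
    if (!setequal(names(r), items) || length(r) != length(items))
      stop("rankings are not over the same item set", call. = FALSE)
  rowMeans(vapply(rankings, function(r) r[items],
                  numeric(length(items))))
}

#' Kendall distance between two orderings
#'
#' The number of item pairs ordered differently by the two lists (pairwise
#' disagreements); between 0 and `m(m-1)/2` for `m` items. Inputs are
#' tie-free ordered item lists over the same item set.
#'
#' @param a,b Character vectors listing the same items, best first.
#' @return A non-negative integer count.
#' @examples
#' kendall_distance(c("A", "B", "C"), c("C", "B", "A"))  # 3
#' @export
kendall_distance <- function(a, b) {
  if (anyDuplicated(a) || anyDuplicated(b))
    stop("ordered lists must not contain duplicates", call. = FALSE)
  if (length(a) != length(b) || !setequal(a, b))
    stop("'a' and 'b' must order the same item set", call. = FALSE)
  pb <- match(a, b)
  sum(vapply(seq_along(pb), function(i)
    sum(pb[seq_len(i - 1L)] > pb[i]), numeric(1)))
}

#' Configuration for cross-entropy Monte Carlo rank aggregation
#'
#' @param rho Elite fraction in (0, 1); default 0.1.
#' @param sample_size Candidate orders sampled per iteration; default
#'   `200 * m` for `m` items (resolved at run time when `NULL`).
#' @param smoothing Weight in (0, 1] pulling the position-probability matrix
#'   toward the elite empirical frequencies each iteration; default 0.7.
#' @param max_iterations Iteration cap; default 100.
#' @param convergence_window Stop after this many iterations without
#'   improvement of the best objective; default 7.
#' @param seed Integer seed for the sampler.
#' @param weights Optional per-input-list weights (default uniform).
#' @return An object of class `"aggregation_config"`.
#' @export
aggregation_config <- function(rho = 0.1, sample_size = NULL, smoothing = 0.7,
                               max_iterations = 100, convergence_window = 7,
                               seed = 1, weights = NULL) {
  if (!is.numeric(rho) || rho <= 0 || rho >= 1)
    stop("'rho' must be in (0, 1)", call. = FALSE)
  if (!is.null(sample_size) &&
      (!is.numeric(sample_size) || sample_size < 1))
    stop("'sample_size' must be a positive integer", call. = FALSE)
  if (!is.numeric(smoothing) || smoothing <= 0 || smoothing > 1)
    stop("'smoothing' must be in (0, 1]", call. = FALSE)
  if (max_iterations < 1 || convergence_window < 1)
    stop("'max_iterations' and 'convergence_window' must be >= 1",
         call. = FALSE)
  structure(list(rho = rho, sample_size = sample_size, smoothing = smoothing,
                 max_iterations = as.integer(max_iterations),
                 convergence_window = as.integer(convergence_window),
                 seed = as.integer(seed), weights = weights),
            class = "aggregation_config")
}

# Weighted Kendall objective against a fixed set of input lists, via a
# precomputed pairwise "j-before-i" weight matrix: the objective of a
# candidate order equals the total weight of input pairs it inverts.
.kendall_objective_fn <- function(rankings, items, weights) {
  m <- length(items)
  C <- matrix(0, m, m, dimnames = list(items, items))
  for (l in seq_along(rankings)) {
    pos <- match(items, rankings[[l]])
    before <- outer(pos, pos, "<")  # [i, j] TRUE if i before j in list l
    C <- C + weights[l] * before
  }
  Ct <- t(C)
  function(ord) {
    po <- match(items, ord)
    sum(outer(po, po, "<") * Ct)
  }
}

#' Consensus ranking by cross-entropy Monte Carlo search
#'
#' Finds an ordering of the items minimizing the (optionally weighted) sum
#' of Kendall distances to the input lists. The search maintains an
#' item-by-position probability matrix, initialized uniform; each iteration
#' samples `sample_size` candidate orders from it, retains the elite
#' `ceiling(rho * sample_size)` by objective, and moves the matrix toward
#' the elite empirical position frequencies with weight `smoothing`. The
#' search stops when the best objective has not improved for
#' `convergence_window` iterations (or at `max_iterations`, or when the
#' objective reaches 0). The input lists and any `initial_candidates` are
#' evaluated up front, so the returned objective never exceeds that of any
#' input list.
#'
#' @param rankings A list of tie-free ordered item lists (character
#'   vectors, best first) over a common item set.
#' @param config An [aggregation_config()].
#' @param initial_candidates Optional list of additional orders to seed the
#'   candidate pool (e.g. the mean-rank order).
#' @return An object of class `"consensus_ranking"`: a list with `order`
#'   (the best-found item order), `objective` (its summed Kendall distance),
#'   `trace` (best objective per iteration) and `iterations`.
#' @export
ce_rank_aggregate <- function(rankings, config = aggregation_config(),
                              initial_candidates = list()) {
  stopifnot(inherits(config, "aggregation_config"))
  if (length(rankings) < 1L)
    stop("need at least one input ranking", call. = FALSE)
  items <- sort(rankings[[1L]])
  for (r in rankings) {
    if (anyDuplicated(r))
      stop("input lists must be tie-free (no duplicates)", call. = FALSE)
    if (!setequal(r, items))
      stop("input lists must share a common item set", call. = FALSE)
  }
  m <- length(items)
  n_samp <- if (is.null(config$sample_size)) 200L * m
            else as.integer(config$sample_size)
  n_elite <- ceiling(config$rho * n_samp)
  if (n_elite < 1)
    stop("rho * sample_size must be >= 1", call. = FALSE)
  weights <- config$weights
  if (is.null(weights)) weights <- rep(1, length(rankings))
  if (length(weights) != length(rankings) || any(weights < 0))
    stop("'weights' must be non-negative, one per input list", call. = FALSE)
  objective <- .kendall_objective_fn(rankings, items, weights)

  seed_pool <- c(rankings, initial_candidates)
  seed_objs <- vapply(seed_pool, objective, numeric(1))
  best_i <- which.min(seed_objs)
  best_ord <- seed_pool[[best_i]]
  best_obj <- seed_objs[best_i]

  trace <- numeric(0)
  it <- 0L
  .with_seed(config$seed, {
    P <- matrix(1 / m, m, m)  # rows: items, cols: positions
    stale <- 0L
    while (it < config$max_iterations && best_obj > 0) {
      it <- it + 1L
      cand <- vector("list", n_samp)
      objs <- numeric(n_samp)
      for (s in seq_len(n_samp)) {
        remaining <- seq_len(m)
        ord <- integer(m)
        for (pos in seq_len(m)) {
          pr <- P[remaining, pos]
          if (sum(pr) <= 0) pr <- rep(1, length(remaining))
          pick <- if (length(remaining) == 1L) 1L
                  else sample.int(length(remaining), 1L, prob = pr)
          ord[pos] <- remaining[pick]
          remaining <- remaining[-pick]
        }
        cand[[s]] <- ord
        objs[s] <- objective(items[ord])
      }
      elite <- order(objs)[seq_len(n_elite)]
      if (objs[elite[1L]] < best_obj) {
        best_obj <- objs[elite[1L]]
        best_ord <- items[cand[[elite[1L]]]]
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
      freq <- matrix(0, m, m)
      for (s in elite) {
        ord <- cand[[s]]
        freq[cbind(ord, seq_len(m))] <- freq[cbind(ord, seq_len(m))] + 1
      }
      P <- (1 - config$smoothing) * P + config$smoothing * freq / n_elite
      trace <- c(trace, best_obj)
      if (stale >= config$convergence_window) break
    }
  })
  structure(list(order = best_ord, objective = best_obj, trace = trace,
                 iterations = it),
            class = "consensus_ranking")
}

#' @export
print.consensus_ranking <- function(x, ...) {
  cat("<consensus_ranking> objective", x$objective, "after", x$iterations,
      "iterations\n")
  cat(paste(seq_along(x$order), x$order, sep = ". "), sep = "\n")
  invisible(x)
}

#' Cluster metric performance profiles with k-means
#'
#' Runs squared-Euclidean k-means (via [stats::kmeans()]) on the metric
#' profile matrix with `restarts` seeded random initializations, keeping the
#' lowest-inertia solution.
#'
#' @param profiles A numeric matrix, one row per item (see
#'   [profile_matrix()]).
#' @param k Number of clusters, at most the number of items.
#' @param restarts Number of random restarts (default 50).
#' @param seed Integer seed.
#' @param standardize Standardize profile columns to zero mean / unit SD
#'   before clustering (default `FALSE`: raw scores).
#' @return An object of class `"profile_clusters"`: list with `assignment`
#'   (named cluster index per item), `centers` and `inertia` (total
#'   within-cluster sum of squares).
#' @export
cluster_profiles <- function(profiles, k, restarts = 50, seed = 1,
                             standardize = FALSE) {
  profiles <- as.matrix(profiles)
  if (!is.numeric(k) || k < 1 || k > nrow(profiles))
    stop("'k' must be between 1 and the number of items (",
         nrow(profiles), ")", call. = FALSE)
  x <- if (standardize) scale(profiles) else profiles
  km <- .with_seed(seed,
    stats::kmeans(x, centers = k, nstart = restarts, iter.max = 100))
  assignment <- stats::setNames(as.integer(km$cluster), rownames(profiles))
  structure(list(assignment = assignment, centers = km$centers,
                 inertia = km$tot.withinss, standardized = standardize),
            class = "profile_clusters")
}

#' @export
print.profile_clusters <- function(x, ...) {
  cat("<profile_clusters>", length(unique(x$assignment)),
      "clusters, inertia", format(x$inertia, digits = 6), "\n")
  for (cl in sort(unique(x$assignment)))
    cat("  [", cl, "] ",
        paste(names(x$assignment)[x$assignment == cl], collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Project performance profiles onto the top two principal components
#'
#' Centered (unscaled) PCA via [stats::prcomp()], returning per-item scores
#' on the first `dims` components — a plotting aid for cluster maps. If the
#' profile matrix has rank below `dims`, trailing columns are zero.
#'
#' @param profiles A numeric matrix with at least `dims` rows.
#' @param dims Number of components (default 2).
#' @return A numeric matrix, items x `dims`.
#' @export
pca_project <- function(profiles, dims = 2) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < dims)
    stop("need at least ", dims, " items for a ", dims,
         "-component projection", call. = FALSE)
  pc <- stats::prcomp(profiles, center = TRUE, scale. = FALSE)
  sc <- pc$x
  if (ncol(sc) < dims)
    sc <- cbind(sc, matrix(0, nrow(sc), dims - ncol(sc)))
  out <- sc[, seq_len(dims), drop = FALSE]
  colnames(out) <- paste0("PC", seq_len(dims))
  out
}

#' Plot metric clusters in PCA space
#'
#' Simple base-graphics scatter of the 2-D PCA projection of the profiles,
#' colored by cluster assignment and labeled with item names.
#'
#' @param profiles A numeric profile matrix.
#' @param clusters A `"profile_clusters"` object for the same items.
#' @param ... Passed to [graphics::plot()].
#' @return The projected coordinates, invisibly.
#' @export
plot_metric_clusters <- function(profiles, clusters, ...) {
  stopifnot(inherits(clusters, "profile_clusters"))
  xy <- pca_project(profiles, 2)
  cl <- clusters$assignment[rownames(profiles)]
  graphics::plot(xy, col = cl + 1L, pch = 19,
                 xlab = "PC1", ylab = "PC2", ...)
  graphics::text(xy, labels = rownames(profiles), pos = 3, cex = 0.8,
                 col = cl + 1L)
  invisible(xy)
}

#' Rank the benchmarked metrics
#'
#' Produces the final ranking table from a score tensor (or best-score
#' table): tie-aware rankings are built per experiment x performance-measure
#' combination (`granularity = "by_measure"`, the default) or per
#' experiment x measure x k (`"by_measure_k"`), then combined by (i) the
#' average rank across rankings and (ii) a cross-entropy Monte Carlo
#' consensus under Kendall distance. Metric performance profiles are also
#' clustered with k-means.
#'
#' @param scores A [score_tensor()] or `"best_scores"` data frame.
#' @param tie_policy Tie policy for per-experiment rankings (see
#'   [rank_with_ties()]).
#' @param granularity `"by_measure"` or `"by_measure_k"`.
#' @param ce_config An [aggregation_config()] for the consensus search.
#' @param cluster_k Number of k-means clusters (default 3).
#' @param restarts k-means restarts (default 50).
#' @param standardize Standardize profiles before clustering.
#' @return A data frame of class `"metric_ranking"` with columns `metric`,
#'   `mean_rank`, `rank_ave`, `rank_ce` and `cluster`, ordered by
#'   `rank_ave`; attributes `ce_objective`, `mean_rank_objective` and
#'   `clusters` carry the consensus objective, the objective of the
#'   mean-rank order, and the full cluster object.
#' @export
rank_metrics <- function(scores, tie_policy = "average",
                         granularity = c("by_measure", "by_measure_k"),
                         ce_config = aggregation_config(),
                         cluster_k = 3, restarts = 50, standardize = FALSE) {
  granularity <- match.arg(granularity)
  has_k <- "k" %in% names(scores) && length(unique(scores$k)) >= 1L &&
    inherits(scores, "score_tensor")
  best <- if (has_k) best_over_k(scores) else scores
  stopifnot(all(c("metric", "performance", "experiment", "score") %in%
                  names(best)))
  base <- if (granularity == "by_measure_k") {
    if (!has_k)
      stop("granularity 'by_measure_k' needs a full score tensor with k",
           call. = FALSE)
    scores
  } else best
  group_cols <- if (granularity == "by_measure_k")
    c("experiment", "performance", "k") else c("experiment", "performance")
  key <- do.call(paste, c(base[group_cols], sep = "\r"))
  groups <- split(base, key)
  rankings <- lapply(groups, function(g)
    rank_with_ties(stats::setNames(g$score, g$metric), policy = tie_policy))
  mean_ranks <- average_rank(rankings)

  # strict orders for the consensus search: score descending, name as a
  # deterministic tie-break
  orders <- lapply(groups, function(g)
    g$metric[order(-g$score, g$metric)])
  mean_rank_order <- names(mean_ranks)[order(mean_ranks, names(mean_ranks))]
  ce <- ce_rank_aggregate(orders, ce_config,
                          initial_candidates = list(mean_rank_order))

  profiles <- profile_matrix(best)
  k_eff <- min(cluster_k, nrow(unique(profiles)))
  if (k_eff < cluster_k)
    message("reducing cluster_k from ", cluster_k, " to ", k_eff,
            " (only ", k_eff, " distinct metric profiles)")
  clusters <- cluster_profiles(profiles, k = k_eff, restarts = restarts,
                               seed = ce_config$seed,
                               standardize = standardize)
  metrics <- names(mean_ranks)
  out <- data.frame(
    metric = metrics,
    mean_rank = as.numeric(mean_ranks),
    rank_ave = as.integer(rank(mean_ranks, ties.method = "min")),
    rank_ce = match(metrics, ce$order),
    cluster = as.integer(clusters$assignment[metrics]),
    stringsAsFactors = FALSE)
  out <- out[order(out$rank_ave, out$metric), ]
  rownames(out) <- NULL
  attr(out, "ce_objective") <- ce$objective
  objective <- .kendall_objective_fn(orders, sort(metrics),
                                     rep(1, length(orders)))
  attr(out, "mean_rank_objective") <- objective(mean_rank_order)
  attr(out, "clusters") <- clusters
  class(out) <- c("metric_ranking", class(out))
  out
}
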