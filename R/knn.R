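# Metric-pluggable k-nearest-neighbor classifier and the four performance
# measures (precision, recall, F1, accuracy) computed from one-vs-rest
# confusion counts.

#' Construct a labeled dataset
#'
#' Bundles a numeric feature matrix with one class label per row. All values
#' must be finite and at least two distinct labels must be present.
#'
#' @param features A numeric matrix (or coercible data frame), rows =
#'   samples, columns = features.
#' @param labels A vector of class labels, one per row.
#' @param name Identifier for the dataset (used in score tables).
#' @return An object of class `"labeled_dataset"`.
#' @export
labeled_dataset <- function(features, labels, name = "dataset") {
  features <- as.matrix(features)
  if (!is.numeric(features))
    stop("'features' must be numeric", call. = FALSE)
  if (any(!is.finite(features)))
    stop("'features' contains missing or non-finite values", call. = FALSE)
  labels <- as.character(labels)
  if (nrow(features) != length(labels))
    stop("number of rows in 'features' (", nrow(features),
         ") != number of labels (", length(labels), ")", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("a labeled dataset needs at least 2 distinct classes", call. = FALSE)
  structure(list(features = features, labels = labels, name = name),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> '", x$name, "': ", nrow(x$features), " samples x ",
      ncol(x$features), " features, ", length(unique(x$labels)),
      " classes\n", sep = "")
  print(table(class = x$labels))
  invisible(x)
}

# Distances from one query to every training row.
.dist_to_all <- function(features, query, fn) {
  vapply(seq_len(nrow(features)),
         function(i) fn(features[i, ], query), numeric(1))
}

# Majority vote among the k nearest neighbours. Vote ties are broken by the
# smallest summed distance of the tied classes' neighbours (nearest_sum) or
# by label sort order; a residual nearest_sum tie falls back to label order.
.vote <- function(labels_k, dist_k, tie_policy) {
  counts <- table(labels_k)
  winners <- names(counts)[counts == max(counts)]
  if (length(winners) == 1L) return(winners)
  if (tie_policy == "nearest_sum") {
    sums <- vapply(winners,
                   function(cl) sum(dist_k[labels_k == cl]), numeric(1))
    winners <- winners[sums == min(sums)]
  }
  sort(winners)[1L]
}

#' Classify a query with k nearest neighbors under a chosen metric
#'
#' Finds the `k` training rows closest to `query` under `metric` and returns
#' the majority label. Distance ties at the k-th rank are broken by training
#' row index (first rows win); vote ties are broken per `tie_policy`.
#'
#' @param train A [labeled_dataset()].
#' @param query A numeric feature vector of matching length.
#' @param k Number of neighbors, `1 <= k <=` number of training rows.
#' @param metric A `"metric_spec"` from [get_metric()], or a metric name /
#'   configuration string (passed to [parse_metric()]).
#' @param tie_policy `"nearest_sum"` (default): among vote-tied classes pick
#'   the one whose neighbors have the smallest summed distance;
#'   `"label_order"`: pick the first tied label in sort order.
#' @return The predicted class label (character scalar).
#' @examples
#' d <- labeled_dataset(rbind(c(0, 0), c(10, 10)), c("A", "B"))
#' knn_predict(d, c(1, 1), k = 1, metric = "euclidean")  # "A"
#' @export
knn_predict <- function(train, query, k, metric = "euclidean",
                        tie_policy = c("nearest_sum", "label_order")) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(inherits(train, "labeled_dataset"))
  if (is.character(metric)) metric <- parse_metric(metric)
  n <- nrow(train$features)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k > n ||
      k != floor(k))
    stop("'k' must be an integer in [1, ", n, "]", call. = FALSE)
  d <- .dist_to_all(train$features, query, metric$fn)
  ord <- order(d, seq_along(d))  # stable: index breaks distance ties
  idx <- ord[seq_len(k)]
  .vote(train$labels[idx], d[idx], tie_policy)
}

#' One-vs-rest confusion counts
#'
#' For every observed class, tallies true positives (TP), true negatives
#' (TN), false positives (FP) and false negatives (FN), treating that class
#' as the positive set and all other classes as the negative set. Each
#' class's four counts sum to the number of evaluated samples.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @return A data frame of class `"confusion_counts"` with columns `class`,
#'   `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("'y_true' and 'y_pred' have different lengths", call. = FALSE)
  if (length(y_true) < 1L)
    stop("need at least one sample", call. = FALSE)
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- sort(unique(c(y_true, y_pred)))
  out <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    fp <- sum(y_true != cl & y_pred == cl)
    tn <- sum(y_true != cl & y_pred != cl)
    data.frame(class = cl, TP = tp, TN = tn, FP = fp, FN = fn,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("confusion_counts", class(out))
  attr(out, "n_samples") <- length(y_true)
  out
}

#' Precision, recall, F1 and accuracy from confusion counts
#'
#' Per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and their harmonic
#' mean F1 are computed from one-vs-rest tallies and combined across classes
#' by `averaging`: `"macro"` (default) averages the per-class values with
#' equal class weight; `"micro"` pools the counts before computing the
#' ratios. Accuracy is the overall fraction of correctly classified samples.
#' A class with no positive predictions (`TP + FP == 0`) contributes
#' precision 0, with a warning when `warn = TRUE`.
#'
#' @param counts A `"confusion_counts"` object from [confusion_counts()].
#' @param averaging `"macro"` or `"micro"`.
#' @param warn Warn about classes with undefined precision/recall
#'   (default `TRUE`).
#' @return A named numeric vector with elements `precision`, `recall`, `f1`,
#'   `accuracy`, all in `[0, 1]`.
#' @export
performance_scores <- function(counts, averaging = c("macro", "micro"),
                               warn = TRUE) {
  averaging <- match.arg(averaging)
  if (!inherits(counts, "confusion_counts") || nrow(counts) == 0L)
    stop("'counts' must be a non-empty confusion_counts object",
         call. = FALSE)
  n <- attr(counts, "n_samples")
  if (is.null(n)) n <- counts$TP[1L] + counts$TN[1L] + counts$FP[1L] +
      counts$FN[1L]
  if (averaging == "macro") {
    per <- class_scores(counts, warn = warn)
    prec <- mean(per$precision); rec <- mean(per$recall); f1 <- mean(per$f1)
  } else {
    tp <- sum(counts$TP); fp <- sum(counts$FP); fn <- sum(counts$FN)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  acc <- sum(counts$TP) / n
  c(precision = prec, recall = rec, f1 = f1, accuracy = acc)
}

#' Per-class precision, recall and F1
#'
#' The one-vs-rest measures for each class: precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and F1 (their harmonic mean). A zero denominator yields 0
#' for that measure, with a warning when `warn = TRUE`.
#'
#' @inheritParams performance_scores
#' @return A data frame with columns `class`, `precision`, `recall`, `f1`.
#' @export
class_scores <- function(counts, warn = TRUE) {
  if (!inherits(counts, "confusion_counts") || nrow(counts) == 0L)
    stop("'counts' must be a non-empty confusion_counts object",
         call. = FALSE)
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (warn && any(den == 0))
      warning("undefined ", what, " for class(es) ",
              paste(counts$class[den == 0], collapse = ", "), "; using 0",
              call. = FALSE)
    out
  }
  prec <- safe_div(counts$TP, counts$TP + counts$FP, "precision")
  rec <- safe_div(counts$TP, counts$TP + counts$FN, "recall")
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  data.frame(class = counts$class, precision = prec, recall = rec, f1 = f1,
             stringsAsFactors = FALSE)
}

#' Evaluation protocol for the benchmark loop
#'
#' Defines how a metric is scored on a dataset: a seeded stratified
#' train/test split at `split_fraction`, repeated `repetitions` times, with
#' predictions evaluated for every `k` in `k_values` and the four
#' performance measures averaged over repetitions.
#'
#' @param k_values Positive integers; the neighborhood sizes to scan
#'   (default `1:20`).
#' @param split_fraction Fraction of each class placed in the training
#'   partition (default 0.7).
#' @param repetitions Number of repeated splits to average over
#'   (default 10).
#' @param seed Integer seed controlling the splits.
#' @param averaging `"macro"` or `"micro"` multiclass averaging.
#' @return An object of class `"eval_protocol"`.
#' @export
eval_protocol <- function(k_values = 1:20, split_fraction = 0.7,
                          repetitions = 10, seed = 1,
                          averaging = c("macro", "micro")) {
  averaging <- match.arg(averaging)
  if (!is.numeric(k_values) || length(k_values) < 1L ||
      any(k_values < 1 | k_values != floor(k_values)))
    stop("'k_values' must be positive integers", call. = FALSE)
  if (!is.numeric(split_fraction) || length(split_fraction) != 1L ||
      split_fraction <= 0 || split_fraction >= 1)
    stop("'split_fraction' must be in (0, 1)", call. = FALSE)
  if (!is.numeric(repetitions) || repetitions < 1)
    stop("'repetitions' must be >= 1", call. = FALSE)
  structure(list(k_values = sort(unique(as.integer(k_values))),
                 split_fraction = split_fraction,
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed),
                 averaging = averaging),
            class = "eval_protocol")
}

# Stratified training indices: per class, round(fraction * n_c) rows,
# clamped so both partitions keep at least one member of every class.
.stratified_split <- function(labels, fraction) {
  idx_train <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 2L)
      stop("class '", cl, "' has fewer than 2 members; ",
           "cannot stratify into train and test", call. = FALSE)
    n_tr <- min(max(round(fraction * length(idx)), 1L), length(idx) - 1L)
    idx_train <- c(idx_train, sample(idx, n_tr))
  }
  sort(idx_train)
}

# Evaluate RNG-dependent code under a fixed seed, restoring the caller's
# RNG state afterwards so package functions do not disturb user simulations.
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Score one metric on one dataset over a range of k
#'
#' Runs the repeated stratified-split protocol: for each repetition the data
#' are split into training and test partitions, distances from every test
#' row to every training row are computed once, and for each `k` in the
#' protocol the four performance measures are derived from the test
#' predictions. Scores are averaged over repetitions.
#'
#' Metrics flagged `requires_nonnegative` (Bhattacharyya, Bray-Curtis,
#' Soergel, Fisher) are not defined or not stable on negative features; when
#' such a metric meets data containing negatives, every row is first mapped
#' to the probability simplex with [simplex_project()].
#'
#' @param data A [labeled_dataset()].
#' @param metric A `"metric_spec"`, metric name, or configuration string.
#' @param protocol An [eval_protocol()].
#' @param tie_policy Vote tie policy, see [knn_predict()].
#' @return A data frame of class `"metric_scores"` with columns
#'   `performance` (precision/recall/f1/accuracy), `k` and `score`, plus a
#'   `metric` attribute.
#' @export
evaluate_metric_on_dataset <- function(data, metric,
                                       protocol = eval_protocol(),
                                       tie_policy = "nearest_sum") {
  stopifnot(inherits(data, "labeled_dataset"),
            inherits(protocol, "eval_protocol"))
  if (is.character(metric)) metric <- parse_metric(metric)
  features <- data$features
  labels <- data$labels
  if (metric$requires_nonnegative && any(features < 0))
    features <- t(apply(features, 1, simplex_project))
  n <- nrow(features)
  n_train_min <- sum(vapply(unique(labels), function(cl) {
    nc <- sum(labels == cl)
    min(max(round(protocol$split_fraction * nc), 1L), nc - 1L)
  }, numeric(1)))
  if (max(protocol$k_values) > n_train_min)
    stop("max(k_values) = ", max(protocol$k_values),
         " exceeds the training partition size (", n_train_min, ")",
         call. = FALSE)
  measures <- c("precision", "recall", "f1", "accuracy")
  acc <- matrix(0, nrow = length(measures), ncol = length(protocol$k_values),
                dimnames = list(measures, protocol$k_values))
  .with_seed(protocol$seed, {
    for (rep in seq_len(protocol$repetitions)) {
      tr <- .stratified_split(labels, protocol$split_fraction)
      te <- setdiff(seq_len(n), tr)
      ftr <- features[tr, , drop = FALSE]
      ltr <- labels[tr]
      d_mat <- t(vapply(te, function(i)
        .dist_to_all(ftr, features[i, ], metric$fn),
        numeric(length(tr))))
      ords <- lapply(seq_len(nrow(d_mat)), function(i)
        order(d_mat[i, ], seq_len(ncol(d_mat))))
      for (ki in seq_along(protocol$k_values)) {
        k <- protocol$k_values[ki]
        preds <- vapply(seq_along(te), function(i) {
          idx <- ords[[i]][seq_len(k)]
          .vote(ltr[idx], d_mat[i, idx], tie_policy)
        }, character(1))
        sc <- performance_scores(confusion_counts(labels[te], preds),
                                 averaging = protocol$averaging,
                                 warn = FALSE)
        acc[, ki] <- acc[, ki] + sc[measures]
      }
    }
  })
  acc <- acc / protocol$repetitions
  out <- data.frame(
    performance = rep(measures, times = length(protocol$k_values)),
    k = rep(protocol$k_values, each = length(measures)),
    score = as.vector(acc),
    stringsAsFactors = FALSE)
  attr(out, "metric") <- metric$name
  class(out) <- c("metric_scores", class(out))
  out
}

#' Run the full benchmark grid
#'
#' Evaluates every metric on every dataset under the given protocol(s) and
#' assembles the resulting scores into a [score_tensor()] indexed by metric,
#' performance measure, experiment (dataset name) and `k`. All metrics see
#' identical splits on a given dataset because the protocol seed is reset
#' per evaluation.
#'
#' @param datasets A list of [labeled_dataset()] objects.
#' @param metrics Character vector of metric names/configuration strings, or
#'   a list of `"metric_spec"` objects (default: the 12 benchmark measures).
#' @param protocol A single [eval_protocol()] applied to every dataset, or a
#'   named list with one protocol per dataset (e.g. to shorten the `k` range
#'   on a small dataset).
#' @param tie_policy Vote tie policy, see [knn_predict()].
#' @param verbose Print a progress line per (dataset, metric) pair.
#' @return A `"score_tensor"` data frame (see [score_tensor()]).
#' @export
run_benchmark <- function(datasets, metrics = default_metric_set(),
                          protocol = eval_protocol(),
                          tie_policy = "nearest_sum", verbose = FALSE) {
  if (inherits(datasets, "labeled_dataset")) datasets <- list(datasets)
  specs <- lapply(metrics, function(m)
    if (is.character(m)) parse_metric(m) else m)
  metric_ids <- vapply(metrics, function(m)
    if (is.character(m)) m else m$name, character(1))
  rows <- list()
  for (ds in datasets) {
    proto <- if (inherits(protocol, "eval_protocol")) protocol
             else protocol[[ds$name]]
    if (is.null(proto))
      stop("no protocol supplied for dataset '", ds$name, "'", call. = FALSE)
    for (mi in seq_along(specs)) {
      if (verbose)
        message("evaluating ", metric_ids[mi], " on ", ds$name)
      sc <- evaluate_metric_on_dataset(ds, specs[[mi]], proto, tie_policy)
      sc$metric <- metric_ids[mi]
      sc$experiment <- ds$name
      rows[[length(rows) + 1L]] <- sc[, c("metric", "performance",
                                          "experiment", "k", "score")]
    }
  }
  score_tensor(do.call(rbind, rows))
}
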