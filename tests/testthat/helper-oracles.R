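# Independent oracles and random-input generators shared across tests.

rand_vec <- function(n, nonneg = FALSE) {
  v <- stats::runif(n, -5, 5)
  if (nonneg) abs(v) else v
}

rand_simplex <- function(n) {
  v <- stats::rexp(n)
  v / sum(v)
}

# Brute-force kNN: materializes the full (distance, index, label) table,
# sorts it exhaustively and applies the same vote rules independently.
brute_knn <- function(features, labels, query, k, fn,
                      tie_policy = "nearest_sum") {
  d <- apply(features, 1, function(row) fn(row, query))
  tab <- data.frame(i = seq_along(d), d = d, lab = labels,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$d, tab$i), ]
  top <- tab[seq_len(k), ]
  counts <- table(top$lab)
  winners <- names(counts)[counts == max(counts)]
  if (length(winners) > 1L && tie_policy == "nearest_sum") {
    sums <- sapply(winners, function(cl) sum(top$d[top$lab == cl]))
    winners <- winners[sums == min(sums)]
  }
  sort(winners)[1L]
}

# Pair-counting Kendall distance, written against item positions rather
# than list matching.
naive_kendall <- function(a, b) {
  items <- sort(a)
  pa <- match(items, a)
  pb <- match(items, b)
  m <- length(items)
  s <- 0L
  for (i in seq_len(m - 1L))
    for (j in seq((i + 1L), m))
      if ((pa[i] - pa[j]) * (pb[i] - pb[j]) < 0) s <- s + 1L
  s
}

all_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in all_perms(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], p)
  out
}

# Exhaustive-search minimum of the summed Kendall objective.
exhaustive_consensus_min <- function(lists) {
  min(vapply(all_perms(sort(lists[[1L]])), function(p)
    sum(vapply(lists, function(l) naive_kendall(p, l), numeric(1))),
    numeric(1)))
}

# Cluster partition as a canonical signature (label-permutation invariant).
partition_signature <- function(assignment) {
  groups <- split(names(assignment), assignment)
  groups <- lapply(groups, sort)
  paste(sort(vapply(groups, paste, character(1), collapse = ",")),
        collapse = " | ")
}

# The twelve registry-wrapped benchmark metrics.
benchmark_metric_fns <- function() {
  specs <- lapply(default_metric_set(), get_metric)
  names(specs) <- default_metric_set()
  specs
}
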