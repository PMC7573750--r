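# Best-over-k scores, rankings, Kendall/CE aggregation, profile clustering.

make_tiny_tensor <- function() {
  grid <- expand.grid(metric = c("m1", "m2"),
                      performance = c("accuracy", "f1"),
                      experiment = "e1", k = 1:3,
                      stringsAsFactors = FALSE)
  grid$score <- c(0.5, 0.4, 0.5, 0.4, 0.7, 0.45, 0.7, 0.45, 0.6, 0.5,
                  0.6, 0.5)
  score_tensor(grid)
}

test_that("score tensors are validated for completeness and range", {
  tensor <- make_tiny_tensor()
  expect_s3_class(tensor, "score_tensor")
  expect_error(score_tensor(tensor[-1, ]), "missing")
  bad <- tensor; bad$score[1] <- 1.5
  expect_error(score_tensor(bad), "\\[0, 1\\]")
})

test_that("best_over_k takes the maximum across the k grid", {
  tensor <- make_tiny_tensor()
  expect_equal(best_over_k(tensor, "m1", "accuracy", "e1"), 0.7)
  expect_equal(best_over_k(tensor, "m2", "accuracy", "e1"), 0.5)
  best <- best_over_k(tensor)
  expect_equal(nrow(best), 4)
  expect_equal(best$score[best$metric == "m1" &
                          best$performance == "accuracy"], 0.7)
  expect_error(best_over_k(tensor, "nope", "accuracy", "e1"), "no scores")
  single <- score_tensor(data.frame(metric = "m", performance = "accuracy",
                                    experiment = "e", k = 1, score = 0.4))
  expect_equal(best_over_k(single, "m", "accuracy", "e"), 0.4)
})

test_that("tie-aware ranking follows the chosen policy", {
  s <- c(a = 0.9, b = 0.8, c = 0.8, d = 0.1)
  expect_equal(unname(rank_with_ties(s)), c(1, 2.5, 2.5, 4),
               ignore_attr = TRUE)
  expect_equal(unname(rank_with_ties(s, "min")), c(1, 2, 2, 4),
               ignore_attr = TRUE)
  expect_equal(sort(unname(rank_with_ties(s, "ordinal"))), 1:4,
               ignore_attr = TRUE)
  expect_equal(unname(rank_with_ties(c(a = 1, b = 1, c = 1, d = 1))),
               rep(2.5, 4), ignore_attr = TRUE)
  expect_error(rank_with_ties(c(a = NaN, b = 1)), "NA")
  # average-policy rank sums are m(m+1)/2
  set.seed(21)
  for (rep in 1:50) {
    m <- sample(3:12, 1)
    scores <- stats::setNames(round(runif(m), 1), paste0("i", 1:m))
    expect_equal(sum(rank_with_ties(scores)), m * (m + 1) / 2)
  }
})

test_that("average_rank aligns items across rankings", {
  r1 <- c(a = 1, b = 2, c = 3)
  r2 <- c(c = 1, b = 2, a = 3)
  expect_equal(average_rank(list(r1, r2)), c(a = 2, b = 2, c = 2))
  expect_equal(average_rank(list(r1, r1)), r1)
  expect_error(average_rank(list(r1, c(a = 1, b = 2, d = 3))), "item set")
})

test_that("Kendall distance counts pairwise disagreements and is a metric", {
  expect_equal(kendall_distance(c("A", "B", "C"), c("A", "B", "C")), 0)
  expect_equal(kendall_distance(c("A", "B", "C"), c("C", "B", "A")), 3)
  expect_equal(kendall_distance(c("A", "B", "C"), c("A", "C", "B")), 1)
  expect_error(kendall_distance(c("A", "B"), c("A", "C")), "item set")
  expect_error(kendall_distance(c("A", "A"), c("A", "A")), "duplicates")
  set.seed(22)
  items <- letters[1:6]
  for (rep in 1:100) {
    a <- sample(items); b <- sample(items); c_ <- sample(items)
    expect_equal(kendall_distance(a, b), naive_kendall(a, b))
    expect_equal(kendall_distance(a, b), kendall_distance(b, a))
    expect_lte(kendall_distance(a, c_),
               kendall_distance(a, b) + kendall_distance(b, c_))
    expect_lte(kendall_distance(a, b), 15)  # 6*5/2
  }
})

test_that("CE consensus handles degenerate inputs and improves monotonically", {
  l <- c("x", "y", "z")
  same <- ce_rank_aggregate(list(l, l, l))
  expect_equal(same$order, l)
  expect_equal(same$objective, 0)
  one <- ce_rank_aggregate(list(c("q", "p", "r")))
  expect_equal(one$order, c("q", "p", "r"))
  expect_equal(one$objective, 0)

  set.seed(23)
  lists <- replicate(4, sample(letters[1:6]), simplify = FALSE)
  res <- ce_rank_aggregate(lists, aggregation_config(seed = 5))
  expect_true(all(diff(res$trace) <= 0))  # best objective never worsens
  for (lst in lists)
    expect_lte(res$objective,
               sum(vapply(lists, function(other) naive_kendall(lst, other),
                          numeric(1))))
  expect_error(aggregation_config(rho = 1.5), "rho")
  expect_error(aggregation_config(smoothing = 0), "smoothing")
})

test_that("CE consensus attains the exhaustive optimum on small problems", {
  set.seed(24)
  for (trial in 1:5) {
    lists <- replicate(3, sample(letters[1:5]), simplify = FALSE)
    res <- ce_rank_aggregate(lists, aggregation_config(seed = trial))
    expect_equal(res$objective, exhaustive_consensus_min(lists))
  }
})

test_that("k-means recovers duplicated profile groups exactly", {
  base <- rbind(c(1, 1, 1, 1), c(5, 5, 5, 5), c(9, 1, 9, 1))
  profiles <- base[rep(1:3, each = 3), ] +
    matrix(0, 9, 4)  # exact duplicates
  rownames(profiles) <- paste0("item", 1:9)
  cl <- cluster_profiles(profiles, k = 3, restarts = 10, seed = 1)
  expect_equal(cl$inertia, 0)
  expect_equal(partition_signature(cl$assignment),
               partition_signature(stats::setNames(rep(1:3, each = 3),
                                                   rownames(profiles))))
  expect_error(cluster_profiles(profiles, k = 10), "between 1 and")
})

test_that("more k-means restarts never worsen the inertia", {
  set.seed(26)
  profiles <- matrix(rnorm(40 * 5), 40, 5)
  rownames(profiles) <- paste0("p", 1:40)
  i1 <- cluster_profiles(profiles, k = 5, restarts = 1, seed = 3)$inertia
  i20 <- cluster_profiles(profiles, k = 5, restarts = 20, seed = 3)$inertia
  expect_lte(i20, i1 + 1e-9)
})

test_that("fixture cluster assignment is stable across seeds", {
  m <- paper_best_scores("matrix")
  sigs <- vapply(1:10, function(s)
    partition_signature(cluster_profiles(m, k = 3, restarts = 50,
                                         seed = s)$assignment),
    character(1))
  expect_equal(length(unique(sigs)), 1L)
})

test_that("PCA projection preserves structure of low-rank profiles", {
  set.seed(27)
  # true rank-2 data: inter-point distances survive the 2-D projection
  basis <- matrix(rnorm(2 * 8), 2, 8)
  coords <- matrix(rnorm(10 * 2), 10, 2)
  profiles <- coords %*% basis
  rownames(profiles) <- paste0("r", 1:10)
  proj <- pca_project(profiles, 2)
  d_orig <- as.matrix(dist(profiles))
  d_proj <- as.matrix(dist(proj))
  expect_equal(d_proj, d_orig, tolerance = 1e-8)

  # collinear profiles load only on the first component
  line <- outer(seq(0, 1, length.out = 6), c(1, 2, 3))
  proj_line <- pca_project(line, 2)
  expect_lt(max(abs(proj_line[, 2])), 1e-8)

  # centering: a constant shift leaves the projection unchanged up to sign
  shifted <- profiles + 5
  proj_s <- pca_project(shifted, 2)
  for (j in 1:2)
    expect_true(isTRUE(all.equal(proj_s[, j], proj[, j],
                                 tolerance = 1e-8)) ||
                isTRUE(all.equal(proj_s[, j], -proj[, j],
                                 tolerance = 1e-8)))
  expect_error(pca_project(line[1, , drop = FALSE], 2), "at least 2")
})

test_that("rank_metrics builds a consensus table from best scores", {
  fx <- paper_best_scores()
  r <- rank_metrics(fx, ce_config = aggregation_config(seed = 6))
  expect_s3_class(r, "metric_ranking")
  expect_setequal(r$metric, default_metric_set())
  expect_equal(sort(r$rank_ce), 1:12)
  # the CE order is at least as good as the mean-rank order
  expect_lte(attr(r, "ce_objective"), attr(r, "mean_rank_objective"))
  # a metric dominating every experiment ranks first under both schemes
  grid <- expand.grid(metric = c("dom", "m2", "m3"),
                      performance = c("accuracy", "f1"),
                      experiment = c("e1", "e2"), k = 1:2,
                      stringsAsFactors = FALSE)
  grid$score <- ifelse(grid$metric == "dom", 0.95,
                       0.3 + 0.05 * as.integer(factor(grid$metric)))
  rd <- rank_metrics(score_tensor(grid), cluster_k = 2,
                     ce_config = aggregation_config(seed = 7))
  expect_equal(rd$metric[rd$rank_ave == 1], "dom")
  expect_equal(rd$metric[rd$rank_ce == 1], "dom")
})
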