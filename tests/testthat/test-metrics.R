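# Distance functions: worked values, invariants, spectra, simplex geometry.

test_that("hand-evaluated distance values are reproduced", {
  expect_equal(minkowski(c(1, 2, 3), c(1, 2, 3), p = 1), 0)
  expect_equal(minkowski(c(0, 0), c(3, 4), p = 2), 5)
  expect_equal(minkowski(c(1, 5), c(4, 1), p = 1), 7)
  expect_equal(manhattan(c(1, 5), c(4, 1)), 7)
  expect_equal(euclidean(c(0, 0), c(3, 4)), 5)

  expect_equal(chebyshev(c(1, 5), c(4, 1)), 4)
  expect_equal(chebyshev(2, 7), 5)  # 1-D collapse to |x - y|

  expect_equal(canberra(c(0, 0), c(0, 0)), 0)  # 0/0 terms contribute 0
  expect_equal(canberra(c(1, 1), c(1, 3)), 0.5)
  expect_equal(canberra(rep(1, 7), rep(-1, 7)), 7)  # each term 2/2

  expect_equal(hamming(c(1, 2, 3), c(1, 0, 3)), 1)
  expect_equal(hamming(c(1, 2), c(1, 2)), 0)
  expect_equal(hamming(1:4, 5:8), 4)

  expect_equal(bhattacharyya(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(bhattacharyya(c(1, 0), c(0, 1)), Inf)
  expect_equal(bhattacharyya(c(0.5, 0.5), c(0.9, 0.1)),
               -log(sqrt(0.45) + sqrt(0.05)), tolerance = 1e-12)

  expect_equal(bray_curtis(c(1, 1), c(3, 1)), 1 / 3)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)

  expect_equal(clark(c(1, 3), c(3, 1)), sqrt(0.5), tolerance = 1e-12)
  expect_equal(clark(1, -1), 1)

  expect_equal(soergel(c(1, 3), c(2, 1)), 0.6)
  expect_equal(soergel(c(1, 0), c(0, 1)), 1)

  expect_equal(hassanat(c(5, 5), c(5, 5)), 0)
  expect_equal(hassanat(1, 3), 0.5)
  expect_equal(hassanat(c(1, -1), c(3, 1)), 0.5 + 2 / 3, tolerance = 1e-12)
})

test_that("distance functions reject malformed input", {
  for (spec in benchmark_metric_fns())
    expect_error(spec$fn(c(1, 2), c(1, 2, 3)), "length")
  expect_error(minkowski(c(1, 2), c(1, 2), p = -1), "positive")
  expect_error(minkowski(c(1, 2), c(1, 2), p = 0), "positive")
  expect_error(bhattacharyya(c(-1, 1), c(1, 1)), "non-negative|>= 0")
  expect_error(bray_curtis(c(1, -1), c(-1, 1)), "undefined")
  expect_error(soergel(c(0, 0), c(0, 0)), "undefined")
})

test_that("symmetry, identity and non-negativity hold across the registry", {
  set.seed(42)
  specs <- benchmark_metric_fns()
  for (rep in 1:100) {
    n <- sample(c(1, 2, 9), 1)
    for (nm in names(specs)) {
      nonneg <- specs[[nm]]$requires_nonnegative
      x <- rand_vec(n, nonneg)
      y <- rand_vec(n, nonneg)
      d_xy <- specs[[nm]]$fn(x, y)
      d_yx <- specs[[nm]]$fn(y, x)
      expect_equal(d_xy, d_yx, tolerance = 1e-12)
      if (nm == "bhattacharyya") {
        # non-negative only on its proper domain (the simplex); on
        # unnormalized input the self-distance is exactly -ln(sum(x))
        expect_gte(specs[[nm]]$fn(rand_simplex(n), rand_simplex(n)), 0)
        expect_equal(specs[[nm]]$fn(x, x), -log(sum(x)), tolerance = 1e-12)
      } else {
        expect_gte(d_xy, 0)  # non-negative inputs used where required
        expect_equal(specs[[nm]]$fn(x, x), 0, tolerance = 1e-12)
      }
    }
  }
})

test_that("bounded measures respect their ranges", {
  set.seed(7)
  for (rep in 1:200) {
    n <- sample(c(2, 9, 15), 1)
    x <- rand_vec(n, nonneg = TRUE)
    y <- rand_vec(n, nonneg = TRUE)
    expect_lte(bray_curtis(x, y), 1)
    expect_lte(soergel(x, y), 1)
    expect_lte(canberra(x, y), n)
    expect_lte(clark(x, y), sqrt(n))
    expect_lt(hassanat(x, y), n)  # each term < 1
    expect_lte(chebyshev(x, y), manhattan(x, y))
    f <- fisher(rand_simplex(n), rand_simplex(n))
    expect_gte(f, 0); expect_lte(f, pi / 2)
  }
})

test_that("sampled triangle inequality holds for the true metrics", {
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(c(2, 9), 1)
    x <- rand_vec(n); y <- rand_vec(n); z <- rand_vec(n)
    for (fn in list(manhattan, euclidean, chebyshev,
                    function(a, b) sobolev(a, b)))
      expect_lte(fn(x, z), fn(x, y) + fn(y, z) + 1e-9)
    xs <- abs(x); ys <- abs(y); zs <- abs(z)
    expect_lte(soergel(xs, zs), soergel(xs, ys) + soergel(ys, zs) + 1e-9)
  }
})

test_that("the DFT matches its two-point closed form and spectral basics", {
  s <- dft(c(1, 0))
  expect_equal(s$coefficients, complex(real = c(1, 1)), tolerance = 1e-12)
  expect_equal(s$frequencies, c(0, pi))
  a <- 2.5; b <- -1.25
  s2 <- dft(c(a, b))
  expect_equal(Re(s2$coefficients), c(a + b, a - b), tolerance = 1e-12)
  z <- dft(rep(0, 8))
  expect_true(all(Mod(z$coefficients) == 0))
  v <- rand_vec(17)
  expect_equal(Re(dft(v)$coefficients[1]), sum(v), tolerance = 1e-10)
  expect_error(dft(numeric(0)), "length")
})

test_that("Sobolev distance matches its spectral definition and dialects", {
  expect_equal(sobolev(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(sobolev(c(1, 0), c(0, 0)), sqrt(2 + pi), tolerance = 1e-12)
  # k = 0 (full dialect) collapses to Parseval: sqrt(N) * Euclidean
  set.seed(3)
  for (n in c(2, 9, 55)) {
    x <- rand_vec(n); y <- rand_vec(n)
    expect_equal(sobolev(x, y, k = 0), sqrt(n) * euclidean(x, y),
                 tolerance = 1e-9)
  }
  # literal dialect drops the j = 0 (mean) coefficient
  expect_equal(sobolev(c(1, 1), c(0, 0), k = 0, dialect = "literal"), 0)
  expect_gt(sobolev(c(1, 1), c(0, 0), k = 0), 0)
  expect_error(sobolev(c(1, 2), c(1, 2), k = -1), "integer")
})

test_that("simplex projection shifts, normalizes and rejects degenerate input", {
  expect_equal(simplex_project(c(2, 2)), c(0.5, 0.5))
  expect_equal(simplex_project(c(-1, 1)), c(0, 1))
  expect_error(simplex_project(c(0, 0)), "degenerate")
  expect_error(simplex_project(c(-3, -3)), "degenerate")
  set.seed(5)
  for (rep in 1:50) {
    p <- simplex_project(rand_vec(sample(2:12, 1)))
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("Fisher distance equals the sphere-embedding arc length", {
  expect_equal(fisher(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(fisher(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(fisher(c(0.25, 0.75), c(0.75, 0.25)), pi / 6,
               tolerance = 1e-12)
  set.seed(9)
  for (rep in 1:100) {
    n <- sample(2:10, 1)
    x <- rand_simplex(n); y <- rand_simplex(n)
    u <- sqrt(x); v <- sqrt(y)  # unit-sphere embedding
    expect_equal(fisher(x, y), acos(min(sum(u * v), 1)), tolerance = 1e-12)
  }
  expect_error(fisher(c(0.5, 0.6), c(0.5, 0.5)), "simplex")
  expect_error(fisher(c(-0.5, 1.5), c(0.5, 0.5)), "simplex")
})

test_that("the metric registry validates names and parameters", {
  m <- get_metric("manhattan")
  expect_equal(m$fn(c(1, 5), c(4, 1)), 7)
  expect_false(m$requires_nonnegative)

  s <- get_metric("sobolev")
  expect_equal(s$parameters$k, 1)
  expect_equal(s$parameters$dialect, "full")
  expect_true(s$is_true_metric)
  expect_false(get_metric("sobolev", dialect = "literal")$is_true_metric)

  expect_error(get_metric("minkowski", p = -1), "positive")
  expect_error(get_metric("mahalanobis"), "unknown metric")
  expect_error(get_metric("sobolev", q = 2), "unknown parameter")

  # fisher's registry wrapper accepts raw (even negative) features
  f <- get_metric("fisher")
  expect_equal(f$fn(c(-1, 1), c(-1, 1)), 0)
  expect_equal(f$fn(c(2, 2), c(0, 4)), fisher(c(0.5, 0.5), c(0, 1)))

  p3 <- parse_metric("minkowski:p=3")
  expect_equal(p3$parameters$p, 3)
  expect_equal(p3$fn(c(0, 0), c(1, 1)), 2^(1 / 3))
  sl <- parse_metric("sobolev:k=2,dialect=literal")
  expect_equal(sl$parameters$k, 2)
  expect_equal(sl$parameters$dialect, "literal")
  expect_error(parse_metric("minkowski:p"), "malformed")
  expect_setequal(default_metric_set(),
                  setdiff(list_metrics(), "minkowski"))
})
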