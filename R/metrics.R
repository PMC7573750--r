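# Distance measures between numeric feature vectors.
#
# All functions take two equal-length numeric vectors and return a scalar
# dissimilarity. Inputs are expected to be finite; length mismatches raise an
# error. Conventions for degenerate terms (0/0 in Canberra/Clark, disjoint
# support in Bhattacharyya) are documented per function.

.check_pair <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y))
    stop("feature vectors must be numeric", call. = FALSE)
  if (length(x) != length(y))
    stop("feature vectors have different lengths (", length(x), " vs ",
         length(y), ")", call. = FALSE)
  if (length(x) < 1L)
    stop("feature vectors must have length >= 1", call. = FALSE)
  invisible(TRUE)
}

#' Minkowski distance
#'
#' The Minkowski family \eqn{d_p(x,y) = (\sum_i |x_i-y_i|^p)^{1/p}} for a
#' positive order `p`. `p = 1` gives the Manhattan distance, `p = 2` the
#' Euclidean distance; the Chebyshev distance is the `p = Inf` limit (see
#' [chebyshev()]).
#'
#' @param x,y Numeric vectors of equal length.
#' @param p Positive order of the distance (default 2).
#' @return A non-negative scalar.
#' @seealso [euclidean()], [manhattan()], [chebyshev()]
#' @examples
#' minkowski(c(0, 0), c(3, 4), p = 2)  # 5
#' @export
minkowski <- function(x, y, p = 2) {
  .check_pair(x, y)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0)
    stop("'p' must be a single positive number", call. = FALSE)
  sum(abs(x - y)^p)^(1 / p)
}

#' Euclidean distance
#'
#' @inheritParams minkowski
#' @return A non-negative scalar.
#' @export
euclidean <- function(x, y) {
  .check_pair(x, y)
  sqrt(sum((x - y)^2))
}

#' Manhattan (city-block) distance
#'
#' @inheritParams minkowski
#' @return A non-negative scalar.
#' @export
manhattan <- function(x, y) {
  .check_pair(x, y)
  sum(abs(x - y))
}

#' Chebyshev (maximum value) distance
#'
#' \eqn{d(x,y) = \max_i |x_i - y_i|}, the limit of the Minkowski family as
#' the order goes to infinity. Also known as the chessboard or Lagrange
#' distance.
#'
#' @inheritParams minkowski
#' @return A non-negative scalar, never larger than [manhattan()].
#' @export
chebyshev <- function(x, y) {
  .check_pair(x, y)
  max(abs(x - y))
}

#' Canberra distance
#'
#' A weighted Manhattan distance,
#' \eqn{\sum_i |x_i-y_i| / (|x_i|+|y_i|)}. Terms where both entries are zero
#' (a 0/0) contribute 0, so identical vectors are at distance 0. The result
#' is at most the vector length.
#'
#' @inheritParams minkowski
#' @return A non-negative scalar in `[0, length(x)]`.
#' @export
canberra <- function(x, y) {
  .check_pair(x, y)
  num <- abs(x - y)
  den <- abs(x) + abs(y)
  ok <- den > 0
  sum(num[ok] / den[ok])
}

#' Hamming distance
#'
#' The number of positions where the two vectors differ, using exact
#' inequality of the stored values (no tolerance). Mainly meaningful for
#' nominal or integer-valued data; on continuous data almost every position
#' differs.
#'
#' @inheritParams minkowski
#' @return An integer in `[0, length(x)]`.
#' @export
hamming <- function(x, y) {
  .check_pair(x, y)
  sum(x != y)
}

#' Bhattacharyya distance
#'
#' \eqn{-\ln \sum_i \sqrt{x_i y_i}}, a dissimilarity between probability
#' distributions. Implemented exactly in that form: for unnormalized
#' non-negative input the value can be negative, and inputs with any
#' negative product `x[i]*y[i]` are rejected. Disjoint support (the sum is
#' zero) returns `Inf` rather than an error so that nearest-neighbour
#' rankings still work: such a point is simply maximally far. For vectors on
#' the probability simplex the value is `>= 0` and is 0 iff `x == y`; see
#' [simplex_project()].
#'
#' @inheritParams minkowski
#' @return A scalar, possibly negative for unnormalized input; `Inf` for
#'   disjoint support.
#' @export
bhattacharyya <- function(x, y) {
  .check_pair(x, y)
  pr <- x * y
  if (any(pr < 0))
    stop("bhattacharyya requires all products x[i]*y[i] >= 0", call. = FALSE)
  s <- sum(sqrt(pr))
  if (s == 0) Inf else -log(s)
}

#' Bray-Curtis (Sorensen) distance
#'
#' \eqn{\sum_i |x_i-y_i| / \sum_i (x_i+y_i)}: a Manhattan distance
#' standardized by the total sum over both vectors. Lies in `[0, 1]` when
#' all entries are non-negative.
#'
#' @inheritParams minkowski
#' @return A scalar; in `[0, 1]` for non-negative input.
#' @export
bray_curtis <- function(x, y) {
  .check_pair(x, y)
  den <- sum(x + y)
  if (den == 0)
    stop("bray_curtis is undefined when sum(x + y) == 0", call. = FALSE)
  sum(abs(x - y)) / den
}

#' Clark distance
#'
#' \eqn{\sqrt{\sum_i ((x_i-y_i)/(|x_i|+|y_i|))^2}}, also known as the
#' coefficient of divergence. Terms with both entries zero contribute 0.
#' The result is at most `sqrt(length(x))`.
#'
#' @inheritParams minkowski
#' @return A non-negative scalar in `[0, sqrt(length(x))]`.
#' @export
clark <- function(x, y) {
  .check_pair(x, y)
  num <- x - y
  den <- abs(x) + abs(y)
  ok <- den > 0
  sqrt(sum((num[ok] / den[ok])^2))
}

#' Soergel (Ruzicka) distance
#'
#' \eqn{\sum_i |x_i-y_i| / \sum_i \max(x_i,y_i)}. The complement of the
#' Jaccard/Tanimoto similarity for binary data; satisfies all metric
#' properties and stays in `[0, 1]` provided all attributes are
#' non-negative.
#'
#' @inheritParams minkowski
#' @return A scalar; in `[0, 1]` for non-negative input.
#' @export
soergel <- function(x, y) {
  .check_pair(x, y)
  den <- sum(pmax(x, y))
  if (den == 0)
    stop("soergel is undefined when sum(pmax(x, y)) == 0", call. = FALSE)
  sum(abs(x - y)) / den
}

#' Hassanat distance
#'
#' A bounded, non-convex distance summing per-dimension terms
#' \deqn{D(a,b) = 1 - \frac{1+\min(a,b)}{1+\max(a,b)} \quad (\min(a,b) \ge 0)}
#' \deqn{D(a,b) = 1 - \frac{1+\min(a,b)+|\min(a,b)|}{1+\max(a,b)+|\min(a,b)|}
#'   \quad (\min(a,b) < 0)}
#' Each term lies in `[0, 1)` and is 0 when the entries are equal, so the
#' total is in `[0, length(x))`. The second branch simplifies to
#' \eqn{1 - 1/(1 + \max - \min)}.
#'
#' @inheritParams minkowski
#' @return A non-negative scalar in `[0, length(x))`.
#' @examples
#' hassanat(c(1, -1), c(3, 1))  # 0.5 + 2/3
#' @export
hassanat <- function(x, y) {
  .check_pair(x, y)
  mn <- pmin(x, y)
  mx <- pmax(x, y)
  term <- ifelse(mn >= 0,
                 1 - (1 + mn) / (1 + mx),
                 1 - 1 / (1 + mx - mn))
  sum(term)
}

#' Discrete Fourier transform of a feature vector
#'
#' Unnormalized forward DFT,
#' \eqn{\hat v(\omega_j) = \sum_{m=0}^{N-1} v_m e^{-i 2\pi j m / N}} for
#' \eqn{j = 0, \dots, N-1} with angular frequencies
#' \eqn{\omega_j = 2\pi j / N}. The coefficient at `j = 0` equals `sum(v)`.
#' Computed with [stats::fft()].
#'
#' @param v A numeric vector of length `N >= 1`.
#' @return An object of class `"dft_spectrum"`: a list with complex
#'   `coefficients` and numeric `frequencies`, both of length `N`.
#' @seealso [sobolev()]
#' @export
dft <- function(v) {
  if (!is.numeric(v) || length(v) < 1L)
    stop("'v' must be a numeric vector of length >= 1", call. = FALSE)
  n <- length(v)
  structure(
    list(coefficients = stats::fft(v),
         frequencies = 2 * pi * (seq_len(n) - 1) / n),
    class = "dft_spectrum")
}

#' @export
print.dft_spectrum <- function(x, ...) {
  cat("<dft_spectrum> length", length(x$coefficients), "\n")
  print(utils::head(data.frame(frequency = x$frequencies,
                               coefficient = x$coefficients), 6L))
  if (length(x$coefficients) > 6L) cat("...\n")
  invisible(x)
}

#' Sobolev distance via the discrete Fourier transform
#'
#' A Sobolev-type metric of degree `k` on discrete signals: with
#' \eqn{\delta = x - y} and \eqn{\hat\delta} its DFT,
#' \deqn{d(x,y) = \sqrt{\sum_j (1+\omega_j)^k \, |\hat\delta(\omega_j)|^2},
#'   \qquad \omega_j = 2\pi j/N.}
#' The frequency weights penalize high-frequency disagreement, emulating the
#' derivative term of the Sobolev norm. Degree `k = 0` reduces, by the
#' Parseval identity for the unnormalized DFT, to
#' `sqrt(N) * euclidean(x, y)`.
#'
#' The sum runs over `j = 0..N-1` (`dialect = "full"`, the default, which
#' keeps Parseval and makes the distance 0 iff `x == y`) or over
#' `j = 1..N-1` (`dialect = "literal"`), which drops the mean coefficient;
#' the literal variant is retained for fidelity studies. Frequencies use the
#' index `j` as-is, without negative-frequency symmetrization, so the weight
#' profile is asymmetric across the spectrum.
#'
#' @inheritParams minkowski
#' @param k Non-negative integer degree (default 1).
#' @param dialect `"full"` (default) or `"literal"`; see Details.
#' @return A non-negative scalar.
#' @examples
#' sobolev(c(1, 0), c(0, 0))           # sqrt(2 + pi)
#' sobolev(c(1, 0), c(0, 0), k = 0)    # sqrt(2) * euclidean
#' @export
sobolev <- function(x, y, k = 1, dialect = c("full", "literal")) {
  .check_pair(x, y)
  dialect <- match.arg(dialect)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0 || k != floor(k))
    stop("'k' must be a single non-negative integer", call. = FALSE)
  delta <- x - y
  n <- length(delta)
  power <- Mod(stats::fft(delta))^2
  omega <- 2 * pi * (seq_len(n) - 1) / n
  idx <- if (dialect == "literal") seq_len(n)[-1L] else seq_len(n)
  if (length(idx) == 0L) return(0)
  sqrt(sum((1 + omega[idx])^k * power[idx]))
}

#' Project a feature vector onto the probability simplex
#'
#' Maps an arbitrary feature vector to a valid probability vector: if any
#' entry is negative, all entries are first shifted by `-min(x)`; the result
#' is then divided by its sum. The output is non-negative and sums to 1.
#' A constant-degenerate input (all entries equal to the minimum after the
#' shift, e.g. the all-zero vector) has a zero sum and is rejected.
#'
#' @param x A numeric vector of length `>= 1`.
#' @return A numeric vector of the same length on the simplex.
#' @seealso [fisher()]
#' @examples
#' simplex_project(c(2, 2))    # c(0.5, 0.5)
#' simplex_project(c(-1, 1))   # c(0, 1)
#' @export
simplex_project <- function(x) {
  if (!is.numeric(x) || length(x) < 1L)
    stop("'x' must be a numeric vector of length >= 1", call. = FALSE)
  if (any(x < 0)) x <- x - min(x)
  s <- sum(x)
  if (s <= 0)
    stop("degenerate input: vector has zero total mass after shifting",
         call. = FALSE)
  x / s
}

#' Fisher information (great-circle) distance on the simplex
#'
#' Geodesic distance induced by the Fisher information metric on the
#' probability simplex. The square-root map \eqn{x \mapsto \sqrt{x}} embeds
#' the simplex in the positive orthant of the unit sphere and pulls back the
#' Euclidean metric of the sphere, so the distance is the great-circle arc
#' length between the embedded points:
#' \deqn{d(x,y) = \arccos\Big(\sum_i \sqrt{x_i y_i}\Big) \in [0, \pi/2].}
#' The arccos argument is clipped to `[0, 1]` to absorb floating-point
#' overshoot (Cauchy-Schwarz guarantees it is at most 1 exactly).
#'
#' Both inputs must already lie on the simplex (non-negative, summing to 1
#' within 1e-9); apply [simplex_project()] first for raw features, as the
#' registry wrapper returned by `get_metric("fisher")` does automatically.
#'
#' @param x,y Probability vectors of equal length.
#' @return A scalar in `[0, pi/2]`.
#' @examples
#' fisher(c(1, 0), c(0, 1))            # pi/2
#' fisher(c(0.25, 0.75), c(0.75, 0.25))  # pi/6
#' @export
fisher <- function(x, y) {
  .check_pair(x, y)
  .check_simplex(x, "x")
  .check_simplex(y, "y")
  arg <- sum(sqrt(x * y))
  acos(min(max(arg, 0), 1))
}

.check_simplex <- function(x, label, tol = 1e-9) {
  if (any(x < 0))
    stop("'", label, "' is not on the simplex: negative entries", call. = FALSE)
  if (abs(sum(x) - 1) > tol)
    stop("'", label, "' is not on the simplex: entries sum to ",
         format(sum(x)), ", not 1", call. = FALSE)
  invisible(TRUE)
}
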