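# Name-keyed registry of distance measures. Each entry carries a factory
# closing over validated parameters plus property flags used by the
# evaluation pipeline (true-metric? requires non-negative input?).

.registry_entry <- function(factory, is_true_metric, requires_nonnegative,
                            defaults = list()) {
  list(factory = factory, is_true_metric = is_true_metric,
       requires_nonnegative = requires_nonnegative, defaults = defaults)
}

.metric_registry <- local({
  reg <- list(
    euclidean = .registry_entry(
      function(params) euclidean, TRUE, FALSE),
    manhattan = .registry_entry(
      function(params) manhattan, TRUE, FALSE),
    minkowski = .registry_entry(
      function(params) {
        p <- params$p
        function(x, y) minkowski(x, y, p = p)
      }, TRUE, FALSE, defaults = list(p = 2)),
    chebyshev = .registry_entry(
      function(params) chebyshev, TRUE, FALSE),
    canberra = .registry_entry(
      function(params) canberra, TRUE, FALSE),
    hamming = .registry_entry(
      function(params) hamming, TRUE, FALSE),
    bhattacharyya = .registry_entry(
      function(params) bhattacharyya, FALSE, TRUE),
    bray_curtis = .registry_entry(
      function(params) bray_curtis, FALSE, TRUE),
    clark = .registry_entry(
      function(params) clark, FALSE, FALSE),
    soergel = .registry_entry(
      function(params) soergel, TRUE, TRUE),
    hassanat = .registry_entry(
      function(params) hassanat, TRUE, FALSE),
    sobolev = .registry_entry(
      function(params) {
        k <- params$k
        dialect <- params$dialect
        function(x, y) sobolev(x, y, k = k, dialect = dialect)
      }, TRUE, FALSE, defaults = list(k = 1, dialect = "full")),
    fisher = .registry_entry(
      function(params) {
        function(x, y) fisher(simplex_project(x), simplex_project(y))
      }, TRUE, TRUE)
  )
  reg
})

.validate_metric_params <- function(name, params) {
  entry <- .metric_registry[[name]]
  unknown <- setdiff(names(params), names(entry$defaults))
  if (length(unknown) > 0)
    stop("unknown parameter(s) for metric '", name, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  params <- utils::modifyList(entry$defaults, params)
  if (name == "minkowski") {
    if (!is.numeric(params$p) || length(params$p) != 1L ||
        is.na(params$p) || params$p <= 0)
      stop("metric 'minkowski' requires a single positive 'p'", call. = FALSE)
  }
  if (name == "sobolev") {
    if (!is.numeric(params$k) || length(params$k) != 1L || is.na(params$k) ||
        params$k < 0 || params$k != floor(params$k))
      stop("metric 'sobolev' requires a non-negative integer 'k'",
           call. = FALSE)
    if (!params$dialect %in% c("full", "literal"))
      stop("metric 'sobolev' dialect must be 'full' or 'literal'",
           call. = FALSE)
  }
  params
}

#' Look up a distance measure by name
#'
#' Returns a validated metric specification whose `fn` field is a two-vector
#' distance function closing over any parameters. The `fisher` entry composes
#' [simplex_project()] on both arguments, so it accepts raw feature vectors.
#'
#' @param name One of `"euclidean"`, `"manhattan"`, `"minkowski"`,
#'   `"chebyshev"`, `"canberra"`, `"hamming"`, `"bhattacharyya"`,
#'   `"bray_curtis"`, `"clark"`, `"soergel"`, `"hassanat"`, `"sobolev"`,
#'   `"fisher"`.
#' @param ... Metric parameters, e.g. `p` for `minkowski`, `k` and `dialect`
#'   for `sobolev`. Alternatively a single named list.
#' @return An object of class `"metric_spec"`: a list with fields `name`,
#'   `fn`, `is_true_metric`, `requires_nonnegative` and `parameters`.
#' @examples
#' m <- get_metric("minkowski", p = 3)
#' m$fn(c(0, 0), c(1, 1))
#' get_metric("sobolev")$parameters
#' @export
get_metric <- function(name, ...) {
  params <- list(...)
  if (length(params) == 1L && is.null(names(params)) && is.list(params[[1L]]))
    params <- params[[1L]]
  if (!is.character(name) || length(name) != 1L)
    stop("'name' must be a single metric name", call. = FALSE)
  if (!name %in% names(.metric_registry))
    stop("unknown metric '", name, "'; available: ",
         paste(names(.metric_registry), collapse = ", "), call. = FALSE)
  entry <- .metric_registry[[name]]
  params <- .validate_metric_params(name, params)
  is_true <- entry$is_true_metric
  if (name == "minkowski" && params$p < 1) is_true <- FALSE
  if (name == "sobolev" && params$dialect == "literal") is_true <- FALSE
  structure(
    list(name = name,
         fn = entry$factory(params),
         is_true_metric = is_true,
         requires_nonnegative = entry$requires_nonnegative,
         parameters = params),
    class = "metric_spec")
}

#' @export
print.metric_spec <- function(x, ...) {
  cat("<metric_spec>", x$name)
  if (length(x$parameters) > 0)
    cat(" (", paste(names(x$parameters), unlist(lapply(x$parameters, format)),
                    sep = "=", collapse = ", "), ")", sep = "")
  cat("\n  true metric:", x$is_true_metric,
      "| requires non-negative input:", x$requires_nonnegative, "\n")
  invisible(x)
}

#' List available metric names
#'
#' @return A character vector of registry names.
#' @export
list_metrics <- function() names(.metric_registry)

#' The twelve benchmark distance measures
#'
#' The default metric set evaluated by the benchmark: eight well-established
#' measures (Euclidean, Manhattan, Chebyshev, Canberra, Hamming,
#' Bhattacharyya, Bray-Curtis, Clark), two more recent ones (Soergel,
#' Hassanat) and the two spectral/information-geometric measures (Sobolev
#' with `k = 1`, Fisher).
#'
#' @return A character vector of 12 metric names.
#' @export
default_metric_set <- function() {
  c("fisher", "sobolev", "clark", "bhattacharyya", "soergel", "hassanat",
    "euclidean", "manhattan", "chebyshev", "hamming", "canberra",
    "bray_curtis")
}

#' Parse a metric configuration string
#'
#' Accepts strings of the form `"name"` or `"name:key=value,key=value"`,
#' e.g. `"minkowski:p=3"` or `"sobolev:k=1,dialect=full"`. Numeric-looking
#' values are converted to numbers.
#'
#' @param spec A single character string.
#' @return A `"metric_spec"` object (see [get_metric()]).
#' @export
parse_metric <- function(spec) {
  if (!is.character(spec) || length(spec) != 1L)
    stop("'spec' must be a single string", call. = FALSE)
  parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
  name <- parts[1L]
  params <- list()
  if (length(parts) > 1L) {
    kvs <- strsplit(paste(parts[-1L], collapse = ":"), ",", fixed = TRUE)[[1L]]
    for (kv in kvs) {
      pair <- strsplit(kv, "=", fixed = TRUE)[[1L]]
      if (length(pair) != 2L)
        stop("malformed metric parameter '", kv, "' in '", spec, "'",
             call. = FALSE)
      val <- suppressWarnings(as.numeric(pair[2L]))
      params[[trimws(pair[1L])]] <- if (is.na(val)) trimws(pair[2L]) else val
    }
  }
  get_metric(name, params)
}
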