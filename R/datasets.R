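# Synthetic dataset generators emulating common cancer data-set shapes
# (multiclass float features, small-n integer panels, flattened image-like
# matrices), plus CSV read/write, so the benchmark runs with no downloads.

#' Specification of a synthetic classification dataset
#'
#' @param kind `"gaussian_float"` (class-conditional Gaussians),
#'   `"integer_sparse"` (rounded, range-clipped Gaussians) or `"image_like"`
#'   (per-class smooth 2-D template plus pixel noise, flattened row-major;
#'   `n_features` must then be a perfect square).
#' @param n_samples Number of samples (at least `2 * n_classes`).
#' @param n_features Number of features.
#' @param n_classes Number of classes (>= 2).
#' @param separation Distance between any two class means, in units of the
#'   within-class standard deviation. 0 means indistinguishable classes.
#' @param noise_sd Within-class standard deviation.
#' @param value_range Integer pair; values are clipped to this range
#'   (`integer_sparse` only; default `c(0, 3)`).
#' @param seed Integer seed; generation is deterministic per seed.
#' @return An object of class `"dataset_spec"`.
#' @seealso [generate_dataset()], [preset()]
#' @export
dataset_spec <- function(kind = c("gaussian_float", "integer_sparse",
                                  "image_like"),
                         n_samples, n_features, n_classes = 2,
                         separation = 3, noise_sd = 1,
                         value_range = c(0, 3), seed = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(n_samples) || n_samples < 2 * n_classes)
    stop("'n_samples' must be at least 2 * n_classes", call. = FALSE)
  if (!is.numeric(n_features) || n_features < 1)
    stop("'n_features' must be >= 1", call. = FALSE)
  if (!is.numeric(n_classes) || n_classes < 2)
    stop("'n_classes' must be >= 2", call. = FALSE)
  if (!is.numeric(separation) || separation < 0)
    stop("'separation' must be >= 0", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("'noise_sd' must be > 0", call. = FALSE)
  if (kind == "image_like" &&
      sqrt(n_features) != floor(sqrt(n_features)))
    stop("'n_features' must be a perfect square for image_like data",
         call. = FALSE)
  if (kind == "integer_sparse" &&
      (length(value_range) != 2L || value_range[1L] >= value_range[2L]))
    stop("'value_range' must be an increasing integer pair", call. = FALSE)
  if (n_features < n_classes)
    stop("'n_features' must be >= 'n_classes' (orthogonal class directions)",
         call. = FALSE)
  structure(list(kind = kind, n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_classes = as.integer(n_classes),
                 separation = separation, noise_sd = noise_sd,
                 value_range = as.integer(value_range),
                 seed = as.integer(seed)),
            class = "dataset_spec")
}

#' @export
print.dataset_spec <- function(x, ...) {
  cat("<dataset_spec> ", x$kind, ": ", x$n_samples, " x ", x$n_features,
      ", ", x$n_classes, " classes, separation ", x$separation,
      " (noise sd ", x$noise_sd, "), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# g orthonormal directions in f-space (columns): white-noise based, or
# built from a low-frequency cosine basis for image-like data.
.random_orthonormal <- function(f, g) {
  qr.Q(qr(matrix(stats::rnorm(f * g), f, g)))[, seq_len(g), drop = FALSE]
}

.smooth_orthonormal <- function(f, g) {
  side <- as.integer(sqrt(f))
  b <- 4L  # low-frequency cosine modes per axis
  i <- seq_len(side) - 0.5
  C <- outer(i, seq_len(b) - 1, function(ii, u) cos(pi * u * ii / side))
  templ <- vapply(seq_len(g), function(cl) {
    A <- matrix(stats::rnorm(b * b), b, b)
    field <- C %*% A %*% t(C)          # side x side smooth random field
    as.vector(t(field))                # row-major flattening
  }, numeric(f))
  qr.Q(qr(templ))[, seq_len(g), drop = FALSE]
}

#' Generate a synthetic labeled dataset
#'
#' Class-balanced (to within one sample) synthetic data matching a
#' [dataset_spec()]. All kinds place the class means on mutually orthogonal
#' directions scaled so that the distance between any two class means equals
#' `separation * noise_sd`, then add isotropic Gaussian noise with SD
#' `noise_sd`:
#'
#' * `gaussian_float`: directions are random (white) unit vectors.
#' * `integer_sparse`: as above, shifted to the middle of `value_range`,
#'   then rounded and clipped to the range.
#' * `image_like`: directions are orthonormalized smooth low-frequency 2-D
#'   cosine fields, so each class has a smooth image template; images are
#'   flattened row-major.
#'
#' Rows are shuffled (within the same seed) so class labels are not blocked
#' by index. Generation is fully deterministic per seed and leaves the
#' caller's RNG state untouched.
#'
#' @param spec A [dataset_spec()].
#' @return A [labeled_dataset()] with labels `"class_1"`, `"class_2"`, ...
#' @examples
#' d <- generate_dataset(dataset_spec("gaussian_float", 40, 5, 2,
#'                                    separation = 4, seed = 7))
#' table(d$labels)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_samples; f <- spec$n_features; g <- spec$n_classes
    counts <- diff(floor(seq(0, n, length.out = g + 1)))
    cls_idx <- rep(seq_len(g), counts)
    dirs <- switch(spec$kind,
                   image_like = .smooth_orthonormal(f, g),
                   .random_orthonormal(f, g))
    radius <- spec$separation * spec$noise_sd / sqrt(2)
    mu <- dirs * radius                       # f x g class means
    center <- if (spec$kind == "integer_sparse")
      mean(spec$value_range) else 0
    X <- matrix(stats::rnorm(n * f, sd = spec$noise_sd), n, f)
    X <- X + t(mu[, cls_idx, drop = FALSE]) + center
    if (spec$kind == "integer_sparse")
      X <- pmin(pmax(round(X), spec$value_range[1L]), spec$value_range[2L])
    perm <- sample.int(n)
    labeled_dataset(X[perm, , drop = FALSE],
                    paste0("class_", cls_idx[perm]),
                    name = paste0("synthetic_", spec$kind))
  })
}

#' Preset dataset shapes
#'
#' Dataset specifications emulating the shapes of four published cancer
#' benchmark sets: `brain_like` (flattened 64x64 MRI-style images, 3
#' classes; sample count scaled from 3064 down to 300 for desk-scale runs —
#' pass `full_size = TRUE` for the original count), `breast_like` (699 x 9
#' float cytology panel, 2 classes), `lung_like` (32 x 55 small-n integer
#' panel, 2 classes, values 0-3) and `prostate_like` (97 x 9 float clinical
#' panel, 2 classes). Class separation defaults to 3 within-class SDs, a
#' moderate overlap giving realistic (imperfect) accuracies.
#'
#' @param name One of `"brain_like"`, `"breast_like"`, `"lung_like"`,
#'   `"prostate_like"`.
#' @param seed Integer seed stored in the spec.
#' @param full_size Use the original sample count for `brain_like`.
#' @return A [dataset_spec()].
#' @export
preset <- function(name = c("brain_like", "breast_like", "lung_like",
                            "prostate_like"),
                   seed = 1, full_size = FALSE) {
  name <- match.arg(name)
  switch(name,
    brain_like = dataset_spec("image_like",
                              n_samples = if (full_size) 3064L else 300L,
                              n_features = 64L * 64L, n_classes = 3,
                              seed = seed),
    breast_like = dataset_spec("gaussian_float", n_samples = 699,
                               n_features = 9, n_classes = 2, seed = seed),
    lung_like = dataset_spec("integer_sparse", n_samples = 32,
                             n_features = 55, n_classes = 2,
                             value_range = c(0, 3), seed = seed),
    prostate_like = dataset_spec("gaussian_float", n_samples = 97,
                                 n_features = 9, n_classes = 2, seed = seed))
}

#' Default k grid for a preset
#'
#' The benchmark scans k from 1 up to 20 on all presets except the small
#' `lung_like` set, where the range is limited to 1 up to 11.
#'
#' @param name A preset name (see [preset()]).
#' @return An integer vector of k values.
#' @export
preset_k_values <- function(name) {
  if (identical(name, "lung_like")) 1:11 else 1:20
}

#' Read a labeled dataset from CSV
#'
#' Expects a header row, numeric feature columns and a label column. Missing
#' or non-numeric feature cells are rejected with the offending row and
#' column named.
#'
#' @param path Path to a CSV file.
#' @param label_col Name of the label column (default `"class"`).
#' @param name Dataset identifier (default: file name without extension).
#' @return A [labeled_dataset()].
#' @export
read_dataset_csv <- function(path, label_col = "class", name = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!label_col %in% names(df))
    stop("parse error in '", path, "': no label column '", label_col, "'",
         call. = FALSE)
  labels <- as.character(df[[label_col]])
  feat <- df[, setdiff(names(df), label_col), drop = FALSE]
  for (col in names(feat)) {
    v <- feat[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop("parse error in '", path, "': non-numeric value ",
           if (is.na(bad)) "" else paste0("'", v[bad], "' at row ", bad, " "),
           "in column '", col, "'", call. = FALSE)
    }
    if (anyNA(v))
      stop("parse error in '", path, "': missing value at row ",
           which(is.na(v))[1L], ", column '", col, "'", call. = FALSE)
  }
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  labeled_dataset(as.matrix(feat), labels, name = name)
}

#' Write a labeled dataset to CSV
#'
#' Feature values are written with full (17 significant digit) precision so
#' that `write_dataset_csv()` followed by [read_dataset_csv()] reproduces
#' the dataset exactly.
#'
#' @param data A [labeled_dataset()].
#' @param path Output path.
#' @param label_col Name for the label column (default `"class"`).
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(data, path, label_col = "class") {
  stopifnot(inherits(data, "labeled_dataset"))
  feat <- data$features
  if (is.null(colnames(feat)))
    colnames(feat) <- paste0("f", seq_len(ncol(feat)))
  out <- as.data.frame(apply(feat, 2, function(v) sprintf("%.17g", v)),
                       stringsAsFactors = FALSE)
  out[[label_col]] <- data$labels
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
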