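#' Canonical variable names
#'
#' The package fixes one ordering for the six model inputs (storage day plus
#' one-hot herb and sample-type indicators) and the sixteen quality responses.
#' All matrices produced or consumed by the package follow these orders.
#'
#' @return Character vector of names.
#' @export
input_names <- function() {
  c("day", "herb_salvia", "herb_thyme", "sample_KC", "sample_KG", "sample_KSFE")
}

#' @rdname input_names
#' @export
response_names <- function() {
  c("DM", "Fat", "Ash", "ProteinsDM", "Proteins", "aw", "pH",
    "TP", "DPPH", "ABTS", "FRAP",
    "Aerobic", "Ecoli", "Lmonocytogenes", "Saureus", "Lactic")
}

#' @rdname input_names
#' @export
response_units <- function() {
  stats::setNames(
    c("%", "%", "%", "%", "%", "unitless", "unitless",
      "mg GAE/g", "uM TE/g", "uM TE/g", "uM TE/g",
      "log CFU/g", "log CFU/g", "log CFU/g", "log CFU/g", "log CFU/g"),
    response_names())
}

#' @rdname input_names
#' @export
herb_levels <- function() c("salvia", "thyme")

#' @rdname input_names
#' @export
sample_levels <- function() c("KC", "KG", "KSFE")

#' Design points of the storage study
#'
#' Validates and builds one or more design points: storage day in `[0, 30]`,
#' herb in `{salvia, thyme}`, sample type in `{KC, KG, KSFE}` (control,
#' ground herb, supercritical-fluid extract).
#'
#' @param day Numeric vector of storage days.
#' @param herb Character vector of herb types.
#' @param sample_type Character vector of cheese sample types.
#' @return A data.frame with columns `day`, `herb`, `sample_type`.
#' @export
design_point <- function(day, herb, sample_type) {
  n <- max(length(day), length(herb), length(sample_type))
  day <- rep_len(as.numeric(day), n)
  herb <- rep_len(as.character(herb), n)
  sample_type <- rep_len(as.character(sample_type), n)
  if (any(!is.finite(day)) || any(day < 0 | day > 30))
    stop("design_point: 'day' must be finite and within [0, 30]")
  bad <- setdiff(unique(herb), herb_levels())
  if (length(bad))
    stop("design_point: unknown 'herb' category: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(sample_type), sample_levels())
  if (length(bad))
    stop("design_point: unknown 'sample_type' category: ",
         paste(bad, collapse = ", "))
  data.frame(day = day, herb = herb, sample_type = sample_type,
             stringsAsFactors = FALSE)
}

#' Full factorial design grid
#'
#' The 2 herbs x 3 sample types x `days` grid of the storage experiment
#' (24 cells with the default four sampling days).
#'
#' @param days Numeric vector of storage days (default `c(0, 10, 20, 30)`).
#' @return Design data.frame, ordered herb-major as in the study layout.
#' @export
design_grid <- function(days = c(0, 10, 20, 30)) {
  g <- expand.grid(day = days, sample_type = sample_levels(),
                   herb = herb_levels(), stringsAsFactors = FALSE)
  # thyme block first, as laid out in the published design table
  g <- g[order(match(g$herb, c("thyme", "salvia")),
               match(g$sample_type, sample_levels()), g$day), ]
  rownames(g) <- NULL
  design_point(g$day, g$herb, g$sample_type)
}

#' Encode design points as model inputs
#'
#' Maps each design point to the fixed 6-vector
#' `[day, herb_salvia, herb_thyme, sample_KC, sample_KG, sample_KSFE]`
#' with one-hot indicators for both category groups (both herb dummies are
#' kept: the published network has six inputs, so no reference level is
#' dropped). The day enters unscaled; standardization is a separate step.
#'
#' @param design A data.frame as returned by [design_point()].
#' @return Numeric matrix, one row per design point, columns [input_names()].
#' @export
encode_design <- function(design) {
  design <- design_point(design$day, design$herb, design$sample_type)
  n <- nrow(design)
  X <- matrix(0, n, 6, dimnames = list(NULL, input_names()))
  X[, "day"] <- design$day
  X[cbind(seq_len(n), 1L + match(design$herb, herb_levels()))] <- 1
  X[cbind(seq_len(n), 3L + match(design$sample_type, sample_levels()))] <- 1
  X
}

#' Read or write a design + response table
#'
#' The interchange format is a plain CSV ("." decimal, UTF-8, header
#' mandatory) with the three design columns (`day`, `herb`, `sample_type`)
#' and the sixteen response columns named as in [response_names()]. Column
#' order in the file is irrelevant; it is normalized to the canonical order
#' on read. Missing or non-numeric cells are rejected.
#'
#' @param path File path.
#' @return `read_response_table`: list with `design` (data.frame) and
#'   `responses` (numeric matrix, canonical column order).
#' @export
read_response_table <- function(path) {
  if (!file.exists(path)) stop("read_response_table: no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("day", "herb", "sample_type")
  miss <- setdiff(c(need, response_names()), names(df))
  if (length(miss))
    stop("read_response_table: missing column(s): ", paste(miss, collapse = ", "))
  dup <- names(df)[duplicated(names(df))]
  if (length(dup))
    stop("read_response_table: duplicated column(s): ", paste(dup, collapse = ", "))
  design <- design_point(df$day, df$herb, df$sample_type)
  Y <- as.matrix(df[, response_names(), drop = FALSE])
  suppressWarnings(storage.mode(Y) <- "double")
  if (any(!is.finite(Y)))
    stop("read_response_table: missing or non-numeric response cells")
  list(design = design, responses = Y)
}

#' @rdname read_response_table
#' @param design Design data.frame.
#' @param responses Response matrix (n x 16).
#' @export
write_response_table <- function(design, responses, path) {
  stopifnot(nrow(design) == nrow(responses))
  responses <- responses[, response_names(), drop = FALSE]
  df <- cbind(design, as.data.frame(responses))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Column standardization
#'
#' Fits per-column centering/scaling parameters: `method = "zscore"` maps to
#' mean 0 / sample SD 1; `method = "minmax"` maps the observed range linearly
#' onto `range` (default `[0.05, 0.95]`, which keeps regression targets
#' strictly inside the open range of a logistic output unit). The transform
#' and its exact inverse are applied with [standardize()] /
#' [destandardize()].
#'
#' @param x Numeric matrix (columns are variables).
#' @param method `"zscore"` or `"minmax"`.
#' @param range Target interval for `"minmax"`.
#' @return An object of class `standardizer`.
#' @export
fit_standardizer <- function(x, method = c("zscore", "minmax"),
                             range = c(0.05, 0.95)) {
  method <- match.arg(method)
  x <- as.matrix(x)
  cn <- colnames(x)
  if (is.null(cn)) cn <- paste0("V", seq_len(ncol(x)))
  rng <- apply(x, 2, function(v) diff(base::range(v)))
  if (any(rng == 0))
    stop("fit_standardizer: constant column(s): ",
         paste(cn[rng == 0], collapse = ", "))
  if (method == "zscore") {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
  } else {
    if (length(range) != 2 || diff(range) <= 0)
      stop("fit_standardizer: 'range' must be an increasing pair")
    lo <- apply(x, 2, min)
    scale <- rng / diff(range)
    center <- lo - range[1] * scale
  }
  structure(list(center = stats::setNames(center, cn),
                 scale = stats::setNames(scale, cn),
                 method = method,
                 range = if (method == "minmax") range else NULL),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param object A `standardizer`.
#' @export
standardize <- function(object, x) {
  stopifnot(inherits(object, "standardizer"))
  x <- as.matrix(x)
  sweep(sweep(x, 2, object$center, "-"), 2, object$scale, "/")
}

#' @rdname fit_standardizer
#' @export
destandardize <- function(object, x) {
  stopifnot(inherits(object, "standardizer"))
  x <- as.matrix(x)
  sweep(sweep(x, 2, object$scale, "*"), 2, object$center, "+")
}

#' @rdname fit_standardizer
#' @param path JSON file path.
#' @export
write_standardizer <- function(object, path) {
  jsonlite::write_json(unclass(object), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname fit_standardizer
#' @export
read_standardizer <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(center = unlist(o$center), scale = unlist(o$scale),
                 method = o$method, range = o$range),
            class = "standardizer")
}

#' Random train/test/validation split
#'
#' Partitions `1:n` into disjoint, exhaustive index sets with the given
#' fractions (default 70/15/15). Test and validation receive the floor of
#' their shares; training receives the remainder (so 24 observations split
#' 18/3/3). Deterministic for a fixed seed.
#'
#' @param n Number of observations (>= 3).
#' @param fractions Length-3 vector (train, test, validation) summing to 1.
#' @param seed Integer RNG seed.
#' @return List with integer index vectors `train`, `test`, `validation`,
#'   plus the `fractions` and `seed` used.
#' @export
split_data <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (n < 3) stop("split_data: need n >= 3")
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9)
    stop("split_data: fractions must sum to 1")
  set.seed(seed)
  p <- sample.int(n)
  n_test <- floor(fractions[2] * n)
  n_val <- floor(fractions[3] * n)
  n_train <- n - n_test - n_val
  if (min(n_train, n_test, n_val) < 0) stop("split_data: degenerate fractions")
  structure(list(train = sort(p[seq_len(n_train)]),
                 test = sort(p[n_train + seq_len(n_test)]),
                 validation = sort(p[n_train + n_test + seq_len(n_val)]),
                 fractions = fractions, seed = seed),
            class = "data_split")
}

#' @rdname split_data
#' @param object A `data_split`.
#' @param path JSON file path.
#' @export
write_split <- function(object, path) {
  jsonlite::write_json(unclass(object), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
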