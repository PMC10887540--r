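#' Yoon's connection-weight relative importance
#'
#' Attributes to each input a signed share of influence on each output from
#' the products of input-to-hidden and hidden-to-output connection weights.
#' For input i and output j the numerator is
#' `N_ij = sum_k W1[i,k] * W2[j,k]` over hidden units k; the default
#' normalization divides by `sum_i |N_ij|`, so for every output the absolute
#' relative importances sum to 100% and each value keeps the sign of its
#' weight-product sum. Biases do not enter the computation: only
#' input-hidden-output connection chains carry attributable signal.
#'
#' `denominator = "signed"` is the literal variant that divides by the
#' signed sum `sum_i N_ij` instead; its values sum to +100% per output but
#' individual magnitudes are unbounded, so it is offered for comparison
#' only.
#'
#' @param weights A [weight_set()].
#' @param denominator `"absolute"` (default, standard form) or `"signed"`.
#' @return Object of class `relative_importance`: matrix outputs x inputs of
#'   signed percentages.
#' @export
yoon_relative_importance <- function(weights,
                                     denominator = c("absolute", "signed")) {
  stopifnot(inherits(weights, "weight_set"))
  denominator <- match.arg(denominator)
  N <- weights$W2 %*% t(weights$W1)     # outputs x inputs
  den <- if (denominator == "absolute") rowSums(abs(N)) else rowSums(N)
  zero <- abs(den) < .Machine$double.eps
  if (any(zero))
    stop("yoon_relative_importance: zero weight-product denominator for ",
         "output(s): ",
         paste(rownames(N)[zero], collapse = ", "))
  RI <- 100 * sweep(N, 1, den, "/")
  structure(RI, class = c("relative_importance", class(RI)))
}

#' Long-form relative-importance table
#'
#' Flattens a `relative_importance` matrix into one record per
#' (output, input) pair; [ri_matrix()] is the inverse.
#'
#' @param ri A [yoon_relative_importance()] result.
#' @return data.frame with columns `output`, `input`, `RI` (percent).
#' @export
ri_table <- function(ri) {
  stopifnot(inherits(ri, "relative_importance"))
  df <- data.frame(output = rep(rownames(ri), times = ncol(ri)),
                   input = rep(colnames(ri), each = nrow(ri)),
                   RI = as.vector(ri), stringsAsFactors = FALSE)
  df
}

#' @rdname ri_table
#' @param df A data.frame as produced by [ri_table()].
#' @export
ri_matrix <- function(df) {
  outs <- unique(df$output); ins <- unique(df$input)
  M <- matrix(NA_real_, length(outs), length(ins),
              dimnames = list(outs, ins))
  M[cbind(match(df$output, outs), match(df$input, ins))] <- df$RI
  structure(M, class = c("relative_importance", class(M)))
}

#' @rdname ri_table
#' @param path CSV file path.
#' @export
write_ri_table <- function(ri, path) {
  utils::write.csv(ri_table(ri), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
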