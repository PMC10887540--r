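## Feed-forward model: Y = f_out(W2 . f_hid(W1' X + B1) + B2)
## W1 is inputs x hidden (rows follow input_names()); W2 is outputs x hidden.

.activations <- list(
  tanh     = list(f = base::tanh,            df = function(a) 1 - a^2),
  logistic = list(f = function(x) 1 / (1 + exp(-x)), df = function(a) a * (1 - a)),
  # negative exponential unit, as in classical MLP toolkits
  exponential = list(f = function(x) exp(-x), df = function(a) -a),
  identity = list(f = identity,              df = function(a) rep(1, length(a)))
)

#' Construct an MLP weight set
#'
#' Bundles the two weight matrices, bias vectors and activation tags of a
#' single-hidden-layer perceptron. `W1` is inputs x hidden (rows named after
#' the inputs), `W2` is outputs x hidden (rows named after the outputs);
#' `B1`/`B2` are the hidden/output biases.
#'
#' @param W1 Numeric matrix, inputs x hidden.
#' @param B1 Numeric vector, length = hidden units.
#' @param W2 Numeric matrix, outputs x hidden.
#' @param B2 Numeric vector, length = outputs.
#' @param hidden,output Activation tags, one of `"tanh"`, `"logistic"`,
#'   `"exponential"`, `"identity"`.
#' @return Object of class `weight_set`.
#' @export
weight_set <- function(W1, B1, W2, B2, hidden = "tanh", output = "logistic") {
  W1 <- as.matrix(W1); W2 <- as.matrix(W2)
  B1 <- as.numeric(B1); B2 <- as.numeric(B2)
  H <- ncol(W1)
  if (H < 1 || H > 64) stop("weight_set: hidden size must be in [1, 64]")
  if (length(B1) != H) stop("weight_set: length(B1) != ncol(W1)")
  if (ncol(W2) != H) stop("weight_set: ncol(W2) != ncol(W1)")
  if (length(B2) != nrow(W2)) stop("weight_set: length(B2) != nrow(W2)")
  if (!hidden %in% names(.activations) || !output %in% names(.activations))
    stop("weight_set: unknown activation tag")
  structure(list(W1 = W1, B1 = B1, W2 = W2, B2 = B2,
                 hidden = hidden, output = output, H = H),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("MLP %d-%d-%d weight set (hidden: %s, output: %s)\n",
              nrow(x$W1), x$H, nrow(x$W2), x$hidden, x$output))
  invisible(x)
}

#' Load the published trained network (MLP 6-10-16)
#'
#' Reads the bundled transcription of the published weight matrices of the
#' cheese-quality network: 6 inputs, 10 tanh hidden units, 16 logistic
#' outputs. Input rows and output rows follow [input_names()] and
#' [response_names()].
#'
#' @return A [weight_set()].
#' @export
load_printed_weights <- function() {
  f1 <- system.file("extdata", "mlp_6_10_16_w1b1.csv", package = "cheesemlp",
                    mustWork = TRUE)
  f2 <- system.file("extdata", "mlp_6_10_16_w2b2.csv", package = "cheesemlp",
                    mustWork = TRUE)
  t1 <- utils::read.csv(f1, stringsAsFactors = FALSE)
  t2 <- utils::read.csv(f2, stringsAsFactors = FALSE)
  if (!identical(t1$input, c(input_names(), "bias")) ||
      !identical(t2$output, response_names()) ||
      ncol(t1) != 11 || ncol(t2) != 12)
    stop("load_printed_weights: fixture dimension mismatch")
  W1 <- as.matrix(t1[seq_len(6), -1, drop = FALSE])
  dimnames(W1) <- list(input_names(), NULL)
  B1 <- as.numeric(t1[7, -1])
  W2 <- as.matrix(t2[, paste0("h", 1:10)])
  dimnames(W2) <- list(response_names(), NULL)
  B2 <- as.numeric(t2$bias)
  weight_set(W1, B1, W2, B2, hidden = "tanh", output = "logistic")
}

#' Forward pass of the MLP
#'
#' Evaluates `y = f_out(W2 . f_hid(W1' x + B1) + B2)` for one input vector or
#' a matrix of row inputs. Inputs must already be on model scale (encoded
#' design, standardized if the network was trained on standardized inputs).
#'
#' @param weights A [weight_set()].
#' @param x Numeric vector (length = inputs) or matrix (n x inputs).
#' @return Numeric matrix n x outputs (named columns when `W2` has rownames).
#' @export
mlp_forward <- function(weights, x) {
  stopifnot(inherits(weights, "weight_set"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != nrow(weights$W1))
    stop("mlp_forward: input dimension mismatch: got ", ncol(x),
         ", expected ", nrow(weights$W1))
  if (any(!is.finite(x))) stop("mlp_forward: non-finite input")
  fh <- .activations[[weights$hidden]]$f
  fo <- .activations[[weights$output]]$f
  A1 <- sweep(x %*% weights$W1, 2, weights$B1, "+")
  Hm <- fh(A1)
  A2 <- sweep(Hm %*% t(weights$W2), 2, weights$B2, "+")
  Y <- fo(A2)
  colnames(Y) <- rownames(weights$W2)
  Y
}

## range attainable by an output activation (open bounds handled by <=/>=)
.activation_range <- function(tag) {
  switch(tag,
         tanh = c(-1, 1), logistic = c(0, 1),
         exponential = c(0, Inf), identity = c(-Inf, Inf))
}

.flatten <- function(ws) c(ws$W1, ws$B1, ws$W2, ws$B2)

.unflatten <- function(theta, d_in, H, d_out, hidden, output) {
  i <- 0L
  W1 <- matrix(theta[i + seq_len(d_in * H)], d_in, H); i <- i + d_in * H
  B1 <- theta[i + seq_len(H)]; i <- i + H
  W2 <- matrix(theta[i + seq_len(d_out * H)], d_out, H); i <- i + d_out * H
  B2 <- theta[i + seq_len(d_out)]
  weight_set(W1, B1, W2, B2, hidden, output)
}

#' Train an MLP by quasi-Newton minimization of summed squared error
#'
#' Fits a single-hidden-layer network to `(X, Y)` by minimizing the
#' sum-of-squares loss `SOS = sum((Y - Yhat)^2)` with BFGS
#' ([stats::optim()]) using analytic gradients (back-propagation). Weights
#' are initialized uniformly in `[-0.5, 0.5]` from the given seed, so a run
#' is fully reproducible. `X` should be standardized and `Y` scaled into the
#' output activation's attainable range (e.g. min-max to `[0.05, 0.95]` for
#' logistic outputs).
#'
#' @param X Input matrix (n x d_in), model scale.
#' @param Y Target matrix (n x d_out), within the output activation's range.
#' @param hidden_units Number of hidden units.
#' @param hidden,output Activation tags.
#' @param seed Integer seed for the random initialization.
#' @param max_iter BFGS iteration budget.
#' @param tol Relative convergence tolerance passed to the optimizer.
#' @return Object of class `mlp_fit`: the fitted `weight_set`, per-evaluation
#'   `loss_history`, `final_loss` (SOS), `converged`, `iterations`, `seed`.
#' @export
mlp_train <- function(X, Y, hidden_units, hidden = "tanh", output = "logistic",
                      seed = 1L, max_iter = 1000L, tol = 1e-8) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("mlp_train: rows(X) != rows(Y)")
  rng <- .activation_range(output)
  if (any(Y < rng[1]) || any(Y > rng[2]))
    stop("mlp_train: Y outside the attainable range of the '", output,
         "' output activation")
  d_in <- ncol(X); d_out <- ncol(Y); H <- as.integer(hidden_units)
  fh <- .activations[[hidden]]; fo <- .activations[[output]]
  n_par <- d_in * H + H + d_out * H + d_out

  hist_env <- new.env(parent = emptyenv())
  hist_env$loss <- numeric(0)

  loss_fn <- function(theta) {
    ws <- .unflatten(theta, d_in, H, d_out, hidden, output)
    A1 <- sweep(X %*% ws$W1, 2, ws$B1, "+")
    Hm <- fh$f(A1)
    A2 <- sweep(Hm %*% t(ws$W2), 2, ws$B2, "+")
    Yh <- fo$f(A2)
    l <- sum((Y - Yh)^2)
    if (!is.finite(l))
      stop("mlp_train: non-finite loss at evaluation ",
           length(hist_env$loss) + 1L)
    hist_env$loss <- c(hist_env$loss, l)
    l
  }
  grad_fn <- function(theta) {
    ws <- .unflatten(theta, d_in, H, d_out, hidden, output)
    A1 <- sweep(X %*% ws$W1, 2, ws$B1, "+")
    Hm <- fh$f(A1)
    A2 <- sweep(Hm %*% t(ws$W2), 2, ws$B2, "+")
    Yh <- fo$f(A2)
    D2 <- 2 * (Yh - Y) * fo$df(Yh)          # n x d_out
    dW2 <- t(D2) %*% Hm                      # d_out x H
    dB2 <- colSums(D2)
    D1 <- (D2 %*% ws$W2) * fh$df(Hm)         # n x H
    dW1 <- t(X) %*% D1                       # d_in x H
    dB1 <- colSums(D1)
    c(dW1, dB1, dW2, dB2)
  }

  set.seed(seed)
  theta0 <- stats::runif(n_par, -0.5, 0.5)
  opt <- stats::optim(theta0, fn = loss_fn, gr = grad_fn, method = "BFGS",
                      control = list(maxit = max_iter, reltol = tol))
  ws <- .unflatten(opt$par, d_in, H, d_out, hidden, output)
  rownames(ws$W1) <- colnames(X)
  rownames(ws$W2) <- colnames(Y)
  structure(list(weights = ws,
                 loss_history = hist_env$loss,
                 final_loss = opt$value,
                 converged = opt$convergence == 0L,
                 iterations = length(hist_env$loss),
                 seed = seed),
            class = "mlp_fit")
}

#' @export
print.mlp_fit <- function(x, ...) {
  cat(sprintf("MLP fit: H=%d, final SOS = %.6g, %s after %d evaluations\n",
              x$weights$H, x$final_loss,
              if (x$converged) "converged" else "stopped", x$iterations))
  invisible(x)
}

#' Coefficient of determination per column
#'
#' `1 - SSE/SST` for each response column; used for model selection.
#'
#' @param y_obs,y_hat Matrices of equal shape.
#' @return Numeric vector, one value per column.
#' @export
r_squared <- function(y_obs, y_hat) {
  y_obs <- as.matrix(y_obs); y_hat <- as.matrix(y_hat)
  sse <- colSums((y_obs - y_hat)^2)
  sst <- colSums(sweep(y_obs, 2, colMeans(y_obs), "-")^2)
  1 - sse / sst
}

#' Search hidden-layer sizes and activation pairs
#'
#' Trains candidate networks for every hidden size in `hidden_range` and
#' every activation pair, each from `restarts` random initializations, and
#' selects the best model by mean validation r-squared (ties broken by
#' smaller hidden layer, then lower test SSE). Candidates are scored on a
#' fixed train/test/validation split.
#'
#' @param X,Y Model-scale input and target matrices.
#' @param hidden_range Integer vector of hidden sizes (default `5:10`).
#' @param activations List of `c(hidden, output)` pairs to try.
#' @param restarts Random restarts per candidate (>= 1).
#' @param split A [split_data()] result; built from `seed` when `NULL`.
#' @param seed Base seed: restart `r` of candidate `c` uses a seed derived
#'   deterministically from it.
#' @param max_iter Per-fit BFGS budget.
#' @return List with `table` (one row per candidate: hidden size,
#'   activations, mean train/test/validation r-squared) and `best` (the
#'   winning `mlp_fit`).
#' @export
architecture_search <- function(X, Y, hidden_range = 5:10,
                                activations = list(c("tanh", "logistic")),
                                restarts = 5L, split = NULL, seed = 1L,
                                max_iter = 500L) {
  if (length(hidden_range) == 0) stop("architecture_search: empty hidden_range")
  if (restarts < 1) stop("architecture_search: need restarts >= 1")
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(split)) split <- split_data(nrow(X), seed = seed)
  rows <- list(); best <- NULL; best_key <- NULL
  cand_id <- 0L
  for (H in hidden_range) for (act in activations) {
    cand_id <- cand_id + 1L
    fits <- lapply(seq_len(restarts), function(r)
      mlp_train(X[split$train, , drop = FALSE], Y[split$train, , drop = FALSE],
                H, act[1], act[2],
                seed = (seed * 1000L + cand_id * 100L + r) %% .Machine$integer.max,
                max_iter = max_iter))
    fit <- fits[[which.min(vapply(fits, `[[`, 0, "final_loss"))]]
    r2 <- function(idx) mean(r_squared(Y[idx, , drop = FALSE],
                                       mlp_forward(fit$weights, X[idx, , drop = FALSE])))
    sse_test <- sum((Y[split$test, , drop = FALSE] -
                     mlp_forward(fit$weights, X[split$test, , drop = FALSE]))^2)
    row <- data.frame(hidden = H, act_hidden = act[1], act_output = act[2],
                      r2_train = r2(split$train), r2_test = r2(split$test),
                      r2_validation = r2(split$validation),
                      sse_test = sse_test, final_loss = fit$final_loss)
    rows[[length(rows) + 1L]] <- row
    key <- c(-row$r2_validation, H, sse_test)
    if (is.null(best_key) ||
        key[1] < best_key[1] - 1e-12 ||
        (abs(key[1] - best_key[1]) <= 1e-12 &&
         (key[2] < best_key[2] ||
          (key[2] == best_key[2] && key[3] < best_key[3])))) {
      best <- fit; best_key <- key
    }
  }
  list(table = do.call(rbind, rows), best = best, split = split)
}

#' Read or write a weight set as JSON
#'
#' Serializes the matrices row-major together with input/output names and
#' activation tags, so a weight file is self-describing.
#'
#' @param weights A [weight_set()].
#' @param path JSON file path.
#' @export
write_weight_set <- function(weights, path) {
  stopifnot(inherits(weights, "weight_set"))
  o <- list(inputs = rownames(weights$W1), outputs = rownames(weights$W2),
            hidden_units = weights$H,
            hidden = weights$hidden, output = weights$output,
            W1 = weights$W1, B1 = weights$B1, W2 = weights$W2, B2 = weights$B2)
  jsonlite::write_json(o, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_weight_set
#' @export
read_weight_set <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  W1 <- as.matrix(o$W1); W2 <- as.matrix(o$W2)
  rownames(W1) <- o$inputs; rownames(W2) <- o$outputs
  weight_set(W1, o$B1, W2, o$B2, o$hidden, o$output)
}
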