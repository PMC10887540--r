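# shared fixtures built in code

random_weight_set <- function(seed, d_in = 6, H = 5, d_out = 3,
                              hidden = "tanh", output = "logistic") {
  set.seed(seed)
  weight_set(matrix(rnorm(d_in * H), d_in, H), rnorm(H),
             matrix(rnorm(d_out * H), d_out, H), rnorm(d_out),
             hidden, output)
}

# independent scalar (double-loop) evaluation of the feed-forward map;
# deliberately avoids matrix algebra so it can serve as an oracle
forward_scalar <- function(ws, x) {
  act <- function(tag, v) switch(tag,
    tanh = tanh(v), logistic = 1 / (1 + exp(-v)),
    exponential = exp(-v), identity = v)
  H <- ws$H
  h <- numeric(H)
  for (k in seq_len(H)) {
    s <- ws$B1[k]
    for (i in seq_len(nrow(ws$W1))) s <- s + ws$W1[i, k] * x[i]
    h[k] <- act(ws$hidden, s)
  }
  y <- numeric(nrow(ws$W2))
  for (j in seq_len(nrow(ws$W2))) {
    s <- ws$B2[j]
    for (k in seq_len(H)) s <- s + ws$W2[j, k] * h[k]
    y[j] <- act(ws$output, s)
  }
  y
}

# independent scalar implementation of the connection-weight importance
yoon_scalar <- function(ws, denominator = "absolute") {
  n_in <- nrow(ws$W1); n_out <- nrow(ws$W2)
  RI <- matrix(NA_real_, n_out, n_in)
  for (j in seq_len(n_out)) {
    num <- numeric(n_in)
    for (i in seq_len(n_in)) {
      s <- 0
      for (k in seq_len(ws$H)) s <- s + ws$W1[i, k] * ws$W2[j, k]
      num[i] <- s
    }
    den <- if (denominator == "absolute") sum(abs(num)) else sum(num)
    RI[j, ] <- 100 * num / den
  }
  dimnames(RI) <- list(rownames(ws$W2), rownames(ws$W1))
  RI
}

# independent one-pass scalar metric computation
metrics_scalar <- function(e, p, n_par) {
  N <- length(e)
  sse <- 0; mbe <- 0; mpe <- 0; aard <- 0; m <- mean(e); sst <- 0
  for (i in seq_len(N)) {
    d <- p[i] - e[i]
    sse <- sse + d^2
    mbe <- mbe + d / N
    mpe <- mpe + 100 * d / e[i] / N
    aard <- aard + 100 * abs(d) / abs(e[i]) / N
    sst <- sst + (e[i] - m)^2
  }
  list(SSE = sse, RMSE = sqrt(sse / N), chi2 = sse / (N - n_par),
       MBE = mbe, MPE = mpe, AARD = aard, r2 = 1 - sse / sst)
}

# quiet wrapper for pipeline-scale syntheses in tests
small_synth <- function(seed = 1, replicates = 2)
  generate_synthetic(synthetic_config(replicates = replicates, seed = seed))
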