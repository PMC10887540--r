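test_that("published weight fixture loads with the printed values", {
  ws <- load_printed_weights()
  expect_equal(ws$H, 10)
  expect_equal(dim(ws$W1), c(6L, 10L))
  expect_equal(dim(ws$W2), c(16L, 10L))
  expect_identical(c(ws$hidden, ws$output), c("tanh", "logistic"))
  # spot checks against the published matrices
  expect_equal(unname(ws$W1["day", 2]), -74.377)
  expect_equal(unname(ws$W2["FRAP", 1]), 3.087)
  expect_equal(ws$B2[match("FRAP", rownames(ws$W2))], -0.582)
  expect_equal(ws$B1[7], -15.175)
})

test_that("forward pass matches an independent scalar evaluation", {
  ws <- load_printed_weights()
  x <- c(0, 1, 0, 0, 0, 1)
  expect_equal(unname(mlp_forward(ws, x)[1, ]), forward_scalar(ws, x),
               tolerance = 1e-12)
  for (s in 1:5) {
    ws_r <- random_weight_set(s, d_in = 4, H = 7, d_out = 5)
    x <- rnorm(4)
    expect_equal(unname(mlp_forward(ws_r, x)[1, ]), forward_scalar(ws_r, x),
                 tolerance = 1e-12)
  }
})

test_that("degenerate networks have their closed-form outputs", {
  zero <- weight_set(matrix(0, 6, 3), rep(0, 3), matrix(0, 2, 3), rep(0, 2))
  expect_equal(unname(mlp_forward(zero, rnorm(6))[1, ]), c(0.5, 0.5))
  one <- weight_set(matrix(1, 1, 1), 0, matrix(1, 1, 1), 0)
  expect_equal(unname(mlp_forward(one, 0)[1, 1]), 0.5)
  # identity activations collapse to the affine map W2 W1' x + W2 B1 + B2
  ws <- random_weight_set(3, d_in = 4, H = 6, d_out = 2,
                          hidden = "identity", output = "identity")
  x <- rnorm(4)
  expect_equal(unname(mlp_forward(ws, x)[1, ]),
               as.numeric(ws$W2 %*% (t(ws$W1) %*% x + ws$B1) + ws$B2),
               tolerance = 1e-12)
})

test_that("forward rejects malformed input", {
  ws <- random_weight_set(1)
  expect_error(mlp_forward(ws, rnorm(5)), "dimension")
  expect_error(mlp_forward(ws, c(1, NA, 1, 1, 1, 1)), "non-finite")
})

test_that("training recovers a known generator to numerical precision", {
  set.seed(42)
  gen <- weight_set(matrix(runif(24, -1, 1), 6, 4), runif(4, -1, 1),
                    matrix(runif(12, -1, 1), 3, 4), runif(3, -1, 1))
  X <- matrix(runif(120 * 6, -1, 1), 120, 6)
  Y <- mlp_forward(gen, X)
  # quasi-Newton training is sensitive to the basin of the random start, so
  # take the best of a few seeded restarts, as a practitioner would
  best <- NULL
  for (s in 1:5) {
    fit <- mlp_train(X, Y, 4, seed = s, max_iter = 2000, tol = 1e-12)
    if (is.null(best) || fit$final_loss < best$final_loss) best <- fit
    if (best$final_loss < 1e-8) break
  }
  expect_lt(best$final_loss, 1e-6)
  expect_lt(max(abs(Y - mlp_forward(best$weights, X))), 1e-3)
})

test_that("training is deterministic per seed and validates targets", {
  set.seed(9)
  X <- matrix(runif(30 * 6, -1, 1), 30, 6)
  Y <- matrix(runif(30 * 2, 0.1, 0.9), 30, 2)
  f1 <- mlp_train(X, Y, 3, seed = 5, max_iter = 50)
  f2 <- mlp_train(X, Y, 3, seed = 5, max_iter = 50)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$weights, f2$weights)

  Ybad <- Y; Ybad[1, 1] <- 1.2
  expect_error(mlp_train(X, Ybad, 3), "attainable range")
})

test_that("architecture search picks by validation fit and reports all", {
  d <- small_synth(seed = 21, replicates = 3)
  X <- encode_design(d$design)
  ins <- fit_standardizer(X[, "day", drop = FALSE], "zscore")
  X[, "day"] <- standardize(ins, X[, "day", drop = FALSE])
  Ys <- standardize(fit_standardizer(d$responses, "minmax"), d$responses)
  sp <- split_data(nrow(X), seed = 21)
  res <- architecture_search(X, Ys, hidden_range = c(3, 6), restarts = 1,
                             split = sp, seed = 21, max_iter = 150)
  expect_equal(nrow(res$table), 2)
  expect_true(all(c("r2_train", "r2_test", "r2_validation") %in%
                  names(res$table)))
  best_row <- res$table[which.max(res$table$r2_validation), ]
  expect_equal(res$best$weights$H, best_row$hidden)
  expect_error(architecture_search(X, Ys, integer(0)), "empty")
  expect_error(architecture_search(X, Ys, 5, restarts = 0), "restarts")
})

test_that("weight sets round-trip through JSON", {
  ws <- load_printed_weights()
  path <- withr::local_tempfile(fileext = ".json")
  write_weight_set(ws, path)
  ws2 <- read_weight_set(path)
  expect_equal(ws2$W1, ws$W1)
  expect_equal(ws2$W2, ws$W2)
  expect_equal(ws2$B1, ws$B1)
  expect_equal(ws2$B2, ws$B2)
  x <- c(15, 0, 1, 0, 1, 0)
  expect_equal(mlp_forward(ws2, x), mlp_forward(ws, x), tolerance = 1e-12)
})
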