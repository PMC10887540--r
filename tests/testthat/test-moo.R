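test_that("dominance follows the standard definition", {
  expect_true(dominates(c(2, 3), c(1, 3)))
  expect_false(dominates(c(2, 1), c(1, 3)))
  expect_false(dominates(c(1, 3), c(2, 1)))
  expect_false(dominates(c(2, 3), c(2, 3)))
  expect_true(dominates(c(1, 5), c(2, 5), directions = c("minimize", "maximize")))
  expect_error(dominates(1:2, 1:3), "length")
})

test_that("pareto_front equals the brute-force filter on random sets", {
  set.seed(8)
  for (rep in 1:5) {
    obj <- matrix(rnorm(50 * 3), 50, 3)
    keep <- pareto_front(obj)
    brute <- vapply(1:50, function(i)
      !any(vapply(1:50, function(j)
        j != i && all(obj[j, ] >= obj[i, ]) && any(obj[j, ] > obj[i, ]),
        TRUE)), TRUE)
    expect_identical(keep, brute)
    # order independence
    perm <- sample(50)
    expect_identical(pareto_front(obj[perm, ])[order(perm)], keep)
  }
  # duplicated best points are all retained
  obj <- rbind(c(5, 5), c(5, 5), c(1, 1))
  expect_identical(pareto_front(obj), c(TRUE, TRUE, FALSE))
})

test_that("single-objective optimization equals the enumeration argmax", {
  ws <- random_weight_set(2, d_in = 6, H = 5, d_out = 16)
  rownames(ws$W2) <- response_names()
  cfg <- objective_config(c(TP = "maximize"))
  ex <- optimize_formulation(ws, cfg, "exhaustive")
  # manual enumeration over the 186-candidate grid
  grid <- expand.grid(day = 0:30, herb = herb_levels(),
                      sample_type = sample_levels(), stringsAsFactors = FALSE)
  Y <- mlp_forward(ws, encode_design(grid))
  best <- grid[which.max(Y[, "TP"]), ]
  expect_equal(nrow(ex$front), 1)
  expect_equal(unname(unlist(ex$front[1, ])), unname(unlist(best)))
  ga <- optimize_formulation(ws, cfg, "ga", seed = 4, generations = 80)
  expect_equal(unname(unlist(ga$front[1, ])), unname(unlist(best)))
})

test_that("GA fronts are reproducible and not dominated by the grid front", {
  ws <- random_weight_set(6, d_in = 6, H = 5, d_out = 16)
  rownames(ws$W2) <- response_names()
  cfg <- objective_config(c(TP = "maximize", Aerobic = "minimize",
                            aw = "minimize"))
  ga1 <- optimize_formulation(ws, cfg, "ga", seed = 9, generations = 60)
  ga2 <- optimize_formulation(ws, cfg, "ga", seed = 9, generations = 60)
  expect_identical(ga1$front, ga2$front)
  # internal non-dominance
  expect_true(all(pareto_front(ga1$objectives)))
  ex <- optimize_formulation(ws, cfg, "exhaustive")
  for (i in seq_len(nrow(ga1$objectives)))
    expect_false(any(apply(ex$objectives, 1, dominates, b = ga1$objectives[i, ])))
  expect_error(optimize_formulation(ws, cfg, "ga"), "seed")
})

test_that("antagonistic objectives produce a true trade-off front", {
  # two outputs pulled in opposite directions by the day input
  W1 <- matrix(0, 6, 2); W1[1, 1] <- 1; W1[1, 2] <- -1
  W2 <- matrix(0, 16, 2); rownames(W2) <- response_names()
  W2["TP", 1] <- 1; W2["DPPH", 2] <- 1
  ws <- weight_set(W1, c(0, 0), W2, rep(0, 16))
  cfg <- objective_config(c(TP = "maximize", DPPH = "maximize"))
  ex <- optimize_formulation(ws, cfg, "exhaustive")
  expect_gte(nrow(ex$front), 2)
})

test_that("exhaustive front is invariant to monotone objective rescaling", {
  ws <- random_weight_set(13, d_in = 6, H = 4, d_out = 16)
  rownames(ws$W2) <- response_names()
  cfg <- objective_config(c(TP = "maximize", FRAP = "maximize"))
  ex <- optimize_formulation(ws, cfg, "exhaustive")
  keep1 <- pareto_front(ex$objectives)
  rescaled <- ex$objectives
  rescaled[, 1] <- exp(3 * rescaled[, 1])   # strictly increasing map
  expect_identical(pareto_front(rescaled), keep1)
})

test_that("objective configs are validated", {
  expect_error(objective_config(c(Bogus = "maximize")), "unknown")
  expect_error(objective_config(c(TP = "embiggen")), "directions")
  expect_error(objective_config(c(DM = "target")), "target values")
  expect_error(objective_config(c(DM = "ignore")), "at least one")
  cfg <- objective_config(c(DM = "target", TP = "maximize"),
                          targets = c(DM = 53.5))
  expect_identical(unname(cfg$directions["DM"]), "target")
})
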