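#' Objective configuration for formulation optimization
#'
#' Assigns each of the sixteen responses a direction: `"maximize"`,
#' `"minimize"`, `"target"` (approach a reference value) or `"ignore"`. The
#' default follows food-safety and antioxidant convention: maximize the
#' antioxidant responses (TP, DPPH, ABTS, FRAP) and lactic acid bacteria;
#' minimize the four undesirable microbial counts and water activity; ignore
#' the compositional responses unless targets are supplied.
#'
#' @param directions Named character vector over (a subset of)
#'   [response_names()]; unnamed responses default to `"ignore"`.
#' @param targets Named numeric vector of reference values for responses in
#'   `"target"` mode.
#' @return Object of class `objective_config`.
#' @export
objective_config <- function(directions = NULL, targets = NULL) {
  dirs <- stats::setNames(rep("ignore", 16), response_names())
  if (is.null(directions)) {
    dirs[c("TP", "DPPH", "ABTS", "FRAP", "Lactic")] <- "maximize"
    dirs[c("Aerobic", "Ecoli", "Lmonocytogenes", "Saureus", "aw")] <- "minimize"
  } else {
    bad <- setdiff(names(directions), response_names())
    if (length(bad))
      stop("objective_config: unknown response(s): ", paste(bad, collapse = ", "))
    ok <- c("maximize", "minimize", "target", "ignore")
    if (!all(directions %in% ok))
      stop("objective_config: directions must be in {",
           paste(ok, collapse = ", "), "}")
    dirs[names(directions)] <- directions
  }
  tg <- names(dirs)[dirs == "target"]
  if (length(tg)) {
    if (is.null(targets) || !all(tg %in% names(targets)) ||
        any(!is.finite(targets[tg])))
      stop("objective_config: finite target values required for: ",
           paste(tg, collapse = ", "))
  }
  if (all(dirs == "ignore"))
    stop("objective_config: at least one response must not be 'ignore'")
  structure(list(directions = dirs, targets = targets),
            class = "objective_config")
}

## Map predicted responses to a maximize-only objective matrix.
.objective_values <- function(Y, config) {
  act <- names(config$directions)[config$directions != "ignore"]
  obj <- sapply(act, function(nm) {
    switch(config$directions[[nm]],
           maximize = Y[, nm],
           minimize = -Y[, nm],
           target = -abs(Y[, nm] - config$targets[[nm]]))
  })
  if (is.null(dim(obj))) obj <- matrix(obj, ncol = length(act))
  colnames(obj) <- act
  obj
}

#' Pareto dominance
#'
#' `a` dominates `b` when it is at least as good on every objective and
#' strictly better on at least one. Objectives are given already oriented
#' (all maximized) or with an explicit `directions` vector of
#' `"maximize"`/`"minimize"` tags.
#'
#' @param a,b Numeric objective vectors of equal length.
#' @param directions Optional character vector; default all `"maximize"`.
#' @return Logical.
#' @export
dominates <- function(a, b, directions = NULL) {
  if (length(a) != length(b)) stop("dominates: length mismatch")
  if (!is.null(directions)) {
    s <- ifelse(directions == "minimize", -1, 1)
    a <- a * s; b <- b * s
  }
  all(a >= b) && any(a > b)
}

#' Non-dominated subset
#'
#' Filters a candidate set (rows of an objective matrix, all objectives
#' oriented to maximize) to exactly its non-dominated members. Duplicated
#' optimal points are all retained; the result is independent of row order.
#'
#' @param obj Numeric matrix (candidates x objectives), maximize-oriented.
#' @return Logical vector marking the non-dominated rows.
#' @export
pareto_front <- function(obj) {
  obj <- as.matrix(obj)
  n <- nrow(obj)
  if (n == 0) stop("pareto_front: empty candidate set")
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && dominates(obj[j, ], obj[i, ])) { keep[i] <- FALSE; break }
    }
  }
  keep
}

.candidate_grid <- function(day_grid) {
  expand.grid(day = day_grid, herb = herb_levels(),
              sample_type = sample_levels(), stringsAsFactors = FALSE)
}

.eval_candidates <- function(weights, design, config, standardizer = NULL,
                             input_standardizer = NULL) {
  X <- encode_design(design)
  if (!is.null(input_standardizer)) {
    Xs <- X
    Xs[, "day"] <- (X[, "day"] - input_standardizer$center["day"]) /
      input_standardizer$scale["day"]
    X <- Xs
  }
  Y <- mlp_forward(weights, X)
  if (!is.null(standardizer)) Y <- destandardize(standardizer, Y)
  colnames(Y) <- rownames(weights$W2)
  Y
}

#' Multi-objective optimization of the cheese formulation
#'
#' Searches the design space (storage day x herb x sample type) for
#' formulations whose predicted quality responses are Pareto-optimal under
#' an [objective_config()]. `method = "exhaustive"` enumerates the full
#' day-grid x 2 herbs x 3 sample types candidate set (186 candidates at the
#' default 1-day step) and filters it to the exact front; `method = "ga"`
#' runs a seeded generational genetic algorithm (tournament selection on
#' Pareto rank, uniform crossover, per-gene mutation) over the same discrete
#' space and returns the non-dominated archive of all evaluated candidates.
#'
#' Predictions are made on model scale; when output/input standardizers from
#' training are supplied, candidates are scored in physical units instead.
#'
#' @param weights A [weight_set()].
#' @param config An [objective_config()].
#' @param method `"exhaustive"` or `"ga"`.
#' @param day_grid Candidate storage days (default `0:30`).
#' @param standardizer Optional output `standardizer` to report physical
#'   units.
#' @param input_standardizer Optional input `standardizer` (applied to the
#'   day column only; indicators stay 0/1).
#' @param population,generations GA parameters (defaults 100 and 500).
#' @param seed RNG seed; mandatory for `"ga"` (reproducibility contract).
#' @return Object of class `pareto_result`: `front` (design data.frame),
#'   `responses` (predicted responses of the front), `objectives`
#'   (maximize-oriented objective values), `method`, `evaluations`.
#' @export
optimize_formulation <- function(weights, config = objective_config(),
                                 method = c("exhaustive", "ga"),
                                 day_grid = 0:30,
                                 standardizer = NULL,
                                 input_standardizer = NULL,
                                 population = 100L, generations = 500L,
                                 seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(weights, "weight_set"), inherits(config, "objective_config"))
  if (length(day_grid) == 0) stop("optimize_formulation: empty day grid")

  if (method == "exhaustive") {
    cand <- .candidate_grid(day_grid)
    Y <- .eval_candidates(weights, cand, config, standardizer, input_standardizer)
    obj <- .objective_values(Y, config)
    keep <- pareto_front(obj)
    res <- list(front = cand[keep, , drop = FALSE],
                responses = Y[keep, , drop = FALSE],
                objectives = obj[keep, , drop = FALSE],
                method = method, evaluations = nrow(cand))
    return(structure(res, class = "pareto_result"))
  }

  if (is.null(seed))
    stop("optimize_formulation: 'seed' is required for the GA ",
         "(reproducibility contract)")
  set.seed(seed)
  herbs <- herb_levels(); samples <- sample_levels()
  n_day <- length(day_grid)
  rand_pop <- function(m)
    cbind(sample.int(n_day, m, replace = TRUE),
          sample.int(2, m, replace = TRUE),
          sample.int(3, m, replace = TRUE))
  decode <- function(P)
    design_point(day_grid[P[, 1]], herbs[P[, 2]], samples[P[, 3]])
  evaluate <- function(P) {
    Y <- .eval_candidates(weights, decode(P), config, standardizer,
                          input_standardizer)
    .objective_values(Y, config)
  }
  ## rank 0 = non-dominated within the set
  pareto_rank <- function(obj) {
    n <- nrow(obj)
    vapply(seq_len(n), function(i)
      sum(vapply(seq_len(n), function(j)
        i != j && dominates(obj[j, ], obj[i, ]), TRUE)), 0)
  }

  P <- rand_pop(population)
  obj <- evaluate(P)
  arch_P <- P; arch_obj <- obj
  stall <- 0L; prev_size <- -1L
  for (g in seq_len(generations)) {
    rk <- pareto_rank(obj)
    ## binary tournament on dominance count
    i1 <- sample.int(nrow(P), population, replace = TRUE)
    i2 <- sample.int(nrow(P), population, replace = TRUE)
    parents <- ifelse(rk[i1] <= rk[i2], i1, i2)
    mates <- parents[sample.int(population)]
    cross <- matrix(stats::runif(population * 3) < 0.5, population, 3)
    child <- P[parents, , drop = FALSE]
    child[cross] <- P[mates, , drop = FALSE][cross]
    mut <- matrix(stats::runif(population * 3) < 0.15, population, 3)
    if (any(mut[, 1])) child[mut[, 1], 1] <- sample.int(n_day, sum(mut[, 1]), replace = TRUE)
    if (any(mut[, 2])) child[mut[, 2], 2] <- sample.int(2, sum(mut[, 2]), replace = TRUE)
    if (any(mut[, 3])) child[mut[, 3], 3] <- sample.int(3, sum(mut[, 3]), replace = TRUE)
    P <- child
    obj <- evaluate(P)
    arch_P <- rbind(arch_P, P); arch_obj <- rbind(arch_obj, obj)
    ## keep the archive compact: prune to unique genotypes
    key <- apply(arch_P, 1, paste, collapse = "/")
    dup <- duplicated(key)
    arch_P <- arch_P[!dup, , drop = FALSE]
    arch_obj <- arch_obj[!dup, , drop = FALSE]
    keep <- pareto_front(arch_obj)
    arch_P <- arch_P[keep, , drop = FALSE]
    arch_obj <- arch_obj[keep, , drop = FALSE]
    if (nrow(arch_P) == prev_size) stall <- stall + 1L else stall <- 0L
    prev_size <- nrow(arch_P)
    if (stall >= 25L) break   # front stopped changing
  }
  front <- decode(arch_P)
  Y <- .eval_candidates(weights, front, config, standardizer, input_standardizer)
  structure(list(front = front, responses = Y, objectives = arch_obj,
                 method = "ga", evaluations = population * (g + 1L)),
            class = "pareto_result")
}

#' @export
print.pareto_result <- function(x, ...) {
  cat(sprintf("Pareto front (%s): %d solution(s), %d evaluations\n",
              x$method, nrow(x$front), x$evaluations))
  print(cbind(x$front, round(as.data.frame(x$objectives), 4)))
  invisible(x)
}

#' @rdname optimize_formulation
#' @param result A `pareto_result`.
#' @param path Output file path (CSV for the front + responses, or JSON).
#' @export
write_pareto <- function(result, path) {
  stopifnot(inherits(result, "pareto_result"))
  df <- cbind(result$front, as.data.frame(result$responses))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
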