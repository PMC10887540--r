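## Factorial-design generator for the storage study: response =
## baseline + slope*day + quad*day^2 + herb offset + sample offset + noise.

.default_synthetic_params <- function() {
  nm <- response_names()
  p <- data.frame(
    response = nm,
    ## magnitudes chosen to be realistic for fresh cheese over 30 days of
    ## cold storage; sign structure mirrors the storage-trend directions the
    ## sensitivity analysis is expected to recover (day the dominant driver,
    ## positive for DM/TP/ABTS, negative for fat, pH, DPPH, FRAP and all
    ## microbial counts; salvia depresses DM/fat/proteins and raises ash and
    ## water activity, thyme mirrored).
    baseline = c(DM = 50, Fat = 25, Ash = 1.7, ProteinsDM = 44, Proteins = 24,
                 aw = 0.950, pH = 4.6, TP = 6, DPPH = 5, ABTS = 6,
                 FRAP = 0.55, Aerobic = 7.5, Ecoli = 3.5, Lmonocytogenes = 4,
                 Saureus = 3.5, Lactic = 8)[nm],
    slope = c(DM = 0.150, Fat = -0.060, Ash = 0.002, ProteinsDM = 0.040,
              Proteins = 0.030, aw = -0.0006, pH = -0.020, TP = 0.050,
              DPPH = -0.030, ABTS = 0.040, FRAP = -0.006,
              Aerobic = -0.060, Ecoli = -0.040, Lmonocytogenes = -0.035,
              Saureus = -0.035, Lactic = -0.045)[nm],
    quad = 0,
    salvia = c(DM = -1.00, Fat = -0.80, Ash = 0.10, ProteinsDM = -1.00,
               Proteins = -0.80, aw = 0.006, pH = -0.10, TP = 0.30,
               DPPH = 0.20, ABTS = 0.20, FRAP = 0.03,
               Aerobic = -0.30, Ecoli = -0.20, Lmonocytogenes = -0.20,
               Saureus = -0.20, Lactic = 0.20)[nm],
    thyme = c(DM = 1.00, Fat = 0.80, Ash = -0.10, ProteinsDM = 1.00,
              Proteins = 0.80, aw = -0.006, pH = 0.10, TP = -0.30,
              DPPH = -0.20, ABTS = -0.20, FRAP = -0.03,
              Aerobic = 0.30, Ecoli = 0.20, Lmonocytogenes = 0.20,
              Saureus = 0.20, Lactic = -0.20)[nm],
    KC = 0,
    KG = c(DM = 0.40, Fat = 0.30, Ash = 0.05, ProteinsDM = 0.40,
           Proteins = 0.30, aw = -0.003, pH = 0.05, TP = 0.40,
           DPPH = 0.30, ABTS = 0.30, FRAP = 0.04,
           Aerobic = -0.40, Ecoli = -0.30, Lmonocytogenes = -0.30,
           Saureus = -0.30, Lactic = 0.30)[nm],
    KSFE = c(DM = 0.20, Fat = 0.15, Ash = 0.08, ProteinsDM = 0.20,
             Proteins = 0.15, aw = 0.004, pH = 0.02, TP = 0.60,
             DPPH = 0.45, ABTS = 0.45, FRAP = 0.06,
             Aerobic = -0.60, Ecoli = -0.45, Lmonocytogenes = -0.45,
             Saureus = -0.45, Lactic = 0.45)[nm],
    ## small measurement noise, roughly 2-5% of each response's design range
    noise_sd = c(DM = 0.15, Fat = 0.08, Ash = 0.01, ProteinsDM = 0.10,
                 Proteins = 0.08, aw = 0.0008, pH = 0.02, TP = 0.06,
                 DPPH = 0.04, ABTS = 0.05, FRAP = 0.008,
                 Aerobic = 0.08, Ecoli = 0.05, Lmonocytogenes = 0.05,
                 Saureus = 0.05, Lactic = 0.06)[nm],
    stringsAsFactors = FALSE)
  rownames(p) <- nm
  p
}

#' Configuration of the synthetic storage study
#'
#' Describes an additive ground-truth response surface over the 2 herbs x 3
#' sample types x storage-day factorial:
#' `response = baseline + slope*day + quad*day^2 + herb offset +
#' sample offset + Normal(0, noise_sd)`.
#' The default parameter table emulates a fortified fresh-cheese storage
#' experiment: storage day is the dominant driver with signed trends per
#' response, herb and sample-type offsets are additive, and measurement
#' noise is small relative to the design range.
#'
#' @param params Optional data.frame overriding the default per-response
#'   parameters (columns `baseline`, `slope`, `quad`, `salvia`, `thyme`,
#'   `KC`, `KG`, `KSFE`, `noise_sd`; rownames = [response_names()]).
#' @param days Storage days of the design (default `c(0, 10, 20, 30)`).
#' @param replicates Replicate measurements per design cell (>= 1).
#' @param seed Integer RNG seed.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(params = NULL, days = c(0, 10, 20, 30),
                             replicates = 1L, seed = 1L) {
  if (is.null(params)) params <- .default_synthetic_params()
  need <- c("baseline", "slope", "quad", "salvia", "thyme",
            "KC", "KG", "KSFE", "noise_sd")
  if (!all(need %in% names(params)) ||
      !all(response_names() %in% rownames(params)))
    stop("synthetic_config: params must have columns ",
         paste(need, collapse = ", "), " and all 16 response rows")
  params <- params[response_names(), ]
  if (any(params$noise_sd < 0)) stop("synthetic_config: noise_sd must be >= 0")
  if (replicates < 1) stop("synthetic_config: replicates must be >= 1")
  structure(list(params = params, days = days,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Noiseless ground-truth surface
#'
#' Evaluates the configured deterministic part of the synthetic surface at
#' the given design points, before noise and range clipping; used for
#' parameter-recovery tests.
#'
#' @param config A [synthetic_config()].
#' @param design Design data.frame; default the configured full grid.
#' @return Numeric matrix (design rows x 16 responses).
#' @export
synthetic_truth <- function(config, design = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(design)) design <- design_grid(config$days)
  p <- config$params
  n <- nrow(design)
  M <- matrix(NA_real_, n, 16, dimnames = list(NULL, response_names()))
  herb_off <- as.matrix(p[, c("salvia", "thyme")])
  samp_off <- as.matrix(p[, c("KC", "KG", "KSFE")])
  for (j in seq_len(16)) {
    M[, j] <- p$baseline[j] + p$slope[j] * design$day +
      p$quad[j] * design$day^2 +
      herb_off[j, match(design$herb, herb_levels())] +
      samp_off[j, match(design$sample_type, sample_levels())]
  }
  M
}

#' Generate a synthetic storage-study dataset
#'
#' One row per design cell x replicate over the full factorial grid, with
#' responses drawn as the configured truth surface plus Gaussian noise.
#' Water activity is clipped to `(0, 1]` and microbial counts to `>= 0`
#' after noise, preserving the domain invariants. Deterministic per seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `design` (data.frame) and `responses` (matrix), in the
#'   schema of [read_response_table()].
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  grid <- design_grid(config$days)
  design <- grid[rep(seq_len(nrow(grid)), each = config$replicates), ]
  rownames(design) <- NULL
  truth <- synthetic_truth(config, design)
  set.seed(config$seed)
  noise <- matrix(stats::rnorm(length(truth)), nrow(truth), ncol(truth))
  noise <- sweep(noise, 2, config$params$noise_sd, "*")
  Y <- truth + noise
  Y[, "aw"] <- pmin(pmax(Y[, "aw"], .Machine$double.eps), 1)
  microb <- c("Aerobic", "Ecoli", "Lmonocytogenes", "Saureus", "Lactic")
  Y[, microb] <- pmax(Y[, microb], 0)
  list(design = design, responses = Y)
}

#' Configured effect size of each input on each response
#'
#' Summarizes the ground truth as one signed effect per (input, response):
#' for the storage day the change over the full day range
#' (`slope * range + quad * range^2`), for each indicator its additive
#' offset. Used to check sign recovery of the sensitivity analysis.
#'
#' @param config A [synthetic_config()].
#' @return Matrix (16 responses x 6 inputs) of signed effects.
#' @export
synthetic_effects <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  p <- config$params
  dr <- diff(range(config$days))
  E <- cbind(day = p$slope * dr + p$quad * dr^2,
             herb_salvia = p$salvia, herb_thyme = p$thyme,
             sample_KC = p$KC, sample_KG = p$KG, sample_KSFE = p$KSFE)
  rownames(E) <- response_names()
  E
}

#' Sign agreement between configured effects and estimated importance
#'
#' For every (input, response) pair whose configured effect exceeds the
#' largest other input's effect on that response by more than
#' `dominance_ratio`-fold,
#' reports whether the sign of the estimated relative importance matches the
#' configured effect sign. Pairs with an all-zero effect row are flagged
#' indeterminate.
#'
#' @param config A [synthetic_config()].
#' @param ri A [yoon_relative_importance()] result from a model trained on
#'   data generated under `config`.
#' @param dominance_ratio Minimum ratio of the pair's `|effect|` to the
#'   largest other `|effect|` on the same response (default 3).
#' @return data.frame with one row per (response, input): configured effect,
#'   estimated RI, `dominant`, `sign_match` (NA when indeterminate).
#' @export
effect_direction_check <- function(config, ri, dominance_ratio = 3) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(ri, "relative_importance"))
  E <- synthetic_effects(config)
  out <- NULL
  for (j in rownames(E)) {
    for (i in colnames(E)) {
      others <- abs(E[j, setdiff(colnames(E), i)])
      dom <- if (all(E[j, ] == 0)) NA
             else abs(E[j, i]) > dominance_ratio * max(others)
      match_sign <- if (is.na(dom) || !dom) NA
                    else sign(E[j, i]) == sign(ri[j, i])
      out <- rbind(out, data.frame(
        response = j, input = i, effect = E[j, i], RI = ri[j, i],
        dominant = dom, sign_match = match_sign, stringsAsFactors = FALSE))
    }
  }
  out
}
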