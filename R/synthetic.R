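#' Generate a ground-truth quadratic viability surface
#'
#' The generative counterpart of the second-order regression model: normalized
#' cell viability (NCV) over coded dose levels is
#' \deqn{NCV(x) = \beta_0 + \sum_i \beta_i x_i + \sum_i \beta_{ii} x_i^2 +
#'   \sum_{i<j} \beta_{ij} x_i x_j.}
#' Baseline viability is 1 at all-zero dose. The coefficient priors are
#' anchored on the dose coding and on cohort heterogeneity: level 2 is the
#' panel's nominal IC20 dose, but nominal IC doses are calibrated on
#' reference material while patient samples span resistant to sensitive, so
#' the single-agent effect at level 2 ranges from essentially none to about
#' 25% inhibition. Linear coefficients are therefore drawn from
#' U(-0.13, 0) (a fully sensitive sample at the nominal IC20 has
#' beta_i near -0.1 with negligible pure-quadratic term, since
#' beta_i + beta_ii = -0.1 and 2 beta_i + 4 beta_ii = -0.2 give
#' beta_ii = 0), quadratic coefficients from U(-0.01, 0.01), and
#' non-planted interaction coefficients are kept within +/-0.02 so that the
#' planted synergistic pairs (interaction coefficient at or below
#' `-effect_scale`) remain identifiable at realistic noise levels. Under
#' this prior a random two-drug therapy's mean NCV centers near 0.8,
#' matching the scale on which screened therapies discriminate clinical
#' response.
#'
#' @param n_drugs Number of drugs (>= 2).
#' @param planted_pairs List of integer pairs (1-based drug indices) to
#'   receive a strongly negative interaction coefficient. Default none.
#' @param effect_scale Magnitude floor of planted interaction coefficients
#'   (> 0); planted `beta_int <= -effect_scale`.
#' @param noise_sd Gaussian readout noise SD on the NCV scale (>= 0); stored
#'   on the surface and used by [simulate_plate()].
#' @param seed RNG seed; the surface is reproducible for a fixed seed.
#' @return A list of class `qpop_truth`: `n_drugs`, `beta0`, `beta_lin`,
#'   `beta_quad`, `beta_int` (named `"i:j"` in `combn` order),
#'   `planted_pairs`, `noise_sd`, `seed`.
#' @export
gen_ground_truth <- function(n_drugs, planted_pairs = list(),
                             effect_scale = 0.2, noise_sd = 0.02,
                             seed = 1L) {
  stopifnot(n_drugs >= 2, effect_scale > 0, noise_sd >= 0)
  planted_pairs <- lapply(planted_pairs, function(p) sort(as.integer(p)))
  for (p in planted_pairs) {
    if (length(p) != 2L || p[1] == p[2] || any(p < 1L) || any(p > n_drugs)) {
      stop("Invalid planted pair (", paste(p, collapse = ","), "): indices must be ",
           "distinct and within 1..", n_drugs, call. = FALSE)
    }
  }
  set.seed(seed)
  f <- as.integer(n_drugs)
  beta_lin <- stats::runif(f, -0.13, 0)
  beta_quad <- stats::runif(f, -0.01, 0.01)
  pairs <- utils::combn(f, 2L)
  beta_int <- stats::runif(ncol(pairs), -0.02, 0.02)
  names(beta_int) <- paste(pairs[1L, ], pairs[2L, ], sep = ":")
  for (p in planted_pairs) {
    beta_int[paste(p[1L], p[2L], sep = ":")] <-
      -effect_scale - stats::runif(1L, 0, 0.25 * effect_scale)
  }
  structure(
    list(n_drugs = f, beta0 = 1, beta_lin = beta_lin, beta_quad = beta_quad,
         beta_int = beta_int, planted_pairs = planted_pairs,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "qpop_truth"
  )
}

#' Full coefficient vector of a truth surface
#'
#' Coefficients in [quadratic_basis()] column order (intercept, linear,
#' quadratic, pairwise interactions): length 1 + 2F + F(F-1)/2.
#'
#' @param truth A `qpop_truth`.
#' @return Named numeric vector.
#' @export
truth_coefficients <- function(truth) {
  nm <- colnames(quadratic_basis(matrix(0, 1L, truth$n_drugs)))
  out <- c(truth$beta0, truth$beta_lin, truth$beta_quad, unname(truth$beta_int))
  names(out) <- nm
  out
}

#' Evaluate a truth surface at coded levels
#'
#' @param truth A `qpop_truth`.
#' @param levels Numeric vector (length `n_drugs`) or matrix (runs by drugs)
#'   of coded levels.
#' @return Numeric NCV value(s), noiseless.
#' @export
truth_ncv <- function(truth, levels) {
  if (is.null(dim(levels))) levels <- matrix(levels, nrow = 1L)
  drop(quadratic_basis(levels) %*% truth_coefficients(truth))
}

#' Simulate a luminescence plate readout from a truth surface
#'
#' Emulates a CellTiter-Glo-style screen of the design: each design run is
#' dispensed in `replicates` technical replicates, plus positive-control
#' wells (vehicle-treated, viability 1) and negative-control wells
#' (background, viability 0). Raw luminescence of a treatment well is
#' `neg_mean + (NCV + e) * (pos_mean - neg_mean)` with `e ~ N(0, noise_sd)`
#' on the NCV scale; control wells get signal-proportional noise around
#' their means (coefficient of variation = `noise_sd`), the way luminescence
#' readout noise scales in practice.
#' The signal is the exact affine transform of the surface: wells where the
#' quadratic surface extrapolates below the background read below
#' `neg_mean` (or below 0) and are retained as-is, so that normalization
#' round-trips to the generating surface exactly. Real luminometers floor
#' at zero counts; that censoring is a feature of real plates this
#' generator deliberately omits.
#'
#' @param truth A `qpop_truth` whose `n_drugs` matches the design.
#' @param design An `oacd_design`.
#' @param replicates Technical replicates per run (>= 1, default 2).
#' @param n_pos_controls,n_neg_controls Control well counts (default 16 each).
#' @param pos_mean,neg_mean Mean raw luminescence of the controls (arbitrary
#'   units, defaults 1e6 and 1e4); must satisfy `pos_mean > neg_mean`.
#' @param seed RNG seed.
#' @return Tibble of class `plate_readout`: `well`, `run_id` (NA for
#'   controls), `replicate`, `role` (`treatment`/`pos_ctrl`/`neg_ctrl`),
#'   `raw`.
#' @export
simulate_plate <- function(truth, design, replicates = 2L,
                           n_pos_controls = 16L, n_neg_controls = 16L,
                           pos_mean = 1e6, neg_mean = 1e4, seed = 1L) {
  lv <- design_levels(design)
  if (ncol(lv) != truth$n_drugs) {
    stop("Design has ", ncol(lv), " factors but truth surface has ",
         truth$n_drugs, " drugs.", call. = FALSE)
  }
  stopifnot(replicates >= 1L)
  if (pos_mean <= neg_mean) {
    stop("Nonpositive control separation: pos_mean must exceed neg_mean.",
         call. = FALSE)
  }
  set.seed(seed)
  span <- pos_mean - neg_mean
  ncv <- truth_ncv(truth, lv)
  run_id <- rep(design$run_id, each = replicates)
  rep_idx <- rep(seq_len(replicates), times = nrow(lv))
  n_trt <- length(run_id)
  raw_trt <- neg_mean +
    (rep(ncv, each = replicates) + stats::rnorm(n_trt, 0, truth$noise_sd)) * span
  raw_pos <- pos_mean * (1 + stats::rnorm(n_pos_controls, 0, truth$noise_sd))
  raw_neg <- neg_mean * (1 + stats::rnorm(n_neg_controls, 0, truth$noise_sd))
  out <- tibble::tibble(
    well = sprintf("W%04d", seq_len(n_trt + n_pos_controls + n_neg_controls)),
    run_id = c(run_id, rep(NA_integer_, n_pos_controls + n_neg_controls)),
    replicate = c(rep_idx, seq_len(n_pos_controls), seq_len(n_neg_controls)),
    role = rep(c("treatment", "pos_ctrl", "neg_ctrl"),
               c(n_trt, n_pos_controls, n_neg_controls)),
    raw = c(raw_trt, raw_pos, raw_neg)
  )
  class(out) <- c("plate_readout", class(out))
  out
}

#' Simulate a four-parameter logistic dose-response experiment
#'
#' Viability follows the 4PL curve
#' `bottom + (top - bottom) / (1 + (dose/ic50)^hill)` with additive Gaussian
#' noise.
#'
#' @param top,bottom Upper/lower viability asymptotes.
#' @param ic50 Half-maximal dose (uM, > 0).
#' @param hill Hill slope.
#' @param doses Positive dose vector (uM).
#' @param noise_sd Gaussian noise SD on the viability scale.
#' @param seed RNG seed.
#' @return Tibble `dose_uM`, `viability`.
#' @export
simulate_dose_response <- function(top = 1, bottom = 0, ic50 = 1, hill = 1,
                                   doses = 10^seq(-4, 2, length.out = 8),
                                   noise_sd = 0, seed = 1L) {
  stopifnot(ic50 > 0, all(doses > 0))
  set.seed(seed)
  v <- bottom + (top - bottom) / (1 + (doses / ic50)^hill) +
    stats::rnorm(length(doses), 0, noise_sd)
  tibble::tibble(dose_uM = as.numeric(doses), viability = v)
}

#' Simulate a screened cohort with outcome-linked treatment labels
#'
#' Each sample receives its own ground-truth surface (sharing the panel's
#' planted synergistic pairs) and a simulated plate on the 155-run design.
#' Treatment outcomes are generated by drawing a case and a two-drug therapy,
#' computing that therapy's true mean NCV (average over its nonzero dose
#' permutations on the case's surface), and labelling it responder with
#' probability `plogis(-k * (meanNCV - c))`, flipped with probability
#' `label_noise`. Responders are split between PR and SD; non-responders are
#' PD, mirroring RECIST classes.
#'
#' @param n_samples Number of patient samples (>= 1).
#' @param panel A `drug_panel`; its size sets the number of drugs.
#' @param n_outcomes Number of treatment outcomes to label (default 27).
#' @param outcome_link List with `c` (NCV threshold), `k` (logistic slope,
#'   may be `Inf` for a hard threshold) and `label_noise` in [0, 0.5).
#' @param planted_pairs,effect_scale,noise_sd Passed to [gen_ground_truth()]
#'   for every sample.
#' @param replicates Technical replicates per design run.
#' @param seed RNG seed; fixed seed gives a byte-identical serialized cohort.
#' @return A list of class `qpop_cohort`: `samples` (list of
#'   `list(sample_id, truth, plate)`), `outcomes` tibble (`case_id`,
#'   `therapy`, `mean_ncv`, `recist`), `panel`, `link`.
#' @export
simulate_cohort <- function(n_samples, panel = default_panel(),
                            n_outcomes = 27L,
                            outcome_link = list(c = 0.8, k = 25, label_noise = 0.05),
                            planted_pairs = list(c(9L, 11L)),
                            effect_scale = 0.2, noise_sd = 0.02,
                            replicates = 2L, seed = 1L) {
  stopifnot(n_samples >= 1L)
  ln <- outcome_link$label_noise
  if (ln < 0 || ln >= 0.5) stop("label_noise must be in [0, 0.5).", call. = FALSE)
  f <- nrow(panel)
  design <- build_oacd(f)
  set.seed(seed)
  sample_seeds <- sample.int(2^31 - 1L, 2L * n_samples)
  samples <- lapply(seq_len(n_samples), function(i) {
    truth <- gen_ground_truth(f, planted_pairs = planted_pairs,
                              effect_scale = effect_scale, noise_sd = noise_sd,
                              seed = sample_seeds[2L * i - 1L])
    plate <- simulate_plate(truth, design, replicates = replicates,
                            seed = sample_seeds[2L * i])
    list(sample_id = sprintf("S%03d", i), truth = truth, plate = plate)
  })
  # outcome labelling, seeded after the per-sample streams
  set.seed(seed + 1L)
  case_idx <- sample.int(n_samples, n_outcomes, replace = TRUE)
  pairs <- utils::combn(f, 2L)
  pair_idx <- sample.int(ncol(pairs), n_outcomes, replace = TRUE)
  perms <- as.matrix(expand.grid(l1 = 1:2, l2 = 1:2))
  mean_ncv <- vapply(seq_len(n_outcomes), function(o) {
    p <- pairs[, pair_idx[o]]
    lv <- matrix(0, nrow(perms), f)
    lv[, p[1L]] <- perms[, 1L]
    lv[, p[2L]] <- perms[, 2L]
    mean(truth_ncv(samples[[case_idx[o]]]$truth, lv))
  }, numeric(1L))
  p_resp <- if (is.infinite(outcome_link$k)) {
    ifelse(mean_ncv < outcome_link$c, 1, ifelse(mean_ncv > outcome_link$c, 0, 0.5))
  } else {
    stats::plogis(-outcome_link$k * (mean_ncv - outcome_link$c))
  }
  responder <- stats::runif(n_outcomes) < p_resp
  flip <- stats::runif(n_outcomes) < ln
  responder <- xor(responder, flip)
  recist <- ifelse(responder,
                   ifelse(stats::runif(n_outcomes) < 7 / 16, "PR", "SD"),
                   "PD")
  outcomes <- tibble::tibble(
    case_id = sprintf("S%03d", case_idx),
    therapy = paste(panel$drug[pairs[1L, pair_idx]],
                    panel$drug[pairs[2L, pair_idx]], sep = " + "),
    mean_ncv = mean_ncv,
    recist = recist
  )
  structure(list(samples = samples, outcomes = outcomes, panel = panel,
                 link = outcome_link),
            class = "qpop_cohort")
}

#' Serialize a simulated cohort to the pipeline's CSV/JSON formats
#'
#' Writes one plate CSV per sample (`<sample_id>_plate.csv`, columns `well`,
#' `run_id`, `replicate`, `role`, `raw`), the outcomes CSV
#' (`outcomes.csv`: `case_id`, `therapy`, `mean_ncv`, `recist`) and the panel
#' JSON (`panel.json`).
#'
#' @param cohort A `qpop_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in cohort$samples) {
    write_plate(s$plate, file.path(dir, paste0(s$sample_id, "_plate.csv")))
  }
  readr::write_csv(cohort$outcomes, file.path(dir, "outcomes.csv"))
  write_panel(cohort$panel, file.path(dir, "panel.json"))
  invisible(dir)
}
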