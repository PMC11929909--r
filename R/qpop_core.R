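#' Fit the second-order viability model
#'
#' Ordinary least squares of replicate-level normalized cell viability on the
#' full quadratic basis of coded dose levels,
#' \eqn{1, x_i, x_i^2, x_i x_j}: 91 terms for 12 drugs. Replicates are used
#' as individual observations (no weighting); under balanced replication
#' this yields the same coefficients as fitting run means.
#'
#' @param viability A `viability_table` (replicate-level `run_id`, `ncv`),
#'   e.g. from [normalize_plate()].
#' @param design The `oacd_design` the plate was run on; every design run
#'   must have at least one observation.
#' @param drugs Optional drug names for the factors (defaults to the
#'   design's column names).
#' @return An object of class `qpop_model`: coefficient blocks (`beta0`,
#'   `beta_lin`, `beta_quad`, `beta_int`), the full named `coefficients`
#'   vector, `drugs`, `n_factors`, and diagnostics `r_squared`, `sigma`
#'   (residual SD), `n_obs`.
#' @export
fit_quadratic <- function(viability, design, drugs = NULL) {
  lv <- design_levels(design)
  if (is.null(drugs)) drugs <- colnames(lv)
  obs <- dplyr::inner_join(tibble::as_tibble(viability),
                           tibble::tibble(run_id = design$run_id,
                                          .row = seq_len(nrow(lv))),
                           by = "run_id")
  missing_runs <- setdiff(design$run_id, obs$run_id)
  if (length(missing_runs)) {
    stop("Design runs without viability observations: ",
         paste(utils::head(missing_runs, 5L), collapse = ", "), call. = FALSE)
  }
  mm <- quadratic_basis(lv, names = drugs)[obs$.row, , drop = FALSE]
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    stop("Quadratic basis is rank-deficient on this design (rank ",
         qr_mm$rank, " < ", ncol(mm), " terms); see validate_design().",
         call. = FALSE)
  }
  fit <- stats::lm.fit(mm, obs$ncv)
  coefs <- fit$coefficients
  f <- length(drugs)
  res <- fit$residuals
  dof <- length(res) - ncol(mm)
  tss <- sum((obs$ncv - mean(obs$ncv))^2)
  structure(
    list(
      coefficients = coefs,
      beta0 = unname(coefs[1L]),
      beta_lin = coefs[1L + seq_len(f)],
      beta_quad = coefs[1L + f + seq_len(f)],
      beta_int = coefs[-seq_len(1L + 2L * f)],
      drugs = drugs,
      n_factors = f,
      r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
      sigma = if (dof > 0) sqrt(sum(res^2) / dof) else NA_real_,
      n_obs = length(res)
    ),
    class = "qpop_model"
  )
}

#' @export
print.qpop_model <- function(x, ...) {
  cat("Second-order viability model: ", x$n_factors, " drugs, ",
      length(x$coefficients), " terms, n = ", x$n_obs,
      ", R^2 = ", formatC(x$r_squared, digits = 4, format = "f"), "\n", sep = "")
  invisible(x)
}

#' Predict normalized cell viability at coded levels
#'
#' Evaluates \eqn{\beta_0 + \sum \beta_i x_i + \sum \beta_{ii} x_i^2 +
#' \sum_{i<j} \beta_{ij} x_i x_j}. Predictions are not clipped to [0, 1].
#'
#' @param model A `qpop_model` (or `qpop_truth`).
#' @param levels Numeric vector of length `n_factors`, or a runs-by-factors
#'   matrix.
#' @return Numeric prediction(s).
#' @export
predict_ncv <- function(model, levels) {
  if (inherits(model, "qpop_truth")) return(truth_ncv(model, levels))
  if (is.null(dim(levels))) levels <- matrix(levels, nrow = 1L)
  if (ncol(levels) != model$n_factors) {
    stop("Level vector length ", ncol(levels), " != ", model$n_factors,
         " factors.", call. = FALSE)
  }
  drop(quadratic_basis(levels, names = model$drugs) %*% model$coefficients)
}

# enumerate all dose permutations of every `order`-drug therapy:
# active drugs at levels {1, 2}, all others at 0
.enumerate_therapies <- function(f, order) {
  combos <- utils::combn(f, order)
  perm_levels <- as.matrix(expand.grid(rep(list(1:2), order)))
  n_perm <- nrow(perm_levels)
  n_comb <- ncol(combos)
  lv <- matrix(0, n_comb * n_perm, f)
  for (j in seq_len(n_comb)) {
    rows <- (j - 1L) * n_perm + seq_len(n_perm)
    lv[rows, combos[, j]] <- perm_levels
  }
  list(combos = combos, perm_levels = perm_levels, levels = lv,
       combo_of_row = rep(seq_len(n_comb), each = n_perm))
}

#' Enumerate and rank all drug-dose therapies
#'
#' A therapy of order k is a set of k distinct drugs, each dispensed at
#' coded level 1 or 2 with all other drugs absent (level 0). All
#' \eqn{\binom{F}{k} 2^k} dose permutations are predicted from the model;
#' each unique therapy is summarized by the arithmetic mean and SD of its
#' permutation predictions and ranked ascending by mean NCV (smaller rank =
#' greater predicted cell killing), with lexicographic drug-index
#' tie-breaking.
#'
#' @param model A fitted `qpop_model`.
#' @param order Number of drugs per therapy (1, 2 or 3; default 2).
#' @return A tibble of class `qpop_ranking`: `rank`, `therapy`,
#'   `drug1`..`drug<order>` (names), `mean_ncv`, `sd_ncv`, `best_ncv`
#'   (lowest permutation prediction), `n_perm`. The per-permutation
#'   predictions are in `attr(, "permutations")` and the model in
#'   `attr(, "model")`.
#' @export
rank_combinations <- function(model, order = 2L) {
  f <- model$n_factors
  if (order > f) stop("Therapy order ", order, " exceeds ", f, " drugs.",
                      call. = FALSE)
  enum <- .enumerate_therapies(f, order)
  pred <- predict_ncv(model, enum$levels)
  therapy_names <- apply(enum$combos, 2L,
                         function(ix) paste(model$drugs[ix], collapse = " + "))
  perms <- tibble::tibble(
    therapy = therapy_names[enum$combo_of_row],
    levels = apply(enum$perm_levels, 1L, paste, collapse = "/")[
      rep(seq_len(nrow(enum$perm_levels)), ncol(enum$combos))],
    predicted_ncv = pred
  )
  n_perm <- nrow(enum$perm_levels)
  pred_by_combo <- split(pred, enum$combo_of_row)
  mean_ncv <- unname(vapply(pred_by_combo, mean, numeric(1L)))
  sd_ncv <- unname(vapply(pred_by_combo, stats::sd, numeric(1L)))
  best_ncv <- unname(vapply(pred_by_combo, min, numeric(1L)))
  drug_names <- matrix(model$drugs[enum$combos], nrow = order)
  out <- tibble::tibble(therapy = therapy_names, mean_ncv = mean_ncv,
                        sd_ncv = sd_ncv, best_ncv = best_ncv,
                        n_perm = n_perm)
  for (k in seq_len(order)) out[[paste0("drug", k)]] <- drug_names[k, ]
  # ascending mean NCV, lexicographic drug-index tie-break
  ord <- do.call(base::order,
                 c(list(out$mean_ncv),
                   lapply(seq_len(order), function(k) enum$combos[k, ])))
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  out$best_rank <- rank(out$best_ncv, ties.method = "first")
  out <- out[, c("rank", "therapy", paste0("drug", seq_len(order)),
                 "mean_ncv", "sd_ncv", "best_ncv", "best_rank", "n_perm")]
  attr(out, "permutations") <- perms
  attr(out, "model") <- model
  attr(out, "order") <- as.integer(order)
  class(out) <- c("qpop_ranking", class(out))
  out
}

#' Mean and SD NCV of named therapies
#'
#' Averages the model's predictions over a therapy's nonzero dose
#' permutations (levels in \{1, 2\} for each active drug): 2 permutations
#' for a single agent, 4 for a pair, 8 for a triplet.
#'
#' @param model A `qpop_model`.
#' @param therapies List of character vectors of drug names (or integer
#'   index vectors); a single vector is treated as one therapy.
#' @return Tibble `therapy`, `order`, `mean_ncv`, `sd_ncv`.
#' @export
therapy_summary <- function(model, therapies) {
  if (!is.list(therapies)) therapies <- list(therapies)
  purrr::map_dfr(therapies, function(th) {
    ix <- if (is.character(th)) match(th, model$drugs) else as.integer(th)
    if (anyNA(ix) || any(ix < 1L) || any(ix > model$n_factors)) {
      stop("Unknown drug in therapy: ", paste(th, collapse = " + "),
           call. = FALSE)
    }
    if (anyDuplicated(ix)) stop("Duplicate drug in therapy.", call. = FALSE)
    k <- length(ix)
    perms <- as.matrix(expand.grid(rep(list(1:2), k)))
    lv <- matrix(0, nrow(perms), model$n_factors)
    lv[, ix] <- perms
    pred <- predict_ncv(model, lv)
    tibble::tibble(
      therapy = paste(model$drugs[ix], collapse = " + "),
      order = k,
      mean_ncv = mean(pred),
      sd_ncv = stats::sd(pred)
    )
  })
}

#' Response-surface-map grid for a drug pair
#'
#' Predicted NCV over the coded-level plane [0, 2] x [0, 2] of one drug pair
#' with every other drug at level 0 — the parabolic response surface used to
#' visualize the modelled interaction between two drugs.
#'
#' @param model A `qpop_model`.
#' @param pair Two distinct drug names or indices.
#' @param grid_n Grid nodes per axis (default 41).
#' @return A tibble of class `rsm_grid` with columns `level_a`, `level_b`,
#'   `ncv`; the pair's names are in `attr(, "pair")`.
#' @export
rsm_grid <- function(model, pair, grid_n = 41L) {
  ix <- if (is.character(pair)) match(pair, model$drugs) else as.integer(pair)
  if (length(ix) != 2L || anyNA(ix)) stop("pair must name two panel drugs.",
                                          call. = FALSE)
  if (ix[1L] == ix[2L]) stop("pair must contain two distinct drugs.",
                             call. = FALSE)
  g <- seq(0, 2, length.out = grid_n)
  nodes <- expand.grid(level_a = g, level_b = g)
  lv <- matrix(0, nrow(nodes), model$n_factors)
  lv[, ix[1L]] <- nodes$level_a
  lv[, ix[2L]] <- nodes$level_b
  out <- tibble::tibble(level_a = nodes$level_a, level_b = nodes$level_b,
                        ncv = predict_ncv(model, lv))
  attr(out, "pair") <- model$drugs[ix]
  class(out) <- c("rsm_grid", class(out))
  out
}

#' Export an RSM grid as a matrix CSV
#'
#' First column = drug A levels, header row = drug B levels, body =
#' predicted NCV.
#'
#' @param grid An `rsm_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rsm_matrix <- function(grid, path) {
  wide <- tidyr::pivot_wider(grid, names_from = "level_b", values_from = "ncv")
  readr::write_csv(wide, path)
  invisible(path)
}

#' Assemble a per-sample screening report
#'
#' The deliverable of one screened sample: the QC block, the top-k unique
#' two-drug therapies with mean +/- SD NCV, the full single-agent table with
#' ranks, and optional named-therapy comparisons (e.g. the standard-of-care
#' doublet). Therapies with predicted mean NCV below 0 are annotated as
#' model extrapolation. Regenerating the report from the same inputs gives a
#' byte-identical document.
#'
#' @param ranking A two-drug `qpop_ranking` (carries its model).
#' @param qc One-row QC tibble from [plate_qc()].
#' @param panel The `drug_panel` screened.
#' @param top_k Number of top pairs to list (default 10).
#' @param sample_id Sample identifier string.
#' @param named_therapies Optional list of drug-name vectors to summarize by
#'   name (e.g. `list(c("ifosfamide", "doxorubicin"))`).
#' @return A list of class `qpop_report` (JSON-serializable).
#' @export
sample_report <- function(ranking, qc, panel, top_k = 10L,
                          sample_id = "sample", named_therapies = NULL) {
  model <- attr(ranking, "model")
  top <- utils::head(tibble::as_tibble(ranking), top_k)
  top$note <- ifelse(top$mean_ncv < 0, "<=0 (model extrapolation)", "")
  ranking1 <- rank_combinations(model, order = 1L)
  one_drug <- tibble::as_tibble(ranking1)[, c("rank", "drug1", "mean_ncv", "sd_ncv")]
  names(one_drug)[2L] <- "drug"
  comparisons <- if (!is.null(named_therapies)) {
    therapy_summary(model, named_therapies)
  } else NULL
  report <- list(
    sample_id = sample_id,
    qc = as.list(qc),
    top_combinations = as.data.frame(
      top[, c("rank", "therapy", "mean_ncv", "sd_ncv", "note")]),
    one_drug_ranking = as.data.frame(one_drug),
    named_therapies = if (!is.null(comparisons)) as.data.frame(comparisons),
    rsm_pairs = as.data.frame(top[, c("drug1", "drug2")]),
    panel = as.data.frame(panel)
  )
  report <- report[!vapply(report, is.null, logical(1L))]
  class(report) <- "qpop_report"
  report
}

#' Write a sample report to JSON
#'
#' @param report A `qpop_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, digits = NA, pretty = TRUE,
                       auto_unbox = TRUE)
  invisible(path)
}
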