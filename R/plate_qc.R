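#' Read / write a plate readout CSV
#'
#' The plate format is the pipeline's interchange format: columns `well`,
#' `run_id` (empty for control wells), `replicate`, `role` (one of
#' `treatment`, `pos_ctrl`, `neg_ctrl`) and `raw` (luminescence, >= 0).
#'
#' @param path CSV file path.
#' @return `read_plate` returns a validated `plate_readout` tibble;
#'   `write_plate` returns `path` invisibly.
#' @export
read_plate <- function(path) {
  if (!file.exists(path)) stop("Plate file not found: ", path, call. = FALSE)
  required <- c("well", "run_id", "replicate", "role", "raw")
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(required, header)
  if (length(missing)) {
    stop("Plate file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          well = readr::col_character(),
                          run_id = readr::col_integer(),
                          replicate = readr::col_integer(),
                          role = readr::col_character(),
                          raw = readr::col_double(),
                          .default = readr::col_guess()
                        ))
  validate_plate(df[, required])
}

#' @rdname read_plate
#' @param plate A `plate_readout` tibble.
#' @export
write_plate <- function(plate, path) {
  readr::write_csv(plate, path)
  invisible(path)
}

#' Validate a plate readout
#'
#' Checks roles, finiteness, presence of both control types, and duplicate
#' treatment rows. Treatment wells may read below the blank (background-
#' subtracted or strongly killed wells); control wells must be nonnegative.
#'
#' @param plate Data frame with plate columns.
#' @return The plate as a `plate_readout` tibble; errors describe the first
#'   violated constraint.
#' @export
validate_plate <- function(plate) {
  bad_role <- setdiff(unique(plate$role), c("treatment", "pos_ctrl", "neg_ctrl"))
  if (length(bad_role)) stop("Unknown well role(s): ",
                             paste(bad_role, collapse = ", "), call. = FALSE)
  if (any(!is.finite(plate$raw))) stop("Non-finite raw luminescence.", call. = FALSE)
  if (any(plate$raw[plate$role != "treatment"] < 0)) {
    stop("Negative raw luminescence in control wells.", call. = FALSE)
  }
  if (!any(plate$role == "pos_ctrl")) stop("No positive controls in plate.", call. = FALSE)
  if (!any(plate$role == "neg_ctrl")) stop("No negative controls in plate.", call. = FALSE)
  trt <- plate[plate$role == "treatment", ]
  if (anyDuplicated(trt[, c("run_id", "replicate")])) {
    stop("Duplicated (run_id, replicate) treatment rows.", call. = FALSE)
  }
  out <- tibble::as_tibble(plate)
  if (!inherits(out, "plate_readout")) class(out) <- c("plate_readout", class(out))
  out
}

#' Normalize raw luminescence to cell viability
#'
#' Normalized cell viability (NCV) rescales the raw signal so the mean
#' positive control (vehicle-treated) reads 1 and the mean negative control
#' (background) reads 0:
#' `NCV = (raw - mean_neg) / (mean_pos - mean_neg)`.
#' NCV is not clipped: values slightly outside [0, 1] from readout noise are
#' retained for regression but flagged when outside [-0.2, 1.5].
#'
#' @param plate A `plate_readout` (validated).
#' @return A tibble of class `viability_table` with replicate-level rows
#'   `run_id`, `replicate`, `ncv`, `flagged`; control means are stored in
#'   attributes `mean_pos` / `mean_neg`.
#' @export
normalize_plate <- function(plate) {
  plate <- validate_plate(plate)
  mean_pos <- mean(plate$raw[plate$role == "pos_ctrl"])
  mean_neg <- mean(plate$raw[plate$role == "neg_ctrl"])
  if (mean_pos <= mean_neg) stop("Inverted controls: mean positive control ",
                                 "does not exceed mean negative control.",
                                 call. = FALSE)
  trt <- plate[plate$role == "treatment", ]
  ncv <- (trt$raw - mean_neg) / (mean_pos - mean_neg)
  out <- tibble::tibble(
    run_id = trt$run_id,
    replicate = trt$replicate,
    ncv = ncv,
    flagged = ncv < -0.2 | ncv > 1.5
  )
  attr(out, "mean_pos") <- mean_pos
  attr(out, "mean_neg") <- mean_neg
  class(out) <- c("viability_table", class(out))
  out
}

#' Per-run viability summary
#'
#' @param viability A `viability_table`.
#' @return Tibble `run_id`, `n_rep`, `mean_ncv`, `sd_ncv` (NA for a single
#'   replicate), ordered by run.
#' @export
viability_summary <- function(viability) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(viability), .data$run_id),
    n_rep = dplyr::n(),
    mean_ncv = mean(.data$ncv),
    sd_ncv = stats::sd(.data$ncv),
    .groups = "drop"
  )
}

#' Z'-factor of an assay
#'
#' `Z' = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|`, with sample
#' standard deviations (n - 1 denominator). Z' of 1 is an ideal assay;
#' >= 0.5 is the conventional pass band for high-throughput screens.
#'
#' @param pos,neg Replicate raw values of positive / negative controls
#'   (>= 2 each).
#' @return Z' as a single number.
#' @export
zprime <- function(pos, neg) {
  stopifnot(length(pos) >= 2L, length(neg) >= 2L)
  mu_p <- mean(pos); mu_n <- mean(neg)
  if (mu_p == mu_n) stop("Z' undefined: control means are equal.", call. = FALSE)
  1 - 3 * (stats::sd(pos) + stats::sd(neg)) / abs(mu_p - mu_n)
}

#' Strictly standardized mean difference (SSMD)
#'
#' `SSMD = (mean_pos - mean_neg) / sqrt(sd_pos^2 + sd_neg^2)` with sample
#' SDs; scale-invariant measure of control separation.
#'
#' @inheritParams zprime
#' @return SSMD as a single number.
#' @export
ssmd <- function(pos, neg) {
  stopifnot(length(pos) >= 2L, length(neg) >= 2L)
  v <- stats::var(pos) + stats::var(neg)
  if (v == 0) stop("SSMD undefined: both control variances are zero.", call. = FALSE)
  (mean(pos) - mean(neg)) / sqrt(v)
}

#' Assay quality report for one plate
#'
#' @param plate A `plate_readout`.
#' @param zprime_min Z' pass threshold (default 0.5, the standard
#'   high-throughput screening convention).
#' @return One-row tibble `zprime`, `ssmd`, `zprime_min`, `pass`
#'   (`pass` is `zprime >= zprime_min`).
#' @export
plate_qc <- function(plate, zprime_min = 0.5) {
  plate <- validate_plate(plate)
  pos <- plate$raw[plate$role == "pos_ctrl"]
  neg <- plate$raw[plate$role == "neg_ctrl"]
  z <- zprime(pos, neg)
  s <- tryCatch(ssmd(pos, neg), error = function(e) NA_real_)
  tibble::tibble(zprime = z, ssmd = s,
                 zprime_min = zprime_min, pass = z >= zprime_min)
}

#' Quality gate and cohort accounting
#'
#' Applies the Z' gate per sample and summarizes the cohort the way a
#' screening CONSORT diagram does: collected, excluded for insufficient
#' material, excluded on QC, reported, and the report yield percentage
#' (reported / collected * 100, one decimal).
#'
#' @param qc Data frame with one row per QC'd sample, containing at least a
#'   `zprime` column (extra columns such as `sample_id` are carried through).
#' @param zprime_min Z' pass threshold.
#' @param n_collected Total samples collected; defaults to
#'   `nrow(qc) + n_insufficient` (every collected sample with enough material
#'   was QC'd).
#' @param n_insufficient Samples excluded before QC for insufficient
#'   material.
#' @return List with `per_sample` (input plus `pass`) and `summary` (one-row
#'   tibble `n_collected`, `n_insufficient`, `n_qc_failed`, `n_reported`,
#'   `yield_pct`).
#' @export
qc_gate <- function(qc, zprime_min = 0.5, n_collected = NULL,
                    n_insufficient = 0L) {
  qc <- tibble::as_tibble(qc)
  qc$pass <- qc$zprime >= zprime_min
  n_failed <- sum(!qc$pass)
  if (is.null(n_collected)) n_collected <- nrow(qc) + n_insufficient
  n_reported <- n_collected - n_insufficient - n_failed
  list(
    per_sample = qc,
    summary = tibble::tibble(
      n_collected = as.integer(n_collected),
      n_insufficient = as.integer(n_insufficient),
      n_qc_failed = as.integer(n_failed),
      n_reported = as.integer(n_reported),
      yield_pct = round(100 * n_reported / n_collected, 1)
    )
  )
}
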