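#' Chou-Talalay combination index curve
#'
#' For a two-drug combination tested at a constant dose ratio, the
#' combination index at affected fraction fa is
#' \deqn{CI(fa) = d_1 / D_{x,A}(fa) + d_2 / D_{x,B}(fa)}
#' (mutually exclusive form, no third product term), where the total
#' combination dose achieving fa comes from the combination's own
#' median-effect fit on total dose, and `d1`, `d2` are its components under
#' the fixed ratio. CI < 1 indicates synergy, CI = 1 additivity, CI > 1
#' antagonism.
#'
#' @param fit_a,fit_b `median_effect_fit`s of the single agents.
#' @param fit_ab `median_effect_fit` of the combination, fitted on total
#'   dose (d1 + d2) at the fixed ratio.
#' @param ratio Length-2 positive numeric: the constant d1:d2 dose ratio
#'   (taken from the panel doses in practice).
#' @param fa_grid Affected fractions to evaluate, strictly in (0, 1).
#' @return A tibble of class `ci_curve`: `fa`, `ci`, plus per-fa component
#'   doses `d1`, `d2`.
#' @export
combination_index <- function(fit_a, fit_b, fit_ab, ratio,
                              fa_grid = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(length(ratio) == 2L, all(ratio > 0))
  if (any(fa_grid <= 0 | fa_grid >= 1)) {
    stop("fa_grid must lie strictly in (0, 1).", call. = FALSE)
  }
  fa_grid <- sort(fa_grid)
  d_total <- dx_from_median_effect(fit_ab, fa_grid)
  d1 <- d_total * ratio[1L] / sum(ratio)
  d2 <- d_total * ratio[2L] / sum(ratio)
  ci <- d1 / dx_from_median_effect(fit_a, fa_grid) +
    d2 / dx_from_median_effect(fit_b, fa_grid)
  out <- tibble::tibble(fa = fa_grid, ci = ci, d1 = d1, d2 = d2)
  attr(out, "ratio") <- ratio
  class(out) <- c("ci_curve", class(out))
  out
}

#' Bliss independence excess matrix
#'
#' From a dose-matrix viability experiment (monotherapy margins at dose 0
#' required), inhibition is `i = 1 - viability` (clamped to [0, 1]); the
#' Bliss expectation for the combination is
#' `i_AB = i_A + i_B - i_A * i_B` from the monotherapy margins, and the
#' excess is `(observed - expected) * 100` percentage points. The summary
#' score is the unweighted mean excess over cells where both doses are
#' nonzero, classified as synergistic (> 10), antagonistic (< -10) or
#' additive otherwise.
#'
#' @param doses_a,doses_b Dose vectors (uM) for the rows / columns; each
#'   must contain 0 (the monotherapy margin).
#' @param viability Numeric matrix, `length(doses_a)` rows by
#'   `length(doses_b)` columns.
#' @return A list of class `bliss_result`: `doses_a`, `doses_b`, `observed`,
#'   `expected`, `excess` (matrices), `score`, `classification`,
#'   `n_clamped`.
#' @export
bliss_matrix <- function(doses_a, doses_b, viability) {
  viability <- as.matrix(viability)
  if (nrow(viability) != length(doses_a) || ncol(viability) != length(doses_b)) {
    stop("viability matrix must be length(doses_a) x length(doses_b).",
         call. = FALSE)
  }
  ia0 <- which(doses_a == 0)
  ib0 <- which(doses_b == 0)
  if (length(ia0) != 1L || length(ib0) != 1L) {
    stop("Missing zero-dose monotherapy margins: each dose list must ",
         "contain 0 exactly once.", call. = FALSE)
  }
  inhib <- 1 - viability
  n_clamped <- sum(inhib < 0 | inhib > 1)
  inhib <- pmin(pmax(inhib, 0), 1)
  i_a <- inhib[, ib0]   # drug A alone (B at 0)
  i_b <- inhib[ia0, ]   # drug B alone (A at 0)
  expected <- outer(i_a, i_b, function(x, y) x + y - x * y)
  excess <- (inhib - expected) * 100
  combo_cells <- outer(doses_a > 0, doses_b > 0, `&`)
  score <- mean(excess[combo_cells])
  structure(
    list(doses_a = doses_a, doses_b = doses_b,
         observed = inhib * 100, expected = expected * 100, excess = excess,
         score = score, classification = classify_bliss(score),
         n_clamped = n_clamped),
    class = "bliss_result"
  )
}

#' Classify a Bliss synergy score
#'
#' Strict thresholds: scores above 10 are synergistic, below -10
#' antagonistic, otherwise additive (10.0 itself is additive).
#'
#' @param score Bliss summary score (mean excess, percentage points).
#' @return `"synergistic"`, `"additive"` or `"antagonistic"` (vectorized).
#' @export
classify_bliss <- function(score) {
  ifelse(score > 10, "synergistic",
         ifelse(score < -10, "antagonistic", "additive"))
}

#' @export
print.bliss_result <- function(x, ...) {
  cat("Bliss independence: mean excess ",
      formatC(x$score, digits = 2, format = "f"), " (",
      x$classification, "), ", length(x$doses_a), "x", length(x$doses_b),
      " dose matrix\n", sep = "")
  invisible(x)
}
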