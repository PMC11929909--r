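#' Fit a four-parameter logistic (4PL) dose-response curve
#'
#' Least-squares fit of
#' `viability = bottom + (top - bottom) / (1 + (dose/ic50)^hill)`
#' on log-dose via Levenberg-Marquardt, with a multi-start grid over Hill
#' slopes and IC50 decades and box constraints
#' `bottom` in [-0.1, 0.5], `top` in [0.5, 1.2], `hill` in (0.1, 10].
#' The best converged start by residual sum of squares is returned.
#'
#' @param data Data frame with columns `dose_uM` (> 0) and `viability`;
#'   at least 4 distinct doses.
#' @return Object of class `fit_4pl`: `top`, `bottom`, `ic50`, `hill`,
#'   `rss`, `converged`, `n`.
#' @export
fit_4pl <- function(data) {
  dose <- data$dose_uM
  y <- data$viability
  stopifnot(all(dose > 0))
  if (length(unique(dose)) < 4L) {
    stop("Need at least 4 distinct positive doses to fit a 4PL curve.",
         call. = FALSE)
  }
  if (diff(range(y)) < 1e-3) {
    stop("Viability shows no dose dependence; IC50 is unidentifiable.",
         call. = FALSE)
  }
  ld <- log(dose)
  df <- data.frame(ld = ld, y = y)
  starts <- expand.grid(
    hill = c(0.5, 1, 2, 4),
    lic50 = seq(min(ld), max(ld), length.out = 5L)
  )
  lower <- c(top = 0.5, bottom = -0.1, lic50 = min(ld) - log(100), hill = 0.1)
  upper <- c(top = 1.2, bottom = 0.5, lic50 = max(ld) + log(100), hill = 10)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + exp(hill * (ld - lic50))),
        data = df,
        start = list(top = max(min(max(y), 1.2), 0.5),
                     bottom = min(max(min(y), -0.1), 0.5),
                     lic50 = starts$lic50[s], hill = starts$hill[s]),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("4PL fit failed to converge from any start (", nrow(starts),
         " starts tried).", call. = FALSE)
  }
  cf <- stats::coef(best$fit)
  structure(
    list(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
         ic50 = exp(unname(cf["lic50"])), hill = unname(cf["hill"]),
         rss = best$rss, converged = TRUE, n = length(y)),
    class = "fit_4pl"
  )
}

#' Evaluate a 4PL curve
#'
#' @param fit A `fit_4pl` (or any list with `top`, `bottom`, `ic50`, `hill`).
#' @param dose Dose vector (uM).
#' @return Predicted viability.
#' @export
predict_4pl <- function(fit, dose) {
  fit$bottom + (fit$top - fit$bottom) / (1 + (dose / fit$ic50)^fit$hill)
}

#' Invert a 4PL curve: dose producing a given inhibition
#'
#' For an effect expressed as the inhibited fraction of the top-bottom span
#' (IC10 = 0.1, IC20 = 0.2, IC50 = 0.5), the closed-form inverse is
#' `dose = ic50 * (effect / (1 - effect))^(1/hill)`.
#'
#' @param fit A `fit_4pl`.
#' @param effect Fraction inhibited, strictly in (0, 1).
#' @return Dose in uM.
#' @export
invert_4pl <- function(fit, effect) {
  if (any(effect <= 0 | effect >= 1)) {
    stop("effect must lie strictly within (0, 1) of the response span.",
         call. = FALSE)
  }
  fit$ic50 * (effect / (1 - effect))^(1 / fit$hill)
}

#' Construct a median-effect fit from known parameters
#'
#' @param m Median-effect slope.
#' @param dm Median-effect dose Dm (uM, > 0; the dose giving fa = 0.5).
#' @param r_squared Linear fit quality (NA when constructed analytically).
#' @param n_used,n_excluded Point counts (0 when constructed analytically).
#' @return Object of class `median_effect_fit`.
#' @export
median_effect_fit <- function(m, dm, r_squared = NA_real_,
                              n_used = 0L, n_excluded = 0L) {
  stopifnot(dm > 0)
  structure(list(m = m, dm = dm, r_squared = r_squared,
                 n_used = n_used, n_excluded = n_excluded),
            class = "median_effect_fit")
}

#' Fit the median-effect (Chou) model
#'
#' Linear regression of the logit of the affected fraction on log dose:
#' `log(fa / (1 - fa)) = m log D - m log Dm`, where fa = 1 - NCV. Points
#' with fa exactly 0 or 1 carry no information on the logit scale and are
#' excluded with a warning; remaining fa values are clamped into
#' [1e-6, 1 - 1e-6].
#'
#' @param data Data frame with columns `dose_uM` (> 0) and `fa` (affected
#'   fraction in [0, 1]).
#' @return A `median_effect_fit` with slope `m`, median-effect dose `dm`,
#'   `r_squared`, and the used/excluded point counts.
#' @export
fit_median_effect <- function(data) {
  dose <- data$dose_uM
  fa <- data$fa
  stopifnot(all(dose > 0))
  drop_idx <- fa <= 0 | fa >= 1
  if (any(drop_idx)) {
    warning(sum(drop_idx), " point(s) with fa at 0 or 1 excluded from the ",
            "median-effect fit.", call. = FALSE)
  }
  dose <- dose[!drop_idx]
  fa <- pmin(pmax(fa[!drop_idx], 1e-6), 1 - 1e-6)
  if (length(fa) < 3L) {
    stop("Fewer than 3 usable points for the median-effect fit.",
         call. = FALSE)
  }
  fit <- stats::lm(log(fa / (1 - fa)) ~ log(dose))
  m <- unname(stats::coef(fit)[2L])
  b <- unname(stats::coef(fit)[1L])
  median_effect_fit(
    m = m, dm = exp(-b / m),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    n_used = length(fa), n_excluded = sum(drop_idx)
  )
}

#' Dose producing a given affected fraction under the median-effect model
#'
#' `Dx = Dm * (fa / (1 - fa))^(1/m)`; strictly increasing in fa.
#'
#' @param fit A `median_effect_fit`.
#' @param fa Affected fraction(s), strictly in (0, 1).
#' @return Dose(s) in uM.
#' @export
dx_from_median_effect <- function(fit, fa) {
  if (any(fa <= 0 | fa >= 1)) stop("fa must lie strictly in (0, 1).",
                                   call. = FALSE)
  fit$dm * (fa / (1 - fa))^(1 / fit$m)
}
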