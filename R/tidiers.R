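#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted second-order viability model
#'
#' One row per model term with its type (`intercept`, `linear`, `quadratic`,
#' `interaction`) and coefficient estimate.
#'
#' @param x A `qpop_model`.
#' @param ... Unused.
#' @return Tibble `term`, `type`, `estimate`.
#' @method tidy qpop_model
#' @export
tidy.qpop_model <- function(x, ...) {
  f <- x$n_factors
  tibble::tibble(
    term = names(x$coefficients),
    type = rep(c("intercept", "linear", "quadratic", "interaction"),
               c(1L, f, f, f * (f - 1L) / 2L)),
    estimate = unname(x$coefficients)
  )
}

#' @rdname tidy.qpop_model
#' @return `glance` returns a one-row tibble `r_squared`, `sigma`, `n_obs`,
#'   `n_terms`.
#' @method glance qpop_model
#' @export
glance.qpop_model <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, sigma = x$sigma,
                 n_obs = x$n_obs, n_terms = length(x$coefficients))
}

#' Tidy a 4PL dose-response fit
#'
#' @param x A `fit_4pl`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate` for top, bottom, ic50, hill.
#' @method tidy fit_4pl
#' @export
tidy.fit_4pl <- function(x, ...) {
  tibble::tibble(term = c("top", "bottom", "ic50", "hill"),
                 estimate = c(x$top, x$bottom, x$ic50, x$hill))
}

#' @rdname tidy.fit_4pl
#' @method glance fit_4pl
#' @export
glance.fit_4pl <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged, n = x$n)
}

#' Tidy a median-effect fit
#'
#' @param x A `median_effect_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate` for the slope m and median-effect dose.
#' @method tidy median_effect_fit
#' @export
tidy.median_effect_fit <- function(x, ...) {
  tibble::tibble(term = c("m", "dm"), estimate = c(x$m, x$dm))
}

#' @rdname tidy.median_effect_fit
#' @method glance median_effect_fit
#' @export
glance.median_effect_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_used = x$n_used,
                 n_excluded = x$n_excluded)
}

#' Tidy a Bliss result into long form
#'
#' @param x A `bliss_result`.
#' @param ... Unused.
#' @return Tibble `dose_a`, `dose_b`, `observed`, `expected`, `excess`
#'   (all on the percent-inhibition scale).
#' @method tidy bliss_result
#' @export
tidy.bliss_result <- function(x, ...) {
  grid <- expand.grid(dose_a = x$doses_a, dose_b = x$doses_b)
  tibble::tibble(
    dose_a = grid$dose_a, dose_b = grid$dose_b,
    observed = as.vector(x$observed),
    expected = as.vector(x$expected),
    excess = as.vector(x$excess)
  )
}

#' @rdname tidy.bliss_result
#' @method glance bliss_result
#' @export
glance.bliss_result <- function(x, ...) {
  tibble::tibble(score = x$score, classification = x$classification,
                 n_clamped = x$n_clamped)
}

#' Tidy a ROC result
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return The tibble of ROC points (`threshold`, `sensitivity`,
#'   `specificity`).
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$points

#' @rdname tidy.roc_result
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, auc_lo = x$auc_ci[1], auc_hi = x$auc_ci[2],
                 p_value = x$p_value, cutoff = x$cutoff,
                 youden_j = x$youden_j, n_pos = x$n_pos, n_neg = x$n_neg)
}
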