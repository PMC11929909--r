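#' ROC analysis of screening predictions against treatment outcomes
#'
#' Treats PR and SD as the positive (responder) class and uses the negated
#' mean NCV as the classifier score, so lower viability predicts response
#' and AUC >= 0.5 for a concordant screen. The AUC is the Mann-Whitney U
#' statistic with tie correction (concordant pairs plus half ties over
#' `n_pos * n_neg`), the p-value is the two-sided Wilcoxon-Mann-Whitney
#' test comparing NCV between classes, the 95% CI is the Hanley-McNeil
#' normal approximation, and the reported cutoff is the NCV threshold
#' maximizing Youden's J over midpoints between adjacent distinct values.
#'
#' @param outcomes Data frame with columns `mean_ncv` and `recist`
#'   (`"PR"`, `"SD"` or `"PD"`).
#' @return A list of class `roc_result`: `points` (tibble `threshold`,
#'   `sensitivity`, `specificity`), `auc`, `auc_ci` (length 2), `p_value`,
#'   `cutoff`, `youden_j`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(outcomes) {
  ncv <- outcomes$mean_ncv
  pos <- outcomes$recist %in% c("PR", "SD")
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("ROC analysis needs both responder (PR/SD) and non-responder (PD) ",
         "outcomes.", call. = FALSE)
  }
  score <- -ncv
  # Mann-Whitney AUC with tie correction via midranks
  r <- rank(score)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  p_value <- suppressWarnings(
    stats::wilcox.test(ncv[pos], ncv[!pos], alternative = "two.sided")$p.value
  )
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  auc_ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  # empirical ROC over NCV midpoint thresholds: call responder when ncv < t
  v <- sort(unique(ncv))
  thresholds <- c(v[1L] - 1, (utils::head(v, -1L) + utils::tail(v, -1L)) / 2,
                  v[length(v)] + 1)
  points <- purrr::map_dfr(thresholds, function(t) {
    tibble::tibble(
      threshold = t,
      sensitivity = mean(ncv[pos] < t),
      specificity = mean(ncv[!pos] >= t)
    )
  })
  j <- points$sensitivity + points$specificity - 1
  best <- which.max(j)
  structure(
    list(points = points, auc = auc, auc_ci = auc_ci, p_value = p_value,
         cutoff = points$threshold[best], youden_j = j[best],
         n_pos = n1, n_neg = n0),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC: AUC ", formatC(x$auc, digits = 3, format = "f"),
      " (95% CI ", formatC(x$auc_ci[1], digits = 3, format = "f"), "-",
      formatC(x$auc_ci[2], digits = 3, format = "f"), "), p = ",
      format.pval(x$p_value, digits = 3), ", NCV cutoff ",
      formatC(x$cutoff, digits = 4, format = "f"), "\n", sep = "")
  invisible(x)
}

#' Responder contingency analysis of a 2x2 outcome table
#'
#' Rows are the screen's call (responder / non-responder), columns the
#' clinical outcome (PR or SD / PD): `a` = called responder and PR/SD,
#' `b` = called responder but PD, `c` = called non-responder but PR/SD,
#' `d` = called non-responder and PD. Reports the sample odds ratio
#' `ad/bc`, a Woolf logit 95% CI (Haldane 0.5 correction on zero cells;
#' a conditional-MLE alternative is available), the two-sided Fisher exact
#' p (sum of hypergeometric point probabilities no larger than the observed
#' table's), total predictive value `(a+d)/N`, sensitivity `a/(a+c)` and
#' specificity `d/(b+d)`.
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @param or_method `"woolf"` (default) or `"cmle"` (conditional maximum
#'   likelihood via [stats::fisher.test()]).
#' @return One-row tibble with the counts, `odds_ratio`, `or_lo`, `or_hi`,
#'   `fisher_p`, `tpv`, `tpv_pct`, `sensitivity`, `specificity`.
#' @export
contingency_analysis <- function(a, b, c, d, or_method = c("woolf", "cmle")) {
  or_method <- match.arg(or_method)
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("Cell counts must be nonnegative integers.", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("All-zero contingency table.", call. = FALSE)
  odds_ratio <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  if (or_method == "woolf") {
    cc <- if (any(counts == 0)) counts + 0.5 else counts
    lor <- log((cc[1] * cc[4]) / (cc[2] * cc[3]))
    se <- sqrt(sum(1 / cc))
    ci <- exp(lor + c(-1, 1) * stats::qnorm(0.975) * se)
  } else {
    ft <- stats::fisher.test(matrix(counts, 2L, byrow = TRUE))
    ci <- ft$conf.int
  }
  fisher_p <- fisher_exact_p(a, b, c, d)
  tpv <- (a + d) / n
  tibble::tibble(
    a = as.integer(a), b = as.integer(b), c = as.integer(c), d = as.integer(d),
    odds_ratio = odds_ratio, or_lo = ci[1], or_hi = ci[2],
    fisher_p = fisher_p,
    tpv = tpv, tpv_pct = round(100 * tpv, 1),
    sensitivity = a / (a + c), specificity = d / (b + d)
  )
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Conditions on both margins and sums the hypergeometric point
#' probabilities of every table at most as probable as the observed one
#' (within a 1e-7 relative tolerance), the standard two-sided convention.
#'
#' @inheritParams contingency_analysis
#' @return The exact p-value.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  row1 <- a + b; row2 <- c + d; col1 <- a + c
  x <- max(0L, col1 - row2):min(col1, row1)
  probs <- stats::dhyper(x, row1, row2, col1)
  p_obs <- stats::dhyper(a, row1, row2, col1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Outcome class proportions
#'
#' @param outcomes Data frame with a `recist` column (`PR`, `SD`, `PD`).
#' @return Tibble `recist`, `n`, `pct` (one decimal; NA on empty input).
#' @export
outcome_proportions <- function(outcomes) {
  classes <- c("PR", "SD", "PD")
  n <- unname(vapply(classes, function(cl) sum(outcomes$recist == cl),
                     integer(1L)))
  total <- sum(n)
  tibble::tibble(
    recist = classes,
    n = n,
    pct = if (total == 0) rep(NA_real_, 3L) else round(100 * n / total, 1)
  )
}

#' Top-combination frequencies across a cohort
#'
#' Counts, for every drug pair, how many samples include that pair in their
#' top-`top_k` unique two-drug combinations, and for every single drug how
#' many top-`top_k` pairs it appears in summed over samples (the upset-plot
#' inputs of a cohort summary figure).
#'
#' @param rankings List of two-drug `qpop_ranking` objects, one per sample.
#' @param top_k Pairs considered per sample (default 10).
#' @return A list of class `cohort_aggregate`: `pair_counts` (tibble
#'   `drug1`, `drug2`, `therapy`, `n`, `pct` of samples, sorted descending),
#'   `drug_counts` (tibble `drug`, `n`), `n_samples`, `top_k`.
#' @export
top_combo_frequencies <- function(rankings, top_k = 10L) {
  stopifnot(length(rankings) >= 1L)
  tops <- purrr::map_dfr(seq_along(rankings), function(i) {
    top <- utils::head(tibble::as_tibble(rankings[[i]]), top_k)
    tibble::tibble(sample = i,
                   drug1 = pmin(top$drug1, top$drug2),
                   drug2 = pmax(top$drug1, top$drug2))
  })
  n_samples <- length(rankings)
  pair_counts <- dplyr::arrange(
    dplyr::summarise(dplyr::group_by(tops, .data$drug1, .data$drug2),
                     n = dplyr::n_distinct(.data$sample), .groups = "drop"),
    dplyr::desc(.data$n), .data$drug1, .data$drug2
  )
  pair_counts$therapy <- paste(pair_counts$drug1, pair_counts$drug2,
                               sep = " + ")
  pair_counts$pct <- round(100 * pair_counts$n / n_samples, 1)
  drug_counts <- dplyr::arrange(
    dplyr::count(
      tidyr::pivot_longer(tops, c("drug1", "drug2"), values_to = "drug"),
      .data$drug, name = "n"),
    dplyr::desc(.data$n), .data$drug
  )
  structure(
    list(pair_counts = pair_counts[, c("therapy", "drug1", "drug2", "n", "pct")],
         drug_counts = drug_counts,
         n_samples = n_samples, top_k = as.integer(top_k)),
    class = "cohort_aggregate"
  )
}

#' One-drug versus two-drug NCV correlation per drug
#'
#' For each drug, pools points across samples and across that drug's
#' appearances in each sample's top-`top_k` two-drug combinations: x = the
#' drug's single-agent mean NCV in that sample, y = the pair's mean NCV.
#' Pearson correlation with a two-sided t-test p-value is reported per drug
#' with at least 3 points; drugs with fewer points are skipped.
#'
#' @param models List of fitted `qpop_model` objects, one per sample (or
#'   `qpop_ranking`s carrying their models).
#' @param top_k Pairs considered per sample (default 20).
#' @return Tibble `drug`, `r`, `p_value`, `n`.
#' @export
one_vs_two_drug_correlation <- function(models, top_k = 20L) {
  models <- purrr::map(models, function(m) {
    if (inherits(m, "qpop_ranking")) attr(m, "model") else m
  })
  pts <- purrr::map_dfr(models, function(m) {
    r1 <- rank_combinations(m, order = 1L)
    one <- stats::setNames(r1$mean_ncv, r1$drug1)
    r2 <- utils::head(rank_combinations(m, order = 2L), top_k)
    tibble::tibble(
      drug = c(r2$drug1, r2$drug2),
      one_drug_ncv = one[c(r2$drug1, r2$drug2)],
      two_drug_ncv = rep(r2$mean_ncv, 2L)
    )
  })
  purrr::map_dfr(split(pts, pts$drug), function(g) {
    if (nrow(g) < 3L) return(NULL)
    ct <- stats::cor.test(g$one_drug_ncv, g$two_drug_ncv, method = "pearson")
    tibble::tibble(drug = g$drug[1L], r = unname(ct$estimate),
                   p_value = ct$p.value, n = nrow(g))
  })
}

#' Two-sided Student's t comparison of group means
#'
#' Equal-variance two-sample or paired Student's t-test (Welch available via
#' `var_equal = FALSE`). Degenerate zero-variance inputs follow the
#' conventions: equal constant groups give t = 0, p = 1; a constant nonzero
#' difference gives p = 0 and is flagged degenerate.
#'
#' @param values_a,values_b Numeric vectors (equal length when paired).
#' @param paired Paired test? Default `FALSE`.
#' @param var_equal Pool variances (classic Student's t)? Default `TRUE`.
#' @return One-row tibble `t`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `degenerate`.
#' @export
group_mean_comparison <- function(values_a, values_b, paired = FALSE,
                                  var_equal = TRUE) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  if (paired && length(values_a) != length(values_b)) {
    stop("Paired comparison needs equal-length groups.", call. = FALSE)
  }
  degenerate <- if (paired) {
    stats::sd(values_a - values_b) == 0
  } else {
    stats::sd(values_a) == 0 && stats::sd(values_b) == 0
  }
  if (degenerate) {
    equal <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    return(tibble::tibble(
      t = if (equal) 0 else sign(mean(values_a) - mean(values_b)) * Inf,
      df = NA_real_, p_value = if (equal) 1 else 0,
      mean_a = mean(values_a), mean_b = mean(values_b), degenerate = TRUE
    ))
  }
  tt <- stats::t.test(values_a, values_b, paired = paired,
                      var.equal = var_equal, alternative = "two.sided")
  tibble::tibble(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, mean_a = mean(values_a), mean_b = mean(values_b),
    degenerate = FALSE
  )
}

#' Ellipsoid tumor volume from caliper diameters
#'
#' `V = pi/6 * A^2 * B` with A the smallest and B the largest superficial
#' diameter (cm), giving volume in cm^3.
#'
#' @param a_cm Smallest superficial diameter (cm, > 0).
#' @param b_cm Largest superficial diameter (cm, >= a_cm).
#' @return Volume in cm^3 (vectorized).
#' @export
tumor_volume <- function(a_cm, b_cm) {
  if (any(a_cm <= 0)) stop("Diameters must be positive.", call. = FALSE)
  if (any(a_cm > b_cm)) {
    stop("A must be the smallest diameter (A <= B).", call. = FALSE)
  }
  pi / 6 * a_cm^2 * b_cm
}

#' Tumor growth rate over a treatment course
#'
#' `(v_last - v_first) / days`, in mm^3 per day; negative under shrinkage.
#'
#' @param v_first,v_last First and last measured volumes (mm^3).
#' @param days Total treatment days (> 0).
#' @return Growth rate in mm^3/day (vectorized).
#' @export
growth_rate <- function(v_first, v_last, days) {
  if (any(days <= 0)) stop("days must be positive.", call. = FALSE)
  (v_last - v_first) / days
}
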