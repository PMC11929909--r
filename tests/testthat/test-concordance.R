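make_outcomes <- function(ncv, pos) {
  tibble::tibble(case_id = sprintf("C%02d", seq_along(ncv)),
                 therapy = "x + y",
                 mean_ncv = ncv,
                 recist = ifelse(pos, "PR", "PD"))
}

test_that("AUC equals brute-force pair counting on random datasets", {
  set.seed(123)
  for (i in 1:50) {
    n <- sample(8:25, 1)
    # discrete support induces ties
    ncv <- sample(seq(0.5, 1, by = 0.05), n, replace = TRUE)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    r <- roc_analysis(make_outcomes(ncv, pos))
    expect_equal(r$auc, oracle_auc(-ncv, pos), tolerance = 1e-12)
  }
})

test_that("AUC from ranks equals the trapezoidal area under the empirical ROC", {
  set.seed(7)
  ncv <- round(stats::runif(30, 0.5, 1), 2)
  pos <- stats::runif(30) < 0.5
  r <- roc_analysis(make_outcomes(ncv, pos))
  pts <- r$points[order(1 - r$points$specificity, r$points$sensitivity), ]
  x <- 1 - pts$specificity; y <- pts$sensitivity
  trap <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  expect_equal(r$auc, trap, tolerance = 1e-12)
})

test_that("ROC handles separation, exchangeable scores, and cross-checks pROC", {
  # perfect separation
  r <- roc_analysis(make_outcomes(c(0.6, 0.65, 0.7, 0.9, 0.95, 1.0),
                                  c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)))
  expect_equal(r$auc, 1)
  expect_equal(r$youden_j, 1)
  expect_gt(r$cutoff, 0.7); expect_lt(r$cutoff, 0.9)
  # identical score distributions across classes
  r2 <- roc_analysis(make_outcomes(rep(c(0.7, 0.8, 0.9), 4),
                                   rep(c(TRUE, FALSE), 6)))
  expect_equal(r2$auc, 0.5)
  # independent implementation agreement
  set.seed(31)
  ncv <- stats::runif(40, 0.4, 1)
  pos <- stats::runif(40) < 0.45
  r3 <- roc_analysis(make_outcomes(ncv, pos))
  proc_auc <- as.numeric(pROC::auc(pROC::roc(
    response = pos, predictor = -ncv, levels = c(FALSE, TRUE),
    direction = "<", quiet = TRUE)))
  expect_equal(r3$auc, proc_auc, tolerance = 1e-12)
  expect_error(roc_analysis(make_outcomes(c(0.7, 0.8), c(TRUE, TRUE))),
               "both responder")
})

test_that("the responder contingency table reproduces the published statistics", {
  cc <- contingency_analysis(12, 2, 4, 9)
  expect_equal(cc$odds_ratio, 13.5)
  expect_equal(cc$fisher_p, 0.0063, tolerance = 0.01)
  expect_equal(cc$tpv, 21 / 27)
  expect_equal(cc$tpv_pct, 77.8)
  expect_equal(cc$sensitivity, 12 / 16)
  expect_equal(cc$specificity, 9 / 11)
  # symmetric table: no association
  s <- contingency_analysis(5, 5, 5, 5)
  expect_equal(s$odds_ratio, 1)
  expect_equal(s$fisher_p, 1)
  # zero-cell handling
  z <- contingency_analysis(8, 0, 2, 7)
  expect_equal(z$odds_ratio, Inf)
  expect_true(is.finite(z$or_lo) && is.finite(z$or_hi))
  # conditional-MLE interval option
  cm <- contingency_analysis(12, 2, 4, 9, or_method = "cmle")
  expect_lt(cm$or_lo, cm$or_hi)
  expect_error(contingency_analysis(0, 0, 0, 0), "All-zero")
})

test_that("Fisher p matches complete enumeration and stats::fisher.test", {
  set.seed(55)
  for (i in 1:20) {
    tab <- sample(0:12, 4, replace = TRUE)
    if (sum(tab) == 0) next
    p <- fisher_exact_p(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p, oracle_fisher(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-10)
    ft <- stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
    expect_equal(p, ft, tolerance = 1e-7)
  }
})

test_that("outcome proportions match published rounding conventions", {
  out <- make_outcomes(rep(0.8, 27), rep(TRUE, 27))
  out$recist <- rep(c("PR", "SD", "PD"), c(7, 9, 11))
  pr <- outcome_proportions(out)
  expect_equal(pr$n, c(7L, 9L, 11L))
  expect_equal(pr$pct, c(25.9, 33.3, 40.7))
  empty <- outcome_proportions(out[0, ])
  expect_equal(empty$n, c(0L, 0L, 0L))
  expect_true(all(is.na(empty$pct)))
  solo <- outcome_proportions(out[out$recist == "PR", ])
  expect_equal(solo$pct, c(100, 0, 0))
})

test_that("top-combination frequencies match a brute-force recount", {
  set.seed(77)
  models <- lapply(1:4, function(s) {
    truth <- gen_ground_truth(12, planted_pairs = list(c(9, 11)),
                              noise_sd = 0.02, seed = 200 + s)
    fit_pipeline(truth, seed = 300 + s)
  })
  rankings <- lapply(models, rank_combinations, order = 2)
  agg <- top_combo_frequencies(rankings, top_k = 10)
  # the planted pair is in every sample's top 10
  planted <- sort(panel12$drug[c(9, 11)])
  hit <- agg$pair_counts[agg$pair_counts$drug1 == planted[1] &
                           agg$pair_counts$drug2 == planted[2], ]
  expect_equal(hit$n, 4L)
  expect_equal(hit$pct, 100)
  # brute-force recount of pair and single-drug appearances
  recount_pairs <- list(); recount_drug <- integer(0)
  for (r in rankings) {
    top <- utils::head(as.data.frame(r), 10)
    for (i in seq_len(nrow(top))) {
      key <- paste(sort(c(top$drug1[i], top$drug2[i])), collapse = "|")
      recount_pairs[[key]] <- c(recount_pairs[[key]], 1L)
      for (dg in c(top$drug1[i], top$drug2[i])) {
        recount_drug[dg] <- sum(recount_drug[dg], 1L, na.rm = TRUE)
      }
    }
  }
  for (i in seq_len(nrow(agg$pair_counts))) {
    key <- paste(agg$pair_counts$drug1[i], agg$pair_counts$drug2[i], sep = "|")
    expect_equal(agg$pair_counts$n[i], length(recount_pairs[[key]]))
  }
  for (i in seq_len(nrow(agg$drug_counts))) {
    expect_equal(agg$drug_counts$n[i],
                 unname(recount_drug[agg$drug_counts$drug[i]]))
  }
  # a drug appears at least as often as any pair containing it
  expect_true(all(agg$pair_counts$n <= agg$n_samples))
  for (i in seq_len(nrow(agg$pair_counts))) {
    for (dg in c(agg$pair_counts$drug1[i], agg$pair_counts$drug2[i])) {
      expect_gte(agg$drug_counts$n[agg$drug_counts$drug == dg],
                 agg$pair_counts$n[i])
    }
  }
})

test_that("one- vs two-drug correlation detects exact affine structure", {
  # samples where every drug shares one sensitivity: two-drug NCV is an
  # affine function of one-drug NCV, so pooled r = 1 for every drug
  models <- lapply(c(-0.02, -0.05, -0.08, -0.11), function(mu) {
    toy_model(beta_lin = rep(mu, 4))
  })
  res <- one_vs_two_drug_correlation(models, top_k = 6)
  expect_equal(nrow(res), 4L)
  expect_equal(res$r, rep(1, 4), tolerance = 1e-12)
  expect_equal(res$n, rep(12L, 4)) # 6 pairs x 2 ends, 4 samples, per drug: 3*4
})

test_that("pooled Pearson r matches a direct formula computation", {
  set.seed(41)
  models <- lapply(1:3, function(s) {
    toy_model(beta_lin = stats::runif(5, -0.12, 0),
              beta_int = stats::runif(10, -0.02, 0.02))
  })
  res <- one_vs_two_drug_correlation(models, top_k = 5)
  # rebuild the pooled point set by explicit loops and compare r per drug
  pts <- list()
  for (m in models) {
    one <- oracle_rank(m, 1)
    two <- utils::head(oracle_rank(m, 2), 5)
    one_ncv <- stats::setNames(one$mean_ncv, one$therapy)
    for (i in seq_len(nrow(two))) {
      for (dg in strsplit(two$therapy[i], " \\+ ")[[1]]) {
        pts[[dg]] <- rbind(pts[[dg]], c(one_ncv[[dg]], two$mean_ncv[i]))
      }
    }
  }
  for (i in seq_len(nrow(res))) {
    p <- pts[[res$drug[i]]]
    r_direct <- stats::cov(p[, 1], p[, 2]) / (stats::sd(p[, 1]) * stats::sd(p[, 2]))
    expect_equal(res$r[i], r_direct, tolerance = 1e-10)
    expect_equal(res$n[i], nrow(p))
  }
})

test_that("group mean comparison matches the pooled-variance t formula", {
  x <- c(5.1, 4.8, 6.0, 5.5, 5.9)
  y <- c(4.2, 4.9, 4.4, 5.0, 4.1)
  got <- group_mean_comparison(x, y)
  want <- oracle_t(x, y)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  same <- group_mean_comparison(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  # paired, constant nonzero difference: flagged degenerate with p -> 0
  deg <- group_mean_comparison(x, x + 1, paired = TRUE)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 0)
  expect_error(group_mean_comparison(x, y[1:3], paired = TRUE),
               "equal-length")
})

test_that("tumor volume and growth rate follow their closed forms", {
  expect_equal(tumor_volume(1, 2), pi / 3)
  expect_equal(tumor_volume(1, 1), pi / 6)
  expect_equal(tumor_volume(2, 4) / tumor_volume(1, 2), 8)
  expect_error(tumor_volume(2, 1), "smallest")
  expect_error(tumor_volume(0, 1), "positive")
  expect_equal(growth_rate(100, 400, 15), 20)
  expect_equal(growth_rate(250, 250, 10), 0)
  expect_lt(growth_rate(400, 100, 15), 0)
  expect_error(growth_rate(100, 200, 0), "positive")
})

test_that("the recovered NCV cutoff concentrates near the generating threshold", {
  cuts <- rep(NA_real_, 200)
  for (s in 1:200) {
    co <- simulate_cohort(3, n_outcomes = 27, seed = s)
    lab <- co$outcomes$recist %in% c("PR", "SD")
    if (length(unique(lab)) < 2) next
    cuts[s] <- roc_analysis(co$outcomes)$cutoff
  }
  expect_lt(abs(stats::median(cuts, na.rm = TRUE) - 0.8), 0.05)
})
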