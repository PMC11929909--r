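test_that("noiseless plates on the composite design recover all 91 coefficients", {
  truth <- gen_ground_truth(12, planted_pairs = list(c(9, 11)),
                            noise_sd = 0, seed = 31)
  model <- fit_pipeline(truth, seed = 32)
  expect_lt(max(abs(model$coefficients - truth_coefficients(truth))), 1e-8)
  # exact fit interpolates: prediction at design rows equals the observed NCV
  lv <- design_levels(design12)
  ncv <- viability_summary(normalize_plate(
    simulate_plate(truth, design12, seed = 32)))
  expect_lt(max(abs(predict_ncv(model, lv) - ncv$mean_ncv)), 1e-10)
})

test_that("constant viability fits to an intercept-only model", {
  v <- tibble::tibble(run_id = rep(design12$run_id, each = 2),
                      replicate = rep(1:2, 155), ncv = 0.8)
  m <- fit_quadratic(v, design12)
  expect_equal(m$beta0, 0.8, tolerance = 1e-12)
  expect_lt(max(abs(m$coefficients[-1])), 1e-12)
})

test_that("balanced replicates and run means give identical coefficients", {
  truth <- gen_ground_truth(12, noise_sd = 0.03, seed = 41)
  plate <- simulate_plate(truth, design12, seed = 42)
  v_rep <- normalize_plate(plate) # 310 observations
  m_rep <- fit_quadratic(v_rep, design12)
  v_mean <- viability_summary(v_rep)
  m_mean <- fit_quadratic(
    tibble::tibble(run_id = v_mean$run_id, replicate = 1L,
                   ncv = v_mean$mean_ncv),
    design12)
  expect_lt(max(abs(m_rep$coefficients - m_mean$coefficients)), 1e-10)
  # missing runs are rejected
  expect_error(fit_quadratic(v_rep[v_rep$run_id != 5, ], design12),
               "without viability")
})

test_that("prediction matches a term-by-term polynomial oracle", {
  truth <- gen_ground_truth(12, noise_sd = 0.02, seed = 51)
  model <- fit_pipeline(truth, seed = 52)
  set.seed(99)
  for (i in 1:100) {
    x <- stats::runif(12, 0, 2)
    expect_equal(predict_ncv(model, x), oracle_poly(model, x),
                 tolerance = 1e-10)
  }
  expect_equal(predict_ncv(model, rep(0, 12)), model$beta0)
  expect_error(predict_ncv(model, rep(0, 5)), "factors")
})

test_that("enumeration counts and hand-computed means are exact", {
  # F = 12, order 2: 66 unique pairs x 4 dose permutations
  m0 <- toy_model(beta_lin = rep(0, 12))
  r <- rank_combinations(m0, order = 2)
  expect_equal(nrow(r), 66L)
  expect_equal(nrow(attr(r, "permutations")), 264L)
  # linear-only effects on A and B: mean pair NCV = 1 - 0.1 * mean(2,3,3,4)
  m1 <- toy_model(beta_lin = c(-0.1, -0.1, rep(0, 10)))
  r1 <- rank_combinations(m1, order = 2)
  expect_equal(r1$mean_ncv[r1$therapy == "A + B"], 0.7)
  expect_equal(r1$rank[r1$therapy == "A + B"], 1L)
  # single-agent summary: mean over levels {1,2} of 1 - 0.1 x
  s <- therapy_summary(m1, list("A"))
  expect_equal(s$mean_ncv, 0.85)
  # SD over permutations is 0 when the model is flat in that drug
  s0 <- therapy_summary(m1, list("C"))
  expect_equal(s0$sd_ncv, 0)
  expect_error(therapy_summary(m1, list("Z")), "Unknown drug")
  expect_error(rank_combinations(m1, order = 13), "exceeds")
})

test_that("ranking agrees with exhaustive brute-force enumeration", {
  truth <- gen_ground_truth(12, planted_pairs = list(c(3, 7)),
                            noise_sd = 0.02, seed = 61)
  model <- fit_pipeline(truth, seed = 62)
  for (ord in 1:2) {
    got <- rank_combinations(model, order = ord)
    want <- oracle_rank(model, ord)
    expect_identical(got$therapy, want$therapy)
    expect_equal(got$mean_ncv, want$mean_ncv, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # the planted synergistic pair tops the two-drug ranking
  r2 <- rank_combinations(model, order = 2)
  expect_setequal(c(r2$drug1[1], r2$drug2[1]), panel12$drug[c(3, 7)])
  # therapy_summary is consistent with the ranking entries
  th <- therapy_summary(model, list(c(r2$drug1[1], r2$drug2[1])))
  expect_equal(th$mean_ncv, r2$mean_ncv[1])
  expect_equal(th$sd_ncv, r2$sd_ncv[1])
})

test_that("predictions are invariant to affine recoding of the levels", {
  truth <- gen_ground_truth(12, noise_sd = 0.01, seed = 71)
  plate <- simulate_plate(truth, design12, seed = 72)
  viab <- normalize_plate(plate)
  m_orig <- fit_quadratic(viab, design12)
  # recode {0,1,2} -> {-1,0,1}: same quadratic model space
  recoded <- design12
  for (col in grep("^x", names(recoded), value = TRUE)) {
    recoded[[col]] <- recoded[[col]] - 1
  }
  m_rec <- fit_quadratic(viab, recoded)
  enum <- as.matrix(expand.grid(rep(list(0:2), 2)))
  for (i in seq_len(nrow(enum))) {
    x <- c(enum[i, ], rep(0, 10))
    expect_equal(predict_ncv(m_orig, x), predict_ncv(m_rec, x - 1),
                 tolerance = 1e-10)
  }
})

test_that("response-surface grids agree with point predictions", {
  truth <- gen_ground_truth(12, planted_pairs = list(c(1, 2)),
                            noise_sd = 0, seed = 81)
  model <- fit_pipeline(truth, seed = 82)
  g <- rsm_grid(model, c("ifosfamide", "doxorubicin"), grid_n = 5)
  expect_equal(nrow(g), 25L)
  # corner (0,0) is the intercept
  expect_equal(g$ncv[g$level_a == 0 & g$level_b == 0], model$beta0)
  # corner (2,2) equals the full-length prediction
  x <- rep(0, 12); x[1:2] <- 2
  expect_equal(g$ncv[g$level_a == 2 & g$level_b == 2], predict_ncv(model, x))
  # negative interaction with non-positive linear terms: deeper along diagonal
  expect_lt(g$ncv[g$level_a == 2 & g$level_b == 2],
            g$ncv[g$level_a == 1 & g$level_b == 1])
  expect_error(rsm_grid(model, c("ifosfamide", "ifosfamide")), "distinct")
  tmp <- tempfile(fileext = ".csv")
  write_rsm_matrix(g, tmp)
  wide <- readr::read_csv(tmp, show_col_types = FALSE)
  expect_equal(dim(wide), c(5L, 6L))
})

test_that("sample reports are complete and regenerate byte-identically", {
  truth <- gen_ground_truth(12, planted_pairs = list(c(9, 11)),
                            noise_sd = 0.02, seed = 91)
  plate <- simulate_plate(truth, design12, seed = 92)
  model <- fit_quadratic(normalize_plate(plate), design12, drugs = panel12$drug)
  ranking <- rank_combinations(model, order = 2)
  qc <- plate_qc(plate)
  rep1 <- sample_report(ranking, qc, panel12, top_k = 10, sample_id = "S001",
                        named_therapies = list(c("ifosfamide", "doxorubicin")))
  expect_equal(nrow(rep1$top_combinations), 10L)
  expect_equal(nrow(rep1$one_drug_ranking), 12L)
  expect_equal(sort(rep1$one_drug_ranking$rank), 1:12)
  expect_equal(rep1$named_therapies$therapy, "ifosfamide + doxorubicin")
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_sample_report(rep1, f1)
  write_sample_report(
    sample_report(ranking, qc, panel12, top_k = 10, sample_id = "S001",
                  named_therapies = list(c("ifosfamide", "doxorubicin"))),
    f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("model tidiers expose terms and diagnostics", {
  truth <- gen_ground_truth(12, noise_sd = 0.02, seed = 95)
  model <- fit_pipeline(truth, seed = 96)
  td <- tidy(model)
  expect_equal(nrow(td), 91L)
  expect_equal(as.integer(table(td$type)[c("linear", "quadratic", "interaction")]),
               c(12L, 12L, 66L))
  gl <- glance(model)
  expect_equal(gl$n_obs, 310L)
  expect_gt(gl$r_squared, 0.9)
})
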