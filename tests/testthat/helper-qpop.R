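# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive (explicit loops, closed forms) and share no
# code with the implementation paths they check.

design12 <- build_oacd(12)
panel12 <- default_panel()

# assemble a qpop_model directly from known coefficient blocks
toy_model <- function(beta_lin, beta_quad = NULL, beta_int = NULL,
                      beta0 = 1, drugs = NULL) {
  f <- length(beta_lin)
  if (is.null(beta_quad)) beta_quad <- rep(0, f)
  if (is.null(beta_int)) beta_int <- rep(0, f * (f - 1) / 2)
  if (is.null(drugs)) drugs <- LETTERS[seq_len(f)]
  coefs <- c(beta0, beta_lin, beta_quad, beta_int)
  names(coefs) <- colnames(quadratic_basis(matrix(0, 1, f), names = drugs))
  structure(
    list(coefficients = coefs, beta0 = beta0,
         beta_lin = stats::setNames(beta_lin, drugs),
         beta_quad = stats::setNames(beta_quad, paste0(drugs, "^2")),
         beta_int = beta_int, drugs = drugs, n_factors = f,
         r_squared = NA_real_, sigma = NA_real_, n_obs = 0L),
    class = "qpop_model")
}

# term-by-term second-order polynomial evaluation, explicit loops
oracle_poly <- function(model, x) {
  f <- model$n_factors
  y <- model$beta0
  for (i in seq_len(f)) {
    y <- y + model$beta_lin[[i]] * x[i] + model$beta_quad[[i]] * x[i]^2
  }
  k <- 0L
  for (i in seq_len(f - 1)) {
    for (j in (i + 1):f) {
      k <- k + 1L
      y <- y + model$beta_int[[k]] * x[i] * x[j]
    }
  }
  unname(y)
}

# exhaustive enumeration of order-k therapies ranked by mean NCV
oracle_rank <- function(model, order) {
  f <- model$n_factors
  combos <- utils::combn(f, order)
  rows <- list()
  for (j in seq_len(ncol(combos))) {
    ix <- combos[, j]
    lv_sets <- as.matrix(expand.grid(rep(list(1:2), order)))
    preds <- numeric(nrow(lv_sets))
    for (p in seq_len(nrow(lv_sets))) {
      x <- rep(0, f)
      x[ix] <- lv_sets[p, ]
      preds[p] <- oracle_poly(model, x)
    }
    rows[[j]] <- data.frame(
      therapy = paste(model$drugs[ix], collapse = " + "),
      mean_ncv = mean(preds), i1 = ix[1],
      i2 = if (order >= 2) ix[2] else NA_integer_,
      i3 = if (order >= 3) ix[3] else NA_integer_)
  }
  df <- do.call(rbind, rows)
  df[order(df$mean_ncv, df$i1, df$i2, df$i3), ]
}

# AUC by explicit pair counting: concordant pairs + half ties
oracle_auc <- function(score, positive) {
  sp <- score[positive]; sn <- score[!positive]
  tot <- 0
  for (i in seq_along(sp)) {
    for (j in seq_along(sn)) {
      tot <- tot + if (sp[i] > sn[j]) 1 else if (sp[i] == sn[j]) 0.5 else 0
    }
  }
  tot / (length(sp) * length(sn))
}

# two-sided Fisher exact p by complete enumeration over tables with the
# observed margins, using binomial coefficients directly
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  p_of <- function(x) choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  p_obs <- p_of(a)
  tot <- 0
  for (x in max(0, c1 - r2):min(c1, r1)) {
    px <- p_of(x)
    if (px <= p_obs * (1 + 1e-7)) tot <- tot + px
  }
  tot
}

# Student's t from the textbook pooled-variance formula
oracle_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df))
}

# simulate -> normalize -> fit -> rank on the shared 12-factor design
fit_pipeline <- function(truth, seed) {
  plate <- simulate_plate(truth, design12, seed = seed)
  fit_quadratic(normalize_plate(plate), design12, drugs = panel12$drug)
}
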