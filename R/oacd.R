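#' Orthogonal array composite design (OACD) construction
#'
#' Builds the run plan used for combinatorial drug screening: a two-level
#' resolution-IV fractional factorial at the extreme coded levels \{0, 2\}
#' for factor screening, stacked on a three-level orthogonal array at coded
#' levels \{0, 1, 2\} that supplies the curvature information needed to fit a
#' full second-order (quadratic) response model. For the registered 12-factor
#' configuration this is a 2^(12-5) fractional factorial (128 runs) plus the
#' first 12 columns of the canonical L27(3^13) array (27 runs), 155 runs in
#' total, and the 91-term quadratic basis evaluated on those runs has full
#' column rank.
#'
#' Coded levels 0/1/2 correspond to the IC0/IC10/IC20 doses of each drug;
#' regression is performed on the codes, so unequal dose spacing between
#' drugs is absorbed by the coding.
#'
#' @param n_factors Number of three-level factors (drugs). Only 12 is
#'   registered; other counts error.
#'
#' @return A tibble of class `oacd_design` with columns `run_id`, `portion`
#'   (`"two_level_factorial"` or `"three_level_oa"`), and one coded-level
#'   column per factor (`x01` ... `x12`).
#' @export
#' @examples
#' design <- build_oacd(12)
#' nrow(design) # 155
build_oacd <- function(n_factors = 12) {
  if (!identical(as.integer(n_factors), 12L)) {
    stop("Unsupported factor count ", n_factors,
         ": only the 12-factor OACD (2^(12-5) + L27) is registered.",
         call. = FALSE)
  }
  ff <- .ff_2_12_5()          # 128 x 12, bits in {0,1}
  oa <- .l27_array()[, 1:12]  # 27 x 12, levels in {0,1,2}
  levels <- rbind(ff * 2L, oa)
  colnames(levels) <- sprintf("x%02d", seq_len(12L))
  out <- tibble::as_tibble(as.data.frame(levels))
  out <- tibble::add_column(
    out,
    run_id = seq_len(nrow(levels)),
    portion = rep(c("two_level_factorial", "three_level_oa"), c(128L, 27L)),
    .before = 1L
  )
  class(out) <- c("oacd_design", class(out))
  out
}

# Generator words of the 2^(12-5) resolution-IV fraction, fixed constants.
# Base factors 1..7 (full 2^7); added factors 8..12 are defined by
#   x8 = x1*x2*x3*x4, x9 = x1*x2*x3*x5, x10 = x1*x4*x5*x6,
#   x11 = x2*x4*x6*x7, x12 = x3*x5*x6*x7   (mod-2 bit arithmetic).
# This set was selected by exhaustive minimum-aberration search over all
# length-4 generator words: every word of the defining contrast subgroup has
# length >= 4 (resolution IV) and only one word has length exactly 4.
.oacd_generators <- list(
  c(1L, 2L, 3L, 4L),
  c(1L, 2L, 3L, 5L),
  c(1L, 4L, 5L, 6L),
  c(2L, 4L, 6L, 7L),
  c(3L, 5L, 6L, 7L)
)

.ff_2_12_5 <- function() {
  base <- as.matrix(expand.grid(rep(list(0:1), 7L)))[, 7:1, drop = FALSE]
  storage.mode(base) <- "integer"
  added <- vapply(.oacd_generators, function(w) {
    as.integer(rowSums(base[, w, drop = FALSE]) %% 2L)
  }, integer(128L))
  cbind(base, added)
}

# Canonical L27(3^13): rows are the 27 points of GF(3)^3; the 13 columns are
# the distinct nonzero linear forms a1*t1 + a2*t2 + a3*t3 (mod 3) with leading
# nonzero coefficient normalized to 1, in lexicographic order of (a1, a2, a3).
.l27_array <- function() {
  pts <- as.matrix(expand.grid(t3 = 0:2, t2 = 0:2, t1 = 0:2))[, 3:1, drop = FALSE]
  forms <- list(
    c(0L, 0L, 1L), c(0L, 1L, 0L), c(0L, 1L, 1L), c(0L, 1L, 2L),
    c(1L, 0L, 0L), c(1L, 0L, 1L), c(1L, 0L, 2L), c(1L, 1L, 0L),
    c(1L, 1L, 1L), c(1L, 1L, 2L), c(1L, 2L, 0L), c(1L, 2L, 1L),
    c(1L, 2L, 2L)
  )
  cols <- vapply(forms, function(a) as.integer((pts %*% a) %% 3L), integer(27L))
  cols
}

#' Extract the coded-level matrix of a design
#'
#' @param design An `oacd_design` tibble (or any data frame whose factor
#'   columns start with `x`).
#' @return Integer matrix of coded levels, runs by factors.
#' @export
design_levels <- function(design) {
  cols <- grep("^x[0-9]+$", names(design), value = TRUE)
  if (length(cols) == 0L) stop("No coded-level columns (x01, x02, ...) found.", call. = FALSE)
  m <- as.matrix(design[, cols])
  storage.mode(m) <- "double"
  rownames(m) <- NULL
  m
}

#' Expand coded levels into the second-order model basis
#'
#' Columns are the intercept, linear terms `x_i`, pure quadratic terms
#' `x_i^2`, and all pairwise interactions `x_i x_j` (i < j):
#' 1 + 2F + F(F-1)/2 terms (91 for F = 12).
#'
#' @param levels Numeric matrix, runs by factors, of coded dose levels.
#' @param names Optional factor names used to label terms.
#' @return Numeric model matrix with named columns.
#' @export
quadratic_basis <- function(levels, names = colnames(levels)) {
  levels <- as.matrix(levels)
  f <- ncol(levels)
  if (is.null(names)) names <- sprintf("x%02d", seq_len(f))
  pairs <- if (f >= 2L) utils::combn(f, 2L) else matrix(integer(), 2L, 0L)
  inter <- apply(pairs, 2L, function(ij) levels[, ij[1L]] * levels[, ij[2L]])
  if (nrow(levels) == 1L) inter <- matrix(inter, nrow = 1L)
  mm <- cbind(1, levels, levels^2, inter)
  colnames(mm) <- c(
    "(Intercept)", names, paste0(names, "^2"),
    apply(pairs, 2L, function(ij) paste(names[ij[1L]], names[ij[2L]], sep = ":"))
  )
  mm
}

#' Map coded design levels to dispensed doses
#'
#' Looks up each run's coded level (0/1/2) in the drug panel's IC0/IC10/IC20
#' dose columns and returns the dispensing plan in long (tidy) form.
#'
#' @param design An `oacd_design`.
#' @param panel A drug panel tibble from [drug_panel()]; its row order must
#'   match the design's factor columns.
#' @return A tibble with columns `run_id`, `drug`, `level`, `dose_uM`, in
#'   stable run-major order.
#' @export
map_levels_to_doses <- function(design, panel) {
  lv <- design_levels(design)
  if (ncol(lv) != nrow(panel)) {
    stop("Design has ", ncol(lv), " factors but panel has ", nrow(panel),
         " drugs.", call. = FALSE)
  }
  dose_tab <- as.matrix(panel[, c("dose_level0", "dose_level1", "dose_level2")])
  long <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(as.data.frame(lv)), run_id = design$run_id),
    cols = -"run_id", names_to = "factor", values_to = "level"
  )
  idx <- match(long$factor, colnames(lv))
  long$drug <- panel$drug[idx]
  long$dose_uM <- dose_tab[cbind(idx, long$level + 1L)]
  dplyr::arrange(long[, c("run_id", "drug", "level", "dose_uM")], .data$run_id)
}

#' Recover coded levels from a dosing plan
#'
#' Inverse of [map_levels_to_doses()]: matches dispensed doses back to the
#' panel's per-drug dose table.
#'
#' @param plan Long dosing plan with `run_id`, `drug`, `dose_uM`.
#' @param panel The drug panel used to create the plan.
#' @return Tibble `run_id`, `drug`, `level`.
#' @export
doses_to_levels <- function(plan, panel) {
  dose_tab <- as.matrix(panel[, c("dose_level0", "dose_level1", "dose_level2")])
  i <- match(plan$drug, panel$drug)
  if (anyNA(i)) stop("Unknown drug in dosing plan.", call. = FALSE)
  lev <- vapply(seq_len(nrow(plan)), function(r) {
    hit <- which(abs(dose_tab[i[r], ] - plan$dose_uM[r]) < 1e-12)
    if (length(hit) == 0L) stop("Dose ", plan$dose_uM[r], " not in panel for ",
                                plan$drug[r], call. = FALSE)
    hit[1L] - 1L
  }, integer(1L))
  tibble::tibble(run_id = plan$run_id, drug = plan$drug, level = as.integer(lev))
}

#' Validate an OACD design
#'
#' Report-only diagnostics: run counts per portion, per-column level balance,
#' and the numerical rank of the expanded quadratic model matrix. The design
#' passes when that rank equals the quadratic term count, i.e. every
#' second-order coefficient is estimable.
#'
#' @param design An `oacd_design` (or compatible tibble).
#' @return A list of class `oacd_validation`: `n_runs`, `portion_counts`,
#'   `level_balance` (tibble factor x level counts), `n_terms`, `rank`,
#'   `pass`.
#' @export
validate_design <- function(design) {
  lv <- design_levels(design)
  if (nrow(lv) == 0L) stop("Design has zero runs.", call. = FALSE)
  mm <- quadratic_basis(lv)
  balance <- purrr::map_dfr(seq_len(ncol(lv)), function(j) {
    tb <- table(factor(lv[, j], levels = 0:2))
    tibble::tibble(factor = colnames(lv)[j],
                   level0 = as.integer(tb[["0"]]),
                   level1 = as.integer(tb[["1"]]),
                   level2 = as.integer(tb[["2"]]))
  })
  rk <- qr(mm)$rank
  out <- list(
    n_runs = nrow(lv),
    portion_counts = if ("portion" %in% names(design)) table(design$portion) else NULL,
    level_balance = balance,
    n_terms = ncol(mm),
    rank = rk,
    pass = rk == ncol(mm)
  )
  class(out) <- "oacd_validation"
  out
}

#' @export
print.oacd_validation <- function(x, ...) {
  cat("OACD validation: ", x$n_runs, " runs, quadratic basis ", x$n_terms,
      " terms, rank ", x$rank, " -> ", if (x$pass) "PASS" else "RANK DEFICIENT",
      "\n", sep = "")
  if (!is.null(x$portion_counts)) print(x$portion_counts)
  invisible(x)
}

#' Defining words of the registered fractional factorial
#'
#' Returns the word lengths of all 31 products of the generator words of the
#' 2^(12-5) fraction, from which the design resolution (minimum word length)
#' can be read off.
#'
#' @return Integer vector of 31 word lengths.
#' @export
oacd_word_lengths <- function() {
  gens <- lapply(seq_along(.oacd_generators), function(k) {
    v <- integer(12L)
    v[.oacd_generators[[k]]] <- 1L
    v[7L + k] <- 1L
    v
  })
  vapply(1:31, function(m) {
    bits <- as.integer(intToBits(m))[1:5]
    word <- Reduce(function(a, b) (a + b) %% 2L, gens[bits == 1L], integer(12L))
    sum(word)
  }, integer(1L))
}
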