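#' Construct a drug panel
#'
#' A panel is the ordered set of drugs screened together with the doses
#' dispensed at the three coded levels: level 0 = IC0 (operationalized as no
#' drug, 0 uM), level 1 = IC10, level 2 = IC20, all in micromolar.
#'
#' @param drug Character vector of unique drug names.
#' @param dose_level0,dose_level1,dose_level2 Numeric dose vectors (uM) per
#'   coded level; must satisfy `0 <= dose_level0 < dose_level1 < dose_level2`.
#' @return A tibble of class `drug_panel`.
#' @export
drug_panel <- function(drug, dose_level0, dose_level1, dose_level2) {
  if (anyDuplicated(drug)) stop("Drug names must be unique.", call. = FALSE)
  ok <- dose_level0 >= 0 & dose_level0 < dose_level1 & dose_level1 < dose_level2
  if (!all(ok)) {
    stop("Doses must satisfy 0 <= level0 < level1 < level2; violated for: ",
         paste(drug[!ok], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    drug = as.character(drug),
    dose_level0 = as.numeric(dose_level0),
    dose_level1 = as.numeric(dose_level1),
    dose_level2 = as.numeric(dose_level2)
  )
  class(out) <- c("drug_panel", class(out))
  out
}

#' The default 12-drug soft-tissue-sarcoma screening panel
#'
#' Drug names follow the screened panel (cytotoxics, epigenetic agents, a CDK
#' inhibitor and two multi-kinase inhibitors). The IC10/IC20 doses shipped
#' here are synthetic placeholders on a realistic micromolar scale: the
#' regression operates on coded levels, so absolute doses only affect the
#' dispensing plan, and per-sample IC values would in practice come from
#' [fit_4pl()] and [invert_4pl()] on that sample's dose-response data.
#'
#' @return A `drug_panel` tibble with 12 rows.
#' @export
default_panel <- function() {
  drug_panel(
    drug = c("ifosfamide", "doxorubicin", "gemcitabine", "paclitaxel",
             "eribulin", "trabectedin", "vorinostat", "azacitidine",
             "AZD5153", "palbociclib", "pazopanib", "ponatinib"),
    dose_level0 = rep(0, 12),
    dose_level1 = c(20, 0.05, 0.01, 0.002, 0.0005, 0.0002,
                    0.5, 1, 0.05, 0.5, 2, 0.05),
    dose_level2 = c(60, 0.15, 0.03, 0.006, 0.0015, 0.0006,
                    1.5, 3, 0.15, 1.5, 6, 0.15)
  )
}

#' Write / read a drug panel as JSON
#'
#' @param panel A `drug_panel`.
#' @param path File path.
#' @return `write_panel` returns `path` invisibly; `read_panel` returns the
#'   panel tibble.
#' @export
write_panel <- function(panel, path) {
  jsonlite::write_json(as.data.frame(panel), path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  drug_panel(df$drug, df$dose_level0, df$dose_level1, df$dose_level2)
}
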