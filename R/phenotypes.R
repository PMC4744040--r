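#' Convert beverage counts to grams of ethanol per week
#'
#' Uses the interview conversion constants: one 4 oz glass of wine = 10.8 g,
#' one 12 oz beer = 13.2 g, one 1.5 oz shot of liquor = 15.1 g ethanol.
#'
#' @param wine_4oz_per_wk,beer_12oz_per_wk,liquor_1_5oz_per_wk weekly
#'   beverage counts; non-negative, fractional allowed.
#' @return grams of ethanol per week.
#' @examples
#' drinks_to_grams(1, 0, 0)   # 10.8
#' drinks_to_grams(2, 2, 1)   # 63.1
#' @export
drinks_to_grams <- function(wine_4oz_per_wk, beer_12oz_per_wk,
                            liquor_1_5oz_per_wk) {
  counts <- cbind(wine_4oz_per_wk, beer_12oz_per_wk, liquor_1_5oz_per_wk)
  if (any(counts < 0, na.rm = TRUE)) {
    stop("beverage counts must be non-negative.", call. = FALSE)
  }
  10.8 * wine_4oz_per_wk + 13.2 * beer_12oz_per_wk +
    15.1 * liquor_1_5oz_per_wk
}

#' Log-alcohol exposure transform
#'
#' The analysis exposure is ln(alcohol in g/wk + 1), which maps abstention
#' (0 g/wk) to 0 and tames the skew of intake.
#'
#' @param g_wk grams of ethanol per week, >= 0 (NA allowed).
#' @return ln(g_wk + 1).
#' @export
log_alcohol <- function(g_wk) {
  if (any(g_wk < 0, na.rm = TRUE)) {
    stop("`g_wk` must be non-negative.", call. = FALSE)
  }
  log1p(g_wk)
}

#' Classify drinker category
#'
#' Never and former drinkers pass through.  Current drinkers with fewer
#' than one drink per week are infrequent (and their intake is recorded as
#' 0 g/wk for analysis); otherwise they are heavy drinkers if intake
#' exceeds 210 g/wk (men) or 105 g/wk (women), and low-to-moderate
#' otherwise.  The thresholds are inclusive on the low-to-moderate side:
#' exactly 210/105 g/wk is low-to-moderate.
#'
#' @param status drinking status, one of never/former/current (vectorized).
#' @param g_wk grams of ethanol per week.
#' @param sex "M" or "F".
#' @param drinks_per_wk beverage units per week (any of the three types).
#' @return character vector over {never, former, infrequent,
#'   low_to_moderate, heavy}.
#' @export
classify_drinker <- function(status, g_wk, sex, drinks_per_wk) {
  n <- max(length(status), length(g_wk), length(sex), length(drinks_per_wk))
  status <- rep_len(as.character(status), n)
  g_wk <- rep_len(g_wk, n)
  sex <- rep_len(as.character(sex), n)
  drinks_per_wk <- rep_len(drinks_per_wk, n)

  ok_status <- status %in% c("never", "former", "current") | is.na(status)
  if (!all(ok_status)) {
    stop("unknown drinking status: ",
         paste(unique(status[!ok_status]), collapse = ", "), call. = FALSE)
  }
  ok_sex <- sex %in% c("M", "F") | is.na(sex)
  if (!all(ok_sex)) {
    stop("unknown sex code: ",
         paste(unique(sex[!ok_sex]), collapse = ", "), call. = FALSE)
  }

  out <- status
  cur <- !is.na(status) & status == "current"
  infreq <- cur & drinks_per_wk < 1
  out[infreq] <- "infrequent"
  reg <- cur & !infreq
  thr <- ifelse(sex == "M", 210, 105)
  out[reg] <- ifelse(g_wk[reg] > thr[reg], "heavy", "low_to_moderate")
  out
}

#' Friedewald LDL cholesterol
#'
#' LDL-c = total cholesterol - HDL-c - TG/5 (all mg/dL), undefined when
#' TG > 400 mg/dL or any input is missing.
#'
#' @param tc,hdl,tg total cholesterol, HDL-c and triglycerides in mg/dL.
#' @return LDL-c in mg/dL, NA where undefined.
#' @export
friedewald_ldl <- function(tc, hdl, tg) {
  if (any(c(tc, hdl, tg) < 0, na.rm = TRUE)) {
    stop("lipid inputs must be non-negative.", call. = FALSE)
  }
  ldl <- tc - hdl - tg / 5
  ldl[!is.na(tg) & tg > 400] <- NA_real_
  ldl
}

#' Isoform-insensitivity correction for Lp(a)
#'
#' Rescales Lp(a) by 1.326 to match an apo(a)-isoform-insensitive assay.
#'
#' @param lpa_raw Lp(a) in mg/dL (NA propagates).
#' @return corrected Lp(a) in mg/dL.
#' @export
correct_lpa <- function(lpa_raw) {
  if (any(lpa_raw < 0, na.rm = TRUE)) {
    stop("`lpa_raw` must be non-negative.", call. = FALSE)
  }
  1.326 * lpa_raw
}

#' Percent change implied by a log-scale coefficient
#'
#' Converts a regression coefficient on a natural-log outcome scale to the
#' implied percent change: 100 * (exp(beta) - 1).
#'
#' @param beta_log coefficient on the ln scale.
#' @return percent change.
#' @examples
#' percent_change(-0.13)  # about -12.19
#' @export
percent_change <- function(beta_log) {
  100 * (exp(beta_log) - 1)
}

# lipids analyzed on the natural-log scale
LOG_SCALE_LIPIDS <- c("tg", "hdl", "hdl2", "sdldl", "apob", "lpa")

#' Derive analysis variables for a cohort table
#'
#' Adds the derived phenotype columns, each with a `derived_` prefix:
#' HDL2-c by subtraction (HDL-c minus HDL3-c), Friedewald LDL-c (missing
#' when TG > 400 mg/dL), isoform-corrected Lp(a), the drinker category,
#' the log-alcohol exposure, and natural-log companions for the six
#' log-analyzed lipids (TG, HDL-c, HDL2-c, sdLDL-c, apoB, corrected
#' Lp(a)).  Non-positive values of a log-target lipid are set missing with
#' a warning rather than producing -Inf.
#'
#' @param cohort data.frame with at minimum the raw lipid columns `tg`,
#'   `total_chol`, `hdl`, `hdl3`, `lpa`, `sdldl`, `apob` and the alcohol
#'   columns `drinking_status`, `alcohol_g_wk`, `drinks_per_wk`, `sex`.
#' @return the cohort with derived columns appended.
#' @export
derive_cohort <- function(cohort) {
  need <- c("tg", "total_chol", "hdl", "hdl3", "lpa", "sdldl", "apob",
            "drinking_status", "alcohol_g_wk", "drinks_per_wk", "sex")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- cohort
  out$derived_hdl2 <- out$hdl - out$hdl3
  out$derived_ldl <- friedewald_ldl(out$total_chol, out$hdl, out$tg)
  out$derived_lpa_corr <- correct_lpa(out$lpa)
  out$derived_drinker_category <- classify_drinker(
    out$drinking_status, out$alcohol_g_wk, out$sex, out$drinks_per_wk)
  out$derived_log_alcohol <- log_alcohol(out$alcohol_g_wk)

  log_sources <- c(tg = "tg", hdl = "hdl", hdl2 = "derived_hdl2",
                   sdldl = "sdldl", apob = "apob",
                   lpa = "derived_lpa_corr")
  for (nm in names(log_sources)) {
    v <- out[[log_sources[[nm]]]]
    bad <- !is.na(v) & v <= 0
    if (any(bad)) {
      warning(sum(bad), " non-positive ", nm,
              " value(s) set missing before log transform.", call. = FALSE)
      v[bad] <- NA_real_
    }
    out[[paste0("derived_ln_", nm)]] <- log(v)
  }
  out
}

#' Column dictionary for the derived cohort table
#'
#' @return data.frame mapping derived column names to descriptions and
#'   units, suitable for writing alongside the table.
#' @export
derived_column_dictionary <- function() {
  data.frame(
    column = c("derived_hdl2", "derived_ldl", "derived_lpa_corr",
               "derived_drinker_category", "derived_log_alcohol",
               paste0("derived_ln_", names(c(tg = 1, hdl = 1, hdl2 = 1,
                                             sdldl = 1, apob = 1, lpa = 1)))),
    description = c(
      "HDL2-c = HDL-c - HDL3-c",
      "Friedewald LDL-c = TC - HDL-c - TG/5; missing when TG > 400",
      "Lp(a) x 1.326 (isoform-insensitive assay scale)",
      "never/former/infrequent/low_to_moderate/heavy",
      "ln(alcohol g/wk + 1)",
      "ln TG", "ln HDL-c", "ln HDL2-c", "ln sdLDL-c", "ln apoB",
      "ln corrected Lp(a)"),
    units = c("mg/dL", "mg/dL", "mg/dL", "category", "ln(g/wk+1)",
              rep("ln(mg/dL)", 6)),
    stringsAsFactors = FALSE
  )
}
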