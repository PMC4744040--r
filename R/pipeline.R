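#' Default outcome roster
#'
#' The nine lipid outcomes with their analysis transform and measurement
#' occasion.  Log-transformed outcomes use the `derived_ln_` columns from
#' [derive_cohort()]; sdLDL-c and apoB are visit-4 measures and their
#' models use age at visit 4.
#'
#' @return data.frame with columns `name`, `column`, `transform`
#'   (log/raw), `visit` (baseline/visit4).
#' @export
default_outcomes <- function() {
  data.frame(
    name      = c("tg", "total_chol", "hdl", "hdl2", "hdl3", "ldl",
                  "sdldl", "apob", "lpa"),
    column    = c("derived_ln_tg", "total_chol", "derived_ln_hdl",
                  "derived_ln_hdl2", "hdl3", "derived_ldl",
                  "derived_ln_sdldl", "derived_ln_apob", "derived_ln_lpa"),
    transform = c("log", "raw", "log", "log", "raw", "raw",
                  "log", "log", "log"),
    visit     = c("baseline", "baseline", "baseline", "baseline",
                  "baseline", "baseline", "visit4", "visit4", "baseline"),
    stringsAsFactors = FALSE
  )
}

SCENARIOS <- c("full", "exclude_heavy", "exclude_never",
               "exclude_never_and_heavy", "exclude_never_and_former")

#' Analysis plan
#'
#' Bundles the outcome roster, covariates, sensitivity scenarios and
#' estimator options for [run_mr()] and [run_sensitivity()].
#'
#' @param outcomes outcome roster as in [default_outcomes()].
#' @param covariates baseline covariates; for visit-4 outcomes `age` is
#'   replaced by `age_v4` automatically.
#' @param scenarios subset of full / exclude_heavy / exclude_never /
#'   exclude_never_and_heavy / exclude_never_and_former.
#' @param exposure_col,score_col analysis exposure and score columns.
#' @param vcov_type second-stage covariance: "HC1" (robust, default) or
#'   "const".
#' @param min_scenario_n refuse scenarios leaving fewer rows than this.
#' @return object of class `mr_plan`.
#' @export
analysis_plan <- function(outcomes = default_outcomes(),
                          covariates = c("sex", "age", "PC1", "PC2"),
                          scenarios = SCENARIOS,
                          exposure_col = "derived_log_alcohol",
                          score_col = "score_unweighted",
                          vcov_type = c("HC1", "const"),
                          min_scenario_n = 100L) {
  vcov_type <- match.arg(vcov_type)
  bad <- setdiff(scenarios, SCENARIOS)
  if (length(bad)) {
    stop("unknown scenario(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!all(outcomes$transform %in% c("log", "raw"))) {
    stop("every outcome needs transform 'log' or 'raw'.", call. = FALSE)
  }
  structure(list(outcomes = outcomes, covariates = covariates,
                 scenarios = scenarios, exposure_col = exposure_col,
                 score_col = score_col, vcov_type = vcov_type,
                 min_scenario_n = as.integer(min_scenario_n)),
            class = "mr_plan")
}

#' Orient instruments and append the unweighted score to a cohort
#'
#' Convenience wrapper: orients each roster SNP's dosage column to the
#' alcohol-raising direction, builds the unweighted score over the
#' (optionally screened) set, and appends it as `score_unweighted`.
#'
#' @param cohort derived cohort data.frame containing the dosage columns
#'   and `derived_log_alcohol`.
#' @param roster instrument roster (rows define the score's SNPs).
#' @return the cohort with a `score_unweighted` column; the `mr_score`
#'   object is attached as attribute "score".
#' @export
score_cohort <- function(cohort, roster = default_instrument_roster()) {
  miss <- setdiff(roster$snp_id, names(cohort))
  if (length(miss)) {
    stop("cohort lacks dosage column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dos <- as.matrix(cohort[, roster$snp_id, drop = FALSE])
  for (j in seq_len(ncol(dos))) {
    v <- stats::var(dos[, j], na.rm = TRUE)
    if (!is.finite(v) || v == 0) {
      # monomorphic in this sample: orientation is moot (constant offset)
      warning("SNP ", roster$snp_id[j],
              " is monomorphic in this cohort; orientation skipped.",
              call. = FALSE)
      next
    }
    ori <- orient_alleles(roster[j, ], dos[, j],
                          cohort$derived_log_alcohol)
    dos[, j] <- ori$dosage
  }
  sc <- build_score(dos)
  cohort$score_unweighted <- sc$score
  attr(cohort, "score") <- sc
  cohort
}

#' Run the instrumental-variable analysis over all outcomes
#'
#' For each outcome: restrict to complete cases on the outcome, exposure,
#' score and (visit-matched) covariates; fit the first stage; cut the
#' fitted exposure into quartiles; fit the quartiled second stage.
#' Quartile cut-points are therefore recomputed per outcome model on that
#' model's complete-case set.
#'
#' @param cohort derived, scored cohort data.frame.
#' @param plan an `mr_plan`.
#' @param scenario label recorded in the output (the cohort is assumed
#'   already filtered).
#' @return data.frame in long (one row per lipid x quartile) form with
#'   columns lipid, n, quartile, beta, ci_low, ci_high, p, p_overall,
#'   partial_r2, F_stat, weak_instrument, transform, visit, scenario.  A
#'   per-fit structured log is attached as attribute "log".
#' @export
run_mr <- function(cohort, plan = analysis_plan(), scenario = "full") {
  rows <- list()
  log_lines <- character(0)
  for (i in seq_len(nrow(plan$outcomes))) {
    oc <- plan$outcomes[i, ]
    covars <- plan$covariates
    if (oc$visit == "visit4") covars[covars == "age"] <- "age_v4"
    need <- c(oc$column, plan$exposure_col, plan$score_col, covars)
    miss <- setdiff(need, names(cohort))
    if (length(miss)) {
      stop("outcome '", oc$name, "': missing column(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    sub <- cohort[stats::complete.cases(cohort[, need, drop = FALSE]), ,
                  drop = FALSE]
    res <- tryCatch({
      fs <- fit_first_stage(sub, plan$exposure_col, plan$score_col, covars)
      qa <- assign_quartiles(fs)
      ss <- fit_second_stage(sub, oc$column, qa, covars,
                             vcov_type = plan$vcov_type)
      list(fs = fs, qa = qa, ss = ss)
    }, error = function(e) {
      stop("outcome '", oc$name, "': ", conditionMessage(e), call. = FALSE)
    })
    fs <- res$fs; ss <- res$ss
    log_lines <- c(log_lines, sprintf(
      "fit outcome=%s scenario=%s n=%d F=%.3f partial_r2=%.6f",
      oc$name, scenario, ss$n, fs$F_stat, fs$partial_r2))
    tab <- ss$table
    rows[[oc$name]] <- data.frame(
      lipid = oc$name, n = ss$n, quartile = tab$quartile,
      beta = tab$beta, ci_low = tab$ci_low, ci_high = tab$ci_high,
      p = tab$p, p_overall = ss$p_overall,
      partial_r2 = fs$partial_r2, F_stat = fs$F_stat,
      weak_instrument = fs$F_stat <= 10,
      transform = oc$transform, visit = oc$visit, scenario = scenario,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "log") <- log_lines
  out
}

scenario_filter <- function(cohort, scenario,
                            category_col = "derived_drinker_category") {
  drop <- switch(scenario,
    full = character(0),
    exclude_heavy = "heavy",
    exclude_never = "never",
    exclude_never_and_heavy = c("never", "heavy"),
    exclude_never_and_former = c("never", "former"),
    stop("unknown scenario: ", scenario, call. = FALSE))
  cohort[!cohort[[category_col]] %in% drop, , drop = FALSE]
}

#' Sensitivity reruns over drinker-status exclusions
#'
#' Each scenario filters the cohort by drinker category and re-runs the
#' first stage, quartile assignment and second stage from scratch on the
#' subset.  The input cohort is never modified.
#'
#' @param cohort derived, scored cohort.
#' @param plan an `mr_plan`; `plan$scenarios` selects the reruns.
#' @return named list of result tables (one per scenario).
#' @export
run_sensitivity <- function(cohort, plan = analysis_plan()) {
  out <- list()
  for (sc in plan$scenarios) {
    sub <- scenario_filter(cohort, sc)
    if (nrow(sub) < plan$min_scenario_n) {
      stop("scenario '", sc, "' leaves only ", nrow(sub),
           " individuals (< ", plan$min_scenario_n, ").", call. = FALSE)
    }
    out[[sc]] <- run_mr(sub, plan, scenario = sc)
  }
  out
}

#' Observational association between drinker category and lipids
#'
#' Regresses a lipid on drinker-category indicators with never drinkers
#' as the reference; former and infrequent drinkers are merged into one
#' category, as is conventional when the two cannot be separated on
#' recorded intake.  Adjusts for sex and age by default (`adjusted =
#' FALSE` gives the bare-category model).  Wald tests use the classical
#' OLS covariance and the normal reference.
#'
#' @param cohort derived cohort.
#' @param lipid_col outcome column.
#' @param category_col drinker-category column.
#' @param covariates adjustment covariates used when `adjusted` is TRUE.
#' @param adjusted adjust for covariates?
#' @return data.frame: one row per category (never first, beta 0), with
#'   beta, ci_low, ci_high, p, and the complete-case n as an attribute.
#' @export
observational_association <- function(cohort, lipid_col,
                                      category_col = "derived_drinker_category",
                                      covariates = c("sex", "age"),
                                      adjusted = TRUE) {
  merged <- merge_categories(cohort[[category_col]])
  dat <- cohort[, c(lipid_col, if (adjusted) covariates), drop = FALSE]
  dat$.cat <- merged
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (!any(dat$.cat == "never")) {
    stop("empty reference category (never drinkers).", call. = FALSE)
  }
  if (is.character(dat$sex)) dat$sex <- factor(dat$sex)
  rhs <- c(".cat", if (adjusted) sprintf("`%s`", covariates))
  fml <- stats::as.formula(paste0("`", lipid_col, "` ~ ",
                                  paste(rhs, collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  lv <- levels(merged)[-1]
  nm <- paste0(".cat", lv)
  est <- b[nm]; se <- sqrt(diag(V)[nm])
  z <- est / se
  out <- data.frame(
    category = c("never", lv),
    beta = c(0, unname(est)),
    ci_low = c(NA, unname(est - stats::qnorm(0.975) * se)),
    ci_high = c(NA, unname(est + stats::qnorm(0.975) * se)),
    p = c(NA, unname(2 * stats::pnorm(-abs(z)))),
    stringsAsFactors = FALSE)
  attr(out, "n") <- nrow(dat)
  attr(out, "category_n") <- table(dat$.cat)
  out
}

merge_categories <- function(category) {
  x <- as.character(category)
  x[x %in% c("former", "infrequent")] <- "former_infrequent"
  factor(x, levels = c("never", "former_infrequent", "low_to_moderate",
                       "heavy"))
}

#' Render a plain-text analysis report
#'
#' Summarizes the main IV table (and any sensitivity tables) in a
#' human-readable form: per-lipid quartile effects with 95% CIs, overall
#' Wald p, first-stage diagnostics, weak-instrument warnings, and percent
#' change conversions for log-scale outcomes.  Regenerating the report
#' from the same tables is idempotent.
#'
#' @param main result table from [run_mr()].
#' @param sensitivity named list of sensitivity tables (may be empty).
#' @param observational optional list of observational tables keyed by
#'   lipid.
#' @param file optional path; when given the report is written there.
#' @return character vector of report lines, invisibly when `file` given.
#' @export
make_report <- function(main, sensitivity = list(), observational = NULL,
                        file = NULL) {
  lines <- c("Mendelian-randomization analysis of alcohol consumption on lipids",
             "================================================================",
             "")
  render_block <- function(tab, title) {
    out <- c(title, strrep("-", nchar(title)))
    for (lp in unique(tab$lipid)) {
      sub <- tab[tab$lipid == lp, ]
      head1 <- sprintf(
        "%s (n = %d, %s scale): overall Wald p = %.3g; first-stage partial R2 = %.3f%%, F = %.2f%s",
        lp, sub$n[1], sub$transform[1], sub$p_overall[1],
        100 * sub$partial_r2[1], sub$F_stat[1],
        if (sub$weak_instrument[1]) "  ** weak instrument (F <= 10) **" else "")
      out <- c(out, head1)
      for (r in seq_len(nrow(sub))) {
        if (sub$quartile[r] == "q1") {
          out <- c(out, "  q1: reference")
        } else {
          pc <- if (sub$transform[r] == "log") {
            sprintf(" (%+.1f%%)", percent_change(sub$beta[r]))
          } else ""
          out <- c(out, sprintf(
            "  %s: beta = %+.3f%s, 95%% CI [%.3f, %.3f], p = %.3g",
            sub$quartile[r], sub$beta[r], pc, sub$ci_low[r],
            sub$ci_high[r], sub$p[r]))
        }
      }
      out <- c(out, "")
    }
    out
  }
  lines <- c(lines, render_block(main, "Main analysis (full cohort)"))
  for (sc in names(sensitivity)) {
    lines <- c(lines,
               render_block(sensitivity[[sc]],
                            paste0("Sensitivity: ", sc)))
  }
  if (!is.null(observational)) {
    lines <- c(lines, "Observational category regressions",
               "----------------------------------")
    for (lp in names(observational)) {
      tab <- observational[[lp]]
      lines <- c(lines, sprintf("%s (n = %d):", lp, attr(tab, "n")))
      for (r in seq_len(nrow(tab))) {
        if (tab$category[r] == "never") {
          lines <- c(lines, "  never: reference")
        } else {
          lines <- c(lines, sprintf(
            "  %s: beta = %+.3f, 95%% CI [%.3f, %.3f], p = %.3g",
            tab$category[r], tab$beta[r], tab$ci_low[r], tab$ci_high[r],
            tab$p[r]))
        }
      }
      lines <- c(lines, "")
    }
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
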