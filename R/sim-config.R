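#' Default instrument roster
#'
#' The five alcohol-dehydrogenase variants used as default genetic
#' instruments, with their minor-allele frequencies in European-ancestry
#' samples and per-allele effects on log-alcohol consumption
#' (slope of ln(g/wk + 1) per alcohol-raising allele from a univariate
#' regression).  `functional_class` and `sample_size` drive the pairwise-LD
#' pruning tie-breaks; sample sizes are representative values for the
#' source association studies.
#'
#' @return data.frame with columns `snp_id`, `gene`, `maf`, `raising_allele`,
#'   `other_allele`, `functional_class`, `sample_size`, `beta`.
#' @export
default_instrument_roster <- function() {
  data.frame(
    snp_id           = c("rs2066702", "rs1693457", "rs1789891",
                         "rs698", "rs1126671"),
    gene             = c("ADH1B", "ADH1B", "ADH1B/1C", "ADH1C", "ADH4"),
    maf              = c(0.001, 0.172, 0.169, 0.409, 0.313),
    raising_allele   = c("G", "T", "A", "C", "A"),
    other_allele     = c("A", "C", "C", "T", "G"),
    functional_class = c("exonic", "intronic", "intergenic",
                         "exonic", "exonic"),
    sample_size      = c(32000L, 12000L, 9500L, 21000L, 18000L),
    beta             = c(0.33, 0.06, 0.07, 0.05, 0.07),
    stringsAsFactors = FALSE
  )
}

#' Default lipid panel generation parameters
#'
#' Baselines and dispersions on each lipid's analysis scale (natural-log
#' scale for log-analyzed lipids, mg/dL otherwise), chosen to emulate the
#' marginal distributions of a middle-aged European-American cohort
#' (e.g. TG mean ~137 mg/dL, HDL3-c ~36.8 mg/dL, total cholesterol
#' ~214.5 mg/dL).  HDL2-c and HDL3-c are generated directly and total
#' HDL-c is stored as their sum, so the subtraction-derived subfraction is
#' exact by construction.  `confounder_effect` is the shift (analysis-scale
#' units) per SD of the latent confounder, before the global
#' `confounder_effect_outcome` multiplier.
#'
#' @return data.frame, one row per generated lipid.
#' @export
default_lipid_params <- function() {
  data.frame(
    name              = c("tg", "total_chol", "hdl2", "hdl3",
                          "lpa", "sdldl", "apob"),
    scale             = c("log", "raw", "log", "raw", "log", "log", "log"),
    baseline          = c(4.75, 214.5, 2.45, 36.8, 2.10, 3.70, 4.58),
    noise_sd          = c(0.52, 38.0, 0.52, 10.5, 1.30, 0.40, 0.23),
    sex_effect        = c(0.15, -5.0, -0.30, -6.0, 0.00, 0.15, 0.05),
    age_effect        = c(0.005, 1.0, 0.002, 0.05, 0.0, 0.004, 0.004),
    confounder_effect = c(0.15, 8.0, -0.10, -2.0, 0.0, 0.12, 0.08),
    missing_rate      = c(0.08, 0.08, 0.06, 0.06, 0.08, 0.20, 0.245),
    stringsAsFactors  = FALSE
  )
}

# default causal curves: a J-shaped benefit accruing up to the
# heavy-drinking threshold (210 g/wk, i.e. ln(211) on the exposure scale)
# and reversing three-fold faster beyond it; amplitudes in each lipid's
# analysis units, null for the lipids without an imposed effect
default_causal_curves <- function() {
  thr <- log(211)
  list(
    tg         = causal_peaked(-0.70, thr, -2.10),
    total_chol = causal_peaked(-41.0, thr, -123.0),
    hdl2       = causal_peaked(0.54, thr, 1.62),
    hdl3       = causal_null(),
    lpa        = causal_null(),
    sdldl      = causal_peaked(-0.43, thr, -1.29),
    apob       = causal_peaked(-0.22, thr, -0.66)
  )
}

#' Strong-instrument configuration for nonlinearity behaviour checks
#'
#' The default configuration is calibrated to the weak-instrument regime
#' (allele score explaining ~0.1% of exposure variance); there, the
#' exposure's dispersion around its genetic prediction smooths any causal
#' curve into a near-linear quartile profile, so curve-shape recovery
#' cannot be assessed.  This configuration scales the per-allele effects
#' to the strength of the strongest known alcohol-metabolism variants
#' (ALDH2-class effects) and tightens exposure noise so the quartiled
#' second stage has resolvable shape information.  The default causal
#' curve for TG peaks at 2.7 ln(g/wk + 1) — the centre of the third
#' quartile of predicted exposure under this configuration — with a
#' gentle reversal beyond it.
#'
#' @param n_individuals cohort size.
#' @param seed integer seed.
#' @param curve causal curve for log-TG.
#' @param ... further arguments passed to [sim_config()].
#' @return an `mr_sim_config`.
#' @export
strong_instrument_config <- function(n_individuals = 10893L, seed = NULL,
                                     curve = causal_peaked(-0.4, 2.7, -0.1),
                                     ...) {
  roster <- default_instrument_roster()
  roster$beta <- roster$beta * 8
  sim_config(n_individuals = n_individuals, seed = seed, snps = roster,
             exposure_noise_sd = 1.2, causal_curve = list(tg = curve), ...)
}

#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by
#' [generate_cohort()].  Defaults reproduce the statistical structure the
#' downstream analysis assumes: five independent instrument SNPs in
#' Hardy-Weinberg equilibrium at the default roster's allele frequencies,
#' an unweighted allele score explaining roughly 0.1% of log-alcohol
#' variance, a latent standard-normal confounder U acting on both exposure
#' and outcomes, never/former/current drinking statuses, and per-lipid
#' causal curves peaked at moderate intake.
#'
#' Per-allele effects are interpreted as whole-sample marginal slopes of
#' ln(g/wk + 1) on dosage (as instrument-discovery studies report them);
#' internally they are rescaled by the attenuation induced by non-drinker
#' zeroing and left-truncation so the configured slopes are recovered by a
#' univariate regression on the generated cohort.
#'
#' @param n_individuals cohort size (>= 1).
#' @param snps instrument roster data.frame as in
#'   [default_instrument_roster()]; `maf` in (0, 0.5], `beta` the marginal
#'   per-allele effect on log-alcohol.
#' @param sex_effect,age_effect effects of male sex and of age (per year,
#'   centred at `age_mean`) on latent log-alcohol.
#' @param confounder_effect_exposure effect of the latent confounder U on
#'   latent log-alcohol.
#' @param confounder_effect_outcome global multiplier on the per-lipid
#'   `confounder_effect` column (0 disables outcome confounding).
#' @param exposure_intercept,exposure_noise_sd intercept and residual SD of
#'   latent log-alcohol among current drinkers.  The default noise SD is a
#'   calibration constant, tuned once by simulation so the default allele
#'   score's first-stage partial R-squared lands near 0.1% (see the methods
#'   vignette).
#' @param alcohol_cap_g_wk plausibility cap on reported intake (g/wk);
#'   keeps the heavy lognormal tail from dominating mean consumption.
#' @param causal_curve either a single [causal_null()]/[causal_linear()]/
#'   [causal_peaked()] curve applied to every lipid, or a named list of
#'   curves keyed by lipid name (missing names default to null).
#' @param lipids lipid generation table as in [default_lipid_params()].
#' @param status_probs named probabilities for never/former/current drinker
#'   status (must sum to 1).
#' @param p_female probability of female sex.
#' @param age_mean,age_sd baseline age distribution (years).
#' @param visit4_age_offset years added to baseline age for the second
#'   (visit-4) measurement occasion.
#' @param abstention_follows_confounder when TRUE, never/former status
#'   becomes more likely at high U (health-related abstention), a
#'   reverse-causation stress scenario; default FALSE, so status is
#'   independent of genotype and U and the exclusion restriction holds.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return object of class `mr_sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 10893L,
                       snps = default_instrument_roster(),
                       sex_effect = 0.8,
                       age_effect = -0.01,
                       confounder_effect_exposure = 0.3,
                       confounder_effect_outcome = 1.0,
                       exposure_intercept = 1.8,
                       exposure_noise_sd = 2.45,
                       alcohol_cap_g_wk = 1200,
                       causal_curve = default_causal_curves(),
                       lipids = default_lipid_params(),
                       status_probs = c(never = 0.181, former = 0.170,
                                        current = 0.649),
                       p_female = 0.531,
                       age_mean = 54.3,
                       age_sd = 5.7,
                       visit4_age_offset = 9,
                       abstention_follows_confounder = FALSE,
                       seed = NULL) {
  n_individuals <- as.integer(n_individuals)
  if (is.na(n_individuals) || n_individuals < 1L) {
    stop("`n_individuals` must be a positive integer.", call. = FALSE)
  }
  req <- c("snp_id", "maf", "beta")
  if (!is.data.frame(snps) || !all(req %in% names(snps))) {
    stop("`snps` must be a data.frame with at least columns ",
         paste(req, collapse = ", "), ".", call. = FALSE)
  }
  check_maf(snps$maf)
  if (anyDuplicated(snps$snp_id)) {
    stop("duplicated snp_id in the instrument roster.", call. = FALSE)
  }
  if (!is.numeric(status_probs) || length(status_probs) != 3L ||
      is.null(names(status_probs)) ||
      !setequal(names(status_probs), c("never", "former", "current"))) {
    stop("`status_probs` must be a named vector over never/former/current.",
         call. = FALSE)
  }
  if (any(status_probs < 0) || any(status_probs > 1) ||
      abs(sum(status_probs) - 1) > 1e-8) {
    stop("`status_probs` must lie in [0,1] and sum to 1.", call. = FALSE)
  }
  if (exposure_noise_sd <= 0 || age_sd <= 0) {
    stop("standard deviations must be positive.", call. = FALSE)
  }
  if (p_female < 0 || p_female > 1) {
    stop("`p_female` must be a probability.", call. = FALSE)
  }
  if (any(lipids$noise_sd <= 0)) {
    stop("lipid noise SDs must be positive.", call. = FALSE)
  }
  if (any(lipids$missing_rate < 0 | lipids$missing_rate >= 1)) {
    stop("lipid missing rates must lie in [0, 1).", call. = FALSE)
  }
  curves <- normalize_curves(causal_curve, lipids$name)
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("`seed` must be an integer.", call. = FALSE)
  }
  structure(list(
    n_individuals = n_individuals,
    snps = snps,
    sex_effect = sex_effect,
    age_effect = age_effect,
    confounder_effect_exposure = confounder_effect_exposure,
    confounder_effect_outcome = confounder_effect_outcome,
    exposure_intercept = exposure_intercept,
    exposure_noise_sd = exposure_noise_sd,
    alcohol_cap_g_wk = alcohol_cap_g_wk,
    causal_curves = curves,
    lipids = lipids,
    status_probs = status_probs[c("never", "former", "current")],
    p_female = p_female,
    age_mean = age_mean,
    age_sd = age_sd,
    visit4_age_offset = visit4_age_offset,
    abstention_follows_confounder = isTRUE(abstention_follows_confounder),
    seed = seed
  ), class = "mr_sim_config")
}

# expand a single curve or partial named list into one curve per lipid
normalize_curves <- function(causal_curve, lipid_names) {
  if (inherits(causal_curve, "mr_curve")) {
    curves <- stats::setNames(
      rep(list(causal_curve), length(lipid_names)), lipid_names)
    return(curves)
  }
  if (!is.list(causal_curve)) {
    stop("`causal_curve` must be an mr_curve or a named list of them.",
         call. = FALSE)
  }
  bad <- setdiff(names(causal_curve), lipid_names)
  if (length(bad)) {
    stop("causal_curve names not in the lipid table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  curves <- stats::setNames(
    rep(list(causal_null()), length(lipid_names)), lipid_names)
  for (nm in names(causal_curve)) {
    cv <- causal_curve[[nm]]
    if (!inherits(cv, "mr_curve")) {
      stop("causal_curve[['", nm, "']] is not an mr_curve.", call. = FALSE)
    }
    curves[[nm]] <- cv
  }
  curves
}

check_maf <- function(maf) {
  if (!is.numeric(maf) || any(!is.finite(maf)) ||
      any(maf <= 0) || any(maf > 0.5)) {
    stop("allele frequencies must lie in (0, 0.5].", call. = FALSE)
  }
  invisible(maf)
}

#' @export
print.mr_sim_config <- function(x, ...) {
  cat("<mr_sim_config>\n")
  cat("  n:", x$n_individuals, " SNPs:", nrow(x$snps),
      " status probs:", paste(sprintf("%s=%.3f", names(x$status_probs),
                                      x$status_probs), collapse = " "), "\n")
  cat("  exposure: intercept", x$exposure_intercept,
      "noise sd", x$exposure_noise_sd,
      "confounding", x$confounder_effect_exposure, "\n")
  invisible(x)
}
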