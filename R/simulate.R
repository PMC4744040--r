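#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Each SNP is drawn independently as Binomial(2, maf); the counted allele
#' is the alcohol-raising allele, so dosages arrive pre-oriented.
#'
#' @param mafs vector of allele frequencies in (0, 0.5].
#' @param n number of individuals (>= 1).
#' @param seed optional integer seed.
#' @return integer matrix, `n` rows by `length(mafs)` columns, entries in
#'   0/1/2.
#' @export
simulate_genotypes <- function(mafs, n, seed = NULL) {
  check_maf(mafs)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1.", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  G <- vapply(mafs, function(p) stats::rbinom(n, 2L, p), integer(n))
  if (n == 1L) G <- matrix(G, nrow = 1L)
  G
}

# attenuation of a latent per-allele effect into the whole-sample marginal
# slope: non-current drinkers are zeroed (factor p_current) and the latent
# is left-truncated at 0 (factor P(latent > 0))
exposure_attenuation <- function(config) {
  p_cur <- unname(config$status_probs["current"])
  pm <- 1 - config$p_female
  mu <- config$exposure_intercept + config$sex_effect * pm
  sigma <- sqrt(config$exposure_noise_sd^2 +
                config$sex_effect^2 * pm * (1 - pm) +
                (config$age_effect * config$age_sd)^2 +
                config$confounder_effect_exposure^2)
  p_cur * stats::pnorm(mu / sigma)
}

#' Simulate log-alcohol exposure and drinking status
#'
#' Latent log-alcohol among current drinkers is
#' intercept + sum(beta_latent_j * G_j) + sex/age effects + confounder +
#' Gaussian noise, left-truncated at 0.  Never/former drinkers are assigned
#' by `status_probs` (independently of genotype unless
#' `abstention_follows_confounder` is set) and carry 0 g/wk.  The
#' configured per-SNP betas are marginal whole-sample slopes; they are
#' rescaled internally (see [sim_config()]).
#'
#' @param genotypes dosage matrix from [simulate_genotypes()], one column
#'   per roster SNP.
#' @param covariates data.frame with columns `male` (0/1) and `age` (years).
#' @param confounder numeric vector U, one value per individual.
#' @param config an `mr_sim_config`.
#' @return list with `log_alcohol` (ln(g/wk + 1)), `drinking_status`
#'   (never/former/current), `alcohol_g_wk`, `drinks_per_wk`, and the
#'   realized `beta_latent` coefficients.
#' @export
simulate_exposure <- function(genotypes, covariates, confounder, config) {
  n <- nrow(genotypes)
  if (nrow(covariates) != n || length(confounder) != n) {
    stop("genotypes, covariates and confounder must have matching sizes.",
         call. = FALSE)
  }
  if (ncol(genotypes) != nrow(config$snps)) {
    stop("genotype matrix has ", ncol(genotypes),
         " SNPs but the roster has ", nrow(config$snps), ".", call. = FALSE)
  }
  atten <- exposure_attenuation(config)
  beta_latent <- config$snps$beta / atten

  latent <- config$exposure_intercept +
    drop(genotypes %*% beta_latent) +
    config$sex_effect * covariates$male +
    config$age_effect * (covariates$age - config$age_mean) +
    config$confounder_effect_exposure * confounder +
    stats::rnorm(n, 0, config$exposure_noise_sd)
  # plausibility cap on self-reported intake keeps the lognormal upper
  # tail from dominating mean g/wk
  log_alc <- pmin(pmax(latent, 0), log1p(config$alcohol_cap_g_wk))

  status <- draw_status(n, confounder, config)
  log_alc[status != "current"] <- 0
  g_wk <- ifelse(status == "current", expm1(log_alc), 0)
  # beverage units per week, using the beer gram equivalent as the unit
  drinks <- g_wk / 13.2

  list(log_alcohol = log_alc, drinking_status = status,
       alcohol_g_wk = g_wk, drinks_per_wk = drinks,
       beta_latent = beta_latent, attenuation = atten)
}

draw_status <- function(n, confounder, config) {
  p <- config$status_probs
  if (!config$abstention_follows_confounder) {
    return(sample(names(p), n, replace = TRUE, prob = p))
  }
  # health-related abstention: odds of never/former rise with U
  shift <- exp(0.5 * confounder)
  w <- cbind(never = p["never"] * shift, former = p["former"] * shift,
             current = p["current"])
  w <- w / rowSums(w)
  nm <- c("never", "former", "current")
  idx <- apply(w, 1L, function(pr) sample.int(3L, 1L, prob = pr))
  nm[idx]
}

#' Simulate the lipid panel
#'
#' Each lipid's analysis-scale value is baseline + causal curve evaluated
#' at realized log-alcohol + confounder and covariate terms + Gaussian
#' noise; log-scale lipids are exponentiated so stored values are mg/dL.
#' HDL2-c and HDL3-c are generated and total HDL-c is their sum.
#'
#' @param log_alcohol realized ln(g/wk + 1) vector.
#' @param confounder latent confounder U.
#' @param covariates data.frame with `male` and `age`.
#' @param config an `mr_sim_config`.
#' @return data.frame of measurement-scale lipid columns
#'   (`tg`, `total_chol`, `hdl`, `hdl3`, `lpa`, `sdldl`, `apob`), with
#'   per-lipid missingness applied.
#' @export
simulate_lipids <- function(log_alcohol, confounder, covariates, config) {
  n <- length(log_alcohol)
  lp <- config$lipids
  vals <- matrix(NA_real_, n, nrow(lp), dimnames = list(NULL, lp$name))
  for (i in seq_len(nrow(lp))) {
    nm <- lp$name[i]
    curve <- config$causal_curves[[nm]]
    if (is.null(curve)) {
      stop("no causal curve defined for lipid '", nm, "'.", call. = FALSE)
    }
    y <- lp$baseline[i] +
      curve_value(curve, log_alcohol) +
      config$confounder_effect_outcome * lp$confounder_effect[i] *
        confounder +
      lp$sex_effect[i] * covariates$male +
      lp$age_effect[i] * (covariates$age - config$age_mean) +
      stats::rnorm(n, 0, lp$noise_sd[i])
    if (lp$scale[i] == "log") y <- exp(y)
    vals[, i] <- y
  }
  out <- as.data.frame(vals)
  # raw-scale lipids: the generator never emits negative concentrations
  for (i in which(lp$scale == "raw")) out[[lp$name[i]]] <- pmax(out[[lp$name[i]]], 0)
  out$hdl <- out$hdl2 + out$hdl3
  out <- out[c("tg", "total_chol", "hdl", "hdl3", "lpa", "sdldl", "apob")]
  for (i in seq_len(nrow(lp))) {
    nm <- lp$name[i]
    if (!nm %in% names(out)) next
    mr <- lp$missing_rate[i]
    if (mr > 0) out[[nm]][stats::runif(n) < mr] <- NA_real_
  }
  out
}

#' Generate a full synthetic cohort
#'
#' Draws sex, age, the latent confounder U and its observed proxies
#' (smoking, BMI, waist-to-hip ratio, diabetes), instrument genotypes,
#' drinking status and alcohol exposure, two ancestry principal components
#' (standard normal by default), and the lipid panel.  With a fixed seed
#' the output is fully reproducible.
#'
#' @param config an `mr_sim_config`.
#' @param genotype_panel optional wider dosage matrix from which PC1/PC2
#'   are computed via [compute_pcs()] instead of being drawn as normals.
#' @return list of class `mr_cohort` with elements `cohort` (data.frame)
#'   and `true_parameters` (the realized generative quantities, including
#'   the confounder vector and latent coefficients).
#' @export
generate_cohort <- function(config, genotype_panel = NULL) {
  if (!inherits(config, "mr_sim_config")) {
    stop("`config` must come from sim_config().", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_individuals

  male <- stats::rbinom(n, 1L, 1 - config$p_female)
  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  U <- stats::rnorm(n)
  covars <- data.frame(male = male, age = age)

  G <- simulate_genotypes(config$snps$maf, n)
  colnames(G) <- config$snps$snp_id
  carriers <- colSums(G > 0)
  few <- carriers < 10
  if (any(few)) {
    warning("fewer than 10 carriers for SNP(s): ",
            paste(config$snps$snp_id[few], collapse = ", "),
            " (rare-allele sampling at this n).", call. = FALSE)
  }

  expo <- simulate_exposure(G, covars, U, config)
  lipids <- simulate_lipids(expo$log_alcohol, U, covars, config)

  if (is.null(genotype_panel)) {
    PC1 <- stats::rnorm(n)
    PC2 <- stats::rnorm(n)
  } else {
    pcs <- compute_pcs(genotype_panel)
    PC1 <- pcs$scores[, 1L]
    PC2 <- pcs$scores[, 2L]
  }

  # observed confounder proxies, noisy functions of U
  smoke_latent <- 0.8 * U + stats::rnorm(n)
  smoking <- cut(smoke_latent, c(-Inf, 0.2, 1.0, Inf),
                 labels = c("never", "former", "current"))
  bmi <- 27.0 + 2.0 * U + stats::rnorm(n, 0, 4.4)
  whr <- 0.90 + 0.02 * U + stats::rnorm(n, 0, 0.09)
  diabetes <- stats::rbinom(n, 1L, stats::plogis(-2.45 + 0.5 * U))

  cohort <- data.frame(
    id = sprintf("ID%06d", seq_len(n)),
    sex = ifelse(male == 1L, "M", "F"),
    age = round(age, 1),
    age_v4 = round(age + config$visit4_age_offset, 1),
    drinking_status = expo$drinking_status,
    alcohol_g_wk = expo$alcohol_g_wk,
    drinks_per_wk = expo$drinks_per_wk,
    smoking = as.character(smoking),
    bmi = bmi,
    whr = whr,
    diabetes = diabetes,
    PC1 = PC1,
    PC2 = PC2,
    stringsAsFactors = FALSE
  )
  cohort <- cbind(cohort, as.data.frame(G), lipids)

  truth <- list(
    config = config,
    beta_latent = expo$beta_latent,
    attenuation = expo$attenuation,
    causal_curves = config$causal_curves,
    confounder = U,
    log_alcohol = expo$log_alcohol
  )
  structure(list(cohort = cohort, true_parameters = truth),
            class = "mr_cohort")
}

#' @export
print.mr_cohort <- function(x, ...) {
  cat("<mr_cohort> ", nrow(x$cohort), " individuals, ",
      nrow(x$true_parameters$config$snps), " instrument SNPs\n", sep = "")
  st <- table(x$cohort$drinking_status)
  cat("  status: ", paste(names(st), st, sep = "=", collapse = " "), "\n",
      sep = "")
  invisible(x)
}
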