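# shared fixtures, all generated in code

# small derived + scored cohort for pipeline-level tests
make_test_cohort <- function(n = 4000, seed = 101, ...) {
  cfg <- sim_config(n_individuals = n, seed = seed, ...)
  cc <- suppressWarnings(generate_cohort(cfg))
  coh <- suppressWarnings(derive_cohort(cc$cohort))
  coh <- suppressWarnings(score_cohort(coh))
  attr(coh, "truth") <- cc$true_parameters
  coh
}

# candidate roster for screening tests
make_candidates <- function(ids, fclass = NULL, ss = NULL) {
  m <- length(ids)
  data.frame(snp_id = ids,
             gene = rep("GENE", m),
             maf = rep(0.3, m),
             raising_allele = rep("A", m),
             other_allele = rep("G", m),
             functional_class = if (is.null(fclass)) rep("intronic", m) else fclass,
             sample_size = if (is.null(ss)) rep(1000L, m) else ss,
             beta = rep(0.05, m),
             stringsAsFactors = FALSE)
}

# copy-with-flips construction targeting high dosage correlation
make_ld_pair <- function(n = 5000, maf = 0.3, flip = 0.02, seed = 11) {
  set.seed(seed)
  a <- stats::rbinom(n, 2, maf)
  b <- a
  idx <- sample(n, round(flip * n))
  b[idx] <- stats::rbinom(length(idx), 2, maf)
  cbind(a = a, b = b)
}

# a benign confounder table uncorrelated with genotype
make_confounders <- function(n, seed = 12) {
  set.seed(seed)
  data.frame(
    smoking = sample(c("never", "former", "current"), n, replace = TRUE),
    bmi = stats::rnorm(n, 27, 4.5),
    whr = stats::rnorm(n, 0.9, 0.09),
    diabetes = stats::rbinom(n, 1, 0.09))
}
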