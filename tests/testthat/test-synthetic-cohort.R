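test_that("genotype simulation respects Hardy-Weinberg and the dosage support", {
  G <- simulate_genotypes(c(0.5), 4, seed = 1)
  expect_true(all(G %in% 0:2))
  expect_equal(dim(G), c(4L, 1L))

  # sample allele frequency within 3 SE of the rs698 default MAF
  n <- 100000
  G <- simulate_genotypes(0.409, n, seed = 2)
  af <- mean(G) / 2
  se <- sqrt(0.409 * (1 - 0.409) / (2 * n))
  expect_lt(abs(af - 0.409), 3 * se)

  # genotype-class proportions match the binomial closed form
  n <- 50000
  G <- simulate_genotypes(0.2, n, seed = 3)
  expected <- c(0.64, 0.32, 0.04)
  counts <- tabulate(G + 1L, nbins = 3L) / n
  se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(counts - expected) < 3 * se))
})

test_that("invalid allele frequencies and sizes are rejected", {
  expect_error(simulate_genotypes(0, 10), "0, 0.5")
  expect_error(simulate_genotypes(0.6, 10), "0, 0.5")
  expect_error(simulate_genotypes(0.2, 0), ">= 1")
  expect_error(sim_config(n_individuals = 0), "positive")
  expect_error(sim_config(status_probs = c(never = 0.5, former = 0.5,
                                           current = 0.5)), "sum to 1")
})

test_that("null genetic effects give null per-SNP slopes", {
  roster <- default_instrument_roster()
  roster$beta[] <- 0
  cfg <- sim_config(n_individuals = 20000, seed = 5, snps = roster,
                    confounder_effect_exposure = 0)
  cc <- suppressWarnings(generate_cohort(cfg))
  la <- log_alcohol(cc$cohort$alcohol_g_wk)
  for (id in c("rs698", "rs1126671")) {
    b <- per_snp_alcohol_beta(cc$cohort[[id]], la)
    se <- stats::sd(la) / (sqrt(20000) * stats::sd(cc$cohort[[id]]))
    expect_lt(abs(b), 3 * se)
  }
})

test_that("configured marginal per-allele effects are recovered at large n", {
  cfg <- sim_config(n_individuals = 200000, seed = 7)
  cc <- suppressWarnings(generate_cohort(cfg))
  la <- log_alcohol(cc$cohort$alcohol_g_wk)
  for (j in seq_len(nrow(cfg$snps))) {
    g <- cc$cohort[[cfg$snps$snp_id[j]]]
    b <- per_snp_alcohol_beta(g, la)
    se <- stats::sd(la) / (sqrt(length(la)) * stats::sd(g))
    expect_lt(abs(b - cfg$snps$beta[j]), 3 * se)
  }
})

test_that("null causal curve and confounding give lipid independent of exposure", {
  lp <- default_lipid_params()
  lp$sex_effect[] <- 0
  lp$age_effect[] <- 0  # shared sex/age effects would induce correlation
  cfg <- sim_config(n_individuals = 20000, seed = 8,
                    causal_curve = causal_null(),
                    confounder_effect_outcome = 0, lipids = lp)
  cc <- suppressWarnings(generate_cohort(cfg))
  ok <- stats::complete.cases(cc$cohort$tg)
  r <- stats::cor(log(cc$cohort$tg[ok]),
                  log_alcohol(cc$cohort$alcohol_g_wk)[ok])
  expect_lt(abs(r), 3 / sqrt(sum(ok)))
})

test_that("unknown curve names and lipids are rejected", {
  expect_error(sim_config(causal_curve = list(nope = causal_null())),
               "not in the lipid table")
  expect_error(curve_value(structure(list(kind = "spline"),
                                     class = "mr_curve"), 1),
               "unknown causal curve")
})

test_that("cohort generation is deterministic and matches status probabilities", {
  cfg <- sim_config(n_individuals = 10893, seed = 1)
  c1 <- suppressWarnings(generate_cohort(cfg))
  c2 <- suppressWarnings(generate_cohort(cfg))
  expect_identical(c1$cohort, c2$cohort)

  counts <- table(c1$cohort$drinking_status)
  p <- cfg$status_probs
  for (st in names(p)) {
    se <- sqrt(p[[st]] * (1 - p[[st]]) * 10893)
    expect_lt(abs(counts[[st]] - p[[st]] * 10893), 3 * se)
  }
  # non-drinkers carry zero intake; nothing negative leaves the generator
  expect_true(all(c1$cohort$alcohol_g_wk[
    c1$cohort$drinking_status != "current"] == 0))
  lips <- c("tg", "total_chol", "hdl", "hdl3", "lpa", "sdldl", "apob")
  expect_true(all(as.matrix(c1$cohort[lips]) >= 0, na.rm = TRUE))
})

test_that("true parameters round-trip through the YAML config serialization", {
  cfg <- sim_config(n_individuals = 500, seed = 3)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config_yaml(cfg, f)
  cfg2 <- read_sim_config_yaml(f)
  expect_equal(cfg2$snps, cfg$snps)
  expect_equal(cfg2$causal_curves, cfg$causal_curves)
  expect_equal(cfg2$exposure_noise_sd, cfg$exposure_noise_sd)
  expect_equal(cfg2$status_probs, cfg$status_probs)
  expect_identical(
    suppressWarnings(generate_cohort(cfg2))$cohort,
    suppressWarnings(generate_cohort(cfg))$cohort)
})

test_that("health-related abstention couples drinking status to the confounder", {
  cfg <- sim_config(n_individuals = 20000, seed = 9,
                    abstention_follows_confounder = TRUE)
  cc <- suppressWarnings(generate_cohort(cfg))
  U <- cc$true_parameters$confounder
  cur <- cc$cohort$drinking_status == "current"
  expect_lt(mean(U[cur]), mean(U[!cur]))

  cfg0 <- sim_config(n_individuals = 20000, seed = 9)
  cc0 <- suppressWarnings(generate_cohort(cfg0))
  U0 <- cc0$true_parameters$confounder
  cur0 <- cc0$cohort$drinking_status == "current"
  expect_lt(abs(mean(U0[cur0]) - mean(U0[!cur0])), 0.05)
})
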