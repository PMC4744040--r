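test_that("per-SNP beta equals the covariance closed form and rejects degenerate input", {
  set.seed(21)
  g <- stats::rbinom(500, 2, 0.3)
  y <- 0.1 * g + stats::rnorm(500)
  expect_equal(per_snp_alcohol_beta(g, y), stats::cov(g, y) / stats::var(g),
               tolerance = 1e-12)
  expect_equal(per_snp_alcohol_beta(g, rep(2, 500)), 0)
  expect_error(per_snp_alcohol_beta(rep(1, 500), y), "degenerate")
  expect_error(per_snp_alcohol_beta(g, y[-1]), "lengths differ")
})

test_that("allele orientation is an idempotent involution with non-negative slope", {
  set.seed(22)
  g <- stats::rbinom(800, 2, 0.4)
  y <- 0.2 * g + stats::rnorm(800)
  v <- list(snp_id = "rsX", raising_allele = "A", other_allele = "G")

  o1 <- orient_alleles(v, g, y)
  expect_false(o1$flipped)
  expect_identical(o1$dosage, g)

  # a negated copy flips back to the oriented dosage
  o2 <- orient_alleles(v, 2 - g, y)
  expect_true(o2$flipped)
  expect_equal(o2$dosage, as.numeric(g))
  expect_equal(o2$variant$raising_allele, "G")

  # idempotence: orienting oriented input changes nothing
  o3 <- orient_alleles(o2$variant, o2$dosage, y)
  expect_false(o3$flipped)
  expect_identical(o3$dosage, o2$dosage)
  expect_gte(per_snp_alcohol_beta(o3$dosage, y), 0)
})

test_that("after orientation all default SNPs have non-negative slopes", {
  coh <- make_test_cohort(n = 8000, seed = 23)
  roster <- default_instrument_roster()
  for (j in seq_len(nrow(roster))) {
    g <- coh[[roster$snp_id[j]]]
    if (stats::var(g) == 0) next
    o <- orient_alleles(roster[j, ], g, coh$derived_log_alcohol)
    expect_gte(per_snp_alcohol_beta(o$dosage, coh$derived_log_alcohol), 0)
  }
  sc <- attr(coh, "score")
  expect_s3_class(sc, "mr_score")
  b <- per_snp_alcohol_beta(coh$score_unweighted, coh$derived_log_alcohol)
  expect_gt(b, 0)
})

test_that("ld_r2 matches brute-force correlation and handles the overlap floor", {
  a <- c(0, 1, 2, 0, 1, 2, 2, 1, 0, 1)
  b <- c(0, 1, 2, 1, 1, 2, 2, 0, 0, 1)
  expect_equal(ld_r2(a, a, min_overlap = 5), 1)
  expect_equal(ld_r2(a, b, min_overlap = 5), stats::cor(a, b)^2,
               tolerance = 1e-12)
  expect_true(is.na(ld_r2(a, b, min_overlap = 50)))  # undetermined
  set.seed(24)
  g1 <- stats::rbinom(20000, 2, 0.3); g2 <- stats::rbinom(20000, 2, 0.3)
  expect_lt(ld_r2(g1, g2), 0.001)
  expect_error(ld_r2(a, rep(1, 10), min_overlap = 5), "degenerate")
})

test_that("a copy-with-noise pair lands near the target r2 of 0.96", {
  pair <- make_ld_pair(n = 20000, flip = 0.028, seed = 25)
  r2 <- ld_r2(pair[, "a"], pair[, "b"])
  expect_lt(abs(r2 - 0.96), 0.02)
})

test_that("screening applies the three screens with deterministic pruning", {
  n <- 5000
  set.seed(26)
  g1 <- stats::rbinom(n, 2, 0.3)
  g2 <- stats::rbinom(n, 2, 0.2)
  pair <- make_ld_pair(n = n, flip = 0.02, seed = 27)  # r2 ~ 0.96
  g3 <- pair[, "a"]; g4 <- pair[, "b"]
  g5 <- stats::rbinom(n, 2, 0.4)
  dos <- cbind(s1 = g1, s2 = g2, s3 = g3, s4 = g4, s5 = g5)
  conf <- make_confounders(n, seed = 28)
  cand <- make_candidates(colnames(dos),
                          fclass = c("intronic", "intronic", "exonic",
                                     "intronic", "intronic"))

  res <- screen_candidates(cand, dos, NULL, conf)
  expect_setequal(res$report$snp_id, colnames(dos))
  # exactly one of the high-LD pair survives, chosen by functional class
  expect_true("s3" %in% res$instruments$snp_id)
  expect_false("s4" %in% res$instruments$snp_id)
  expect_equal(res$report$reason[res$report$snp_id == "s4"],
               "pruned_pairwise")
  expect_setequal(res$instruments$snp_id, c("s1", "s2", "s3", "s5"))

  # a planted confounder correlation of r ~ 0.15 fails that SNP
  conf2 <- conf
  conf2$bmi <- 0.15 * 4.5 * (g5 - mean(g5)) / stats::sd(g5) +
    stats::rnorm(n, 27, 4.5 * sqrt(1 - 0.15^2))
  res2 <- screen_candidates(cand, dos, NULL, conf2)
  row5 <- res2$report[res2$report$snp_id == "s5", ]
  expect_equal(row5$reason, "fail_confounder_corr")
  expect_gt(abs(row5$statistic), 0.1)

  # lipid-locus LD screen
  lipid_loci <- cbind(L1 = make_ld_pair(n = n, maf = 0.3, flip = 0.3,
                                        seed = 29)[, "b"])
  # construct a locus in moderate LD with s1 by reusing s1 with heavy noise
  set.seed(30)
  mix <- stats::runif(n) < 0.5
  lipid_loci[mix, 1] <- g1[mix]
  res3 <- screen_candidates(cand, dos, lipid_loci, conf)
  r2_check <- ld_r2(g1, lipid_loci[, 1])
  if (r2_check > 0.2) {
    expect_equal(res3$report$reason[res3$report$snp_id == "s1"],
                 "fail_ld_lipid_locus")
  }
  expect_error(screen_candidates(cand[0, ], dos, NULL, conf), "empty")
  expect_error(screen_candidates(cand, dos, NULL, conf[, -2]),
               "missing column")
})

test_that("screening is invariant to candidate order", {
  n <- 4000
  pair <- make_ld_pair(n = n, flip = 0.02, seed = 31)
  set.seed(32)
  dos <- cbind(a1 = pair[, "a"], a2 = pair[, "b"],
               a3 = stats::rbinom(n, 2, 0.25),
               a4 = stats::rbinom(n, 2, 0.45))
  conf <- make_confounders(n, seed = 33)
  cand <- make_candidates(colnames(dos),
                          fclass = c("intronic", "intronic", "exonic",
                                     "exonic"),
                          ss = c(5000L, 9000L, 1000L, 2000L))
  base <- screen_candidates(cand, dos, NULL, conf)$instruments$snp_id
  for (perm in list(c(4, 3, 2, 1), c(2, 1, 4, 3), c(3, 1, 4, 2))) {
    got <- screen_candidates(cand[perm, ], dos, NULL,
                             conf)$instruments$snp_id
    expect_setequal(got, base)
  }
  # within the high-LD pair of equal functional class, larger sample wins
  expect_true("a2" %in% base)
  expect_false("a1" %in% base)
})

test_that("unweighted score is the dosage sum with bounds and variance as expected", {
  expect_equal(build_score(matrix(0, 5, 3))$score, rep(0, 5))
  expect_equal(build_score(matrix(2, 1, 5))$score, 10)

  mafs <- c(0.1, 0.25, 0.4)
  G <- simulate_genotypes(mafs, 50000, seed = 34)
  colnames(G) <- paste0("v", 1:3)
  sc <- build_score(G)
  expect_true(all(sc$score >= 0 & sc$score <= 6))
  v_theory <- sum(2 * mafs * (1 - mafs))
  expect_lt(abs(stats::var(sc$score) - v_theory), 4 * v_theory / sqrt(50000))

  # incomplete dosages give NA scores, no imputation
  G2 <- G[1:100, ]
  G2[3, 2] <- NA
  sc2 <- build_score(G2)
  expect_true(is.na(sc2$score[3]))
  expect_equal(sum(is.na(sc2$score)), 1L)
  expect_error(build_score(matrix(numeric(0), 5, 0)), "no instrument")
})

test_that("score revalidation flags confounder and lipid-locus breaches", {
  n <- 3000
  G <- simulate_genotypes(c(0.3, 0.4), n, seed = 35)
  colnames(G) <- c("v1", "v2")
  conf <- make_confounders(n, seed = 36)
  sc <- build_score(G, confounder_table = conf)
  expect_true(sc$flags[["confounders"]])

  s <- rowSums(G)
  conf_bad <- conf
  conf_bad$bmi <- 27 + 2 * s + stats::rnorm(n, 0, 1)
  expect_error(build_score(G, confounder_table = conf_bad, strict = TRUE),
               "failed validation")
  sc_bad <- build_score(G, confounder_table = conf_bad, strict = FALSE)
  expect_false(sc_bad$flags[["confounders"]])
})
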