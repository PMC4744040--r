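test_that("first-stage F and partial R2 satisfy the algebraic identity", {
  coh <- make_test_cohort(n = 4000, seed = 41)
  fs <- fit_first_stage(coh)
  expect_gte(fs$partial_r2, 0)
  expect_lte(fs$partial_r2, 1)
  expect_gte(fs$F_stat, 0)
  expect_equal(fs$F_stat,
               fs$partial_r2 / (1 - fs$partial_r2) * (fs$n - fs$k),
               tolerance = 1e-8)

  # a score orthogonalized to the exposure gives a null F
  set.seed(42)
  coh$score_null <- sample(coh$score_unweighted)
  fs0 <- fit_first_stage(coh, score_col = "score_null")
  expect_lt(fs0$partial_r2, 0.005)
})

test_that("first stage rejects rank-deficient designs naming the column", {
  coh <- make_test_cohort(n = 500, seed = 43)
  coh$PC3 <- coh$PC1
  expect_error(
    fit_first_stage(coh, covariates = c("sex", "age", "PC1", "PC2", "PC3")),
    "PC3")
})

test_that("quartile assignment partitions fitted values with ties to the lower quartile", {
  qa <- assign_quartiles(as.numeric(1:8))
  expect_equal(as.integer(table(qa$label)), c(2L, 2L, 2L, 2L))
  expect_equal(qa$breaks_g_wk, expm1(qa$breaks))

  # datum exactly on a break goes low: for 1..9 the 25th percentile is 3
  qa9 <- assign_quartiles(as.numeric(1:9))
  expect_equal(qa9$breaks[1], 3)
  expect_equal(as.character(qa9$label[3]), "q1")

  expect_error(assign_quartiles(rep(1, 100)), "degenerate")
  expect_error(assign_quartiles(1:5), "at least 8")

  coh <- make_test_cohort(n = 10000, seed = 44)
  qa <- assign_quartiles(fit_first_stage(coh))
  shares <- prop.table(table(qa$label))
  expect_true(all(abs(shares - 0.25) < 0.01))
})

test_that("second stage is null-calibrated and matches the brute-force Wald form", {
  coh <- make_test_cohort(n = 5000, seed = 45,
                          causal_curve = causal_null(),
                          confounder_effect_outcome = 0)
  sub <- coh[stats::complete.cases(
    coh[, c("derived_ln_tg", "score_unweighted", "derived_log_alcohol",
            "sex", "age", "PC1", "PC2")]), ]
  fs <- fit_first_stage(sub)
  ss <- fit_second_stage(sub, "derived_ln_tg", assign_quartiles(fs))
  expect_true(all(abs(ss$table$beta[-1]) < 0.2))
  expect_equal(ss$table$beta[1], 0)

  # overall Wald equals c' V^-1 c computed directly from the lm fit
  b <- stats::coef(ss$fit)
  qn <- paste0(".quartile", c("q2", "q3", "q4"))
  V <- ss$vcov[qn, qn]
  expect_equal(ss$wald_overall,
               drop(t(b[qn]) %*% solve(V) %*% b[qn]), tolerance = 1e-10)
  # CIs bracket the estimates
  expect_true(all(ss$table$ci_low[-1] <= ss$table$beta[-1] &
                    ss$table$beta[-1] <= ss$table$ci_high[-1]))
})

test_that("continuous 2SLS equals the closed-form IV solution on random designs", {
  set.seed(46)
  for (rep in 1:20) {
    n <- 60
    dat <- data.frame(z = stats::rnorm(n), c1 = stats::rnorm(n),
                      c2 = stats::rnorm(n))
    dat$x <- 0.5 * dat$z + 0.3 * dat$c1 + stats::rnorm(n)
    dat$y <- -0.4 * dat$x + 0.2 * dat$c2 + stats::rnorm(n)
    fit <- fit_linear_2sls(dat, "y", "x", "z", covariates = c("c1", "c2"))
    Z <- cbind(1, dat$c1, dat$c2, dat$z)
    W <- cbind(1, dat$c1, dat$c2, dat$x)
    closed <- solve(crossprod(Z, W), crossprod(Z, dat$y))
    expect_equal(unname(fit$coefficients[["xhat"]]), closed[4, 1],
                 tolerance = 1e-8)
  }
})

test_that("single-instrument no-covariate 2SLS is the Wald ratio, identity instrument is OLS", {
  set.seed(47)
  n <- 300
  z <- stats::rbinom(n, 2, 0.3)
  x <- 0.3 * z + stats::rnorm(n)
  y <- 0.7 * x + stats::rnorm(n)
  dat <- data.frame(z = z, x = x, y = y)
  fit <- fit_linear_2sls(dat, "y", "x", "z", covariates = character(0))
  expect_equal(fit$beta, stats::cov(z, y) / stats::cov(z, x),
               tolerance = 1e-10)

  fit_id <- fit_linear_2sls(dat, "y", "x", "x", covariates = character(0))
  ols <- stats::coef(stats::lm(y ~ x))
  expect_equal(fit_id$beta, unname(ols[2]), tolerance = 1e-10)
  expect_true(fit$ci[1] < fit$beta && fit$beta < fit$ci[2])
})

test_that("adding a constant to the exposure shifts only intercepts", {
  coh <- make_test_cohort(n = 4000, seed = 48)
  sub <- coh[stats::complete.cases(
    coh[, c("derived_ln_tg", "score_unweighted", "derived_log_alcohol",
            "sex", "age", "PC1", "PC2")]), ]
  fs1 <- fit_first_stage(sub)
  q1 <- assign_quartiles(fs1)
  s1 <- fit_second_stage(sub, "derived_ln_tg", q1)

  sub2 <- sub
  sub2$derived_log_alcohol <- sub2$derived_log_alcohol + 5
  fs2 <- fit_first_stage(sub2)
  q2 <- assign_quartiles(fs2)
  s2 <- fit_second_stage(sub2, "derived_ln_tg", q2)

  expect_identical(as.character(q1$label), as.character(q2$label))
  expect_equal(s2$table$beta, s1$table$beta, tolerance = 1e-8)
  expect_equal(fs2$coefficients[["(Intercept)"]],
               fs1$coefficients[["(Intercept)"]] + 5, tolerance = 1e-8)
  expect_equal(fs2$partial_r2, fs1$partial_r2, tolerance = 1e-10)
})

test_that("principal components separate populations and obey conventions", {
  set.seed(49)
  n_per <- 150; m <- 60
  maf_a <- stats::runif(m, 0.1, 0.5)
  shift <- stats::runif(m, -0.25, 0.25)
  maf_b <- pmin(pmax(maf_a + shift, 0.05), 0.95)
  Ga <- sapply(maf_a, function(p) stats::rbinom(n_per, 2, p))
  Gb <- sapply(maf_b, function(p) stats::rbinom(n_per, 2, p))
  G <- rbind(Ga, Gb)
  pcs <- compute_pcs(G)

  pop <- rep(c(0, 1), each = n_per)
  expect_gt(abs(mean(pcs$scores[pop == 1, 1]) -
                  mean(pcs$scores[pop == 0, 1])),
            2 * stats::sd(pcs$scores[, 1]) / sqrt(n_per))
  # orthonormal to numerical precision
  expect_equal(crossprod(pcs$scores), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # sign convention stable under row permutation
  perm <- sample(nrow(G))
  pcs_p <- compute_pcs(G[perm, ])
  expect_equal(pcs_p$scores[order(perm)[1:10], 1], pcs$scores[1:10, 1],
               tolerance = 1e-8)

  Gc <- cbind(G, const = 2)
  expect_warning(compute_pcs(Gc), "constant")
  expect_error(compute_pcs(matrix(1, 10, 3)), "constant")
})
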