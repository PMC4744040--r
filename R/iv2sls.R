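#' First-stage exposure regression with weak-instrument diagnostics
#'
#' OLS of the exposure (log-alcohol) on the genetic score plus covariates.
#' The instrument-strength F is the nested-model F comparing the full
#' model against the covariate-only model, and the partial R-squared is
#' the proportional RSS reduction attributable to the score:
#' (RSS_reduced - RSS_full) / RSS_reduced.  These satisfy
#' F = partialR2 / (1 - partialR2) * (n - k) exactly, with k the number of
#' full-model coefficients.
#'
#' @param cohort data.frame of complete-case rows.
#' @param exposure_col name of the exposure column.
#' @param score_col name of the score column.
#' @param covariates character vector of covariate column names (default
#'   sex, age, PC1, PC2; `sex` may be character M/F).
#' @return object of class `mr_first_stage` with coefficients, fitted
#'   values, `rss`, `n`, `k`, `F_stat`, `partial_r2`.
#' @export
fit_first_stage <- function(cohort, exposure_col = "derived_log_alcohol",
                            score_col = "score_unweighted",
                            covariates = c("sex", "age", "PC1", "PC2")) {
  dat <- model_data(cohort, c(exposure_col, score_col, covariates))
  n <- nrow(dat)
  Xf <- design_matrix(dat, c(score_col, covariates))
  Xr <- design_matrix(dat, covariates)
  k <- ncol(Xf)
  if (n <= k) stop("fewer observations than coefficients.", call. = FALSE)
  check_full_rank(Xf)
  y <- dat[[exposure_col]]

  fit_full <- stats::lm.fit(Xf, y)
  fit_red <- stats::lm.fit(Xr, y)
  rss_full <- sum(fit_full$residuals^2)
  rss_red <- sum(fit_red$residuals^2)
  partial_r2 <- (rss_red - rss_full) / rss_red
  F_stat <- (rss_red - rss_full) / (rss_full / (n - k))

  structure(list(coefficients = fit_full$coefficients,
                 fitted = drop(Xf %*% fit_full$coefficients),
                 rss = rss_full, n = n, k = k,
                 F_stat = F_stat, partial_r2 = partial_r2,
                 exposure_col = exposure_col, score_col = score_col,
                 covariates = covariates,
                 rows = attr(dat, "rows")),
            class = "mr_first_stage")
}

#' @export
print.mr_first_stage <- function(x, ...) {
  cat("<mr_first_stage> n =", x$n, "\n")
  cat(sprintf("  score coefficient: %.4g\n", x$coefficients[[x$score_col]]))
  cat(sprintf("  partial R2 = %.4g (%.2f%%), F = %.2f%s\n",
              x$partial_r2, 100 * x$partial_r2, x$F_stat,
              if (x$F_stat <= 10) "  [weak-instrument warning]" else ""))
  invisible(x)
}

#' Quartiles of predicted exposure
#'
#' Cuts the first-stage fitted log-alcohol at its empirical 25/50/75
#' percentiles.  Individuals exactly on a boundary go to the lower
#' quartile.  Boundaries are also reported back-transformed to g/wk via
#' exp(x) - 1.
#'
#' @param first_stage an `mr_first_stage`, or a numeric vector of fitted
#'   values.
#' @return object of class `mr_quartiles`: `label` (factor q1..q4),
#'   `breaks` (log scale), `breaks_g_wk`.
#' @export
assign_quartiles <- function(first_stage) {
  fitted <- if (inherits(first_stage, "mr_first_stage")) {
    first_stage$fitted
  } else {
    as.numeric(first_stage)
  }
  if (length(fitted) < 8) {
    stop("insufficient data: need at least 8 fitted values.", call. = FALSE)
  }
  br <- stats::quantile(fitted, c(0.25, 0.5, 0.75), names = FALSE)
  if (anyDuplicated(br)) {
    stop("degenerate quartiles: fitted values cannot be partitioned.",
         call. = FALSE)
  }
  lab <- cut(fitted, c(-Inf, br, Inf), labels = paste0("q", 1:4),
             right = TRUE)
  structure(list(label = lab, breaks = br, breaks_g_wk = expm1(br)),
            class = "mr_quartiles")
}

#' @export
print.mr_quartiles <- function(x, ...) {
  cat("<mr_quartiles> breaks (ln scale):",
      paste(sprintf("%.3f", x$breaks), collapse = ", "), "\n")
  cat("  back-transformed (g/wk):",
      paste(sprintf("%.2f", x$breaks_g_wk), collapse = ", "), "\n")
  print(table(x$label))
  invisible(x)
}

#' Second-stage quartile regression with Wald tests
#'
#' Regresses the (possibly log-transformed) lipid on indicators for
#' quartiles 2-4 of predicted exposure (quartile 1 is the reference) plus
#' covariates.  Reports per-quartile Wald z tests and 95% CIs and a
#' 3-degree-of-freedom overall Wald chi-squared test, using either a
#' heteroskedasticity-robust (HC1 sandwich, the default) or classical OLS
#' covariance.  Large-sample normal/chi-squared reference distributions
#' are used throughout.  CIs are conditional on the estimated quartile
#' assignment (no generated-regressor correction exists in closed form
#' for quartiled fitted values).
#'
#' @param cohort data.frame (same rows the first stage was fit on).
#' @param lipid_col outcome column name.
#' @param quartiles an `mr_quartiles` for those rows.
#' @param covariates covariate column names.
#' @param vcov_type "HC1" (sandwich, default) or "const" (classical).
#' @return object of class `mr_second_stage`: `table` (per-quartile beta,
#'   CI, p), `p_overall`, `wald_overall`, `n`, `vcov_type`.
#' @export
fit_second_stage <- function(cohort, lipid_col, quartiles,
                             covariates = c("sex", "age", "PC1", "PC2"),
                             vcov_type = c("HC1", "const")) {
  vcov_type <- match.arg(vcov_type)
  if (!inherits(quartiles, "mr_quartiles")) {
    stop("`quartiles` must come from assign_quartiles().", call. = FALSE)
  }
  if (nrow(cohort) != length(quartiles$label)) {
    stop("cohort rows and quartile labels differ in length.", call. = FALSE)
  }
  dat <- cohort[, c(lipid_col, covariates), drop = FALSE]
  dat$.quartile <- quartiles$label
  ok <- stats::complete.cases(dat)
  dat <- dat[ok, , drop = FALSE]
  counts <- table(dat$.quartile)
  if (any(counts == 0)) {
    stop("empty quartile after missing-data removal: ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  }
  fml <- stats::as.formula(paste0(
    "`", lipid_col, "` ~ .quartile + ",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  dat2 <- dat
  if (is.character(dat2$sex)) dat2$sex <- factor(dat2$sex)
  fit <- stats::lm(fml, data = dat2)
  V <- if (vcov_type == "HC1") sandwich::vcovHC(fit, type = "HC1") else
    stats::vcov(fit)
  b <- stats::coef(fit)
  qnames <- paste0(".quartile", c("q2", "q3", "q4"))
  se <- sqrt(diag(V)[qnames])
  est <- b[qnames]
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  ci_lo <- est - stats::qnorm(0.975) * se
  ci_hi <- est + stats::qnorm(0.975) * se

  Vq <- V[qnames, qnames]
  wald <- drop(t(est) %*% solve(Vq, est))
  p_overall <- stats::pchisq(wald, df = 3, lower.tail = FALSE)

  tab <- data.frame(quartile = c("q1", "q2", "q3", "q4"),
                    beta = c(0, unname(est)),
                    ci_low = c(NA, unname(ci_lo)),
                    ci_high = c(NA, unname(ci_hi)),
                    p = c(NA, unname(p)),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, p_overall = p_overall, wald_overall = wald,
                 n = nrow(dat), vcov_type = vcov_type, fit = fit,
                 vcov = V, lipid_col = lipid_col),
            class = "mr_second_stage")
}

#' @export
print.mr_second_stage <- function(x, ...) {
  cat("<mr_second_stage> outcome:", x$lipid_col, " n =", x$n, "\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("  overall Wald chi2(3) = %.3f, p = %.4g  [%s vcov]\n",
              x$wald_overall, x$p_overall, x$vcov_type))
  invisible(x)
}

#' Continuous-exposure two-stage least squares
#'
#' The explicit two-step estimator: stage 1 regresses the exposure on the
#' instrument plus covariates; stage 2 regresses the outcome on the
#' stage-1 fitted exposure plus the same covariates.  The coefficient on
#' fitted exposure is the 2SLS causal-effect estimate; its standard error
#' uses the proper 2SLS residual correction (residuals recomputed with the
#' observed, not predicted, exposure).
#'
#' @param cohort data.frame.
#' @param outcome_col,exposure_col,instrument_col column names.
#' @param covariates covariate column names (may be empty).
#' @return list of class `mr_2sls`: `beta`, `se`, `ci` (95%), `n`,
#'   `first_stage_F`, plus the full coefficient vector.
#' @export
fit_linear_2sls <- function(cohort, outcome_col, exposure_col,
                            instrument_col,
                            covariates = c("sex", "age", "PC1", "PC2")) {
  dat <- model_data(cohort, c(outcome_col, exposure_col, instrument_col,
                              covariates))
  n <- nrow(dat)
  C <- if (length(covariates)) design_matrix(dat, covariates) else
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  y <- dat[[outcome_col]]
  x <- dat[[exposure_col]]
  z <- dat[[instrument_col]]

  Z <- cbind(C, z)
  colnames(Z)[ncol(Z)] <- instrument_col
  check_full_rank(Z)
  s1 <- stats::lm.fit(Z, x)
  xhat <- drop(Z %*% s1$coefficients)
  rss_red <- sum(stats::lm.fit(C, x)$residuals^2)
  rss_full <- sum(s1$residuals^2)
  F_stat <- (rss_red - rss_full) / (rss_full / (n - ncol(Z)))

  W_hat <- cbind(xhat = xhat, C)
  s2 <- stats::lm.fit(W_hat, y)
  beta <- s2$coefficients
  # 2SLS sigma^2 from residuals with the observed exposure
  W_obs <- cbind(xhat = x, C)
  resid <- y - drop(W_obs %*% beta)
  sigma2 <- sum(resid^2) / (n - ncol(W_hat))
  XtXinv <- chol2inv(chol(crossprod(W_hat)))
  se <- sqrt(sigma2 * diag(XtXinv))
  names(se) <- colnames(W_hat)

  b <- beta[["xhat"]]
  s <- se[["xhat"]]
  structure(list(beta = b, se = s,
                 ci = c(b - stats::qnorm(0.975) * s,
                        b + stats::qnorm(0.975) * s),
                 n = n, first_stage_F = F_stat,
                 coefficients = beta, se_all = se),
            class = "mr_2sls")
}

#' @export
print.mr_2sls <- function(x, ...) {
  cat(sprintf("<mr_2sls> beta = %.4g (SE %.4g), 95%% CI [%.4g, %.4g], n = %d\n",
              x$beta, x$se, x$ci[1], x$ci[2], x$n))
  cat(sprintf("  first-stage F = %.2f\n", x$first_stage_F))
  invisible(x)
}

#' Ancestry principal components from a genotype matrix
#'
#' A functional stand-in for standard population-stratification PCs:
#' dosage columns are centred at twice the allele frequency and scaled by
#' sqrt(2 p (1 - p)), constant columns are dropped with a warning, and the
#' leading two left singular vectors are returned (unit norm).  Signs are
#' fixed by making each component's largest-magnitude score positive, so
#' the convention is stable under row permutation.
#'
#' @param genotypes dosage matrix (individuals by SNPs, values in [0, 2]).
#' @param n_pcs number of components (default 2).
#' @return list with `scores` (n x n_pcs matrix, columns PC1, PC2, ...)
#'   and `d` (singular values).
#' @export
compute_pcs <- function(genotypes, n_pcs = 2L) {
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) < 2 || nrow(genotypes) < 3) {
    stop("need at least 2 SNPs and 3 individuals.", call. = FALSE)
  }
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  v <- apply(genotypes, 2, stats::var, na.rm = TRUE)
  keep <- p > 0 & p < 1 & is.finite(v) & v > 0
  if (!any(keep)) stop("all SNP columns are constant.", call. = FALSE)
  if (any(!keep)) {
    warning(sum(!keep), " constant SNP column(s) dropped.", call. = FALSE)
  }
  G <- genotypes[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(G, 2, 2 * p, "-")
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  Z[is.na(Z)] <- 0
  n_pcs <- min(n_pcs, ncol(Z), nrow(Z))
  sv <- svd(Z, nu = n_pcs, nv = 0)
  scores <- sv$u
  for (j in seq_len(ncol(scores))) {
    i_max <- which.max(abs(scores[, j]))
    if (scores[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  list(scores = scores, d = sv$d[seq_len(n_pcs)])
}

# ---- shared design helpers ------------------------------------------------

# complete-case subset, remembering which rows survive
model_data <- function(cohort, cols) {
  miss <- setdiff(cols, names(cohort))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  dat <- cohort[, cols, drop = FALSE]
  ok <- stats::complete.cases(dat)
  out <- dat[ok, , drop = FALSE]
  attr(out, "rows") <- which(ok)
  out
}

# intercept + numeric columns; character sex coded M = 1
design_matrix <- function(dat, cols) {
  X <- matrix(1, nrow(dat), 1, dimnames = list(NULL, "(Intercept)"))
  for (cl in cols) {
    v <- dat[[cl]]
    if (is.character(v) || is.factor(v)) {
      v <- as.character(v)
      if (!all(v %in% c("M", "F"))) {
        stop("cannot code non-numeric column '", cl, "'.", call. = FALSE)
      }
      v <- as.numeric(v == "M")
    }
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cl
  }
  X
}

check_full_rank <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1, ncol(X))]]
    stop("collinear design; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
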