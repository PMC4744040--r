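#' Univariate per-SNP effect on log-alcohol
#'
#' Ordinary least-squares slope of log-alcohol on dosage (the scale on
#' which instrument effects are reported: change in ln(g/wk + 1) per
#' raising allele).
#'
#' @param dosage genotype dosage vector (0..2; NA allowed).
#' @param log_alcohol ln(g/wk + 1) vector, same length.
#' @return the OLS slope.
#' @export
per_snp_alcohol_beta <- function(dosage, log_alcohol) {
  if (length(dosage) != length(log_alcohol)) {
    stop("dosage and log_alcohol lengths differ.", call. = FALSE)
  }
  ok <- stats::complete.cases(dosage, log_alcohol)
  d <- dosage[ok]; y <- log_alcohol[ok]
  v <- stats::var(d)
  if (!is.finite(v) || v == 0) {
    stop("degenerate regressor: dosage is constant.", call. = FALSE)
  }
  stats::cov(d, y) / v
}

#' Orient dosages to the alcohol-raising allele
#'
#' If the fitted univariate slope of log-alcohol on dosage is negative,
#' the dosage is flipped to 2 - G and the recorded raising allele is
#' swapped, so that after orientation every instrument's slope is
#' non-negative.  Applying the operation twice is a no-op.
#'
#' @param variant one-row data.frame (or list) with at least `snp_id` and
#'   `raising_allele`; `other_allele` is swapped in when present.
#' @param dosage dosage vector.
#' @param log_alcohol exposure vector.
#' @return list with `dosage` (oriented), `variant` (updated record) and
#'   `flipped` (logical).
#' @export
orient_alleles <- function(variant, dosage, log_alcohol) {
  slope <- per_snp_alcohol_beta(dosage, log_alcohol)
  flipped <- slope < 0
  if (flipped) {
    dosage <- 2 - dosage
    if (!is.null(variant$other_allele)) {
      tmp <- variant$raising_allele
      variant$raising_allele <- variant$other_allele
      variant$other_allele <- tmp
    } else {
      variant$raising_allele <- NA_character_
    }
  }
  list(dosage = dosage, variant = variant, flipped = flipped)
}

# pairwise-complete Pearson r with a minimum-overlap floor; returns NA
# ("undetermined") below the floor
pairwise_r <- function(a, b, min_overlap = 50L) {
  ok <- stats::complete.cases(a, b)
  if (sum(ok) < min_overlap) return(NA_real_)
  if (stats::var(a[ok]) == 0 || stats::var(b[ok]) == 0) {
    stop("degenerate vector: no variation on the overlap.", call. = FALSE)
  }
  stats::cor(a[ok], b[ok])
}

#' Composite-genotype linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of the two dosage vectors, the standard LD
#' estimator for unphased genotype data.
#'
#' @param dosage_a,dosage_b dosage vectors of equal length.
#' @param min_overlap minimum pairwise-complete sample size below which
#'   the statistic is undetermined (NA).
#' @return r-squared in [0, 1], or NA when undetermined.
#' @export
ld_r2 <- function(dosage_a, dosage_b, min_overlap = 50L) {
  if (length(dosage_a) != length(dosage_b)) {
    stop("dosage vectors must have equal length.", call. = FALSE)
  }
  pairwise_r(dosage_a, dosage_b, min_overlap)^2
}

# numeric coding for the confounder screen: smoking never/former/current
# as 0/1/2, logicals as 0/1, numerics as-is
code_confounder <- function(x) {
  if (is.numeric(x)) return(x)
  if (is.logical(x)) return(as.numeric(x))
  lv <- c(never = 0, former = 1, current = 2)
  x <- as.character(x)
  if (all(x %in% c(names(lv), NA))) return(unname(lv[x]))
  stop("cannot numerically code confounder values: ",
       paste(utils::head(unique(x)), collapse = ", "), call. = FALSE)
}

#' Screen candidate instruments against the IV assumptions
#'
#' Applies, in order: (1) LD with lipid-associated loci (fail when
#' r-squared exceeds `thresholds["ld_lipid"]` for any supplied lipid-locus
#' genotype), (2) Pearson correlation with potential confounders (fail
#' when |r| exceeds `thresholds["confounder_r"]` for any confounder), and
#' (3) pairwise-redundancy pruning: within each connected component of the
#' r-squared > `thresholds["ld_pairwise"]` graph, one SNP is kept, chosen
#' by functional class (exonic/splicing outrank all else), then largest
#' source sample size, then lexicographically smallest snp_id.  The
#' surviving-set choice is therefore invariant to candidate order.
#'
#' @param candidates data.frame with `snp_id`, `functional_class`,
#'   `sample_size` (and any other roster columns, carried through).
#' @param dosages matrix of candidate dosages, columns named by snp_id.
#' @param lipid_locus_dosages matrix of lipid-associated locus dosages, or
#'   NULL to skip screen (1).
#' @param confounder_table data.frame with columns smoking, bmi, whr,
#'   diabetes (smoking may be character never/former/current).
#' @param thresholds named vector, defaults
#'   `c(ld_lipid = 0.2, confounder_r = 0.1, ld_pairwise = 0.7)`.
#' @param strict when TRUE, an undetermined statistic (insufficient
#'   pairwise overlap) fails the screen; when FALSE it passes with a
#'   recorded NA.
#' @return list with `report` (one row per candidate: decision, reason,
#'   statistic) and `instruments` (the surviving subset of `candidates`).
#' @export
screen_candidates <- function(candidates, dosages,
                              lipid_locus_dosages = NULL,
                              confounder_table,
                              thresholds = c(ld_lipid = 0.2,
                                             confounder_r = 0.1,
                                             ld_pairwise = 0.7),
                              strict = TRUE) {
  if (!nrow(candidates)) {
    stop("empty candidate set.", call. = FALSE)
  }
  if (!all(candidates$snp_id %in% colnames(dosages))) {
    stop("dosage columns missing for: ",
         paste(setdiff(candidates$snp_id, colnames(dosages)),
               collapse = ", "), call. = FALSE)
  }
  need_conf <- c("smoking", "bmi", "whr", "diabetes")
  miss <- setdiff(need_conf, names(confounder_table))
  if (length(miss)) {
    stop("confounder table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  thr <- thresholds
  ids <- candidates$snp_id
  m <- length(ids)
  reason <- rep("pass", m)
  stat <- rep(NA_real_, m)

  conf_num <- lapply(confounder_table[need_conf], code_confounder)

  for (i in seq_len(m)) {
    g <- dosages[, ids[i]]
    # screen 1: LD with lipid-related loci
    if (!is.null(lipid_locus_dosages) && ncol(lipid_locus_dosages) > 0) {
      r2 <- vapply(seq_len(ncol(lipid_locus_dosages)),
                   function(j) ld_r2(g, lipid_locus_dosages[, j]),
                   numeric(1))
      worst <- if (all(is.na(r2))) NA_real_ else max(r2, na.rm = TRUE)
      if ((is.na(worst) && strict) ||
          (!is.na(worst) && worst > thr[["ld_lipid"]])) {
        reason[i] <- "fail_ld_lipid_locus"
        stat[i] <- worst
        next
      }
    }
    # screen 2: correlation with potential confounders
    r <- vapply(conf_num, function(cf) pairwise_r(g, cf), numeric(1))
    worst <- if (all(is.na(r))) NA_real_ else r[which.max(abs(r))]
    if ((anyNA(r) && strict) ||
        (!is.na(worst) && abs(worst) > thr[["confounder_r"]])) {
      reason[i] <- "fail_confounder_corr"
      stat[i] <- worst
    }
  }

  # screen 3: pairwise pruning of the survivors
  alive <- which(reason == "pass")
  if (length(alive) > 1) {
    k <- length(alive)
    adj <- matrix(FALSE, k, k)
    for (a in seq_len(k - 1)) {
      for (b in seq(a + 1, k)) {
        r2 <- ld_r2(dosages[, ids[alive[a]]], dosages[, ids[alive[b]]])
        linked <- if (is.na(r2)) strict else r2 > thr[["ld_pairwise"]]
        if (linked) adj[a, b] <- adj[b, a] <- TRUE
      }
    }
    comp <- connected_components(adj)
    for (cc in unique(comp)) {
      members <- alive[comp == cc]
      if (length(members) < 2) next
      keep <- members[order(functional_rank(candidates$functional_class[members]),
                            -candidates$sample_size[members],
                            candidates$snp_id[members])][1L]
      drop <- setdiff(members, keep)
      for (d in drop) {
        reason[d] <- "pruned_pairwise"
        stat[d] <- ld_r2(dosages[, ids[d]], dosages[, ids[keep]])
      }
    }
  }

  report <- data.frame(snp_id = ids,
                       decision = ifelse(reason == "pass", "pass", "fail"),
                       reason = reason,
                       statistic = stat,
                       stringsAsFactors = FALSE)
  list(report = report,
       instruments = candidates[reason == "pass", , drop = FALSE])
}

# exonic/splicing outrank everything else
functional_rank <- function(x) {
  ifelse(x %in% c("exonic", "splicing"), 1L, 2L)
}

# connected components of an undirected adjacency matrix (tiny graphs)
connected_components <- function(adj) {
  k <- nrow(adj)
  comp <- integer(k)
  cur <- 0L
  for (s in seq_len(k)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Build the unweighted genetic risk score
#'
#' The score is the plain sum of oriented raising-allele dosages over the
#' surviving instrument SNPs, computed only for individuals with complete
#' dosages (no imputation).  The score itself is then re-validated with
#' the same confounder-correlation and lipid-locus-LD criteria used for
#' individual SNPs; outcomes are stored as flags, and in strict mode a
#' flag breach is an error.
#'
#' @param dosages matrix of oriented dosages for the surviving set (one
#'   column per SNP).
#' @param confounder_table as in [screen_candidates()] (optional).
#' @param lipid_locus_dosages as in [screen_candidates()] (optional).
#' @param thresholds as in [screen_candidates()].
#' @param strict error on a validation-flag breach.
#' @return list of class `mr_score`: `score` (integer vector, NA where
#'   dosages incomplete), `snp_ids`, `flags` (named logical: TRUE = clean).
#' @export
build_score <- function(dosages, confounder_table = NULL,
                        lipid_locus_dosages = NULL,
                        thresholds = c(ld_lipid = 0.2, confounder_r = 0.1,
                                       ld_pairwise = 0.7),
                        strict = FALSE) {
  dosages <- as.matrix(dosages)
  if (!ncol(dosages)) stop("no instrument SNPs supplied.", call. = FALSE)
  complete <- stats::complete.cases(dosages)
  score <- rep(NA_real_, nrow(dosages))
  score[complete] <- rowSums(dosages[complete, , drop = FALSE])
  if (any(score < 0 | score > 2 * ncol(dosages), na.rm = TRUE)) {
    stop("dosages outside [0, 2]: score bounds violated.", call. = FALSE)
  }

  flags <- c(confounders = NA, lipid_loci = NA)
  if (!is.null(confounder_table)) {
    conf_num <- lapply(confounder_table[c("smoking", "bmi", "whr",
                                          "diabetes")], code_confounder)
    r <- vapply(conf_num, function(cf) pairwise_r(score, cf), numeric(1))
    flags["confounders"] <- all(abs(r) <= thresholds[["confounder_r"]],
                                na.rm = TRUE) && !all(is.na(r))
  }
  if (!is.null(lipid_locus_dosages) && ncol(lipid_locus_dosages) > 0) {
    r2 <- vapply(seq_len(ncol(lipid_locus_dosages)),
                 function(j) ld_r2(score, lipid_locus_dosages[, j]),
                 numeric(1))
    flags["lipid_loci"] <- all(r2 <= thresholds[["ld_lipid"]],
                               na.rm = TRUE) && !all(is.na(r2))
  }
  if (strict && any(!flags, na.rm = TRUE)) {
    stop("genetic score failed validation: ",
         paste(names(flags)[which(!flags)], collapse = ", "),
         call. = FALSE)
  }
  structure(list(score = score,
                 snp_ids = colnames(dosages),
                 flags = flags),
            class = "mr_score")
}

#' @export
print.mr_score <- function(x, ...) {
  cat("<mr_score> unweighted sum over ", length(x$snp_ids), " SNPs (",
      paste(x$snp_ids, collapse = ", "), ")\n", sep = "")
  cat("  complete:", sum(!is.na(x$score)), "of", length(x$score),
      " range:", paste(range(x$score, na.rm = TRUE), collapse = "-"), "\n")
  invisible(x)
}
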