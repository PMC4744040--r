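#' Read and write cohort tables
#'
#' Cohorts travel as plain TSV, one row per individual.
#'
#' @param cohort data.frame.
#' @param file path.
#' @return `read_cohort_tsv` returns a data.frame.
#' @export
write_cohort_tsv <- function(cohort, file) {
  utils::write.table(cohort, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(file)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(file) {
  utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE)
}

#' Write genotypes as a minimal VCF 4.2
#'
#' Hard-call dosages are emitted as unphased GT fields (0/0, 0/1, 1/1)
#' with the alcohol-raising allele as ALT, so the ALT allele count equals
#' the dosage.  Positions are synthetic ordinals unless the roster
#' carries `chrom`/`pos` columns.
#'
#' @param genotypes dosage matrix, columns named by snp_id, values 0/1/2.
#' @param roster instrument roster with `snp_id`, `raising_allele`,
#'   `other_allele`.
#' @param file output path.
#' @param sample_ids optional individual ids (default ID000001...).
#' @export
write_genotypes_vcf <- function(genotypes, roster, file,
                                sample_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  if (!all(genotypes %in% c(0, 1, 2, NA))) {
    stop("VCF export requires hard-call dosages in {0,1,2}.", call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("ID%06d", seq_len(nrow(genotypes)))
  }
  idx <- match(colnames(genotypes), roster$snp_id)
  if (anyNA(idx)) {
    stop("roster lacks SNP(s): ",
         paste(colnames(genotypes)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  chrom <- if ("chrom" %in% names(roster)) roster$chrom[idx] else "4"
  pos <- if ("pos" %in% names(roster)) roster$pos[idx] else
    100000L + seq_along(idx)
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##source=mrlipids synthetic cohort generator",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", sample_ids),
                    collapse = "\t"))
  body <- vapply(seq_along(idx), function(j) {
    g <- genotypes[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    paste(c(chrom[j], pos[j], colnames(genotypes)[j],
            roster$other_allele[idx[j]], roster$raising_allele[idx[j]],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), file)
  invisible(file)
}

#' Read genotype dosages
#'
#' `read_genotypes_vcf` parses GT fields from a VCF (via the vcfR package
#' when installed, falling back to a minimal parser for the plain-text
#' single-FORMAT files this package writes); the returned dosage counts
#' the ALT allele.  `read_dosage_tsv` reads a plain individuals-by-SNPs
#' dosage table.
#'
#' @param file path.
#' @return numeric matrix, individuals by SNPs, columns named by SNP id.
#' @export
read_genotypes_vcf <- function(file) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(file, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, c(1, 2), gt_to_dosage)
    return(t(dos))
  }
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  samples <- hdr[-(1:9)]
  body <- strsplit(lines[-1], "\t")
  ids <- vapply(body, `[[`, character(1), 3L)
  dos <- vapply(body, function(f) {
    vapply(f[-(1:9)], function(s) gt_to_dosage(strsplit(s, ":")[[1]][1]),
           numeric(1), USE.NAMES = FALSE)
  }, numeric(length(samples)))
  dimnames(dos) <- list(samples, ids)
  dos
}

gt_to_dosage <- function(gt) {
  if (is.na(gt) || gt %in% c("./.", ".")) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  sum(alleles == "1")
}

#' @rdname read_genotypes_vcf
#' @export
read_dosage_tsv <- function(file) {
  d <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE)
  id_col <- intersect(c("id", "sample", "IID"), names(d))[1]
  if (!is.na(id_col)) {
    rn <- d[[id_col]]
    d[[id_col]] <- NULL
    m <- as.matrix(d)
    rownames(m) <- rn
  } else {
    m <- as.matrix(d)
  }
  storage.mode(m) <- "double"
  m
}

#' Serialize a simulation configuration to and from YAML
#'
#' @param config an `mr_sim_config`.
#' @param file path.
#' @return `read_sim_config_yaml` returns an `mr_sim_config`.
#' @export
write_sim_config_yaml <- function(config, file) {
  yaml::write_yaml(sim_config_to_list(config), file, precision = 15)
  invisible(file)
}

#' @rdname write_sim_config_yaml
#' @export
read_sim_config_yaml <- function(file) {
  sim_config_from_list(yaml::read_yaml(file))
}

sim_config_to_list <- function(config) {
  x <- unclass(config)
  x$snps <- as.list(config$snps)
  x$lipids <- as.list(config$lipids)
  x$causal_curves <- lapply(config$causal_curves, curve_to_list)
  x$status_probs <- as.list(config$status_probs)
  x
}

sim_config_from_list <- function(x) {
  sim_config(
    n_individuals = x$n_individuals,
    snps = as.data.frame(x$snps, stringsAsFactors = FALSE),
    sex_effect = x$sex_effect,
    age_effect = x$age_effect,
    confounder_effect_exposure = x$confounder_effect_exposure,
    confounder_effect_outcome = x$confounder_effect_outcome,
    exposure_intercept = x$exposure_intercept,
    exposure_noise_sd = x$exposure_noise_sd,
    alcohol_cap_g_wk = x$alcohol_cap_g_wk,
    causal_curve = lapply(x$causal_curves, curve_from_list),
    lipids = as.data.frame(x$lipids, stringsAsFactors = FALSE),
    status_probs = unlist(x$status_probs),
    p_female = x$p_female,
    age_mean = x$age_mean,
    age_sd = x$age_sd,
    visit4_age_offset = x$visit4_age_offset,
    abstention_follows_confounder = x$abstention_follows_confounder,
    seed = x$seed
  )
}

#' Write realized true parameters as JSON
#'
#' Persists the generative quantities of a cohort draw (configuration,
#' attenuation-scaled latent per-allele effects, causal curves) next to
#' the simulated data; per-individual latent vectors are not serialized.
#'
#' @param truth the `true_parameters` element of an [generate_cohort()]
#'   result.
#' @param file path.
#' @export
write_true_parameters_json <- function(truth, file) {
  payload <- list(
    config = sim_config_to_list(truth$config),
    beta_latent = truth$beta_latent,
    attenuation = truth$attenuation,
    causal_curves = lapply(truth$causal_curves, curve_to_list)
  )
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(file)
}

#' Write an IV results table as TSV
#'
#' @param results table from [run_mr()].
#' @param file path.
#' @export
write_results_tsv <- function(results, file) {
  utils::write.table(results, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(file)
}
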