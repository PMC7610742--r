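#' Construct a dosage set
#'
#' The container for genotype dosages: a samples x variants matrix of
#' alternate-allele dosages plus per-sample sex and per-variant identity.
#' Dosages are stored in the "raw" ploidy coding: diploid calls (autosomes,
#' PARs, all female X) lie in [0, 2]; haploid male non-PAR X calls lie in
#' [0, 1]. The (0, 2) dosage-compensation coding used by the association
#' scan is applied downstream by [encode_x_dosage()].
#'
#' @param dosage Numeric matrix, samples x variants (`NA` = missing).
#' @param sample_id Character vector of unique sample ids (rows).
#' @param sex Character vector in `{"female", "male"}` per sample.
#' @param variants Data frame with columns `variant_id, chromosome, bp, ref,
#'   alt` (one row per matrix column); `region` is derived if absent.
#' @param par PAR configuration, see [par_intervals()].
#' @return A list of class `dosage_set`.
#' @export
dosage_set <- function(dosage, sample_id, sex, variants, par = par_intervals()) {
  dosage <- as.matrix(dosage)
  variants <- as_tibble(variants)
  if (anyDuplicated(sample_id)) abort("Sample ids must be unique.")
  if (length(sample_id) != nrow(dosage)) {
    abort("`sample_id` length must equal nrow(dosage).")
  }
  if (length(sex) != nrow(dosage)) abort("`sex` must be defined for every sample.")
  sex <- as.character(sex)
  if (!all(sex %in% c("female", "male"))) {
    abort("`sex` labels must be 'female' or 'male'.")
  }
  if (nrow(variants) != ncol(dosage)) {
    abort("`variants` must have one row per dosage column.")
  }
  variants$chromosome <- normalize_chromosome(variants$chromosome)
  if (!("region" %in% names(variants))) {
    variants$region <- variant_region(variants$chromosome, variants$bp, par)
  }
  # range check: haploid male non-PAR in [0,1], everything else [0,2]
  male <- sex == "male"
  nonpar <- variants$region == "X_nonPAR"
  if (any(nonpar) && any(male)) {
    block <- dosage[male, nonpar, drop = FALSE]
    if (any(block > 1 + 1e-8, na.rm = TRUE)) {
      abort("Male non-PAR X dosages must be raw haploid calls in [0, 1].")
    }
  }
  if (any(dosage < -1e-8 | dosage > 2 + 1e-8, na.rm = TRUE)) {
    abort("Dosages must lie in [0, 2].")
  }
  rownames(dosage) <- sample_id
  colnames(dosage) <- variants$variant_id
  structure(list(dosage = dosage, sample_id = as.character(sample_id),
                 sex = sex, variants = variants),
            class = "dosage_set")
}

#' @exportS3Method base::print
print.dosage_set <- function(x, ...) {
  cat("<dosage_set> ", length(x$sample_id), " samples (",
      sum(x$sex == "female"), " female, ", sum(x$sex == "male"), " male) x ",
      nrow(x$variants), " variants\n", sep = "")
  cat("  chromosomes: ",
      paste(unique(x$variants$chromosome), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read dosages from a VCF (DS field) or TSV matrix
#'
#' The VCF path extracts the per-sample `DS` FORMAT field. The TSV path
#' expects columns `variant_id, chromosome, position, ref, alt` followed by
#' one column per sample.
#'
#' @param path Input file.
#' @param format `"vcf_ds"` or `"tsv"`.
#' @param sex_table Data frame with columns `sample_id, sex` covering every
#'   sample in the file.
#' @param par PAR configuration.
#' @return A [dosage_set()].
#' @export
read_dosages <- function(path, format = c("tsv", "vcf_ds"), sex_table,
                         par = par_intervals()) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("Dosage file not found: ", path))
  if (format == "vcf_ds") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
    variants <- tibble(
      variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                          paste0(fix$CHROM, ":", fix$POS, ":", fix$REF, ":", fix$ALT),
                          fix$ID),
      chromosome = fix$CHROM, bp = as.numeric(fix$POS),
      ref = fix$REF, alt = fix$ALT)
    mat <- t(ds)
    sample_ids <- rownames(mat)
  } else {
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    meta_cols <- c("variant_id", "chromosome", "position", "ref", "alt")
    missing_cols <- setdiff(meta_cols, names(raw))
    if (length(missing_cols) > 0) {
      abort(paste0("Dosage TSV missing column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    variants <- tibble(variant_id = raw$variant_id, chromosome = raw$chromosome,
                       bp = as.numeric(raw$position), ref = raw$ref, alt = raw$alt)
    sample_ids <- setdiff(names(raw), meta_cols)
    mat <- t(as.matrix(raw[, sample_ids]))
    rownames(mat) <- sample_ids
  }
  sex <- reconcile_sex(sample_ids, sex_table)
  dosage_set(mat, sample_ids, sex, variants, par = par)
}

reconcile_sex <- function(sample_ids, sex_table) {
  sex_table <- as_tibble(sex_table)
  if (!all(c("sample_id", "sex") %in% names(sex_table))) {
    abort("Sex table must have columns `sample_id` and `sex`.")
  }
  idx <- match(sample_ids, sex_table$sample_id)
  if (anyNA(idx)) {
    abort(paste0("Samples missing from the sex table: ",
                 paste(head(sample_ids[is.na(idx)], 10), collapse = ", ")))
  }
  as.character(sex_table$sex[idx])
}

#' Write a dosage set as a TSV matrix
#'
#' @param dosages A [dosage_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosages <- function(dosages, path) {
  df <- dplyr::bind_cols(
    tibble(variant_id = dosages$variants$variant_id,
           chromosome = dosages$variants$chromosome,
           position = dosages$variants$bp,
           ref = dosages$variants$ref, alt = dosages$variants$alt),
    as_tibble(t(dosages$dosage))
  )
  readr::write_tsv(format_full_precision(df), path, progress = FALSE)
  invisible(path)
}

#' Read a phenotype (or confound) matrix
#'
#' First column is the sample id; remaining columns are phenotypes.
#'
#' @param path TSV path.
#' @return A tibble whose first column is `sample_id`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) abort(paste0("Phenotype file not found: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(raw)[1] <- "sample_id"
  raw$sample_id <- as.character(raw$sample_id)
  if (anyDuplicated(raw$sample_id)) abort("Duplicate sample ids in phenotype file.")
  if (anyDuplicated(names(raw))) abort("Duplicate phenotype ids in phenotype file.")
  raw
}

#' Write a phenotype matrix
#' @param pheno Tibble with `sample_id` first column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  readr::write_tsv(format_full_precision(pheno), path, progress = FALSE)
  invisible(path)
}

#' Check sample alignment between dosage and phenotype tables
#'
#' @param dosages A [dosage_set()].
#' @param pheno Phenotype tibble with `sample_id`.
#' @return Invisibly, the common sample ids; errors listing offenders when
#'   either side has samples the other lacks.
#' @export
reconcile_samples <- function(dosages, pheno) {
  a <- dosages$sample_id
  b <- pheno$sample_id
  only_a <- setdiff(a, b)
  only_b <- setdiff(b, a)
  if (length(only_a) > 0 || length(only_b) > 0) {
    abort(paste0(
      "Sample-id mismatch between dosage and phenotype tables. ",
      "Dosage-only: [", paste(head(only_a, 5), collapse = ", "), "]",
      if (length(only_a) > 5) "..." else "",
      "; phenotype-only: [", paste(head(only_b, 5), collapse = ", "), "]",
      if (length(only_b) > 5) "..." else ""))
  }
  invisible(intersect(a, b))
}

#' Write and read cluster reports
#'
#' The cluster report mirrors the lead-association table layout: cluster
#' number, lead variant id, lead phenotype, chromosome, position, alleles,
#' -log10 p of the lead, number of member (phenotype, variant) pairs, and
#' the replication/Bonferroni flags. The member table is written alongside
#' (same path + `.members.tsv`) so the full lead/member structure round-trips.
#'
#' @param clusters A `gwas_clusters` object from [cluster_peaks()].
#' @param path Output TSV path for the lead table.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(clusters, path) {
  leads <- clusters$clusters
  cols <- c("cluster_id", "lead_variant_id", "lead_phenotype_id", "chromosome",
            "bp", "ref", "alt", "lead_neglog10p", "lead_cm", "n_snps",
            "replicated", "bonferroni")
  readr::write_tsv(format_full_precision(leads[, intersect(cols, names(leads))]),
                   path, progress = FALSE)
  readr::write_tsv(format_full_precision(clusters$members),
                   paste0(path, ".members.tsv"), progress = FALSE)
  invisible(path)
}

#' @rdname write_cluster_report
#' @export
read_cluster_report <- function(path) {
  leads <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  members_path <- paste0(path, ".members.tsv")
  members <- if (file.exists(members_path)) {
    readr::read_tsv(members_path, show_col_types = FALSE, progress = FALSE)
  } else {
    NULL
  }
  new_gwas_clusters(as_tibble(leads), as_tibble(members))
}
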