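#' Pipeline run configuration
#'
#' Builds (or validates) the configuration for [run_pipeline()]. Either a
#' synthetic cohort is simulated (`simulate` block) or input paths are
#' given for dosages, phenotypes, confounds, sex table and genetic map.
#'
#' @param config A named list, or a path to a YAML file with the same
#'   structure. Recognised top-level fields: `simulate` (list passed to
#'   [sim_config()]), or `paths` (list with `dosages`, `dosage_format`,
#'   `phenotypes`, `confounds`, `sex`, `map`); plus `thresholds` (list:
#'   `genomewide` 7.5, `cover_cm` 0.25, `replication_p` 0.05), `qc` (list:
#'   `maf_min` 0.001, `info_min` 0.3, `hwe_max` 7, `hit_maf_min` 0.01),
#'   `split_seed`, `split_fraction`, `out_dir` (optional), `sex_meta`
#'   (logical: also run the sex-stratified scans and meta-analysis).
#' @return A validated list of class `run_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("Config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    thresholds = list(genomewide = 7.5, cover_cm = 0.25, replication_p = 0.05),
    qc = list(maf_min = 0.001, info_min = 0.3, hwe_max = 7, hit_maf_min = 0.01),
    split_fraction = 2 / 3, sex_meta = FALSE, out_dir = NULL)
  for (nm in names(defaults)) {
    if (is.list(defaults[[nm]])) {
      for (sub in names(defaults[[nm]])) {
        config[[nm]][[sub]] <- config[[nm]][[sub]] %||% defaults[[nm]][[sub]]
      }
    } else if (is.null(config[[nm]])) {
      config[nm] <- defaults[nm]
    }
  }
  if (is.null(config$simulate) && is.null(config$paths)) {
    abort("Config must contain either a `simulate` or a `paths` block.")
  }
  if (!is.null(config$paths)) {
    needed <- c("dosages", "phenotypes", "sex", "map")
    for (field in needed) {
      if (is.null(config$paths[[field]])) {
        abort(paste0("Config field `paths$", field, "` is required."))
      }
      if (!file.exists(config$paths[[field]])) {
        abort(paste0("Config field `paths$", field, "`: file not found: ",
                     config$paths[[field]]))
      }
    }
  }
  if (is.null(config$split_seed)) abort("Config field `split_seed` is required.")
  structure(config, class = c("run_config", "list"))
}

#' Run the full association pipeline
#'
#' Chains the stages: simulate (or load) -> phenotype cleaning (outlier
#' mask, sparse-subject drop, cohort split, per-cohort quantile
#' normalisation and residualisation) -> variant QC -> discovery scan ->
#' MAF hit filter -> per-phenotype peak extraction -> cross-phenotype
#' clustering -> replication scan and tagging -> (optionally)
#' sex-stratified scans with Fisher meta-analysis and meta-vs-main cluster
#' overlap. With `out_dir` set, every stage's table is written as TSV and a
#' provenance JSON records all thresholds and seeds; reruns with the same
#' config are byte-identical.
#'
#' @param config A [pipeline_config()] (list or YAML path).
#' @return A list with `clusters` (a `gwas_clusters`), `peaks`, `sumstats`,
#'   `replication`, `qc`, `prep`, `map`, `truth` (when simulated),
#'   `meta` (when `sex_meta`), and `provenance`.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  thr <- config$thresholds
  qc_thr <- config$qc

  if (!is.null(config$simulate)) {
    sim <- simulate_cohort(do.call(sim_config, config$simulate))
    dosages <- sim$dosages
    map <- sim$map
    pheno <- sim$pheno
    confounds <- sim$confounds
    truth <- sim$truth
  } else {
    sex_table <- readr::read_tsv(config$paths$sex, show_col_types = FALSE,
                                 progress = FALSE)
    dosages <- read_dosages(config$paths$dosages,
                            format = config$paths$dosage_format %||% "tsv",
                            sex_table = sex_table)
    map <- read_genetic_map(config$paths$map)
    pheno <- read_phenotypes(config$paths$phenotypes)
    confounds <- if (!is.null(config$paths$confounds)) {
      read_phenotypes(config$paths$confounds)
    }
    truth <- NULL
    reconcile_samples(dosages, pheno)
  }

  prep <- prep_phenotypes(pheno, confounds, seed = config$split_seed,
                          fraction = config$split_fraction)

  metrics <- variant_qc_metrics(dosages)
  metrics <- apply_variant_filters(metrics, maf_min = qc_thr$maf_min,
                                   info_min = qc_thr$info_min,
                                   hwe_max = qc_thr$hwe_max)
  keep <- metrics$variant_id[metrics$pass]
  dosages_qc <- subset_dosages(dosages, keep)

  sumstats <- linear_scan(prep$discovery, dosages_qc)
  hits <- hit_filter(sumstats, metrics, maf_min = qc_thr$hit_maf_min)
  peaks <- extract_peaks(hits, map, threshold = thr$genomewide,
                         cover_cm = thr$cover_cm)
  n_pheno <- length(setdiff(names(pheno), "sample_id"))
  bonf <- bonferroni_threshold(n_pheno, base = thr$genomewide)
  clusters <- cluster_peaks(peaks, cover_cm = thr$cover_cm,
                            bonferroni_threshold = bonf)
  replication <- if (nrow(peaks) > 0) {
    rep_dos <- subset_dosages(dosages_qc, unique(peaks$variant_id))
    linear_scan(prep$replication, rep_dos,
                phenotype_ids = unique(peaks$phenotype_id))
  } else {
    sumstats[0, ]
  }
  clusters <- tag_replication(clusters, replication)

  meta <- NULL
  if (isTRUE(config$sex_meta)) {
    disc_ids <- prep$split$discovery_ids
    sex <- dosages_qc$sex[match(disc_ids, dosages_qc$sample_id)]
    f_scan <- linear_scan(prep$discovery, dosages_qc,
                          cohort = disc_ids[sex == "female"])
    m_scan <- linear_scan(prep$discovery, dosages_qc,
                          cohort = disc_ids[sex == "male"])
    meta_ss <- meta_analyse_sex_scans(f_scan, m_scan)
    meta_hits <- hit_filter(meta_ss, metrics, maf_min = qc_thr$hit_maf_min)
    meta_peaks <- extract_peaks(meta_hits, map, threshold = thr$genomewide,
                                cover_cm = thr$cover_cm)
    meta_clusters <- cluster_peaks(meta_peaks, cover_cm = thr$cover_cm,
                                   bonferroni_threshold = bonf)
    overlap <- cluster_overlap(meta_clusters, clusters, tol_cm = thr$cover_cm)
    meta <- list(female = f_scan, male = m_scan, sumstats = meta_ss,
                 clusters = meta_clusters, overlap = overlap)
  }

  provenance <- list(
    thresholds = thr, qc = qc_thr, split_seed = config$split_seed,
    split_fraction = config$split_fraction,
    bonferroni_threshold = bonf, n_phenotypes = n_pheno,
    n_variants_input = nrow(metrics), n_variants_pass = length(keep),
    qc_tally = as.list(attr(metrics, "tally")),
    prep = prep$provenance,
    sim_seed = config$simulate$seed %||% NULL)

  result <- list(clusters = clusters, peaks = peaks, sumstats = sumstats,
                 replication = replication, qc = metrics, prep = prep,
                 map = map, truth = truth, meta = meta,
                 provenance = provenance)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

subset_dosages <- function(dosages, variant_ids) {
  j <- which(dosages$variants$variant_id %in% variant_ids)
  dosage_set(dosages$dosage[, j, drop = FALSE], dosages$sample_id,
             dosages$sex, dosages$variants[j, , drop = FALSE])
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  readr::write_tsv(format_full_precision(result$sumstats), p("sumstats.tsv"),
                   progress = FALSE)
  readr::write_tsv(format_full_precision(result$peaks), p("peaks.tsv"),
                   progress = FALSE)
  readr::write_tsv(format_full_precision(result$replication),
                   p("replication.tsv"), progress = FALSE)
  readr::write_tsv(format_full_precision(result$qc), p("variant_qc.tsv"),
                   progress = FALSE)
  write_cluster_report(result$clusters, p("clusters.tsv"))
  if (!is.null(result$truth)) {
    readr::write_tsv(format_full_precision(result$truth), p("truth.tsv"),
                     progress = FALSE)
  }
  jsonlite::write_json(result$provenance, p("provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Export a Manhattan-plot data table
#'
#' One row per variant in the (hit-filtered) scan of one phenotype:
#' chromosome, bp, cM, -log10 p, whether the variant is a peak, and the
#' cluster id of peak rows (empty otherwise).
#'
#' @param sumstats Hit-filtered scan tibble for one phenotype (or with a
#'   `phenotype_id` column).
#' @param peaks Peaks from [extract_peaks()].
#' @param clusters Optional `gwas_clusters` supplying cluster ids.
#' @param map Optional [genetic_map()] to fill the `cM` column.
#' @return A tibble `(phenotype_id, variant_id, chromosome, bp, cM,
#'   neglog10p, is_peak, cluster_id)`.
#' @export
export_manhattan_table <- function(sumstats, peaks, clusters = NULL,
                                   map = NULL) {
  df <- as_tibble(sumstats)
  if (!("phenotype_id" %in% names(df))) df$phenotype_id <- "phenotype"
  pk <- as_tibble(peaks)
  if (nrow(pk) > 0 && !("phenotype_id" %in% names(pk))) {
    pk$phenotype_id <- "phenotype"
  }
  df$cM <- if (!is.null(map)) {
    interpolate_cm(map, df$chromosome, df$bp)
  } else if ("cM" %in% names(df)) df$cM else NA_real_
  peak_key <- paste(pk$phenotype_id, pk$variant_id)
  df$is_peak <- paste(df$phenotype_id, df$variant_id) %in% peak_key
  df$cluster_id <- NA_integer_
  if (!is.null(clusters)) {
    mem <- clusters$members
    idx <- match(paste(df$phenotype_id, df$variant_id),
                 paste(mem$phenotype_id, mem$variant_id))
    df$cluster_id <- mem$cluster_id[idx]
  }
  df[, c("phenotype_id", "variant_id", "chromosome", "bp", "cM",
         "neglog10p", "is_peak", "cluster_id")]
}
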