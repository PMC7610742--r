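#' Synthetic cohort configuration
#'
#' Parameters of the synthetic genotype/phenotype simulator used for
#' end-to-end validation. Genotypes are LD-blocked alternate-allele counts
#' generated by a Gaussian copula: each haplotype's latent normal is a
#' blockwise equicorrelated draw (`within_block_r`) thresholded at the
#' allele frequency, so adjacent variants in a block are correlated like
#' nearby variants in real data. Females are diploid everywhere; males are
#' haploid (raw dosage in [0, 1]) on the X non-PAR region and diploid on
#' the PARs. `dosage_noise` in [0, 1) shrinks hard calls toward the
#' Hardy-Weinberg mean dosage, emulating imputation uncertainty
#' (INFO ~ (1 - dosage_noise)^2).
#'
#' @param n_female,n_male Cohort sizes.
#' @param chromosomes Chromosome labels to simulate.
#' @param n_variants Variants per chromosome (scalar or per-chromosome).
#' @param ld_block_size Variants per LD block (1 = independent).
#' @param within_block_r Latent correlation within a block, in [0, 1).
#' @param maf_range Length-2 range the per-variant MAF is drawn from.
#' @param missing_rate Fraction of dosage entries set missing.
#' @param dosage_noise Imputation-uncertainty shrinkage in [0, 1).
#' @param cm_per_mb Constant genetic-map rate (default 1 cM/Mb).
#' @param bp_spacing Mean spacing between variants in bp (default 1e5, i.e.
#'   0.1 cM between neighbours at the default rate).
#' @param n_phenotypes Number of phenotypes.
#' @param n_causal Planted causal variants per phenotype.
#' @param effect_size_sd SD of planted per-allele effects (SD units);
#'   ignored when `effect_range` is given.
#' @param effect_range Optional length-2 range of |effect| (signs random).
#' @param n_confounds Shared confound columns.
#' @param confound_sd SD of confound loadings.
#' @param pheno_missing_rate Fraction of phenotype entries set missing.
#' @param dc_multiplier Male non-PAR genetic-value multiplier applied to
#'   the (0, 2)-encoded dosage (1 = full dosage compensation).
#' @param seed Integer seed (mandatory).
#' @param par PAR intervals for X region assignment.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_female = 250, n_male = 250,
                       chromosomes = c("1", "2", "X"),
                       n_variants = 100, ld_block_size = 5,
                       within_block_r = 0.6, maf_range = c(0.05, 0.5),
                       missing_rate = 0, dosage_noise = 0,
                       cm_per_mb = 1, bp_spacing = 1e5,
                       n_phenotypes = 10, n_causal = 2,
                       effect_size_sd = 0.2, effect_range = NULL,
                       n_confounds = 3, confound_sd = 0.3,
                       pheno_missing_rate = 0, dc_multiplier = 1,
                       seed, par = par_intervals()) {
  if (missing(seed)) abort("`seed` is mandatory.")
  rates <- c(missing_rate, dosage_noise, pheno_missing_rate)
  if (any(rates < 0 | rates > 1)) abort("Rates must lie in [0, 1].")
  if (within_block_r < 0 || within_block_r >= 1) {
    abort("`within_block_r` must lie in [0, 1).")
  }
  if (any(maf_range <= 0) || any(maf_range > 0.5)) {
    abort("`maf_range` must lie in (0, 0.5].")
  }
  chromosomes <- normalize_chromosome(chromosomes)
  n_variants <- rep_len(n_variants, length(chromosomes))
  names(n_variants) <- chromosomes
  structure(as.list(environment()), class = "sim_config")
}

# one chromosome's haplotype matrix (samples x variants x n_hap collapsed):
# latent z = sqrt(r) * block_factor + sqrt(1-r) * noise, allele = z < qnorm(maf)
simulate_haplotypes <- function(n_samples, maf, block, r) {
  n_var <- length(maf)
  z <- matrix(rnorm(n_samples * n_var), n_samples, n_var)
  if (r > 0) {
    for (b in unique(block)) {
      idx <- which(block == b)
      u <- rnorm(n_samples)
      z[, idx] <- sqrt(r) * u + sqrt(1 - r) * z[, idx, drop = FALSE]
    }
  }
  thresh <- qnorm(maf)
  (z < matrix(thresh, n_samples, n_var, byrow = TRUE)) + 0
}

#' Simulate genotype dosages and a genetic map
#'
#' See [sim_config()] for the generative model. Positions are evenly spaced
#' at `bp_spacing` (X positions spread over the real chromosome length so a
#' realistic share lands in the PARs); the map has a constant `cm_per_mb`
#' rate per chromosome, so centimorgan distances in tests are exactly
#' controllable.
#'
#' @param config A [sim_config()].
#' @return A list with `dosages` (a [dosage_set()]) and `map`
#'   (a [genetic_map()]).
#' @export
simulate_genotypes <- function(config) {
  withr::with_seed(config$seed, simulate_genotypes_impl(config))
}

simulate_genotypes_impl <- function(config) {
  n_f <- config$n_female
  n_m <- config$n_male
  n <- n_f + n_m
  sample_id <- sprintf("S%05d", seq_len(n))
  sex <- c(rep("female", n_f), rep("male", n_m))
  all_var <- list()
  all_dos <- list()
  map_rows <- list()
  x_len <- 155270560 # full X span so PAR1/PAR2 get their natural share
  for (chr in config$chromosomes) {
    n_var <- config$n_variants[[chr]]
    if (chr == "X") {
      bp <- sort(sample.int(x_len, n_var))
    } else {
      bp <- round(seq(config$bp_spacing, by = config$bp_spacing,
                      length.out = n_var))
    }
    maf <- runif(n_var, config$maf_range[1], config$maf_range[2])
    block <- ceiling(seq_len(n_var) / config$ld_block_size)
    region <- variant_region(chr, bp, config$par)
    h1 <- simulate_haplotypes(n, maf, block, config$within_block_r)
    h2 <- simulate_haplotypes(n, maf, block, config$within_block_r)
    g <- h1 + h2
    if (chr == "X") {
      male <- sex == "male"
      nonpar <- region == "X_nonPAR"
      # males carry a single X: drop the second haplotype on non-PAR
      g[male, nonpar] <- h1[male, nonpar, drop = FALSE]
    }
    if (config$dosage_noise > 0) {
      w <- config$dosage_noise
      ploidy <- matrix(2, n, n_var)
      if (chr == "X") ploidy[sex == "male", region == "X_nonPAR"] <- 1
      centre <- ploidy * matrix(maf, n, n_var, byrow = TRUE)
      g <- (1 - w) * g + w * centre
    }
    if (config$missing_rate > 0) {
      g[runif(length(g)) < config$missing_rate] <- NA
    }
    all_dos[[chr]] <- g
    all_var[[chr]] <- tibble(
      variant_id = sprintf("var_%s_%04d", chr, seq_len(n_var)),
      chromosome = chr, bp = as.numeric(bp), ref = "A", alt = "G",
      region = region, true_maf = maf)
    span <- max(bp) + config$bp_spacing
    map_rows[[chr]] <- tibble(chromosome = chr, bp = c(1, span),
                              cM = c(0, span / 1e6 * config$cm_per_mb))
  }
  variants <- dplyr::bind_rows(all_var)
  dosage <- do.call(cbind, all_dos)
  list(dosages = dosage_set(dosage, sample_id, sex,
                            dplyr::select(variants, -"true_maf"),
                            par = config$par),
       map = genetic_map(dplyr::bind_rows(map_rows)),
       variant_maf = variants$true_maf)
}

#' Simulate phenotypes with planted effects
#'
#' Each phenotype is a sparse linear genetic signal plus shared confounds
#' plus unit-variance Gaussian noise:
#' `y = sum_j beta_j g_enc_j + C gamma + e`. Genetic values use the (0, 2)
#' dosage-compensation encoding on male non-PAR X, times `dc_multiplier`.
#' Causal variants, effects and confound loadings are drawn per phenotype
#' and returned as ground truth. Missing phenotype entries are injected at
#' `pheno_missing_rate`.
#'
#' @param dosages A [dosage_set()] from [simulate_genotypes()].
#' @param config The same [sim_config()].
#' @param truth Optional pre-specified truth tibble
#'   (`phenotype_id, variant_id, true_beta`) overriding the random draw.
#' @return A list with `pheno` (tibble, `sample_id` + phenotype columns),
#'   `confounds` (tibble), and `truth` (tibble of planted effects).
#' @export
simulate_phenotypes <- function(dosages, config, truth = NULL) {
  withr::with_seed(config$seed + 1L,
                   simulate_phenotypes_impl(dosages, config, truth))
}

simulate_phenotypes_impl <- function(dosages, config, truth) {
  n <- length(dosages$sample_id)
  variants <- dosages$variants
  pheno_ids <- sprintf("P%03d", seq_len(config$n_phenotypes))

  if (!is.null(truth)) {
    bad <- setdiff(truth$variant_id, variants$variant_id)
    if (length(bad) > 0) {
      abort(paste0("Truth references unknown variant(s): ",
                   paste(head(bad, 5), collapse = ", ")))
    }
  } else {
    truth <- purrr::map(pheno_ids, function(pid) {
      if (config$n_causal == 0) return(NULL)
      j <- sample.int(nrow(variants), config$n_causal)
      beta <- if (!is.null(config$effect_range)) {
        sample(c(-1, 1), config$n_causal, replace = TRUE) *
          runif(config$n_causal, config$effect_range[1], config$effect_range[2])
      } else {
        rnorm(config$n_causal, 0, config$effect_size_sd)
      }
      tibble(phenotype_id = pid, variant_id = variants$variant_id[j],
             true_beta = beta)
    })
    truth <- dplyr::bind_rows(truth)
    if (nrow(truth) == 0) {
      truth <- tibble(phenotype_id = character(), variant_id = character(),
                      true_beta = numeric())
    }
  }

  C <- matrix(rnorm(n * config$n_confounds), n, config$n_confounds)
  colnames(C) <- sprintf("C%02d", seq_len(config$n_confounds))

  # encoded dosages with mean imputation of missing entries (simulation
  # only; the association scan itself uses casewise deletion)
  enc <- dosages$dosage
  male <- dosages$sex == "male"
  nonpar <- variants$region == "X_nonPAR"
  if (any(nonpar) && any(male)) {
    enc[male, nonpar] <- config$dc_multiplier * 2 *
      enc[male, nonpar, drop = FALSE]
  }
  pheno <- matrix(NA_real_, n, length(pheno_ids),
                  dimnames = list(NULL, pheno_ids))
  loadings <- matrix(rnorm(config$n_confounds * length(pheno_ids),
                           0, config$confound_sd),
                     config$n_confounds, length(pheno_ids))
  for (k in seq_along(pheno_ids)) {
    y <- rnorm(n)
    rows <- truth[truth$phenotype_id == pheno_ids[k], , drop = FALSE]
    if (nrow(rows) > 0) {
      j <- match(rows$variant_id, variants$variant_id)
      gk <- enc[, j, drop = FALSE]
      gk[is.na(gk)] <- rep(colMeans(gk, na.rm = TRUE),
                           each = nrow(gk))[is.na(gk)]
      y <- y + drop(gk %*% rows$true_beta)
    }
    y <- y + drop(C %*% loadings[, k])
    pheno[, k] <- y
  }
  if (config$pheno_missing_rate > 0) {
    pheno[runif(length(pheno)) < config$pheno_missing_rate] <- NA
  }
  list(pheno = dplyr::bind_cols(tibble(sample_id = dosages$sample_id),
                                as_tibble(pheno)),
       confounds = dplyr::bind_cols(tibble(sample_id = dosages$sample_id),
                                    as_tibble(C)),
       truth = as_tibble(truth),
       confound_loadings = loadings)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: genotypes + map + confounds + phenotypes + truth.
#'
#' @param config A [sim_config()].
#' @return A list with `dosages`, `map`, `pheno`, `confounds`, `truth`.
#' @export
simulate_cohort <- function(config) {
  g <- simulate_genotypes(config)
  p <- simulate_phenotypes(g$dosages, config)
  list(dosages = g$dosages, map = g$map, pheno = p$pheno,
       confounds = p$confounds, truth = p$truth,
       variant_maf = g$variant_maf)
}
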