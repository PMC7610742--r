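#' Summary-statistics column dialects
#'
#' Summary-statistics tables arrive with many header conventions. A dialect
#' maps canonical column names onto the header names present in the file.
#' The `"compact"` preset matches the compact headers used by public
#' brain-imaging GWAS summary servers
#' (`rsid chr pos a1 a2 beta se pval(-log10)`), where `a1` is the reference
#' and `a2` the alternate (effect) allele.
#'
#' @param preset `"default"` or `"compact"`.
#' @param ... Named overrides, e.g. `neglog10p = "LOG10P"`.
#' @return Named character vector mapping canonical -> file column names.
#' @export
#' @examples
#' sumstats_dialect("compact")
sumstats_dialect <- function(preset = c("default", "compact"), ...) {
  preset <- match.arg(preset)
  d <- switch(preset,
    default = c(variant_id = "variant_id", chromosome = "chromosome",
                bp = "position", ref = "ref", alt = "alt", beta = "beta",
                se = "se", neglog10p = "neglog10p", n = "n"),
    compact = c(variant_id = "rsid", chromosome = "chr", bp = "pos",
              ref = "a1", alt = "a2", beta = "beta", se = "se",
              neglog10p = "pval(-log10)", n = "n")
  )
  overrides <- c(...)
  if (length(overrides) > 0) {
    bad <- setdiff(names(overrides), names(d))
    if (length(bad) > 0) {
      abort(paste0("Unknown dialect field(s): ", paste(bad, collapse = ", ")))
    }
    d[names(overrides)] <- overrides
  }
  d
}

sumstats_numeric_cols <- c("bp", "beta", "se", "neglog10p", "n")

#' Read a summary-statistics table
#'
#' Reads one phenotype's association results: variant identity, alleles,
#' effect size per alternate-allele copy (in phenotype SD units), its
#' standard error, and the two-sided -log10 p-value. The -log10 p is stored
#' directly (never the raw p) so associations beyond double-precision
#' underflow survive a round trip. Chromosome aliases are normalised and the
#' PAR/non-PAR region resolved from position.
#'
#' @param path Path to a TSV file.
#' @param dialect Column mapping from [sumstats_dialect()].
#' @param par PAR configuration, see [par_intervals()].
#' @return A tibble with columns `variant_id, chromosome, region, bp, ref,
#'   alt, beta, se, neglog10p, n` in file order.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(),
                          par = par_intervals()) {
  if (!file.exists(path)) abort(paste0("Summary-statistics file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- dialect[!(dialect %in% names(raw))]
  # n is optional in the wild; everything else is mandatory
  mandatory <- setdiff(names(missing_cols), "n")
  if (length(mandatory) > 0) {
    abort(paste0("Summary-statistics file is missing mandatory column(s): ",
                 paste(dialect[mandatory], collapse = ", ")))
  }
  out <- tibble(
    variant_id = raw[[dialect[["variant_id"]]]],
    chromosome = raw[[dialect[["chromosome"]]]],
    bp = raw[[dialect[["bp"]]]],
    ref = toupper(raw[[dialect[["ref"]]]]),
    alt = toupper(raw[[dialect[["alt"]]]]),
    beta = raw[[dialect[["beta"]]]],
    se = raw[[dialect[["se"]]]],
    neglog10p = raw[[dialect[["neglog10p"]]]],
    n = if (dialect[["n"]] %in% names(raw)) raw[[dialect[["n"]]]] else NA_character_
  )
  if (nrow(out) == 0) {
    out <- dplyr::mutate(out, chromosome = character(),
                         region = character(),
                         dplyr::across(dplyr::all_of(sumstats_numeric_cols), as.numeric))
    return(out[, c("variant_id", "chromosome", "region", "bp", "ref", "alt",
                   "beta", "se", "neglog10p", "n")])
  }
  for (col in sumstats_numeric_cols) {
    val <- parse_numeric_strict(out[[col]])
    bad <- which(is.na(val) & !is.na(out[[col]]) & out[[col]] != "" &
                   !(col == "n"))
    if (length(bad) > 0) {
      abort(paste0("Non-numeric value(s) in column '", dialect[[col]],
                   "' at data line(s): ",
                   paste(head(bad, 10) + 1, collapse = ", ")))
    }
    out[[col]] <- val
  }
  out$chromosome <- normalize_chromosome(out$chromosome)
  out$region <- variant_region(out$chromosome, out$bp, par)
  bad <- which(out$se < 0 | out$neglog10p < 0)
  if (length(bad) > 0) {
    abort(paste0("Negative se or -log10 p at data line(s): ",
                 paste(head(bad, 10) + 1, collapse = ", ")))
  }
  out[, c("variant_id", "chromosome", "region", "bp", "ref", "alt",
          "beta", "se", "neglog10p", "n")]
}

# tolerate unicode minus signs from copy-pasted tables
parse_numeric_strict <- function(x) {
  x <- gsub("−|–", "-", x)
  suppressWarnings(as.numeric(x))
}

#' Write a summary-statistics table
#'
#' @param sumstats A tibble as returned by [read_sumstats()] or
#'   [linear_scan()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(sumstats, path) {
  cols <- intersect(c("variant_id", "chromosome", "bp", "ref", "alt",
                      "beta", "se", "neglog10p", "n"), names(sumstats))
  out <- sumstats[, cols]
  names(out)[names(out) == "bp"] <- "position"
  readr::write_tsv(format_full_precision(out), path, progress = FALSE)
  invisible(path)
}

# write doubles at 17 significant digits so write->read is the identity
# to better than 1e-12 relative
format_full_precision <- function(df) {
  dplyr::mutate(df, dplyr::across(
    dplyr::where(is.double),
    function(x) {
      s <- formatC(x, digits = 17, format = "g")
      s[is.na(x)] <- NA_character_
      trimws(s)
    }
  ))
}
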