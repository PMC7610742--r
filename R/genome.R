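#' Pseudoautosomal region intervals
#'
#' The two X-chromosome pseudoautosomal regions (PARs) are homologous with
#' chromosome Y and are diploid in both sexes, so they are analysed like
#' autosomes. Positions are 1-based inclusive base pairs on the X chromosome;
#' defaults are the GRCh37/hg19 intervals.
#'
#' @param par1 Integer vector of length 2, start/end of PAR1 (bp, inclusive).
#' @param par2 Integer vector of length 2, start/end of PAR2 (bp, inclusive).
#' @return A list of class `par_intervals`.
#' @export
#' @examples
#' par_intervals()
par_intervals <- function(par1 = c(60001L, 2699520L),
                          par2 = c(154931044L, 155260560L)) {
  stopifnot(length(par1) == 2, length(par2) == 2,
            par1[1] <= par1[2], par2[1] <= par2[2], par1[2] < par2[1])
  structure(list(par1 = as.numeric(par1), par2 = as.numeric(par2)),
            class = "par_intervals")
}

#' Normalise chromosome labels
#'
#' Maps common aliases onto the canonical label set `{1..22, X}`:
#' `"chr"` prefixes are stripped and the X aliases `"23"`, `"X"`, `"x"`,
#' `"XY"`, `"25"` (the PAR pseudo-chromosome used by some tools) all map
#' to `"X"`.
#'
#' @param chromosome Character or numeric vector of chromosome labels.
#' @return Character vector with labels in `{1..22, X}`.
#' @export
#' @examples
#' normalize_chromosome(c("chr1", "23", "XY", "x", 7))
normalize_chromosome <- function(chromosome) {
  chr <- sub("^chr", "", as.character(chromosome), ignore.case = TRUE)
  chr[chr %in% c("23", "25", "X", "x", "XY", "xy", "Xy", "xY")] <- "X"
  bad <- !(chr %in% c(as.character(1:22), "X"))
  if (any(bad)) {
    abort(paste0("Unrecognised chromosome label(s): ",
                 paste(unique(chr[bad]), collapse = ", ")))
  }
  chr
}

#' Assign the genomic region of a variant
#'
#' Region is a pure function of (chromosome, position) given the configured
#' PAR intervals: autosomes map to `"autosome"`; X positions inside PAR1/PAR2
#' map to `"X_PAR1"`/`"X_PAR2"`; all other X positions to `"X_nonPAR"`.
#'
#' @param chromosome Chromosome labels (normalised with
#'   [normalize_chromosome()]).
#' @param bp 1-based base-pair positions.
#' @param par PAR configuration from [par_intervals()].
#' @return Character vector in
#'   `{"autosome", "X_nonPAR", "X_PAR1", "X_PAR2"}`.
#' @export
#' @examples
#' variant_region("X", c(100000, 5000000))
variant_region <- function(chromosome, bp, par = par_intervals()) {
  n <- max(length(chromosome), length(bp))
  chr <- rep_len(normalize_chromosome(chromosome), n)
  bp <- rep_len(as.numeric(bp), n)
  if (any(!is.finite(bp)) || any(bp < 1)) abort("`bp` must be >= 1.")
  region <- rep("autosome", length(chr))
  on_x <- chr == "X"
  region[on_x] <- "X_nonPAR"
  region[on_x & bp >= par$par1[1] & bp <= par$par1[2]] <- "X_PAR1"
  region[on_x & bp >= par$par2[1] & bp <= par$par2[2]] <- "X_PAR2"
  region
}

is_par_region <- function(region) region %in% c("X_PAR1", "X_PAR2")

chromosome_order <- function(chromosome) {
  match(chromosome, c(as.character(1:22), "X"))
}
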