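#' Construct a genetic map
#'
#' A genetic map is a set of per-chromosome anchor points (bp, cM) defining a
#' piecewise-linear interpolation from physical position to genetic distance.
#' Within each chromosome, `bp` must be strictly increasing and `cM`
#' non-decreasing, with at least two anchors.
#'
#' @param map A data frame with columns `chromosome`, `bp`, `cM`.
#' @return A tibble of class `genetic_map`, sorted by chromosome and bp.
#' @export
#' @examples
#' genetic_map(data.frame(chromosome = "1", bp = c(1, 1e6), cM = c(0, 1)))
genetic_map <- function(map) {
  map <- as_tibble(map)
  required <- c("chromosome", "bp", "cM")
  missing_cols <- setdiff(required, names(map))
  if (length(missing_cols) > 0) {
    abort(paste0("Genetic map is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  map <- dplyr::mutate(map,
                       chromosome = normalize_chromosome(.data$chromosome),
                       bp = as.numeric(.data$bp), cM = as.numeric(.data$cM))
  # stable sort on chromosome only: within-chromosome anchor order is part
  # of the file's contract and is validated, not repaired
  map <- map[order(chromosome_order(map$chromosome)), , drop = FALSE]
  by_chr <- split(map, map$chromosome)
  for (chr in names(by_chr)) {
    m <- by_chr[[chr]]
    if (nrow(m) < 2) abort(paste0("Chromosome ", chr, ": need >= 2 map anchors."))
    if (any(diff(m$bp) <= 0)) {
      abort(paste0("Chromosome ", chr, ": map bp positions must be strictly increasing."))
    }
    if (any(diff(m$cM) < 0)) {
      abort(paste0("Chromosome ", chr, ": map cM values must be non-decreasing."))
    }
  }
  class(map) <- c("genetic_map", class(map))
  map
}

#' Read a genetic map from a TSV/whitespace table
#'
#' Accepts SHAPEIT/plink-style columns. Recognised column names (case
#' insensitive): position/bp/pos for physical position, any name containing
#' "cm" or "genetic_map" for cumulative cM, chromosome/chr for the chromosome.
#' Single-chromosome files (no chromosome column) require `chromosome =`.
#'
#' @param path Path to the map file.
#' @param chromosome Chromosome label for single-chromosome files.
#' @return A [genetic_map()] object.
#' @export
read_genetic_map <- function(path, chromosome = NULL) {
  if (!file.exists(path)) abort(paste0("Map file not found: ", path))
  raw <- readr::read_table(path, show_col_types = FALSE, progress = FALSE)
  nm <- tolower(names(raw))
  pos_col <- which(nm %in% c("position", "bp", "pos"))[1]
  cm_col <- which(grepl("genetic_map|^cm$|\\(cm\\)$|cum", nm) &
                    !grepl("rate", nm))[1]
  chr_col <- which(nm %in% c("chromosome", "chr"))[1]
  if (is.na(pos_col)) abort("Could not identify a position column in the map file.")
  if (is.na(cm_col)) abort("Could not identify a cumulative cM column in the map file.")
  chr <- if (!is.na(chr_col)) raw[[chr_col]] else {
    if (is.null(chromosome)) {
      abort("Map file has no chromosome column; supply `chromosome =`.")
    }
    chromosome
  }
  genetic_map(tibble(chromosome = chr, bp = raw[[pos_col]], cM = raw[[cm_col]]))
}

#' Interpolate genetic-map positions
#'
#' Linear interpolation of cM between the flanking anchors; positions outside
#' the anchored range are extrapolated along the boundary segment and floored
#' at 0 cM (a genetic distance cannot be negative). Deterministic and
#' vectorised.
#'
#' @param map A [genetic_map()].
#' @param chromosome,bp Vectors (recycled to common length) of query
#'   positions.
#' @return Numeric vector of cM values.
#' @export
#' @examples
#' m <- genetic_map(data.frame(chromosome = "1", bp = c(100, 300), cM = c(0, 1)))
#' interpolate_cm(m, "1", 200)
interpolate_cm <- function(map, chromosome, bp) {
  if (!inherits(map, "genetic_map")) map <- genetic_map(map)
  n <- max(length(chromosome), length(bp))
  chr <- rep_len(normalize_chromosome(chromosome), n)
  bp <- rep_len(as.numeric(bp), n)
  out <- numeric(n)
  for (c_i in unique(chr)) {
    anchors <- map[map$chromosome == c_i, ]
    if (nrow(anchors) == 0) {
      abort(paste0("Chromosome ", c_i, " is absent from the genetic map."))
    }
    idx <- which(chr == c_i)
    x <- anchors$bp
    y <- anchors$cM
    q <- bp[idx]
    cm <- approx(x, y, xout = q, rule = 2)$y
    k <- length(x)
    lo <- q < x[1]
    hi <- q > x[k]
    if (any(lo)) {
      slope <- (y[2] - y[1]) / (x[2] - x[1])
      cm[lo] <- y[1] + slope * (q[lo] - x[1])
    }
    if (any(hi)) {
      slope <- (y[k] - y[k - 1]) / (x[k] - x[k - 1])
      cm[hi] <- y[k] + slope * (q[hi] - x[k])
    }
    out[idx] <- pmax(cm, 0)
  }
  out
}
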