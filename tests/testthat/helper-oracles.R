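# Independent reference implementations used to check the package's fast
# paths. These deliberately share no code with the implementation.

# naive O(n^2) greedy clustering: repeatedly take the most significant
# remaining peak (ties: chromosome, bp, phenotype ascending) and sweep all
# same-chromosome peaks within `cover_cm` (inclusive) into its cluster
naive_cluster_oracle <- function(peaks, cover_cm = 0.25) {
  df <- as.data.frame(peaks)
  df$cluster <- NA_integer_
  df$lead <- FALSE
  chr_rank <- match(df$chromosome, c(as.character(1:22), "X"))
  k <- 0L
  while (anyNA(df$cluster)) {
    open <- which(is.na(df$cluster))
    o <- open[order(-df$neglog10p[open], chr_rank[open], df$bp[open],
                    df$phenotype_id[open])][1]
    k <- k + 1L
    members <- open[df$chromosome[open] == df$chromosome[o] &
                      abs(df$cM[open] - df$cM[o]) <= cover_cm]
    df$cluster[members] <- k
    df$lead[o] <- TRUE
  }
  df
}

# least-squares via explicitly solved normal equations
ols_oracle <- function(y, X) {
  X <- cbind(1, X)
  solve(t(X) %*% X, t(X) %*% y)
}

# slope/se/t for simple regression with intercept, textbook formulas
simple_ols_oracle <- function(y, g) {
  n <- length(y)
  b <- sum((g - mean(g)) * (y - mean(y))) / sum((g - mean(g))^2)
  a <- mean(y) - b * mean(g)
  rss <- sum((y - a - b * g)^2)
  se <- sqrt(rss / (n - 2) / sum((g - mean(g))^2))
  list(beta = b, se = se, t = b / se,
       neglog10p = -log10(2 * stats::pt(abs(b / se), df = n - 2,
                                        lower.tail = FALSE)))
}

# exact Hardy-Weinberg p-value by exhaustive enumeration: all C(2N, n_alt)
# placements of the alt alleles into 2N ordered allele slots are equally
# likely; slots (1,2), (3,4), ... form the genotypes. Feasible for N <= 6.
hwe_enum_oracle <- function(n_ref_hom, n_het, n_alt_hom) {
  n <- n_ref_hom + n_het + n_alt_hom
  n_alt <- 2 * n_alt_hom + n_het
  slots <- 2 * n
  if (n_alt == 0 || n_alt == slots) return(1)
  placements <- utils::combn(slots, n_alt)
  het_of <- apply(placements, 2, function(pos) {
    allele <- integer(slots)
    allele[pos] <- 1L
    g <- allele[seq(1, slots, 2)] + allele[seq(2, slots, 2)]
    sum(g == 1L)
  })
  tab <- table(het_of) / ncol(placements)
  p_obs <- tab[as.character(n_het)]
  sum(tab[tab <= p_obs + 1e-12])
}

# random peak instances for the oracle-equivalence suite, with ties in both
# the -log10 p values and the cM positions
random_peak_instance <- function(n, n_pheno = 8, n_chrom = 3) {
  chroms <- c(as.character(seq_len(max(n_chrom - 1, 1))), "X")[seq_len(n_chrom)]
  chromosome <- sample(chroms, n, replace = TRUE)
  bp <- sample.int(5e6, n) # unique, so the tie order is unambiguous
  tibble::tibble(
    phenotype_id = paste0("P", sample.int(n_pheno, n, replace = TRUE)),
    variant_id = paste0("v", seq_len(n)),
    chromosome = chromosome,
    bp = bp,
    cM = round(bp / 1e6, sample(c(1, 3), n, replace = TRUE)),
    neglog10p = 7.5 + round(stats::rexp(n, 1 / 3), sample(c(0, 2), n,
                                                          replace = TRUE)))
}
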