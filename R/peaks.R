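# ---- binary max-heap with arbitrary deletion --------------------------------
#
# The cross-phenotype aggregation is a greedy loop: repeatedly take the most
# significant remaining (phenotype, variant) pair and delete its 0.25 cM
# cover. A binary max-heap with position tracking gives O(n) build
# (bottom-up heapify), O(log n) extract-max and O(log n) arbitrary deletion,
# so the whole clustering runs in O(n log n).
#
# Items are identified by integer ids 1..n; priority is a precomputed total
# order (rank 1 = extracted first), which encodes both the -log10 p key and
# the deterministic tie rule. Internally this is a min-heap on rank, i.e. a
# max-heap on significance.

heap_new <- function(rank) {
  n <- length(rank)
  h <- new.env(parent = emptyenv())
  h$rank <- rank
  h$heap <- seq_len(n)      # heap slots -> item ids
  h$pos <- seq_len(n)       # item ids -> heap slots (0 = removed)
  h$size <- n
  for (i in rev(seq_len(n %/% 2))) heap_sink(h, i)
  h
}

heap_swap <- function(h, i, j) {
  a <- h$heap[i]; b <- h$heap[j]
  h$heap[i] <- b; h$heap[j] <- a
  h$pos[a] <- j; h$pos[b] <- i
}

heap_sink <- function(h, i) {
  n <- h$size
  rank <- h$rank
  repeat {
    l <- 2L * i
    r <- l + 1L
    best <- i
    if (l <= n && rank[h$heap[l]] < rank[h$heap[best]]) best <- l
    if (r <= n && rank[h$heap[r]] < rank[h$heap[best]]) best <- r
    if (best == i) break
    heap_swap(h, i, best)
    i <- best
  }
}

heap_swim <- function(h, i) {
  rank <- h$rank
  while (i > 1L) {
    parent <- i %/% 2L
    if (rank[h$heap[i]] >= rank[h$heap[parent]]) break
    heap_swap(h, i, parent)
    i <- parent
  }
}

heap_extract_max <- function(h) {
  if (h$size == 0L) return(NA_integer_)
  top <- h$heap[1L]
  heap_delete(h, top)
  top
}

heap_delete <- function(h, item) {
  i <- h$pos[item]
  if (i == 0L) return(invisible(FALSE))
  last <- h$size
  if (i != last) heap_swap(h, i, last)
  h$pos[item] <- 0L
  h$size <- last - 1L
  if (i <= h$size) {
    heap_sink(h, i)
    heap_swim(h, i)
  }
  invisible(TRUE)
}

heap_contains <- function(h, item) h$pos[item] > 0L

# deterministic total order: -log10 p descending, ties broken by
# (chromosome, bp, phenotype_id) ascending
peak_priority_rank <- function(df) {
  o <- order(-df$neglog10p, chromosome_order(df$chromosome), df$bp,
             df$phenotype_id)
  r <- integer(nrow(df))
  r[o] <- seq_len(nrow(df))
  r
}

# greedy cover extraction on one chromosome: heapify, then repeatedly
# extract the max and delete everything within `cover_cm` of it.
# Returns per-item cluster assignment and whether the item led its cluster.
greedy_cover_chromosome <- function(cm, rank, cover_cm) {
  n <- length(cm)
  ord <- order(cm)                 # cm-sorted view for O(log n) range lookup
  cm_sorted <- cm[ord]
  h <- heap_new(rank)
  cluster <- integer(n)
  lead <- logical(n)
  k <- 0L
  while (h$size > 0L) {
    top <- heap_extract_max(h)
    k <- k + 1L
    cluster[top] <- k
    lead[top] <- TRUE
    # candidate window with a small slack, then the defining inequality
    # |cM - lead cM| <= cover decides membership (floating-point safe)
    lo <- findInterval(cm[top] - cover_cm - 1e-9, cm_sorted,
                       left.open = TRUE) + 1L
    hi <- findInterval(cm[top] + cover_cm + 1e-9, cm_sorted)
    if (hi >= lo) {
      for (s in lo:hi) {
        item <- ord[s]
        if (abs(cm[item] - cm[top]) <= cover_cm && heap_contains(h, item)) {
          heap_delete(h, item)
          cluster[item] <- k
        }
      }
    }
  }
  list(cluster = cluster, lead = lead)
}

# ---- peak extraction ---------------------------------------------------------

#' Extract peak associations from one or more scans
#'
#' Greedy within-phenotype hit extraction: per phenotype and chromosome,
#' repeatedly take the supra-threshold record with the largest -log10 p,
#' emit it as a peak, and remove every record within `cover_cm`
#' centimorgans (inclusive), until nothing above the threshold remains.
#' Ties are broken by (chromosome, bp, phenotype) ascending, making the
#' output deterministic. Records must already carry the MAF >= 0.01 hit
#' filter if that is wanted (see [hit_filter()]).
#'
#' @param sumstats Association tibble (`variant_id, chromosome, bp,
#'   neglog10p`, optionally `phenotype_id, beta, se, n`).
#' @param map A [genetic_map()] used to assign cM positions.
#' @param threshold Genome-wide -log10 p threshold (default 7.5).
#' @param cover_cm Exclusion radius in cM (default 0.25).
#' @return A tibble of peaks with a `cM` column; within one phenotype and
#'   chromosome any two peaks are more than `cover_cm` apart.
#' @export
extract_peaks <- function(sumstats, map, threshold = 7.5, cover_cm = 0.25) {
  df <- as_tibble(sumstats)
  if (!("phenotype_id" %in% names(df))) df$phenotype_id <- "phenotype"
  df <- df[!is.na(df$neglog10p) & df$neglog10p > threshold, , drop = FALSE]
  if (nrow(df) == 0) return(dplyr::mutate(df, cM = numeric(0)))
  df$cM <- interpolate_cm(map, df$chromosome, df$bp)
  parts <- split(df, list(df$phenotype_id, df$chromosome), drop = TRUE)
  peaks <- purrr::map(parts, function(part) {
    rank <- peak_priority_rank(part)
    res <- greedy_cover_chromosome(part$cM, rank, cover_cm)
    part[res$lead, , drop = FALSE]
  })
  out <- dplyr::bind_rows(peaks)
  out[order(chromosome_order(out$chromosome), out$bp, out$phenotype_id), ]
}

# ---- cross-phenotype clustering ---------------------------------------------

new_gwas_clusters <- function(clusters, members) {
  structure(list(clusters = clusters, members = members),
            class = "gwas_clusters")
}

#' Cluster peaks across phenotypes
#'
#' The cross-phenotype aggregation: per chromosome, all (phenotype, variant)
#' peaks are built into a binary max-heap keyed on -log10 p (linear-time
#' heapify); then, while the heap is non-empty, the maximum pair is
#' extracted as the lead of a new cluster and every remaining peak within
#' `cover_cm` centimorgans of the lead (inclusive) is removed from the heap
#' and assigned to that cluster. Every peak lands in exactly one cluster;
#' no member out-significates its lead; total work is O(n log n).
#'
#' Clusters are numbered by chromosome (1..22 then X) and, within a
#' chromosome, by descending lead -log10 p.
#'
#' @param peaks Peak tibble from [extract_peaks()] (must carry `cM`).
#' @param cover_cm Cluster radius in cM (default 0.25).
#' @param bonferroni_threshold Optional -log10 p level for the Bonferroni
#'   flag (see [bonferroni_threshold()]); `NA` leaves the flag `NA`.
#' @return A `gwas_clusters` object: `$clusters` (one row per cluster with
#'   lead identity, `n_snps`, `replicated`, `bonferroni`) and `$members`
#'   (every peak with its `cluster_id` and `is_lead`).
#' @export
cluster_peaks <- function(peaks, cover_cm = 0.25, bonferroni_threshold = NA) {
  df <- as_tibble(peaks)
  if (nrow(df) > 0 && (!("cM" %in% names(df)) || anyNA(df$cM))) {
    abort("Every peak must carry a cM coordinate (see extract_peaks()).")
  }
  if (nrow(df) == 0) {
    empty <- tibble(cluster_id = integer(), lead_variant_id = character(),
                    lead_phenotype_id = character(), chromosome = character(),
                    bp = numeric(), lead_cm = numeric(),
                    lead_neglog10p = numeric(), n_snps = integer(),
                    replicated = logical(), bonferroni = logical())
    return(new_gwas_clusters(empty, dplyr::mutate(df, cluster_id = integer(),
                                                  is_lead = logical())))
  }
  if (!("phenotype_id" %in% names(df))) df$phenotype_id <- "phenotype"
  df$.row <- seq_len(nrow(df))
  parts <- split(df, df$chromosome)
  assigned <- purrr::map(parts, function(part) {
    rank <- peak_priority_rank(part)
    res <- greedy_cover_chromosome(part$cM, rank, cover_cm)
    part$.chr_cluster <- res$cluster
    part$is_lead <- res$lead
    part
  })
  members <- dplyr::bind_rows(assigned)
  # global cluster ids: chromosome order, then descending lead -log10 p
  leads <- members[members$is_lead, , drop = FALSE]
  leads <- leads[order(chromosome_order(leads$chromosome),
                       -leads$neglog10p, leads$bp, leads$phenotype_id), ]
  leads$cluster_id <- seq_len(nrow(leads))
  key <- paste(leads$chromosome, leads$.chr_cluster)
  members$cluster_id <- leads$cluster_id[
    match(paste(members$chromosome, members$.chr_cluster), key)]
  members <- members[order(members$cluster_id, -members$neglog10p,
                           members$bp, members$phenotype_id), ]
  members$.chr_cluster <- NULL
  n_snps <- table(members$cluster_id)
  clusters <- tibble(
    cluster_id = leads$cluster_id,
    lead_variant_id = leads$variant_id,
    lead_phenotype_id = leads$phenotype_id,
    chromosome = leads$chromosome,
    bp = leads$bp,
    ref = if ("ref" %in% names(leads)) leads$ref else NA_character_,
    alt = if ("alt" %in% names(leads)) leads$alt else NA_character_,
    lead_cm = leads$cM,
    lead_neglog10p = leads$neglog10p,
    n_snps = as.integer(n_snps[as.character(leads$cluster_id)]),
    replicated = NA,
    bonferroni = if (is.na(bonferroni_threshold)) NA else
      leads$neglog10p >= bonferroni_threshold
  )
  members$.row <- NULL
  new_gwas_clusters(clusters, members)
}

#' Bonferroni-adjusted genome-wide threshold
#'
#' Adjusts the genome-wide -log10 p threshold for the number of phenotypes
#' scanned: `base + log10(n_phenotypes)`. Returned unrounded; display
#' convention is one decimal.
#'
#' @param n_phenotypes Number of phenotypes (>= 1).
#' @param base Genome-wide threshold (default 7.5).
#' @return The adjusted threshold.
#' @export
#' @examples
#' bonferroni_threshold(3935) # ~11.1
bonferroni_threshold <- function(n_phenotypes, base = 7.5) {
  if (length(n_phenotypes) != 1 || is.na(n_phenotypes) || n_phenotypes < 1) {
    abort("`n_phenotypes` must be a single integer >= 1.")
  }
  base + log10(n_phenotypes)
}

#' Annotate clusters with replication status
#'
#' A cluster replicates when at least one of its member (phenotype, variant)
#' pairs reaches nominal two-sided significance, p < 0.05 strictly
#' (-log10 p > 1.30103), in the held-out replication scan. Members that are
#' untestable in replication (monomorphic or absent) count as
#' non-significant and are logged.
#'
#' @param clusters A `gwas_clusters` object.
#' @param replication_sumstats Replication-scan tibble with `phenotype_id`,
#'   `variant_id`, `neglog10p`.
#' @return The `gwas_clusters` with the `replicated` flag filled in and a
#'   `replication_neglog10p` column on the members.
#' @export
tag_replication <- function(clusters, replication_sumstats) {
  members <- clusters$members
  if (nrow(members) == 0) {
    clusters$members$replication_neglog10p <- numeric(0)
    clusters$clusters$replicated <- logical(0)
    return(clusters)
  }
  if (is.null(replication_sumstats) || nrow(replication_sumstats) == 0) {
    warn("Empty replication set: no cluster can replicate.")
    rep_p <- rep(NA_real_, nrow(members))
  } else {
    key <- paste(replication_sumstats$phenotype_id,
                 replication_sumstats$variant_id)
    idx <- match(paste(members$phenotype_id, members$variant_id), key)
    rep_p <- replication_sumstats$neglog10p[idx]
    n_untestable <- sum(is.na(rep_p))
    if (n_untestable > 0) {
      inform(paste0(n_untestable, " member pair(s) untestable in replication",
                    " (monomorphic or absent); treated as non-significant."))
    }
  }
  members$replication_neglog10p <- rep_p
  sig <- !is.na(rep_p) & rep_p > -log10(0.05)
  replicated_ids <- unique(members$cluster_id[sig])
  clusters$members <- members
  clusters$clusters$replicated <- clusters$clusters$cluster_id %in% replicated_ids
  clusters
}

#' @exportS3Method base::print
print.gwas_clusters <- function(x, ...) {
  cat("<gwas_clusters> ", nrow(x$clusters), " clusters over ",
      nrow(x$members), " peak (phenotype, variant) pairs\n", sep = "")
  if (nrow(x$clusters) > 0) {
    if (!all(is.na(x$clusters$replicated))) {
      cat("  replicated: ", sum(x$clusters$replicated, na.rm = TRUE), "\n",
          sep = "")
    }
    if (!all(is.na(x$clusters$bonferroni))) {
      cat("  Bonferroni-significant leads: ",
          sum(x$clusters$bonferroni, na.rm = TRUE), "\n", sep = "")
    }
    print(head(x$clusters, 10))
  }
  invisible(x)
}

#' @export
tidy.gwas_clusters <- function(x, ...) x$members

#' @export
glance.gwas_clusters <- function(x, ...) {
  tibble(n_clusters = nrow(x$clusters),
         n_peaks = nrow(x$members),
         n_replicated = sum(x$clusters$replicated, na.rm = TRUE),
         n_bonferroni = sum(x$clusters$bonferroni, na.rm = TRUE),
         n_phenotypes = length(unique(x$members$phenotype_id)),
         n_chromosomes = length(unique(x$clusters$chromosome)))
}
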