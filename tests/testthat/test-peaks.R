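toy_map <- genetic_map(data.frame(chromosome = rep(c("1", "2", "X"), each = 2),
                                  bp = rep(c(1, 5e6), 3),
                                  cM = rep(c(0, 5), 3)))

test_that("within-phenotype peak extraction prunes the 0.25 cM cover greedily", {
  # cM 1.0 (-log10 p 10), 1.1 (9), 1.4 (8): 1.1 removed by 1.0; 1.4 survives
  # (anchors placed at the query positions, so cM values are exact)
  exact_map <- genetic_map(data.frame(chromosome = "1",
                                      bp = c(1.0e6, 1.1e6, 1.4e6),
                                      cM = c(1.0, 1.1, 1.4)))
  ss <- tibble::tibble(variant_id = c("a", "b", "c"), chromosome = "1",
                       bp = c(1.0e6, 1.1e6, 1.4e6),
                       neglog10p = c(10, 9, 8))
  pk <- extract_peaks(ss, exact_map, threshold = 7.5)
  expect_equal(pk$variant_id, c("a", "c"))
  expect_equal(pk$cM, c(1.0, 1.4), tolerance = 1e-9)

  # all below threshold -> nothing
  expect_equal(nrow(extract_peaks(dplyr::mutate(ss, neglog10p = c(7, 6, 5)),
                                  exact_map)), 0)
  # single supra-threshold record -> itself
  one <- extract_peaks(ss[3, ], exact_map)
  expect_equal(one$variant_id, "c")
})

test_that("peak extraction separates phenotypes and respects the exact boundary", {
  # anchors at the query positions: cM separations are exactly 0.25 / 0.26
  exact_map <- genetic_map(data.frame(chromosome = "1",
                                      bp = c(1.00e6, 1.25e6, 1.26e6),
                                      cM = c(1.00, 1.25, 1.26)))
  ss <- tibble::tibble(
    phenotype_id = rep(c("A", "B"), each = 2),
    variant_id = paste0("v", 1:4), chromosome = "1",
    bp = c(1.00e6, 1.25e6, 1.00e6, 1.26e6),
    neglog10p = c(10, 9, 10, 9))
  pk <- extract_peaks(ss, exact_map)
  # phenotype A: 0.25 cM apart exactly -> inside the cover, pruned
  expect_equal(sum(pk$phenotype_id == "A"), 1)
  # phenotype B: 0.26 cM apart -> both survive
  expect_equal(sum(pk$phenotype_id == "B"), 2)
})

test_that("extract_peaks output never holds two peaks within the cover of one phenotype", {
  withr::local_seed(51)
  for (i in 1:25) {
    ss <- random_peak_instance(sample(20:150, 1))
    ss$neglog10p <- ss$neglog10p + runif(nrow(ss), -3, 0)
    pk <- extract_peaks(dplyr::select(ss, -"cM"), toy_map, threshold = 7.5)
    groups <- split(pk$cM, paste(pk$phenotype_id, pk$chromosome))
    sep <- vapply(groups, function(cm) {
      length(cm) < 2 || all(diff(sort(cm)) > 0.25)
    }, logical(1))
    expect_true(all(sep))
    expect_true(all(pk$neglog10p > 7.5))
  }
})

test_that("raising the threshold never increases the number of peaks", {
  withr::local_seed(52)
  ss <- random_peak_instance(300)
  ss <- dplyr::select(ss, -"cM")
  counts <- vapply(c(7.5, 8.5, 9.5, 11), function(thr) {
    nrow(extract_peaks(ss, toy_map, threshold = thr))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cross-phenotype clustering reproduces the worked example", {
  peaks <- tibble::tibble(
    phenotype_id = c("phenoA", "phenoB", "phenoC"),
    variant_id = c("v1", "v2", "v3"), chromosome = "1",
    bp = c(1, 2, 3), cM = c(10.0, 10.2, 10.5),
    neglog10p = c(12, 9, 8))
  cl <- cluster_peaks(peaks)
  expect_equal(nrow(cl$clusters), 2)
  expect_equal(cl$clusters$lead_phenotype_id, c("phenoA", "phenoC"))
  members1 <- cl$members$phenotype_id[cl$members$cluster_id == 1]
  expect_setequal(members1, c("phenoA", "phenoB"))
  expect_equal(cl$members$is_lead[cl$members$phenotype_id == "phenoB"], FALSE)

  # all peaks within cover of the max -> a single cluster
  tight <- dplyr::mutate(peaks, cM = c(10.0, 10.1, 10.2))
  expect_equal(nrow(cluster_peaks(tight)$clusters), 1)

  # different chromosomes never co-cluster
  split_chr <- dplyr::mutate(peaks, chromosome = c("1", "2", "2"),
                             cM = c(10, 10, 10.1))
  expect_equal(nrow(cluster_peaks(split_chr)$clusters), 2)
})

test_that("heap clustering equals the naive greedy oracle, with ties", {
  withr::local_seed(53)
  for (i in 1:60) {
    peaks <- random_peak_instance(sample(5:250, 1))
    got <- cluster_peaks(peaks)
    want <- naive_cluster_oracle(peaks, 0.25)
    got_m <- got$members[order(got$members$variant_id), ]
    want_ord <- order(want$variant_id)
    # same partition with the same leads
    expect_equal(got_m$is_lead, want$lead[want_ord])
    got_lead_of <- got$clusters$lead_variant_id[
      match(got_m$cluster_id, got$clusters$cluster_id)]
    want_lead_of <- want$variant_id[want$lead][
      match(want$cluster[want_ord], want$cluster[want$lead])]
    expect_equal(got_lead_of, want_lead_of)
  }
})

test_that("cluster output satisfies the partition, dominance and ordering invariants", {
  withr::local_seed(54)
  peaks <- random_peak_instance(400)
  cl <- cluster_peaks(peaks)
  # partition: every peak in exactly one cluster
  expect_equal(nrow(cl$members), nrow(peaks))
  expect_equal(sum(cl$clusters$n_snps), nrow(peaks))
  expect_false(anyDuplicated(paste(cl$members$phenotype_id,
                                   cl$members$variant_id)) > 0)
  # lead dominance and cover containment
  for (k in cl$clusters$cluster_id) {
    mem <- cl$members[cl$members$cluster_id == k, ]
    lead <- cl$clusters[cl$clusters$cluster_id == k, ]
    expect_true(all(mem$neglog10p <= lead$lead_neglog10p))
    expect_true(all(abs(mem$cM - lead$lead_cm) <= 0.25))
    expect_true(all(mem$chromosome == lead$chromosome))
  }
  # report ordering: chromosome, then descending lead significance
  expect_false(is.unsorted(match(cl$clusters$chromosome,
                                 c(as.character(1:22), "X"))))
  by_chr <- split(cl$clusters$lead_neglog10p, cl$clusters$chromosome)
  expect_true(all(vapply(by_chr, function(x) !is.unsorted(rev(x)), logical(1))))
})

test_that("clustering is deterministic under exact ties", {
  peaks <- tibble::tibble(
    phenotype_id = c("B", "A", "A", "C"),
    variant_id = c("v1", "v2", "v3", "v4"), chromosome = "1",
    bp = c(200, 100, 5e6, 5e6 + 1), cM = c(0.2, 0.1, 5, 5.000001),
    neglog10p = c(9, 9, 9, 9))
  cl1 <- cluster_peaks(peaks)
  cl2 <- cluster_peaks(peaks[c(3, 1, 4, 2), ])
  # tie rule: lowest bp wins; input order irrelevant
  expect_equal(cl1$clusters$lead_variant_id, c("v2", "v3"))
  expect_equal(cl2$clusters$lead_variant_id, cl1$clusters$lead_variant_id)
  expect_equal(cl2$members$cluster_id[order(cl2$members$variant_id)],
               cl1$members$cluster_id[order(cl1$members$variant_id)])
})

test_that("peaks lacking cM coordinates are rejected", {
  bad <- tibble::tibble(phenotype_id = "A", variant_id = "v", chromosome = "1",
                        bp = 1, cM = NA_real_, neglog10p = 9)
  expect_error(cluster_peaks(bad), "cM")
})

test_that("the Bonferroni threshold adds log10 of the phenotype count", {
  expect_equal(bonferroni_threshold(1), 7.5)
  expect_equal(bonferroni_threshold(10), 8.5)
  expect_equal(bonferroni_threshold(3935), 7.5 + log10(3935))
  expect_equal(round(bonferroni_threshold(3935), 1), 11.1)
  expect_error(bonferroni_threshold(0), ">= 1")
})

test_that("replication tagging uses strict nominal significance", {
  peaks <- tibble::tibble(
    phenotype_id = c("A", "B", "C"), variant_id = c("v1", "v2", "v3"),
    chromosome = "1", bp = 1:3, cM = c(1, 5, 9), neglog10p = c(10, 9, 8))
  cl <- cluster_peaks(peaks)
  rep_ss <- tibble::tibble(
    phenotype_id = c("A", "B"), variant_id = c("v1", "v2"),
    neglog10p = c(-log10(0.04), -log10(0.05)))
  tagged <- suppressMessages(tag_replication(cl, rep_ss))
  got <- tagged$clusters$replicated[order(tagged$clusters$lead_variant_id)]
  expect_equal(got, c(TRUE, FALSE, FALSE)) # 0.04 yes; 0.05 exact no; missing no
  # empty replication set: warning, nothing replicates
  expect_warning(tag_replication(cl, rep_ss[0, ]), "[Ee]mpty")
})

test_that("tidy and glance summarise a cluster object", {
  peaks <- tibble::tibble(
    phenotype_id = c("A", "B"), variant_id = c("v1", "v2"),
    chromosome = "1", bp = 1:2, cM = c(1, 1.1), neglog10p = c(12, 9))
  cl <- cluster_peaks(peaks, bonferroni_threshold = 11.1)
  expect_equal(nrow(tidy(cl)), 2)
  g <- glance(cl)
  expect_equal(g$n_clusters, 1)
  expect_equal(g$n_bonferroni, 1)
})
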