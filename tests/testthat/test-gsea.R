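test_that("gene ranking uses signed -log10 p with deterministic tie-breaks", {
  de <- tibble::tibble(
    gene_id = c("b", "a", "c"),
    log2fc = c(2, -1, 2),
    p = c(0.01, 0.1, 0.01)
  )
  r <- rank_genes(de)
  expect_equal(r$score[r$gene_id == "b"], 2)
  expect_equal(r$score[r$gene_id == "a"], -1)
  # equal scores resolve lexicographically: b and c tie at +2, b first
  expect_equal(r$gene_id, c("b", "c", "a"))
  expect_identical(r, rank_genes(de[c(3, 1, 2), ]))

  expect_message(
    r0 <- rank_genes(tibble::tibble(gene_id = "x", log2fc = 1, p = 0)),
    "clamped"
  )
  expect_true(is.finite(r0$score))
  expect_equal(
    rank_genes(de, metric = "log2fc")$score[1], 2
  )
})

test_that("enrichment score matches hand-computed runs", {
  ranked <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"), score = c(3, 2, 1, -1)
  )
  expect_equal(enrichment_score(ranked, "a")$es, 1)

  # equal |scores|, singleton set at the exact bottom: the running sum
  # drifts to -1 just before the final hit
  flat <- tibble::tibble(
    gene_id = c("a", "b", "c", "z"), score = c(1, 1, 1, 1)
  )
  expect_equal(enrichment_score(flat, "z")$es, -1)

  expect_error(enrichment_score(ranked, character()), "some but not all")
  expect_error(enrichment_score(ranked, ranked$gene_id), "some but not all")
})

test_that("enrichment score equals brute-force enumeration on small lists", {
  set.seed(31)
  for (k in 1:60) {
    n <- sample(3:8, 1)
    ranked <- tibble::tibble(
      gene_id = paste0("g", 1:n),
      score = sort(round(rnorm(n), 2), decreasing = TRUE)
    )
    set_size <- sample(1:min(3, n - 1), 1)
    gene_set <- sample(ranked$gene_id, set_size)
    got <- enrichment_score(ranked, gene_set)
    expect_equal(
      got$es,
      oracle_es(ranked$score, ranked$gene_id %in% gene_set),
      tolerance = 1e-12
    )
    # the stored running sum peaks exactly at the ES
    dev <- got$running_sum[which.max(abs(got$running_sum))]
    expect_equal(dev, got$es)
  }
})

test_that("enrichment score agrees with an independent reference implementation", {
  set.seed(55)
  stats <- sort(rnorm(300), decreasing = TRUE)
  ranked <- tibble::tibble(gene_id = sprintf("g%03d", 1:300), score = stats)
  idx <- sort(sample(300, 25))
  ours <- enrichment_score(ranked, ranked$gene_id[idx])$es
  ref <- fgsea::calcGseaStat(stats, idx, gseaParam = 1)
  expect_equal(ours, ref, tolerance = 1e-8)
})

test_that("weighted ES is invariant under positive rescaling of all scores", {
  set.seed(8)
  ranked <- tibble::tibble(
    gene_id = paste0("g", 1:50), score = sort(rnorm(50), decreasing = TRUE)
  )
  gs <- sample(ranked$gene_id, 8)
  a <- enrichment_score(ranked, gs)$es
  scaled <- dplyr::mutate(ranked, score = score * 3.7)
  expect_equal(enrichment_score(scaled, gs)$es, a)
  # with weight 0 the ES only sees the order, so any monotone transform works
  warped <- dplyr::mutate(ranked, score = rank(score))
  expect_equal(
    enrichment_score(ranked, gs, weight = 0)$es,
    enrichment_score(warped, gs, weight = 0)$es
  )
})

test_that("random gene sets score near zero on average", {
  set.seed(12)
  ranked <- tibble::tibble(
    gene_id = paste0("g", 1:40), score = sort(rnorm(40), decreasing = TRUE)
  )
  es <- vapply(1:1000, function(k) {
    enrichment_score(ranked, sample(ranked$gene_id, 6))$es
  }, numeric(1))
  expect_lt(abs(mean(es)), 0.05)
})

test_that("permutation significance is seeded, stable in ES, and calibrated", {
  set.seed(21)
  ranked <- tibble::tibble(
    gene_id = paste0("g", 1:200), score = sort(rnorm(200), decreasing = TRUE)
  )
  gs <- sample(ranked$gene_id, 15)
  a <- gsea_significance(ranked, gs, n_perm = 200, seed = 4)
  b <- gsea_significance(ranked, gs, n_perm = 400, seed = 4)
  expect_equal(a$es, b$es) # ES is permutation-free
  expect_identical(
    glance(gsea_significance(ranked, gs, n_perm = 200, seed = 4)),
    glance(a)
  )
  expect_error(gsea_significance(ranked, gs, n_perm = 50), "n_perm")

  # under a true null the p-value is (super-)uniform at the 5% level
  ps <- vapply(1:40, function(k) {
    set.seed(4000 + k)
    gsea_significance(ranked, sample(ranked$gene_id, 10),
      n_perm = 100, seed = 4000 + k
    )$p_perm
  }, numeric(1))
  expect_lte(mean(ps <= 0.05), 0.05 + 0.09) # binomial slack at 40 draws
})

test_that("a set planted at the bottom of the list is negatively enriched", {
  tx <- generate_transcriptome(toy_transcriptome_scenario(3))
  # scale up: use a mid-sized planted scenario for a stable sign
  sc <- new_scenario(list(
    name = "mid", rng_seed = 6,
    transcriptome = list(
      n_genes = 800, n_target_genes = 100, n_up_sig = 150, n_down_sig = 170,
      n_up_targets = 20, n_down_targets = 60, utr_len = 80
    )
  ))
  tx <- generate_transcriptome(sc)
  res <- gsea_significance(
    rank_genes(tx$de), tx$target_ids,
    n_perm = 500, seed = 11
  )
  expect_lt(res$es, 0)
  expect_lt(res$p_perm, 0.01)
  expect_lt(res$fdr, 0.05)
})
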