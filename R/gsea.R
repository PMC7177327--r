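#' Rank genes for preranked enrichment analysis
#'
#' Builds the ranked list from a DE table using the signed evidence score
#' `sign(log2fc) * (-log10 p)`; the metric is configurable to plain
#' `log2fc`. Ties are broken by lexicographic `gene_id` so the ordering is
#' deterministic across runs. p-values of exactly 0 are clamped to the
#' smallest representable double (with a message).
#'
#' @param de DE tibble with `gene_id`, `log2fc`, `p`.
#' @param metric `"signed_logp"` (default) or `"log2fc"`.
#' @return Tibble `gene_id`, `score`, sorted by descending score.
#' @examples
#' de <- tibble::tibble(
#'   gene_id = c("a", "b"), log2fc = c(2, -1), p = c(0.01, 0.1)
#' )
#' rank_genes(de)
#' @export
rank_genes <- function(de, metric = c("signed_logp", "log2fc")) {
  metric <- match.arg(metric)
  miss <- setdiff(c("gene_id", "log2fc", "p"), names(de))
  if (length(miss)) {
    abort(paste0("DE table missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(de$gene_id)) abort("gene_id values must be unique")
  p <- de$p
  if (any(p < 0 | p > 1)) abort("p values must lie in [0, 1]")
  if (any(p == 0)) {
    inform("p values of 0 clamped to the smallest representable double")
    p[p == 0] <- .Machine$double.xmin
  }
  score <- switch(metric,
    signed_logp = sign(de$log2fc) * (-log10(p)),
    log2fc = de$log2fc
  )
  tibble(gene_id = de$gene_id, score = score) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene_id)
}

# Signed enrichment score from sorted scores and hit positions.
# Weighted KS running sum: each hit advances by |score|^weight / sum over
# hits, each miss by 1/(N - Nh); extrema can only occur at a hit (upper)
# or immediately before a hit (lower).
.es_from_hits <- function(scores, hit_idx, weight = 1) {
  n <- length(scores)
  nh <- length(hit_idx)
  hit_idx <- sort(hit_idx)
  w <- abs(scores[hit_idx])^weight
  if (sum(w) == 0) w <- rep(1, nh) # degenerate all-zero scores: unweighted
  cum_hit <- cumsum(w) / sum(w)
  miss_at_hit <- (hit_idx - seq_len(nh)) / (n - nh)
  top <- cum_hit - miss_at_hit
  bottom <- c(0, cum_hit[-nh]) - miss_at_hit
  k_pos <- which.max(top)
  k_neg <- which.min(bottom)
  es_pos <- top[k_pos]
  es_neg <- bottom[k_neg]
  if (abs(es_pos - abs(es_neg)) < 1e-15) {
    # exact magnitude tie: the deviation reached earlier in the list wins
    if (hit_idx[k_pos] <= hit_idx[k_neg] - 1) es_pos else es_neg
  } else if (es_pos > -es_neg) {
    es_pos
  } else {
    es_neg
  }
}

#' Enrichment score of a gene set in a ranked list
#'
#' Classic weighted Kolmogorov-Smirnov-style statistic: walking down the
#' ranked list, the running sum rises by `|score|^weight / sum(|score| over
#' hits)` at each gene-set member and falls by `1/(N - N_hits)` otherwise;
#' the enrichment score (ES) is the signed maximal deviation from zero.
#' `weight = 1` is the standard preranked default; `weight = 0` reduces to
#' the unweighted KS statistic.
#'
#' @param ranked Ranked tibble from [rank_genes()] (`gene_id`, `score`).
#' @param gene_set Character vector of gene ids.
#' @param weight Weight exponent on `|score|`.
#' @return A `perimir_gsea` object with `es`, `running_sum` (per-rank
#'   deviation), `hit_ranks`, `leading_edge`, `n`, `n_hits`.
#' @examples
#' ranked <- tibble::tibble(gene_id = c("a", "b", "c", "d"), score = c(3, 2, 1, -1))
#' enrichment_score(ranked, "a")$es
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  if (!all(c("gene_id", "score") %in% names(ranked))) {
    abort("ranked list needs columns gene_id, score")
  }
  hits <- which(ranked$gene_id %in% gene_set)
  n <- nrow(ranked)
  if (length(hits) == 0 || length(hits) == n) {
    abort("gene set must hit some but not all of the ranked list")
  }
  w <- abs(ranked$score[hits])^weight
  if (sum(w) == 0) w <- rep(1, length(hits))
  inc <- numeric(n)
  inc[hits] <- w / sum(w)
  dec <- numeric(n)
  dec[-hits] <- 1 / (n - length(hits))
  running <- cumsum(inc - dec)
  es <- .es_from_hits(ranked$score, hits, weight)
  le <- if (es >= 0) {
    peak <- which.max(running)
    ranked$gene_id[intersect(hits, seq_len(peak))]
  } else {
    trough <- which.min(c(0, running)[seq_len(n)]) # value just before each rank
    ranked$gene_id[hits[hits >= trough]]
  }
  structure(
    list(
      es = es, running_sum = running, hit_ranks = hits,
      leading_edge = le, n = n, n_hits = length(hits), weight = weight,
      nes = NA_real_, p_perm = NA_real_, fdr = NA_real_, n_perm = 0L
    ),
    class = "perimir_gsea"
  )
}

#' Permutation significance for a preranked enrichment score
#'
#' Gene-set permutation null: the ES of `n_perm` random gene sets of the
#' same size drawn from the ranked list. The one-sided p-value uses the
#' add-one correction `(1 + #{null at least as extreme, same sign}) /
#' (n_perm + 1)`; NES divides the ES by the mean magnitude of same-sign
#' null ES values; the FDR q-value follows the standard single-set
#' preranked convention (fraction of same-sign null ES at least as extreme
#' as the observed, normalized by the fraction of null ES of that sign).
#' The ES itself is permutation-free, so it is unchanged by `n_perm`.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of gene-set permutations (>= 100).
#' @param seed Integer seed for the permutation draws.
#' @return A `perimir_gsea` object with `es`, `nes`, `p_perm`, `fdr`,
#'   `null_es`, `running_sum`, `leading_edge` filled in.
#' @examples
#' de <- generate_transcriptome(new_scenario(list(
#'   name = "toy", rng_seed = 1,
#'   transcriptome = list(
#'     n_genes = 60, n_target_genes = 10, n_up_sig = 5, n_down_sig = 10,
#'     n_up_targets = 2, n_down_targets = 8, utr_len = 50
#'   )
#' )))
#' res <- gsea_significance(rank_genes(de$de), de$target_ids,
#'   n_perm = 200, seed = 7
#' )
#' glance(res)
#' @export
gsea_significance <- function(ranked, gene_set, n_perm = 1000, seed = 1,
                              weight = 1) {
  if (n_perm < 100) abort("n_perm must be >= 100")
  res <- enrichment_score(ranked, gene_set, weight)
  null_es <- .local_seed(seed, {
    vapply(
      seq_len(n_perm),
      function(i) {
        .es_from_hits(
          ranked$score, sample.int(res$n, res$n_hits),
          weight
        )
      },
      numeric(1)
    )
  })
  if (length(unique(null_es)) == 1) {
    abort("degenerate permutation null: all null enrichment scores identical")
  }
  same_sign <- if (res$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  extreme <- sum(abs(same_sign) >= abs(res$es))
  res$p_perm <- (1 + extreme) / (n_perm + 1)
  res$nes <- if (length(same_sign)) res$es / mean(abs(same_sign)) else NA_real_
  res$fdr <- min(1, extreme / max(1, length(same_sign)))
  res$null_es <- null_es
  res$n_perm <- as.integer(n_perm)
  res
}

#' @export
print.perimir_gsea <- function(x, ...) {
  cat("<perimir_gsea> ES = ", signif(x$es, 4),
    " (", x$n_hits, "/", x$n, " genes in set)\n",
    sep = ""
  )
  if (x$n_perm > 0) {
    cat(
      "  NES =", signif(x$nes, 4), ", p =", signif(x$p_perm, 3),
      ", FDR =", signif(x$fdr, 3), " (", x$n_perm, "permutations )\n"
    )
  }
  invisible(x)
}
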