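#' Generate a synthetic transcriptome with planted miRNA target sites
#'
#' Builds a 3'UTR set and a matching differential-expression table with
#' exactly controlled structure: `n_target_genes` UTRs carry at least one
#' planted canonical seed site for the miRNA, while every other UTR is
#' rejection-sampled to contain zero 6mer seed matches, so the seed-site
#' scanner's positive set equals the planted set exactly. The DE table
#' contains exactly `n_up_sig` genes with `p < 0.05 & log2fc > 0` and
#' `n_down_sig` with `p < 0.05 & log2fc < 0`, of which exactly
#' `n_up_targets` / `n_down_targets` are planted targets. Downregulated
#' targets are given the most extreme p-values so that the planted target
#' set is negatively enriched in the ranked list, mirroring the biological
#' expectation when the repressing miRNA is lost.
#'
#' @param scenario A [scenario()] with a `transcriptome` block.
#' @param mirna Mature miRNA sequence (RNA); defaults to the miRNA derived
#'   from the packaged detection probe.
#' @param seed Optional integer overriding the scenario seed.
#' @return List with `utrs` (named character vector of RNA sequences),
#'   `de` (tibble `gene_id`, `log2fc`, `p`) and `target_ids`.
#' @examples
#' sc <- new_scenario(list(
#'   name = "toy", rng_seed = 1,
#'   transcriptome = list(
#'     n_genes = 10, n_target_genes = 4, n_up_sig = 3, n_down_sig = 2,
#'     n_up_targets = 2, n_down_targets = 1, utr_len = 60
#'   )
#' ))
#' tx <- generate_transcriptome(sc)
#' length(tx$target_ids)
#' @export
generate_transcriptome <- function(scenario, mirna = NULL, seed = NULL) {
  stopifnot(inherits(scenario, "perimir_scenario"))
  tr <- scenario$transcriptome
  if (is.null(tr)) abort("scenario has no transcriptome block")
  mirna <- mirna %||% mirna_from_probe(.default_probe)
  seed <- seed %||% .derive_seed(scenario$rng_seed, 999L)
  sites <- .seed_site_strings(mirna)

  .local_seed(seed, {
    n <- tr$n_genes
    len <- tr$utr_len
    ids <- sprintf("gene%05d", seq_len(n))

    utrs <- .random_utrs(n, len)
    # rejection: regenerate any UTR carrying a chance 6mer seed match
    repeat {
      hit <- grepl(sites[["6mer"]], utrs, fixed = TRUE)
      if (!any(hit)) break
      utrs[hit] <- .random_utrs(sum(hit), len)
    }
    names(utrs) <- ids

    target_ids <- sort(sample(ids, tr$n_target_genes))
    if (tr$n_target_genes > 0) {
      plant_type <- sample(c("8mer", "7mer-m8", "7mer-A1"),
        tr$n_target_genes,
        replace = TRUE
      )
      for (k in seq_along(target_ids)) {
        site <- sites[[plant_type[k]]]
        pos <- sample.int(len - nchar(site) + 1L, 1)
        substr(utrs[[target_ids[k]]], pos, pos + nchar(site) - 1L) <- site
      }
    }

    nt_ids <- setdiff(ids, target_ids)
    up_t <- sample(target_ids, tr$n_up_targets)
    down_t <- sample(setdiff(target_ids, up_t), tr$n_down_targets)
    up_nt <- sample(nt_ids, tr$n_up_sig - tr$n_up_targets)
    down_nt <- sample(setdiff(nt_ids, up_nt), tr$n_down_sig - tr$n_down_targets)

    p <- runif(n, 0.051, 1)
    lfc <- rnorm(n, 0, 0.2)
    # significant non-targets: moderate evidence, either direction
    p[match(c(up_nt, down_nt), ids)] <-
      10^-runif(length(up_nt) + length(down_nt), 1.32, 3.5)
    # significant up-targets: mild evidence
    p[match(up_t, ids)] <- 10^-runif(length(up_t), 1.32, 2.5)
    # significant down-targets: strongest evidence (drives negative enrichment)
    p[match(down_t, ids)] <- 10^-runif(length(down_t), 3, 7)

    sig_up <- c(up_t, up_nt)
    sig_down <- c(down_t, down_nt)
    lfc[match(sig_up, ids)] <- 0.5 + stats::rexp(length(sig_up), 1.4)
    lfc[match(sig_down, ids)] <- -(0.5 + stats::rexp(length(sig_down), 1.4))
    lfc[lfc == 0] <- 1e-6

    list(
      utrs = utrs,
      de = tibble(gene_id = ids, log2fc = lfc, p = p),
      target_ids = target_ids
    )
  })
}

.random_utrs <- function(n, len) {
  if (n == 0) return(character())
  m <- matrix(sample(.rna_letters, n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste0, collapse = "")
}
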