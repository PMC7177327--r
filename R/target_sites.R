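#' Derive the mature miRNA from a detection-probe sequence
#'
#' Chromogenic ISH probes are antisense to the mature miRNA, so the miRNA
#' is the reverse complement of the probe. Case markup used to annotate
#' probe chemistry is stripped by uppercasing; the chemistry itself plays
#' no role at sequence level.
#'
#' @param probe_sequence Probe in RNA alphabet (case-insensitive).
#' @return Mature miRNA sequence, RNA alphabet, 5' to 3'.
#' @examples
#' mirna_from_probe("GgcAuuCacCgcGugCcuuA")
#' @export
mirna_from_probe <- function(probe_sequence) {
  s <- toupper(probe_sequence)
  .check_rna(s, "probe_sequence")
  .rc_rna(s)
}

.check_rna <- function(s, what = "sequence") {
  if (length(s) != 1 || is.na(s) || !nzchar(s)) {
    abort(paste0(what, " must be a single non-empty string"))
  }
  if (grepl("[^ACGU]", s)) {
    abort(paste0(what, " contains non-RNA characters (alphabet is A/C/G/U)"))
  }
  invisible(s)
}

.rc_rna <- function(s) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

.comp_rna <- function(ch) chartr("ACGU", "UGCA", ch)

# target-strand strings of the canonical site types for a given miRNA:
# the 6mer is the reverse complement of miRNA nt 2-7; 7mer-m8 adds the
# complement of miRNA nt 8 on the 5' (target) side; 7mer-A1 adds an A on
# the 3' side; 8mer adds both.
.seed_site_strings <- function(mirna) {
  .check_rna(mirna, "mirna")
  if (nchar(mirna) < 8) abort("mirna must be at least 8 nt")
  six <- .rc_rna(substr(mirna, 2, 7))
  m8c <- .comp_rna(substr(mirna, 8, 8))
  c(
    "6mer" = six,
    "7mer-A1" = paste0(six, "A"),
    "7mer-m8" = paste0(m8c, six),
    "8mer" = paste0(m8c, six, "A")
  )
}

#' Scan a 3'UTR for canonical miRNA seed sites
#'
#' Finds every locus whose target sequence is the reverse complement of the
#' miRNA seed (nt 2-7) and classifies it into the canonical hierarchy:
#' `8mer` (seed match + complement of miRNA nt 8 on the 5' side + A across
#' from miRNA nt 1) > `7mer-m8` > `7mer-A1` > `6mer`. Each locus (distinct
#' 6mer start) is reported once, at its strongest type. `start` is the
#' 1-based position of the site's 5'-most target nucleotide (so a
#' 7mer-m8/8mer starts one base before its 6mer core).
#'
#' @param utr Target 3'UTR sequence (RNA).
#' @param mirna Mature miRNA sequence (RNA), length >= 8.
#' @return Tibble with `start` and `site_type` (empty when the UTR is
#'   shorter than a site or carries no match).
#' @examples
#' mir <- mirna_from_probe("GGCAUUCACCGCGUGCCUUA")
#' scan_sites("AAAGUGCCUUAAAA", mir)
#' @export
scan_sites <- function(utr, mirna) {
  .check_rna(utr, "utr")
  sites <- .seed_site_strings(mirna)
  six <- sites[["6mer"]]
  m8c <- .comp_rna(substr(mirna, 8, 8))
  if (nchar(utr) < 6) {
    return(tibble(start = integer(), site_type = character()))
  }
  hits <- gregexpr(six, utr, fixed = TRUE)[[1]]
  if (hits[1] == -1) {
    return(tibble(start = integer(), site_type = character()))
  }
  pos <- as.integer(hits)
  has_m8 <- pos > 1 & substr(utr, pos - 1, pos - 1) == m8c
  has_a1 <- pos + 6 <= nchar(utr) & substr(utr, pos + 6, pos + 6) == "A"
  type <- dplyr::case_when(
    has_m8 & has_a1 ~ "8mer",
    has_m8 ~ "7mer-m8",
    has_a1 ~ "7mer-A1",
    TRUE ~ "6mer"
  )
  tibble(
    start = ifelse(has_m8, pos - 1L, pos),
    site_type = type
  )
}

#' Predicted target set of a miRNA over a UTR collection
#'
#' @param utrs Named character vector of RNA 3'UTR sequences (a UTR set),
#'   e.g. from [generate_transcriptome()] or [read_utr_fasta()].
#' @param mirna Mature miRNA sequence (RNA).
#' @return Character vector of transcript ids with at least one canonical
#'   seed site.
#' @examples
#' mir <- mirna_from_probe("GGCAUUCACCGCGUGCCUUA")
#' predicted_target_set(c(t1 = "AAAGUGCCUUAAAA", t2 = "AAACCCAAA"), mir)
#' @export
predicted_target_set <- function(utrs, mirna) {
  if (length(utrs) == 0) return(character())
  if (is.null(names(utrs)) || any(!nzchar(names(utrs)))) {
    abort("utrs must be a named vector of sequences")
  }
  six <- .seed_site_strings(mirna)[["6mer"]]
  names(utrs)[grepl(six, utrs, fixed = TRUE)]
}

#' Overlap of a predicted target set with a differential-expression table
#'
#' Counts significantly up- and downregulated genes (`p < alpha`, sign of
#' `log2fc`) and how many of each are predicted miRNA targets, plus the
#' fraction of the predicted target set that is regulated at all.
#'
#' @param de DE tibble with columns `gene_id`, `log2fc`, `p`.
#' @param targets Character vector of predicted target gene ids.
#' @param alpha Significance threshold, in (0, 1).
#' @return One-row tibble: `n_predicted_targets`, `n_up_sig`, `n_down_sig`,
#'   `n_up_targets`, `n_down_targets`, `fraction_targets_regulated`,
#'   `n_targets_missing` (target ids absent from the DE table).
#' @examples
#' de <- tibble::tibble(
#'   gene_id = c("a", "b", "c"), log2fc = c(1, -2, 0.5),
#'   p = c(0.01, 0.001, 0.8)
#' )
#' de_overlap(de, targets = c("a", "b"))
#' @export
de_overlap <- function(de, targets, alpha = 0.05) {
  .check_de(de)
  if (alpha <= 0 || alpha >= 1) abort("alpha must be strictly inside (0, 1)")
  missing_ids <- setdiff(targets, de$gene_id)
  if (length(missing_ids)) {
    inform(paste0(
      length(missing_ids), " target id(s) absent from the DE table"
    ))
  }
  is_t <- de$gene_id %in% targets
  up <- de$p < alpha & de$log2fc > 0
  down <- de$p < alpha & de$log2fc < 0
  n_t <- length(unique(targets))
  tibble(
    n_predicted_targets = n_t,
    n_up_sig = sum(up),
    n_down_sig = sum(down),
    n_up_targets = sum(up & is_t),
    n_down_targets = sum(down & is_t),
    fraction_targets_regulated =
      if (n_t > 0) (sum(up & is_t) + sum(down & is_t)) / n_t else NA_real_,
    n_targets_missing = length(missing_ids)
  )
}

.check_de <- function(de) {
  miss <- setdiff(c("gene_id", "log2fc", "p"), names(de))
  if (length(miss)) {
    abort(paste0("DE table missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(de$gene_id)) abort("DE table gene_id values must be unique")
  if (any(de$p <= 0 | de$p > 1)) abort("DE table p values must lie in (0, 1]")
  invisible(de)
}
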