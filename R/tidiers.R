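#' Tidy and glance methods for fitted pipeline objects
#'
#' broom-style accessors: `tidy()` returns the per-observation table
#' (per-sample relative quantities, per-rank running sum, per-pair duplex
#' trace), `glance()` the one-row model summary.
#'
#' @param x A fitted perimir object.
#' @param ... Unused.
#' @name perimir_tidiers
NULL

#' @rdname perimir_tidiers
#' @method tidy perimir_ddct
#' @export
tidy.perimir_ddct <- function(x, ...) {
  dplyr::select(
    x$samples, "sample_id", "group_label", "role",
    "target", "reference", "dct", "rq"
  )
}

#' @rdname perimir_tidiers
#' @method glance perimir_ddct
#' @export
glance.perimir_ddct <- function(x, ...) {
  tibble(
    case_group = x$case_group,
    control_group = x$control_group,
    mean_dct_case = x$mean_dct_case,
    mean_dct_control = x$mean_dct_control,
    ddct = x$ddct,
    fold_change = x$fold_change,
    p_value = x$test$p_value,
    n_case = sum(x$samples$role == "case"),
    n_control = sum(x$samples$role == "control")
  )
}

#' @rdname perimir_tidiers
#' @method tidy perimir_gsea
#' @export
tidy.perimir_gsea <- function(x, ...) {
  tibble(
    rank = seq_len(x$n),
    running_sum = x$running_sum,
    hit = seq_len(x$n) %in% x$hit_ranks
  )
}

#' @rdname perimir_tidiers
#' @method glance perimir_gsea
#' @export
glance.perimir_gsea <- function(x, ...) {
  tibble(
    es = x$es, nes = x$nes, p_perm = x$p_perm, fdr = x$fdr,
    n = x$n, n_hits = x$n_hits, n_perm = x$n_perm,
    n_leading_edge = length(x$leading_edge)
  )
}

#' @rdname perimir_tidiers
#' @method tidy perimir_duplex
#' @export
tidy.perimir_duplex <- function(x, ...) {
  m <- strsplit(x$mirna, "")[[1]]
  t <- strsplit(x$target, "")[[1]]
  dplyr::mutate(
    x$pairing,
    mirna_base = m[.data$mirna_pos],
    target_base = t[.data$target_pos]
  )
}

#' @rdname perimir_tidiers
#' @method glance perimir_duplex
#' @export
glance.perimir_duplex <- function(x, ...) {
  tibble(
    mfe = x$mfe,
    n_pairs = nrow(x$pairing),
    binding_start = x$binding_start,
    mirna_length = nchar(x$mirna),
    target_length = nchar(x$target)
  )
}

#' @rdname perimir_tidiers
#' @method tidy perimir_contrast
#' @export
tidy.perimir_contrast <- function(x, ...) x$groups

#' @rdname perimir_tidiers
#' @method glance perimir_contrast
#' @export
glance.perimir_contrast <- function(x, ...) {
  tibble(
    reference_group = x$reference_group,
    n_groups = nrow(x$groups),
    kruskal_h = x$kruskal$statistic,
    kruskal_p = x$kruskal$p_value,
    min_pairwise_p = min(x$pairwise$p_value)
  )
}
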