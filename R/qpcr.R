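#' Relative quantification by the 2^-ddCt method
#'
#' Livak relative quantification with an endogenous control: per-sample
#' delta-Ct = Ct(target) - Ct(reference); delta-delta-Ct = mean delta-Ct of
#' the case group minus mean delta-Ct of the control group; fold change =
#' `2^-ddCt`. Per-sample relative quantities `2^-(dCt_i - mean dCt_control)`
#' are reported for plotting, so the control group has mean relative
#' quantity 1 on the delta-Ct scale. A Mann-Whitney test on the per-sample
#' delta-Ct values accompanies the estimate.
#'
#' @param ct Ct table tibble: `sample_id`, `group_label`, `assay`
#'   (`"target"`/`"reference"`), `ct`. Every sample must carry both assays.
#' @param case_group,control_group Group labels to contrast.
#' @return A `perimir_ddct` object; see [tidy()][tidy.perimir_ddct] for the
#'   per-sample table and [glance()][glance.perimir_ddct] for the one-row
#'   summary.
#' @examples
#' ct <- generate_ct_table(scenario("cohort1_7d"), "mir124")
#' res <- ddct_fold_change(ct, "TBI", "sham")
#' glance(res)
#' @export
ddct_fold_change <- function(ct, case_group, control_group) {
  miss <- setdiff(c("sample_id", "group_label", "assay", "ct"), names(ct))
  if (length(miss)) {
    abort(paste0("Ct table missing column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- setdiff(c(case_group, control_group), ct$group_label)
  if (length(bad)) {
    abort(paste0("unknown group(s): ", paste(bad, collapse = ", ")))
  }
  wide <- ct |>
    dplyr::filter(.data$group_label %in% c(case_group, control_group)) |>
    tidyr::pivot_wider(
      id_cols = c("sample_id", "group_label"),
      names_from = "assay", values_from = "ct"
    )
  if (!all(c("target", "reference") %in% names(wide)) ||
    anyNA(wide$target) || anyNA(wide$reference)) {
    abort("every sample needs both a 'target' and a 'reference' Ct")
  }
  wide <- dplyr::mutate(wide, dct = .data$target - .data$reference)

  mean_case <- mean(wide$dct[wide$group_label == case_group])
  mean_control <- mean(wide$dct[wide$group_label == control_group])
  ddct <- mean_case - mean_control
  wide <- dplyr::mutate(
    wide,
    rq = 2^-(.data$dct - mean_control),
    role = ifelse(.data$group_label == case_group, "case", "control")
  )
  test <- mann_whitney(
    wide$dct[wide$role == "case"],
    wide$dct[wide$role == "control"]
  )

  structure(
    list(
      samples = wide,
      case_group = case_group,
      control_group = control_group,
      mean_dct_case = mean_case,
      mean_dct_control = mean_control,
      ddct = ddct,
      fold_change = 2^-ddct,
      test = test
    ),
    class = "perimir_ddct"
  )
}

#' @export
print.perimir_ddct <- function(x, ...) {
  cat("<perimir_ddct> ", x$case_group, " vs ", x$control_group,
    ": ddCt = ", signif(x$ddct, 4),
    ", fold change = ", signif(x$fold_change, 4),
    " (Mann-Whitney p = ", signif(x$test$p_value, 3), ")\n",
    sep = ""
  )
  invisible(x)
}

#' Grubbs test for a single outlier
#'
#' Two-sided single-outlier screen: `G = max |x_i - mean| / s` (sample
#' standard deviation) compared against the t-based critical value at level
#' `alpha`. Single pass, no iterative removal — matching the convention of
#' the common online calculators used for qPCR quality control.
#'
#' @param values Numeric vector, length >= 3, non-constant.
#' @param alpha Two-sided significance level.
#' @return One-row tibble: `is_outlier`, `index`, `value`, `G`,
#'   `G_critical`, `n`, `alpha`.
#' @examples
#' grubbs_test(c(1, 1, 1, 10))
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3) abort("Grubbs test needs at least 3 values")
  s <- sd(values)
  if (s == 0) abort("Grubbs test undefined for zero-variance data")
  dev <- abs(values - mean(values))
  g <- max(dev) / s
  tcrit <- qt(1 - alpha / (2 * n), df = n - 2)
  gcrit <- ((n - 1) / sqrt(n)) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  idx <- which.max(dev)
  tibble(
    is_outlier = g > gcrit,
    index = idx,
    value = values[idx],
    G = g,
    G_critical = gcrit,
    n = n,
    alpha = alpha
  )
}

#' Correlate miRNA levels with a target's expression
#'
#' Spearman rank correlation of paired relative-expression values,
#' delegating to [rank_correlation()].
#'
#' @param mir_values,target_values Paired numeric vectors (same samples).
#' @return One-row tibble with `r`, `p_value`, `method`, `n`, `exact`.
#' @examples
#' correlate_mir_target(c(3, 2, 1, 0.5), c(1, 2, 3, 4))
#' @export
correlate_mir_target <- function(mir_values, target_values) {
  rank_correlation(mir_values, target_values)
}
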