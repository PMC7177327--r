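#' Generate a synthetic qPCR Ct table
#'
#' Emulates a relative-quantification experiment with one target and one
#' endogenous reference assay per sample. Control-group delta-Ct
#' (target minus reference) is centred on `baseline_dct`; the case group is
#' centred on `baseline_dct - log2(planted_fc)`, so the expected
#' delta-delta-Ct is `-log2(planted_fc)` and the expected recovered fold
#' change equals the planted one. Gaussian noise with total delta-Ct
#' standard deviation `ct_sd` is split evenly between the two assays.
#'
#' @param scenario A [scenario()] with a `qpcr` block (one or more named
#'   assays).
#' @param assay Name of the assay block to simulate (defaults to the first).
#' @param seed Optional integer overriding the scenario-derived seed, used
#'   for replicate draws.
#' @return A Ct table tibble: `sample_id`, `group_label`,
#'   `assay` (`"target"`/`"reference"`), `ct`.
#' @examples
#' ct <- generate_ct_table(scenario("cohort1_7d"), assay = "mir124")
#' dplyr::count(ct, group_label, assay)
#' @export
generate_ct_table <- function(scenario, assay = NULL, seed = NULL) {
  stopifnot(inherits(scenario, "perimir_scenario"))
  if (is.null(scenario$qpcr)) abort("scenario has no qpcr block")
  assay <- assay %||% names(scenario$qpcr)[1]
  q <- scenario$qpcr[[assay]]
  if (is.null(q)) abort(paste0("unknown qpcr assay '", assay, "'"))
  if (q$planted_fc <= 0) abort("planted_fc must be > 0")
  seed <- seed %||% .derive_seed(scenario$rng_seed, match(assay, names(scenario$qpcr)))

  .local_seed(seed, {
    n <- q$n_case + q$n_control
    group <- c(rep(q$case_label, q$n_case), rep(q$control_label, q$n_control))
    id <- paste0(group, "_", c(seq_len(q$n_case), seq_len(q$n_control)))
    dct_center <- q$baseline_dct -
      ifelse(group == q$case_label, log2(q$planted_fc), 0)
    sd_each <- q$ct_sd / sqrt(2) # so that sd(dct) == ct_sd
    ref_ct <- q$reference_ct_mean + rnorm(n, 0, sd_each)
    tgt_ct <- q$reference_ct_mean + dct_center + rnorm(n, 0, sd_each)
    tibble(
      sample_id = rep(id, 2),
      group_label = rep(group, 2),
      assay = rep(c("target", "reference"), each = n),
      ct = c(tgt_ct, ref_ct)
    )
  })
}

#' Simulate paired expression values with a planted rank correlation
#'
#' Draws `n` pairs from a Gaussian copula whose Pearson parameter is chosen
#' so that the population Spearman correlation equals `rho` (the classic
#' conversion `r = 2 sin(pi * rho / 6)`), then maps both margins through
#' `exp()` so the values look like positive relative-expression levels
#' (any strictly monotone margin leaves rank correlation untouched).
#'
#' @param n Number of pairs.
#' @param rho Planted Spearman correlation, in (-1, 1).
#' @param seed Integer seed.
#' @return Tibble with columns `mir` and `target`.
#' @examples
#' simulate_correlated_pairs(10, -0.647, seed = 1)
#' @export
simulate_correlated_pairs <- function(n, rho, seed) {
  if (abs(rho) >= 1) abort("rho must be in (-1, 1)")
  if (n < 3) abort("n must be >= 3")
  r <- 2 * sin(pi * rho / 6)
  .local_seed(seed, {
    z1 <- rnorm(n)
    z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
    tibble(mir = exp(z1), target = exp(z2))
  })
}
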