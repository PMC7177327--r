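#' Simulation scenarios
#'
#' A scenario bundles every parameter the synthetic-data generators need:
#' section-image geometry, experimental groups with planted group effects,
#' the layer-dependent signal structure, qPCR assay definitions with planted
#' fold-changes, and the transcriptome/differential-expression structure.
#' Packaged scenarios encode the effect sizes of the study the package
#' emulates; [scenario()] loads one by name, [read_scenario()] reads any
#' YAML scenario file.
#'
#' @param name Name of a packaged scenario. One of
#'   `"cohort1_7d"`, `"cohort1_3mo"`, `"cohort2_layers"`, `"cohort3"`,
#'   `"human_patch"`, `"null"`.
#' @return A `perimir_scenario` object (a validated named list).
#' @examples
#' sc <- scenario("cohort1_7d")
#' sc$qpcr$mir124$planted_fc
#' @export
scenario <- function(name) {
  path <- system.file("extdata", "scenarios", paste0(name, ".yaml"),
    package = "perimir"
  )
  if (!nzchar(path)) {
    abort(paste0(
      "unknown packaged scenario '", name, "'; available: ",
      paste(packaged_scenarios(), collapse = ", ")
    ))
  }
  read_scenario(path)
}

#' @rdname scenario
#' @export
packaged_scenarios <- function() {
  dir <- system.file("extdata", "scenarios", package = "perimir")
  sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
}

#' @rdname scenario
#' @param path Path to a YAML scenario file.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) abort(paste0("scenario file not found: ", path))
  new_scenario(yaml::read_yaml(path))
}

#' @rdname scenario
#' @param x A named list of scenario fields (as parsed from YAML).
#' @export
new_scenario <- function(x) {
  if (is.null(x$name)) abort("scenario needs a 'name'")
  if (is.null(x$rng_seed)) abort("scenario needs an integer 'rng_seed'")
  x$rng_seed <- as.integer(x$rng_seed)

  if (!is.null(x$image_geom)) {
    g <- x$image_geom
    need <- c("width_um", "depth_um", "microns_per_pixel", "background_gray")
    miss <- setdiff(need, names(g))
    if (length(miss)) {
      abort(paste0("image_geom missing field(s): ", paste(miss, collapse = ", ")))
    }
    if (g$background_gray <= 0 || g$background_gray > 1) {
      abort("background_gray must be in (0, 1]")
    }
    x$image_geom$pixel_noise_sd <- g$pixel_noise_sd %||% 0.01
    x$layer_effect <- x$layer_effect %||% 1
    x$signal_mean <- x$signal_mean %||% 0.25
    x$signal_noise_sd <- x$signal_noise_sd %||% 0.2
    x$cell_radius_um <- x$cell_radius_um %||% 8
    x$n_cells_per_subject <- x$n_cells_per_subject %||% 100
    x$gray_threshold <- x$gray_threshold %||%
      (g$background_gray * (1 - x$signal_mean * min(unlist(x$group_scale %||% 1)) / 2))
    if (x$layer_effect <= 0) abort("layer_effect must be > 0")
    if (any(unlist(x$group_scale) <= 0)) abort("group_scale entries must be > 0")
    if (is.null(x$groups)) abort("image scenarios need 'groups'")
    labs <- vapply(x$groups, `[[`, "", "group_label")
    if (anyDuplicated(labs)) abort("duplicate group_label in groups")
    bad <- setdiff(labs, names(x$group_scale))
    if (length(bad)) {
      abort(paste0("group_scale missing group(s): ", paste(bad, collapse = ", ")))
    }
  }

  if (!is.null(x$qpcr)) {
    # single-assay blocks are promoted to a one-element named list
    if (!is.null(x$qpcr$planted_fc)) x$qpcr <- list(assay = x$qpcr)
    for (nm in names(x$qpcr)) {
      q <- x$qpcr[[nm]]
      if (is.null(q$planted_fc) || q$planted_fc <= 0) {
        abort(paste0("qpcr assay '", nm, "': planted_fc must be > 0"))
      }
      if (is.null(q$ct_sd) || q$ct_sd <= 0) {
        abort(paste0("qpcr assay '", nm, "': ct_sd must be > 0"))
      }
      x$qpcr[[nm]]$n_case <- q$n_case %||% 6
      x$qpcr[[nm]]$n_control <- q$n_control %||% 6
      x$qpcr[[nm]]$reference_ct_mean <- q$reference_ct_mean %||% 20
      x$qpcr[[nm]]$baseline_dct <- q$baseline_dct %||% 3
      x$qpcr[[nm]]$case_label <- q$case_label %||% "TBI"
      x$qpcr[[nm]]$control_label <- q$control_label %||% "sham"
    }
  }

  if (!is.null(x$transcriptome)) {
    tr <- x$transcriptome
    need <- c(
      "n_genes", "n_target_genes", "n_up_sig", "n_down_sig",
      "n_up_targets", "n_down_targets"
    )
    miss <- setdiff(need, names(tr))
    if (length(miss)) {
      abort(paste0("transcriptome missing field(s): ", paste(miss, collapse = ", ")))
    }
    x$transcriptome$utr_len <- tr$utr_len %||% 300
    if (tr$n_target_genes > tr$n_genes) {
      abort("n_target_genes must be <= n_genes")
    }
    if (tr$n_up_targets > min(tr$n_up_sig, tr$n_target_genes)) {
      abort("n_up_targets exceeds min(n_up_sig, n_target_genes)")
    }
    if (tr$n_down_targets > tr$n_target_genes - tr$n_up_targets ||
      tr$n_down_targets > tr$n_down_sig) {
      abort("n_down_targets infeasible")
    }
    if (tr$n_up_sig + tr$n_down_sig - tr$n_up_targets - tr$n_down_targets >
      tr$n_genes - tr$n_target_genes) {
      abort("not enough non-target genes for the requested significant counts")
    }
  }

  if (!is.null(x$correlation)) {
    rho <- x$correlation$planted_rho
    if (is.null(rho) || abs(rho) >= 1) abort("correlation$planted_rho must be in (-1, 1)")
    x$correlation$n_pairs <- x$correlation$n_pairs %||% 24
  }

  structure(x, class = "perimir_scenario")
}

#' @export
print.perimir_scenario <- function(x, ...) {
  cat("<perimir_scenario> ", x$name, " (seed ", x$rng_seed, ")\n", sep = "")
  stages <- c(
    if (!is.null(x$image_geom)) "ish",
    if (!is.null(x$qpcr)) paste0("qpcr[", paste(names(x$qpcr), collapse = ","), "]"),
    if (!is.null(x$correlation)) "correlation",
    if (!is.null(x$transcriptome)) "transcriptome"
  )
  cat("  stages:", paste(stages, collapse = ", "), "\n")
  invisible(x)
}

# total subjects and group lookup for a subject index (1-based, global)
.subject_group <- function(scenario, subject_index) {
  n <- vapply(scenario$groups, function(g) as.integer(g$n_subjects), 1L)
  total <- sum(n)
  if (subject_index < 1 || subject_index > total) {
    abort(paste0("subject_index must be in 1..", total))
  }
  grp <- rep(vapply(scenario$groups, `[[`, "", "group_label"), n)
  grp[subject_index]
}

.n_subjects <- function(scenario) {
  sum(vapply(scenario$groups, function(g) as.integer(g$n_subjects), 1L))
}
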