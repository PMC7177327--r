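#' Run the ISH quantification stage over every subject of a scenario
#'
#' Generates one synthetic section per subject, detects cells with the
#' scenario's detection threshold, computes background-normalized
#' intensities and assigns perilesional sectors using a 2x2 layout that
#' spans the whole scene.
#'
#' @param scenario A [scenario()] with an `image_geom` block.
#' @return List with `cells` (tibble over all subjects, with `group` and
#'   `subject` columns), `layout` (the [sector_layout()] used) and
#'   `scenes` (list of `perimir_scene`).
#' @examples
#' stage <- run_ish_stage(scenario("null"))
#' dplyr::count(stage$cells, group, sector)
#' @export
run_ish_stage <- function(scenario) {
  stopifnot(inherits(scenario, "perimir_scenario"))
  g <- scenario$image_geom
  if (is.null(g)) abort("scenario has no image_geom block")
  layout <- sector_layout(
    origin_x_um = 0, width_um = g$width_um,
    depth_min_um = 0, depth_max_um = g$depth_um
  )
  scenes <- purrr::map(seq_len(.n_subjects(scenario)), function(s) {
    generate_ish_scene(scenario, s)
  })
  cells <- purrr::map_dfr(scenes, function(scene) {
    detect_cells(
      scene$image, scene$microns_per_pixel, scenario$gray_threshold
    ) |>
      assign_sectors(layout) |>
      dplyr::mutate(group = scene$group, subject = scene$subject_index)
  })
  list(cells = cells, layout = layout, scenes = scenes)
}

#' Replicate-level parameter recovery for the qPCR stage
#'
#' Draws `n_rep` independent Ct tables from a scenario's assay and runs
#' [ddct_fold_change()] on each; used to study how well the planted fold
#' change is recovered under the scenario's Ct noise.
#'
#' @param scenario A [scenario()] with a `qpcr` block.
#' @param assay Assay name within the block.
#' @param n_rep Number of replicate experiments.
#' @param seed Integer base seed; replicate `r` uses a sub-seed derived
#'   from it.
#' @return Tibble with `rep`, `ddct`, `fold_change`, `p_value`.
#' @examples
#' reps <- replicate_ddct(scenario("cohort1_7d"), "mir124", n_rep = 20, seed = 1)
#' median(reps$fold_change)
#' @export
replicate_ddct <- function(scenario, assay = NULL, n_rep = 200, seed = 1) {
  assay <- assay %||% names(scenario$qpcr)[1]
  q <- scenario$qpcr[[assay]]
  if (is.null(q)) abort(paste0("unknown qpcr assay '", assay, "'"))
  purrr::map_dfr(seq_len(n_rep), function(r) {
    ct <- generate_ct_table(scenario, assay, seed = .derive_seed(seed, r))
    res <- ddct_fold_change(ct, q$case_label, q$control_label)
    tibble(
      rep = r, ddct = res$ddct, fold_change = res$fold_change,
      p_value = res$test$p_value
    )
  })
}

#' Replicate-level recovery of a planted rank correlation
#'
#' @param scenario A [scenario()] with a `correlation` block.
#' @param n_rep Number of replicates.
#' @param seed Integer base seed.
#' @return Tibble with `rep`, `r`, `p_value`.
#' @export
replicate_correlation <- function(scenario, n_rep = 500, seed = 1) {
  cc <- scenario$correlation
  if (is.null(cc)) abort("scenario has no correlation block")
  purrr::map_dfr(seq_len(n_rep), function(r) {
    pairs <- simulate_correlated_pairs(
      cc$n_pairs, cc$planted_rho,
      seed = .derive_seed(seed, r)
    )
    res <- correlate_mir_target(pairs$mir, pairs$target)
    tibble(rep = r, r = res$r, p_value = res$p_value)
  })
}

#' Run a scenario end-to-end and write all artifacts
#'
#' Orchestrates every stage a scenario configures: synthetic section
#' images with cell detection, sector assignment and group contrasts;
#' Ct-table generation with 2^-ddCt quantification and Grubbs screening;
#' correlated miRNA/target pairs with rank correlation; transcriptome
#' generation with seed-site scanning, DE overlap, preranked enrichment
#' and duplex MFE of the strongest-scoring targets. All intermediate
#' artifacts are written under `out_dir` in plain formats (CSV, FASTA,
#' TIFF/PNG, JSON) and a self-contained JSON report maps every headline
#' estimate to its planted value.
#'
#' @param config A scenario object, packaged scenario name, or path to a
#'   scenario YAML file.
#' @param out_dir Output directory (created if needed).
#' @param n_perm Permutations for the enrichment stage.
#' @return The report, invisibly (also written to `report.json`).
#' @export
run_scenario <- function(config, out_dir, n_perm = 1000) {
  sc <- if (inherits(config, "perimir_scenario")) {
    config
  } else if (file.exists(config)) {
    read_scenario(config)
  } else {
    scenario(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    inform(paste0("[", sc$name, "] ", msg))
  }
  outputs <- list()
  headline <- list()
  add_headline <- function(quantity, planted, estimated, tolerance, source) {
    headline[[length(headline) + 1]] <<- tibble(
      quantity = quantity, planted = planted, estimated = estimated,
      tolerance = tolerance,
      pass = abs(estimated - planted) <= tolerance,
      source = source
    )
  }
  mirna <- mirna_from_probe(.default_probe)

  if (!is.null(sc$image_geom)) {
    say("ISH stage: generating ", .n_subjects(sc), " scenes")
    ish_dir <- file.path(out_dir, "ish")
    dir.create(ish_dir, showWarnings = FALSE)
    stage <- run_ish_stage(sc)
    for (scene in stage$scenes) {
      stem <- file.path(
        ish_dir, paste0("scene_", scene$group, "_", scene$subject_index)
      )
      write_scene_tiff(scene$image, paste0(stem, ".tiff"))
      write_scene_png(scene$image, paste0(stem, ".png"))
    }
    truth <- purrr::map_dfr(stage$scenes, function(s) {
      dplyr::mutate(s$truth, group = s$group, subject = s$subject_index)
    })
    readr::write_csv(truth, file.path(ish_dir, "truth.csv"))
    readr::write_csv(
      dplyr::select(stage$cells, -dplyr::any_of("intensities")),
      file.path(ish_dir, "cells.csv")
    )
    sectors <- stage$cells |>
      dplyr::group_by(.data$group) |>
      dplyr::group_modify(function(d, key) {
        dplyr::select(sector_summary(d, stage$layout), -"intensities")
      }) |>
      dplyr::ungroup()
    readr::write_csv(sectors, file.path(ish_dir, "sectors.csv"))
    outputs$ish <- ish_dir

    grp_labels <- vapply(sc$groups, `[[`, "", "group_label")
    if (all(c("inside", "outside") %in% grp_labels)) {
      area <- sc$image_geom$width_um * sc$image_geom$depth_um / 1e6
      regions <- compare_regions(
        dplyr::filter(stage$cells, .data$group == "inside"),
        dplyr::filter(stage$cells, .data$group == "outside"),
        area, area
      )
      jsonlite::write_json(
        list(
          summary = dplyr::select(regions$summary, -"intensities"),
          density_ratio = regions$density_ratio,
          test = regions$test
        ),
        file.path(ish_dir, "regions.json"),
        auto_unbox = TRUE, digits = NA
      )
      say(
        "inside-vs-outside intensity p = ",
        signif(regions$test$p_value, 3)
      )
    } else {
      ref <- if ("naive" %in% grp_labels) "naive" else grp_labels[1]
      contrast <- group_contrast(stage$cells, ref)
      jsonlite::write_json(
        list(
          groups = contrast$groups, kruskal = contrast$kruskal,
          pairwise = contrast$pairwise, reference = ref
        ),
        file.path(ish_dir, "contrasts.json"),
        auto_unbox = TRUE, digits = NA
      )
      for (k in seq_len(nrow(contrast$groups))) {
        row <- contrast$groups[k, ]
        add_headline(
          paste0("deep_superficial_fc_", row$group), sc$layer_effect,
          row$deep_superficial_fc, 0.1, "ish/contrasts.json"
        )
        add_headline(
          paste0("percent_of_", ref, "_", row$group),
          100 * sc$group_scale[[row$group]] / sc$group_scale[[ref]],
          row$percent_of_reference, 5, "ish/contrasts.json"
        )
      }
    }
  }

  if (!is.null(sc$qpcr)) {
    qdir <- file.path(out_dir, "qpcr")
    dir.create(qdir, showWarnings = FALSE)
    for (assay in names(sc$qpcr)) {
      q <- sc$qpcr[[assay]]
      ct <- generate_ct_table(sc, assay)
      readr::write_csv(ct, file.path(qdir, paste0("ct_", assay, ".csv")))
      res <- ddct_fold_change(ct, q$case_label, q$control_label)
      readr::write_csv(tidy(res), file.path(qdir, paste0("rq_", assay, ".csv")))
      screen <- grubbs_test(res$samples$dct)
      jsonlite::write_json(
        list(ddct = glance(res), grubbs = screen),
        file.path(qdir, paste0("ddct_", assay, ".json")),
        auto_unbox = TRUE, digits = NA
      )
      say(
        "qPCR ", assay, ": planted FC ", q$planted_fc,
        ", estimated ", signif(res$fold_change, 3)
      )
      add_headline(
        paste0("fold_change_", assay), q$planted_fc, res$fold_change,
        max(0.05, 0.15 * q$planted_fc), paste0("qpcr/ddct_", assay, ".json")
      )
    }
    outputs$qpcr <- qdir
  }

  if (!is.null(sc$correlation)) {
    pairs <- simulate_correlated_pairs(
      sc$correlation$n_pairs, sc$correlation$planted_rho,
      seed = .derive_seed(sc$rng_seed, 555L)
    )
    res <- correlate_mir_target(pairs$mir, pairs$target)
    readr::write_csv(pairs, file.path(out_dir, "correlation_pairs.csv"))
    jsonlite::write_json(res, file.path(out_dir, "correlation.json"),
      auto_unbox = TRUE, digits = NA
    )
    outputs$correlation <- file.path(out_dir, "correlation.json")
    say("correlation: r = ", signif(res$r, 3))
  }

  if (!is.null(sc$transcriptome)) {
    tdir <- file.path(out_dir, "targets")
    dir.create(tdir, showWarnings = FALSE)
    say("transcriptome stage: ", sc$transcriptome$n_genes, " genes")
    tx <- generate_transcriptome(sc)
    write_utr_fasta(tx$utrs, file.path(tdir, "utrs.fasta"))
    readr::write_csv(tx$de, file.path(tdir, "de.csv"))
    writeLines(tx$target_ids, file.path(tdir, "target_ids.txt"))

    targets <- predicted_target_set(tx$utrs, mirna)
    sites <- purrr::map_dfr(targets, function(id) {
      dplyr::mutate(scan_sites(tx$utrs[[id]], mirna), transcript_id = id, .before = 1)
    })
    readr::write_csv(sites, file.path(tdir, "sites.csv"))
    overlap <- de_overlap(tx$de, targets, alpha = 0.05)
    jsonlite::write_json(overlap, file.path(tdir, "overlap.json"),
      auto_unbox = TRUE, digits = NA
    )
    add_headline(
      "n_predicted_targets", sc$transcriptome$n_target_genes,
      overlap$n_predicted_targets, 0, "targets/overlap.json"
    )
    add_headline(
      "n_up_targets", sc$transcriptome$n_up_targets,
      overlap$n_up_targets, 0, "targets/overlap.json"
    )
    add_headline(
      "n_down_targets", sc$transcriptome$n_down_targets,
      overlap$n_down_targets, 0, "targets/overlap.json"
    )

    gdir <- file.path(out_dir, "gsea")
    dir.create(gdir, showWarnings = FALSE)
    ranked <- rank_genes(tx$de)
    gsea <- gsea_significance(ranked, targets,
      n_perm = n_perm,
      seed = .derive_seed(sc$rng_seed, 777L)
    )
    readr::write_csv(tidy(gsea), file.path(gdir, "running_sum.csv"))
    jsonlite::write_json(
      c(as.list(glance(gsea)), list(leading_edge = gsea$leading_edge)),
      file.path(gdir, "gsea.json"),
      auto_unbox = TRUE, digits = NA
    )
    say(
      "GSEA: ES = ", signif(gsea$es, 3), ", p = ", signif(gsea$p_perm, 3)
    )

    ddir <- file.path(out_dir, "duplex")
    dir.create(ddir, showWarnings = FALSE)
    # duplex the top 10 target sites from each end of the ranked list
    ranked_targets <- ranked$gene_id[ranked$gene_id %in% targets]
    pick <- unique(c(head(ranked_targets, 10), tail(ranked_targets, 10)))
    regions <- setNames(
      purrr::map_chr(pick, function(id) {
        s <- scan_sites(tx$utrs[[id]], mirna)
        extract_site_region(tx$utrs[[id]], s$start[1])
      }),
      pick
    )
    dup <- duplex_table(mirna, regions)
    dup$direction <- ifelse(dup$id %in% head(ranked_targets, 10), "up", "down")
    readr::write_csv(dup, file.path(ddir, "duplex.csv"))
    outputs$targets <- tdir
    outputs$gsea <- gdir
    outputs$duplex <- ddir
  }

  report <- list(
    scenario = sc$name,
    seed = sc$rng_seed,
    tool_version = as.character(packageVersion("perimir")),
    outputs = outputs,
    headline = if (length(headline)) dplyr::bind_rows(headline) else NULL,
    log = log_lines
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(report)
}
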