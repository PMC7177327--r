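# Independent oracles used across the test files. These deliberately use
# naive, direct computations (explicit running sums, exhaustive
# enumeration) so they share no code path with the implementation.

# direct running-sum enrichment score: walk the list rank by rank
oracle_es <- function(scores, is_hit, weight = 1) {
  n <- length(scores)
  w <- abs(scores[is_hit])^weight
  if (sum(w) == 0) w <- rep(1, sum(is_hit))
  run <- 0
  best <- 0
  wi <- 0
  for (k in seq_len(n)) {
    if (is_hit[k]) {
      wi <- wi + 1
      run <- run + w[wi] / sum(w)
    } else {
      run <- run - 1 / (n - sum(is_hit))
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# exhaustive minimum-free-energy: enumerate every strictly monotone set of
# legal base pairs (miRNA ascending, target descending) recursively and
# score it with the same energy accessors the model exposes
oracle_duplex_mfe <- function(mirna, target, model, max_loop = 10) {
  m <- strsplit(mirna, "")[[1]]
  t <- strsplit(target, "")[[1]]
  legal <- c("AU", "UA", "CG", "GC", "GU", "UG")
  n <- length(m)
  L <- length(t)
  best <- 0

  score_pairs <- function(pairs) {
    e <- model$duplex_init
    for (k in seq_len(nrow(pairs))[-1]) {
      a <- pairs[k, 1] - pairs[k - 1, 1] - 1
      b <- pairs[k - 1, 2] - pairs[k, 2] - 1
      if (a > max_loop || b > max_loop) return(Inf)
      e <- e + if (a == 0 && b == 0) {
        model$stacks[[paste0(
          m[pairs[k - 1, 1]], m[pairs[k, 1]], "/",
          t[pairs[k - 1, 2]], t[pairs[k, 2]]
        )]]
      } else if (a == 0 || b == 0) {
        model$bulge_open + model$bulge_extend * (a + b - 1)
      } else {
        model$internal_open + model$internal_extend * (a + b - 2)
      }
    }
    e
  }

  grow <- function(pairs) {
    if (nrow(pairs) > 0) {
      e <- score_pairs(pairs)
      if (e < best) best <<- e
    }
    i0 <- if (nrow(pairs)) pairs[nrow(pairs), 1] else 0
    j0 <- if (nrow(pairs)) pairs[nrow(pairs), 2] else L + 1
    for (i in seq_len(n)) {
      if (i <= i0) next
      for (j in seq_len(L)) {
        if (j >= j0) next
        if (!(paste0(m[i], t[j]) %in% legal)) next
        grow(rbind(pairs, c(i, j)))
      }
    }
  }
  grow(matrix(numeric(0), ncol = 2))
  best
}

# small single-purpose scenarios built in code
toy_transcriptome_scenario <- function(seed = 42) {
  new_scenario(list(
    name = "toy_tx", rng_seed = seed,
    transcriptome = list(
      n_genes = 10, n_target_genes = 4, n_up_sig = 3, n_down_sig = 2,
      n_up_targets = 2, n_down_targets = 1, utr_len = 60
    )
  ))
}

toy_scene_scenario <- function(seed = 7, n_cells = 20, layer_effect = 1,
                               scales = list(naive = 1.0)) {
  new_scenario(list(
    name = "toy_scene", rng_seed = seed,
    image_geom = list(
      width_um = 500, depth_um = 500, microns_per_pixel = 2,
      background_gray = 0.9, pixel_noise_sd = 0.01
    ),
    groups = lapply(names(scales), function(g) {
      list(group_label = g, n_subjects = 1)
    }),
    group_scale = scales,
    layer_effect = layer_effect,
    signal_mean = 0.3, signal_noise_sd = 0.15,
    n_cells_per_subject = n_cells, cell_radius_um = 8,
    gray_threshold = 0.8
  ))
}

test_mirna <- function() mirna_from_probe("GGCAUUCACCGCGUGCCUUA")
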