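#' Generate a synthetic chromogenic ISH section image
#'
#' Emulates a grayscale photomicrograph of an in situ hybridization
#' preparation: a light background with darker, disk-shaped stained cells.
#' Cells are placed by rejection sampling so that no two overlap, and each
#' cell's planted signal depends on its cortical layer (deep cells carry
#' `layer_effect` times the superficial mean) and on the experimental group
#' of the subject (`group_scale`). The per-cell normalized signal `s` is
#' drawn as a mean-one lognormal around its planted mean, and the painted
#' gray value is `background_gray * (1 - s)` — stained cells are darker
#' than background, so the downstream normalized intensity
#' `(bg - cell)/bg` recovers `s`.
#'
#' @param scenario A [scenario()] with an `image_geom` block.
#' @param subject_index Global subject index (1-based, across groups in the
#'   order they are listed); each `(scenario, subject)` pair has its own
#'   seeded stream, so subjects are independently reproducible.
#' @return A `perimir_scene`: list with `image` (matrix in `[0,1]`, rows =
#'   depth, cols = lateral position), `microns_per_pixel`,
#'   `lesion_edge_x_um`, `group`, `subject_index`, and `truth`, a tibble of
#'   planted cells (`x_um`, `depth_um`, `radius_um`, `planted_signal`,
#'   `planted_gray`, `layer`).
#' @examples
#' sc <- scenario("null")
#' scene <- generate_ish_scene(sc, 1)
#' nrow(scene$truth)
#' @export
generate_ish_scene <- function(scenario, subject_index) {
  stopifnot(inherits(scenario, "perimir_scenario"))
  if (is.null(scenario$image_geom)) abort("scenario has no image_geom block")
  group <- .subject_group(scenario, subject_index)
  g <- scenario$image_geom
  mpp <- g$microns_per_pixel
  w_px <- round(g$width_um / mpp)
  h_px <- round(g$depth_um / mpp)
  n_cells <- scenario$n_cells_per_subject
  r_um <- scenario$cell_radius_um
  scale <- scenario$group_scale[[group]]

  .local_seed(.derive_seed(scenario$rng_seed, subject_index), {
    centers <- .place_cells(
      n_cells, g$width_um, g$depth_um, r_um,
      min_sep = 2 * r_um + 2 * mpp
    )
    layer <- ifelse(centers$depth_um >= g$depth_um / 2, "deep", "superficial")
    mean_s <- scenario$signal_mean * scale *
      ifelse(layer == "deep", scenario$layer_effect, 1)
    # optional per-group dispersion (used by the patchy-loss scenario)
    sdl <- scenario$group_noise_sd[[group]] %||% scenario$signal_noise_sd
    s <- mean_s * rlnorm(n_cells, meanlog = -sdl^2 / 2, sdlog = sdl)
    # guard: keep gray strictly positive (vanishingly rare at defaults)
    while (any(bad <- s >= 0.95)) {
      s[bad] <- mean_s[bad] * rlnorm(sum(bad), -sdl^2 / 2, sdl)
    }
    gray <- g$background_gray * (1 - s)

    img <- matrix(g$background_gray, nrow = h_px, ncol = w_px)
    px_x <- (seq_len(w_px) - 0.5) * mpp
    px_y <- (seq_len(h_px) - 0.5) * mpp
    for (k in seq_len(n_cells)) {
      jj <- which(abs(px_x - centers$x_um[k]) <= r_um)
      ii <- which(abs(px_y - centers$depth_um[k]) <= r_um)
      d2 <- outer(
        (px_y[ii] - centers$depth_um[k])^2,
        (px_x[jj] - centers$x_um[k])^2, `+`
      )
      img[ii, jj][d2 <= r_um^2] <- gray[k]
    }
    img <- img + rnorm(length(img), 0, g$pixel_noise_sd)
    img <- pmin(pmax(img, 0), 1)

    structure(
      list(
        image = img,
        microns_per_pixel = mpp,
        lesion_edge_x_um = 0,
        group = group,
        subject_index = subject_index,
        truth = tibble(
          cell = seq_len(n_cells),
          x_um = centers$x_um,
          depth_um = centers$depth_um,
          radius_um = r_um,
          planted_signal = s,
          planted_gray = gray,
          layer = layer
        )
      ),
      class = "perimir_scene"
    )
  })
}

# uniform non-overlapping placement; errors out when geometry is too tight
.place_cells <- function(n, width_um, depth_um, r_um, min_sep) {
  if (width_um < 2 * r_um || depth_um < 2 * r_um) {
    abort("image geometry smaller than a single cell")
  }
  xs <- numeric(n)
  ys <- numeric(n)
  placed <- 0L
  tries <- 0L
  max_tries <- 400L * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort(paste0(
        "cell placement failure: could not place ", n,
        " non-overlapping cells of radius ", r_um, " um in ",
        width_um, " x ", depth_um, " um"
      ))
    }
    x <- runif(1, r_um, width_um - r_um)
    y <- runif(1, r_um, depth_um - r_um)
    if (placed > 0L) {
      i <- seq_len(placed)
      if (any((xs[i] - x)^2 + (ys[i] - y)^2 < min_sep^2)) next
    }
    placed <- placed + 1L
    xs[placed] <- x
    ys[placed] <- y
  }
  list(x_um = xs, depth_um = ys)
}

#' @export
print.perimir_scene <- function(x, ...) {
  cat("<perimir_scene> group ", x$group, ", subject ", x$subject_index,
    ": ", nrow(x$image), "x", ncol(x$image), " px (",
    x$microns_per_pixel, " um/px), ", nrow(x$truth), " planted cells\n",
    sep = ""
  )
  invisible(x)
}
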