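#' Background-normalized staining intensity
#'
#' The per-cell intensity of chromogenic staining:
#' `(background - cell) / background` on grayscale values, so a cell darker
#' than background scores positive and an unstained region scores 0.
#' Values below 0 (cell lighter than background) are legal and should be
#' flagged downstream rather than clamped. Because the measure is a
#' relative contrast against a background taken from the same image, it is
#' invariant to global linear rescaling of the image.
#'
#' @param cell_mean_gray Mean gray value(s) of the cell ROI, in `[0, 1]`.
#' @param background_mean_gray Mean gray of the background ROI, > 0.
#' @return Numeric vector of normalized intensities.
#' @examples
#' normalized_intensity(0.4, 0.8)
#' @export
normalized_intensity <- function(cell_mean_gray, background_mean_gray) {
  if (any(background_mean_gray <= 0)) {
    abort("background_mean_gray must be > 0 (normalized intensity undefined)")
  }
  (background_mean_gray - cell_mean_gray) / background_mean_gray
}

#' Detect stained cells in a grayscale section image
#'
#' Chromogenic signal is darker than background, so cells are connected
#' components of pixels with `gray < gray_threshold`, filtered to an area
#' window. Per component, the mean gray, area and centroid (in micrometres,
#' origin at the image's top-left corner, x lateral and depth downward from
#' the pial surface) are recorded, and the background-normalized intensity
#' is computed against `background_gray` (estimated from the cell-free part
#' of the same image when not supplied).
#'
#' @param image Numeric matrix in `[0, 1]`; rows = depth, cols = x.
#' @param microns_per_pixel Pixel size in micrometres.
#' @param gray_threshold Detection threshold, strictly inside (0, 1).
#' @param min_area_um2,max_area_um2 Component area window in square
#'   micrometres.
#' @param background_gray Optional background gray; default
#'   [estimate_background()] of the same image.
#' @return Tibble of cell records: `cell_id`, `x_um`, `depth_um`,
#'   `area_um2`, `mean_gray`, `norm_intensity`, `flag_negative`, `sector`
#'   (unset, `NA`).
#' @examples
#' scene <- generate_ish_scene(scenario("null"), 1)
#' cells <- detect_cells(scene$image, scene$microns_per_pixel, 0.8)
#' nrow(cells)
#' @export
detect_cells <- function(image, microns_per_pixel, gray_threshold,
                         min_area_um2 = 40, max_area_um2 = 1000,
                         background_gray = NULL) {
  if (length(image) == 0) abort("empty image")
  if (any(image < 0 | image > 1)) abort("image values must lie in [0, 1]")
  if (gray_threshold <= 0 || gray_threshold >= 1) {
    abort("gray_threshold must be strictly inside (0, 1)")
  }
  bg <- background_gray %||% estimate_background(image, gray_threshold)

  lab <- EBImage::bwlabel((image < gray_threshold) * 1)
  idx <- which(lab > 0)
  empty <- tibble(
    cell_id = integer(), x_um = double(), depth_um = double(),
    area_um2 = double(), mean_gray = double(), norm_intensity = double(),
    flag_negative = logical(), sector = NA_character_[0]
  )
  if (length(idx) == 0) return(empty)
  l <- as.integer(lab[idx])
  nr <- nrow(image)
  i <- (idx - 1L) %% nr + 1L
  j <- (idx - 1L) %/% nr + 1L
  area_px <- tabulate(l)
  gray_sum <- as.vector(rowsum(image[idx], l))
  x_sum <- as.vector(rowsum((j - 0.5) * microns_per_pixel, l))
  d_sum <- as.vector(rowsum((i - 0.5) * microns_per_pixel, l))

  out <- tibble(
    cell_id = seq_along(area_px),
    x_um = x_sum / area_px,
    depth_um = d_sum / area_px,
    area_um2 = area_px * microns_per_pixel^2,
    mean_gray = gray_sum / area_px
  ) |>
    dplyr::filter(
      .data$area_um2 >= min_area_um2, .data$area_um2 <= max_area_um2
    ) |>
    dplyr::mutate(
      cell_id = dplyr::row_number(),
      norm_intensity = normalized_intensity(.data$mean_gray, bg),
      flag_negative = .data$norm_intensity < 0,
      sector = NA_character_
    )
  out
}

#' @rdname detect_cells
#' @details `estimate_background()` returns the mean gray over all pixels at
#'   or above the detection threshold after excluding a one-pixel margin
#'   around below-threshold pixels, i.e. the cell-free part of the image.
#' @export
estimate_background <- function(image, gray_threshold) {
  mask <- (image < gray_threshold) * 1
  if (all(mask > 0)) abort("no background pixels at or above the threshold")
  grown <- EBImage::dilate(mask, EBImage::makeBrush(3, "box"))
  free <- image[as.matrix(grown) < 0.5]
  if (length(free) == 0) free <- image[!mask]
  mean(free)
}

#' Perilesional sector layout
#'
#' The analysis window is a sector of `width_um` starting at the proximal
#' (lesion-side) edge `origin_x_um`, spanning `[depth_min_um,
#' depth_max_um)` in depth, and split into a 2x2 grid: proximal/distal at
#' `x_split_um` and superficial/deep at `depth_split_um` (both default to
#' the midpoints). Sector labels follow the deep-vs-superficial pairing:
#' `s1` proximal-deep, `s2` proximal-superficial, `s3` distal-deep, `s4`
#' distal-superficial. All intervals are half-open `[min, split)`.
#'
#' @param origin_x_um Proximal edge of the window (at the lesion).
#' @param width_um Window width (default 1000).
#' @param depth_min_um,depth_max_um Depth span of the window.
#' @param x_split_um,depth_split_um Split coordinates; default midpoints.
#' @return A `perimir_layout` list.
#' @examples
#' sector_layout(depth_max_um = 1000)
#' @export
sector_layout <- function(origin_x_um = 0, width_um = 1000,
                          depth_min_um = 0, depth_max_um = 1000,
                          x_split_um = NULL, depth_split_um = NULL) {
  x_split_um <- x_split_um %||% (origin_x_um + width_um / 2)
  depth_split_um <- depth_split_um %||% ((depth_min_um + depth_max_um) / 2)
  if (x_split_um <= origin_x_um || x_split_um >= origin_x_um + width_um) {
    abort("x_split_um must lie strictly inside the window")
  }
  if (depth_split_um <= depth_min_um || depth_split_um >= depth_max_um) {
    abort("depth_split_um must lie strictly inside the depth span")
  }
  structure(
    list(
      origin_x_um = origin_x_um, width_um = width_um,
      depth_min_um = depth_min_um, depth_max_um = depth_max_um,
      x_split_um = x_split_um, depth_split_um = depth_split_um
    ),
    class = "perimir_layout"
  )
}

#' Assign detected cells to perilesional sectors
#'
#' @param cells Cell tibble from [detect_cells()] (needs `x_um`,
#'   `depth_um`).
#' @param layout A [sector_layout()].
#' @return `cells` with the `sector` column filled: `s1`..`s4`, or `"none"`
#'   for cells outside the window.
#' @examples
#' cells <- tibble::tibble(x_um = c(100, 900), depth_um = c(800, 100))
#' assign_sectors(cells, sector_layout(depth_max_um = 1000))$sector
#' @export
assign_sectors <- function(cells, layout) {
  stopifnot(inherits(layout, "perimir_layout"))
  x <- cells$x_um
  d <- cells$depth_um
  in_window <- x >= layout$origin_x_um &
    x < layout$origin_x_um + layout$width_um &
    d >= layout$depth_min_um & d < layout$depth_max_um
  proximal <- x < layout$x_split_um
  deep <- d >= layout$depth_split_um
  cells$sector <- dplyr::case_when(
    !in_window ~ "none",
    proximal & deep ~ "s1",
    proximal & !deep ~ "s2",
    !proximal & deep ~ "s3",
    TRUE ~ "s4"
  )
  cells
}

.sector_area_mm2 <- function(layout) {
  wx_p <- layout$x_split_um - layout$origin_x_um
  wx_d <- layout$origin_x_um + layout$width_um - layout$x_split_um
  dd_s <- layout$depth_split_um - layout$depth_min_um
  dd_d <- layout$depth_max_um - layout$depth_split_um
  c(
    s1 = wx_p * dd_d, s2 = wx_p * dd_s,
    s3 = wx_d * dd_d, s4 = wx_d * dd_s
  ) / 1e6
}

#' Per-sector summary of cell counts, density and intensity
#'
#' @param cells Cell tibble with sectors assigned ([assign_sectors()]).
#' @param layout The [sector_layout()] used for assignment (provides the
#'   geometric sector areas for the density in cells/mm^2).
#' @return Tibble with one row per sector (`s1`..`s4`, always all four):
#'   `n_cells`, `area_mm2`, `density`, `mean_intensity` (`NA` for an empty
#'   sector), and `intensities` (list column of the per-cell values).
#' @examples
#' scene <- generate_ish_scene(scenario("null"), 1)
#' cells <- detect_cells(scene$image, scene$microns_per_pixel, 0.85) |>
#'   assign_sectors(sector_layout(depth_max_um = 1000))
#' sector_summary(cells, sector_layout(depth_max_um = 1000))
#' @export
sector_summary <- function(cells, layout) {
  if (!"sector" %in% names(cells) || anyNA(cells$sector)) {
    abort("cells must have sectors assigned first (see assign_sectors)")
  }
  areas <- .sector_area_mm2(layout)
  purrr::map_dfr(names(areas), function(s) {
    v <- cells$norm_intensity[cells$sector == s]
    tibble(
      sector = s,
      n_cells = length(v),
      area_mm2 = unname(areas[s]),
      density = length(v) / areas[[s]],
      mean_intensity = if (length(v)) mean(v) else NA_real_,
      intensities = list(v)
    )
  })
}

#' Contrast staining intensity between experimental groups
#'
#' Computes, per group, the deep-vs-superficial intensity fold change
#' (mean over sectors s1+s3 divided by mean over s2+s4) and the group mean
#' intensity as a percentage of the reference group, then tests the groups
#' with a Kruskal-Wallis omnibus test followed by pairwise Mann-Whitney
#' tests on the per-cell intensities (in-window cells only).
#'
#' @param cells Cell tibble with `group` and assigned `sector` columns
#'   (rows from several subjects/groups bound together).
#' @param reference_group Group label used as the 100% reference.
#' @return A `perimir_contrast` object: `groups` tibble (`group`,
#'   `n_cells`, `mean_intensity`, `deep_superficial_fc`,
#'   `percent_of_reference`), `kruskal` one-row tibble, `pairwise` tibble.
#' @export
group_contrast <- function(cells, reference_group) {
  if (!all(c("group", "sector", "norm_intensity") %in% names(cells))) {
    abort("cells need columns group, sector, norm_intensity")
  }
  cells <- dplyr::filter(cells, .data$sector != "none")
  groups <- unique(cells$group)
  if (length(groups) < 2) abort("need cells from at least 2 groups")
  if (!reference_group %in% groups) {
    abort(paste0("reference group '", reference_group, "' has no cells"))
  }
  ref_mean <- mean(cells$norm_intensity[cells$group == reference_group])
  if (ref_mean == 0) abort("reference group mean intensity is 0")

  gtab <- cells |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      mean_intensity = mean(.data$norm_intensity),
      deep_superficial_fc =
        mean(.data$norm_intensity[.data$sector %in% c("s1", "s3")]) /
          mean(.data$norm_intensity[.data$sector %in% c("s2", "s4")]),
      .groups = "drop"
    ) |>
    dplyr::mutate(percent_of_reference = 100 * .data$mean_intensity / ref_mean)

  split_int <- split(cells$norm_intensity, cells$group)
  kw <- kruskal_wallis(split_int)
  pairs <- utils::combn(sort(groups), 2, simplify = FALSE)
  pw <- purrr::map_dfr(pairs, function(p) {
    dplyr::mutate(
      mann_whitney(split_int[[p[1]]], split_int[[p[2]]]),
      group1 = p[1], group2 = p[2], .before = 1
    )
  })

  structure(
    list(
      groups = gtab, reference_group = reference_group,
      kruskal = kw, pairwise = pw
    ),
    class = "perimir_contrast"
  )
}

#' @export
print.perimir_contrast <- function(x, ...) {
  cat("<perimir_contrast> reference:", x$reference_group, "\n")
  print(x$groups)
  cat(
    "Kruskal-Wallis H =", signif(x$kruskal$statistic, 4),
    ", p =", signif(x$kruskal$p_value, 3), "\n"
  )
  invisible(x)
}

#' Compare staining between two regions of the same section
#'
#' Used for the inside-vs-outside-patch comparison in human cortex:
#' reports per-region cell densities, a Mann-Whitney test on the per-cell
#' intensities, dispersion statistics, and the full intensity
#' distributions for violin-style plotting.
#'
#' @param cells_inside,cells_outside Cell tibbles (need `norm_intensity`).
#' @param area_inside_mm2,area_outside_mm2 Region areas in mm^2.
#' @return A list (`perimir_regions`): `summary` tibble (one row per
#'   region: `n_cells`, `density`, `mean_intensity`, `sd_intensity`,
#'   `iqr_intensity`, `cv_intensity`, `intensities` list column),
#'   `density_ratio`, and `test` (Mann-Whitney one-row tibble).
#' @export
compare_regions <- function(cells_inside, cells_outside,
                            area_inside_mm2, area_outside_mm2) {
  if (nrow(cells_inside) == 0 || nrow(cells_outside) == 0) {
    abort("both regions must contain cells")
  }
  one <- function(cells, region, area) {
    v <- cells$norm_intensity
    tibble(
      region = region, n_cells = length(v), area_mm2 = area,
      density = length(v) / area,
      mean_intensity = mean(v), sd_intensity = sd(v),
      iqr_intensity = IQR(v),
      cv_intensity = sd(v) / mean(v),
      intensities = list(v)
    )
  }
  summary <- dplyr::bind_rows(
    one(cells_inside, "inside", area_inside_mm2),
    one(cells_outside, "outside", area_outside_mm2)
  )
  structure(
    list(
      summary = summary,
      density_ratio = summary$density[1] / summary$density[2],
      test = mann_whitney(
        cells_inside$norm_intensity, cells_outside$norm_intensity
      )
    ),
    class = "perimir_regions"
  )
}
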