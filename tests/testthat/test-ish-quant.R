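test_that("normalized intensity follows the background-contrast formula", {
  expect_equal(normalized_intensity(0.9, 0.9), 0)
  expect_equal(normalized_intensity(0.4, 0.8), 0.5)
  expect_equal(normalized_intensity(1.0, 0.8), -0.25)
  expect_error(normalized_intensity(0.5, 0), "background")
})

test_that("normalized intensity is invariant to global linear rescaling", {
  img_cells <- c(0.3, 0.5, 0.6)
  bg <- 0.9
  for (a in c(0.5, 0.8, 1.0)) {
    expect_equal(
      normalized_intensity(a * img_cells, a * bg),
      normalized_intensity(img_cells, bg)
    )
  }
})

test_that("detection recovers planted non-overlapping cells", {
  sc <- toy_scene_scenario(seed = 21, n_cells = 20)
  scene <- generate_ish_scene(sc, 1)
  # threshold midway between the darkest expectation and background
  thr <- (max(scene$truth$planted_gray) + sc$image_geom$background_gray) / 2
  cells <- detect_cells(scene$image, scene$microns_per_pixel, thr)
  expect_equal(nrow(cells), 20)
  # every detection within one radius of a planted center, and vice versa
  d <- sqrt(outer(cells$x_um, scene$truth$x_um, "-")^2 +
    outer(cells$depth_um, scene$truth$depth_um, "-")^2)
  expect_true(all(apply(d, 1, min) <= sc$cell_radius_um))
  expect_true(all(apply(d, 2, min) <= sc$cell_radius_um))
})

test_that("blank images and over-tight area filters yield zero detections", {
  blank <- matrix(0.9, 100, 100)
  expect_equal(nrow(detect_cells(blank, 2, 0.5)), 0)
  sc <- toy_scene_scenario(seed = 22, n_cells = 10)
  scene <- generate_ish_scene(sc, 1)
  none <- detect_cells(scene$image, 2, 0.8, min_area_um2 = 5000)
  expect_equal(nrow(none), 0)
})

test_that("detection validates its inputs", {
  img <- matrix(0.5, 10, 10)
  expect_error(detect_cells(img, 2, 0), "threshold")
  expect_error(detect_cells(img, 2, 1.2), "threshold")
  expect_error(detect_cells(matrix(2, 5, 5), 2, 0.5), "\\[0, 1\\]")
  expect_error(detect_cells(matrix(numeric(0), 0, 0), 2, 0.5), "empty")
})

test_that("sector assignment follows the 2x2 perilesional convention", {
  layout <- sector_layout(
    origin_x_um = 0, width_um = 1000,
    depth_min_um = 0, depth_max_um = 1000
  )
  cells <- tibble::tibble(
    x_um = c(250, 250, 750, 750, 1500, 499.999, 500),
    depth_um = c(800, 100, 800, 100, 500, 500, 499.999)
  )
  got <- assign_sectors(cells, layout)$sector
  expect_equal(got[1:5], c("s1", "s2", "s3", "s4", "none"))
  # half-open boundaries: x just below the split is proximal, depth at the
  # split is deep, depth just below is superficial
  expect_equal(got[6], "s1")
  expect_equal(got[7], "s4")
})

test_that("in-window cells get exactly one sector label", {
  layout <- sector_layout(depth_max_um = 800)
  set.seed(1)
  cells <- tibble::tibble(
    x_um = runif(500, -100, 1200), depth_um = runif(500, -50, 900)
  )
  got <- assign_sectors(cells, layout)
  expect_false(anyNA(got$sector))
  inside <- got$x_um >= 0 & got$x_um < 1000 &
    got$depth_um >= 0 & got$depth_um < 800
  expect_true(all(got$sector[inside] %in% c("s1", "s2", "s3", "s4")))
  expect_true(all(got$sector[!inside] == "none"))
})

test_that("uniform cells land in sectors proportionally to area", {
  layout <- sector_layout(
    width_um = 1000, depth_max_um = 1000,
    x_split_um = 250, depth_split_um = 750
  )
  set.seed(42)
  cells <- tibble::tibble(
    x_um = runif(20000, 0, 1000), depth_um = runif(20000, 0, 1000)
  )
  counts <- table(assign_sectors(cells, layout)$sector)
  areas <- c(s1 = 0.25 * 0.25, s2 = 0.25 * 0.75, s3 = 0.75 * 0.25, s4 = 0.75 * 0.75)
  expect_equal(
    as.numeric(counts[names(areas)] / 20000),
    as.numeric(areas),
    tolerance = 0.05
  )
})

test_that("sector summaries report counts, densities and means per sector", {
  layout <- sector_layout(depth_max_um = 1000)
  cells <- tibble::tibble(
    x_um = c(250, 250, 750, 750), depth_um = c(800, 100, 800, 100),
    norm_intensity = c(0.1, 0.2, 0.3, 0.4)
  ) |> assign_sectors(layout)
  s <- sector_summary(cells, layout)
  expect_equal(s$sector, c("s1", "s2", "s3", "s4"))
  expect_equal(s$mean_intensity, c(0.1, 0.2, 0.3, 0.4))
  expect_equal(s$n_cells, rep(1L, 4))
  # equal-area sectors with equal counts have equal densities
  expect_equal(s$density, rep(1 / 0.25, 4))
  # empty sector: n = 0, undefined mean flagged as NA
  s2 <- sector_summary(cells[1:3, ], layout)
  expect_equal(s2$n_cells[4], 0L)
  expect_true(is.na(s2$mean_intensity[4]))
})

test_that("identical groups contrast at 100% with high p-values", {
  layout <- sector_layout(depth_max_um = 500)
  set.seed(5)
  base <- tibble::tibble(
    x_um = runif(200, 0, 1000), depth_um = runif(200, 0, 500),
    norm_intensity = runif(200, 0.2, 0.4)
  ) |> assign_sectors(layout)
  cells <- dplyr::bind_rows(
    dplyr::mutate(base, group = "naive"),
    dplyr::mutate(base, group = "sham")
  )
  con <- group_contrast(cells, "naive")
  expect_equal(con$groups$percent_of_reference, c(100, 100))
  expect_equal(con$pairwise$p_value, 1, tolerance = 1e-6)
})

test_that("region comparison flags planted inside-patch downregulation", {
  # identical sets: ratio 1, p = 1
  same <- tibble::tibble(norm_intensity = c(0.2, 0.3, 0.4))
  r0 <- compare_regions(same, same, 1, 1)
  expect_equal(r0$density_ratio, 1)
  expect_equal(r0$test$p_value, 1)

  # equal counts, different areas: densities scale inversely with area
  r1 <- compare_regions(same, same, 0.5, 2)
  expect_equal(r1$density_ratio, 4)

  # planted shift: inside lower mean, higher spread; power at alpha = 0.01
  rejections <- vapply(1:20, function(k) {
    set.seed(300 + k)
    inside <- tibble::tibble(norm_intensity = rlnorm(80, log(0.15), 0.5))
    outside <- tibble::tibble(norm_intensity = rlnorm(80, log(0.3), 0.25))
    compare_regions(inside, outside, 1, 1)$test$p_value < 0.01
  }, logical(1))
  expect_gte(mean(rejections), 0.9)
  expect_error(
    compare_regions(same[0, ], same, 1, 1), "both regions"
  )
})

test_that("estimated background matches the painted background level", {
  sc <- toy_scene_scenario(seed = 31, n_cells = 30)
  scene <- generate_ish_scene(sc, 1)
  bg <- estimate_background(scene$image, sc$gray_threshold)
  expect_equal(bg, sc$image_geom$background_gray, tolerance = 0.005)
})
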