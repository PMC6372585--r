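test_that("systematic grids are reproducible and cover the extent", {
  g <- point_grid(c(0, 10, 0, 10), 1, offset = c(0, 0))
  expect_equal(nrow(grid_points(g)), 100)
  g1 <- point_grid(c(0, 10, 0, 10), 2, seed = 5)
  g2 <- point_grid(c(0, 10, 0, 10), 2, seed = 5)
  expect_identical(g1$offset, g2$offset)
  expect_error(point_grid(c(0, 1, 0, 1), 5), class = "glom_empty_grid")
})

test_that("grid offsets are uniform on [0, s)^2 across seeds", {
  offs <- t(vapply(1:10000, function(s) {
    point_grid(c(0, 100, 0, 100), 4, seed = s)$offset
  }, numeric(2)))
  expect_gt(stats::ks.test(offs[, 1] / 4, "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(offs[, 2] / 4, "punif")$p.value, 0.01)
})

test_that("Cavalieri counting matches closed forms, incl. the half rule", {
  sq <- contour(c(0, 10, 10, 0), c(0, 0, 10, 10), "tuft", 0, "t")
  g <- point_grid(c(-0.5, 10.4, -0.5, 10.4), 1, offset = c(0, 0))
  # offset (0.5, 0.5) relative to the square: all 100 points interior
  res <- cavalieri_volume(sq, grid = g, compartment = "tuft",
                          thickness_um = 1)
  expect_equal(res$volume_um3, 100)
  # points on edges/corners count one half
  g2 <- point_grid(c(0, 10.1, 0, 10.1), 5, offset = c(0, 0))
  hits <- count_grid_hits(sq, grid = g2)
  expect_equal(hits$p_ref, 1 + 0.5 * 8) # 1 interior + 8 boundary points
  # empty compartment
  expect_equal(cavalieri_volume(sq, grid = g, compartment = "mesangium",
                                thickness_um = 1)$volume_um3, 0)
})

test_that("grid at pixel pitch reproduces the mask area exactly", {
  st <- sphere_masks(r = 8, t = 2, voxel = 0.5)
  mask_area_vol <- sum(vapply(st$mesangium, sum, numeric(1))) * 0.5^2 * 2
  res <- cavalieri_volume(st, spacing_um = 0.5, seed = 3,
                          compartment = "tuft")
  expect_equal(res$volume_um3, mask_area_vol, tolerance = 1e-3)
})

test_that("SUR Cavalieri is unbiased on a voxel sphere", {
  st <- sphere_masks(r = 8, t = 2, voxel = 0.25)
  truth <- sum(vapply(st$mesangium, sum, numeric(1))) * 0.25^2 * 2
  est <- vapply(1:150, function(s) {
    cavalieri_volume(st, spacing_um = 2, seed = s,
                     compartment = "tuft")$volume_um3
  }, numeric(1))
  expect_lt(abs(mean(est) - truth) / truth, 0.01)
})

test_that("PSI fractional volume handles nested and degenerate inputs", {
  tuft <- contour(c(0, 10, 10, 0), c(0, 0, 10, 10), "tuft", 0, "t")
  mes_same <- contour(tuft$x, tuft$y, "mesangium", 0, "m")
  g <- point_grid(c(-0.7, 10.6, -0.7, 10.6), 1, offset = c(0.2, 0.2))
  both <- dplyr::bind_rows(tuft, mes_same)
  expect_equal(psi_fractional_volume(both, grid = g)$vv, 1.0)
  expect_equal(psi_fractional_volume(tuft, grid = g)$vv, 0.0)
  # no reference hits
  far_grid <- point_grid(c(100, 120, 100, 120), 5, offset = c(0, 0))
  expect_error(psi_fractional_volume(tuft, grid = far_grid),
               class = "glom_undefined_fraction")
  # phantom truth: masks-based Vv near voxel truth
  spec <- small_phantom_spec(seed = 41, target_vv = 0.5,
                             n_sections = 12L)
  truth <- generate_phantom(spec)
  st <- phantom_section_masks(truth)
  vvs <- vapply(1:40, function(s) {
    psi_fractional_volume(st, spacing_um = 1, seed = s)$vv
  }, numeric(1))
  expect_lt(abs(mean(vvs) - truth$true_vv), 0.02)
})

test_that("Vv is invariant to a global rigid transform of the sections", {
  spec <- small_phantom_spec(seed = 43)
  truth <- generate_phantom(spec)
  tc <- truth_contours(truth)
  tr <- rigid_transform(0.4, 12, -7)
  moved <- transform_contours(tc, tr)
  vv0 <- mean(vapply(1:25, function(s) {
    psi_fractional_volume(tc, spacing_um = 1, seed = s)$vv
  }, numeric(1)))
  vv1 <- mean(vapply(1:25, function(s) {
    psi_fractional_volume(moved, spacing_um = 1, seed = s)$vv
  }, numeric(1)))
  expect_equal(vv1, vv0, tolerance = 0.02)
})

test_that("planimetry implements both area-to-volume models", {
  sq <- contour(c(0, 10, 10, 0), c(0, 0, 10, 10), "mesangium", 0, "m")
  res <- planimetry(sq, "extrusion", t_equiv_um = 1)
  expect_equal(res$mean_mesangial_area_um2, 100)
  expect_equal(res$estimated_volume_um3, 100)
  # two profiles of 100 and 200 um^2
  two <- dplyr::bind_rows(
    sq,
    contour(c(0, 20, 20, 0), c(0, 0, 10, 10), "mesangium", 1, "m"))
  expect_equal(planimetry(two, "extrusion", 1)$mean_mesangial_area_um2, 150)
  # Weibel-Gomez on a sphere's equatorial disc, against an independently
  # coded evaluation of (beta / k) * A^(3/2)
  r <- 10
  disc <- circle_polygon(r, 512)
  prof <- contour(disc$x, disc$y, "mesangium", 0, "m", check_simple = FALSE)
  res <- planimetry(prof, "weibel_gomez")
  a <- polygon_area(disc$x, disc$y)
  beta <- 1.38; k <- 1.1
  expect_equal(res$estimated_volume_um3, beta / k * a^1.5, tolerance = 1e-12)
  expect_equal(res$estimated_volume_um3, (1.38 / 1.1) * (pi * r^2)^1.5,
               tolerance = 0.001)
  expect_error(planimetry(sq[0, ]), class = "glom_no_profiles")
})
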