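test_that("prism extrusion reproduces closed-form solids", {
  sq <- contour(c(0, 10, 10, 0), c(0, 0, 10, 10), "tuft", 0, "t1")
  m <- reconstruct_mesh(sq, thickness_um = 1, compartment = "tuft")
  expect_equal(m$volume_um3, 100, tolerance = 1e-12)
  expect_equal(m$surface_area_um2, 2 * 100 + 4 * 10 * 1, tolerance = 1e-12)
  expect_true(is_watertight(m))
  # six identical 64-gon discs: V = 6 * A64 * t exactly
  r <- 10
  p <- circle_polygon(r, 64)
  stack <- dplyr::bind_rows(lapply(0:5, function(s) {
    contour(p$x, p$y, "tuft", s, "c1")
  }))
  m6 <- reconstruct_mesh(stack, 1, "tuft")
  a64 <- 0.5 * 64 * r^2 * sin(2 * pi / 64)
  expect_equal(m6$volume_um3, 6 * a64, tolerance = 1e-9)
  expect_true(is_watertight(m6))
})

test_that("sphere stack volume matches the stacked-disc quadrature oracle", {
  r <- 10
  for (n in c(20, 40)) {
    stack <- sphere_stack(r, n, n_gon = 256)
    m <- reconstruct_mesh(stack, 2 * r / n, "tuft")
    # oracle uses exact discs; correct for the regular-polygon area factor
    poly_factor <- 0.5 * 256 * sin(2 * pi / 256) / pi
    expect_equal(m$volume_um3, stacked_disc_volume(r, n) * poly_factor,
                 tolerance = 1e-9)
  }
})

test_that("mesh volume equals sum of contour areas times thickness", {
  set.seed(123)
  for (i in 1:15) {
    stack <- rand_stack(n_sections = sample(2:5, 1))
    for (comp in intersect(unique(stack$compartment),
                           c("mesangium", "tuft"))) {
      t_um <- stats::runif(1, 0.5, 3)
      m <- reconstruct_mesh(stack, t_um, comp)
      areas <- contour_areas(stack)
      expected <- sum(areas$area_um2[areas$compartment == comp]) * t_um
      expect_equal(m$volume_um3, expected, tolerance = 1e-9)
      expect_true(is_watertight(m))
    }
  }
})

test_that("volumes are invariant under a global rigid transform", {
  set.seed(9)
  stack <- rand_stack(n_sections = 3)
  tr <- rand_rigid()
  moved <- transform_contours(stack, tr)
  for (comp in intersect(unique(stack$compartment), c("mesangium", "tuft"))) {
    v0 <- reconstruct_mesh(stack, 1, comp)$volume_um3
    v1 <- reconstruct_mesh(moved, 1, comp)$volume_um3
    expect_equal(v1, v0, tolerance = 1e-9)
  }
})

test_that("degenerate stacks are refused with informative errors", {
  expect_error(
    reconstruct_mesh(
      contour(c(0, 1, 1, 0), c(0, 0, 1, 1), "tuft", 0, "t"), 1, "mesangium"),
    class = "glom_no_geometry")
  # self-intersecting contour smuggled past construction checks
  bow <- tibble::tibble(section_index = 2L, contour_id = "bad",
                        compartment = "tuft",
                        x = c(0, 1, 1, 0), y = c(0, 1, 0, 1))
  expect_error(reconstruct_mesh(bow, 1, "tuft"),
               class = "glom_degenerate_geometry")
})

test_that("morphometrics summarise areas, volumes and the area ratio", {
  tuft <- contour(c(0, 10, 10, 0), c(0, 0, 10, 10), "tuft", 0, "t1")
  mes <- contour(c(2, 6, 6, 2), c(2, 2, 6, 6), "mesangium", 0, "m1")
  rec <- compute_morphometrics(dplyr::bind_rows(tuft, mes), 1)
  expect_equal(rec$mes_to_total_ratio, 16 / 100)
  expect_equal(rec$mesangial_volume_um3, 16)
  expect_equal(rec$tuft_volume_um3, 100)
  # mesangium identical to tuft -> ratio 1; absent -> ratio 0
  mes_full <- contour(tuft$x, tuft$y, "mesangium", 0, "m1")
  expect_equal(
    compute_morphometrics(dplyr::bind_rows(tuft, mes_full), 1)$mes_to_total_ratio,
    1.0)
  rec0 <- compute_morphometrics(tuft, 1)
  expect_equal(rec0$mes_to_total_ratio, 0)
  expect_equal(rec0$mesangial_volume_um3, 0)
})

test_that("mesh export round-trips through OBJ and STL", {
  cube <- reconstruct_mesh(
    contour(c(0, 2, 2, 0), c(0, 0, 2, 2), "tuft", 0, "t"), 2, "tuft")
  expect_equal(nrow(cube$vertices), 8)
  expect_equal(nrow(cube$faces), 12)
  for (fmt in c("obj", "stl")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_mesh(cube, path)
    back <- read_mesh(path)
    expect_equal(back$volume_um3, cube$volume_um3, tolerance = 1e-6)
    expect_true(is_watertight(back))
  }
  empty <- cube
  empty$faces <- empty$faces[0, ]
  expect_error(write_mesh(empty, tempfile(fileext = ".obj")),
               class = "glom_no_geometry")
})
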