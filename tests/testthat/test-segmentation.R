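test_that("optical density and stain unmixing invert the forward model", {
  # pure white -> OD ~ 0
  white <- array(255, c(2, 2, 3))
  expect_lt(max(abs(rgb_to_od(white))), 0.002)
  model <- stain_model()
  # forward Beer-Lambert render of a pure PAS pixel at known concentration
  conc <- 0.7
  od <- model$stains[, "pas"] * conc
  img <- array(rep(256 * 10^(-od) - 1, each = 1), c(1, 1, 3))
  out <- separate_stains(img, model)
  expect_equal(unname(out[1, 1, "pas"]), conc, tolerance = 0.01)
  expect_lt(unname(out[1, 1, "hematoxylin"]), 0.01)
  # 50/50 two-stain mixture
  od <- model$stains[, "pas"] * 0.5 + model$stains[, "hematoxylin"] * 0.5
  img <- array(256 * 10^(-od) - 1, c(1, 1, 3))
  out <- separate_stains(img, model)
  expect_equal(unname(out[1, 1, c("pas", "hematoxylin")]), c(0.5, 0.5),
               tolerance = 0.01)
})

test_that("collinear stain vectors are rejected", {
  expect_error(stain_model(pas = c(1, 0, 0), hematoxylin = c(2, 0, 0)),
               class = "glom_collinear_stains")
})

test_that("Otsu threshold separates bimodal data and matches brute force", {
  # equal-mass two-delta histogram
  v <- c(rep(0.1, 500), rep(0.9, 500))
  thr <- otsu_threshold(v)
  expect_gt(thr, 0.1)
  expect_lt(thr, 0.9)
  # brute-force minimum within-class variance over all 256 bin edges
  set.seed(8)
  v <- c(stats::rnorm(2000, 0.2, 0.05), stats::rnorm(1000, 0.8, 0.1))
  thr <- otsu_threshold(v)
  # independent route: exhaustive minimum of the within-class variance over
  # every histogram bin edge (the implementation maximizes between-class
  # variance; the two must pick the same edge)
  edges <- seq(min(v), max(v), length.out = 257)
  counts <- tabulate(pmin(256, pmax(1, findInterval(v, edges,
                                                   rightmost.closed = TRUE))),
                     256)
  mids <- (edges[-1] + edges[-257]) / 2
  wcv <- vapply(1:255, function(k) {
    lo <- seq_len(k); hi <- (k + 1):256
    n0 <- sum(counts[lo]); n1 <- sum(counts[hi])
    if (n0 == 0 || n1 == 0) return(Inf)
    m0 <- sum(counts[lo] * mids[lo]) / n0
    m1 <- sum(counts[hi] * mids[hi]) / n1
    sum(counts[lo] * (mids[lo] - m0)^2) + sum(counts[hi] * (mids[hi] - m1)^2)
  }, numeric(1))
  best <- edges[which.min(wcv) + 1L]
  expect_equal(thr, best, tolerance = 1e-12)
  # shift equivariance
  expect_equal(otsu_threshold(v + 3), thr + 3, tolerance = 1e-9)
  expect_error(otsu_threshold(rep(1, 100)), class = "glom_no_contrast")
})

test_that("blank images yield no contours", {
  white <- array(255, c(32, 32, 3))
  res <- segment_section(white, pixel_size_um = 0.25)
  expect_equal(nrow(res), 0)
})

test_that("segmentation is deterministic and recovers phantom truth", {
  spec <- small_phantom_spec(seed = 31)
  truth <- generate_phantom(spec)
  render <- render_sections(truth)
  seg1 <- segment_section(render$images[[3]], spec$pixel_size_um, 2L)
  seg2 <- segment_section(render$images[[3]], spec$pixel_size_um, 2L)
  expect_identical(seg1$x, seg2$x)
  expect_identical(seg1$y, seg2$y)
  dices <- vapply(seq_along(render$images), function(i) {
    seg <- segment_section(render$images[[i]], spec$pixel_size_um, i - 1L)
    dice_coefficient(truth$section_masks[[i]] == 2L,
                     attr(seg, "masks")$mesangium)
  }, numeric(1))
  expect_true(all(dices >= 0.90))
  # mesangial area never exceeds tuft area
  seg <- segment_section(render$images[[3]], spec$pixel_size_um, 2L)
  areas <- contour_areas(seg)
  expect_lte(sum(areas$area_um2[areas$compartment == "mesangium"]),
             sum(areas$area_um2[areas$compartment == "tuft"]))
})

test_that("small regions are filtered and thresholds act monotonically", {
  # label image: tuft disc with one large and one tiny mesangial blob
  n <- 120
  ps <- 0.25
  lab <- matrix(0L, n, n)
  cx <- (col(lab) - n / 2) * ps
  cy <- (row(lab) - n / 2) * ps
  lab[cx^2 + cy^2 <= 12^2] <- 1L
  lab[(cx - 4)^2 + (cy - 2)^2 <= 2^2] <- 2L     # ~12.6 um^2, kept
  lab[(cx + 5)^2 + (cy + 5)^2 <= 0.85^2] <- 2L  # ~2.3 um^2 < 5, dropped
  img <- flat_pas_image(lab)
  seg <- segment_section(img, ps, model = stain_model())
  mes_ids <- unique(seg$contour_id[seg$compartment == "mesangium"])
  expect_length(mes_ids, 1)
  a <- contour_areas(seg)
  expect_equal(a$area_um2[a$compartment == "mesangium"], pi * 2^2,
               tolerance = 0.1)
  # raising the threshold never increases total mesangial area
  thr0 <- attr(seg, "od_threshold")
  areas <- vapply(thr0 * c(0.6, 0.8, 1.0, 1.2, 1.4), function(th) {
    # low thresholds legitimately trip the >50%-positive calibration warning
    s <- suppressWarnings(
      segment_section(img, ps, model = stain_model(od_threshold = th)))
    ar <- contour_areas(s)
    sum(ar$area_um2[ar$compartment == "mesangium"])
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("oversized positive fraction triggers a calibration warning", {
  lab <- matrix(2L, 60, 60) # everything mesangium
  lab[1:5, ] <- 0L
  img <- flat_pas_image(lab)
  expect_warning(
    segment_section(img, 0.25, model = stain_model(od_threshold = 0.2)),
    "positive")
})
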