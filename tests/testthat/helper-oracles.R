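# Independent oracles and fixture builders used across the suite.

# Star-shaped simple polygon: jittered regular angles (gaps stay below pi,
# so the origin is in the kernel) with random radii.
rand_polygon <- function(n = 20, scale = 10) {
  ang <- (seq_len(n) - 1) * 2 * pi / n +
    stats::runif(n, 0, 0.8 * 2 * pi / n)
  rad <- stats::runif(n, 0.3, 1) * scale
  list(x = rad * cos(ang), y = rad * sin(ang))
}

# Monte-Carlo area via pracma's point-in-polygon (independent of the
# package's own classifier).
mc_area <- function(x, y, n_points = 1e6) {
  xr <- range(x); yr <- range(y)
  px <- stats::runif(n_points, xr[1], xr[2])
  py <- stats::runif(n_points, yr[1], yr[2])
  frac <- mean(pracma::inpolygon(px, py, x, y))
  frac * diff(xr) * diff(yr)
}

rand_rigid <- function() {
  rigid_transform(stats::runif(1, -pi, pi), stats::rnorm(1, 0, 20),
                  stats::rnorm(1, 0, 20))
}

# Random multi-section, multi-contour stack of simple polygons.
rand_stack <- function(n_sections = 4, max_contours = 3) {
  rows <- list()
  for (s in seq_len(n_sections) - 1L) {
    for (k in seq_len(sample(max_contours, 1))) {
      p <- rand_polygon(n = sample(5:24, 1), scale = stats::runif(1, 2, 12))
      cx <- stats::rnorm(1, 0, 30); cy <- stats::rnorm(1, 0, 30)
      rows[[length(rows) + 1L]] <- contour(
        p$x + cx, p$y + cy,
        compartment = sample(c("mesangium", "tuft"), 1),
        section_index = s, contour_id = sprintf("s%d_k%d", s, k))
    }
  }
  dplyr::bind_rows(rows)
}

# Brute-force within-subject ANOVA decomposition, written independently of
# the package implementation (explicit sums of squares).
bf_rm_anova <- function(wide) {
  n <- nrow(wide); k <- ncol(wide)
  gm <- mean(wide)
  col_m <- colMeans(wide)
  row_m <- rowMeans(wide)
  ss_method <- n * sum((col_m - gm)^2)
  ss_subject <- k * sum((row_m - gm)^2)
  ss_total <- sum((wide - gm)^2)
  ss_error <- ss_total - ss_method - ss_subject
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  f <- (ss_method / df1) / (ss_error / df2)
  list(f = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE),
       ss = c(method = ss_method, subject = ss_subject, error = ss_error,
              total = ss_total))
}

# Stacked-disc quadrature for a sphere cut into n slabs of thickness t:
# each slab contributes (mid-plane disc area) x t.
stacked_disc_volume <- function(r, n) {
  t <- 2 * r / n
  zmid <- -r + (seq_len(n) - 0.5) * t
  sum(pi * pmax(r^2 - zmid^2, 0) * t)
}

# Regular polygon approximating a circle (CCW).
circle_polygon <- function(r, n = 64, cx = 0, cy = 0) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  list(x = cx + r * cos(ang), y = cy + r * sin(ang))
}

# Circle contour stack for a sphere of radius r sliced into n slabs.
sphere_stack <- function(r, n, n_gon = 256, compartment = "tuft") {
  t <- 2 * r / n
  zmid <- -r + (seq_len(n) - 0.5) * t
  rows <- lapply(seq_len(n), function(i) {
    ri <- sqrt(max(r^2 - zmid[i]^2, 0))
    if (ri <= 0) return(NULL)
    p <- circle_polygon(ri, n_gon)
    contour(p$x, p$y, compartment, section_index = i - 1L,
            contour_id = "c1", check_simple = FALSE)
  })
  dplyr::bind_rows(rows)
}

# Voxelized sphere mask stack (for the counting estimators).
sphere_masks <- function(r = 20, t = 2, voxel = 0.25, pad = 1) {
  half <- r + pad
  xs <- seq(-half + voxel / 2, half, by = voxel)
  n <- round(2 * r / t)
  zmid <- -r + (seq_len(n) - 0.5) * t
  masks <- lapply(zmid, function(z) {
    r2 <- r^2 - z^2
    if (r2 <= 0) return(matrix(FALSE, length(xs), length(xs)))
    outer(xs^2, xs^2, "+") <= r2
  })
  mask_stack(masks, pixel_size_um = voxel, thickness_um = t,
             origin = c(-half, -half))
}

# Small, fast phantom used widely in the tests.
small_phantom_spec <- function(seed = 1L, target_vv = 0.5,
                               n_sections = 6L, ...) {
  phantom_spec(tuft_radii_um = c(8, 7, 6), n_mesangial_blobs = 6L,
               target_vv = target_vv, voxel_size_um = 0.25,
               n_sections = n_sections, seed = seed, ...)
}

# PAS-like flat-colour renderer for hand-built label images (white
# background, tuft wash, strong-PAS mesangium), independent of the phantom.
flat_pas_image <- function(labels, noise = 0) {
  stains <- stain_model()$stains
  conc_pas <- c(0, 0.15, 0.9)[labels + 1L]
  conc_hem <- c(0, 0.5, 0.3)[labels + 1L]
  od <- array(0, dim = c(nrow(labels), ncol(labels), 3))
  for (ch in 1:3) {
    od[, , ch] <- conc_pas * stains[ch, "pas"] + conc_hem * stains[ch, "hematoxylin"]
  }
  img <- 256 * 10^(-od) - 1
  if (noise > 0) img <- img + stats::rnorm(length(img), 0, noise)
  round(pmin(pmax(img, 0), 255))
}
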