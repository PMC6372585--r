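#' Synthetic glomerulus phantoms with exact voxel ground truth
#'
#' The phantom emulates the specimens the toolkit is designed for: a roughly
#' ellipsoidal glomerular tuft containing blob-like mesangial regions at a
#' controllable volume fraction, cut into ~1 um serial sections, rendered as
#' PAS-like RGB images with pixel noise and per-section rigid misalignment,
#' with embedded fiducial markers. Ground truth (compartment volumes, section
#' masks, applied transforms) is exact by construction — voxel counts times
#' voxel volume — and serves as the oracle for every estimator in the
#' package.
#'
#' @name phantom
NULL

#' Phantom specification
#'
#' Defaults mirror the acquisition this toolkit targets: six 1-um serial
#' sections photographed at sub-micron pixel size, four fiducial landmarks,
#' modest manual-alignment error. The voxel size (0.25 um) is four times
#' finer than the section thickness so voxelization error is negligible
#' against estimator error.
#'
#' @param tuft_radii_um Ellipsoid semi-axes `c(a, b, c)` in um (c is the
#'   cutting axis).
#' @param n_mesangial_blobs Number of Gaussian blob kernels forming the
#'   mesangium.
#' @param target_vv Target mesangial fractional volume Vv(mes/glom) in (0,1).
#' @param voxel_size_um Ground-truth voxel edge in um.
#' @param section_thickness_um Section thickness t in um.
#' @param n_sections Number of serial sections (stack centred on the
#'   equator).
#' @param pixel_size_um Rendered image pixel size in um.
#' @param misalignment_sigma `c(translation_um, rotation_rad)` SDs of the
#'   per-section rigid perturbation.
#' @param noise_sigma Gaussian pixel noise SD in 8-bit intensity units.
#' @param blob_sigma_um Kernel SD of the mesangial blobs; default
#'   `0.3 * min(tuft_radii_um)`.
#' @param pad_um Background margin around the tuft in um.
#' @param seed Integer seed; the same spec + seed reproduces the phantom
#'   bit-for-bit.
#' @return A `glom_phantom_spec` list.
#' @export
phantom_spec <- function(tuft_radii_um = c(12, 10, 8),
                         n_mesangial_blobs = 8L,
                         target_vv = 0.5,
                         voxel_size_um = 0.25,
                         section_thickness_um = 1,
                         n_sections = 6L,
                         pixel_size_um = 0.25,
                         misalignment_sigma = c(1, 0.02),
                         noise_sigma = 5,
                         blob_sigma_um = NULL,
                         pad_um = 1,
                         seed = 1L) {
  stopifnot(length(tuft_radii_um) == 3L, all(tuft_radii_um > 0),
            target_vv > 0, target_vv < 1, n_sections >= 1L)
  structure(
    list(tuft_radii_um = tuft_radii_um,
         n_mesangial_blobs = as.integer(n_mesangial_blobs),
         target_vv = target_vv,
         voxel_size_um = voxel_size_um,
         section_thickness_um = section_thickness_um,
         n_sections = as.integer(n_sections),
         pixel_size_um = pixel_size_um,
         misalignment_sigma = misalignment_sigma,
         noise_sigma = noise_sigma,
         blob_sigma_um = blob_sigma_um %||% 0.3 * min(tuft_radii_um),
         pad_um = pad_um,
         seed = as.integer(seed)),
    class = "glom_phantom_spec"
  )
}

# Poisson-disc-style dart throwing inside the (scaled) tuft ellipsoid.
blob_centers <- function(n, radii, min_dist) {
  centers <- matrix(numeric(0), 0L, 3L)
  attempts <- 0L
  shrink <- 0.8
  while (nrow(centers) < n && attempts < 5000L) {
    p <- stats::runif(3, -1, 1) * radii * shrink
    if (sum((p / (radii * shrink))^2) > 1) {
      attempts <- attempts + 1L
      next
    }
    if (nrow(centers) == 0L ||
        min(sqrt(colSums((t(centers) - p)^2))) >= min_dist) {
      centers <- rbind(centers, p)
    }
    attempts <- attempts + 1L
    # relax the spacing if the ellipsoid is too crowded for n darts
    if (attempts %% 1000L == 0L) min_dist <- min_dist * 0.7
  }
  centers
}

#' Generate a voxel phantom with exact compartment ground truth
#'
#' The tuft is a voxelized ellipsoid; the mesangium is the level set of a
#' sum-of-Gaussian blob field, with the level found by bisection so the
#' realized voxel Vv is within 0.01 of the target. Per-section truth masks,
#' rigid misalignment transforms and fiducial coordinates are generated here
#' (seeded) so rendering and ground truth always agree.
#'
#' @param spec A [phantom_spec()].
#' @return A `glom_phantom` object: voxel `labels` (0 background / 1 tuft /
#'   2 mesangium), exact `true_*` volumes and `true_vv`, per-section truth
#'   label masks in the rendered (misaligned) frame, `true_transforms`,
#'   reference-frame `fiducial_points`, and raster metadata.
#' @export
generate_phantom <- function(spec) {
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  r <- spec$tuft_radii_um
  v <- spec$voxel_size_um
  pad <- spec$pad_um
  half <- r + pad
  xs <- seq(-half[1] + v / 2, half[1], by = v)
  ys <- seq(-half[2] + v / 2, half[2], by = v)
  zs <- seq(-half[3] + v / 2, half[3], by = v)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  ex2 <- (xs / r[1])^2
  ey2 <- (ys / r[2])^2
  ez2 <- (zs / r[3])^2
  tuft <- outer(outer(ex2, ey2, "+"), ez2, "+") <= 1
  labels <- array(0L, dim = c(nx, ny, nz))
  labels[tuft] <- 1L
  n_tuft <- sum(tuft)
  realized_vv <- 0
  if (spec$n_mesangial_blobs > 0L) {
    sigma <- spec$blob_sigma_um
    centers <- blob_centers(spec$n_mesangial_blobs, r, min_dist = 1.2 * sigma)
    idx <- which(tuft)
    ij <- arrayInd(idx, dim(tuft))
    px <- xs[ij[, 1]]; py <- ys[ij[, 2]]; pz <- zs[ij[, 3]]
    field <- numeric(length(idx))
    for (k in seq_len(nrow(centers))) {
      d2 <- (px - centers[k, 1])^2 + (py - centers[k, 2])^2 +
        (pz - centers[k, 3])^2
      field <- field + exp(-d2 / (2 * sigma^2))
    }
    # bisection on the level-set threshold for the target Vv
    lo <- 0; hi <- max(field) * (1 + 1e-9)
    best_tau <- NA_real_; best_err <- Inf
    for (step in seq_len(60L)) {
      tau <- (lo + hi) / 2
      vv <- sum(field >= tau) / n_tuft
      err <- abs(vv - spec$target_vv)
      if (err < best_err) {
        best_err <- err; best_tau <- tau
      }
      if (err <= 0.005) break
      if (vv > spec$target_vv) lo <- tau else hi <- tau
    }
    if (best_err > 0.01) {
      abort(sprintf(
        "Target Vv %.3f unreachable with %d blobs; best achieved |error| = %.4f.",
        spec$target_vv, spec$n_mesangial_blobs, best_err),
        class = "glom_vv_unreachable")
    }
    mes_idx <- idx[field >= best_tau]
    labels[mes_idx] <- 2L
    realized_vv <- length(mes_idx) / n_tuft
  }
  vol_voxel <- v^3
  true_tuft <- n_tuft * vol_voxel
  true_mes <- sum(labels == 2L) * vol_voxel
  # per-section rigid misalignment and fiducials
  t_um <- spec$section_thickness_um
  n_sec <- spec$n_sections
  depth <- 2 * half[3]
  if (n_sec * t_um > depth + 1e-9) {
    abort("n_sections x thickness exceeds the phantom depth.")
  }
  z0 <- -n_sec * t_um / 2
  z_mid <- z0 + (seq_len(n_sec) - 0.5) * t_um
  tf <- lapply(seq_len(n_sec), function(i) {
    rigid_transform(
      angle = stats::rnorm(1, 0, spec$misalignment_sigma[2]),
      dx = stats::rnorm(1, 0, spec$misalignment_sigma[1]),
      dy = stats::rnorm(1, 0, spec$misalignment_sigma[1])
    )
  })
  fid <- cbind(x = c(-1, 1, 1, -1) * (half[1] - 0.4),
               y = c(-1, -1, 1, 1) * (half[2] - 0.4))
  # rendered-frame truth masks: label at T^{-1}(pixel centre), mid-plane z
  ps <- spec$pixel_size_um
  ncol_img <- as.integer(round(2 * half[1] / ps))
  nrow_img <- as.integer(round(2 * half[2] / ps))
  pcx <- -half[1] + (seq_len(ncol_img) - 0.5) * ps
  pcy <- -half[2] + (seq_len(nrow_img) - 0.5) * ps
  gx <- rep(pcx, each = nrow_img)
  gy <- rep(pcy, times = ncol_img)
  section_masks <- lapply(seq_len(n_sec), function(i) {
    inv <- invert_transform(tf[[i]])
    q <- apply_transform(inv, gx, gy)
    iz <- which.min(abs(zs - z_mid[i]))
    ix <- round((q[, 1] - xs[1]) / v) + 1L
    iy <- round((q[, 2] - ys[1]) / v) + 1L
    ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny &
      abs(zs[iz] - z_mid[i]) <= v
    lab <- integer(length(gx))
    lab[ok] <- labels[cbind(ix[ok], iy[ok], iz)]
    matrix(lab, nrow = nrow_img, ncol = ncol_img)
  })
  structure(
    list(spec = spec,
         labels = labels,
         voxel_origin = c(xs[1] - v / 2, ys[1] - v / 2, zs[1] - v / 2),
         true_tuft_volume_um3 = true_tuft,
         true_mesangial_volume_um3 = true_mes,
         true_vv = if (n_tuft > 0 && spec$n_mesangial_blobs > 0L) {
           true_mes / true_tuft
         } else {
           0
         },
         realized_vv = realized_vv,
         section_z_um = z_mid,
         true_transforms = tf,
         fiducial_points = fid,
         section_masks = section_masks,
         image_origin = c(-half[1], -half[2]),
         pixel_size_um = ps),
    class = "glom_phantom"
  )
}

#' @export
print.glom_phantom <- function(x, ...) {
  cat(sprintf(
    "<glomerulus phantom> tuft %.4g um^3, mesangium %.4g um^3 (Vv = %.3f), %d sections\n",
    x$true_tuft_volume_um3, x$true_mesangial_volume_um3, x$true_vv,
    x$spec$n_sections))
  invisible(x)
}

#' Logical compartment masks for each phantom section
#'
#' @param truth A `glom_phantom`.
#' @return A [mask_stack()] with mesangium and tuft masks in the rendered
#'   frame.
#' @export
phantom_section_masks <- function(truth) {
  mask_stack(
    mesangium = lapply(truth$section_masks, function(m) m == 2L),
    tuft = lapply(truth$section_masks, function(m) m >= 1L),
    pixel_size_um = truth$pixel_size_um,
    thickness_um = truth$spec$section_thickness_um,
    origin = truth$image_origin
  )
}

#' Ground-truth contours of a phantom's sections
#'
#' Extracts sub-pixel contours from the truth masks — the measurement an
#' ideal segmenter would produce, useful for isolating estimator error from
#' segmentation error.
#'
#' @param truth A `glom_phantom`.
#' @return A contour table across sections (rendered frame).
#' @export
truth_contours <- function(truth) {
  ps <- truth$pixel_size_um
  res <- lapply(seq_along(truth$section_masks), function(i) {
    m <- truth$section_masks[[i]]
    s <- i - 1L
    tuft <- loops_to_contours(mask_to_loops(m >= 1L, ps), "tuft", s, "t",
                              ps, 0)
    mes <- loops_to_contours(mask_to_loops(m == 2L, ps), "mesangium", s, "m",
                             ps, 0)
    dplyr::bind_rows(tuft, mes)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out)) {
    out$x <- out$x + truth$image_origin[1]
    out$y <- out$y + truth$image_origin[2]
  }
  as_glom_contours(out)
}

#' The true alignment chain of a phantom
#'
#' Composites `T_ref o T_s^{-1}` mapping each rendered section into the
#' reference section's frame — what a perfect registration should recover.
#'
#' @param truth A `glom_phantom`.
#' @param reference_index 0-based reference section (default middle).
#' @return A `glom_alignment`.
#' @export
phantom_true_chain <- function(truth, reference_index = NULL) {
  n <- truth$spec$n_sections
  secs <- 0:(n - 1L)
  if (is.null(reference_index)) reference_index <- secs[ceiling(n / 2)]
  t_ref <- truth$true_transforms[[reference_index + 1L]]
  transforms <- lapply(secs, function(s) {
    compose_transforms(t_ref, invert_transform(truth$true_transforms[[s + 1L]]))
  })
  structure(
    list(reference_index = as.integer(reference_index),
         transforms = stats::setNames(transforms, as.character(secs)),
         rms_um = stats::setNames(rep(0, n - 1L),
                                  as.character(secs[-n]))),
    class = "glom_alignment"
  )
}

#' Render phantom sections as PAS-like RGB images with fiducials
#'
#' Compartment labels become stain concentrations (mesangium: strong PAS;
#' tuft: counterstain-dominant; background: unstained), forward-modelled to
#' RGB through Beer-Lambert absorption with the segmentation module's default
#' stain vectors, plus Gaussian pixel noise. Each section carries the rigid
#' misalignment already recorded in the phantom truth; the four fiducial
#' landmarks are returned as matched coordinate pairs for adjacent sections
#' and optionally drawn as high-contrast dots.
#'
#' @param truth A `glom_phantom`.
#' @param draw_fiducials Draw the fiducial dots into the images (default
#'   `TRUE`).
#' @return A list: `images` (list of `[rows, cols, 3]` arrays, 0..255),
#'   `fiducial_pairs` (tibble consumable by [build_alignment_chain()]),
#'   `fiducial_points` (per-section transformed coordinates),
#'   `pixel_size_um`, `image_origin`.
#' @export
render_sections <- function(truth, draw_fiducials = TRUE) {
  spec <- truth$spec
  with_seed(spec$seed + 1000003L, {
    stains <- stain_model()$stains
    conc <- list(
      background = c(pas = 0, hematoxylin = 0),
      tuft = c(pas = 0.15, hematoxylin = 0.5),
      mes = c(pas = 0.9, hematoxylin = 0.3)
    )
    ps <- truth$pixel_size_um
    fid_by_section <- lapply(truth$true_transforms, function(tf) {
      apply_transform(tf, truth$fiducial_points)
    })
    images <- lapply(seq_along(truth$section_masks), function(i) {
      lab <- truth$section_masks[[i]]
      nrp <- nrow(lab); ncp <- ncol(lab)
      c_pas <- ifelse(lab == 2L, conc$mes["pas"],
                      ifelse(lab == 1L, conc$tuft["pas"], 0))
      c_hem <- ifelse(lab == 2L, conc$mes["hematoxylin"],
                      ifelse(lab == 1L, conc$tuft["hematoxylin"], 0))
      od <- array(0, dim = c(nrp, ncp, 3))
      for (ch in 1:3) {
        od[, , ch] <- c_pas * stains[ch, "pas"] +
          c_hem * stains[ch, "hematoxylin"]
      }
      img <- od_to_rgb(od)
      if (draw_fiducials) {
        fid <- fid_by_section[[i]]
        col_c <- (fid[, 1] - truth$image_origin[1]) / ps + 0.5
        row_c <- (fid[, 2] - truth$image_origin[2]) / ps + 0.5
        rad <- max(1, 0.5 / ps)
        for (k in seq_len(nrow(fid))) {
          rr <- pmax(1L, floor(row_c[k] - rad)):pmin(nrp, ceiling(row_c[k] + rad))
          cc <- pmax(1L, floor(col_c[k] - rad)):pmin(ncp, ceiling(col_c[k] + rad))
          if (!length(rr) || !length(cc)) next
          d2 <- outer((rr - row_c[k])^2, (cc - col_c[k])^2, "+")
          hit <- which(d2 <= rad^2, arr.ind = TRUE)
          if (!nrow(hit)) next
          dot_col <- c(60, 40, 40)
          for (ch in 1:3) {
            img[cbind(rr[hit[, 1]], cc[hit[, 2]], ch)] <- dot_col[ch]
          }
        }
      }
      if (spec$noise_sigma > 0) {
        img <- img + stats::rnorm(length(img), 0, spec$noise_sigma)
      }
      round(pmin(pmax(img, 0), 255))
    })
    pairs <- if (spec$n_sections > 1L) {
      dplyr::bind_rows(lapply(seq_len(spec$n_sections - 1L), function(a) {
        fiducial_pair(a - 1L, a,
                      points_a = fid_by_section[[a]],
                      points_b = fid_by_section[[a + 1L]])
      }))
    } else {
      fiducial_pair(0L, 1L, truth$fiducial_points,
                    truth$fiducial_points)[0, ]
    }
    list(images = images,
         fiducial_pairs = pairs,
         fiducial_points = fid_by_section,
         pixel_size_um = ps,
         image_origin = truth$image_origin)
  })
}

#' Generate a cohort of phantoms at preset group Vv levels
#'
#' Per-phantom targets are drawn Normal(group mean, group SD), truncated to
#' (0.05, 0.95); child seeds derive from the cohort seed by fixed arithmetic
#' (`seed + index`) and are logged in the manifest.
#'
#' @param n_per_group Named integer vector of group sizes.
#' @param group_vv Named numeric vector of group mean Vv levels.
#' @param group_sd Between-phantom SD of Vv per group (same order).
#' @param seed Cohort seed.
#' @param base_spec A [phantom_spec()] supplying every non-Vv parameter.
#' @return A list with `truths` (list of `glom_phantom`) and `manifest`
#'   (tibble: phantom_id, group, child_seed, target_vv, realized Vv and true
#'   volumes).
#' @export
generate_cohort <- function(n_per_group = c(normo = 8L, micro = 6L, macro = 8L),
                            group_vv = c(normo = 0.47, micro = 0.53,
                                         macro = 0.76),
                            group_sd = c(normo = 0.15, micro = 0.09,
                                         macro = 0.08),
                            seed = 1L,
                            base_spec = phantom_spec()) {
  stopifnot(all(group_vv > 0 & group_vv < 1),
            length(n_per_group) == length(group_vv))
  groups <- rep(names(n_per_group), times = n_per_group)
  targets <- with_seed(seed, {
    vapply(groups, function(g) {
      repeat {
        x <- stats::rnorm(1, group_vv[[g]], group_sd[[g]])
        if (x > 0.05 && x < 0.95) return(x)
      }
    }, numeric(1))
  })
  truths <- vector("list", length(groups))
  rows <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    sp <- base_spec
    sp$target_vv <- targets[i]
    sp$seed <- as.integer(seed + i)
    truths[[i]] <- generate_phantom(sp)
    rows[[i]] <- tibble(
      phantom_id = sprintf("p%03d", i),
      group = groups[i],
      child_seed = sp$seed,
      target_vv = targets[i],
      true_vv = truths[[i]]$true_vv,
      true_tuft_volume_um3 = truths[[i]]$true_tuft_volume_um3,
      true_mesangial_volume_um3 = truths[[i]]$true_mesangial_volume_um3
    )
  }
  list(truths = truths, manifest = dplyr::bind_rows(rows))
}
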