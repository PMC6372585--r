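#' Segmentation of PAS-stained sections by colour deconvolution
#'
#' PAS stains mesangial matrix magenta against a haematoxylin counterstain.
#' Segmentation converts RGB to optical density, unmixes the stain
#' contributions by least squares against a stain matrix, thresholds the
#' PAS-positive channel (Otsu by default), cleans the binary masks
#' morphologically and extracts sub-pixel contours at the 0.5 iso-level.
#'
#' @name segmentation
NULL

#' Stain model for PAS / haematoxylin unmixing
#'
#' Default optical-density stain vectors are the published PAS and
#' haematoxylin unmixing vectors; the residual axis is their cross product.
#' Real slides should be calibrated: all parameters are overridable.
#'
#' @param pas,hematoxylin Length-3 OD-space stain vectors (normalized
#'   internally).
#' @param od_threshold PAS-channel OD threshold for mesangium; `NULL` (default)
#'   means automatic Otsu thresholding per section.
#' @param tissue_od_min Total-OD floor distinguishing tissue from background
#'   (OD units).
#' @param min_region_area_um2 Mesangial regions smaller than this are
#'   discarded (um^2).
#' @param morphology_radius_um Disc radius for binary opening + closing of the
#'   mesangial mask (um).
#' @param tuft_close_radius_um Disc radius for the morphological closing that
#'   defines the outer tuft boundary from the union of tissue-positive pixels
#'   (um).
#' @return A `glom_stain_model` list.
#' @export
stain_model <- function(pas = c(0.175, 0.972, 0.154),
                        hematoxylin = c(0.644, 0.717, 0.267),
                        od_threshold = NULL,
                        tissue_od_min = 0.1,
                        min_region_area_um2 = 5,
                        morphology_radius_um = 0.5,
                        tuft_close_radius_um = 2) {
  unit <- function(v) v / sqrt(sum(v^2))
  pas <- unit(pas)
  hematoxylin <- unit(hematoxylin)
  if (abs(sum(pas * hematoxylin)) > 1 - 1e-6) {
    abort("Stain vectors are collinear; the stain matrix is singular.",
          class = "glom_collinear_stains")
  }
  residual <- unit(c(
    pas[2] * hematoxylin[3] - pas[3] * hematoxylin[2],
    pas[3] * hematoxylin[1] - pas[1] * hematoxylin[3],
    pas[1] * hematoxylin[2] - pas[2] * hematoxylin[1]
  ))
  structure(
    list(stains = cbind(pas = pas, hematoxylin = hematoxylin,
                        residual = residual),
         od_threshold = od_threshold,
         tissue_od_min = tissue_od_min,
         min_region_area_um2 = min_region_area_um2,
         morphology_radius_um = morphology_radius_um,
         tuft_close_radius_um = tuft_close_radius_um),
    class = "glom_stain_model"
  )
}

#' Convert an 8-bit RGB image to optical density
#'
#' Per-channel OD = -log10((I + 1) / 256), so a pure white pixel maps to
#' OD ~ 0 and black to OD ~ 2.4.
#'
#' @param img Numeric array `[rows, cols, 3]` with values in 0..255.
#' @return Array of the same shape holding OD values.
#' @export
rgb_to_od <- function(img) {
  -log10((img + 1) / 256)
}

od_to_rgb <- function(od) {
  256 * 10^(-od) - 1
}

#' Unmix stain contributions from an RGB section image
#'
#' Least-squares projection of each pixel's OD vector onto the stain matrix;
#' negative coefficients are clipped at zero.
#'
#' @param img Numeric array `[rows, cols, 3]`, 8-bit scale (0..255).
#' @param model A [stain_model()].
#' @return Array `[rows, cols, n_stains]` of per-stain concentrations, with
#'   stain names on the third dimension.
#' @export
separate_stains <- function(img, model = stain_model()) {
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L) abort("`img` must be rows x cols x 3.")
  S <- model$stains
  od <- matrix(rgb_to_od(img), ncol = 3L) # pixels x channels
  # least squares: coef = od %*% S (S^T S)^-1, then clip
  M <- S %*% solve(crossprod(S))
  coef <- od %*% M
  coef[coef < 0] <- 0
  array(coef, dim = c(d[1], d[2], ncol(S)),
        dimnames = list(NULL, NULL, colnames(S)))
}

#' Otsu threshold on an optical-density channel
#'
#' Histogram with 256 bins over the observed range; returns the bin edge
#' minimizing within-class variance (equivalently maximizing between-class
#' variance). Deterministic for a fixed input, and shift-equivariant because
#' the bins follow the observed range.
#'
#' @param v Numeric vector (or matrix) of channel values; must not be
#'   constant.
#' @return The threshold value; pixels with value > threshold form the
#'   positive class.
#' @export
otsu_threshold <- function(v) {
  v <- as.numeric(v)
  v <- v[is.finite(v)]
  r <- range(v)
  if (diff(r) <= 0) {
    abort("Channel is constant: no contrast to threshold.",
          class = "glom_no_contrast")
  }
  nbins <- 256L
  edges <- seq(r[1], r[2], length.out = nbins + 1L)
  counts <- tabulate(
    pmin(nbins, pmax(1L, findInterval(v, edges, rightmost.closed = TRUE))),
    nbins
  )
  mids <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  total_w <- w[nbins]
  total_m <- m[nbins]
  w0 <- w[-nbins]
  w1 <- total_w - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m[-nbins] / w0
  mu1 <- (total_m - m[-nbins]) / w1
  between <- w0 * w1 * (mu0 - mu1)^2
  between[!valid] <- -Inf
  k <- which.max(between)
  edges[k + 1L]
}

disc_brush <- function(radius_px) {
  EBImage::makeBrush(2L * radius_px + 1L, shape = "disc")
}

clean_mask <- function(mask, radius_px) {
  if (radius_px < 1L) return(mask)
  b <- disc_brush(radius_px)
  m <- EBImage::closing(EBImage::opening(mask + 0, b), b)
  m > 0
}

# Marching-squares contours of a binary mask at the 0.5 iso-level, in um.
# The mask is zero-padded so boundary-touching regions still close.
mask_to_loops <- function(mask, pixel_size_um) {
  nr <- nrow(mask); nc <- ncol(mask)
  z <- matrix(0, nr + 2L, nc + 2L)
  z[2:(nr + 1L), 2:(nc + 1L)] <- mask
  xs <- (seq_len(nc + 2L) - 1.5) * pixel_size_um # padded col centers
  ys <- (seq_len(nr + 2L) - 1.5) * pixel_size_um
  cl <- grDevices::contourLines(x = xs, y = ys, z = t(z), levels = 0.5)
  lapply(cl, function(l) {
    x <- l$x; y <- l$y
    n <- length(x)
    if (n > 1 && x[1] == x[n] && y[1] == y[n]) {
      x <- x[-n]; y <- y[-n]
    }
    cbind(x = x, y = y)
  })
}

# Ramer-Douglas-Peucker polyline simplification (closed polygon; the first
# vertex is kept as an anchor).
simplify_polygon <- function(x, y, tol) {
  n <- length(x)
  if (n <= 4L || tol <= 0) return(cbind(x = x, y = y))
  keep <- logical(n)
  rdp <- function(i, j) {
    keep[i] <<- TRUE; keep[j] <<- TRUE
    if (j <= i + 1L) return(invisible())
    idx <- (i + 1L):(j - 1L)
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    len <- sqrt(dx^2 + dy^2)
    d <- if (len < 1e-12) {
      sqrt((x[idx] - x[i])^2 + (y[idx] - y[i])^2)
    } else {
      abs(dx * (y[idx] - y[i]) - dy * (x[idx] - x[i])) / len
    }
    k <- idx[which.max(d)]
    if (max(d) > tol) {
      rdp(i, k); rdp(k, j)
    }
    invisible()
  }
  mid <- 1L + (n %/% 2L)
  rdp(1L, mid)
  rdp(mid, n)
  cbind(x = x[keep], y = y[keep])
}

loops_to_contours <- function(loops, compartment, section_index, prefix,
                              pixel_size_um, min_area_um2) {
  out <- list()
  k <- 0L
  for (l in loops) {
    s <- simplify_polygon(l[, 1], l[, 2], tol = 0.25 * pixel_size_um)
    if (nrow(s) < 3L) next
    a <- tryCatch(polygon_area(s[, 1], s[, 2]), error = function(e) 0)
    if (a < min_area_um2) next
    k <- k + 1L
    out[[k]] <- contour(s[, 1], s[, 2], compartment = compartment,
                        section_index = section_index,
                        contour_id = paste0(prefix, k),
                        check_simple = FALSE)
  }
  if (!length(out)) return(empty_contours())
  as_glom_contours(dplyr::bind_rows(out))
}

empty_contours <- function() {
  as_glom_contours(tibble(
    section_index = integer(), contour_id = character(),
    compartment = character(), x = numeric(), y = numeric()
  ))
}

#' Segment mesangium and tuft compartments on one section image
#'
#' Pipeline: colour deconvolution, PAS-channel threshold (Otsu over tissue
#' pixels unless the model fixes one), morphological opening + closing of the
#' mesangial mask, tuft defined as the largest connected component of the
#' morphologically closed tissue mask (holes filled), contours extracted at
#' the 0.5 iso-level with sub-pixel interpolation and simplified with
#' tolerance `0.25 * pixel_size_um`. Mesangium is restricted to the tuft, and
#' mesangial regions below the model's minimum area are dropped.
#'
#' @param img Numeric array `[rows, cols, 3]`, 0..255.
#' @param pixel_size_um Pixel size in um (uniform in both axes).
#' @param section_index Section index recorded on the output contours.
#' @param model A [stain_model()].
#' @return A contour table (possibly empty if the image holds no tissue), with
#'   attributes `masks` (list of logical matrices `mesangium`, `tuft`) and
#'   `od_threshold` (the threshold actually used).
#' @export
segment_section <- function(img, pixel_size_um, section_index = 0L,
                            model = stain_model()) {
  stopifnot_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  conc <- separate_stains(img, model)
  pas <- conc[, , "pas"]
  total_od <- pas + conc[, , "hematoxylin"]
  tissue <- total_od >= model$tissue_od_min
  if (!any(tissue)) {
    res <- empty_contours()
    attr(res, "masks") <- list(
      mesangium = matrix(FALSE, nrow(pas), ncol(pas)),
      tuft = matrix(FALSE, nrow(pas), ncol(pas))
    )
    attr(res, "od_threshold") <- NA_real_
    return(res)
  }
  thr <- model$od_threshold
  if (is.null(thr)) thr <- otsu_threshold(pas[tissue])
  mes <- pas >= thr
  if (mean(mes) > 0.5) {
    warn(sprintf(
      "PAS threshold %.3g marks %.0f%% of the image positive; possible miscalibration.",
      thr, 100 * mean(mes)))
  }
  mes <- clean_mask(mes, as.integer(round(model$morphology_radius_um / pixel_size_um)))
  mes <- EBImage::fillHull(mes + 0) > 0
  # tuft: largest connected component of the closed tissue union, filled
  close_px <- max(1L, as.integer(round(model$tuft_close_radius_um / pixel_size_um)))
  tuft <- EBImage::closing(tissue + 0, disc_brush(close_px)) > 0
  tuft <- EBImage::fillHull(tuft + 0) > 0
  lab <- EBImage::bwlabel(tuft + 0)
  if (max(lab) >= 1L) {
    sizes <- tabulate(lab[lab > 0])
    tuft <- lab == which.max(sizes)
  }
  mes <- mes & tuft
  mes_contours <- loops_to_contours(
    mask_to_loops(mes, pixel_size_um), "mesangium", section_index, "m",
    pixel_size_um, model$min_region_area_um2
  )
  tuft_contours <- loops_to_contours(
    mask_to_loops(tuft, pixel_size_um), "tuft", section_index, "t",
    pixel_size_um, min_area_um2 = 0
  )
  res <- as_glom_contours(dplyr::bind_rows(tuft_contours, mes_contours))
  attr(res, "masks") <- list(mesangium = mes, tuft = tuft)
  attr(res, "od_threshold") <- thr
  res
}

#' Segment a stack of section images
#'
#' @param images List of RGB arrays (one per section, in section order).
#' @param pixel_size_um Pixel size in um.
#' @param model A [stain_model()].
#' @param section_indices Integer indices for the sections (default 0-based
#'   order).
#' @return A combined contour table across sections; per-section masks are not
#'   retained (use [segment_section()] for mask-level access).
#' @export
segment_stack <- function(images, pixel_size_um, model = stain_model(),
                          section_indices = seq_along(images) - 1L) {
  res <- purrr::map2(images, section_indices, function(img, s) {
    segment_section(img, pixel_size_um, section_index = s, model = model)
  })
  as_glom_contours(dplyr::bind_rows(res))
}

#' Dice overlap between two binary masks
#'
#' @param a,b Logical matrices of identical shape.
#' @return 2|A n B| / (|A| + |B|); 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
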