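#' Stereological volume estimation: Cavalieri point counting and PSI
#'
#' The Cavalieri principle gives an object's volume as section thickness
#' times the summed section areas over systematic parallel sections; areas
#' are estimated by counting hits of a systematic uniform random (SUR) point
#' grid, each point representing `a_p = spacing^2` of area. The PSI
#' (point-sampled-intercept) fractional volume Vv(mes/glom) is the ratio of
#' mesangial hits to tuft hits pooled over sections.
#'
#' @name stereology
NULL

#' Systematic uniform random point grid
#'
#' Points sit at `(ox + i s, oy + j s)` over the extent; the offset is drawn
#' uniformly from `[0, s)^2` under the given seed (SUR sampling, the classic
#' unbiasedness device), or can be fixed for exact-reproducibility runs.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in um.
#' @param spacing_um Grid pitch s in um; area per point is `s^2`.
#' @param seed Integer seed for the offset draw (ignored when `offset` given).
#' @param offset Optional fixed `c(ox, oy)` in `[0, s)^2`.
#' @return A `glom_grid` object.
#' @export
point_grid <- function(extent, spacing_um, seed = NULL, offset = NULL) {
  stopifnot_scalar_num(spacing_um, "spacing_um", positive = TRUE)
  if (length(extent) != 4L || extent[2] <= extent[1] || extent[4] <= extent[3]) {
    abort("`extent` must be c(xmin, xmax, ymin, ymax) with positive spans.")
  }
  if (spacing_um > (extent[2] - extent[1]) &&
      spacing_um > (extent[4] - extent[3])) {
    abort("Grid spacing exceeds both extent dimensions: empty grid.",
          class = "glom_empty_grid")
  }
  if (is.null(offset)) {
    offset <- with_seed(seed, stats::runif(2, 0, spacing_um))
  }
  if (any(offset < 0) || any(offset >= spacing_um)) {
    abort("`offset` must lie in [0, spacing)^2.")
  }
  structure(
    list(spacing_um = spacing_um, offset = offset, extent = extent,
         seed = seed),
    class = "glom_grid"
  )
}

#' Materialize the points of a grid
#'
#' @param grid A [point_grid()].
#' @return A tibble with columns `x`, `y` (um).
#' @export
grid_points <- function(grid) {
  s <- grid$spacing_um
  e <- grid$extent
  # half-open extent: a point on the upper edge belongs to the next tile
  xs <- seq(e[1] + grid$offset[1], e[2], by = s)
  ys <- seq(e[3] + grid$offset[2], e[4], by = s)
  xs <- xs[xs < e[2]]
  ys <- ys[ys < e[4]]
  tibble(x = rep(xs, times = length(ys)), y = rep(ys, each = length(xs)))
}

classify_against_polys <- function(px, py, polys, tol = 1e-9) {
  status <- rep("outside", length(px))
  for (p in polys) {
    cls <- point_in_polygon(px, py, p$x, p$y, tol = tol)
    status[cls == "boundary" & status == "outside"] <- "boundary"
    status[cls == "inside"] <- "inside"
  }
  status
}

count_rule_weights <- function(status, rule) {
  switch(rule,
    half = sum(status == "inside") + 0.5 * sum(status == "boundary"),
    interior = sum(status == "inside"),
    inclusive = sum(status != "outside"),
    abort("Unknown counting rule.")
  )
}

#' Bundle per-section compartment masks with their physical metadata
#'
#' A raster alternative to contour input for the counting estimators: grid
#' points are classified by nearest-pixel lookup (a pixel covers the
#' half-open square starting at its lower corner).
#'
#' @param mesangium List of logical matrices, one per section.
#' @param tuft List of logical matrices (reference compartment); defaults to
#'   `mesangium` when the object has a single compartment.
#' @param pixel_size_um Pixel size in um.
#' @param thickness_um Section thickness in um.
#' @param origin `c(x0, y0)` of the raster's lower pixel corner, in um.
#' @param section_indices Integer section indices (default 0-based order).
#' @return A `glom_mask_stack`.
#' @export
mask_stack <- function(mesangium, tuft = NULL, pixel_size_um, thickness_um,
                       origin = c(0, 0),
                       section_indices = seq_along(mesangium) - 1L) {
  tuft <- tuft %||% mesangium
  stopifnot(length(tuft) == length(mesangium))
  structure(
    list(mesangium = mesangium, tuft = tuft,
         pixel_size_um = pixel_size_um, thickness_um = thickness_um,
         origin = origin, section_indices = as.integer(section_indices)),
    class = "glom_mask_stack"
  )
}

mask_lookup <- function(mask, px, py, pixel_size_um, origin) {
  col <- floor((px - origin[1]) / pixel_size_um) + 1L
  row <- floor((py - origin[2]) / pixel_size_um) + 1L
  ok <- col >= 1L & col <= ncol(mask) & row >= 1L & row <= nrow(mask)
  out <- rep(FALSE, length(px))
  out[ok] <- mask[cbind(row[ok], col[ok])]
  out
}

mask_stack_extent <- function(stack) {
  nr <- nrow(stack$mesangium[[1]])
  nc <- ncol(stack$mesangium[[1]])
  c(stack$origin[1], stack$origin[1] + nc * stack$pixel_size_um,
    stack$origin[2], stack$origin[2] + nr * stack$pixel_size_um)
}

contour_stack_extent <- function(contours, pad) {
  ref <- contours[contours$compartment == "tuft", , drop = FALSE]
  if (nrow(ref) == 0L) ref <- contours
  c(min(ref$x) - pad, max(ref$x) + pad, min(ref$y) - pad, max(ref$y) + pad)
}

#' Count grid hits per section and compartment
#'
#' The shared counting engine behind [cavalieri_volume()] and
#' [psi_fractional_volume()]. For contour input, points are classified with
#' [point_in_polygon()]; the default Gundersen rule counts boundary points as
#' one half.
#'
#' @param x A contour table or a [mask_stack()].
#' @param grid A [point_grid()]; for contour input `NULL` builds one over the
#'   tuft bounding box padded by one spacing.
#' @param spacing_um,seed,offset Used to build the grid when `grid` is `NULL`.
#' @param rule Counting rule: `"half"` (boundary counts 1/2), `"interior"`,
#'   or `"inclusive"`.
#' @return A tibble `(section_index, p_mes, p_ref)` with attributes `grid` and
#'   `a_p_um2`.
#' @export
count_grid_hits <- function(x, grid = NULL, spacing_um = NULL, seed = NULL,
                            offset = NULL, rule = c("half", "interior",
                                                    "inclusive")) {
  rule <- match.arg(rule)
  if (inherits(x, "glom_mask_stack")) {
    if (is.null(grid)) {
      grid <- point_grid(mask_stack_extent(x), spacing_um, seed = seed,
                         offset = offset)
    }
    pts <- grid_points(grid)
    counts <- purrr::map2_dfr(
      seq_along(x$mesangium), x$section_indices,
      function(i, s) {
        tibble(
          section_index = s,
          p_mes = sum(mask_lookup(x$mesangium[[i]], pts$x, pts$y,
                                  x$pixel_size_um, x$origin)),
          p_ref = sum(mask_lookup(x$tuft[[i]], pts$x, pts$y,
                                  x$pixel_size_um, x$origin))
        )
      })
  } else {
    if (is.null(grid)) {
      grid <- point_grid(contour_stack_extent(x, spacing_um), spacing_um,
                         seed = seed, offset = offset)
    }
    pts <- grid_points(grid)
    counts <- purrr::map_dfr(sort(unique(x$section_index)), function(s) {
      mes_polys <- section_polys(x[x$compartment == "mesangium", ], s)
      ref_polys <- section_polys(x[x$compartment == "tuft", ], s)
      tibble(
        section_index = s,
        p_mes = count_rule_weights(
          classify_against_polys(pts$x, pts$y, mes_polys), rule),
        p_ref = count_rule_weights(
          classify_against_polys(pts$x, pts$y, ref_polys), rule)
      )
    })
  }
  attr(counts, "grid") <- grid
  attr(counts, "a_p_um2") <- grid$spacing_um^2
  counts
}

#' Cavalieri point-count volume estimate
#'
#' `V = t * a_p * sum(P)` over sections, with `a_p = spacing^2` and P the
#' per-section grid hits on the chosen compartment.
#'
#' @inheritParams count_grid_hits
#' @param compartment `"mesangium"` or `"tuft"` — which hit count enters the
#'   estimator.
#' @param thickness_um Uniform section thickness t in um (taken from a
#'   [mask_stack()] when omitted).
#' @return A list with `volume_um3`, the per-section `counts` tibble, and the
#'   `grid` used.
#' @export
cavalieri_volume <- function(x, grid = NULL, spacing_um = NULL, seed = NULL,
                             offset = NULL,
                             compartment = c("mesangium", "tuft"),
                             thickness_um = NULL,
                             rule = c("half", "interior", "inclusive")) {
  compartment <- match.arg(compartment)
  rule <- match.arg(rule)
  if (is.null(thickness_um)) {
    if (inherits(x, "glom_mask_stack")) {
      thickness_um <- x$thickness_um
    } else {
      abort("`thickness_um` is required for contour input.")
    }
  }
  if (length(thickness_um) != 1L) {
    abort("Sections must share one thickness.", class = "glom_mixed_thickness")
  }
  counts <- count_grid_hits(x, grid = grid, spacing_um = spacing_um,
                            seed = seed, offset = offset, rule = rule)
  p <- if (compartment == "mesangium") counts$p_mes else counts$p_ref
  list(
    volume_um3 = thickness_um * attr(counts, "a_p_um2") * sum(p),
    counts = counts,
    grid = attr(counts, "grid")
  )
}

#' PSI fractional volume Vv(mes/glom)
#'
#' `Vv = sum(P_mes) / sum(P_ref)` pooled over the supplied sections (use a
#' single mid-glomerular section or the full serial stack; the output records
#' which via `n_sections`).
#'
#' @inheritParams count_grid_hits
#' @return A list with `vv`, `n_sections`, the per-section `counts` tibble,
#'   and the `grid` used.
#' @export
psi_fractional_volume <- function(x, grid = NULL, spacing_um = NULL,
                                  seed = NULL, offset = NULL,
                                  rule = c("half", "interior", "inclusive")) {
  rule <- match.arg(rule)
  counts <- count_grid_hits(x, grid = grid, spacing_um = spacing_um,
                            seed = seed, offset = offset, rule = rule)
  if (sum(counts$p_ref) <= 0) {
    abort("No reference (tuft) hits: Vv undefined.",
          class = "glom_undefined_fraction")
  }
  list(
    vv = sum(counts$p_mes) / sum(counts$p_ref),
    n_sections = nrow(counts),
    counts = counts,
    grid = attr(counts, "grid")
  )
}

#' Planimetry of traced mesangial profiles
#'
#' The TEM-style comparator: per-profile areas are measured directly from
#' traced polygons, averaged, and converted to a volume either by extrusion
#' (`V = mean area x t_equiv`) or by the Weibel-Gomez shape model
#' (`V = (beta / k) * mean_area^(3/2)` with `beta = 1.38`, `k = 1.1`).
#' Each section index in the input is one profile; all polygon pieces on a
#' profile are summed.
#'
#' @param profiles Contour table of mesangial tracings; `section_index`
#'   identifies the profile.
#' @param volume_model `"extrusion"` (default) or `"weibel_gomez"`.
#' @param t_equiv_um Equivalent thickness for the extrusion model (um).
#' @return A one-row tibble: `n_profiles`, `mean_mesangial_area_um2`,
#'   `estimated_volume_um3`, `volume_model`, plus a `profile_areas_um2`
#'   list-column.
#' @export
planimetry <- function(profiles, volume_model = c("extrusion", "weibel_gomez"),
                       t_equiv_um = NULL) {
  volume_model <- match.arg(volume_model)
  if (!is.data.frame(profiles) || nrow(profiles) == 0L) {
    abort("No profiles supplied.", class = "glom_no_profiles")
  }
  areas <- contour_areas(profiles) |>
    dplyr::group_by(.data$section_index) |>
    dplyr::summarise(area_um2 = sum(.data$area_um2), .groups = "drop")
  mean_area <- mean(areas$area_um2)
  vol <- switch(volume_model,
    extrusion = {
      if (is.null(t_equiv_um)) {
        abort("`t_equiv_um` is required for the extrusion model.")
      }
      mean_area * t_equiv_um
    },
    weibel_gomez = (1.38 / 1.1) * mean_area^1.5
  )
  tibble(
    n_profiles = nrow(areas),
    mean_mesangial_area_um2 = mean_area,
    estimated_volume_um3 = vol,
    volume_model = volume_model,
    profile_areas_um2 = list(areas$area_um2)
  )
}

#' Erode binary masks by a pixel radius
#'
#' Utility for bias experiments: conservative boundary handling in point
#' counting is emulated by eroding the positive mask before counting.
#'
#' @param masks A logical matrix or list of logical matrices.
#' @param px Erosion radius in pixels (box structuring element of side
#'   `2 px + 1`).
#' @return Eroded mask(s) of the same shape.
#' @export
erode_masks <- function(masks, px = 1L) {
  er <- function(m) {
    EBImage::erode(m + 0, EBImage::makeBrush(2L * px + 1L, "box")) > 0
  }
  if (is.list(masks)) lapply(masks, er) else er(masks)
}
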