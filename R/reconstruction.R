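#' Serial-section 3D reconstruction by prism extrusion
#'
#' Each traced contour on section i is extruded into a right prism spanning
#' z in `[i t, (i+1) t]` (the Cavalieri slab convention), so the mesh volume
#' is exactly the sum of contour areas times section thickness — the volume
#' model implicit in reconstructing a small number of serial sections, whose
#' shape "resembles a cylinder". Contours are never interpolated between
#' planes.
#'
#' @name reconstruction
NULL

# Ear-clipping triangulation of a simple CCW polygon; returns an (n-2) x 3
# matrix of vertex indices into the input.
triangulate_polygon <- function(x, y) {
  n <- length(x)
  if (n == 3L) return(matrix(1:3, nrow = 1L))
  # convex fast path: fan triangulation
  nx <- c(2:n, 1L); pv <- c(n, 1:(n - 1L))
  cz_all <- (x - x[pv]) * (y[nx] - y[pv]) - (y - y[pv]) * (x[nx] - x[pv])
  if (all(cz_all >= 0)) {
    return(cbind(1L, 2:(n - 1L), 3:n))
  }
  idx <- seq_len(n)
  tris <- matrix(0L, n - 2L, 3L)
  k <- 0L
  cross_z <- function(a, b, c) {
    (x[b] - x[a]) * (y[c] - y[a]) - (y[b] - y[a]) * (x[c] - x[a])
  }
  in_tri <- function(a, b, c, p) {
    d1 <- cross_z(a, b, p)
    d2 <- cross_z(b, c, p)
    d3 <- cross_z(c, a, p)
    (d1 >= 0 & d2 >= 0 & d3 >= 0)
  }
  guard <- 0L
  while (length(idx) > 3L) {
    m <- length(idx)
    clipped <- FALSE
    for (j in seq_len(m)) {
      a <- idx[(j - 2L) %% m + 1L]
      b <- idx[(j - 1L) %% m + 1L]
      c <- idx[j %% m + 1L]
      if (cross_z(a, b, c) <= 0) next # reflex or degenerate corner
      others <- setdiff(idx, c(a, b, c))
      if (length(others) && any(in_tri(a, b, c, others))) next
      k <- k + 1L
      tris[k, ] <- c(a, b, c)
      idx <- idx[idx != b]
      clipped <- TRUE
      break
    }
    if (!clipped) {
      # numerical fallback: clip the most convex corner unconditionally
      cz <- vapply(seq_len(m), function(j) {
        cross_z(idx[(j - 2L) %% m + 1L], idx[(j - 1L) %% m + 1L],
                idx[j %% m + 1L])
      }, numeric(1))
      j <- which.max(cz)
      k <- k + 1L
      tris[k, ] <- c(idx[(j - 2L) %% m + 1L], idx[(j - 1L) %% m + 1L],
                     idx[j %% m + 1L])
      idx <- idx[-((j - 1L) %% m + 1L)]
    }
    guard <- guard + 1L
    if (guard > n * n) abort("Triangulation failed to terminate.")
  }
  k <- k + 1L
  tris[k, ] <- idx
  tris[seq_len(k), , drop = FALSE]
}

# One extruded prism for a CCW polygon between z0 and z1; returns vertices
# and outward-oriented faces.
prism_mesh <- function(x, y, z0, z1) {
  n <- length(x)
  verts <- rbind(cbind(x, y, z0), cbind(x, y, z1))
  tris <- triangulate_polygon(x, y)
  bottom <- tris[, c(1L, 3L, 2L), drop = FALSE]      # normal -z
  top <- tris + n                                     # normal +z
  nxt <- c(2:n, 1L)
  side1 <- cbind(seq_len(n), nxt, nxt + n)            # outward for CCW
  side2 <- cbind(seq_len(n), nxt + n, seq_len(n) + n)
  list(vertices = verts, faces = rbind(bottom, top, side1, side2))
}

new_mesh <- function(vertices, faces, compartment,
                     volume_um3, surface_area_um2) {
  structure(
    list(vertices = vertices, faces = faces, compartment = compartment,
         volume_um3 = volume_um3, surface_area_um2 = surface_area_um2),
    class = "glom_mesh"
  )
}

#' @export
print.glom_mesh <- function(x, ...) {
  cat(sprintf(
    "<surface mesh: %s> %d vertices, %d faces, volume %.6g um^3, surface %.6g um^2\n",
    x$compartment, nrow(x$vertices), nrow(x$faces), x$volume_um3,
    x$surface_area_um2))
  invisible(x)
}

#' Signed (divergence-theorem) volume of a triangle mesh
#'
#' @param mesh A `glom_mesh`, or a list with `vertices` and `faces`.
#' @return Signed volume in um^3 (positive for outward-oriented meshes).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Total face area of a triangle mesh
#'
#' @inheritParams mesh_volume
#' @return Sum of triangle areas in um^2.
#' @export
mesh_face_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  ab <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  ac <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2]
  cy <- ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3]
  cz <- ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Check that a mesh is watertight and consistently oriented
#'
#' Every undirected edge must be shared by exactly two faces, traversed once
#' in each direction (edge-manifold, consistently outward-oriented closed
#' surface, possibly with several connected components).
#'
#' @inheritParams mesh_volume
#' @return `TRUE` or `FALSE`.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e_from <- c(f[, 1], f[, 2], f[, 3])
  e_to <- c(f[, 2], f[, 3], f[, 1])
  directed <- paste(e_from, e_to)
  if (anyDuplicated(directed)) return(FALSE)
  undirected <- paste(pmin(e_from, e_to), pmax(e_from, e_to))
  all(table(undirected) == 2L)
}

# union area of polygons (x/y list) sampled on a raster; polys assumed
# disjoint or overlapping arbitrarily
raster_overlap_area <- function(polys_a, polys_b, res_um) {
  all_x <- unlist(lapply(c(polys_a, polys_b), function(p) p$x))
  all_y <- unlist(lapply(c(polys_a, polys_b), function(p) p$y))
  xr <- range(all_x); yr <- range(all_y)
  gx <- seq(xr[1] + res_um / 2, xr[2], by = res_um)
  gy <- seq(yr[1] + res_um / 2, yr[2], by = res_um)
  if (!length(gx) || !length(gy)) return(0)
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  in_union <- function(polys) {
    acc <- rep(FALSE, length(px))
    for (p in polys) {
      acc <- acc | point_in_polygon(px, py, p$x, p$y, tol = 0) != "outside"
    }
    acc
  }
  sum(in_union(polys_a) & in_union(polys_b)) * res_um^2
}

section_polys <- function(contours, sec) {
  df <- contours[contours$section_index == sec, , drop = FALSE]
  lapply(split(df, df$contour_id), function(d) list(x = d$x, y = d$y))
}

same_poly_set <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  sig <- function(p) paste(signif(c(p$x, p$y), 12), collapse = ",")
  setequal(vapply(a, sig, character(1)), vapply(b, sig, character(1)))
}

#' Reconstruct a watertight prism mesh from an aligned contour stack
#'
#' @param contours A contour table (already aligned into one frame).
#' @param thickness_um Uniform section thickness t in um.
#' @param compartment Which compartment to mesh (`"mesangium"` or `"tuft"`).
#' @param surface_raster_um Grid resolution for estimating the overlap of
#'   adjacent sections when computing the exposed (external) cap area;
#'   `NULL` chooses 1/96 of the stack's bounding-box diagonal. Identical
#'   adjacent contour sets are detected and handled exactly.
#' @param union_surface If `TRUE` (default) the reported surface area counts
#'   only the externally exposed top/bottom caps of the stacked union
#'   (raster-estimated); if `FALSE` every prism contributes both caps in
#'   full (component-sum convention, cheap and exact per prism). The
#'   convention in force is recorded in the mesh's `surface_convention`
#'   field. Volume is unaffected.
#' @return A `glom_mesh`. The recorded `volume_um3` is the exact per-prism
#'   (divergence-theorem) volume, equal to the sum of contour areas times
#'   thickness. `surface_area_um2` is lateral wall area (perimeter x t) plus
#'   the estimated exposed top/bottom cap area of the stacked union.
#' @export
reconstruct_mesh <- function(contours, thickness_um,
                             compartment = c("mesangium", "tuft"),
                             surface_raster_um = NULL,
                             union_surface = TRUE) {
  compartment <- match.arg(compartment)
  stopifnot_scalar_num(thickness_um, "thickness_um", positive = TRUE)
  df <- contours[contours$compartment == compartment, , drop = FALSE]
  if (nrow(df) == 0L) {
    abort(sprintf("No %s contours to reconstruct.", compartment),
          class = "glom_no_geometry")
  }
  secs <- sort(unique(df$section_index))
  verts <- list(); faces <- list()
  off <- 0L
  lateral <- 0
  polys_by_sec <- lapply(secs, function(s) section_polys(df, s))
  areas_by_sec <- numeric(length(secs))
  for (si in seq_along(secs)) {
    s <- secs[si]
    z0 <- s * thickness_um
    z1 <- (s + 1) * thickness_um
    for (cid in names(polys_by_sec[[si]])) {
      p <- polys_by_sec[[si]][[cid]]
      if (!is_simple_polygon(p$x, p$y)) {
        abort(sprintf(
          "Self-intersecting contour '%s' on section %d.", cid, s),
          class = "glom_degenerate_geometry")
      }
      areas_by_sec[si] <- areas_by_sec[si] + polygon_area(p$x, p$y)
      lateral <- lateral + polygon_perimeter(p$x, p$y) * thickness_um
      pm <- prism_mesh(p$x, p$y, z0, z1)
      verts[[length(verts) + 1L]] <- pm$vertices
      faces[[length(faces) + 1L]] <- pm$faces + off
      off <- off + nrow(pm$vertices)
    }
  }
  vertices <- do.call(rbind, verts)
  faces <- do.call(rbind, faces)
  # exposed caps: full area minus the raster-estimated overlap with the
  # neighbouring section (consecutive section indices only)
  if (is.null(surface_raster_um)) {
    dx <- diff(range(df$x)); dy <- diff(range(df$y))
    surface_raster_um <- max(sqrt(dx^2 + dy^2) / 96, 1e-6)
  }
  caps <- 0
  for (si in seq_along(secs)) {
    for (nb in c(si - 1L, si + 1L)) {
      adjacent <- nb >= 1L && nb <= length(secs) &&
        abs(secs[nb] - secs[si]) == 1L
      overlap <- 0
      if (adjacent && union_surface) {
        pa <- polys_by_sec[[si]]
        pb <- polys_by_sec[[nb]]
        overlap <- if (same_poly_set(pa, pb)) {
          areas_by_sec[si]
        } else {
          raster_overlap_area(pa, pb, surface_raster_um)
        }
      }
      caps <- caps + max(0, areas_by_sec[si] - overlap)
    }
  }
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  mesh <- new_mesh(vertices, faces, compartment,
                   volume_um3 = NA_real_,
                   surface_area_um2 = lateral + caps)
  mesh$surface_convention <- if (union_surface) {
    "union_external"
  } else {
    "component_sum"
  }
  mesh$volume_um3 <- mesh_volume(mesh)
  mesh
}

#' Morphometric summary of one reconstructed glomerulus
#'
#' Computes the quantities reported per glomerulus: mesangial volume and
#' surface from the prism mesh, per-section summed mesangial and tuft areas,
#' and the mesangial-to-total area ratio
#' (sum of mesangial areas) / (sum of tuft areas) across sections.
#'
#' @param contours Aligned contour table holding `tuft` (required) and
#'   `mesangium` contours.
#' @param thickness_um Section thickness in um.
#' @param specimen_id,glomerulus_id Identifiers copied into the output.
#' @return A one-row tibble: `specimen_id`, `glomerulus_id`,
#'   `mesangial_volume_um3`, `mesangial_surface_um2`, `mesangial_area_um2`,
#'   `tuft_area_um2`, `tuft_volume_um3`, `mes_to_total_ratio`.
#' @export
compute_morphometrics <- function(contours, thickness_um,
                                  specimen_id = "specimen",
                                  glomerulus_id = "glom") {
  areas <- contour_areas(contours)
  tuft_area <- sum(areas$area_um2[areas$compartment == "tuft"])
  mes_area <- sum(areas$area_um2[areas$compartment == "mesangium"])
  if (tuft_area <= 0) {
    abort("Zero tuft area: mesangial/total ratio undefined.",
          class = "glom_undefined_ratio")
  }
  mesh_tuft <- reconstruct_mesh(contours, thickness_um, "tuft")
  has_mes <- any(contours$compartment == "mesangium")
  if (has_mes) {
    mesh_mes <- reconstruct_mesh(contours, thickness_um, "mesangium")
    mes_vol <- mesh_mes$volume_um3
    mes_surf <- mesh_mes$surface_area_um2
  } else {
    mes_vol <- 0
    mes_surf <- 0
  }
  tibble(
    specimen_id = specimen_id,
    glomerulus_id = glomerulus_id,
    mesangial_volume_um3 = mes_vol,
    mesangial_surface_um2 = mes_surf,
    mesangial_area_um2 = mes_area,
    tuft_area_um2 = tuft_area,
    tuft_volume_um3 = mesh_tuft$volume_um3,
    mes_to_total_ratio = mes_area / tuft_area
  )
}
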