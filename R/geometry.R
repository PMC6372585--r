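#' Planar geometry primitives for traced glomerular contours
#'
#' All coordinates throughout the package are physical micrometres (um).
#' Image pixel `(row, col)` maps to `(y, x)` with y increasing downward and
#' both axes scaled by the same `pixel_size_um`. A contour is a closed simple
#' polygon stored counter-clockwise; the closing edge (last vertex back to the
#' first) is implicit.
#'
#' @name geometry
NULL

COMPARTMENTS <- c("mesangium", "tuft", "other")

signed_area <- function(x, y) {
  n <- length(x)
  xn <- x[c(2:n, 1L)]
  yn <- y[c(2:n, 1L)]
  sum(x * yn - xn * y) / 2
}

polygon_perimeter <- function(x, y) {
  n <- length(x)
  sum(sqrt(diff(c(x, x[1L]))^2 + diff(c(y, y[1L]))^2))
}

#' Test whether a closed polygon is simple (non-self-intersecting)
#'
#' @param x,y Numeric vectors of vertex coordinates in um (closing edge
#'   implicit).
#' @return `TRUE` if no two non-adjacent edges intersect and no edge has zero
#'   length.
#' @export
is_simple_polygon <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(FALSE)
  xs <- c(x, x[1L])
  ys <- c(y, y[1L])
  if (any(xs[-1] == xs[-(n + 1)] & ys[-1] == ys[-(n + 1)])) return(FALSE)
  # edge i vs all non-adjacent edges j > i, vectorized over j per i
  x1a <- xs[-(n + 1L)]; y1a <- ys[-(n + 1L)]
  x2a <- xs[-1L]; y2a <- ys[-1L]
  for (i in seq_len(n - 2L)) {
    j <- (i + 2L):n
    if (i == 1L) j <- j[j != n] # wrap-around adjacency
    if (!length(j)) next
    x1 <- x1a[i]; y1 <- y1a[i]; x2 <- x2a[i]; y2 <- y2a[i]
    x3 <- x1a[j]; y3 <- y1a[j]; x4 <- x2a[j]; y4 <- y2a[j]
    d1 <- (x4 - x3) * (y1 - y3) - (y4 - y3) * (x1 - x3)
    d2 <- (x4 - x3) * (y2 - y3) - (y4 - y3) * (x2 - x3)
    d3 <- (x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1)
    d4 <- (x2 - x1) * (y4 - y1) - (y2 - y1) * (x4 - x1)
    proper <- (sign(d1) * sign(d2) < 0) & (sign(d3) * sign(d4) < 0)
    if (any(proper)) return(FALSE)
    on1 <- d1 == 0 & x1 >= pmin(x3, x4) & x1 <= pmax(x3, x4) &
      y1 >= pmin(y3, y4) & y1 <= pmax(y3, y4)
    on2 <- d2 == 0 & x2 >= pmin(x3, x4) & x2 <= pmax(x3, x4) &
      y2 >= pmin(y3, y4) & y2 <= pmax(y3, y4)
    on3 <- d3 == 0 & x3 >= min(x1, x2) & x3 <= max(x1, x2) &
      y3 >= min(y1, y2) & y3 <= max(y1, y2)
    on4 <- d4 == 0 & x4 >= min(x1, x2) & x4 <= max(x1, x2) &
      y4 >= min(y1, y2) & y4 <= max(y1, y2)
    if (any(on1 | on2 | on3 | on4)) return(FALSE)
  }
  TRUE
}

#' Shoelace area of a closed polygon
#'
#' @inheritParams is_simple_polygon
#' @return Strictly positive area in um^2, invariant under rotation and
#'   translation of the vertices.
#' @examples
#' polygon_area(c(0, 1, 1, 0), c(0, 0, 1, 1)) # unit square -> 1
#' @export
polygon_area <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("A polygon needs at least 3 vertices with matching x and y.")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("Polygon vertices must be finite.")
  }
  a <- abs(signed_area(x, y))
  scale2 <- max(1, max(abs(x)), max(abs(y)))^2
  if (a <= 1e-12 * scale2) {
    abort("Degenerate polygon: zero area (collinear vertices).",
          class = "glom_degenerate_geometry")
  }
  a
}

#' Build a validated contour table
#'
#' Returns one traced closed outline as a long tibble with one row per vertex,
#' the universal currency between segmentation, registration, reconstruction
#' and stereology. Vertices are normalized to counter-clockwise order.
#'
#' @param x,y Vertex coordinates in um, at least 3 vertices, simple polygon.
#' @param compartment One of `"mesangium"`, `"tuft"`, `"other"`.
#' @param section_index Non-negative integer section index.
#' @param contour_id Identifier, unique within a section.
#' @param check_simple Run the O(n^2) self-intersection check (default `TRUE`;
#'   callers producing contours from guaranteed-simple sources may skip it).
#' @return A `glom_contours` tibble with columns `section_index`, `contour_id`,
#'   `compartment`, `x`, `y`.
#' @export
contour <- function(x, y, compartment = "other", section_index = 0L,
                    contour_id = "c1", check_simple = TRUE) {
  compartment <- match.arg(compartment, COMPARTMENTS)
  if (length(section_index) != 1L || section_index < 0) {
    abort("`section_index` must be a single non-negative integer.")
  }
  polygon_area(x, y) # validates vertex count, finiteness, non-degeneracy
  if (check_simple && !is_simple_polygon(x, y)) {
    abort("Contour polygon is self-intersecting.",
          class = "glom_degenerate_geometry")
  }
  if (signed_area(x, y) < 0) {
    x <- rev(x)
    y <- rev(y)
  }
  out <- tibble(
    section_index = as.integer(section_index),
    contour_id = as.character(contour_id),
    compartment = compartment,
    x = as.numeric(x),
    y = as.numeric(y)
  )
  as_glom_contours(out)
}

as_glom_contours <- function(df) {
  class(df) <- unique(c("glom_contours", class(df)))
  df
}

#' Per-contour areas of a contour table
#'
#' @param contours A contour table (`section_index`, `contour_id`,
#'   `compartment`, `x`, `y`).
#' @return A tibble with one row per contour and its shoelace `area_um2`.
#' @export
contour_areas <- function(contours) {
  contours |>
    dplyr::group_by(.data$section_index, .data$contour_id, .data$compartment) |>
    dplyr::summarise(area_um2 = polygon_area(.data$x, .data$y),
                     .groups = "drop")
}

#' Classify points against a closed polygon
#'
#' Ray-crossing classification with an explicit boundary band: points within
#' `tol` um of any edge are reported as `"boundary"` (the Cavalieri half-count
#' rule consumes this).
#'
#' @param px,py Query point coordinates in um (vectors).
#' @param x,y Polygon vertices in um (closing edge implicit).
#' @param tol Boundary tolerance in um (default 1e-9).
#' @return Character vector: `"inside"`, `"outside"` or `"boundary"`.
#' @export
point_in_polygon <- function(px, py, x, y, tol = 1e-9) {
  n <- length(x)
  np <- length(px)
  inside <- logical(np)
  on_bd <- logical(np)
  xs <- c(x, x[1L])
  ys <- c(y, y[1L])
  for (i in seq_len(n)) {
    x1 <- xs[i]; y1 <- ys[i]; x2 <- xs[i + 1L]; y2 <- ys[i + 1L]
    # distance from each point to this segment
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
    d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    on_bd <- on_bd | d2 <= tol * tol
    # ray casting (horizontal ray to +x)
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xint <- x1 + (py[crosses] - y1) / (y2 - y1) * dx
      hit <- logical(np)
      hit[crosses] <- px[crosses] < xint
      inside <- xor(inside, hit)
    }
  }
  out <- ifelse(on_bd, "boundary", ifelse(inside, "inside", "outside"))
  out
}

#' Rigid (rotation + translation) transform of the section plane
#'
#' Angles are radians, translations um. The implied 2x2 rotation matrix is
#' orthonormal with determinant +1: no scaling, no reflection — serial
#' sections from one block at one magnification can only shift and rotate.
#'
#' @param angle Rotation angle in radians (counter-clockwise).
#' @param dx,dy Translation in um.
#' @return A `glom_rigid` object.
#' @export
rigid_transform <- function(angle = 0, dx = 0, dy = 0) {
  stopifnot_scalar_num(angle, "angle")
  stopifnot_scalar_num(dx, "dx")
  stopifnot_scalar_num(dy, "dy")
  structure(list(angle = unname(angle), dx = unname(dx), dy = unname(dy)),
            class = "glom_rigid")
}

#' @export
print.glom_rigid <- function(x, ...) {
  cat(sprintf("<rigid2d> angle = %.6g rad, translation = (%.6g, %.6g) um\n",
              x$angle, x$dx, x$dy))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform equivalent to applying
#' `b` first, then `a`.
#'
#' @param a,b `glom_rigid` transforms.
#' @return A `glom_rigid` transform.
#' @export
compose_transforms <- function(a, b) {
  ca <- cos(a$angle); sa <- sin(a$angle)
  rigid_transform(
    angle = a$angle + b$angle,
    dx = a$dx + ca * b$dx - sa * b$dy,
    dy = a$dy + sa * b$dx + ca * b$dy
  )
}

#' Invert a rigid transform
#'
#' @param t A `glom_rigid` transform.
#' @return The inverse `glom_rigid` transform.
#' @export
invert_transform <- function(t) {
  ca <- cos(t$angle); sa <- sin(t$angle)
  rigid_transform(
    angle = -t$angle,
    dx = -(ca * t$dx + sa * t$dy),
    dy = -(-sa * t$dx + ca * t$dy)
  )
}

#' Apply a rigid transform to points
#'
#' @param t A `glom_rigid` transform.
#' @param x,y Point coordinates in um, or `x` an n x 2 matrix with `y` missing.
#' @return An n x 2 matrix of transformed coordinates.
#' @export
apply_transform <- function(t, x, y = NULL) {
  if (is.null(y)) {
    y <- x[, 2L]
    x <- x[, 1L]
  }
  ca <- cos(t$angle); sa <- sin(t$angle)
  cbind(x = ca * x - sa * y + t$dx, y = sa * x + ca * y + t$dy)
}

#' Apply a rigid transform to every vertex of a contour table
#'
#' @param contours A contour table.
#' @param t A `glom_rigid` transform (applied to all rows), or a named list of
#'   transforms keyed by section index as character.
#' @return The transformed contour table.
#' @export
transform_contours <- function(contours, t) {
  if (inherits(t, "glom_rigid")) {
    xy <- apply_transform(t, contours$x, contours$y)
    contours$x <- xy[, 1L]
    contours$y <- xy[, 2L]
    return(contours)
  }
  contours |>
    dplyr::group_by(.data$section_index) |>
    dplyr::group_modify(function(df, key) {
      tr <- t[[as.character(key$section_index)]]
      if (is.null(tr)) return(df)
      xy <- apply_transform(tr, df$x, df$y)
      df$x <- xy[, 1L]
      df$y <- xy[, 2L]
      df
    }) |>
    dplyr::ungroup() |>
    as_glom_contours()
}
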