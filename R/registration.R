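#' Landmark-based rigid registration of serial sections
#'
#' Serial sections are aligned from matched fiducial points (recognizable
#' fixed structures marked in both members of each adjacent section pair),
#' replacing manual alignment. The fit is 2D orthogonal Procrustes without
#' scaling or reflection: with sections cut from one block at one
#' magnification only rotation and translation are physical.
#'
#' @name registration
NULL

#' Least-squares rigid fit between matched fiducial sets
#'
#' Finds the rotation + translation minimizing the sum of squared distances
#' from the transformed `points_b` to `points_a` (Kabsch / sign-corrected SVD;
#' determinant +1 enforced so the fit can never reflect).
#'
#' @param points_a,points_b n x 2 matrices (or data frames with columns x, y)
#'   of matched fiducial coordinates in um; correspondence is by row order.
#'   At least 2 non-coincident pairs (4 were used in practice).
#' @return A list with `transform` (`glom_rigid` mapping `points_b` onto
#'   `points_a`) and `rms_um`, the root-mean-square residual distance per
#'   point after alignment.
#' @export
fit_rigid_transform <- function(points_a, points_b) {
  pa <- as_xy_matrix(points_a)
  pb <- as_xy_matrix(points_b)
  n <- nrow(pa)
  if (nrow(pb) != n) abort("Fiducial sets must have the same number of points.")
  if (n < 2L) {
    abort("At least 2 matched fiducial pairs are required.",
          class = "glom_insufficient_fiducials")
  }
  if (anyDuplicated(pa) || max(dist(pa)) < 1e-12) {
    abort("Fiducial points within a section must be distinct.",
          class = "glom_insufficient_fiducials")
  }
  ca <- colMeans(pa)
  cb <- colMeans(pb)
  A <- sweep(pa, 2, ca)
  B <- sweep(pb, 2, cb)
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  angle <- atan2(R[2, 1], R[1, 1])
  tr <- ca - as.numeric(R %*% cb)
  transform <- rigid_transform(angle = angle, dx = tr[1], dy = tr[2])
  resid <- apply_transform(transform, pb) - pa
  rms <- sqrt(mean(rowSums(resid^2)))
  list(transform = transform, rms_um = rms)
}

as_xy_matrix <- function(p) {
  if (is.data.frame(p)) p <- cbind(p$x, p$y)
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 2L || !all(is.finite(p))) {
    abort("Points must be an n x 2 matrix of finite um coordinates.")
  }
  colnames(p) <- c("x", "y")
  p
}

#' Build a fiducial pair table
#'
#' @param section_a,section_b Adjacent section indices (`section_b` must equal
#'   `section_a + 1`).
#' @param points_a,points_b Matched fiducial coordinates (n x 2, by row order).
#' @return A one-row tibble with list-columns `points_a`, `points_b`.
#' @export
fiducial_pair <- function(section_a, section_b, points_a, points_b) {
  if (section_b != section_a + 1L) {
    abort("Fiducial pairs must link adjacent sections (b = a + 1).")
  }
  tibble(
    section_a = as.integer(section_a),
    section_b = as.integer(section_b),
    points_a = list(as_xy_matrix(points_a)),
    points_b = list(as_xy_matrix(points_b))
  )
}

#' Chain pairwise fits into a stack-wide alignment
#'
#' Fits each adjacent pair, then composes the fits along the chain so every
#' section is mapped into the reference section's frame. The reference
#' defaults to the middle of the stack, which halves the longest composition
#' path and hence the accumulated error.
#'
#' @param pairs A tibble of fiducial pairs (rows as made by [fiducial_pair()]),
#'   covering every adjacent pair of the stack exactly once.
#' @param reference_index Section mapped by the identity; default middle
#'   section.
#' @return A `glom_alignment` object: list with `reference_index`,
#'   `transforms` (named by section index; identity at the reference) and
#'   `rms_um` (per fitted pair, named by the pair's first section).
#' @export
build_alignment_chain <- function(pairs, reference_index = NULL) {
  if (nrow(pairs) == 0L) {
    # single-section stack: nothing to align
    if (is.null(reference_index)) {
      abort("No fiducial pairs supplied and no reference section given.")
    }
    return(structure(
      list(reference_index = as.integer(reference_index),
           transforms = stats::setNames(list(rigid_transform()),
                                        as.character(reference_index)),
           rms_um = stats::setNames(numeric(0), character(0))),
      class = "glom_alignment"
    ))
  }
  sections <- sort(unique(c(pairs$section_a, pairs$section_b)))
  lo <- min(sections); hi <- max(sections)
  needed <- lo:(hi - 1L)
  have <- pairs$section_a
  if (anyDuplicated(have)) {
    abort("Each adjacent pair must appear exactly once.")
  }
  missing <- setdiff(needed, have)
  if (length(missing)) {
    abort(sprintf("Gap in alignment chain: no fiducials for pair (%d, %d).",
                  missing[1], missing[1] + 1L),
          class = "glom_chain_gap")
  }
  if (is.null(reference_index)) {
    reference_index <- sections[ceiling(length(sections) / 2)]
  }
  if (!reference_index %in% sections) {
    abort("`reference_index` must be one of the chained sections.")
  }
  # pairwise fits: step[[as.character(a)]] maps section a+1 coords -> section a
  fits <- lapply(seq_len(nrow(pairs)), function(i) {
    fit_rigid_transform(pairs$points_a[[i]], pairs$points_b[[i]])
  })
  step <- stats::setNames(lapply(fits, `[[`, "transform"),
                          as.character(pairs$section_a))
  rms <- stats::setNames(vapply(fits, `[[`, numeric(1), "rms_um"),
                         as.character(pairs$section_a))
  transforms <- stats::setNames(vector("list", length(sections)),
                                as.character(sections))
  transforms[[as.character(reference_index)]] <- rigid_transform()
  # walk downward from the reference: ref -> ... -> lo
  if (reference_index > lo) {
    for (s in seq(reference_index - 1L, lo)) {
      transforms[[as.character(s)]] <- compose_transforms(
        transforms[[as.character(s + 1L)]],
        invert_transform(step[[as.character(s)]])
      )
    }
  }
  # walk upward: each step maps s+1 -> s, so into-reference composes forward
  if (reference_index < hi) {
    for (s in seq(reference_index + 1L, hi)) {
      transforms[[as.character(s)]] <- compose_transforms(
        transforms[[as.character(s - 1L)]],
        step[[as.character(s - 1L)]]
      )
    }
  }
  structure(
    list(reference_index = as.integer(reference_index),
         transforms = transforms, rms_um = rms),
    class = "glom_alignment"
  )
}

#' @export
print.glom_alignment <- function(x, ...) {
  cat(sprintf("<alignment chain> %d sections, reference = %d\n",
              length(x$transforms), x$reference_index))
  for (s in names(x$transforms)) {
    t <- x$transforms[[s]]
    cat(sprintf("  section %s: angle %.4g rad, shift (%.4g, %.4g) um\n",
                s, t$angle, t$dx, t$dy))
  }
  invisible(x)
}

#' Map a contour table into the reference frame of an alignment chain
#'
#' @param contours A contour table spanning the chained sections.
#' @param chain A `glom_alignment` from [build_alignment_chain()].
#' @return The aligned contour table.
#' @export
align_contours <- function(contours, chain) {
  transform_contours(contours, chain$transforms)
}
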