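#' Contour JSON exchange format
#'
#' One document per specimen: `format_version`, `pixel_size_um`,
#' `section_thickness_um`, `sections` (each with `section_index` and a list
#' of `{compartment, vertices_um}`), and an optional `fiducials` list of
#' `{section_pair, points_a_um, points_b_um}`.
#'
#' @name contour_json
NULL

FORMAT_VERSION <- "1.0"

#' Write contours (and optional fiducials) to the JSON exchange format
#'
#' @param contours A contour table.
#' @param path Output path.
#' @param pixel_size_um,section_thickness_um Acquisition metadata in um.
#' @param fiducial_pairs Optional tibble of [fiducial_pair()] rows.
#' @param metadata Optional named list merged into the document root.
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path, pixel_size_um,
                           section_thickness_um, fiducial_pairs = NULL,
                           metadata = NULL) {
  secs <- lapply(sort(unique(contours$section_index)), function(s) {
    df <- contours[contours$section_index == s, ]
    list(
      section_index = s,
      contours = lapply(split(df, df$contour_id), function(d) {
        list(compartment = d$compartment[1],
             vertices_um = unname(cbind(d$x, d$y)))
      })
    )
  })
  doc <- c(
    list(format_version = FORMAT_VERSION,
         pixel_size_um = pixel_size_um,
         section_thickness_um = section_thickness_um,
         sections = secs),
    metadata %||% list()
  )
  if (!is.null(fiducial_pairs) && nrow(fiducial_pairs)) {
    doc$fiducials <- lapply(seq_len(nrow(fiducial_pairs)), function(i) {
      list(section_pair = c(fiducial_pairs$section_a[i],
                            fiducial_pairs$section_b[i]),
           points_a_um = unname(fiducial_pairs$points_a[[i]]),
           points_b_um = unname(fiducial_pairs$points_b[[i]]))
    })
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a contour JSON document
#'
#' @param path Path to a document written by [write_contours()].
#' @return A list: `contours` (contour table), `pixel_size_um`,
#'   `section_thickness_um`, `fiducial_pairs` (tibble, possibly empty),
#'   `format_version`.
#' @export
read_contours <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  if (is.null(doc$format_version)) {
    abort("Not a contour exchange document (missing format_version).")
  }
  rows <- list()
  for (sec in doc$sections) {
    cid <- 0L
    for (ct in sec$contours) {
      cid <- cid + 1L
      v <- ct$vertices_um
      rows[[length(rows) + 1L]] <- contour(
        v[, 1], v[, 2], compartment = ct$compartment,
        section_index = sec$section_index,
        contour_id = sprintf("s%d_c%d", sec$section_index, cid),
        check_simple = FALSE
      )
    }
  }
  fid <- NULL
  if (!is.null(doc$fiducials)) {
    fid <- dplyr::bind_rows(lapply(doc$fiducials, function(f) {
      fiducial_pair(f$section_pair[1], f$section_pair[2],
                    f$points_a_um, f$points_b_um)
    }))
  }
  list(
    contours = if (length(rows)) {
      as_glom_contours(dplyr::bind_rows(rows))
    } else {
      empty_contours()
    },
    pixel_size_um = doc$pixel_size_um,
    section_thickness_um = doc$section_thickness_um,
    fiducial_pairs = fid,
    format_version = doc$format_version
  )
}

#' Export an alignment chain to JSON
#'
#' Angles in radians, translations in um, plus per-pair RMS residuals and
#' the reference-section convention.
#'
#' @param chain A `glom_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(chain, path) {
  doc <- list(
    format_version = FORMAT_VERSION,
    reference_index = chain$reference_index,
    reference_convention = "middle section unless overridden",
    transforms = lapply(names(chain$transforms), function(s) {
      t <- chain$transforms[[s]]
      list(section_index = as.integer(s), angle_rad = t$angle,
           translation_um = c(t$dx, t$dy))
    }),
    rms_residuals_um = as.list(chain$rms_um)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a section image (TIFF or PNG) as an 8-bit RGB array
#'
#' @param path Image path.
#' @return Numeric array `[rows, cols, 3]` with values in 0..255.
#' @export
read_section_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    abort("Unsupported image format; expected TIFF or PNG.")
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write an 8-bit RGB array as TIFF or PNG
#'
#' @param img Numeric array `[rows, cols, 3]`, 0..255.
#' @param path Output path; format from extension.
#' @return `path`, invisibly.
#' @export
write_section_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  x <- pmin(pmax(img / 255, 0), 1)
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    png = png::writePNG(x, path),
    abort("Unsupported image format; expected TIFF or PNG.")
  )
  invisible(path)
}

#' Effective run configuration
#'
#' A flat, fully serializable record of every tunable the pipeline uses; a
#' run's effective configuration is always written next to its outputs so
#' stochastic results can be reproduced exactly.
#'
#' @param ... Overrides of the defaults.
#' @return A named list of class `glom_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    pixel_size_um = 0.25,
    section_thickness_um = 1,
    od_threshold = NA,
    tissue_od_min = 0.1,
    min_region_area_um2 = 5,
    morphology_radius_um = 0.5,
    tuft_close_radius_um = 2,
    grid_spacing_um = 2,
    grid_seed = 1L,
    counting_rule = "half",
    planimetry_model = "extrusion",
    t_equiv_um = 1,
    seed = 1L,
    log_level = "INFO"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(sprintf("Unknown config field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = c("glom_config", "list"))
}

#' Write the effective configuration next to a run's outputs
#'
#' @param config A [run_config()].
#' @param dir Output directory (created if needed).
#' @return The config path, invisibly.
#' @export
write_run_config <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "run_config.yaml")
  meta <- c(unclass(config),
            list(tool = "glomorph",
                 tool_version = as.character(utils::packageVersion("glomorph"))))
  yaml::write_yaml(meta, path)
  invisible(path)
}

#' Read a configuration file (YAML key-value)
#'
#' @param path Path to a YAML config.
#' @return A [run_config()] with the file's overrides applied.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals <- vals[intersect(names(vals), names(run_config()))]
  do.call(run_config, vals)
}
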