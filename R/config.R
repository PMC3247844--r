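#' Assay configuration
#'
#' Bundles every constant of the counting-chamber viability assay. The
#' defaults are the published protocol values: particles below 35 um^2 are
#' artefacts, a particle whose mean green intensity exceeds 50 (on the 8-bit
#' scale) is scored non-viable, the tiled micrographs of one chamber fill
#' cover 0.084 ul, and the culture is mixed 1:2 with glycerol before loading
#' (final concentration one half of the original, hence dilution factor 2).
#'
#' @param min_area_um2 Minimum particle footprint in um^2; smaller connected
#'   components are discarded as segmentation artefacts. Default 35.
#' @param green_cutoff Mean green intensity (0-255) above which a particle is
#'   classified non-viable. Default 50. Microscope-dependent; recalibrate for
#'   other instruments.
#' @param imaged_volume_ul Chamber volume in ul covered by *all* fields of one
#'   run together. Default 0.084.
#' @param dilution_factor Factor by which counted concentration is multiplied
#'   to undo pre-loading dilution. Default 2 (1:2 glycerol mixing). Must be
#'   >= 1.
#' @param connectivity Pixel connectivity for particle registration, 4 or 8.
#'   Default 8, matching ImageJ's Particle Analyzer.
#' @param include_edge_particles Keep particles touching the image border?
#'   Default `TRUE`.
#'
#' @return An object of class `assay_config` (a validated named list).
#' @examples
#' assay_config()
#' assay_config(green_cutoff = 60)
#' @export
assay_config <- function(min_area_um2 = 35,
                         green_cutoff = 50,
                         imaged_volume_ul = 0.084,
                         dilution_factor = 2,
                         connectivity = 8,
                         include_edge_particles = TRUE) {
  cfg <- list(
    min_area_um2 = as.numeric(min_area_um2),
    green_cutoff = as.numeric(green_cutoff),
    imaged_volume_ul = as.numeric(imaged_volume_ul),
    dilution_factor = as.numeric(dilution_factor),
    connectivity = as.integer(connectivity),
    include_edge_particles = isTRUE(include_edge_particles)
  )
  validate_assay_config(cfg)
  structure(cfg, class = "assay_config")
}

validate_assay_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.numeric(cfg$min_area_um2) || length(cfg$min_area_um2) != 1 ||
      is.na(cfg$min_area_um2) || cfg$min_area_um2 < 0) {
    abort("`min_area_um2` must be a single non-negative number.")
  }
  if (!is.numeric(cfg$green_cutoff) || length(cfg$green_cutoff) != 1 ||
      is.na(cfg$green_cutoff) ||
      cfg$green_cutoff < 0 || cfg$green_cutoff > 255) {
    abort("`green_cutoff` must be a single number in [0, 255].")
  }
  if (!is.numeric(cfg$imaged_volume_ul) || length(cfg$imaged_volume_ul) != 1 ||
      is.na(cfg$imaged_volume_ul) || cfg$imaged_volume_ul <= 0) {
    abort("`imaged_volume_ul` must be a single positive number.")
  }
  if (!is.numeric(cfg$dilution_factor) || length(cfg$dilution_factor) != 1 ||
      is.na(cfg$dilution_factor) || cfg$dilution_factor < 1) {
    abort("`dilution_factor` must be a single number >= 1.")
  }
  if (!cfg$connectivity %in% c(4L, 8L)) {
    abort("`connectivity` must be 4 or 8.")
  }
  if (!is.logical(cfg$include_edge_particles) ||
      length(cfg$include_edge_particles) != 1 ||
      is.na(cfg$include_edge_particles)) {
    abort("`include_edge_particles` must be TRUE or FALSE.")
  }
  invisible(cfg)
}

#' Load an assay configuration from JSON
#'
#' Reads a JSON file whose keys are exactly the [assay_config()] field names;
#' absent keys take the protocol defaults. With `path = NULL` the defaults are
#' returned unchanged.
#'
#' @param path Path to a JSON config file, or `NULL` for the defaults.
#' @return An `assay_config` object.
#' @examples
#' load_config()                      # protocol defaults
#' f <- tempfile(fileext = ".json")
#' writeLines('{"green_cutoff": 60}', f)
#' load_config(f)$green_cutoff        # 60, everything else default
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) {
    return(assay_config())
  }
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path))
  }
  vals <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) abort(paste0("malformed config JSON: ", conditionMessage(e)))
  )
  if (!is.list(vals)) abort("config JSON must be an object.")
  known <- names(formals(assay_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    warn(paste0("ignoring unknown config keys: ", paste(unknown, collapse = ", ")))
    vals <- vals[intersect(names(vals), known)]
  }
  do.call(assay_config, vals)
}

#' @export
print.assay_config <- function(x, ...) {
  cat("<assay_config>\n")
  cat(sprintf("  min_area_um2:           %g\n", x$min_area_um2))
  cat(sprintf("  green_cutoff:           %g\n", x$green_cutoff))
  cat(sprintf("  imaged_volume_ul:       %g\n", x$imaged_volume_ul))
  cat(sprintf("  dilution_factor:        %g\n", x$dilution_factor))
  cat(sprintf("  connectivity:           %d\n", x$connectivity))
  cat(sprintf("  include_edge_particles: %s\n", x$include_edge_particles))
  invisible(x)
}
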