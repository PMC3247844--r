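#' Combine the red- and green-channel masks
#'
#' Pixelwise logical OR: a pixel belongs to a cell if it is foreground in
#' either fluorescence channel.
#'
#' @param red_mask,green_mask Logical matrices of equal dimensions.
#' @return Logical matrix.
#' @export
combine_masks <- function(red_mask, green_mask) {
  if (!identical(dim(red_mask), dim(green_mask))) {
    abort("mask dimensions differ.")
  }
  red_mask | green_mask
}

#' Label connected components of a binary mask
#'
#' Components are found under 4- or 8-connectivity by building the adjacency
#' graph of foreground pixels and extracting its connected components
#' (igraph). Labels are assigned in raster order of each component's first
#' pixel, starting at 1.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
#' @return Integer matrix of the mask's dimensions; 0 = background.
#' @export
label_components <- function(mask, connectivity = 8) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) abort("`connectivity` must be 4 or 8.")
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask)                    # column-major linear indices
  if (length(fg) == 0) return(lab)

  # vertex ids 1..length(fg) for foreground pixels
  vid <- integer(nr * nc)
  vid[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% nr) + 1L
  co <- ((fg - 1L) %/% nr) + 1L

  edge_to <- function(dr, dc) {
    ok <- r + dr >= 1L & r + dr <= nr & co + dc >= 1L & co + dc <= nc
    nb <- fg[ok] + dr + dc * nr
    keep <- vid[nb] > 0L
    cbind(vid[fg[ok]][keep], vid[nb][keep])
  }
  offs <- list(c(1L, 0L), c(0L, 1L))                 # down, right
  if (connectivity == 8L) {
    offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))     # both diagonals
  }
  edges <- do.call(rbind, lapply(offs, function(o) edge_to(o[1], o[2])))
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  memb <- igraph::components(g)$membership
  # renumber so labels follow raster order (column-major) of first occurrence
  first_seen <- !duplicated(memb)
  relabel <- integer(max(memb))
  relabel[memb[first_seen]] <- seq_len(sum(first_seen))
  lab[fg] <- relabel[memb]
  lab
}

#' Register particles from a segmentation mask
#'
#' Each connected component of the mask is one particle. Areas are converted
#' to um^2 with the field's calibration; mean red and green intensities are
#' measured on the *original* channels (classification thresholds a raw
#' intensity, so masked-out values must not be substituted). Particles
#' touching the image border are flagged and, depending on
#' `config$include_edge_particles`, kept or dropped.
#'
#' @param mask Logical matrix with the field's dimensions.
#' @param field The [calibrated_field()] the mask was derived from.
#' @param config An [assay_config()].
#' @return A tibble with one row per particle: `field_id`, `particle_id`,
#'   `area_px`, `area_um2`, `centroid_row`, `centroid_col` (1-based pixel
#'   coordinates), `mean_red`, `mean_green`, `touches_edge`.
#' @export
register_particles <- function(mask, field, config = assay_config()) {
  stopifnot(inherits(field, "calibrated_field"))
  validate_assay_config(config)
  if (!identical(dim(mask), dim(field$pixels)[1:2])) {
    abort("mask dimensions do not match the field.")
  }
  lab <- label_components(mask, config$connectivity)
  empty <- tibble(
    field_id = character(), particle_id = integer(),
    area_px = integer(), area_um2 = numeric(),
    centroid_row = numeric(), centroid_col = numeric(),
    mean_red = numeric(), mean_green = numeric(),
    touches_edge = logical()
  )
  n <- max(lab)
  if (n == 0) return(empty)

  idx <- which(lab > 0L)
  id <- lab[idx]
  nr <- nrow(mask)
  row_i <- ((idx - 1L) %% nr) + 1L
  col_i <- ((idx - 1L) %/% nr) + 1L
  red <- field_channel(field, "red")[idx]
  green <- field_channel(field, "green")[idx]
  on_edge <- row_i == 1L | row_i == nr | col_i == 1L | col_i == ncol(mask)

  area_px <- tabulate(id, nbins = n)
  sums <- unname(rowsum(cbind(row_i, col_i, red, green, on_edge), id))
  out <- tibble(
    field_id = field$field_id,
    particle_id = seq_len(n),
    area_px = as.integer(area_px),
    area_um2 = area_px * field$um_per_px^2,
    centroid_row = sums[, 1] / area_px,
    centroid_col = sums[, 2] / area_px,
    mean_red = sums[, 3] / area_px,
    mean_green = sums[, 4] / area_px,
    touches_edge = sums[, 5] > 0
  )
  if (!config$include_edge_particles) {
    out <- dplyr::filter(out, !.data$touches_edge)
  }
  out
}

#' Remove sub-area artefacts
#'
#' Thresholding noisy backgrounds (especially in the green channel) produces
#' small spurious components; particles with a footprint *smaller than*
#' `min_area_um2` are excluded. The boundary value itself (area equal to the
#' cutoff) is retained. Idempotent; order and particle ids are preserved.
#'
#' @param particles Particle tibble from [register_particles()].
#' @param config An [assay_config()].
#' @return The filtered particle tibble.
#' @export
filter_artifacts <- function(particles, config = assay_config()) {
  validate_assay_config(config)
  dplyr::filter(particles, .data$area_um2 >= config$min_area_um2)
}

#' Write a per-particle CSV
#'
#' @param particles Particle tibble (optionally carrying a `class` column).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_particles_csv <- function(particles, path) {
  write.csv(particles, path, row.names = FALSE)
  invisible(path)
}
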