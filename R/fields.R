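#' Construct a calibrated fluorescence field
#'
#' A field is one RGB micrograph (integer intensities 0-255, stored as an
#' `height x width x 3` array) with its spatial calibration in micrometres per
#' pixel edge. The red channel carries chlorophyll autofluorescence (viable
#' cells), the green channel the unspecific autofluorescence of dead cells.
#'
#' @param pixels Numeric array `h x w x 3` with values in \[0, 255\].
#' @param um_per_px Micrometres per pixel edge, positive.
#' @param field_id Text label; defaults to `"field"`.
#' @return An object of class `calibrated_field`.
#' @export
calibrated_field <- function(pixels, um_per_px, field_id = "field") {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    abort("`pixels` must be an h x w x 3 array (RGB).")
  }
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1) {
    abort("image must have at least one pixel in each dimension.")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    abort("channel intensities must lie in [0, 255].")
  }
  if (!is.numeric(um_per_px) || length(um_per_px) != 1 ||
      is.na(um_per_px) || um_per_px <= 0) {
    abort("`um_per_px` must be a single positive number.")
  }
  pixels <- array(as.integer(pixels), dim(pixels))  # drop stray attributes
  structure(
    list(field_id = as.character(field_id), pixels = pixels,
         um_per_px = as.numeric(um_per_px)),
    class = "calibrated_field"
  )
}

#' @export
print.calibrated_field <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<calibrated_field> '%s': %d x %d px, %.4g um/px (%.4g x %.4g um)\n",
              x$field_id, d[2], d[1], x$um_per_px,
              d[2] * x$um_per_px, d[1] * x$um_per_px))
  invisible(x)
}

#' @export
dim.calibrated_field <- function(x) dim(x$pixels)

#' Extract one colour channel of a field
#'
#' @param field A [calibrated_field()].
#' @param channel `"red"`, `"green"` or `"blue"`.
#' @return Integer matrix of intensities in \[0, 255\].
#' @export
field_channel <- function(field, channel = c("red", "green", "blue")) {
  channel <- match.arg(channel)
  idx <- match(channel, c("red", "green", "blue"))
  field$pixels[, , idx]
}

#' Bundle the fields of one assay run
#'
#' One run is all micrographs taken of a single chamber fill; its
#' `imaged_volume_ul` in the configuration is the volume covered by all of
#' them together. All fields must share the same calibration.
#'
#' @param fields List of [calibrated_field()] objects (at least one).
#' @param config An [assay_config()]; defaults to the protocol constants.
#' @return An object of class `field_set`.
#' @export
field_set <- function(fields, config = assay_config()) {
  if (inherits(fields, "calibrated_field")) fields <- list(fields)
  if (!is.list(fields) || length(fields) == 0 ||
      !all(vapply(fields, inherits, logical(1), "calibrated_field"))) {
    abort("`fields` must be a non-empty list of calibrated_field objects.")
  }
  validate_assay_config(config)
  cal <- vapply(fields, function(f) f$um_per_px, numeric(1))
  if (length(unique(cal)) != 1) {
    abort("all fields of a run must share the same um_per_px calibration.")
  }
  ids <- vapply(fields, function(f) f$field_id, character(1))
  if (anyDuplicated(ids)) {
    abort("field_id labels within a run must be unique.")
  }
  structure(list(fields = fields, config = config), class = "field_set")
}

#' @export
print.field_set <- function(x, ...) {
  cat(sprintf("<field_set> %d field(s), %.4g um/px\n",
              length(x$fields), x$fields[[1]]$um_per_px))
  invisible(x)
}

#' @export
length.field_set <- function(x) length(x$fields)

# ---- file IO ---------------------------------------------------------------

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext == "png") return("png")
  abort(paste0("unsupported image format '.", ext,
               "' (expected .tif/.tiff/.png): ", path))
}

#' Read a fluorescence micrograph
#'
#' Reads an 8- or 16-bit RGB TIFF or PNG into a [calibrated_field()].
#' 16-bit input is linearly rescaled to \[0, 255\] by the per-image maximum
#' (the rescaling is reported via a message). Single-channel grayscale images
#' are rejected: the assay needs separate red and green channels. An alpha
#' channel, if present, is dropped.
#'
#' @param path Path to the image file.
#' @param um_per_px Micrometres per pixel edge (explicit by design; embedded
#'   calibration metadata is never trusted silently).
#' @param field_id Label for the field; defaults to the file name.
#' @return A [calibrated_field()].
#' @export
read_field <- function(path, um_per_px, field_id = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  fmt <- img_format(path)
  if (fmt == "tiff") {
    info <- tiff::readTIFF(path, payload = FALSE)
    bits <- info$bits.per.sample[1]
    img <- tiff::readTIFF(path)       # values in [0, 1]
  } else {
    img <- png::readPNG(path, info = TRUE)
    bits <- attr(img, "info")$bit.depth
  }
  if (!bits %in% c(8, 16)) {
    abort(paste0("unsupported bit depth (", bits, "); expected 8 or 16."))
  }
  if (is.matrix(img) || (length(dim(img)) == 3 && dim(img)[3] == 1)) {
    abort("two channels required: single-channel grayscale input cannot carry both the red and green fluorescence signal.")
  }
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] != 3) {
    abort(paste0("unsupported colour model with ", dim(img)[3], " channels."))
  }
  if (bits == 16) {
    mx <- max(img)
    if (mx <= 0) {
      px <- array(0L, dim(img))
    } else {
      px <- round(img / mx * 255)
    }
    message(sprintf("read_field: 16-bit input '%s' rescaled to [0,255] by per-image max %d",
                    basename(path), as.integer(round(mx * 65535))))
  } else {
    px <- round(img * 255)
  }
  calibrated_field(px, um_per_px,
                   field_id = field_id %||% basename(path))
}

#' Write a field losslessly to TIFF or PNG
#'
#' The container is chosen by file extension (`.tif`/`.tiff` or `.png`);
#' output is always 8-bit RGB and round-trips bit-exactly through
#' [read_field()].
#'
#' @param field A [calibrated_field()].
#' @param path Output path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "calibrated_field"))
  fmt <- img_format(path)
  if (!dir.exists(dirname(path))) {
    abort(paste0("directory does not exist: ", dirname(path)))
  }
  img <- field$pixels / 255
  if (fmt == "tiff") {
    tiff::writeTIFF(img, path, bits.per.sample = 8, compression = "LZW")
  } else {
    png::writePNG(img, path)
  }
  invisible(path)
}

#' Read every image in a directory as one assay run
#'
#' @param dir Directory containing the run's TIFF/PNG fields.
#' @param um_per_px Micrometres per pixel edge, shared by all fields.
#' @param config An [assay_config()].
#' @return A [field_set()]; fields are ordered by file name.
#' @export
read_field_dir <- function(dir, um_per_px, config = assay_config()) {
  if (!dir.exists(dir)) abort(paste0("directory not found: ", dir))
  paths <- sort(list.files(dir, pattern = "\\.(tif|tiff|png)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(paths) == 0) abort(paste0("no fields found in ", dir))
  fields <- lapply(paths, read_field, um_per_px = um_per_px)
  field_set(fields, config)
}
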