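#' Count fluorescent colonies on a plate image
#'
#' Colonies imaged by their phycocyanin autofluorescence appear as bright
#' blobs on a dark plate. The selected channel is auto-thresholded
#' (maximum-entropy criterion), components are extracted under
#' 8-connectivity, and components smaller than `min_colony_area_px` pixels
#' are discarded as specks. A plate whose histogram is degenerate (uniform
#' image) yields zero colonies with a warning — an empty plate is a
#' legitimate outcome, not an error: a fully non-viable sample forms no
#' colonies.
#'
#' @param image A [calibrated_field()] or a plain intensity matrix in
#'   \[0, 255\].
#' @param min_colony_area_px Minimum component size in pixels; no universal
#'   value exists, it depends on plate magnification, so it must be given.
#' @param method Thresholding method; currently `"max_entropy"`.
#' @param channel Channel to analyse when `image` is RGB: `"red"`, `"green"`
#'   or `"luminance"` (Rec.601 weights).
#' @param plate_id Label for the plate.
#' @return One-row tibble: `plate_id`, `n_colonies`, `threshold_used`
#'   (`NA` for a degenerate plate), `min_colony_area_px`.
#' @export
count_colonies <- function(image, min_colony_area_px,
                           method = c("max_entropy"),
                           channel = c("luminance", "red", "green"),
                           plate_id = "plate") {
  method <- match.arg(method)
  channel <- match.arg(channel)
  if (!is.numeric(min_colony_area_px) || length(min_colony_area_px) != 1 ||
      is.na(min_colony_area_px) || min_colony_area_px < 1) {
    abort("`min_colony_area_px` must be a single integer >= 1.")
  }
  if (inherits(image, "calibrated_field")) {
    plate_id <- image$field_id
    grid <- switch(channel,
      red = field_channel(image, "red"),
      green = field_channel(image, "green"),
      luminance = round(0.299 * field_channel(image, "red") +
                        0.587 * field_channel(image, "green") +
                        0.114 * field_channel(image, "blue"))
    )
  } else if (is.matrix(image)) {
    grid <- image
  } else {
    abort("`image` must be a calibrated_field or an intensity matrix.")
  }
  if (length(grid) == 0) abort("plate image is empty.")

  t_used <- tryCatch(
    max_entropy_threshold(channel_histogram(grid)),
    cyanovia_degenerate_histogram = function(e) NA_integer_
  )
  if (is.na(t_used)) {
    warn(paste0("plate '", plate_id,
                "': degenerate histogram, counting 0 colonies."))
    n <- 0L
  } else {
    lab <- label_components(binarize(grid, t_used), connectivity = 8)
    if (max(lab) == 0) {
      n <- 0L
    } else {
      sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
      n <- sum(sizes >= min_colony_area_px)
    }
  }
  tibble(
    plate_id = plate_id,
    n_colonies = as.integer(n),
    threshold_used = t_used,
    min_colony_area_px = as.integer(min_colony_area_px)
  )
}

#' Percent viability by plating
#'
#' Normalises a sample's colony count by the count of the all-viable control
#' plated at the same cell number: `100 * n_sample / n_control`. The plated
#' cell number and plate areas cancel in this ratio and are not modelled.
#' Values above 100% are possible (counting noise) and returned as-is.
#'
#' @param sample,control Colony-count rows from [count_colonies()], or bare
#'   non-negative counts.
#' @return Percent viability (numeric scalar).
#' @export
plating_viability <- function(sample, control) {
  n_of <- function(x) {
    if (is.data.frame(x)) x$n_colonies else x
  }
  ns <- n_of(sample)
  nc <- n_of(control)
  if (!is.numeric(ns) || length(ns) != 1 || is.na(ns) || ns < 0) {
    abort("sample colony count must be a single non-negative number.")
  }
  if (!is.numeric(nc) || length(nc) != 1 || is.na(nc) || nc <= 0) {
    abort("control colony count must be positive: cannot normalize by an empty control plate.")
  }
  100 * ns / nc
}
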