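#' Classify particles as viable or non-viable
#'
#' A particle is non-viable iff its mean green intensity exceeds
#' `config$green_cutoff` (strictly); chlorophyll-bearing viable cells have
#' little green signal. The boundary value (mean green exactly at the cutoff)
#' is scored viable. The red mean is recorded for inspection but is not used
#' in the rule.
#'
#' @param particles Particle tibble (after [filter_artifacts()]).
#' @param config An [assay_config()].
#' @return The tibble with an added `class` column, `"viable"` or
#'   `"nonviable"`.
#' @export
classify_particles <- function(particles, config = assay_config()) {
  validate_assay_config(config)
  dplyr::mutate(
    particles,
    class = dplyr::if_else(.data$mean_green > config$green_cutoff,
                           "nonviable", "viable")
  )
}

#' Aggregate classified particles into a run-level result
#'
#' Counts are pooled over all fields of the run; the concentration is
#' \deqn{c = \frac{n_{total}}{V_{ul}} \times 1000 \times d}
#' with `V_ul` the total imaged chamber volume in ul and `d` the dilution
#' factor, giving cells per ml of the undiluted culture.
#'
#' @param particles Classified particle tibble (must carry `class`).
#' @param config An [assay_config()].
#' @param field_ids Character vector of every field id in the run, so fields
#'   with zero particles still appear in the per-field table. Defaults to the
#'   ids present in `particles`.
#' @param thresholds Optional tibble of per-field thresholds
#'   (`field_id`, `t_red`, `t_green`) to carry in the result.
#' @return A `viability_result`: list with `n_viable`, `n_nonviable`,
#'   `n_total`, `viable_fraction` (`NA` when no particles),
#'   `concentration_cells_per_ml`, `per_field_counts` tibble, `particles`,
#'   `thresholds`, `config`.
#' @export
quantify <- function(particles, config = assay_config(),
                     field_ids = NULL, thresholds = NULL) {
  validate_assay_config(config)
  if (!"class" %in% names(particles)) {
    abort("particles must be classified first (missing `class` column).")
  }
  field_ids <- field_ids %||% unique(particles$field_id)
  if (length(field_ids) == 0) abort("a run must contain at least one field.")

  per_field <- tidyr::complete(
    dplyr::count(particles, .data$field_id, .data$class),
    field_id = field_ids,
    class = c("viable", "nonviable"),
    fill = list(n = 0L)
  )
  per_field <- tidyr::pivot_wider(per_field, names_from = "class",
                                  values_from = "n", values_fill = 0L)
  for (col in c("viable", "nonviable")) {
    if (!col %in% names(per_field)) per_field[[col]] <- 0L
  }
  per_field <- tibble(
    field_id = per_field$field_id,
    n_viable = as.integer(per_field$viable),
    n_nonviable = as.integer(per_field$nonviable)
  )
  per_field <- per_field[match(field_ids, per_field$field_id), ]

  n_viable <- sum(per_field$n_viable)
  n_nonviable <- sum(per_field$n_nonviable)
  n_total <- n_viable + n_nonviable
  structure(
    list(
      n_viable = n_viable,
      n_nonviable = n_nonviable,
      n_total = n_total,
      viable_fraction = if (n_total > 0) n_viable / n_total else NA_real_,
      concentration_cells_per_ml =
        n_total / config$imaged_volume_ul * 1000 * config$dilution_factor,
      per_field_counts = per_field,
      particles = particles,
      thresholds = thresholds,
      config = config
    ),
    class = "viability_result"
  )
}

threshold_or_na <- function(channel) {
  tryCatch(
    max_entropy_threshold(channel_histogram(channel)),
    cyanovia_degenerate_histogram = function(e) NA_integer_
  )
}

#' Run the full viability assay on a set of fields
#'
#' For every field: split channels, auto-threshold red and green separately
#' with the maximum-entropy criterion, binarize, OR-combine the masks,
#' register connected components, discard sub-area artefacts, and classify
#' each surviving particle by its mean green intensity. Counts are then
#' pooled and converted to cells/ml. Deterministic: identical input bytes
#' give an identical result.
#'
#' A channel whose histogram is degenerate (fewer than two occupied
#' intensities) contributes an empty mask — a fully viable culture
#' legitimately has a blank green channel and vice versa. If *both* channels
#' of a field are degenerate the field contributes zero particles and a
#' warning is raised, but the run continues.
#'
#' @param run A [field_set()] (or a single [calibrated_field()], analysed
#'   with the default configuration).
#' @param config Overrides the `field_set`'s configuration if given.
#' @return A `viability_result`; see [quantify()]. Its `thresholds` element
#'   logs `t_red`/`t_green` per field (`NA` where a channel was degenerate).
#' @examples
#' sc <- scene_spec(n_red = 20, n_green = 20, noise_sigma = 0, seed = 7)
#' fld <- render_field(sc)
#' res <- run_assay(field_set(fld$field))
#' res$n_viable
#' res$n_nonviable
#' @export
run_assay <- function(run, config = NULL) {
  if (inherits(run, "calibrated_field")) run <- field_set(run)
  stopifnot(inherits(run, "field_set"))
  config <- config %||% run$config
  validate_assay_config(config)

  per_field <- purrr::map(run$fields, function(fld) {
    red <- field_channel(fld, "red")
    green <- field_channel(fld, "green")
    t_red <- threshold_or_na(red)
    t_green <- threshold_or_na(green)
    if (is.na(t_red) && is.na(t_green)) {
      warn(paste0("field '", fld$field_id,
                  "': both channels degenerate; contributes no particles."))
    }
    mask_red <- if (is.na(t_red)) red < 0 else binarize(red, t_red)
    mask_green <- if (is.na(t_green)) green < 0 else binarize(green, t_green)
    mask <- combine_masks(mask_red, mask_green)
    parts <- filter_artifacts(register_particles(mask, fld, config), config)
    list(particles = parts,
         thresholds = tibble(field_id = fld$field_id,
                             t_red = t_red, t_green = t_green))
  })

  particles <- classify_particles(
    dplyr::bind_rows(purrr::map(per_field, "particles")), config)
  thresholds <- dplyr::bind_rows(purrr::map(per_field, "thresholds"))
  quantify(particles, config,
           field_ids = vapply(run$fields, function(f) f$field_id, character(1)),
           thresholds = thresholds)
}

#' @export
print.viability_result <- function(x, ...) {
  cat("<viability_result>\n")
  cat(sprintf("  fields:         %d\n", nrow(x$per_field_counts)))
  cat(sprintf("  viable:         %d\n", x$n_viable))
  cat(sprintf("  non-viable:     %d\n", x$n_nonviable))
  if (is.na(x$viable_fraction)) {
    cat("  viable percent: undefined (no particles)\n")
  } else {
    cat(sprintf("  viable percent: %.1f%%\n", 100 * x$viable_fraction))
  }
  cat(sprintf("  concentration:  %.3g cells/ml\n",
              x$concentration_cells_per_ml))
  invisible(x)
}

#' Tidy a viability result into per-field counts
#'
#' @param x A `viability_result`.
#' @param ... Unused.
#' @return Tibble with `field_id`, `n_viable`, `n_nonviable`, `t_red`,
#'   `t_green`.
#' @method tidy viability_result
#' @export
tidy.viability_result <- function(x, ...) {
  out <- x$per_field_counts
  if (!is.null(x$thresholds)) {
    out <- dplyr::left_join(out, x$thresholds, by = "field_id")
  }
  out
}

#' One-row summary of a viability result
#'
#' @param x A `viability_result`.
#' @param ... Unused.
#' @return Tibble with `n_fields`, `n_viable`, `n_nonviable`, `n_total`,
#'   `viable_fraction`, `viable_percent`, `concentration_cells_per_ml`.
#' @method glance viability_result
#' @export
glance.viability_result <- function(x, ...) {
  tibble(
    n_fields = nrow(x$per_field_counts),
    n_viable = x$n_viable,
    n_nonviable = x$n_nonviable,
    n_total = x$n_total,
    viable_fraction = x$viable_fraction,
    viable_percent = 100 * x$viable_fraction,
    concentration_cells_per_ml = x$concentration_cells_per_ml
  )
}

#' Write the run-level summary CSV
#'
#' @param result A `viability_result`.
#' @param path Output CSV path.
#' @param run_id Run label recorded in the file.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(result, path, run_id = "run") {
  stopifnot(inherits(result, "viability_result"))
  g <- glance(result)
  row <- data.frame(
    run_id = run_id,
    n_fields = g$n_fields,
    n_viable = g$n_viable,
    n_nonviable = g$n_nonviable,
    viable_percent = g$viable_percent,
    concentration_cells_per_ml = g$concentration_cells_per_ml,
    t_red_per_field = as.character(
      jsonlite::toJSON(result$thresholds$t_red %||% integer(0))),
    t_green_per_field = as.character(
      jsonlite::toJSON(result$thresholds$t_green %||% integer(0))),
    min_area_um2 = result$config$min_area_um2,
    green_cutoff = result$config$green_cutoff,
    imaged_volume_ul = result$config$imaged_volume_ul,
    dilution_factor = result$config$dilution_factor
  )
  write.csv(row, path, row.names = FALSE)
  invisible(path)
}
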