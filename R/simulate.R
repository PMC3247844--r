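#' Specify a synthetic counting-chamber field
#'
#' Describes a synthetic two-channel fluorescence scene: disk-shaped cells
#' that are bright in exactly one channel (red = chlorophyll
#' autofluorescence of viable cells, green = unspecific autofluorescence of
#' dead cells) on a dark background, with optional sub-area noise "specks"
#' and Gaussian read noise. Defaults follow the assay's geometry: at 0.5
#' um/px a 4 um cell radius renders a footprint of about 50 um^2, safely
#' above the 35 um^2 artefact cutoff, while the default speck (10 um^2) is
#' safely below it; class intensity distributions straddle the green cutoff
#' of 50 by construction.
#'
#' @param width_px,height_px Field size in pixels.
#' @param um_per_px Calibration, micrometres per pixel edge.
#' @param n_red,n_green Number of viable (red) and non-viable (green) cells.
#' @param cell_radius_um Rendered cell radius in um.
#' @param red_cell_intensity,green_cell_intensity Length-2 vectors
#'   `c(mean, sd)` of the on-channel brightness of each class (8-bit scale);
#'   one draw per cell.
#' @param off_channel_intensity Brightness of a cell's other channel.
#' @param background_level Background intensity of all channels.
#' @param noise_sigma SD of pixelwise Gaussian read noise added to every
#'   channel.
#' @param n_specks Number of bright sub-area specks (segmentation-artefact
#'   stand-ins), each placed in a randomly chosen channel.
#' @param speck_area_um2 Footprint of one speck; must stay below the artefact
#'   cutoff.
#' @param min_separation_um Minimum distance between cell centres (prevents
#'   merged particles). Default `2.5 * cell_radius_um`.
#' @param blur_sigma_px Optional Gaussian blur (pixel SD) applied to the
#'   rendered scene before noise, for robustness testing; 0 disables.
#' @param seed Integer seed; the whole scene is a deterministic function of
#'   the scene spec including the seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width_px = 640, height_px = 480, um_per_px = 0.5,
                       n_red = 50, n_green = 50, cell_radius_um = 4,
                       red_cell_intensity = c(mean = 180, sd = 15),
                       green_cell_intensity = c(mean = 120, sd = 15),
                       off_channel_intensity = 20,
                       background_level = 8, noise_sigma = 3,
                       n_specks = 0, speck_area_um2 = 10,
                       min_separation_um = 2.5 * cell_radius_um,
                       blur_sigma_px = 0, seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` is required: every scene must be replayable.")
  }
  sp <- list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    um_per_px = as.numeric(um_per_px),
    n_red = as.integer(n_red), n_green = as.integer(n_green),
    cell_radius_um = as.numeric(cell_radius_um),
    red_cell_intensity = as.numeric(red_cell_intensity),
    green_cell_intensity = as.numeric(green_cell_intensity),
    off_channel_intensity = as.numeric(off_channel_intensity),
    background_level = as.numeric(background_level),
    noise_sigma = as.numeric(noise_sigma),
    n_specks = as.integer(n_specks),
    speck_area_um2 = as.numeric(speck_area_um2),
    min_separation_um = as.numeric(min_separation_um),
    blur_sigma_px = as.numeric(blur_sigma_px),
    seed = as.integer(seed)
  )
  if (sp$width_px < 1 || sp$height_px < 1) abort("field size must be positive.")
  if (sp$um_per_px <= 0) abort("`um_per_px` must be positive.")
  if (sp$n_red < 0 || sp$n_green < 0 || sp$n_specks < 0) {
    abort("object counts must be non-negative.")
  }
  if (sp$cell_radius_um <= 0) abort("`cell_radius_um` must be positive.")
  if (sp$noise_sigma < 0) abort("`noise_sigma` must be non-negative.")
  if (pi * sp$cell_radius_um^2 < 35) {
    warn("cell footprint is below the default 35 um^2 artefact cutoff; cells would be filtered out by the default configuration.")
  }
  if (sp$speck_area_um2 >= 35) {
    warn("speck area is not below the default 35 um^2 artefact cutoff; specks would count as cells under the default configuration.")
  }
  structure(sp, class = "scene_spec")
}

# Run code under a seed without disturbing the caller's RNG stream.
with_scene_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Sequential rejection placement of disks. `body_r` is each disk's rendered
# radius (px); centres are kept `margin` px inside the border. `extra_sep`
# adds a class-specific minimum centre distance on top of the no-touching
# constraint (body_i + body_j + 2 px).
place_disks <- function(n, nr, nc, body_r, extra_sep = 0,
                        existing = NULL, max_tries = 2000L) {
  if (n == 0) {
    return(tibble(center_row = numeric(), center_col = numeric(),
                  body_r = numeric(), extra = numeric()))
  }
  body_r <- rep_len(body_r, n)
  extra_sep <- rep_len(extra_sep, n)
  rows <- numeric(n); cols <- numeric(n)
  ex_r <- existing$center_row; ex_c <- existing$center_col
  ex_b <- existing$body_r; ex_e <- existing$extra
  for (i in seq_len(n)) {
    margin <- ceiling(body_r[i]) + 1
    if (nr - 2 * margin < 0 || nc - 2 * margin < 0) {
      abort("field too small to place objects of this radius.")
    }
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      r0 <- runif(1, margin + 1, nr - margin)
      c0 <- runif(1, margin + 1, nc - margin)
      ok <- TRUE
      if (length(ex_r) > 0) {
        d <- sqrt((ex_r - r0)^2 + (ex_c - c0)^2)
        need <- pmax(ex_b + body_r[i] + 2, pmax(ex_e, extra_sep[i]))
        ok <- all(d >= need)
      }
      if (ok) {
        rows[i] <- r0; cols[i] <- c0
        ex_r <- c(ex_r, r0); ex_c <- c(ex_c, c0)
        ex_b <- c(ex_b, body_r[i]); ex_e <- c(ex_e, extra_sep[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort("could not place all objects without violating the minimum separation; reduce counts or enlarge the field.")
    }
  }
  tibble(center_row = rows, center_col = cols,
         body_r = body_r, extra = extra_sep)
}

paint_disk <- function(mat, r0, c0, radius, value) {
  rr <- max(1, floor(r0 - radius)):min(nrow(mat), ceiling(r0 + radius))
  cc <- max(1, floor(c0 - radius)):min(ncol(mat), ceiling(c0 + radius))
  sub <- outer((rr - r0)^2, (cc - c0)^2, "+") <= radius^2
  block <- mat[rr, cc, drop = FALSE]
  block[sub] <- value
  mat[rr, cc] <- block
  mat
}

# Separable Gaussian blur via banded kernel matrices (replicate padding
# implicit through kernel renormalisation at the borders).
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  kern_mat <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-d^2 / (2 * sigma^2))
    k[d > ceiling(3 * sigma)] <- 0
    sweep(k, 1, rowSums(k), "/")
  }
  kern_mat(nrow(mat)) %*% mat %*% t(kern_mat(ncol(mat)))
}

#' Render a synthetic field with ground truth
#'
#' Deterministically renders the scene described by a [scene_spec()]: disks
#' with per-cell on-channel intensity drawn from the class distribution, an
#' off-channel level below the classification cutoff, optional specks,
#' optional blur, then pixelwise Gaussian noise, clipped to \[0, 255\].
#'
#' @param spec A [scene_spec()].
#' @param field_id Label for the rendered field.
#' @return List with `field` (a [calibrated_field()]) and `truth`, a list of
#'   `cells` (tibble: `cell_id`, `class`, `center_row`, `center_col`,
#'   `radius_um`, `intensity`), `specks` (tibble: `speck_id`, `channel`,
#'   `center_row`, `center_col`, `radius_um`), `seed` and the `spec` echo.
#' @examples
#' out <- render_field(scene_spec(n_red = 5, n_green = 5, seed = 1))
#' out$truth$cells
#' @export
render_field <- function(spec, field_id = paste0("synthetic_seed", spec$seed)) {
  stopifnot(inherits(spec, "scene_spec"))
  with_scene_seed(spec$seed, {
    nr <- spec$height_px; nc <- spec$width_px
    r_cell <- spec$cell_radius_um / spec$um_per_px
    r_speck <- sqrt(spec$speck_area_um2 / pi) / spec$um_per_px
    min_sep_px <- spec$min_separation_um / spec$um_per_px

    n_cells <- spec$n_red + spec$n_green
    classes <- sample(rep(c("viable", "nonviable"),
                          c(spec$n_red, spec$n_green)))
    cells <- place_disks(n_cells, nr, nc, body_r = r_cell,
                         extra_sep = min_sep_px)
    specks <- place_disks(spec$n_specks, nr, nc, body_r = r_speck,
                          extra_sep = 0, existing = cells)

    red <- matrix(spec$background_level, nr, nc)
    green <- matrix(spec$background_level, nr, nc)
    blue <- matrix(spec$background_level, nr, nc)

    cell_int <- numeric(n_cells)
    for (i in seq_len(n_cells)) {
      pars <- if (classes[i] == "viable") spec$red_cell_intensity
              else spec$green_cell_intensity
      val <- min(255, max(0, rnorm(1, pars[1], pars[2])))
      cell_int[i] <- val
      if (classes[i] == "viable") {
        red <- paint_disk(red, cells$center_row[i], cells$center_col[i],
                          r_cell, val)
        green <- paint_disk(green, cells$center_row[i], cells$center_col[i],
                            r_cell, spec$off_channel_intensity)
      } else {
        green <- paint_disk(green, cells$center_row[i], cells$center_col[i],
                            r_cell, val)
        red <- paint_disk(red, cells$center_row[i], cells$center_col[i],
                          r_cell, spec$off_channel_intensity)
      }
    }

    speck_channel <- character(spec$n_specks)
    for (i in seq_len(spec$n_specks)) {
      speck_channel[i] <- sample(c("red", "green"), 1)
      pars <- if (speck_channel[i] == "red") spec$red_cell_intensity
              else spec$green_cell_intensity
      val <- min(255, max(0, rnorm(1, pars[1], pars[2])))
      if (speck_channel[i] == "red") {
        red <- paint_disk(red, specks$center_row[i], specks$center_col[i],
                          r_speck, val)
      } else {
        green <- paint_disk(green, specks$center_row[i], specks$center_col[i],
                            r_speck, val)
      }
    }

    if (spec$blur_sigma_px > 0) {
      red <- gaussian_blur(red, spec$blur_sigma_px)
      green <- gaussian_blur(green, spec$blur_sigma_px)
      blue <- gaussian_blur(blue, spec$blur_sigma_px)
    }
    px <- array(c(red, green, blue), c(nr, nc, 3))
    if (spec$noise_sigma > 0) {
      px <- px + rnorm(length(px), 0, spec$noise_sigma)
    }
    px <- array(pmin(255, pmax(0, round(px))), c(nr, nc, 3))

    truth <- list(
      cells = tibble(
        cell_id = seq_len(n_cells),
        class = classes,
        center_row = cells$center_row,
        center_col = cells$center_col,
        radius_um = spec$cell_radius_um,
        intensity = cell_int
      ),
      specks = tibble(
        speck_id = seq_len(spec$n_specks),
        channel = speck_channel,
        center_row = specks$center_row,
        center_col = specks$center_col,
        radius_um = sqrt(spec$speck_area_um2 / pi)
      ),
      seed = spec$seed,
      spec = spec
    )
    list(field = calibrated_field(px, spec$um_per_px, field_id = field_id),
         truth = truth)
  })
}

#' Render a viability mixture series
#'
#' Emulates the validation design in which viable and heat-killed cultures
#' are mixed at known ratios (e.g. 1:0, 4:1, 2:1, 1:4, 0:1, i.e. viable
#' fractions 1, 0.8, ~0.67, 0.2, 0) and each mixture is imaged over several
#' fields. `total_cells * fraction`, rounded to nearest, gives each sample's
#' viable count; cells are assigned to fields uniformly at random, so
#' ground-truth totals match the request exactly.
#'
#' @param base A [scene_spec()] providing geometry, intensities and noise;
#'   its `n_red`/`n_green`/`seed` are overridden per sample.
#' @param fractions Numeric vector of true viable fractions in \[0, 1\].
#' @param total_cells Cells per sample (summed over its fields).
#' @param fields_per_sample Number of fields imaged per sample.
#' @param seed Master seed for the series.
#' @param config [assay_config()] attached to each generated run.
#' @return A list with one element per fraction: `fraction`,
#'   `n_viable_true`, `n_nonviable_true`, `run` (a [field_set()]) and
#'   `truth` (list of per-field ground truths).
#' @export
render_mixture_series <- function(base, fractions, total_cells = 200,
                                  fields_per_sample = 4, seed,
                                  config = assay_config()) {
  stopifnot(inherits(base, "scene_spec"))
  if (any(fractions < 0 | fractions > 1)) {
    abort("`fractions` must lie in [0, 1].")
  }
  if (missing(seed)) abort("`seed` is required.")
  with_scene_seed(seed, {
    lapply(seq_along(fractions), function(s) {
      frac <- fractions[s]
      n_viable <- round(total_cells * frac)
      n_nonviable <- total_cells - n_viable
      cls <- rep(c("viable", "nonviable"), c(n_viable, n_nonviable))
      fld_of <- sample(fields_per_sample, length(cls), replace = TRUE)
      field_seeds <- sample.int(.Machine$integer.max, fields_per_sample)
      rendered <- lapply(seq_len(fields_per_sample), function(k) {
        sp <- spec_with(base,
                        n_red = sum(cls == "viable" & fld_of == k),
                        n_green = sum(cls == "nonviable" & fld_of == k),
                        seed = field_seeds[k])
        render_field(sp, field_id = sprintf("mix%02d_field%02d", s, k))
      })
      list(
        fraction = frac,
        n_viable_true = n_viable,
        n_nonviable_true = n_nonviable,
        run = field_set(lapply(rendered, `[[`, "field"), config),
        truth = lapply(rendered, `[[`, "truth")
      )
    })
  })
}

# scene_spec copy with some fields replaced (re-validated)
spec_with <- function(spec, ...) {
  args <- utils::modifyList(unclass(spec), list(...))
  do.call(scene_spec, args)
}

#' Render a synthetic colony plate
#'
#' Bright non-overlapping disks (colonies imaged by phycocyanin
#' autofluorescence) on a dark plate, plus optional sub-area specks, as a
#' single-channel image for [count_colonies()].
#'
#' @param n_colonies Number of colonies.
#' @param min_colony_radius_px Smallest colony radius; radii are drawn
#'   uniformly in `[min, 1.5 * min]`.
#' @param n_specks Specks of radius `speck_radius_px` (keep their area below
#'   the `min_colony_area_px` you intend to count with).
#' @param seed Integer seed.
#' @param width_px,height_px Plate image size.
#' @param colony_intensity `c(mean, sd)` of colony brightness.
#' @param speck_radius_px Speck radius in px. Default 2 (~13 px area).
#' @param background_level Plate background intensity.
#' @param noise_sigma Pixelwise Gaussian noise SD.
#' @return List with `image` (integer matrix in \[0,255\]) and `truth`
#'   (tibble of colony/speck centres and radii, plus the seed).
#' @export
render_plate <- function(n_colonies, min_colony_radius_px = 6, n_specks = 0,
                         seed, width_px = 800, height_px = 800,
                         colony_intensity = c(mean = 200, sd = 10),
                         speck_radius_px = 2, background_level = 10,
                         noise_sigma = 0) {
  if (missing(seed)) abort("`seed` is required.")
  if (n_colonies < 0 || n_specks < 0) abort("counts must be non-negative.")
  with_scene_seed(seed, {
    nr <- height_px; nc <- width_px
    radii <- if (n_colonies > 0) {
      runif(n_colonies, min_colony_radius_px, 1.5 * min_colony_radius_px)
    } else numeric(0)
    colonies <- place_disks(n_colonies, nr, nc, body_r = radii)
    specks <- place_disks(n_specks, nr, nc, body_r = speck_radius_px,
                          existing = colonies)
    img <- matrix(background_level, nr, nc)
    for (i in seq_len(n_colonies)) {
      val <- min(255, max(0, rnorm(1, colony_intensity[1], colony_intensity[2])))
      img <- paint_disk(img, colonies$center_row[i], colonies$center_col[i],
                        radii[i], val)
    }
    for (i in seq_len(n_specks)) {
      val <- min(255, max(0, rnorm(1, colony_intensity[1], colony_intensity[2])))
      img <- paint_disk(img, specks$center_row[i], specks$center_col[i],
                        speck_radius_px, val)
    }
    if (noise_sigma > 0) img <- img + rnorm(length(img), 0, noise_sigma)
    img <- matrix(as.integer(pmin(255, pmax(0, round(img)))), nr, nc)
    truth <- list(
      colonies = tibble(colony_id = seq_len(n_colonies),
                        center_row = colonies$center_row,
                        center_col = colonies$center_col,
                        radius_px = radii),
      specks = tibble(speck_id = seq_len(n_specks),
                      center_row = specks$center_row,
                      center_col = specks$center_col,
                      radius_px = rep(speck_radius_px, n_specks)),
      seed = seed
    )
    list(image = img, truth = truth)
  })
}

#' Write a scene's ground truth as JSON
#'
#' @param truth Ground-truth list from [render_field()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth
  out$spec <- unclass(out$spec)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
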