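test_that("rendering is a deterministic function of the scene spec", {
  sp <- scene_spec(n_red = 10, n_green = 10, n_specks = 20, seed = 1)
  a <- render_field(sp)
  b <- render_field(sp)
  expect_identical(a$field$pixels, b$field$pixels)
  expect_identical(a$truth$cells, b$truth$cells)
  # and does not disturb the caller's RNG stream
  set.seed(77); x1 <- runif(1)
  set.seed(77); invisible(render_field(sp)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("ground truth conserves the requested object counts", {
  sp <- scene_spec(n_red = 12, n_green = 7, n_specks = 9, seed = 2)
  out <- render_field(sp)
  expect_equal(sum(out$truth$cells$class == "viable"), 12)
  expect_equal(sum(out$truth$cells$class == "nonviable"), 7)
  expect_equal(nrow(out$truth$specks), 9)
})

test_that("an empty spec renders background plus noise only", {
  out <- render_field(scene_spec(n_red = 0, n_green = 0, n_specks = 0,
                                 width_px = 64, height_px = 64, seed = 3))
  expect_equal(nrow(out$truth$cells), 0)
  expect_lt(max(out$field$pixels), 30)  # background 8 with sd-3 noise
})

test_that("noise-free class means sit on the correct side of the green cutoff", {
  out <- render_field(scene_spec(n_red = 20, n_green = 20, noise_sigma = 0,
                                 seed = 4))
  res <- run_assay(field_set(out$field))
  p <- res$particles
  expect_true(all(p$mean_green[p$class == "nonviable"] > 50))
  expect_true(all(p$mean_green[p$class == "viable"] < 50))
  # rendered footprints exceed the artefact cutoff
  expect_true(all(p$area_um2 >= 35))
})

test_that("cell placement respects the minimum separation or fails loudly", {
  out <- render_field(scene_spec(n_red = 25, n_green = 25, seed = 5))
  ct <- out$truth$cells
  d <- as.matrix(dist(cbind(ct$center_row, ct$center_col))) * 0.5  # um
  diag(d) <- Inf
  expect_gte(min(d), out$truth$spec$min_separation_um)
  # an impossible request errors instead of looping forever
  expect_error(
    render_field(scene_spec(width_px = 60, height_px = 60, n_red = 50,
                            n_green = 50, seed = 6)),
    "could not place"
  )
})

test_that("mixture series hits the requested per-sample composition exactly", {
  base <- scene_spec(seed = 1)
  series <- render_mixture_series(base, c(1, 0.25), total_cells = 100,
                                  fields_per_sample = 3, seed = 31)
  expect_length(series, 2)
  expect_equal(series[[1]]$n_viable_true, 100)
  expect_equal(series[[1]]$n_nonviable_true, 0)
  expect_equal(series[[2]]$n_viable_true, 25)
  expect_equal(series[[2]]$n_nonviable_true, 75)
  for (s in series) {
    truth_viable <- sum(vapply(s$truth, function(t) {
      sum(t$cells$class == "viable")
    }, numeric(1)))
    expect_equal(truth_viable, s$n_viable_true)
    expect_length(s$run$fields, 3)
  }
})

test_that("plates render deterministically with the requested composition", {
  a <- render_plate(10, 6, n_specks = 5, seed = 9, width_px = 300,
                    height_px = 300)
  b <- render_plate(10, 6, n_specks = 5, seed = 9, width_px = 300,
                    height_px = 300)
  expect_identical(a$image, b$image)
  expect_equal(nrow(a$truth$colonies), 10)
  expect_equal(nrow(a$truth$specks), 5)
  blank <- render_plate(0, 6, seed = 10, width_px = 100, height_px = 100)
  expect_equal(nrow(blank$truth$colonies), 0)
  expect_true(all(blank$image == 10))
})

test_that("scene specs flag geometry that defeats the artefact filter", {
  expect_warning(scene_spec(cell_radius_um = 2, seed = 1), "35 um\\^2")
  expect_warning(scene_spec(speck_area_um2 = 40, seed = 1), "35 um\\^2")
  expect_error(scene_spec(n_red = 10), "seed")
})

test_that("optional blur keeps forced counts intact at moderate strength", {
  out <- render_field(scene_spec(n_red = 15, n_green = 15, noise_sigma = 0,
                                 blur_sigma_px = 1, seed = 12))
  res <- run_assay(field_set(out$field))
  expect_equal(res$n_viable, 15)
  expect_equal(res$n_nonviable, 15)
})
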