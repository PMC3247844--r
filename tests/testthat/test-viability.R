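particle_row <- function(mean_green, id = 1L, field = "f1") {
  tibble::tibble(field_id = field, particle_id = id, area_px = 200L,
                 area_um2 = 50, centroid_row = 10, centroid_col = 10,
                 mean_red = 100, mean_green = mean_green,
                 touches_edge = FALSE)
}

test_that("classification thresholds the mean green intensity strictly at the cutoff", {
  cfg <- assay_config()
  cls <- function(g) classify_particles(particle_row(g), cfg)$class
  expect_equal(cls(120), "nonviable")
  expect_equal(cls(49.9), "viable")
  expect_equal(cls(50.0), "viable")    # boundary: not strictly above
  expect_equal(cls(50.0001), "nonviable")
})

test_that("quantify pools counts and applies the chamber-volume formula", {
  parts <- classify_particles(
    dplyr::bind_rows(lapply(1:2100, function(i) particle_row(20, id = i))))
  res <- quantify(parts)
  expect_equal(res$n_total, 2100)
  # 2100 cells / 0.084 ul * 1000 * dilution 2 = 5e7 cells/ml
  expect_equal(res$concentration_cells_per_ml, 5e7)

  mixed <- classify_particles(dplyr::bind_rows(
    lapply(1:98, function(i) particle_row(20, id = i)),
    lapply(99:100, function(i) particle_row(120, id = i))))
  res2 <- quantify(mixed)
  expect_equal(res2$viable_fraction, 0.98)
  expect_equal(res2$n_viable + res2$n_nonviable, res2$n_total)

  none <- quantify(classify_particles(particle_row(20)[0, ]),
                   field_ids = "f1")
  expect_equal(none$n_total, 0)
  expect_equal(none$concentration_cells_per_ml, 0)
  expect_true(is.na(none$viable_fraction))
})

test_that("concentration is linear in count and dilution factor", {
  mk <- function(n, dil) {
    quantify(
      classify_particles(
        dplyr::bind_rows(lapply(seq_len(n), function(i) particle_row(20, i)))),
      assay_config(dilution_factor = dil)
    )$concentration_cells_per_ml
  }
  expect_equal(mk(200, 2), 2 * mk(100, 2))
  expect_equal(mk(100, 4), 2 * mk(100, 2))
})

test_that("run_assay recovers exact counts on a noise-free field", {
  out <- render_field(scene_spec(n_red = 50, n_green = 50, noise_sigma = 0,
                                 n_specks = 0, seed = 101))
  res <- run_assay(field_set(out$field))
  expect_equal(res$n_viable, 50)
  expect_equal(res$n_nonviable, 50)
  expect_equal(res$viable_fraction, 0.5)
  expect_equal(nrow(res$thresholds), 1)
  expect_false(any(is.na(res$thresholds$t_red)))
})

test_that("a field with both channels degenerate warns and contributes nothing", {
  fld <- field_from_channels(matrix(0, 30, 30), matrix(0, 30, 30))
  expect_warning(res <- run_assay(field_set(fld)), "degenerate")
  expect_equal(res$n_total, 0)
  expect_true(is.na(res$thresholds$t_red))
})

test_that("one-sided cultures process the remaining channel", {
  # fully viable culture: green channel nearly empty is legitimate
  out <- render_field(scene_spec(n_red = 40, n_green = 0, noise_sigma = 0,
                                 seed = 102))
  res <- run_assay(field_set(out$field))
  expect_equal(res$n_viable, 40)
  expect_equal(res$n_nonviable, 0)
})

test_that("swapping channels swaps the class counts on symmetric scenes", {
  sp <- scene_spec(n_red = 30, n_green = 10,
                   red_cell_intensity = c(150, 10),
                   green_cell_intensity = c(150, 10),
                   noise_sigma = 0, seed = 103)
  out <- render_field(sp)
  res <- run_assay(field_set(out$field))
  swapped <- out$field
  swapped$pixels <- swapped$pixels[, , c(2, 1, 3)]
  res_sw <- run_assay(field_set(swapped))
  expect_equal(res$n_viable, 30)
  expect_equal(res$n_nonviable, 10)
  expect_equal(res_sw$n_viable, res$n_nonviable)
  expect_equal(res_sw$n_nonviable, res$n_viable)
})

test_that("tidy and glance expose per-field and run-level summaries", {
  out1 <- render_field(scene_spec(n_red = 10, n_green = 5, noise_sigma = 0,
                                  seed = 104), field_id = "f1")
  out2 <- render_field(scene_spec(n_red = 0, n_green = 8, noise_sigma = 0,
                                  seed = 105), field_id = "f2")
  res <- run_assay(field_set(list(out1$field, out2$field)))
  td <- tidy(res)
  expect_equal(td$field_id, c("f1", "f2"))
  expect_equal(td$n_viable, c(10L, 0L))
  expect_equal(td$n_nonviable, c(5L, 8L))
  expect_true(all(c("t_red", "t_green") %in% names(td)))
  g <- glance(res)
  expect_equal(g$n_total, 23)
  expect_equal(g$viable_percent, 100 * 10 / 23)
})
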