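test_that("mask combination is a pixelwise OR with the usual identities", {
  a <- matrix(c(TRUE, FALSE), 1, 2)
  b <- matrix(c(FALSE, TRUE), 1, 2)
  expect_identical(combine_masks(a, b), matrix(TRUE, 1, 2))
  expect_identical(combine_masks(a, matrix(FALSE, 1, 2)), a)
  expect_identical(combine_masks(a, a), a)
  expect_error(combine_masks(a, matrix(TRUE, 2, 2)), "dimensions")
})

test_that("connectivity semantics: diagonal pixels join under 8 but not 4", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE
  m[3, 3] <- TRUE
  expect_equal(max(label_components(m, 8)), 1)
  expect_equal(max(label_components(m, 4)), 2)
})

test_that("labelling agrees with EBImage::bwlabel under 4-connectivity", {
  set.seed(31)
  for (i in 1:5) {
    m <- matrix(runif(60 * 60) < 0.35, 60, 60)
    ours <- label_components(m, 4)
    ref <- EBImage::bwlabel(m * 1)
    expect_equal(max(ours), max(ref))
    # identical partition: each of our labels maps to exactly one reference label
    expect_true(all(tapply(ref[m], ours[m], function(v) length(unique(v))) == 1))
    expect_true(all(tapply(ours[m], ref[m], function(v) length(unique(v))) == 1))
  }
})

test_that("particle measurements: area, calibrated area, centroid, raw-channel means", {
  red <- matrix(0, 20, 20)
  green <- matrix(0, 20, 20)
  mask <- matrix(FALSE, 20, 20)
  mask[3:5, 3:5] <- TRUE      # 3x3 square
  mask[10:12, 14:16] <- TRUE  # second, disjoint
  red[3:5, 3:5] <- 200
  green[3:5, 3:5] <- 120
  green[10:12, 14:16] <- 40
  fld <- field_from_channels(red, green, um_per_px = 0.5)

  ps <- register_particles(mask, fld)
  expect_equal(nrow(ps), 2)
  expect_equal(ps$area_px, c(9L, 9L))
  expect_equal(ps$area_um2, c(2.25, 2.25))       # 9 px * 0.25 um^2
  expect_equal(ps$centroid_row[1], 4)
  expect_equal(ps$centroid_col[1], 4)
  expect_equal(ps$mean_red, c(200, 0))
  expect_equal(ps$mean_green, c(120, 40))
  expect_false(any(ps$touches_edge))
  expect_equal(sum(ps$area_px), sum(mask))       # pixel conservation
})

test_that("edge-touching particles are flagged and droppable", {
  mask <- matrix(FALSE, 10, 10)
  mask[1, 1:3] <- TRUE      # touches border
  mask[5:6, 5:6] <- TRUE    # interior
  fld <- field_from_channels(matrix(0, 10, 10), matrix(0, 10, 10))
  ps <- register_particles(mask, fld)
  expect_equal(sum(ps$touches_edge), 1)
  cfg <- assay_config(include_edge_particles = FALSE)
  ps2 <- register_particles(mask, fld, cfg)
  expect_equal(nrow(ps2), 1)
  expect_false(any(ps2$touches_edge))
})

test_that("artifact filter is a strict < 35 um^2 exclusion at the printed boundary", {
  # at 0.5 um/px each pixel is 0.25 um^2: 139 px = 34.75 um^2, 140 px = 35 um^2
  fld <- field_from_channels(matrix(0, 60, 60), matrix(0, 60, 60),
                             um_per_px = 0.5)
  for (case in list(list(n = 139L, kept = 0L), list(n = 140L, kept = 1L))) {
    ps <- register_particles(blob_mask(60, 60, case$n), fld)
    expect_equal(nrow(ps), 1)
    kept <- filter_artifacts(ps)
    expect_equal(nrow(kept), case$kept)
  }
})

test_that("artifact filter is idempotent and preserves ids and order", {
  fld <- field_from_channels(matrix(0, 80, 80), matrix(0, 80, 80), 0.5)
  mask <- blob_mask(80, 80, 150, at = c(5, 5)) |
    blob_mask(80, 80, 20, at = c(40, 40)) |
    blob_mask(80, 80, 200, at = c(60, 5))
  ps <- register_particles(mask, fld)
  once <- filter_artifacts(ps)
  expect_identical(filter_artifacts(once), once)
  expect_identical(once$particle_id, ps$particle_id[ps$area_um2 >= 35])
  expect_identical(filter_artifacts(ps[0, ]), ps[0, ])
  big <- ps[ps$area_um2 >= 35, ]
  expect_identical(filter_artifacts(big), big)
})

test_that("empty masks register no particles", {
  fld <- field_from_channels(matrix(0, 10, 10), matrix(0, 10, 10))
  ps <- register_particles(matrix(FALSE, 10, 10), fld)
  expect_equal(nrow(ps), 0)
})
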