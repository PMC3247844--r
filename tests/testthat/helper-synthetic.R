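# Shared fixture builders. Everything is generated in code; no image files
# ship with the tests.

# Random bimodal-ish histogram as a 256-bin count vector.
random_histogram <- function(seed) {
  set.seed(seed)
  m1 <- sample(5:90, 1)
  m2 <- sample(110:245, 1)
  v <- c(round(rnorm(sample(500:5000, 1), m1, sample(3:20, 1))),
         round(rnorm(sample(100:3000, 1), m2, sample(3:25, 1))))
  tabulate(pmin(255, pmax(0, v)) + 1L, nbins = 256L)
}

# Field whose pixels are given explicitly per channel (matrices).
field_from_channels <- function(red, green, um_per_px = 0.5,
                                field_id = "manual") {
  blue <- matrix(0, nrow(red), ncol(red))
  calibrated_field(array(c(red, green, blue), c(dim(red), 3)),
                   um_per_px, field_id = field_id)
}

# A connected blob of exactly `n_px` pixels inside an otherwise FALSE mask,
# grown row-wise from a corner of a bounding box.
blob_mask <- function(nrow_img, ncol_img, n_px, at = c(10, 10), width = 14) {
  mask <- matrix(FALSE, nrow_img, ncol_img)
  rows <- at[1] + (seq_len(n_px) - 1) %/% width
  cols <- at[2] + (seq_len(n_px) - 1) %% width
  mask[cbind(rows, cols)] <- TRUE
  mask
}
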