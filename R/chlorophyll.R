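#' Chlorophyll concentration of a methanol extract
#'
#' Converts the absorbance at 650 nm of a methanol extract into a chlorophyll
#' concentration:
#' \deqn{\mathrm{chlorophyll}\ (\mu g/ml) = \frac{A_{650} \times 13.9}{V}}
#' with the standard protocol extracting the pellet of `V = 2` ml of culture.
#' The coefficient 13.9 is the methanol-extraction calibration constant; both
#' it and the volume are exposed so other extraction protocols can reuse the
#' formula.
#'
#' @param abs650 Absorbance at 650 nm (non-negative; vectorised).
#' @param sample_volume_ml Volume of culture pelleted for the extraction, ml.
#'   Default 2.
#' @param coefficient Calibration coefficient. Default 13.9.
#' @return Chlorophyll concentration in ug/ml.
#' @examples
#' chlorophyll_ug_per_ml(1.0)   # 6.95
#' chlorophyll_ug_per_ml(0.5)   # 3.475
#' @export
chlorophyll_ug_per_ml <- function(abs650, sample_volume_ml = 2,
                                  coefficient = 13.9) {
  if (!is.numeric(abs650) || length(abs650) == 0 || anyNA(abs650) ||
      any(abs650 < 0)) {
    abort("`abs650` must be non-negative absorbance value(s).")
  }
  if (!is.numeric(sample_volume_ml) || length(sample_volume_ml) != 1 ||
      is.na(sample_volume_ml) || sample_volume_ml <= 0) {
    abort("`sample_volume_ml` must be a single positive number.")
  }
  abs650 * coefficient / sample_volume_ml
}
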