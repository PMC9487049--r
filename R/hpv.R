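#' Classify tumor HPV status
#'
#' A tumor counts as HPV-positive only on double positivity: HPV DNA detected
#' *and* diffuse p16INK4a immunostaining in at least 70% of tumor cells
#' (inclusive threshold).
#'
#' @param hpv_dna_positive logical; HPV DNA detected by PCR.
#' @param p16_percent_stained percentage of tumor cells with strong p16
#'   staining, in `[0, 100]`.
#' @return character vector, `"positive"` or `"negative"` (vectorized).
#' @examples
#' classify_hpv_status(TRUE, 85)   # "positive"
#' classify_hpv_status(TRUE, 69.9) # "negative"
#' classify_hpv_status(FALSE, 100) # "negative"
#' @export
classify_hpv_status <- function(hpv_dna_positive, p16_percent_stained) {
  if (!is.logical(hpv_dna_positive)) .err("'hpv_dna_positive' must be logical")
  p <- as.numeric(p16_percent_stained)
  if (anyNA(p) || any(p < 0 | p > 100)) {
    .err("'p16_percent_stained' must lie in [0, 100]")
  }
  ifelse(hpv_dna_positive & p >= 70, "positive", "negative")
}
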