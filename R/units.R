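#' Unit conversion registry
#'
#' All volume arithmetic inside the package is done in mm^3 (nodule scale) or
#' um^3 (bacteroid scale); rates in umol/h. Conversions between scales use the
#' exact factors below, centralized so no literal appears twice.
#'
#' @format A named list of exact conversion factors:
#' \describe{
#'   \item{mm3_to_um3}{1e9 cubic micrometres per cubic millimetre}
#'   \item{mm3_to_cm3}{1e-3 cubic centimetres per cubic millimetre}
#'   \item{umol_to_nmol}{1e3}
#'   \item{umol_to_amol}{1e12}
#'   \item{ug_to_mg}{1e-3}
#'   \item{N2_molar_mass}{28.0134 g/mol for dinitrogen}
#' }
#' @export
unit_registry <- list(
  mm3_to_um3   = 1e9,
  mm3_to_cm3   = 1e-3,
  umol_to_nmol = 1e3,
  umol_to_amol = 1e12,
  ug_to_mg     = 1e-3,
  N2_molar_mass = 28.0134
)

# internal: positive scalar/vector check with a readable error
.check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' must be finite numeric", name), call. = FALSE)
  }
  bad <- if (strict) any(x <= 0) else any(x < 0)
  if (bad) {
    stop(sprintf("'%s' must be %s", name, if (strict) "> 0" else ">= 0"),
         call. = FALSE)
  }
  invisible(x)
}
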