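#' Unit conversions used throughout the package
#'
#' All geometry is in millimetres, solid stresses in kPa, and wall shear
#' stress in dyn/cm^2 (the unit cardiovascular papers report). Pressures are
#' entered in mmHg and converted once, here.
#'
#' @param mmHg,kPa numeric vectors.
#' @return Converted numeric vector.
#' @examples
#' mmHg_to_kPa(100)      # 13.3322 kPa
#' kPa_to_dyncm2(1)      # 1e4 dyn/cm^2
#' @name units
NULL

#' @rdname units
#' @export
mmHg_to_kPa <- function(mmHg) mmHg * 0.133322

#' @rdname units
#' @export
kPa_to_mmHg <- function(kPa) kPa / 0.133322

#' @rdname units
#' @export
kPa_to_dyncm2 <- function(kPa) kPa * 1e4
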