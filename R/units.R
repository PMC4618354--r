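#' Unit conversions between bench units and CGS
#'
#' Internally the package works in CGS units (cm, seconds, arbitrary
#' concentration). Measured pulse kinetics are conventionally quoted in
#' mm/hr (velocity) and mm^2/hr (spreading rate); these helpers convert
#' between the two systems and are used by every presentation-level
#' function.
#'
#' @param x numeric vector of values to convert.
#' @return numeric vector in the target unit.
#' @examples
#' mmhr_to_cms(36000)   # 1 cm/s
#' cm2s_to_mm2hr(1e-5)  # 3.6 mm^2/hr
#' @name units
NULL

#' @rdname units
#' @export
cms_to_mmhr <- function(x) x * 36000

#' @rdname units
#' @export
mmhr_to_cms <- function(x) x / 36000

#' @rdname units
#' @export
cm2s_to_mm2hr <- function(x) x * 360000

#' @rdname units
#' @export
mm2hr_to_cm2s <- function(x) x / 360000

#' @rdname units
#' @export
um_to_cm <- function(x) x * 1e-4

#' @rdname units
#' @export
cm_to_mm <- function(x) x * 10

#' @rdname units
#' @export
mm_to_cm <- function(x) x / 10
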