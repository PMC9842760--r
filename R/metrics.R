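#' Assay metrics
#'
#' Small closed-form assay quantities used alongside the genomics
#' pipeline: LDH-release cytotoxicity and caliper tumor volume.
#'
#' @name metrics
NULL

#' LDH-release cytotoxicity (%)
#'
#' `100 * (treated - spontaneous) / (maximum - spontaneous)` on OD490
#' readings. Values below 0% or above 100% are reported as-is with a
#' warning flag attribute.
#'
#' @param od_treated OD490 of interferon-treated LDH activity.
#' @param od_spontaneous OD490 of spontaneous LDH activity.
#' @param od_maximum OD490 of maximum (full-lysis) LDH activity.
#' @return Percent cytotoxicity (vectorized).
#' @export
ldh_cytotoxicity <- function(od_treated, od_spontaneous, od_maximum) {
  if (any(c(od_treated, od_spontaneous, od_maximum) < 0))
    stop("OD readings must be non-negative")
  if (any(od_maximum <= od_spontaneous))
    stop("maximum LDH activity must exceed spontaneous activity")
  pct <- 100 * (od_treated - od_spontaneous) / (od_maximum - od_spontaneous)
  out_of_range <- pct < 0 | pct > 100
  if (any(out_of_range))
    attr(pct, "out_of_range") <- which(out_of_range)
  pct
}

#' Caliper tumor volume (mm^3)
#'
#' `volume = length x width^2 x 0.5`, with length the longer axis.
#' Measurements in cm are converted to mm first.
#'
#' @param length,width Caliper measurements (positive; length >= width).
#' @param unit `"mm"` (default) or `"cm"`.
#' @return Volume in mm^3 (vectorized).
#' @export
tumor_volume <- function(length, width, unit = c("mm", "cm")) {
  unit <- match.arg(unit)
  if (any(length <= 0) || any(width <= 0))
    stop("measurements must be positive")
  if (any(width > length))
    stop("length must be the longer axis (length >= width)")
  if (unit == "cm") {
    length <- length * 10
    width <- width * 10
  }
  length * width^2 * 0.5
}
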