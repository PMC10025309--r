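# Semi-quantification against a deuterated injection standard, and the
# detection floor that turns trace peaks into "not detected".

#' Deuterated injection standard
#'
#' Describes the internal (injection) standard added to each sample just
#' before GC-MS analysis. The defaults mirror common practice for 3-OH FA
#' work: a 0.5 mg/mL solution of a deuterated 3-hydroxy acid, 3 uL of
#' standard per 100 uL of sample, i.e. 1.5 ug injected. The deuterated
#' fragment used for integration (m/z 178 vs 175 for the analytes) is
#' metadata only; no spectra are modelled.
#'
#' @param measured_area Integrated peak area of the standard (same arbitrary
#'   units as the analyte areas); must be positive for quantification.
#' @param concentration Standard concentration in mg/mL (> 0).
#' @param volume_added Volume of standard added per sample aliquot, in uL
#'   (> 0).
#' @return An object of class `internal_standard` with the derived
#'   `amount_injected` in ug (`concentration * volume_added`).
#' @export
internal_standard <- function(measured_area, concentration = 0.5,
                              volume_added = 3) {
  if (!is.numeric(concentration) || concentration <= 0) {
    stop("standard concentration must be > 0", call. = FALSE)
  }
  if (!is.numeric(volume_added) || volume_added <= 0) {
    stop("standard volume must be > 0", call. = FALSE)
  }
  if (!is.numeric(measured_area) || length(measured_area) != 1L ||
      is.na(measured_area) || measured_area < 0) {
    stop("measured standard area must be a non-negative number",
         call. = FALSE)
  }
  structure(
    list(concentration = concentration,     # mg/mL
         volume_added = volume_added,       # uL
         amount_injected = concentration * volume_added,  # ug
         measured_area = measured_area),
    class = "internal_standard"
  )
}

#' Semi-quantify a peak area against the injection standard
#'
#' Single-point linear response: the amount of analyte (ug per sample
#' aliquot) is the amount of standard injected scaled by the area ratio,
#' `amount_injected * response_factor * area / standard_area`. No
#' per-compound calibration curve is assumed (response factor 1); a
#' per-compound multiplier can be supplied if response factors become
#' available.
#'
#' @param area Non-negative numeric vector of analyte peak areas.
#' @param standard An [internal_standard()] with `measured_area > 0`.
#' @param response_factor Positive multiplier (default 1).
#' @return Numeric vector of amounts in ug.
#' @export
semi_quantify <- function(area, standard, response_factor = 1) {
  stopifnot(inherits(standard, "internal_standard"))
  if (standard$measured_area <= 0) {
    stop("cannot semi-quantify: the injection standard's measured area is 0",
         call. = FALSE)
  }
  if (any(area < 0, na.rm = TRUE)) {
    stop("peak areas must be non-negative", call. = FALSE)
  }
  if (any(response_factor <= 0)) {
    stop("response factor must be > 0", call. = FALSE)
  }
  standard$amount_injected * response_factor * area / standard$measured_area
}

#' Apply a detection floor to measurements
#'
#' Values strictly below `floor` become undetected (n.d.); values at or
#' above the floor are unchanged. With `floor = 0` this is the identity.
#' Models how low-abundance homologues vanish from printed tables.
#'
#' @param x A measurement data frame ([fa_measurements()]) or a
#'   [sample_profile()].
#' @param floor Non-negative threshold in the units of `value`.
#' @return Object of the same type as `x`.
#' @export
apply_detection_floor <- function(x, floor) {
  if (!is.numeric(floor) || length(floor) != 1L || is.na(floor) || floor < 0) {
    stop("detection floor must be a non-negative number", call. = FALSE)
  }
  if (inherits(x, "sample_profile")) {
    x$measurements <- apply_detection_floor(x$measurements, floor)
    return(x)
  }
  drop <- x$detected & !is.na(x$value) & x$value < floor
  x$value[drop] <- NA_real_
  x$detected[drop] <- FALSE
  x
}
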