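#' Clinical cardiac-function targets
#'
#' Measured targets used for model personalization: systolic/diastolic cuff
#' pressure \[mmHg\], stroke volume \[mL\], ejection fraction \[-\], and
#' optionally heart rate \[bpm\], cardiac output \[L/min\] and ventricular
#' volumes \[mL\].
#'
#' @param sbp,dbp systolic and diastolic blood pressure \[mmHg\].
#' @param stroke_volume stroke volume \[mL\].
#' @param ejection_fraction LV ejection fraction, in (0, 1).
#' @param heart_rate heart rate \[bpm\] (default 70).
#' @param cardiac_output optional \[L/min\]; derived from SV and HR if NULL.
#' @param edv,esv optional end-diastolic/systolic volumes \[mL\].
#' @return an object of class `clinical_targets`.
#' @export
clinical_targets <- function(sbp, dbp, stroke_volume, ejection_fraction,
                             heart_rate = 70, cardiac_output = NULL,
                             edv = NULL, esv = NULL) {
  stopifnot(sbp > dbp, dbp > 0)
  stopifnot(ejection_fraction > 0, ejection_fraction < 1)
  stopifnot(stroke_volume > 0, heart_rate > 0)
  if (is.null(cardiac_output)) {
    cardiac_output <- stroke_volume * heart_rate / 1000
  }
  structure(list(sbp = sbp, dbp = dbp, stroke_volume = stroke_volume,
                 ejection_fraction = ejection_fraction,
                 heart_rate = heart_rate, cardiac_output = cardiac_output,
                 edv = edv, esv = esv),
            class = "clinical_targets")
}

#' Reference patient target presets
#'
#' A small table of measured cardiac-function presets (BP, SV, LVEF) spanning
#' the clinical range used for testing and for the synthetic patient
#' generator; `patient` selects a row.
#'
#' @param patient integer 1..6.
#' @return a `clinical_targets` object.
#' @export
preset_targets <- function(patient = 2L) {
  tab <- data.frame(
    sbp = c(132, 137, 135, 156, 109, 162),
    dbp = c(69, 73, 80, 72, 75, 65),
    sv  = c(66.3, 40.4, 67.2, 58.4, 80.4, 52.1),
    ef  = c(0.68, 0.65, 0.60, 0.60, 0.60, 0.63)
  )
  stopifnot(patient >= 1, patient <= nrow(tab))
  r <- tab[patient, ]
  clinical_targets(sbp = r$sbp, dbp = r$dbp, stroke_volume = r$sv,
                   ejection_fraction = r$ef)
}

#' Mean arterial pressure from cuff values
#'
#' The standard clinical estimate dbp + (sbp - dbp)/3, in mmHg.
#'
#' @param targets a `clinical_targets`.
#' @return mean arterial pressure \[mmHg\].
#' @export
mean_arterial_pressure <- function(targets) {
  targets$dbp + (targets$sbp - targets$dbp) / 3
}

#' Read / write clinical targets as JSON
#' @param path file path.
#' @return `read_targets`: a `clinical_targets`.
#' @export
read_targets <- function(path) {
  x <- jsonlite::fromJSON(path)
  clinical_targets(sbp = x$sbp, dbp = x$dbp, stroke_volume = x$stroke_volume,
                   ejection_fraction = x$ejection_fraction,
                   heart_rate = if (is.null(x$heart_rate)) 70 else x$heart_rate,
                   cardiac_output = x$cardiac_output,
                   edv = x$edv, esv = x$esv)
}

#' @rdname read_targets
#' @param targets a `clinical_targets`.
#' @export
write_targets <- function(targets, path) {
  jsonlite::write_json(unclass(targets), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
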