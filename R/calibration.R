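#' Physical scale calibration from scanner resolution
#'
#' Converts the scanner resolution (dots per inch) into the physical size of a
#' pixel. All downstream lengths are derived from this: skeleton edge lengths,
#' root diameters, hair lengths. One inch is 25.4 mm, so a pixel spans
#' `25.4 / dpi` mm and one centimetre spans `dpi / 2.54` pixels.
#'
#' @param dpi scanner resolution in dots per inch (positive).
#' @return an object of class `scale_calibration` with fields `dpi`,
#'   `mm_per_px` and `px_per_cm`.
#' @examples
#' cal <- calibrate(1200)
#' cal$mm_per_px # 0.02116667
#' @export
calibrate <- function(dpi) {
  if (!is.numeric(dpi) || length(dpi) != 1L || !is.finite(dpi) || dpi <= 0)
    stop("`dpi` must be a single positive number")
  structure(
    list(dpi = dpi, mm_per_px = 25.4 / dpi, px_per_cm = dpi / 2.54),
    class = "scale_calibration"
  )
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf("scale_calibration: %g dpi (%.6g mm/px, %.6g px/cm)\n",
              x$dpi, x$mm_per_px, x$px_per_cm))
  invisible(x)
}

# pixel path length -> mm, given a calibration
px_to_mm <- function(px, calibration) px * calibration$mm_per_px
mm_to_px <- function(mm, calibration) mm / calibration$mm_per_px
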