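#' @title Image records, series catalogs and raster I/O
#' @name imageio
#' @description
#' A scanner acquisition campaign produces, per pot, one frame per day at one
#' or two resolutions: a morphology resolution (default 1200 dpi) for root
#' traits and lifespan, and a hair resolution (default 4800 dpi) on which
#' individual root hairs become visible. Frames are encoded on disk as PNG or
#' TIFF with the acquisition metadata in the file name; the default convention
#' is `pot<ID>_d<DAY>_<DPI>dpi.png`, e.g. `pot03_d014_1200dpi.png`.
NULL

# default file-name convention: pot id, day after sowing, dpi, extension
DEFAULT_NAMING_PATTERN <- "^pot(\\d+)_d(\\d+)_(\\d+)dpi\\.(png|tif|tiff)$"

#' Default hair-resolution threshold (dpi)
#'
#' Frames at or above this resolution are classed as hair-resolution frames;
#' root hairs are only quantified on such frames.
#' @export
HAIR_DPI_DEFAULT <- 4800

image_record <- function(path, pot_id, day, dpi,
                         hair_dpi_threshold = HAIR_DPI_DEFAULT) {
  stopifnot(day >= 0, dpi >= 50, dpi <= 4800)
  structure(
    list(path = path, pot_id = pot_id, day = as.integer(day),
         dpi = as.integer(dpi),
         resolution_class = if (dpi >= hair_dpi_threshold) "hair" else "morphology"),
    class = "image_record"
  )
}

new_image_series <- function(pot_id, records, frame_width_cm, frame_height_cm) {
  stopifnot(frame_width_cm > 0, frame_height_cm > 0)
  days <- vapply(records, `[[`, integer(1), "day")
  records <- records[order(days)]
  days <- sort(days)
  if (anyDuplicated(days))
    stop("duplicate days within series: ", paste(days[duplicated(days)], collapse = ", "))
  dpis <- unique(vapply(records, `[[`, integer(1), "dpi"))
  if (length(dpis) > 1L)
    stop("records of one series must share dpi; found: ", paste(dpis, collapse = ", "))
  structure(
    list(pot_id = pot_id, records = records,
         frame_width_cm = frame_width_cm, frame_height_cm = frame_height_cm,
         dpi = dpis, days = days),
    class = "image_series"
  )
}

#' @export
print.image_series <- function(x, ...) {
  cat(sprintf("image_series: pot %s, %d frames (days %s..%s) at %d dpi, frame %.3g x %.3g cm\n",
              x$pot_id, length(x$records), min(x$days), max(x$days), x$dpi,
              x$frame_width_cm, x$frame_height_cm))
  invisible(x)
}

#' Frame area of an image series
#'
#' Physical area (cm^2) of the observed rhizotron frame; the `A` of the root
#' length density formula `RLD = RL / (A x DOF)`.
#' @param series an `image_series`.
#' @export
frame_area_cm2 <- function(series) series$frame_width_cm * series$frame_height_cm

#' Load a per-pot time series of scanner frames from a directory
#'
#' Scans `directory` for files matching `naming_pattern` (a regex with three
#' capture groups: pot id, day after sowing, dpi), keeps the requested pot and
#' resolution, and returns the frames sorted by day. Files that do not match
#' the pattern are skipped with a warning naming each file.
#'
#' @param directory path containing the frames.
#' @param naming_pattern regex with capture groups `(pot)(day)(dpi)`; the
#'   default matches names like `pot03_d001_1200dpi.png`.
#' @param pot_id keep only this pot; if `NULL` the directory must contain a
#'   single pot.
#' @param dpi keep only frames at this resolution; if `NULL` the catalog must
#'   be single-resolution.
#' @param frame_width_cm,frame_height_cm physical size of the scanned window.
#'   The rhizotron face used here is 20 cm wide by 34 cm tall; the scanned
#'   window may be smaller, so both are overridable.
#' @param hair_dpi_threshold dpi at or above which frames are classed as
#'   hair-resolution.
#' @return an `image_series`.
#' @export
load_series <- function(directory,
                        naming_pattern = DEFAULT_NAMING_PATTERN,
                        pot_id = NULL, dpi = NULL,
                        frame_width_cm = 20, frame_height_cm = 34,
                        hair_dpi_threshold = HAIR_DPI_DEFAULT) {
  if (!dir.exists(directory)) stop("directory not found: ", directory)
  files <- list.files(directory)
  files <- files[!dir.exists(file.path(directory, files))]
  is_raster <- grepl("\\.(png|tif|tiff)$", files, ignore.case = TRUE)
  m <- regmatches(files, regexec(naming_pattern, files, ignore.case = TRUE))
  parsed <- lengths(m) >= 4L
  for (f in files[is_raster & !parsed])
    warning("skipping file with unparsable name: ", f, call. = FALSE)
  files <- files[parsed]
  if (length(files) == 0L) stop("no frames found in ", directory)
  meta <- do.call(rbind, lapply(m[parsed], function(g)
    data.frame(pot = as.integer(g[2]), day = as.integer(g[3]),
               dpi = as.integer(g[4]), stringsAsFactors = FALSE)))
  meta$file <- files

  key <- paste(meta$pot, meta$day, meta$dpi)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    clash <- meta$file[key == d]
    stop("duplicate (pot, day, dpi) frames: ", paste(clash, collapse = " and "))
  }
  if (!is.null(pot_id)) meta <- meta[meta$pot == pot_id, , drop = FALSE]
  if (!is.null(dpi)) meta <- meta[meta$dpi == dpi, , drop = FALSE]
  if (nrow(meta) == 0L) stop("no frames found for requested pot/dpi")
  if (length(unique(meta$pot)) > 1L)
    stop("multiple pots present (", paste(unique(meta$pot), collapse = ", "),
         "); pass `pot_id`")
  if (length(unique(meta$dpi)) > 1L)
    stop("multiple resolutions present (", paste(unique(meta$dpi), collapse = ", "),
         "); pass `dpi`")
  records <- lapply(seq_len(nrow(meta)), function(i)
    image_record(file.path(directory, meta$file[i]), meta$pot[i], meta$day[i],
                 meta$dpi[i], hair_dpi_threshold))
  new_image_series(unique(meta$pot), records, frame_width_cm, frame_height_cm)
}

#' Catalog manifest of an image series
#'
#' @param series an `image_series`.
#' @return data.frame with columns `pot_id`, `day`, `dpi`, `path`.
#' @export
series_catalog <- function(series) {
  data.frame(
    pot_id = vapply(series$records, `[[`, integer(1), "pot_id"),
    day = vapply(series$records, `[[`, integer(1), "day"),
    dpi = vapply(series$records, `[[`, integer(1), "dpi"),
    path = vapply(series$records, `[[`, character(1), "path"),
    stringsAsFactors = FALSE
  )
}

#' Read a raster frame as an RGB array
#'
#' @param x an `image_record` or a file path (PNG or TIFF).
#' @return numeric array `height x width x 3`, values in `[0, 1]`.
#' @export
read_frame <- function(x) {
  if (inherits(x, "image_record") && !is.null(x$pixels)) return(x$pixels)
  path <- if (inherits(x, "image_record")) x$path else x
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext)
  )
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE] # drop alpha
  px
}

write_frame <- function(pixels, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(pixels, path),
    tif = ,
    tiff = tiff::writeTIFF(pixels, path, compression = "none"),
    stop("unsupported raster format: .", ext)
  )
  invisible(path)
}

#' Write a binary root mask as a black/white image
#'
#' Foreground (root) pixels are written white, background black — the
#' convention expected by downstream root-morphology software. The format is
#' lossless, so a write/read round trip is bit exact.
#'
#' @param mask binary matrix (values 0/1 or logical).
#' @param path output path (`.png`, `.tif`/`.tiff`).
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  write_frame(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
}

#' Read a binary mask written by [write_mask()]
#'
#' @param path image path.
#' @return binary integer matrix (0 background, 1 root).
#' @export
read_mask <- function(path) {
  px <- read_frame(path)
  m <- px[, , 1]
  (m > 0.5) + 0L
}

# validate and coerce a mask to an integer 0/1 matrix
as_binary_mask <- function(mask) {
  if (is.logical(mask)) mask <- mask + 0L
  if (!is.matrix(mask) && !(is.array(mask) && length(dim(mask)) == 2L))
    stop("mask must be a 2-D matrix")
  v <- unique(as.vector(mask))
  if (!all(v %in% c(0, 1))) stop("mask is not binary (values outside {0, 1})")
  matrix(as.integer(mask), nrow(mask), ncol(mask))
}
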