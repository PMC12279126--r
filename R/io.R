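#' Read and write radiographs (PNG/TIFF with a JSON spacing sidecar)
#'
#' Images are stored as 8- or 16-bit PNG or TIFF; because neither format
#' carries physical units, the pixel spacing travels in a JSON sidecar
#' (`<image>.json` with field `spacing_mm`) written alongside the image.
#' Gray levels are mapped to 0-255 on read.
#'
#' @param path Image path (`.png`, `.tif`, `.tiff`).
#' @param spacing Spacing in mm/pixel; if `NULL`, read from the sidecar.
#' @param id Identifier; defaults to the file name.
#' @return A [radiograph].
#' @export
read_radiograph <- function(path, spacing = NULL, id = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stopf("apexfa_io_error", "unsupported image format '%s'", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]     # first channel of RGB(A)
  if (is.null(spacing)) {
    sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
    if (!file.exists(sidecar)) {
      stopf("apexfa_io_error",
            "no spacing given and no sidecar %s", basename(sidecar))
    }
    spacing <- jsonlite::read_json(sidecar)$spacing_mm
  }
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  radiograph(img * 255, spacing, id = id)
}

#' @rdname read_radiograph
#' @param x A [radiograph].
#' @param bits Bit depth for PNG output (8 or 16).
#' @export
write_radiograph <- function(x, path, bits = 8L) {
  stopifnot(inherits(x, "radiograph"))
  ext <- tolower(tools::file_ext(path))
  v <- pmin(pmax(x$pixels / 255, 0), 1)
  switch(ext,
         png = png::writePNG(v, path, dpi = NULL,
                             asp = NULL),
         tif = ,
         tiff = tiff::writeTIFF(v, path, bits.per.sample = as.integer(bits)),
         stopf("apexfa_io_error", "unsupported image format '%s'", ext))
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(list(spacing_mm = x$spacing, id = x$id), sidecar,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
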