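# Grayscale image I/O. 16-bit TIFF is the canonical output; PNG is accepted
# on input. Every written image gets a JSON sidecar recording pixel size,
# the linear intensity mapping, and any run parameters, so results can be
# reproduced exactly.

#' Write an image as 16-bit grayscale TIFF with a JSON sidecar
#'
#' Values are mapped linearly onto the 16-bit range; the mapping (min, max)
#' and the pixel size are stored in `<path>.json` so [read_micrograph()]
#' can restore physical values.
#'
#' @param image an [image_grid()].
#' @param path output file path (`.tif`/`.tiff`).
#' @param params optional named list of run parameters echoed into the
#'   sidecar.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(image, path, params = list()) {
  stopifnot(inherits(image, "image_grid"))
  lo <- min(image$values); hi <- max(image$values)
  scaled <- if (hi > lo) (image$values - lo) / (hi - lo) else
    image$values * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 16)
  sidecar <- c(list(pixel_size_nm = image$pixel_size, value_min = lo,
                    value_max = hi, width = image$width,
                    height = image$height), params)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a grayscale TIFF or PNG micrograph
#'
#' If a `<path>.json` sidecar written by [write_micrograph()] exists, the
#' original value range and pixel size are restored; otherwise values are
#' returned on the raw \[0, 1\] scale at the supplied `pixel_size`.
#'
#' @param path image path (`.tif`, `.tiff` or `.png`).
#' @param pixel_size fallback pixel size in nm/px when no sidecar exists.
#' @return an [image_grid()].
#' @export
read_micrograph <- function(path, pixel_size = 1) {
  ext <- tolower(tools::file_ext(path))
  v <- switch(ext,
              tif = , tiff = tiff::readTIFF(path),
              png = png::readPNG(path),
              stop("unsupported image format '.", ext, "'", call. = FALSE))
  if (length(dim(v)) == 3L) v <- v[, , 1L]  # first channel of colour input
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    v <- v * (meta$value_max - meta$value_min) + meta$value_min
    pixel_size <- meta$pixel_size_nm
  }
  image_grid(v, pixel_size)
}
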