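#' En-face angiogram image container
#'
#' A light S3 container for a fovea-centered grayscale en-face OCTA projection.
#' Pixels are stored as a numeric matrix in image convention (rows = y, top to
#' bottom; columns = x, left to right) with intensities in `[0, 1]`. The pixel
#' in row `r`, column `c` covers the half-open square
#' `[c-1, c) x [r-1, r)` in pixel units, so its center sits at
#' `(c - 0.5, r - 0.5)`.
#'
#' @param pixels square numeric matrix of intensities in `[0, 1]`.
#' @param pixel_size_mm physical side length of one pixel in millimetres
#'   (default 0.0057, i.e. 5.7 um lateral resolution).
#' @param fovea_center continuous `(x, y)` position of the fovea in pixel
#'   units; defaults to the geometric image center `(W/2, H/2)`.
#' @return an object of class `angiogram`.
#' @export
angiogram <- function(pixels, pixel_size_mm = 0.0057, fovea_center = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) != ncol(pixels))
    stop("`pixels` must be square", call. = FALSE)
  if (anyNA(pixels) || !all(is.finite(pixels)))
    stop("`pixels` must be finite", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("`pixels` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(pixel_size_mm) || length(pixel_size_mm) != 1L ||
      pixel_size_mm <= 0)
    stop("`pixel_size_mm` must be a positive scalar", call. = FALSE)
  if (is.null(fovea_center))
    fovea_center <- c(ncol(pixels) / 2, nrow(pixels) / 2)
  stopifnot(length(fovea_center) == 2L, all(is.finite(fovea_center)))
  structure(
    list(pixels = pixels, pixel_size_mm = pixel_size_mm,
         fovea_center = as.numeric(fovea_center)),
    class = "angiogram"
  )
}

#' @export
print.angiogram <- function(x, ...) {
  cat(sprintf(
    "<angiogram> %d x %d px, %.4f mm/px (%.2f x %.2f mm), fovea at (%.1f, %.1f)\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_size_mm,
    ncol(x$pixels) * x$pixel_size_mm, nrow(x$pixels) * x$pixel_size_mm,
    x$fovea_center[1], x$fovea_center[2]))
  invisible(x)
}

# Accept either an angiogram or a bare matrix wherever only pixels are needed.
as_pixels <- function(image) {
  if (inherits(image, "angiogram")) image$pixels
  else if (is.matrix(image) && is.numeric(image)) image
  else stop("expected an `angiogram` or a numeric matrix", call. = FALSE)
}
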