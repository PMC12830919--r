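#' Parafoveal sector and perifoveal quadrant masks
#'
#' Builds the measurement layout: a parafoveal annulus of default outer
#' diameter 2.9 mm centered on the fovea, excluding a central foveal
#' avascular zone (FAZ) disk, subdivided into `n_sectors` equal angular
#' sectors (S1...S12); and the perifoveal remainder of the scan, split into
#' four corner quadrants (Q1...Q4) by the horizontal and vertical lines
#' through the fovea center.
#'
#' Membership is decided by the pixel-center coordinate with half-open radial
#' boundaries (`inner < r <= outer` for the annulus, `r > outer` for the
#' perifovea), so the sector masks, the quadrant masks and the FAZ disk tile
#' the image exactly once.
#'
#' By default sector S1 starts at 90 degrees (12 o'clock) and sectors advance
#' clockwise on the displayed image. Quadrants are numbered Q1 = top-right,
#' Q2 = top-left, Q3 = bottom-left, Q4 = bottom-right.
#'
#' @param shape image dimensions `c(nrow, ncol)`, or an `angiogram` (in which
#'   case `pixel_size_mm` and `fovea_center` default to the image's).
#' @param pixel_size_mm physical pixel size in mm.
#' @param fovea_center `(x, y)` in pixel units; default image center.
#' @param inner_radius_mm FAZ-exclusion radius (default 0.5 mm, the ETDRS
#'   central-subfield radius).
#' @param outer_radius_mm parafoveal outer radius (default 1.45 mm).
#' @param n_sectors number of parafoveal sectors (default 12, i.e. 30 deg).
#' @param sector_origin_deg angle at which S1 starts, degrees, 90 = 12
#'   o'clock on the displayed image.
#' @param clockwise direction in which sector indices advance.
#' @return an object of class `region_layout` with named logical masks
#'   `S1...S<n>`, `Q1...Q4`, the `faz` mask, and the geometry used.
#' @export
make_region_layout <- function(shape, pixel_size_mm = NULL, fovea_center = NULL,
                               inner_radius_mm = 0.5, outer_radius_mm = 1.45,
                               n_sectors = 12L, sector_origin_deg = 90,
                               clockwise = TRUE) {
  if (inherits(shape, "angiogram")) {
    if (is.null(pixel_size_mm)) pixel_size_mm <- shape$pixel_size_mm
    if (is.null(fovea_center)) fovea_center <- shape$fovea_center
    shape <- dim(shape$pixels)
  }
  stopifnot(length(shape) == 2L, all(shape >= 1))
  if (is.null(pixel_size_mm) || pixel_size_mm <= 0)
    stop("`pixel_size_mm` must be a positive scalar", call. = FALSE)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  if (is.null(fovea_center)) fovea_center <- c(nc / 2, nr / 2)
  if (!(inner_radius_mm > 0 && outer_radius_mm > inner_radius_mm))
    stop("need 0 < inner_radius_mm < outer_radius_mm", call. = FALSE)
  n_sectors <- as.integer(n_sectors)
  stopifnot(n_sectors >= 1L)
  half_diag_mm <- pixel_size_mm * sqrt((nc / 2)^2 + (nr / 2)^2)
  if (outer_radius_mm > half_diag_mm)
    stop("`outer_radius_mm` exceeds the image half-diagonal", call. = FALSE)

  cx <- fovea_center[1]; cy <- fovea_center[2]
  x <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
  y <- matrix(rep(seq_len(nr) - 0.5, times = nc), nr, nc)
  dx <- x - cx
  dy <- y - cy
  r_mm <- pixel_size_mm * sqrt(dx^2 + dy^2)

  # image y grows downward; measure angles with 90 deg at 12 o'clock
  theta <- atan2(-dy, dx) * 180 / pi
  a <- if (clockwise) (sector_origin_deg - theta) %% 360
       else (theta - sector_origin_deg) %% 360
  sector <- pmin(floor(a / (360 / n_sectors)) + 1, n_sectors)

  annulus <- r_mm > inner_radius_mm & r_mm <= outer_radius_mm
  peri <- r_mm > outer_radius_mm
  faz <- r_mm <= inner_radius_mm

  masks <- vector("list", n_sectors + 4L)
  names(masks) <- c(paste0("S", seq_len(n_sectors)),
                    paste0("Q", 1:4))
  for (s in seq_len(n_sectors)) masks[[s]] <- annulus & sector == s
  masks[[n_sectors + 1L]] <- peri & dx >= 0 & dy < 0   # Q1 top-right
  masks[[n_sectors + 2L]] <- peri & dx < 0 & dy < 0    # Q2 top-left
  masks[[n_sectors + 3L]] <- peri & dx < 0 & dy >= 0   # Q3 bottom-left
  masks[[n_sectors + 4L]] <- peri & dx >= 0 & dy >= 0  # Q4 bottom-right

  structure(
    list(masks = masks, faz = faz,
         shape = c(nr, nc), pixel_size_mm = pixel_size_mm,
         fovea_center = c(cx, cy),
         inner_radius_mm = inner_radius_mm, outer_radius_mm = outer_radius_mm,
         n_sectors = n_sectors, sector_origin_deg = sector_origin_deg,
         clockwise = clockwise),
    class = "region_layout"
  )
}

#' @export
print.region_layout <- function(x, ...) {
  cat(sprintf(
    "<region_layout> %d x %d px, annulus %.2f-%.2f mm, %d sectors + 4 quadrants\n",
    x$shape[1], x$shape[2], x$inner_radius_mm, x$outer_radius_mm, x$n_sectors))
  invisible(x)
}

#' Overlay the region layout on an angiogram for visual QC
#'
#' Draws the image in grayscale with the FAZ-exclusion circle, the parafoveal
#' outer circle, the sector rays and the quadrant axes.
#'
#' @param image an `angiogram` (or numeric matrix, with geometry taken from
#'   `layout`).
#' @param layout a `region_layout`.
#' @param ... passed to [graphics::image()].
#' @return invisibly, `NULL`.
#' @export
plot_region_overlay <- function(image, layout, ...) {
  px <- as_pixels(image)
  nr <- nrow(px); nc <- ncol(px)
  graphics::image(x = seq_len(nc) - 0.5, y = seq_len(nr) - 0.5,
                  z = t(px[nr:1, , drop = FALSE]),
                  col = grDevices::gray.colors(256, 0, 1), asp = 1,
                  xlab = "x [px]", ylab = "y [px]", useRaster = TRUE, ...)
  cx <- layout$fovea_center[1]
  cy <- nr - layout$fovea_center[2]          # flipped for plotting
  th <- seq(0, 2 * pi, length.out = 256)
  for (r_mm in c(layout$inner_radius_mm, layout$outer_radius_mm)) {
    r <- r_mm / layout$pixel_size_mm
    graphics::lines(cx + r * cos(th), cy + r * sin(th), col = "red")
  }
  r0 <- layout$inner_radius_mm / layout$pixel_size_mm
  r1 <- layout$outer_radius_mm / layout$pixel_size_mm
  for (i in seq_len(layout$n_sectors)) {
    a <- (layout$sector_origin_deg +
            (if (layout$clockwise) -1 else 1) * (i - 1) * 360 / layout$n_sectors) * pi / 180
    graphics::segments(cx + r0 * cos(a), cy + r0 * sin(a),
                       cx + r1 * cos(a), cy + r1 * sin(a), col = "red")
  }
  graphics::segments(c(0, cx), c(cy, 0), c(nc, cx), c(cy, nr),
                     col = "orange", lty = 3)
  invisible(NULL)
}

#' Vessel density of a region
#'
#' The percentage of vessel pixels among all pixels of the region:
#' `100 * sum(vessel & mask) / sum(mask)`.
#'
#' @param binary a `binary_vessel_map` or logical matrix (`TRUE` = vessel).
#' @param mask logical matrix, same shape, with at least one `TRUE` pixel.
#' @return vessel density in percent, in `[0, 100]`.
#' @export
vessel_density <- function(binary, mask) {
  bp <- if (inherits(binary, "binary_vessel_map")) binary$pixels else binary
  stopifnot(is.logical(bp), is.logical(mask))
  if (!identical(dim(bp), dim(mask)))
    stop("`binary` and `mask` must have the same shape", call. = FALSE)
  n <- sum(mask)
  if (n == 0L) stop("empty mask", call. = FALSE)
  100 * sum(bp & mask) / n
}

#' Per-region VD feature vectors of one eye
#'
#' Runs the full extraction chain (Frangi enhancement, Otsu binarization, then
#' per-region vessel density) for the requested plexuses and zones. Parafoveal
#' features are the 12 sector VDs ordered S1...S12; perifoveal features are
#' the 4 quadrant VDs ordered Q1...Q4.
#'
#' @param eye an `eye_record` (see [generate_cohort()]).
#' @param layout a `region_layout` matching the eye's image geometry.
#' @param params [vesselness_params()] for the enhancement step.
#' @param n_bins histogram bins for the Otsu step.
#' @param plexuses which plexuses to process (default: all present).
#' @param zones `"parafoveal"`, `"perifoveal"`, or both.
#' @return named list keyed `<plexus>.<zone>`, each element a
#'   `feature_vector`: list with `plexus`, `zone` and the named numeric
#'   `values` (VD percentages).
#' @export
extract_features <- function(eye, layout, params = vesselness_params(),
                             n_bins = 256L, plexuses = names(eye$images),
                             zones = c("parafoveal", "perifoveal")) {
  stopifnot(inherits(layout, "region_layout"))
  zones <- match.arg(zones, several.ok = TRUE)
  sector_names <- paste0("S", seq_len(layout$n_sectors))
  quad_names <- paste0("Q", 1:4)
  out <- list()
  for (pl in plexuses) {
    img <- eye$images[[pl]]
    if (is.null(img))
      stop(sprintf("eye %s/%s has no image for plexus %s",
                   eye$patient_id, eye$eye, pl), call. = FALSE)
    v <- frangi_vesselness(img, params)
    bin <- binarize_map(v, n_bins)
    for (zn in zones) {
      rn <- if (zn == "parafoveal") sector_names else quad_names
      vals <- vapply(rn, function(m) vessel_density(bin, layout$masks[[m]]),
                     numeric(1))
      out[[paste(pl, zn, sep = ".")]] <- structure(
        list(plexus = pl, zone = zn, values = vals),
        class = "feature_vector")
    }
  }
  out
}
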