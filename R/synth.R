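#' Configuration of the synthetic OCTA cohort generator
#'
#' Describes a two-class (healthy vs. glaucoma) cohort of fovea-centered
#' en-face angiograms. Glaucomatous eyes lose whole vessel segments with
#' zone-dependent probability: `dropout_para` inside the parafoveal annulus
#' and `dropout_peri` outside it, both multiplied by a per-plexus scale
#' (by default strongest in the SVP). Defaults mirror the geometry of a
#' 3x3 mm scan at 5.7 um/px and a registry-sized cohort of 240 patients
#' contributing 352 eyes (~44% healthy).
#'
#' @param image_size_px square image side in pixels (>= 64).
#' @param pixel_size_mm physical pixel size in mm (> 0).
#' @param faz_radius_mm radius of the central avascular zone.
#' @param para_outer_mm outer radius of the parafoveal annulus, used as the
#'   boundary between the two dropout zones.
#' @param n_patients number of patients.
#' @param two_eye_fraction proportion of patients contributing both eyes.
#' @param glaucoma_fraction proportion of patients labelled glaucoma.
#' @param dropout_para probability in `[0, 1]` of removing a vessel segment
#'   whose centroid lies in the parafoveal annulus (glaucoma eyes only).
#' @param dropout_peri same for segments centred outside the annulus.
#' @param plexus_effect_scale named positive multipliers on the dropout
#'   probabilities per plexus; default `SVP >= ICP >= DCP`.
#' @param noise_level multiplicative speckle amplitude.
#' @param density_cv lognormal coefficient of variation of per-eye capillary
#'   density (inter-individual VD spread).
#' @param seed RNG seed; the whole cohort is a deterministic function of the
#'   configuration.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(image_size_px = 526L, pixel_size_mm = 0.0057,
                         faz_radius_mm = 0.25, para_outer_mm = 1.45,
                         n_patients = 240L, two_eye_fraction = 0.467,
                         glaucoma_fraction = 198 / 352,
                         dropout_para = 0.15, dropout_peri = 0.35,
                         plexus_effect_scale = c(SVP = 1, ICP = 0.7, DCP = 0.45),
                         noise_level = 0.15, density_cv = 0.15, seed = 1L) {
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop(sprintf("`%s` must be a probability in [0, 1]", nm), call. = FALSE)
  }
  if (!is.numeric(image_size_px) || length(image_size_px) != 1L ||
      image_size_px < 64)
    stop("`image_size_px` must be >= 64", call. = FALSE)
  if (!is.numeric(pixel_size_mm) || length(pixel_size_mm) != 1L ||
      pixel_size_mm <= 0)
    stop("`pixel_size_mm` must be > 0", call. = FALSE)
  half_width_mm <- image_size_px * pixel_size_mm / 2
  if (!(faz_radius_mm > 0 && faz_radius_mm < para_outer_mm))
    stop("`faz_radius_mm` must satisfy 0 < faz_radius_mm < para_outer_mm",
         call. = FALSE)
  if (!(para_outer_mm < half_width_mm))
    stop("`para_outer_mm` must be smaller than the image half-width",
         call. = FALSE)
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1)
    stop("`n_patients` must be a positive count", call. = FALSE)
  chk_prob(two_eye_fraction, "two_eye_fraction")
  chk_prob(glaucoma_fraction, "glaucoma_fraction")
  chk_prob(dropout_para, "dropout_para")
  chk_prob(dropout_peri, "dropout_peri")
  if (!is.numeric(plexus_effect_scale) ||
      !all(c("SVP", "ICP", "DCP") %in% names(plexus_effect_scale)) ||
      any(plexus_effect_scale < 0))
    stop("`plexus_effect_scale` must be non-negative and named SVP/ICP/DCP",
         call. = FALSE)
  if (!is.numeric(noise_level) || length(noise_level) != 1L || noise_level < 0)
    stop("`noise_level` must be >= 0", call. = FALSE)
  if (!is.numeric(density_cv) || length(density_cv) != 1L || density_cv < 0)
    stop("`density_cv` must be >= 0", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be an integer", call. = FALSE)
  structure(
    list(image_size_px = as.integer(image_size_px),
         pixel_size_mm = pixel_size_mm,
         faz_radius_mm = faz_radius_mm, para_outer_mm = para_outer_mm,
         n_patients = as.integer(n_patients),
         two_eye_fraction = two_eye_fraction,
         glaucoma_fraction = glaucoma_fraction,
         dropout_para = dropout_para, dropout_peri = dropout_peri,
         plexus_effect_scale = plexus_effect_scale[c("SVP", "ICP", "DCP")],
         noise_level = noise_level, density_cv = density_cv,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Rendering constants per plexus. Widths are physical; the rasterization
# sigma is floored (capillaries 0.6 px, arterioles 1.3 px) so sub-pixel
# vessels at coarse test resolutions still render as clean ridges while the
# thick/thin distinction is preserved at every resolution.
plexus_render_spec <- function(plexus) {
  switch(plexus,
    SVP = list(cap_density_mm2 = 26, n_thick = 8L, amp_cap = 0.50,
               amp_thick = 0.85),
    ICP = list(cap_density_mm2 = 30, n_thick = 0L, amp_cap = 0.50,
               amp_thick = 0),
    DCP = list(cap_density_mm2 = 33, n_thick = 0L, amp_cap = 0.50,
               amp_thick = 0),
    stop("unknown plexus kind: ", plexus, call. = FALSE))
}

# geometry used by the renderer (all radii in mm, center in pixel units)
synth_geometry <- function(config) {
  list(size_px = config$image_size_px,
       pixel_size_mm = config$pixel_size_mm,
       fovea_center = c(config$image_size_px / 2, config$image_size_px / 2),
       faz_radius_mm = config$faz_radius_mm,
       para_outer_mm = config$para_outer_mm)
}

# row-wise cumulative sum (paths are rows)
row_cumsum <- function(m) {
  if (ncol(m) == 1L) m else t(apply(m, 1L, cumsum))
}

# uniform start points with radius > rmin_px from the center
draw_starts <- function(n, size, cx, cy, rmin_px) {
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    x <- stats::runif(2L * n, 0, size)
    y <- stats::runif(2L * n, 0, size)
    ok <- (x - cx)^2 + (y - cy)^2 > rmin_px^2
    xs <- c(xs, x[ok]); ys <- c(ys, y[ok])
  }
  list(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

# accumulate sample points (pixel units) into a counts grid, skipping
# out-of-bounds and FAZ-interior samples
rasterize_points <- function(x, y, w, size, cx, cy, faz_px) {
  keep <- x >= 0 & x < size & y >= 0 & y < size &
    (x - cx)^2 + (y - cy)^2 > faz_px^2
  grid <- matrix(0, size, size)
  if (!any(keep)) return(grid)
  idx <- (floor(x[keep]) ) * size + floor(y[keep]) + 1  # column-major [y, x]
  acc <- rowsum(w[keep], idx)
  grid[as.integer(rownames(acc))] <- acc
  grid
}

#' Render one synthetic en-face vessel network
#'
#' Vessels are generated as stochastic random-walk segments (a capillary mesh
#' for every plexus, plus a few thick radially oriented arterioles with short
#' branches for the SVP), thinned segment-wise by the zone dropout
#' probabilities, rasterized onto a centerline grid and blurred to their
#' physical width. Background plus multiplicative speckle completes the image.
#' No vessel centerline enters the FAZ disk. Consumes the current R RNG
#' stream; callers control determinism with `set.seed()`.
#'
#' @param geometry list with `size_px`, `pixel_size_mm`, `fovea_center`,
#'   `faz_radius_mm`, `para_outer_mm` (see [synth_config()]).
#' @param plexus `"SVP"`, `"ICP"` or `"DCP"`.
#' @param dropout length-2 numeric `c(para, peri)` segment-removal
#'   probabilities (already scaled per plexus).
#' @param density_mult multiplier on the capillary count (per-eye variation).
#' @param noise_level multiplicative speckle amplitude.
#' @return an `angiogram`.
#' @export
render_vessel_network <- function(geometry, plexus = "SVP",
                                  dropout = c(para = 0, peri = 0),
                                  density_mult = 1, noise_level = 0.15) {
  spec <- plexus_render_spec(plexus)
  size <- geometry$size_px
  pxmm <- geometry$pixel_size_mm
  cx <- geometry$fovea_center[1]; cy <- geometry$fovea_center[2]
  faz_px <- geometry$faz_radius_mm / pxmm
  outer_px <- geometry$para_outer_mm / pxmm
  field_mm <- size * pxmm
  sigma_cap <- max(0.6, 0.0038 / pxmm)
  sigma_thick <- max(1.3, 0.0094 / pxmm)
  step <- 0.7                                   # px between centerline samples

  ## --- capillary mesh: one random-walk path per capillary segment ---
  n_cap <- max(1L, round(spec$cap_density_mm2 * field_mm^2 * density_mult))
  st <- draw_starts(n_cap, size, cx, cy, faz_px + 1)
  len_mm <- pmin(pmax(stats::rnorm(n_cap, 0.45, 0.12), 0.15), 0.80)
  nst <- pmax(2L, as.integer(round(len_mm / (step * pxmm))))
  mmax <- max(nst)
  phi0 <- stats::runif(n_cap, 0, 2 * pi)
  dphi <- matrix(stats::rnorm(n_cap * mmax, 0, 0.35), n_cap, mmax)
  phi <- phi0 + row_cumsum(dphi)
  xs <- st$x + row_cumsum(cos(phi) * step)
  ys <- st$y + row_cumsum(sin(phi) * step)
  live <- col(xs) <= nst                        # per-path length mask
  # dropout unit: the zone-homogeneous piece of a path. A path straddling the
  # annulus boundary contributes one parafoveal and one perifoveal segment
  # with independent survival draws, so dropout in one zone never removes
  # pixels from the other (effect locality).
  rmat <- sqrt((xs - cx)^2 + (ys - cy)^2)
  in_peri <- rmat * pxmm > geometry$para_outer_mm
  keep_u_para <- stats::runif(n_cap)            # drawn even when dropout = 0
  keep_u_peri <- stats::runif(n_cap)
  keep_path <- ifelse(in_peri, keep_u_peri[row(xs)] >= dropout[2],
                      keep_u_para[row(xs)] >= dropout[1])
  sel <- live & keep_path
  cap_grid <- rasterize_points(xs[sel], ys[sel], rep(step, sum(sel)),
                               size, cx, cy, faz_px)

  ## --- SVP arterioles: border-seeded walks steered around the fovea ---
  thick_grid <- matrix(0, size, size)
  if (spec$n_thick > 0L) {
    n_th <- spec$n_thick + sample.int(5L, 1L) - 3L     # jitter 6..10
    seg_x <- list(); seg_y <- list()
    for (v in seq_len(n_th)) {
      side <- sample.int(4L, 1L)
      u <- stats::runif(1, 0.1, 0.9) * size
      p <- switch(side, c(u, 0), c(u, size), c(0, u), c(size, u))
      ang <- atan2(cy - p[2], cx - p[1]) + stats::rnorm(1, 0, 0.25)
      pts_x <- p[1]; pts_y <- p[2]
      n_steps <- as.integer(1.4 * size)
      branch_at <- sample.int(n_steps, 2L)
      for (s in seq_len(n_steps)) {
        ang <- ang + stats::rnorm(1, 0, 0.06)
        nx <- pts_x[length(pts_x)] + cos(ang)
        ny <- pts_y[length(pts_y)] + sin(ang)
        rn <- sqrt((nx - cx)^2 + (ny - cy)^2)
        if (rn < faz_px + 0.25 * outer_px) {
          # steer tangentially around the avascular center
          tang <- atan2(ny - cy, nx - cx) + pi / 2
          if (cos(tang - ang) < 0) tang <- tang + pi
          ang <- atan2(0.6 * sin(ang) + 0.4 * sin(tang),
                       0.6 * cos(ang) + 0.4 * cos(tang))
          nx <- pts_x[length(pts_x)] + cos(ang)
          ny <- pts_y[length(pts_y)] + sin(ang)
        }
        if (nx < 0 || nx >= size || ny < 0 || ny >= size) break
        pts_x <- c(pts_x, nx); pts_y <- c(pts_y, ny)
        if (s %in% branch_at && length(pts_x) > 4L) {
          bl <- as.integer(stats::runif(1, 0.1, 0.3) * size)
          bang <- ang + sample(c(-1, 1), 1L) * stats::runif(1, 0.4, 0.9)
          bx <- nx + cumsum(cos(bang + cumsum(stats::rnorm(bl, 0, 0.1))))
          by <- ny + cumsum(sin(bang + cumsum(stats::rnorm(bl, 0, 0.1))))
          okb <- bx >= 0 & bx < size & by >= 0 & by < size
          if (any(okb)) {
            seg_x <- c(seg_x, list(bx[okb])); seg_y <- c(seg_y, list(by[okb]))
          }
        }
      }
      seg_x <- c(seg_x, list(pts_x)); seg_y <- c(seg_y, list(pts_y))
    }
    # split each arteriole polyline into zone-homogeneous runs; arterioles
    # are structural vessels, so dropout acts at half the capillary rate
    ax <- numeric(0); ay <- numeric(0)
    for (g in seq_along(seg_x)) {
      px_g <- seg_x[[g]]; py_g <- seg_y[[g]]
      peri_g <- sqrt((px_g - cx)^2 + (py_g - cy)^2) * pxmm >
        geometry$para_outer_mm
      runs <- rle(peri_g)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      keep_u <- stats::runif(length(runs$values))
      p_drop <- 0.5 * ifelse(runs$values, dropout[2], dropout[1])
      for (rr in which(keep_u >= p_drop)) {
        ax <- c(ax, px_g[starts[rr]:ends[rr]])
        ay <- c(ay, py_g[starts[rr]:ends[rr]])
      }
    }
    if (length(ax))
      thick_grid <- rasterize_points(ax, ay, rep(1, length(ax)),
                                     size, cx, cy, faz_px)
  }

  ## --- compose: background + width-blurred centerlines + speckle ---
  img <- matrix(0.12, size, size)
  img <- img + spec$amp_cap * sqrt(2 * pi) * sigma_cap *
    gaussian_blur(cap_grid, sigma_cap)
  if (spec$amp_thick > 0)
    img <- img + spec$amp_thick * sqrt(2 * pi) * sigma_thick *
      gaussian_blur(thick_grid, sigma_thick)
  img <- pmin(img, 1)
  if (noise_level > 0) {
    img <- img * (1 + noise_level * matrix(stats::rnorm(size * size), size, size))
  }
  img <- pmin(pmax(img, 0), 1)
  angiogram(img, pixel_size_mm = pxmm,
            fovea_center = geometry$fovea_center)
}

#' Generate a synthetic two-class cohort of eyes
#'
#' Deterministic for a fixed configuration (including its seed). Patients are
#' labelled healthy/glaucoma per `glaucoma_fraction`; a `two_eye_fraction`
#' subset contributes both eyes (all eyes of a patient share its label, so
#' grouped splitting is exercised). Each eye carries one angiogram per plexus
#' (SVP/ICP/DCP). Glaucomatous eyes are rendered with segment-wise vessel
#' dropout: probability `dropout_para` inside the parafoveal annulus and
#' `dropout_peri` outside it, multiplied by `plexus_effect_scale[plexus]`.
#'
#' @param config a [synth_config()].
#' @return an object of class `octa_cohort`: a list of `eye_record`s, each
#'   with `patient_id`, `eye` (`"OD"`/`"OS"`), `label`, `sex`, `age` and
#'   `images` (named list of `angiogram`s). The configuration is attached as
#'   attribute `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  n <- config$n_patients
  geom <- synth_geometry(config)
  n_g <- round(n * config$glaucoma_fraction)
  labels <- sample(c(rep("glaucoma", n_g), rep("healthy", n - n_g)))
  two_eye <- logical(n)
  two_eye[sample.int(n, round(n * config$two_eye_fraction))] <- TRUE
  plexuses <- c("SVP", "ICP", "DCP")

  cohort <- list()
  for (i in seq_len(n)) {
    pid <- sprintf("P%04d", i)
    lab <- labels[i]
    sex <- if (lab == "glaucoma") {
      if (stats::runif(1) < 104 / 198) "M" else "F"
    } else {
      if (stats::runif(1) < 70 / 154) "M" else "F"
    }
    age <- if (lab == "glaucoma") stats::rnorm(1, 65.04, 11.69)
           else stats::rnorm(1, 63.38, 13.10)
    age <- round(min(max(age, 35), 95), 1)
    eyes <- if (two_eye[i]) c("OD", "OS") else sample(c("OD", "OS"), 1L)
    for (eye_side in eyes) {
      dens <- exp(stats::rnorm(1, 0, config$density_cv))
      images <- list()
      for (pl in plexuses) {
        sc <- config$plexus_effect_scale[[pl]]
        drop <- if (lab == "glaucoma")
          c(para = config$dropout_para * sc, peri = config$dropout_peri * sc)
        else c(para = 0, peri = 0)
        images[[pl]] <- render_vessel_network(
          geom, plexus = pl, dropout = drop, density_mult = dens,
          noise_level = config$noise_level)
      }
      cohort[[length(cohort) + 1L]] <- structure(
        list(patient_id = pid, eye = eye_side, label = lab,
             sex = sex, age = age, images = images),
        class = "eye_record")
    }
  }
  structure(cohort, class = "octa_cohort", config = config)
}

#' Cohort summary table
#'
#' @param cohort an `octa_cohort`.
#' @return data.frame with one row per eye: `patient_id`, `eye`, `label`,
#'   `sex`, `age`.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "octa_cohort"))
  data.frame(
    patient_id = vapply(cohort, `[[`, "", "patient_id"),
    eye = vapply(cohort, `[[`, "", "eye"),
    label = vapply(cohort, `[[`, "", "label"),
    sex = vapply(cohort, `[[`, "", "sex"),
    age = vapply(cohort, function(e) e$age, numeric(1)),
    stringsAsFactors = FALSE)
}

#' @export
print.octa_cohort <- function(x, ...) {
  tab <- cohort_table(x)
  cat(sprintf("<octa_cohort> %d eyes of %d patients (%d glaucoma / %d healthy eyes)\n",
              nrow(tab), length(unique(tab$patient_id)),
              sum(tab$label == "glaucoma"), sum(tab$label == "healthy")))
  invisible(x)
}
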