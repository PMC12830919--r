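# Shared fixtures, all generated in code.

# renderer geometry for a 3 mm field at a reduced test resolution
test_geom <- function(size = 96L) {
  list(size_px = as.integer(size), pixel_size_mm = 3 / size,
       fovea_center = c(size / 2, size / 2),
       faz_radius_mm = 0.25, para_outer_mm = 1.45)
}

# bright ridge with Gaussian cross-section on a dark background
make_ridge <- function(size = 64L, width = 2, amp = 0.8, background = 0.1,
                       vertical = TRUE) {
  center <- (size + 1) / 2
  prof <- background + amp * exp(-((seq_len(size) - center)^2) / (2 * width^2))
  m <- matrix(rep(prof, each = size), size, size)   # vertical ridge: varies in x
  if (!vertical) m <- t(m)
  m
}

# small synthetic cohort (96 px, 3 mm field) for pipeline-level tests
test_cohort_config <- function(n_patients = 20L, seed = 1L, ...) {
  synth_config(image_size_px = 96L, pixel_size_mm = 3 / 96,
               n_patients = n_patients, two_eye_fraction = 0.2,
               seed = seed, ...)
}

# independent exhaustive Otsu oracle over the same binning definition
otsu_oracle <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  lo <- min(v); hi <- max(v)
  w <- (hi - lo) / n_bins
  bin <- pmin(floor((v - lo) / w) + 1, n_bins)
  centers <- lo + (seq_len(n_bins) - 0.5) * w
  best_k <- NA_integer_
  best <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    c0 <- bin <= k
    n0 <- sum(c0); n1 <- length(v) - n0
    if (n0 == 0L || n1 == 0L) next
    w0 <- n0 / length(v)
    mu0 <- mean(centers[bin[c0]])
    mu1 <- mean(centers[bin[!c0]])
    sb <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (sb > best + 1e-15) { best <- sb; best_k <- k }
  }
  lo + best_k * w
}

# brute-force pair-counting AUROC oracle (ties count one half)
auroc_oracle <- function(scores, pos) {
  s_pos <- scores[pos]; s_neg <- scores[!pos]
  total <- 0
  for (a in s_pos) for (b in s_neg)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(s_pos) * length(s_neg))
}
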