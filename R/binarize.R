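#' Otsu threshold of an intensity grid
#'
#' Builds an `n_bins`-bin histogram spanning the data range and returns the
#' bin edge that maximizes the between-class variance
#' `w0(t) * w1(t) * (mu0(t) - mu1(t))^2`. Ties are broken toward the smallest
#' threshold. The vessel class is everything whose quantized intensity (bin
#' center) lies strictly above the returned threshold; because the threshold
#' is a bin edge this is the same as "bin index greater than the cut bin".
#'
#' Spanning the data range (rather than a fixed `[0, 1]`) makes the threshold
#' exactly equivariant under affine rescaling of the intensities.
#'
#' @param values numeric vector or matrix of finite intensities with at least
#'   two distinct quantized levels.
#' @param n_bins histogram bin count (default 256).
#' @return the threshold (a bin edge), with attribute `bin` giving the index
#'   of the last background bin.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  if (anyNA(v) || !all(is.finite(v)))
    stop("`values` must be finite", call. = FALSE)
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 2L)
    stop("`n_bins` must be >= 2", call. = FALSE)
  n_bins <- as.integer(n_bins)
  lo <- min(v)
  hi <- max(v)
  if (hi <= lo)
    stop("degenerate image: a single intensity class (constant input)",
         call. = FALSE)
  w <- (hi - lo) / n_bins
  bin <- pmin(as.integer(floor((v - lo) / w)) + 1L, n_bins)
  cnt <- tabulate(bin, nbins = n_bins)
  if (sum(cnt > 0L) < 2L)
    stop("degenerate image: a single intensity class after quantization",
         call. = FALSE)
  p <- cnt / length(v)
  centers <- lo + (seq_len(n_bins) - 0.5) * w
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  muT <- mu[n_bins]
  k <- seq_len(n_bins - 1L)
  num <- (muT * w0[k] - mu[k])^2
  den <- w0[k] * (1 - w0[k])
  sigma_b2 <- ifelse(den > 0, num / den, -Inf)
  kstar <- which.max(sigma_b2)          # which.max takes the first maximum
  structure(lo + kstar * w, bin = kstar)
}

#' Binarize a vesselness map with the Otsu threshold
#'
#' @param map numeric matrix (or `angiogram`) of vesselness values in `[0, 1]`.
#' @param n_bins histogram bin count passed to [otsu_threshold()].
#' @return an object of class `binary_vessel_map`: logical `pixels`
#'   (`TRUE` = vessel), the `threshold_used`, and `n_bins`.
#' @export
binarize_map <- function(map, n_bins = 256L) {
  px <- as_pixels(map)
  if (min(px) < 0 || max(px) > 1)
    stop("`map` must lie in [0, 1]", call. = FALSE)
  t <- otsu_threshold(px, n_bins)
  kstar <- attr(t, "bin")
  lo <- min(px)
  w <- (max(px) - lo) / as.integer(n_bins)
  bin <- pmin(floor((px - lo) / w) + 1, n_bins)
  structure(
    list(pixels = matrix(bin > kstar, nrow(px), ncol(px)),
         threshold_used = as.numeric(t), n_bins = as.integer(n_bins)),
    class = "binary_vessel_map"
  )
}

#' @export
print.binary_vessel_map <- function(x, ...) {
  cat(sprintf("<binary_vessel_map> %d x %d px, vessel fraction %.3f, threshold %.4g\n",
              nrow(x$pixels), ncol(x$pixels), mean(x$pixels), x$threshold_used))
  invisible(x)
}
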