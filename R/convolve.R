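# Separable convolution via banded matrices with reflective (symmetric)
# boundary handling. For the image sizes used here (<= ~600 px) building the
# n x n band matrix and using BLAS matrix products is both simple and fast,
# and reflective padding avoids the dark-border ridge artifacts that would
# otherwise bias vessel density in the corner (perifoveal) quadrants.

# Band matrix B such that (B %*% v)[i] = sum_o kern[o] * v[reflect(i + o)].
conv_band_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  stopifnot(length(kernel) == 2L * r + 1L)
  if (2L * r + 1L > 2L * n)
    stop("kernel support exceeds image size", call. = FALSE)
  B <- matrix(0, n, n)
  i <- seq_len(n)
  for (o in -r:r) {
    j <- i + o
    j <- ifelse(j < 1L, 1L - j, j)        # symmetric reflection: 0 -> 1, -1 -> 2
    j <- ifelse(j > n, 2L * n + 1L - j, j)
    idx <- cbind(i, j)
    B[idx] <- B[idx] + kernel[o + r + 1L]
  }
  B
}

# Correlate rows with ky (y direction) and columns with kx (x direction):
# out = Ky %*% img %*% t(Kx), img in [row = y, col = x] convention.
sep_convolve <- function(img, kx, ky) {
  Ky <- conv_band_matrix(nrow(img), ky)
  Kx <- conv_band_matrix(ncol(img), kx)
  Ky %*% img %*% t(Kx)
}

# Sampled Gaussian and its exact first/second derivatives on -r..r,
# normalized by the sum of the plain Gaussian samples so that the smoothing
# kernel integrates to 1. First-derivative kernels are flipped so that
# correlation with them equals convolution with g' (a true d/dx estimate).
gaussian_kernels <- function(sigma, truncate = 4) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  nrm <- sum(g)
  g <- g / nrm
  d1 <- (x / sigma^2) * exp(-x^2 / (2 * sigma^2)) / nrm   # -g'(x), flipped
  d2 <- ((x^2 - sigma^2) / sigma^4) * exp(-x^2 / (2 * sigma^2)) / nrm
  d2 <- d2 - mean(d2)    # exact zero DC response despite truncation
  list(g = g, d1 = d1, d2 = d2, radius = r)
}

# Whole-image Gaussian blur (used by the synthetic renderer).
gaussian_blur <- function(img, sigma, truncate = 4) {
  k <- gaussian_kernels(sigma, truncate)$g
  sep_convolve(img, k, k)
}
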