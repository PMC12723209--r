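#' @keywords internal
#' @useDynLib jointmap, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Orthonormal n-dimensional FFT
#'
#' Forward and inverse discrete Fourier transforms scaled by 1/sqrt(N) so that
#' the transform is unitary and the adjoint of the forward FFT is the inverse.
#' Frequencies are kept in native FFT order; signed k-space indices are mapped
#' to array indices with [k_index()].
#'
#' @param x numeric or complex array
#' @return complex array of the same dimension
#' @export
fftn <- function(x) stats::fft(x) / sqrt(length(x))

#' @rdname fftn
#' @export
ifftn <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

#' Map a signed k-space coordinate to a 1-based array index
#'
#' @param k integer signed coordinate in [-n/2, n/2)
#' @param n grid size along that dimension
#' @return 1-based index into native FFT ordering
#' @export
k_index <- function(k, n) ((k %% n) + n) %% n + 1L

#' Signed frequency grid for a dimension of length n (native FFT order)
#' @param n grid size
#' @return integer vector of signed frequencies, index i holds freq of bin i
#' @export
k_freqs <- function(n) {
  f <- seq_len(n) - 1L
  f[f >= ceiling(n / 2)] <- f[f >= ceiling(n / 2)] - n
  f
}

#' Gaussian low-pass filter for 2D/3D arrays
#'
#' Separable Gaussian smoothing implemented in the Fourier domain (circular
#' boundary). Accepts real or complex input; complex input is smoothed
#' componentwise, which is the behaviour wanted for phasor smoothing.
#'
#' @param x array (2D or 3D)
#' @param sigma kernel standard deviation in voxels (scalar or per-dimension)
#' @return smoothed array, complex iff input was complex
#' @export
gauss_smooth <- function(x, sigma) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  sigma <- rep_len(sigma, length(d))
  if (all(sigma <= 0)) return(x)
  G <- 1
  for (i in seq_along(d)) {
    f <- k_freqs(d[i]) / d[i]
    g1 <- exp(-2 * pi^2 * sigma[i]^2 * f^2)
    shape <- rep(1L, length(d)); shape[i] <- d[i]
    G <- G * array(rep(g1, each = prod(d[seq_len(i - 1)])), dim = d)
  }
  out <- stats::fft(stats::fft(x) * G, inverse = TRUE) / length(x)
  if (is.complex(x)) out else Re(out)
}

#' Normalised root-mean-square error
#'
#' @param x estimate array
#' @param ref reference array (normalisation by its RMS)
#' @return scalar NRMSE
#' @export
nrmse <- function(x, ref) {
  sqrt(mean(Mod(x - ref)^2)) / sqrt(mean(Mod(ref)^2))
}

#' Coefficient of variation in percent (sample SD, n-1 denominator)
#' @param x numeric vector
#' @return 100 * sd(x)/mean(x)
#' @export
cv_pct <- function(x) 100 * stats::sd(x) / mean(x)

## complex inner product <a, b> = sum(conj(a) * b)
cdot <- function(a, b) sum(Conj(a) * b)

## trilinear interpolation weights as a sparse matrix mapping a vectorised
## volume to its values at (points + displacement); out-of-volume weight is
## dropped (zero boundary).  Rows index target voxels, columns source voxels.
interp_matrix <- function(dims, disp) {
  n <- prod(dims)
  idx <- arrayInd(seq_len(n), dims)
  pts <- idx + disp  # n x 3 fractional source coordinates
  f0 <- floor(pts)
  fr <- pts - f0
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    px <- f0[, 1] + cx; py <- f0[, 2] + cy; pz <- f0[, 3] + cz
    w <- (cx * fr[, 1] + (1 - cx) * (1 - fr[, 1])) *
         (cy * fr[, 2] + (1 - cy) * (1 - fr[, 2])) *
         (cz * fr[, 3] + (1 - cz) * (1 - fr[, 3]))
    ok <- px >= 1 & px <= dims[1] & py >= 1 & py <= dims[2] &
          pz >= 1 & pz <= dims[3] & w > 0
    if (any(ok)) {
      rows <- c(rows, which(ok))
      cols <- c(cols, (pz[ok] - 1) * dims[1] * dims[2] + (py[ok] - 1) * dims[1] + px[ok])
      vals <- c(vals, w[ok])
    }
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
}
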