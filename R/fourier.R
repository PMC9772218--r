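# Internal Fourier helpers. Conventions (documented in README):
#  - frequencies in cycles/micrometre, wavelengths and pixel sizes in nm
#  - FFT grids keep DC at element [1,1]; fftshift() centres for display
#  - real-space coordinates are centred: pixel floor(n/2)+1 sits at the origin

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' @noRd
fft_freq <- function(n, d = 1) {
  # cycles per unit of d, DC first, wrapped like the FFT output
  c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1) / (n * d)
}

centered_coords <- function(n, d = 1) (seq_len(n) - 1 - floor(n / 2)) * d

#' Frequency grids for an n x n image
#' @return list(kx, ky, kr) matrices in cycles/unit with DC at [1,1];
#'   rows index y, columns index x.
#' @noRd
freq_grids <- function(n, d = 1) {
  f <- fft_freq(n, d)
  kx <- matrix(f, n, n, byrow = TRUE)
  ky <- matrix(f, n, n)
  list(kx = kx, ky = ky, kr = sqrt(kx^2 + ky^2))
}

fftshift <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  x[c((floor(n1 / 2) + 1):n1, 1:floor(n1 / 2)),
    c((floor(n2 / 2) + 1):n2, 1:floor(n2 / 2))]
}

ifftshift <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  x[c((n1 - floor(n1 / 2) + 1):n1, 1:(n1 - floor(n1 / 2))),
    c((n2 - floor(n2 / 2) + 1):n2, 1:(n2 - floor(n2 / 2)))]
}

#' Zero-pad a DC-at-corner spectrum to `factor` times the grid (Fourier upsampling)
#' @noRd
upsample_spectrum <- function(spec, factor = 2L) {
  n <- nrow(spec)
  m <- n * factor
  out <- matrix(0 + 0i, m, m)
  cs <- fftshift(spec)
  i0 <- floor(m / 2) - floor(n / 2)
  out[i0 + (1:n), i0 + (1:n)] <- cs
  ifftshift(out) * factor^2
}

#' Shift a spectrum by a continuous frequency offset:
#' out(k) = spec(k + k0), k0 = c(kx, ky) in cycles/unit, via a real-space ramp.
#' @noRd
shift_spectrum <- function(spec, k0, d) {
  n <- nrow(spec)
  x <- centered_coords(n, d)
  ramp <- exp(-2i * pi * (outer(rep(1, n), k0[1] * x) + outer(k0[2] * x, rep(1, n))))
  fft2(ifft2(spec) * ramp)
}

#' Direct DFT of an image at one continuous frequency (centred coordinates)
#' @noRd
dft_at <- function(img, k0, d) {
  n <- nrow(img)
  x <- centered_coords(n, d)
  ex <- exp(-2i * pi * k0[1] * x)
  ey <- exp(-2i * pi * k0[2] * x)
  # sum_{y,x} img[y,x] ey[y] ex[x]
  as.complex(crossprod(ey, img %*% ex))
}

#' Tukey (tapered cosine) window, outer product for 2D use
#' @noRd
tukey_window <- function(n, alpha = 0.2) {
  if (alpha <= 0) return(rep(1, n))
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / alpha - 1)))
  w
}

tukey_window_2d <- function(n, alpha = 0.2) {
  w <- tukey_window(n, alpha)
  outer(w, w)
}

#' Evaluate an expression with a temporarily-seeded RNG, restoring global state
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
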