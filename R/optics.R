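#' Optical configuration of the detection path
#'
#' Bundles the microscope parameters the simulator and reconstructor need:
#' objective numerical aperture, immersion index, the excitation/emission
#' wavelength pair of each color channel, the (sample-referred) camera pixel
#' size and the amount of primary spherical aberration.
#'
#' @param na Numerical aperture of the objective (dimensionless).
#' @param n_immersion Refractive index of the immersion medium; must be
#'   at least `na`.
#' @param channels List of channels, each a list/vector with elements
#'   `ex_nm` (excitation wavelength, nm) and `em_nm` (emission wavelength, nm).
#' @param pixel_nm Camera pixel size referred to the sample plane, nm. Must
#'   satisfy the widefield Nyquist bound `pixel_nm <= em_nm / (4 na)` for
#'   every channel.
#' @param image_px Side length of the (square) camera frame in pixels.
#' @param sa_waves RMS amplitude of the primary-spherical pupil mode, in waves.
#'
#' @return An object of class `optical_config`.
#' @export
#' @examples
#' cfg <- optical_config(na = 1.2, channels = list(c(ex_nm = 488, em_nm = 515)))
#' detection_cutoff(cfg, 1)  # cycles/um
optical_config <- function(na, n_immersion = 1.33,
                           channels = list(c(ex_nm = 488, em_nm = 515)),
                           pixel_nm = 60, image_px = 256, sa_waves = 0) {
  stopifnot(is.numeric(na), length(na) == 1)
  if (!(na > 0)) stop("numerical aperture must be positive")
  if (na > n_immersion) stop("numerical aperture cannot exceed the immersion index")
  if (length(channels) < 1) stop("at least one channel is required")
  channels <- lapply(channels, function(ch) {
    ch <- as.list(ch)
    if (is.null(ch$ex_nm) || is.null(ch$em_nm))
      stop("each channel needs ex_nm and em_nm")
    lam <- c(ch$ex_nm, ch$em_nm)
    if (any(lam < 400) || any(lam > 800))
      stop("wavelengths must lie in [400, 800] nm")
    list(ex_nm = as.numeric(ch$ex_nm), em_nm = as.numeric(ch$em_nm))
  })
  for (ch in channels) {
    if (pixel_nm > ch$em_nm / (4 * na))
      stop(sprintf("pixel_nm = %g violates Nyquist for em = %g nm (limit %.1f nm)",
                   pixel_nm, ch$em_nm, ch$em_nm / (4 * na)))
  }
  if (image_px < 16) stop("image_px too small")
  structure(list(na = na, n_immersion = n_immersion, channels = channels,
                 pixel_nm = pixel_nm, image_px = as.integer(image_px),
                 sa_waves = sa_waves),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf("optical_config: NA %.2f (n = %.2f), %d channel(s), pixel %g nm, %d px, SA %.3g waves\n",
              x$na, x$n_immersion, length(x$channels), x$pixel_nm, x$image_px, x$sa_waves))
  for (i in seq_along(x$channels))
    cat(sprintf("  channel %d: ex %g nm / em %g nm, cutoff %.3f cyc/um\n",
                i, x$channels[[i]]$ex_nm, x$channels[[i]]$em_nm,
                detection_cutoff(x, i)))
  invisible(x)
}

check_channel <- function(config, channel) {
  if (!is.numeric(channel) || length(channel) != 1 ||
      channel < 1 || channel > length(config$channels))
    stop(sprintf("channel index %s out of range (1..%d)",
                 toString(channel), length(config$channels)))
  as.integer(channel)
}

#' Widefield detection cutoff frequency
#'
#' The incoherent passband limit of the detection optics, `2 NA / lambda_em`.
#'
#' @inheritParams make_psf
#' @return Cutoff frequency in cycles/um.
#' @export
detection_cutoff <- function(config, channel = 1) {
  channel <- check_channel(config, channel)
  2 * config$na / (config$channels[[channel]]$em_nm * 1e-3)
}

#' Excitation-side passband `2 NA / lambda_ex` (cycles/um)
#' @inheritParams make_psf
#' @export
excitation_passband <- function(config, channel = 1) {
  channel <- check_channel(config, channel)
  2 * config$na / (config$channels[[channel]]$ex_nm * 1e-3)
}

# primary spherical pupil phase in radians at normalized pupil radius rho
spherical_phase <- function(rho, sa_waves) {
  2 * pi * sa_waves * sqrt(5) * (6 * rho^4 - 6 * rho^2 + 1)
}

# complex pupil sampled on the FFT frequency grid (DC at corner);
# edge pixels are weighted by approximate sub-pixel coverage.
pupil_on_grid <- function(n, pixel_um, na, lambda_um, sa_waves) {
  g <- freq_grids(n, pixel_um)
  r_cut <- na / lambda_um              # coherent pupil radius, cycles/um
  dk <- 1 / (n * pixel_um)
  amp <- pmin(1, pmax(0, (r_cut - g$kr) / dk + 0.5))
  rho <- pmin(g$kr / r_cut, 1)
  amp * exp(1i * spherical_phase(rho, sa_waves))
}

#' Point spread function of the detection path
#'
#' Computes the incoherent PSF from a scalar circular-pupil model: a uniform
#' pupil of radius `NA/lambda_em` carrying a primary-spherical phase of
#' `sa_waves` RMS; the PSF is the squared modulus of its Fourier transform.
#' The computation runs on a `pad`-times padded grid to avoid wrap-around of
#' the Airy rings and is cropped back to `size` pixels.
#'
#' @param config An [optical_config()].
#' @param channel Channel index (1-based).
#' @param size Output grid side length in pixels (default `config$image_px`).
#' @param pixel_nm Sampling of the output grid in nm (default camera pixel).
#' @param pad Padding factor used internally (default 2).
#' @return `size x size` matrix, non-negative, summing to 1, centred at
#'   pixel `floor(size/2)+1`.
#' @export
make_psf <- function(config, channel = 1, size = config$image_px,
                     pixel_nm = config$pixel_nm, pad = 2L) {
  channel <- check_channel(config, channel)
  lam_um <- config$channels[[channel]]$em_nm * 1e-3
  p_um <- pixel_nm * 1e-3
  if (1 / (2 * p_um) < config$na / lam_um)
    stop("grid too coarse to sample the pupil")
  nbig <- as.integer(size * pad)
  pup <- pupil_on_grid(nbig, p_um, config$na, lam_um, config$sa_waves)
  amp <- ifft2(pup)
  psf <- Re(amp * Conj(amp))
  psf <- fftshift(psf)
  ctr <- floor(nbig / 2) + 1
  half <- floor(size / 2)
  idx <- (ctr - half):(ctr - half + size - 1)
  crop <- psf[idx, idx]
  kept <- sum(crop) / sum(psf)
  if (kept < 0.99)
    stop(sprintf("PSF support exceeds the grid (%.2f%% of energy clipped); increase size",
                 100 * (1 - kept)))
  crop / sum(crop)
}

# --- radial OTF profile -------------------------------------------------

# Numeric pupil-overlap integral for the incoherent OTF of a circular pupil
# with a radially symmetric phase aberration.  s is |k| in units of the
# coherent cutoff NA/lambda (incoherent cutoff at s = 2).  Gauss-Legendre
# quadrature over the lens-shaped overlap region, smoothed with y = ymax sin(t).
otf_overlap_integral <- function(s, sa_waves, n_nodes = 64) {
  gl <- pracma::gaussLegendre(n_nodes, -1, 1)
  tx <- gl$x; wx <- gl$w
  vapply(s, function(si) {
    if (si >= 2) return(0)
    ymax <- sqrt(1 - si^2 / 4)
    # y = ymax * sin(pi t / 2) removes the sqrt singularity at the rim
    y <- ymax * sin(pi * tx / 2)
    jac_y <- ymax * (pi / 2) * cos(pi * tx / 2)
    a <- sqrt(pmax(1 - y^2, 0)) - si / 2      # half-width in x at each y
    a <- pmax(a, 0)
    acc <- 0
    for (j in seq_along(y)) {
      if (a[j] <= 0) next
      x <- a[j] * tx
      r_plus <- sqrt((x + si / 2)^2 + y[j]^2)
      r_minus <- sqrt((x - si / 2)^2 + y[j]^2)
      ph <- spherical_phase(pmin(r_plus, 1), sa_waves) -
            spherical_phase(pmin(r_minus, 1), sa_waves)
      acc <- acc + wx[j] * jac_y[j] * a[j] * sum(wx * cos(ph))
    }
    acc / pi
  }, numeric(1))
}

.otf_cache <- new.env(parent = emptyenv())

#' Radial OTF profile as a function of frequency
#'
#' Returns a vectorized function `f(k_cyc_per_um)` giving the normalized OTF
#' of the detection path (1 at DC, 0 beyond `2 NA / lambda_em`).  Because the
#' only modelled aberration (primary spherical) is rotationally symmetric, the
#' OTF is radial; the profile is computed once by numerical integration of the
#' pupil-overlap integral and cached.
#'
#' @inheritParams make_psf
#' @export
otf_radial <- function(config, channel = 1) {
  channel <- check_channel(config, channel)
  lam_um <- config$channels[[channel]]$em_nm * 1e-3
  key <- sprintf("%.6g_%.6g_%.6g", config$na, lam_um, config$sa_waves)
  if (is.null(.otf_cache[[key]])) {
    s <- seq(0, 2, length.out = 801)
    vals <- otf_overlap_integral(s, config$sa_waves)
    vals <- vals / vals[1]
    .otf_cache[[key]] <- stats::approxfun(s, vals, yleft = 1, yright = 0)
  }
  prof <- .otf_cache[[key]]
  r_coh <- config$na / lam_um
  function(k) {
    out <- prof(pmin(abs(k) / r_coh, 2))
    out[abs(k) >= 2 * r_coh] <- 0
    out
  }
}

#' Optical transfer function on the image Fourier grid
#'
#' @inheritParams make_psf
#' @return An object of class `otf_grid`: a real `size x size` matrix with DC
#'   at element `[1,1]`, normalized to 1 at DC and identically zero beyond the
#'   detection cutoff; attributes `cutoff` (cycles/um), `pixel_nm`, `channel`.
#' @export
make_otf <- function(config, channel = 1, size = config$image_px,
                     pixel_nm = config$pixel_nm) {
  channel <- check_channel(config, channel)
  prof <- otf_radial(config, channel)
  g <- freq_grids(size, pixel_nm * 1e-3)
  otf <- matrix(prof(g$kr), size, size)
  structure(otf, class = c("otf_grid", "matrix"),
            cutoff = detection_cutoff(config, channel),
            pixel_nm = pixel_nm, channel = channel)
}
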