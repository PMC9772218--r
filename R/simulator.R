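#' Synthetic ground-truth specimens
#'
#' Generates fluorophore-density images on the fine (reconstruction) grid:
#' `"beads"` — hard disks of a given diameter at random sub-pixel positions
#' with a minimum separation (calibration-slide analogue); `"filaments"` —
#' smoothed random-walk curvilinear networks emulating tubulin/ER structure;
#' `"texture"` — band-limited positive random fields.  Output is normalized
#' to peak 1 and is deterministic given `seed`.
#'
#' @param kind One of `"beads"`, `"filaments"`, `"texture"`.
#' @param size Grid side length in pixels (>= 64).
#' @param pixel_nm Grid sampling in nm (fine grid: half the camera pixel).
#' @param seed Integer RNG seed.
#' @param n_beads,bead_diameter_nm,min_separation_nm Bead-field parameters.
#' @param margin_px Margin kept free of structure at the image border.
#' @param n_filaments,filament_width_nm Filament-network parameters.
#' @param texture_cutoff_frac Texture band limit as a fraction of grid Nyquist.
#' @return `size x size` non-negative matrix with attributes `kind`,
#'   `pixel_nm`, `params` (the realized parameter record, including bead
#'   positions for `"beads"`).
#' @export
#' @examples
#' gt <- generate_sample("beads", size = 128, pixel_nm = 30, seed = 1, n_beads = 10)
#' range(gt)
generate_sample <- function(kind = c("beads", "filaments", "texture"),
                            size = 512, pixel_nm = 30, seed = 1,
                            n_beads = 50, bead_diameter_nm = 100,
                            min_separation_nm = 800, margin_px = max(8L, size %/% 16L),
                            n_filaments = 10, filament_width_nm = 60,
                            texture_cutoff_frac = 0.5) {
  kind <- match.arg(kind)
  if (size < 64) stop("size must be at least 64 px")
  img <- with_seed(seed, switch(kind,
    beads = sample_beads(size, pixel_nm, n_beads, bead_diameter_nm,
                         min_separation_nm, margin_px),
    filaments = sample_filaments(size, pixel_nm, n_filaments, filament_width_nm,
                                 margin_px),
    texture = sample_texture(size, texture_cutoff_frac)))
  params <- attr(img, "params")
  img <- img / max(img)
  structure(img, kind = kind, pixel_nm = pixel_nm,
            params = c(params, list(seed = seed)))
}

sample_beads <- function(size, pixel_nm, n, diameter_nm, min_sep_nm, margin_px) {
  rad_px <- (diameter_nm / 2) / pixel_nm
  sep_px <- min_sep_nm / pixel_nm
  pos <- matrix(NA_real_, n, 2)
  placed <- 0
  tries <- 0
  while (placed < n && tries < 40000) {
    tries <- tries + 1
    p <- stats::runif(2, margin_px + rad_px, size - margin_px - rad_px)
    if (placed == 0 ||
        min(sqrt(colSums((t(pos[seq_len(placed), , drop = FALSE]) - p)^2))) >= sep_px) {
      placed <- placed + 1
      pos[placed, ] <- p
    }
  }
  if (placed < n)
    stop(sprintf("could only place %d of %d beads at separation %g nm",
                 placed, n, min_sep_nm))
  img <- matrix(0, size, size)
  w <- ceiling(rad_px) + 2
  for (i in seq_len(n)) {
    cx <- pos[i, 1]; cy <- pos[i, 2]
    ix <- max(1, floor(cx) - w):min(size, ceiling(cx) + w)
    iy <- max(1, floor(cy) - w):min(size, ceiling(cy) + w)
    d <- sqrt(outer((iy - cy)^2, (ix - cx)^2, "+"))
    img[iy, ix] <- img[iy, ix] + pmin(1, pmax(0, rad_px - d + 0.5))
  }
  attr(img, "params") <- list(n_beads = n, bead_diameter_nm = diameter_nm,
                              min_separation_nm = min_sep_nm,
                              positions_px = pos)
  img
}

sample_filaments <- function(size, pixel_nm, n_filaments, width_nm, margin_px) {
  counts <- matrix(0, size, size)
  n_steps <- size * 3L
  for (f in seq_len(n_filaments)) {
    p <- stats::runif(2, margin_px, size - margin_px)
    heading <- stats::runif(1, 0, 2 * pi)
    for (s in seq_len(n_steps)) {
      heading <- heading + stats::rnorm(1, 0, 0.08)
      p <- p + c(cos(heading), sin(heading))
      if (any(p < margin_px) || any(p > size - margin_px)) {
        heading <- heading + pi / 2 + stats::runif(1, 0, pi)  # bounce inward
        p <- pmin(pmax(p, margin_px), size - margin_px)
      }
      i <- round(p[2]); j <- round(p[1])
      counts[i, j] <- counts[i, j] + 1
    }
  }
  # blur the skeleton to the requested filament width
  sigma_px <- (width_nm / 2.355) / pixel_nm
  g <- freq_grids(size, 1)
  kernel <- exp(-2 * pi^2 * sigma_px^2 * g$kr^2)   # FT of a Gaussian
  img <- Re(ifft2(fft2(counts) * kernel))
  img[img < 0] <- 0
  attr(img, "params") <- list(n_filaments = n_filaments, width_nm = width_nm)
  img
}

sample_texture <- function(size, cutoff_frac) {
  g <- freq_grids(size, 1)                 # frequencies in cycles/px
  noise <- fft2(matrix(stats::rnorm(size^2), size, size))
  sigma_k <- cutoff_frac * 0.5 / 2         # Nyquist = 0.5 cyc/px
  field <- Re(ifft2(noise * exp(-g$kr^2 / (2 * sigma_k^2))))
  img <- field - min(field)
  attr(img, "params") <- list(texture_cutoff_frac = cutoff_frac)
  img
}

#' Camera noise model
#'
#' @param peak_signal Expected photon count at the brightest widefield pixel.
#' @param read_noise_sd Gaussian read noise, electrons RMS.
#' @param background Uniform background, photons/pixel.
#' @param gain Camera gain, electrons/photon.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(peak_signal = 200, read_noise_sd = 1,
                        background = 2, gain = 1) {
  stopifnot(peak_signal >= 0, read_noise_sd >= 0, background >= 0, gain >= 0)
  structure(list(peak_signal = peak_signal, read_noise_sd = read_noise_sd,
                 background = background, gain = gain),
            class = "noise_model")
}

# 2x2 block mean
downsample2 <- function(x) {
  n <- nrow(x)
  stopifnot(n %% 2 == 0)
  m <- n %/% 2
  0.25 * (x[seq(1, n, 2), seq(1, n, 2)] + x[seq(2, n, 2), seq(1, n, 2)] +
          x[seq(1, n, 2), seq(2, n, 2)] + x[seq(2, n, 2), seq(2, n, 2)])
}

#' Simulate a raw SIM acquisition
#'
#' Forward model of image formation: on the fine grid the specimen density is
#' multiplied by the sinusoidal excitation pattern
#' `1 + m cos(2 pi k.r + phi)`, blurred by the emission-wavelength PSF
#' (applied as the radial OTF in the Fourier domain), area-downsampled to the
#' camera grid, scaled so the brightest widefield pixel expects
#' `noise$peak_signal` photons, and offset by the background.  Recorded
#' counts are `Poisson(E) * gain + N(0, read_noise_sd)`, clipped at zero.
#' With `noise = NULL` the noiseless expected signal (no background) is
#' returned.
#'
#' @param sample Ground-truth matrix from [generate_sample()], sampled at
#'   twice the camera resolution (`2 * config$image_px`).
#' @param protocol An [acquisition_protocol()].
#' @param config An [optical_config()].
#' @param noise A [noise_model()] or `NULL` for noiseless output.
#' @param seed RNG seed for the noise draws.
#' @return Object of class `sim_stack`: `frames` is a list (one per channel)
#'   of `N x N x 9` arrays in angle-major phase-minor order, plus `config`,
#'   `protocol`, `noise`, `seed` metadata.
#' @export
simulate_stack <- function(sample, protocol, config, noise = noise_model(),
                           seed = 1) {
  n_cam <- config$image_px
  if (nrow(sample) != 2 * n_cam || ncol(sample) != 2 * n_cam)
    stop(sprintf("sample must be %d x %d (2x the camera grid)", 2 * n_cam, 2 * n_cam))
  p_fine_um <- config$pixel_nm * 1e-3 / 2
  nf <- 2L * n_cam
  g <- freq_grids(nf, p_fine_um)
  xc <- centered_coords(nf, p_fine_um)
  X <- matrix(xc, nf, nf, byrow = TRUE)
  Y <- matrix(xc, nf, nf)
  sample_ft <- fft2(sample)

  frames <- with_seed(seed, lapply(seq_along(protocol$channels), function(ci) {
    if (detection_cutoff(config, ci) > 1 / (2 * config$pixel_nm * 1e-3))
      stop("camera grid violates Nyquist for the detection cutoff")
    otf_fine <- matrix(otf_radial(config, ci)(g$kr), nf, nf)
    # widefield normalization: brightest expected widefield pixel = peak_signal
    wf <- downsample2(pmax(Re(ifft2(sample_ft * otf_fine)), 0))
    alpha <- if (is.null(noise)) 1 / max(wf) else noise$peak_signal / max(wf)
    arr <- array(0, dim = c(n_cam, n_cam, 9))
    for (j in 1:9) {
      st <- protocol$channels[[ci]][[j]]
      if (st$m > 1) stop("modulation depth above 1 gives negative intensities")
      pat <- 1 + st$m * cos(2 * pi * (st$k[1] * X + st$k[2] * Y) + st$phase)
      e <- downsample2(pmax(Re(ifft2(fft2(sample * pat) * otf_fine)), 0)) * alpha
      if (is.null(noise)) {
        arr[, , j] <- e
      } else {
        e <- e + noise$background
        counts <- matrix(stats::rpois(length(e), e), n_cam, n_cam)
        rec <- counts * noise$gain +
          matrix(stats::rnorm(length(e), 0, noise$read_noise_sd), n_cam, n_cam)
        arr[, , j] <- pmax(rec, 0)
      }
    }
    arr
  }))

  structure(list(frames = frames, config = config, protocol = protocol,
                 noise = noise, seed = seed),
            class = "sim_stack")
}

#' @export
print.sim_stack <- function(x, ...) {
  cat(sprintf("sim_stack: %d channel(s) x 9 frames of %d x %d px (%s mode, seed %s)\n",
              length(x$frames), dim(x$frames[[1]])[1], dim(x$frames[[1]])[2],
              x$protocol$mode, format(x$seed)))
  invisible(x)
}

#' Generate a randomized synthetic training set
#'
#' Draws, for each example, the imaging parameters from the stated ranges —
#' spherical aberration, a global rotation of the three orientations, the
#' phase-stepping mode (`even`, `uneven_wavelength`: steps scaled by a
#' reference-to-actual wavelength ratio as in simultaneous multicolor
#' acquisition, or `jitter`: even steps plus uniform perturbations),
#' modulation depth, peak signal, and the specimen kind — simulates the
#' 9-frame stack, and records every draw.  Deterministic given `seed`.
#'
#' @param n_examples Number of examples.
#' @param size Camera patch size in pixels (ground truth is `2*size`).
#' @param ranges Named list of randomization ranges; see defaults in the
#'   function signature of `training_ranges()`.
#' @param seed Integer seed.
#' @param pixel_nm Camera pixel size.
#' @return List of examples, each with `stack` (single-channel [sim_stack]),
#'   `truth` (fine-grid ground truth), and `params` (the recorded draws).
#' @export
generate_training_set <- function(n_examples, size = 64, ranges = training_ranges(),
                                  seed = 1, pixel_nm = 60) {
  stopifnot(n_examples >= 1)
  for (r in ranges) if (length(r) == 2 && is.numeric(r) && r[1] > r[2])
    stop("invalid range: min exceeds max")
  draws <- with_seed(seed, lapply(seq_len(n_examples), function(i) {
    list(sa = stats::runif(1, ranges$sa[1], ranges$sa[2]),
         rot = stats::runif(1, ranges$rotation_deg[1], ranges$rotation_deg[2]),
         mode = sample(ranges$phase_modes, 1),
         lambda_ex = stats::runif(1, ranges$lambda_ex[1], ranges$lambda_ex[2]),
         m = stats::runif(1, ranges$m[1], ranges$m[2]),
         peak = stats::runif(1, ranges$peak[1], ranges$peak[2]),
         jitter = stats::runif(3, ranges$phase_jitter[1], ranges$phase_jitter[2]),
         kind = sample(c("beads", "filaments", "texture"), 1),
         seed_sample = sample.int(2^20, 1),
         seed_noise = sample.int(2^20, 1))
  }))
  lapply(draws, function(d) {
    cfg <- optical_config(1.2, 1.33,
                          channels = list(c(ex_nm = d$lambda_ex,
                                            em_nm = d$lambda_ex + 25)),
                          pixel_nm = pixel_nm, image_px = size, sa_waves = d$sa)
    geom <- interferometer_geometry(pattern_fraction = 0.95,
                                    orientations_deg = c(0, 120, 240) + d$rot,
                                    reference_ex_nm = ranges$reference_ex_nm,
                                    modulation_depth = d$m)
    prot <- acquisition_protocol(geom, cfg, "sequential")
    step <- switch(d$mode,
                   even = 2 * pi / 3,
                   uneven_wavelength = (2 * pi / 3) * ranges$reference_ex_nm / d$lambda_ex,
                   jitter = 2 * pi / 3)
    for (j in 1:9) {
      ph_idx <- (j - 1) %% 3
      prot$channels[[1]][[j]]$phase <- ph_idx * step +
        if (d$mode == "jitter" && ph_idx > 0) d$jitter[ph_idx] else 0
    }
    truth <- generate_sample(d$kind, size = 2 * size, pixel_nm = pixel_nm / 2,
                             seed = d$seed_sample,
                             n_beads = max(3, round(size^2 / 400)),
                             min_separation_nm = 10 * pixel_nm,
                             n_filaments = max(2, size %/% 16))
    stk <- simulate_stack(truth, prot, cfg,
                          noise_model(peak_signal = d$peak), seed = d$seed_noise)
    list(stack = stk, truth = truth, params = d)
  })
}

#' Default randomization ranges for training-set generation
#' @export
training_ranges <- function() {
  list(sa = c(0, 0.25),                  # waves RMS
       rotation_deg = c(-10, 10),
       phase_modes = c("even", "uneven_wavelength", "jitter"),
       lambda_ex = c(460, 660),          # nm
       m = c(0.3, 1.0),
       peak = c(20, 400),                # photons
       phase_jitter = c(-0.6, 0.6),      # rad
       reference_ex_nm = 561)
}
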