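test_that("detection cutoff follows 2 NA / lambda and validates inputs", {
  cfg <- optical_config(1.2, 1.33, list(c(ex_nm = 488, em_nm = 515),
                                        c(ex_nm = 647, em_nm = 680)),
                        pixel_nm = 60, image_px = 64)
  expect_equal(detection_cutoff(cfg, 1), 4.6602, tolerance = 1e-4)
  expect_equal(detection_cutoff(cfg, 2), 3.5294, tolerance = 1e-4)
  expect_error(detection_cutoff(cfg, 3), "out of range")
  expect_error(optical_config(0, channels = list(c(ex_nm = 488, em_nm = 515))),
               "positive")
  expect_error(optical_config(1.5, n_immersion = 1.33,
                              channels = list(c(ex_nm = 488, em_nm = 515))),
               "immersion")
  expect_error(optical_config(1.2, channels = list(c(ex_nm = 300, em_nm = 515))),
               "400")
  expect_error(optical_config(1.2, channels = list(c(ex_nm = 488, em_nm = 515)),
                              pixel_nm = 150), "Nyquist")
})

test_that("PSF is a normalized, centred Airy pattern matching a direct pupil sum", {
  cfg <- cfg_green(64)
  psf <- make_psf(cfg, 1, size = 64)
  expect_true(all(psf >= 0))
  expect_equal(sum(psf), 1, tolerance = 1e-9)
  ctr <- floor(64 / 2) + 1
  expect_equal(unname(which(psf == max(psf), arr.ind = TRUE)[1, ]), c(ctr, ctr))
  # radial symmetry
  expect_equal(psf[ctr + 5, ctr], psf[ctr - 5, ctr], tolerance = 1e-9)
  expect_equal(psf[ctr, ctr + 5], psf[ctr + 5, ctr], tolerance = 1e-9)

  # independent oracle: brute-force DFT over the same discrete pupil
  n <- 128  # the padded grid make_psf uses internally (pad = 2)
  p_um <- 0.06
  pup <- simscope:::pupil_on_grid(n, p_um, 1.2, 0.515, 0)
  g <- simscope:::freq_grids(n, p_um)
  brute <- function(x_um, y_um)
    Mod(sum(pup * exp(2i * pi * (g$kx * x_um + g$ky * y_um))))^2
  pk <- brute(0, 0)
  for (off in list(c(1, 0), c(0, 2), c(3, 3))) {
    got <- psf[ctr + off[2], ctr + off[1]] / psf[ctr, ctr]
    want <- brute(off[1] * p_um, off[2] * p_um) / pk
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("PSF errors when the grid clips its support", {
  cfg <- cfg_green(64)
  expect_error(make_psf(cfg, 1, size = 16), "clipped|support")
})

test_that("OTF matches the closed-form chat function and is bandlimited", {
  cfg <- cfg_green(96)
  otf <- make_otf(cfg, 1, size = 96)
  expect_equal(otf[1, 1], 1)
  cutoff <- detection_cutoff(cfg, 1)
  # closed-form incoherent OTF of an unaberrated circular pupil
  chat <- function(s) ifelse(s >= 2, 0,
    (2 / pi) * (acos(s / 2) - (s / 2) * sqrt(1 - (s / 2)^2)))
  prof <- otf_radial(cfg, 1)
  s <- seq(0.05, 1.75, by = 0.05)   # |k| < 0.9 * cutoff has s < 1.8
  kc <- 1.2 / 0.515
  expect_equal(prof(s * kc), chat(s), tolerance = 1e-4)
  # identically zero beyond the cutoff
  expect_identical(prof(1.01 * cutoff), 0)
  g <- simscope:::freq_grids(96, 0.06)
  expect_true(all(otf[g$kr > cutoff] == 0))
  # Hermitian symmetry of the grid (real OTF, real PSF)
  expect_true(all(abs(otf - Re(otf)) == 0))
})

test_that("OTF varies continuously with spherical aberration", {
  base <- optical_config(1.2, channels = list(c(ex_nm = 488, em_nm = 515)),
                         image_px = 64, sa_waves = 0.1)
  pert <- optical_config(1.2, channels = list(c(ex_nm = 488, em_nm = 515)),
                         image_px = 64, sa_waves = 0.1 + 1e-3)
  k <- seq(0.2, 4.4, by = 0.2)
  d <- max(abs(otf_radial(base, 1)(k) - otf_radial(pert, 1)(k)))
  expect_lt(d, 0.01)
  # and aberration really does change the OTF at a macroscopic scale
  strong <- optical_config(1.2, channels = list(c(ex_nm = 488, em_nm = 515)),
                           image_px = 64, sa_waves = 0.5)
  expect_gt(max(abs(otf_radial(base, 1)(k) - otf_radial(strong, 1)(k))), 0.02)
})

test_that("PSF normalization is equivalent to unit DC of the OTF", {
  cfg <- optical_config(1.2, channels = list(c(ex_nm = 488, em_nm = 515)),
                        image_px = 96, sa_waves = 0.1)
  psf <- make_psf(cfg, 1, size = 96)
  otf_dc <- sum(psf)   # OTF(0) = sum of the PSF
  expect_equal(otf_dc, 1, tolerance = 1e-9)
})
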