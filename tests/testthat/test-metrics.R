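make_gaussian <- function(n, x0, y0, sigma_px, amp = 1, offset = 0) {
  x <- matrix(seq_len(n), n, n, byrow = TRUE)
  y <- matrix(seq_len(n), n, n)
  amp * exp(-((x - x0)^2 + (y - y0)^2) / (2 * sigma_px^2)) + offset
}

test_that("exact Gaussians are fitted to machine-level FWHM accuracy", {
  px <- 10   # nm per pixel; sigma = 50 nm = 5 px
  img <- make_gaussian(128, 64.3, 62.7, 5, amp = 3, offset = 0.2)
  rep <- fit_fwhm(img, cbind(64, 63), pixel_nm = px, expected_fwhm_nm = 120)
  expect_equal(rep$n_fit, 1)
  expect_equal(rep$mean_fwhm_nm, 2 * sqrt(2 * log(2)) * 50, tolerance = 1e-6)
  expect_equal(rep$emitters$fwhm_x_nm, rep$emitters$fwhm_y_nm, tolerance = 1e-6)
})

test_that("FWHM estimation is unbiased across sub-pixel positions", {
  px <- 30
  offs <- seq(0, 0.9, by = 0.15)
  fw <- vapply(offs, function(o) {
    img <- make_gaussian(48, 24 + o, 24 - o / 2, 2.2)
    fit_fwhm(img, cbind(24, 24), pixel_nm = px,
             expected_fwhm_nm = 2.2 * 2.3548 * px)$mean_fwhm_nm
  }, numeric(1))
  want <- 2.3548200450309493 * 2.2 * px
  expect_lt(max(abs(fw - want)) / want, 0.01)
})

test_that("merged peaks are excluded with a diagnostic", {
  img <- make_gaussian(64, 30, 32, 3) + make_gaussian(64, 36, 32, 3)
  rep <- fit_fwhm(img, cbind(c(30, 36), c(32, 32)), pixel_nm = 30,
                  expected_fwhm_nm = 200)
  expect_equal(rep$n_fit, 0)
  expect_equal(rep$n_excluded, 2)
  expect_match(rep$exclusions[1], "merged")
})

test_that("FRC of identical images is 1 with no threshold crossing", {
  set.seed(1)
  img <- matrix(rnorm(64^2), 64, 64)
  out <- frc_resolution(img, img, pixel_nm = 60)
  expect_true(all(abs(out$frc - 1) < 1e-9))
  expect_true(is.na(out$resolution_nm))
  expect_identical(out$status, "beyond_nyquist")
})

test_that("FRC of independent noise fluctuates about zero and is symmetric", {
  set.seed(2)
  a <- matrix(rnorm(128^2), 128, 128)
  b <- matrix(rnorm(128^2), 128, 128)
  out <- frc_resolution(a, b, pixel_nm = 60)
  expect_lt(abs(mean(out$frc[-1])), 0.05)
  expect_lt(max(abs(out$frc[-1])), 0.5)
  out_ba <- frc_resolution(b, a, pixel_nm = 60)
  expect_identical(out$frc, out_ba$frc)
})

test_that("FRC resolution recovers a constructed band limit", {
  set.seed(3)
  n <- 256; p_um <- 0.06
  g <- simscope:::freq_grids(n, p_um)
  k_lim <- 4   # cycles/um
  scene <- Re(simscope:::ifft2(simscope:::fft2(matrix(rnorm(n^2), n, n)) *
                               (g$kr < k_lim)))
  scene <- scene / sd(scene)
  a <- scene + matrix(rnorm(n^2, 0, 0.05), n, n)
  b <- scene + matrix(rnorm(n^2, 0, 0.05), n, n)
  # the constructed scene is periodic, so no window is needed (and the
  # window's spectral smearing would blur the hard band edge)
  out <- frc_resolution(a, b, pixel_nm = 60, window = FALSE)
  expect_identical(out$status, "ok")
  dk <- 1 / (n * p_um)
  expect_equal(1000 / out$resolution_nm, k_lim, tolerance = 2 * dk / k_lim)
})

test_that("stripe energy flags pattern-frequency power and is scale invariant", {
  n <- 128; p_um <- 0.03
  x <- simscope:::centered_coords(n, p_um)
  k0 <- c(4.4, 0)
  set.seed(4)
  base <- matrix(runif(n^2), n, n)
  striped <- base * (1 + 0.5 * cos(2 * pi * k0[1] * matrix(x, n, n, byrow = TRUE)))
  k_list <- list(k0, c(-2.2, 3.81), c(-2.2, -3.81))
  se_base <- stripe_energy(base, k_list, 30)
  se_striped <- stripe_energy(striped, k_list, 30)
  expect_gt(se_striped, 5 * se_base)
  expect_equal(stripe_energy(17.3 * striped, k_list, 30), se_striped,
               tolerance = 1e-12)
  expect_error(stripe_energy(base, list(c(40, 0)), 30), "outside")
})

test_that("psnr matches the closed form and saturates at identity", {
  set.seed(5)
  truth <- matrix(runif(256^2), 256, 256)
  expect_identical(psnr(truth, truth), Inf)
  sigma <- 0.1
  noisy <- truth + matrix(rnorm(256^2, 0, sigma), 256, 256)
  want <- 10 * log10(max(truth)^2 / sigma^2)
  expect_equal(psnr(noisy, truth), want, tolerance = 0.1)
  less_noisy <- truth + matrix(rnorm(256^2, 0, sigma / 2), 256, 256)
  expect_gt(psnr(less_noisy, truth), psnr(noisy, truth))
})
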