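test_that("band separation is exact for even and uneven phase triples", {
  for (case in list(list(ph = c(0, 2 * pi / 3, 4 * pi / 3), m = 1),
                    list(ph = c(0, 2.4077, 4.8154), m = 1),
                    list(ph = c(0.3, 1.1, 3.9), m = 0.55))) {
    o <- make_frames_from_bands(48, c(3.1, 1.2), case$ph, case$m)
    sep <- separate_bands(o$frames, case$ph, m = case$m)
    scale <- max(abs(o$b0))
    expect_lt(max(abs(sep$b0 - o$b0)) / scale, 1e-10)
    expect_lt(max(abs(sep$b_plus - o$b_plus)) / scale, 1e-10)
    # the -1 band is the conjugate-carrier partner of the +1 band
    expect_lt(max(abs(sep$b_minus - o$b_minus)) / scale, 1e-10)
    expect_lt(max(abs(simscope:::ifft2(sep$b_minus) -
                        Conj(simscope:::ifft2(sep$b_plus)))), 1e-10)
  }
})

test_that("generalized separation matches the phase-index DFT for even steps", {
  ph <- c(0, 2 * pi / 3, 4 * pi / 3)
  o <- make_frames_from_bands(48, c(2.5, -1.8), ph, 1)
  sep <- separate_bands(o$frames, ph, m = 1)
  # classic separation: DFT over the phase index
  D <- lapply(1:3, function(j) simscope:::fft2(o$frames[, , j]))
  b0 <- (D[[1]] + D[[2]] + D[[3]]) / 3
  bp <- (2 / 3) * (D[[1]] + exp(-1i * ph[2]) * D[[2]] + exp(-1i * ph[3]) * D[[3]])
  expect_lt(max(abs(sep$b0 - b0)) / max(abs(b0)), 1e-10)
  expect_lt(max(abs(sep$b_plus - bp)) / max(abs(b0)), 1e-10)
})

test_that("nearly coincident phases raise a singularity error naming the pair", {
  o <- make_frames_from_bands(32, c(3, 0), c(0, 1e-9, 2 * pi / 3), 1)
  expect_error(separate_bands(o$frames, c(0, 1e-9, 2 * pi / 3)), "1 and 2")
})

test_that("wavevector, phases and modulation depth are recovered from data", {
  cfg <- cfg_green(256)
  geom <- interferometer_geometry(pattern_fraction = 0.95, modulation_depth = 0.8,
                                  reference_ex_nm = 561)
  prot <- acquisition_protocol(geom, cfg, "sequential")
  # uneven steps: overwrite with the 561-reference simultaneous law
  for (j in 1:9)
    prot$channels[[1]][[j]]$phase <- ((j - 1) %% 3) * (2 * pi / 3) * 561 / 488
  gt <- generate_sample("filaments", size = 512, pixel_nm = 30, seed = 7)
  stk <- simulate_stack(gt, prot, cfg, noise = noise_model(200), seed = 1)
  cutoff <- detection_cutoff(cfg, 1)
  for (a in 1:3) {
    est <- estimate_wavevector(stk$frames[[1]][, , (a - 1) * 3 + 1:3], cfg)
    k_true <- prot$channels[[1]][[(a - 1) * 3 + 1]]$k
    expect_lt(sqrt(sum((est$k - k_true)^2)), 0.002 * cutoff)
    expect_equal(est$m, 0.8, tolerance = 0.05)
    ph_true <- vapply(prot$channels[[1]][(a - 1) * 3 + 1:3], `[[`, numeric(1), "phase")
    rel_err <- wrap_pi((est$phases - est$phases[1]) - (ph_true - ph_true[1]))
    expect_lt(max(abs(rel_err)), 0.12)
  }
})

test_that("estimation fails loudly when there is no pattern", {
  cfg <- cfg_green(128)
  geom0 <- interferometer_geometry(modulation_depth = 0)
  gt <- generate_sample("filaments", size = 256, pixel_nm = 30, seed = 7)
  stk <- simulate_stack(gt, acquisition_protocol(geom0, cfg), cfg,
                        noise = noise_model(200), seed = 2)
  expect_error(estimate_wavevector(stk$frames[[1]][, , 1:3], cfg),
               "pattern not found")
})

test_that("parameter recovery improves with photon budget", {
  cfg <- cfg_green(128)
  geom <- interferometer_geometry(pattern_fraction = 0.95, modulation_depth = 0.8)
  prot <- acquisition_protocol(geom, cfg, "sequential")
  gt <- generate_sample("filaments", size = 256, pixel_nm = 30, seed = 7)
  k_true <- prot$channels[[1]][[1]]$k
  err_at <- function(peak) {
    e <- vapply(1:3, function(s) {
      stk <- simulate_stack(gt, prot, cfg, noise_model(peak), seed = s)
      est <- estimate_wavevector(stk$frames[[1]][, , 1:3], cfg)
      sqrt(sum((est$k - k_true)^2))
    }, numeric(1))
    median(e)
  }
  expect_lt(err_at(2000), err_at(20))
})

test_that("flat fields reconstruct flat: no pattern imprinting", {
  # grid-commensurate fringes (integer cycles across the field of view), so
  # the algebraic identity is not confounded by periodic-boundary seams
  cfg <- cfg_matched(64)
  n <- 64; p_um <- 0.06
  dk <- 1 / (n * p_um)
  k_list <- list(16 * dk * c(1, 0), dk * c(-8, 14), dk * c(-8, -14))
  m <- 0.8
  prof <- otf_radial(cfg, 1)
  xc <- simscope:::centered_coords(n, p_um)
  X <- matrix(xc, n, n, byrow = TRUE); Y <- matrix(xc, n, n)
  phases <- c(0, 2 * pi / 3, 4 * pi / 3) + 0.37
  seps <- lapply(k_list, function(k0) {
    fr <- array(0, c(n, n, 3))
    amp <- m * prof(sqrt(sum(k0^2)))   # fringe contrast after detection blur
    for (j in 1:3)
      fr[, , j] <- 1 + amp * cos(2 * pi * (k0[1] * X + k0[2] * Y) + phases[j])
    separate_bands(fr, phases, m = 1)
  })
  rec <- wiener_combine(seps, k_list, rep(m, 3), cfg, 1,
                        recon_options(wiener_parameter = 0.05))
  img <- rec$image
  ripple <- (max(img) - min(img)) / mean(img)
  expect_lt(ripple, 1e-6)
})

test_that("support mask reaches widefield cutoff plus pattern frequency", {
  cfg <- cfg_matched(64)
  geom <- interferometer_geometry(pattern_fraction = 1, modulation_depth = 0.8)
  prot <- acquisition_protocol(geom, cfg)
  gt <- generate_sample("texture", size = 128, pixel_nm = 30, seed = 1)
  stk <- simulate_stack(gt, prot, cfg, noise = NULL)
  rec <- reconstruct_sim(stk, known_params = list(true_params(prot)))
  g <- simscope:::freq_grids(nrow(rec$image), cfg$pixel_nm * 1e-3 / 2)
  cutoff <- detection_cutoff(cfg, 1)
  kmag <- sqrt(sum(prot$channels[[1]][[1]]$k^2))
  dk <- 1 / (nrow(rec$image) * cfg$pixel_nm * 1e-3 / 2)
  # maximal radius along the first pattern direction (+x here)
  on_axis <- abs(g$ky) < dk / 2 & g$kx > 0
  expect_equal(max(g$kx[on_axis & rec$support]), cutoff + kmag, tolerance = 2 * dk)
  # support mask radius never below the widefield cutoff
  expect_true(all(rec$support[g$kr < cutoff - dk]))
})

test_that("two-point response: reconstruction transfers 1.8x the widefield cutoff", {
  cfg <- cfg_matched(64)
  cutoff <- detection_cutoff(cfg, 1)
  p_fine <- 0.03
  x <- simscope:::centered_coords(128, p_fine)
  # 1.84x the cutoff, snapped to an integer cycle count across the field
  k_hi <- 33 / (64 * 0.06)
  gt <- 1 + 0.9 * cos(2 * pi * k_hi * matrix(x, 128, 128, byrow = TRUE))
  geom <- interferometer_geometry(pattern_fraction = 1, modulation_depth = 1)
  prot <- acquisition_protocol(geom, cfg)
  stk <- simulate_stack(gt, prot, cfg, noise = NULL)
  rec <- reconstruct_sim(stk, recon_options(wiener_parameter = 1e-4,
                                            fade_border = FALSE),
                         known_params = list(true_params(prot)))
  resp <- abs(simscope:::dft_at(rec$image, c(k_hi, 0), p_fine)) /
          abs(simscope:::dft_at(rec$image, c(0, 0), p_fine))
  wf <- widefield_image(stk)
  resp_wf <- abs(simscope:::dft_at(wf, c(k_hi, 0), 0.06)) /
             abs(simscope:::dft_at(wf, c(0, 0), 0.06))
  expect_gt(resp, 1e-3)
  expect_lt(resp_wf, 1e-8)
})

test_that("reconstruction beats upsampled widefield and flags frame-count errors", {
  cfg <- cfg_green(128)
  geom <- interferometer_geometry(pattern_fraction = 0.95, modulation_depth = 0.8)
  prot <- acquisition_protocol(geom, cfg)
  gt <- generate_sample("filaments", size = 256, pixel_nm = 30, seed = 5)
  stk <- simulate_stack(gt, prot, cfg, noise = noise_model(200), seed = 1)
  rec <- reconstruct_sim(stk)
  tr <- unclass(gt) / max(gt)
  wfu <- simscope:::bilinear2x(widefield_image(stk))
  expect_gt(psnr(match_scale(rec$image, tr), tr),
            psnr(match_scale(wfu, tr), tr))
  bad <- stk
  bad$frames[[1]] <- bad$frames[[1]][, , 1:8]
  expect_error(reconstruct_sim(bad), "9 frames")
})

test_that("false even-phase assumptions honeycomb the spectrum; true phases do not", {
  # pattern placed at 0.75 of the excitation passband so the second
  # harmonics +-2k stay inside the enlarged support where the mixing
  # artifact is not masked away
  cfg <- cfg_green(128)
  geom <- interferometer_geometry(pattern_fraction = 0.75, modulation_depth = 0.8)
  prot <- acquisition_protocol(geom, cfg)
  for (j in 1:9)   # uneven steps from the 561-reference law
    prot$channels[[1]][[j]]$phase <- ((j - 1) %% 3) * (2 * pi / 3) * 561 / 488
  gt <- generate_sample("filaments", size = 256, pixel_nm = 30, seed = 9)
  stk <- simulate_stack(gt, prot, cfg, noise = noise_model(1000), seed = 4)
  kp <- true_params(prot)
  k_list <- kp$k
  base <- stripe_energy(unclass(gt), k_list, 30)
  rec_true <- reconstruct_sim(stk, known_params = list(kp))
  kp_false <- kp
  kp_false$phases <- lapply(1:3, function(a) c(0, 2 * pi / 3, 4 * pi / 3))
  rec_false <- reconstruct_sim(stk, known_params = list(kp_false))
  se_true <- stripe_energy(rec_true$image, k_list, 30)
  se_false <- stripe_energy(rec_false$image, k_list, 30)
  expect_gt(se_false, 3 * base)
  expect_lt(se_true, 2 * base)
  expect_gt(se_false, 3 * se_true)
})

test_that("recon options are validated", {
  expect_error(recon_options(wiener_parameter = -1), "positive")
  expect_error(recon_options(wiener_parameter = 0), "positive")
})
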