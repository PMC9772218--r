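test_that("ground-truth generators are deterministic, non-negative and sized", {
  for (kind in c("beads", "filaments", "texture")) {
    a <- generate_sample(kind, size = 96, pixel_nm = 30, seed = 1, n_beads = 10,
                         min_separation_nm = 600)
    b <- generate_sample(kind, size = 96, pixel_nm = 30, seed = 1, n_beads = 10,
                         min_separation_nm = 600)
    expect_identical(unclass(a), unclass(b))
    expect_true(min(a) >= 0)
    expect_true(all(is.finite(a)))
    expect_equal(dim(a), c(96, 96))
  }
  expect_error(generate_sample("beads", size = 32), "64")
  expect_error(generate_sample("voronoi", size = 96), "arg")
})

test_that("bead fields respect count and minimum separation", {
  gt <- generate_sample("beads", size = 256, pixel_nm = 30, seed = 3,
                        n_beads = 25, bead_diameter_nm = 100,
                        min_separation_nm = 800)
  pos <- attr(gt, "params")$positions_px
  expect_equal(nrow(pos), 25)
  d <- as.matrix(dist(pos)) * 30
  diag(d) <- Inf
  expect_gte(min(d), 800)
})

test_that("fringes cancel: phase-averaged frames equal the widefield image", {
  cfg <- cfg_matched(64)
  for (seed in 1:3) {
    gt <- generate_sample("texture", size = 128, pixel_nm = 30, seed = seed)
    geom <- interferometer_geometry(pattern_fraction = 0.9, modulation_depth = 0.8)
    stk <- simulate_stack(gt, acquisition_protocol(geom, cfg), cfg, noise = NULL)
    geom0 <- interferometer_geometry(pattern_fraction = 0.9, modulation_depth = 0)
    stk0 <- simulate_stack(gt, acquisition_protocol(geom0, cfg), cfg, noise = NULL)
    for (a in 0:2) {
      avg <- (stk$frames[[1]][, , a * 3 + 1] + stk$frames[[1]][, , a * 3 + 2] +
              stk$frames[[1]][, , a * 3 + 3]) / 3
      expect_equal(avg, stk0$frames[[1]][, , a * 3 + 1], tolerance = 1e-9)
    }
  }
})

test_that("zero modulation depth gives nine identical frames", {
  cfg <- cfg_matched(64)
  gt <- generate_sample("texture", size = 128, pixel_nm = 30, seed = 2)
  geom0 <- interferometer_geometry(modulation_depth = 0)
  stk <- simulate_stack(gt, acquisition_protocol(geom0, cfg), cfg, noise = NULL)
  for (j in 2:9)
    expect_equal(stk$frames[[1]][, , j], stk$frames[[1]][, , 1], tolerance = 1e-12)
})

test_that("Poisson noise has unit variance-to-mean ratio", {
  cfg <- cfg_matched(64)
  gt <- matrix(1, 128, 128)   # uniform sample
  geom0 <- interferometer_geometry(modulation_depth = 0)
  prot <- acquisition_protocol(geom0, cfg)
  nm <- noise_model(peak_signal = 50, read_noise_sd = 0, background = 0, gain = 1)
  # a uniform noiseless expectation: every pixel of every frame is an
  # independent Poisson(50) draw, so pool them all
  stk <- simulate_stack(gt, prot, cfg, noise = nm, seed = 4)
  vals <- as.vector(stk$frames[[1]])
  ratio <- stats::var(vals) / mean(vals)
  expect_gt(ratio, 0.95); expect_lt(ratio, 1.05)  # ~37k draws
})

test_that("expected counts scale linearly with peak_signal", {
  cfg <- cfg_matched(64)
  gt <- generate_sample("texture", size = 128, pixel_nm = 30, seed = 2)
  prot <- acquisition_protocol(interferometer_geometry(), cfg)
  tot <- vapply(c(50, 100, 200), function(p) {
    s <- simulate_stack(gt, prot, cfg,
                        noise_model(p, read_noise_sd = 0, background = 0), seed = 1)
    sum(s$frames[[1]])
  }, numeric(1))
  expect_equal(tot[2] / tot[1], 2, tolerance = 0.02)
  expect_equal(tot[3] / tot[1], 4, tolerance = 0.02)
})

test_that("a moire beat carries super-resolution content into the passband", {
  cfg <- cfg_matched(64)
  p_fine <- 0.03
  x <- simscope:::centered_coords(128, p_fine)
  cutoff <- detection_cutoff(cfg, 1)
  k_s <- 1.5 * cutoff              # sample frequency beyond the passband
  gt <- 1 + 0.9 * cos(2 * pi * k_s * matrix(x, 128, 128, byrow = TRUE))
  geom <- interferometer_geometry(pattern_fraction = 1, orientations_deg = c(0, 120, 240),
                                  modulation_depth = 1)
  stk <- simulate_stack(gt, acquisition_protocol(geom, cfg), cfg, noise = NULL)
  geom0 <- interferometer_geometry(pattern_fraction = 1, modulation_depth = 0)
  stk0 <- simulate_stack(gt, acquisition_protocol(geom0, cfg), cfg, noise = NULL)
  k_pat <- cutoff                  # angle 1 pattern along +x at the passband
  beat <- c(k_s - k_pat, 0)        # inside the passband
  # window and mean-subtract to keep DC leakage out of the beat measurement
  win <- simscope:::tukey_window_2d(64, 0.4)
  probe <- function(fr) abs(simscope:::dft_at((fr - mean(fr)) * win, beat, 0.06))
  a_mod <- probe(stk$frames[[1]][, , 1])
  a_wf <- probe(stk0$frames[[1]][, , 1])
  expect_gt(a_mod, 20 * max(a_wf, 1e-12))
})

test_that("simulate_stack validates its inputs", {
  cfg <- cfg_matched(64)
  gt_wrong <- generate_sample("texture", size = 96, pixel_nm = 30, seed = 1)
  prot <- acquisition_protocol(interferometer_geometry(), cfg)
  expect_error(simulate_stack(gt_wrong, prot, cfg), "2x the camera grid")
})

test_that("training-set generation is deterministic and honours ranges", {
  a <- generate_training_set(3, size = 32, seed = 7)
  b <- generate_training_set(3, size = 32, seed = 7)
  expect_identical(lapply(a, `[[`, "params"), lapply(b, `[[`, "params"))
  expect_identical(a[[2]]$stack$frames, b[[2]]$stack$frames)
  # collapsed ranges give identical parameters across examples
  rng <- training_ranges()
  rng$sa <- c(0.1, 0.1); rng$m <- c(0.7, 0.7); rng$peak <- c(100, 100)
  rng$rotation_deg <- c(0, 0); rng$lambda_ex <- c(510, 510)
  rng$phase_modes <- "even"
  cc <- generate_training_set(3, size = 32, ranges = rng, seed = 1)
  expect_equal(cc[[1]]$params$sa, 0.1)
  expect_equal(vapply(cc, function(e) e$params$m, numeric(1)), rep(0.7, 3))
  # uneven-by-wavelength mode reproduces the interferometer phase law
  rng$phase_modes <- "uneven_wavelength"
  dd <- generate_training_set(2, size = 32, ranges = rng, seed = 2)
  ph <- vapply(dd[[1]]$stack$protocol$channels[[1]][1:3], `[[`, numeric(1), "phase")
  expect_equal(ph[2], (2 * pi / 3) * 561 / 510, tolerance = 1e-9)
  expect_error(generate_training_set(2, ranges = within(training_ranges(),
                                                        sa <- c(0.3, 0.1))),
               "range")
})
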