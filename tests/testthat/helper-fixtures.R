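# Shared fixtures: small optical configurations and stack builders used
# across the test files.  Everything is generated in code at test time.

cfg_green <- function(image_px = 128, pixel_nm = 60)
  optical_config(1.2, 1.33, list(c(ex_nm = 488, em_nm = 515)),
                 pixel_nm = pixel_nm, image_px = image_px)

# matched excitation/emission: pattern at the detection cutoff is reachable
cfg_matched <- function(image_px = 128, pixel_nm = 60)
  optical_config(1.2, 1.33, list(c(ex_nm = 515, em_nm = 515)),
                 pixel_nm = pixel_nm, image_px = image_px)

cfg_two_color <- function(image_px = 64)
  optical_config(1.2, 1.33, list(c(ex_nm = 488, em_nm = 515),
                                 c(ex_nm = 561, em_nm = 580)),
                 pixel_nm = 60, image_px = image_px)

# protocol parameters of a simulated stack, in the layout reconstruct_sim
# accepts as known_params
true_params <- function(prot, channel = 1) {
  list(k = lapply(1:3, function(a) prot$channels[[channel]][[(a - 1) * 3 + 1]]$k),
       phases = lapply(1:3, function(a)
         vapply(prot$channels[[channel]][(a - 1) * 3 + 1:3], `[[`, numeric(1), "phase")),
       m = vapply(1:3, function(a) prot$channels[[channel]][[(a - 1) * 3 + 1]]$m,
                  numeric(1)))
}

quick_bead_stack <- function(cfg, seed = 2, n_beads = 8, noise = NULL,
                             pattern_fraction = 0.95, m = 0.8,
                             min_separation_nm = 1500) {
  geom <- interferometer_geometry(pattern_fraction = pattern_fraction,
                                  modulation_depth = m)
  prot <- acquisition_protocol(geom, cfg, "sequential")
  gt <- generate_sample("beads", size = 2 * cfg$image_px,
                        pixel_nm = cfg$pixel_nm / 2, seed = seed,
                        n_beads = n_beads, min_separation_nm = min_separation_nm)
  list(gt = gt, prot = prot,
       stack = simulate_stack(gt, prot, cfg, noise = noise, seed = seed))
}

wrap_pi <- function(x) (x + pi) %% (2 * pi) - pi

# forward-construction oracle: frames assembled directly from known bands
make_frames_from_bands <- function(n, k0, phases, m, p_um = 0.06, seed = 3) {
  set.seed(seed)
  s <- matrix(runif(n * n), n, n)
  xc <- simscope:::centered_coords(n, p_um)
  carrier <- exp(2i * pi * (k0[1] * matrix(xc, n, n, byrow = TRUE) +
                            k0[2] * matrix(xc, n, n)))
  p <- s * carrier
  fr <- array(0, c(n, n, 3))
  for (j in 1:3)
    fr[, , j] <- Re(s + (m / 2) * exp(1i * phases[j]) * p +
                      (m / 2) * exp(-1i * phases[j]) * Conj(p))
  list(frames = fr, b0 = simscope:::fft2(s), b_plus = simscope:::fft2(p),
       b_minus = simscope:::fft2(Conj(p)))
}
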