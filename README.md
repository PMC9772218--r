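# simscope

Simulation and reconstruction of two-dimensional structured illumination
microscopy (SIM) data for an **interferometric pattern generator** — the
instrument class in which the excitation fringes are formed by a Michelson
mirror pair, so the fringe period scales with the excitation wavelength and
the pattern spatial frequency is automatically the same fraction of every
color's excitation passband.

The package is aimed at microscope builders and image-analysis developers
who need to (1) generate physically faithful synthetic SIM stacks, (2)
reconstruct acquisitions whose phase steps are *not* the classical
2π/3 — the unavoidable situation in simultaneous multicolor imaging — and
(3) quantify resolution and reconstruction artifacts.

## The model in brief

A raw SIM acquisition is nine frames per color channel: three pattern
orientations separated by 120°, three phase steps each.  Frame *n* of one
orientation mixes three Fourier bands of the specimen *S*,

    D_n(k) = B0(k) + (m/2) e^{+i φ_n} B+(k) + (m/2) e^{-i φ_n} B-(k),
    B0 = S̃(k) H(k),   B± = S̃(k ∓ k0) H(k),

with `H` the detection OTF (cutoff `2 NA/λ_em`), `k0` the pattern
wavevector (`|k0| = f · 2 NA/λ_ex`, pattern fraction `f`) and `m` the
modulation depth.  Phase stepping is a lateral fringe displacement, so a
displacement tuned to 2π/3 steps at a reference wavelength gives channel
*c* the uneven steps `(2π/3)·λ_ref/λ_c`.  simscope inverts the mixing as a
3×3 linear system per Fourier pixel — exact for *any* pairwise-distinct
phase triple — estimates `k0`, the three phases, and `m` from the data,
and merges the re-shifted bands with a Wiener filter and an
ideal-aperture apodizer on a twice-finer grid.  A compact residual
channel-attention network trained on the simulator provides a
parameter-free alternative reconstructor.

Conventions: frequencies in cycles/µm, wavelengths and pixel sizes in nm;
spectra keep DC at index [1,1]; real-space coordinates are centred (origin
at pixel `floor(n/2)+1`); frames are ordered angle-major, phase-minor.

## Worked example

Simulate a 100 nm bead slide (NA 1.2, 488/515 nm, pattern at 0.95 of the
excitation passband, ~200 peak photons), reconstruct it, and measure bead
sizes:

```r
library(simscope)

cfg  <- optical_config(1.2, 1.33, list(c(ex_nm = 488, em_nm = 515)),
                       pixel_nm = 60, image_px = 256)
geom <- interferometer_geometry(pattern_fraction = 0.95, modulation_depth = 0.8)
prot <- acquisition_protocol(geom, cfg, "sequential")

gt  <- generate_sample("beads", size = 512, pixel_nm = 30, seed = 2,
                       n_beads = 30, bead_diameter_nm = 100,
                       min_separation_nm = 1800)
stk <- simulate_stack(gt, prot, cfg, noise = noise_model(200), seed = 1)

rec <- reconstruct_sim(stk)    # estimates k0, phases, m per orientation
rec
#> sim_recon: 512 x 512 px at 30 nm/px
#>   angle 1: |k| = 4.674 cyc/um, m = 0.795, phases 0.463, 2.532, 4.594
#>   angle 2: |k| = 4.672 cyc/um, m = 0.802, phases 0.038, 2.293, 4.446
#>   angle 3: |k| = 4.673 cyc/um, m = 0.796, phases 5.786, 1.421, 3.606

pos <- attr(gt, "params")$positions_px
fit_fwhm(rec$image, pos, pixel_nm = 30, expected_fwhm_nm = 130)
#> fwhm_report: 30 emitter(s) fitted (0 excluded), mean FWHM 121.4 nm

wf <- wiener_deconvolve(widefield_image(stk), cfg)
fit_fwhm(wf, (pos + 0.5) / 2, pixel_nm = 60, expected_fwhm_nm = 220)
#> fwhm_report: 30 emitter(s) fitted (0 excluded), mean FWHM 186.1 nm
```

The reconstruction roughly halves the bead FWHM (121 nm vs 186 nm for the
Wiener-deconvolved widefield image; the diffraction-limited PSF at these
wavelengths is ~219 nm).  The estimated pattern frequency, 4.67 cycles/µm,
sits just above the 4.66 cycles/µm detection cutoff — the fringes
themselves are barely visible in the raw frames, and parameter estimation
works from the band overlap instead.  The recovered modulation depths and
phase steps (2.07–2.09 rad) match the simulated `m = 0.8` and even 2π/3
stepping; phases are reported in the camera-grid coordinate convention, so
only differences are comparable across runs.

For simultaneous two-color acquisition, pass a two-channel
`optical_config` and `mode = "simultaneous"` with a reference wavelength;
the 488 nm channel then receives steps of 2.408 rad, and
`reconstruct_sim()` handles them without any even-step assumption.  The
learned route is `build_network(desk_preset())`, `train_network()` on
`generate_training_set()` output, then `infer_ml()`.

A command-line wrapper (`inst/cli/simscope`) exposes
`simulate`, `reconstruct`, `train`, and `evaluate` subcommands over
multi-page TIFF stacks with JSON sidecars; see `?sim_cli`.

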