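#' Geometry of the interferometric pattern generator
#'
#' Describes the Michelson mirror-pair fringe projector: the pattern spatial
#' frequency as a fixed fraction of each channel's excitation passband (the
#' interferometer produces fringes whose period scales with the excitation
#' wavelength, so this fraction is wavelength-independent by construction),
#' the three pattern orientations, and the mapping from galvo beam
#' displacement to lateral fringe displacement that generates phase steps.
#'
#' @param pattern_fraction Pattern frequency as a fraction of the excitation
#'   passband `2 NA / lambda_ex`; in (0, 1].
#' @param orientations_deg Three pattern orientations in degrees; pairwise
#'   distinct modulo 180.
#' @param reference_ex_nm Excitation wavelength (nm) whose phase steps are
#'   tuned to exactly 2*pi/3 in simultaneous mode; `NULL` for sequential-only
#'   use.
#' @param modulation_depth Pattern contrast m in \[0, 1\]; folds coherence and
#'   polarization losses into one scalar.
#' @param displacement_gain Fringe displacement (nm) per unit galvo step.
#' @param phase_origin Phase of the first frame of each orientation (radians).
#' @return Object of class `interferometer_geometry`.
#' @export
interferometer_geometry <- function(pattern_fraction = 0.95,
                                    orientations_deg = c(0, 120, 240),
                                    reference_ex_nm = NULL,
                                    modulation_depth = 0.8,
                                    displacement_gain = 1,
                                    phase_origin = 0) {
  if (!(pattern_fraction > 0 && pattern_fraction <= 1))
    stop("pattern_fraction must lie in (0, 1]")
  if (length(orientations_deg) != 3) stop("exactly three orientations required")
  d <- abs(outer(orientations_deg, orientations_deg, "-")) %% 180
  if (any(pmin(d, 180 - d)[upper.tri(d)] < 1e-9))
    stop("orientations must be pairwise distinct modulo 180 degrees")
  if (modulation_depth < 0 || modulation_depth > 1)
    stop("modulation_depth must lie in [0, 1]")
  structure(list(pattern_fraction = pattern_fraction,
                 orientations_deg = orientations_deg,
                 reference_ex_nm = reference_ex_nm,
                 modulation_depth = modulation_depth,
                 displacement_gain = displacement_gain,
                 phase_origin = phase_origin),
            class = "interferometer_geometry")
}

#' Fringe period of the projected pattern
#'
#' `p = lambda_ex / (pattern_fraction * 2 NA)`: the interferometer fringes get
#' wider with increasing excitation wavelength, the root cause of unequal
#' phase steps in simultaneous multicolor acquisition.
#'
#' @param geom An [interferometer_geometry()].
#' @param config An [optical_config()].
#' @param lambda_ex_nm Excitation wavelength in nm.
#' @return Period in nm.
#' @export
fringe_period <- function(geom, config, lambda_ex_nm) {
  stopifnot(lambda_ex_nm > 0)
  lambda_ex_nm / (geom$pattern_fraction * 2 * config$na)
}

#' Pattern wavevector for one channel and orientation
#' @inheritParams fringe_period
#' @param orientation_deg Pattern orientation in degrees.
#' @return `c(kx, ky)` in cycles/um.
#' @export
pattern_wavevector <- function(geom, config, lambda_ex_nm, orientation_deg) {
  kmag <- geom$pattern_fraction * 2 * config$na / (lambda_ex_nm * 1e-3)
  th <- orientation_deg * pi / 180
  c(kx = kmag * cos(th), ky = kmag * sin(th))
}

#' Phase shift produced by a lateral fringe displacement
#'
#' `delta_phi = 2 pi dx / p(lambda_ex)`: a fixed physical displacement
#' advances the phase of a short-wavelength (fine) pattern by more than that
#' of a long-wavelength (coarse) one, in proportion to `1 / lambda_ex`.
#'
#' @inheritParams fringe_period
#' @param dx_nm Lateral fringe displacement in nm.
#' @return Phase in radians.
#' @export
phase_from_displacement <- function(geom, config, dx_nm, lambda_ex_nm) {
  2 * pi * dx_nm / fringe_period(geom, config, lambda_ex_nm)
}

#' Build the 9-frame acquisition protocol
#'
#' Returns, per channel, the nine illumination states (3 orientations x 3
#' phases, angle-major phase-minor).  In `sequential` mode the displacement
#' is re-tuned per channel so every channel receives even steps of 2*pi/3.
#' In `simultaneous` mode one galvo displacement sequence, sized for the
#' reference wavelength, serves all channels at once, so channel `c` receives
#' steps `(2 pi / 3) * lambda_ref / lambda_c` — even only for the reference
#' channel.
#'
#' @inheritParams fringe_period
#' @param mode `"sequential"` or `"simultaneous"`.
#' @return Object of class `sim_protocol`: list with `channels` (each a list
#'   of 9 pattern states: `angle`, `orientation_deg`, `k`, `phase`, `m`),
#'   `mode`, and the geometry used.
#' @export
#' @examples
#' cfg <- optical_config(1.2, channels = list(c(ex_nm = 488, em_nm = 515),
#'                                            c(ex_nm = 561, em_nm = 580)))
#' geom <- interferometer_geometry(reference_ex_nm = 561)
#' p <- acquisition_protocol(geom, cfg, "simultaneous")
#' sapply(p$channels[[1]][1:3], `[[`, "phase")  # uneven steps for 488 nm
acquisition_protocol <- function(geom, config, mode = c("sequential", "simultaneous")) {
  mode <- match.arg(mode)
  if (length(config$channels) < 1) stop("config has no channels")
  if (mode == "simultaneous") {
    if (is.null(geom$reference_ex_nm))
      stop("simultaneous mode requires a reference wavelength (reference_ex_nm)")
    ex <- vapply(config$channels, `[[`, numeric(1), "ex_nm")
    if (!any(abs(ex - geom$reference_ex_nm) < 1e-6))
      stop("no channel matches the reference wavelength in simultaneous mode")
  }
  channels <- lapply(config$channels, function(ch) {
    step <- if (mode == "sequential") 2 * pi / 3
            else (2 * pi / 3) * geom$reference_ex_nm / ch$ex_nm
    states <- vector("list", 9)
    n <- 1
    for (a in 1:3) {
      k <- pattern_wavevector(geom, config, ch$ex_nm, geom$orientations_deg[a])
      for (ph in 0:2) {
        states[[n]] <- list(angle = a,
                            orientation_deg = geom$orientations_deg[a],
                            k = k,
                            phase = geom$phase_origin + ph * step,
                            m = geom$modulation_depth)
        n <- n + 1
      }
    }
    states
  })
  structure(list(channels = channels, mode = mode, geometry = geom),
            class = "sim_protocol")
}

#' @export
print.sim_protocol <- function(x, ...) {
  cat(sprintf("sim_protocol: %s mode, %d channel(s), 9 frames each\n",
              x$mode, length(x$channels)))
  for (i in seq_along(x$channels)) {
    ph <- vapply(x$channels[[i]][1:3], `[[`, numeric(1), "phase")
    cat(sprintf("  channel %d: |k| = %.3f cyc/um, phases %s rad\n", i,
                sqrt(sum(x$channels[[i]][[1]]$k^2)),
                paste(sprintf("%.4f", ph), collapse = ", ")))
  }
  invisible(x)
}
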