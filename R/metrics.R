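#' Fit 2D Gaussians to point emitters and report FWHM
#'
#' For each candidate peak a window of about seven expected FWHMs is cut out
#' and a 2D Gaussian (amplitude, centre, sigma_x, sigma_y, offset) is fitted
#' by Levenberg-Marquardt least squares; `FWHM = 2 sqrt(2 ln 2) sigma *
#' pixel`.  Candidates whose windows would overlap another candidate are
#' excluded up front (merged peaks cannot be fitted reliably), as are
#' non-convergent or high-residual fits; all exclusions are counted.
#'
#' @param image Real matrix.
#' @param peaks Two-column matrix or data.frame of candidate peak positions
#'   (`x`, `y`) in 1-based pixel coordinates (x = column, y = row).
#' @param pixel_nm Pixel size in nm.
#' @param expected_fwhm_nm Rough FWHM used to size the fit window.
#' @param window_px Window side length; default `7 * expected FWHM` (odd).
#' @param max_resid Relative RMS residual above which a fit is discarded.
#' @return Object of class `fwhm_report`: data.frame `emitters` with
#'   `x, y, fwhm_x_nm, fwhm_y_nm, fwhm_nm` (geometric mean) and `resid`;
#'   `mean_fwhm_nm`; `n_fit`; `n_excluded`.
#' @export
fit_fwhm <- function(image, peaks, pixel_nm, expected_fwhm_nm = 4 * pixel_nm,
                     window_px = NULL, max_resid = 0.25) {
  peaks <- as.matrix(peaks)[, 1:2, drop = FALSE]
  if (is.null(window_px))
    window_px <- max(9L, 2L * floor(3.5 * expected_fwhm_nm / pixel_nm) + 1L)
  if (window_px %% 2 == 0) window_px <- window_px + 1L
  half <- (window_px - 1L) %/% 2L
  n <- nrow(image)
  excluded <- character(0)
  keep <- rep(TRUE, nrow(peaks))
  if (nrow(peaks) > 1) {
    dd <- as.matrix(stats::dist(peaks))
    diag(dd) <- Inf
    merged <- apply(dd, 1, min) < window_px
    if (any(merged)) {
      keep[merged] <- FALSE
      excluded <- c(excluded, sprintf("peak %d: merged with a neighbour inside the fit window",
                                      which(merged)))
    }
  }
  on_edge <- peaks[, 1] <= half | peaks[, 1] > ncol(image) - half |
             peaks[, 2] <= half | peaks[, 2] > n - half
  if (any(on_edge & keep)) {
    excluded <- c(excluded, sprintf("peak %d: too close to the image border",
                                    which(on_edge & keep)))
    keep[on_edge] <- FALSE
  }
  rows <- list()
  for (i in which(keep)) {
    cx <- round(peaks[i, 1]); cy <- round(peaks[i, 2])
    ix <- (cx - half):(cx + half); iy <- (cy - half):(cy + half)
    z <- image[iy, ix]
    df <- data.frame(x = rep(ix, each = length(iy)),
                     y = rep(iy, times = length(ix)),
                     z = as.vector(z))
    s0 <- expected_fwhm_nm / pixel_nm / 2.3548
    pk <- which(z == max(z), arr.ind = TRUE)[1, ]
    start <- list(a = max(z) - min(z), x0 = ix[pk[2]], y0 = iy[pk[1]],
                  sx = s0, sy = s0, b = min(z))
    fit <- tryCatch(
      minpack.lm::nlsLM(z ~ a * exp(-((x - x0)^2 / (2 * sx^2) +
                                      (y - y0)^2 / (2 * sy^2))) + b,
                        data = df, start = start,
                        lower = c(0, min(ix), min(iy), 0.3, 0.3, -Inf),
                        upper = c(Inf, max(ix), max(iy), window_px, window_px, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      excluded <- c(excluded, sprintf("peak %d: fit did not converge", i))
      next
    }
    cf <- stats::coef(fit)
    resid <- sqrt(mean(stats::resid(fit)^2)) / cf[["a"]]
    if (!is.finite(resid) || resid > max_resid) {
      excluded <- c(excluded, sprintf("peak %d: residual %.3f above threshold", i, resid))
      next
    }
    fx <- 2.3548200450309493 * abs(cf[["sx"]]) * pixel_nm
    fy <- 2.3548200450309493 * abs(cf[["sy"]]) * pixel_nm
    rows[[length(rows) + 1]] <- data.frame(
      x = cf[["x0"]], y = cf[["y0"]], fwhm_x_nm = fx, fwhm_y_nm = fy,
      fwhm_nm = sqrt(fx * fy), resid = resid)
  }
  emitters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = numeric(0), y = numeric(0), fwhm_x_nm = numeric(0),
               fwhm_y_nm = numeric(0), fwhm_nm = numeric(0), resid = numeric(0))
  structure(list(emitters = emitters,
                 mean_fwhm_nm = if (nrow(emitters)) mean(emitters$fwhm_nm) else NA_real_,
                 n_fit = nrow(emitters), n_excluded = length(excluded),
                 exclusions = excluded, window_px = window_px),
            class = "fwhm_report")
}

#' @export
print.fwhm_report <- function(x, ...) {
  cat(sprintf("fwhm_report: %d emitter(s) fitted (%d excluded), mean FWHM %.1f nm\n",
              x$n_fit, x$n_excluded, x$mean_fwhm_nm))
  invisible(x)
}

#' Fourier ring correlation between two images of the same scene
#'
#' Computes the normalized cross-correlation of the two Fourier transforms
#' over rings of one frequency-pixel width; the resolution is the inverse of
#' the frequency at the first downward crossing of the threshold (linearly
#' interpolated between rings).  A Tukey taper is applied by default to
#' suppress spectral leakage from non-periodic borders.
#'
#' @param image_a,image_b Equal-size real matrices with independent noise.
#' @param pixel_nm Pixel size in nm.
#' @param threshold Correlation threshold (default the standard 1/7).
#' @param window Apply a Tukey(0.25) taper before transforming.
#' @return Object of class `frc_curve`: `freq_cyc_um`, `frc`,
#'   `resolution_nm` (`NA` when no crossing occurs), `status`
#'   (`"ok"` or `"beyond_nyquist"`), `threshold`.
#' @export
frc_resolution <- function(image_a, image_b, pixel_nm, threshold = 1 / 7,
                           window = TRUE) {
  stopifnot(all(dim(image_a) == dim(image_b)))
  n <- nrow(image_a)
  if (window) {
    w <- tukey_window_2d(n, 0.25)
    image_a <- (image_a - mean(image_a)) * w
    image_b <- (image_b - mean(image_b)) * w
  }
  p_um <- pixel_nm * 1e-3
  fa <- fft2(image_a); fb <- fft2(image_b)
  g <- freq_grids(n, p_um)
  dk <- 1 / (n * p_um)
  ring <- as.integer(round(g$kr / dk))
  nbins <- n %/% 2
  sel <- ring <= nbins
  idx <- ring[sel] + 1L
  num <- vapply(split(Re(fa[sel] * Conj(fb[sel])), idx), sum, numeric(1))
  d1 <- vapply(split(abs(fa[sel])^2, idx), sum, numeric(1))
  d2 <- vapply(split(abs(fb[sel])^2, idx), sum, numeric(1))
  frc <- num / sqrt(d1 * d2)
  freq <- (as.integer(names(d1)) - 1L) * dk
  res <- NA_real_
  status <- "beyond_nyquist"
  for (i in 2:length(frc)) {
    if (!is.na(frc[i]) && !is.na(frc[i - 1]) &&
        frc[i - 1] >= threshold && frc[i] < threshold) {
      f_cross <- freq[i - 1] + (frc[i - 1] - threshold) /
        (frc[i - 1] - frc[i]) * (freq[i] - freq[i - 1])
      res <- unname(1000 / f_cross)
      status <- "ok"
      break
    }
  }
  structure(list(freq_cyc_um = freq, frc = unname(frc), resolution_nm = res,
                 threshold = threshold, status = status),
            class = "frc_curve")
}

#' @export
print.frc_curve <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("frc_curve: resolution %.1f nm at threshold %.3f\n",
                x$resolution_nm, x$threshold))
  else cat("frc_curve: no threshold crossing (resolution beyond Nyquist)\n")
  invisible(x)
}

#' Stripe-artifact energy of a reconstruction
#'
#' Measures spectral power concentrated at the pattern frequencies `+-k` and
#' their second harmonics `+-2k`.  Incorrect phase assumptions during band
#' separation mix the frequency bands, which imprints the illumination
#' pattern onto the output — striping at `+-k` and honeycombing at `+-2k`.
#' With `reference = "local"` (default) the statistic is the mean
#' peak-to-background ratio: power inside a small disk at each mask centre
#' divided by the power in the surrounding equal-radius annulus, so a value
#' near 1 means no artifact regardless of the sample's spectral envelope.
#' `reference = "total"` instead reports the fraction of total non-DC power
#' inside Gaussian masks at the same frequencies; this variant is dominated
#' by the sample's own spectrum and is kept for completeness.  Both are
#' invariant to global intensity scaling.
#'
#' @param image Real matrix (the reconstruction, fine grid).
#' @param k_list List or 3x2 matrix of pattern wavevectors (cycles/um).
#' @param pixel_nm Pixel size of `image` in nm.
#' @param sigma_px Mask radius/width in frequency pixels.
#' @param harmonics Include the `+-2k` masks.
#' @param reference `"local"` or `"total"` (see above).
#' @return Dimensionless statistic (ratio for `"local"`, fraction for
#'   `"total"`).
#' @export
stripe_energy <- function(image, k_list, pixel_nm, sigma_px = 2,
                          harmonics = TRUE,
                          reference = c("local", "total")) {
  reference <- match.arg(reference)
  n <- nrow(image)
  p_um <- pixel_nm * 1e-3
  if (is.matrix(k_list)) k_list <- lapply(seq_len(nrow(k_list)), function(i) k_list[i, ])
  nyq <- 1 / (2 * p_um) * sqrt(2)
  for (k in k_list)
    if (sqrt(sum(k^2)) * (if (harmonics) 2 else 1) > nyq)
      stop("pattern frequency outside the spectral grid")
  g <- freq_grids(n, p_um)
  P <- abs(fft2(image - mean(image)))^2
  dk <- 1 / (n * p_um)
  mults <- if (harmonics) c(1, -1, 2, -2) else c(1, -1)
  if (reference == "total") {
    sig <- sigma_px * dk
    mask <- matrix(0, n, n)
    for (k in k_list) for (s in mults) {
      d2 <- (g$kx - s * k[1])^2 + (g$ky - s * k[2])^2
      mask <- pmax(mask, exp(-d2 / (2 * sig^2)))
    }
    total <- sum(P) - P[1, 1]
    if (total <= 0) return(0)
    return(sum(P * mask) / total)
  }
  vals <- c()
  for (k in k_list) for (s in mults) {
    kk <- s * k
    d <- sqrt((g$kx - kk[1])^2 + (g$ky - kk[2])^2)
    peak <- mean(P[d < sigma_px * dk])
    ann <- abs(g$kr - sqrt(sum(kk^2))) < 4 * sigma_px * dk & d >= 2 * sigma_px * dk
    bg <- mean(P[ann])
    vals <- c(vals, if (bg > 0) peak / bg else 0)
  }
  mean(vals)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` with `peak` the maximum of the reference.
#' Identical images give `Inf`.
#'
#' @param recon,truth Equal-size matrices.
#' @export
psnr <- function(recon, truth) {
  stopifnot(all(dim(recon) == dim(truth)))
  mse <- mean((recon - truth)^2)
  if (mse == 0) return(Inf)
  10 * log10(max(truth)^2 / mse)
}

#' Affine intensity match of an image to a reference
#'
#' Least-squares `a * image + b` fit to the reference; used to compare
#' reconstructions in arbitrary intensity units against ground truth.
#' @param image,ref Equal-size matrices.
#' @export
match_scale <- function(image, ref) {
  x <- as.vector(image); y <- as.vector(ref)
  vx <- stats::var(x)
  a <- if (vx > 0) stats::cov(x, y) / vx else 0
  b <- mean(y) - a * mean(x)
  matrix(a * x + b, nrow(ref), ncol(ref))
}
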