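# Stack and reconstruction IO: multi-page TIFF with a JSON sidecar.
# Raw stacks are written as 16-bit unsigned integers through the `tiff`
# package; reconstructions as IEEE float32 pages through a minimal writer
# below (readable by `tiff::readTIFF` and standard TIFF tools), because
# `tiff::writeTIFF`'s 32-bit mode stores scaled integers, not floats.

#' Write a raw SIM stack as multi-page TIFF (+ JSON sidecar)
#'
#' Pages are angle-major phase-minor, 16-bit unsigned, values rounded;
#' multichannel stacks are written as one file per channel suffixed `_chN`.
#' A sidecar `<path>.json` records the configuration, protocol, seed and
#' channel count, so the acquisition is reproducible from the file pair.
#'
#' @param stack A `sim_stack`.
#' @param path Output path (`.tif`).
#' @return Invisibly, the vector of files written.
#' @export
write_stack <- function(stack, path) {
  nch <- length(stack$frames)
  paths <- if (nch == 1) path else
    vapply(seq_len(nch), function(i) sub("(\\.tiff?)?$", sprintf("_ch%d\\1", i), path),
           character(1))
  for (ci in seq_len(nch)) {
    fr <- stack$frames[[ci]]
    pages <- lapply(seq_len(dim(fr)[3]), function(j) {
      v <- round(fr[, , j])
      if (any(v > 65535)) warning("values above 65535 clipped in 16-bit output")
      pmin(pmax(v, 0), 65535) / 65535
    })
    tiff::writeTIFF(pages, paths[ci], bits.per.sample = 16L, compression = "none")
  }
  sidecar <- list(
    format = "simscope-stack-v1",
    n_channels = nch,
    frame_order = "angle-major, phase-minor",
    seed = stack$seed,
    config = unclass(stack$config),
    mode = stack$protocol$mode,
    geometry = unclass(stack$protocol$geometry),
    phases = lapply(stack$protocol$channels,
                    function(ch) vapply(ch, `[[`, numeric(1), "phase")),
    noise = if (!is.null(stack$noise)) unclass(stack$noise))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Read a raw SIM stack written by [write_stack()]
#'
#' @param path Path of the (first-channel) TIFF.
#' @param sidecar Optional explicit sidecar path; default `<path>.json`.
#' @return A `sim_stack`.  A missing or corrupt sidecar degrades to a
#'   single-channel stack with a warning; a page count not divisible by 9 is
#'   an error.
#' @export
read_stack <- function(path, sidecar = paste0(path, ".json")) {
  meta <- NULL
  if (file.exists(sidecar)) {
    meta <- tryCatch(jsonlite::read_json(sidecar, simplifyVector = TRUE),
                     error = function(e) {
                       warning("corrupt sidecar ignored: ", conditionMessage(e))
                       NULL
                     })
  } else warning("no sidecar found; assuming a single channel")
  read_pages <- function(p) {
    pages <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    if (length(pages) %% 9 != 0)
      stop(sprintf("page count %d is not divisible by 9", length(pages)))
    pages
  }
  nch_declared <- if (!is.null(meta)) meta$n_channels else 1L
  frames <- list()
  if (nch_declared > 1 && !file.exists(path)) {
    # multichannel layout: one file per channel
    for (ci in seq_len(nch_declared)) {
      p <- sub("(\\.tiff?)?$", sprintf("_ch%d\\1", ci), path)
      pages <- read_pages(p)
      frames[[ci]] <- simplify2array(pages)
    }
  } else {
    pages <- read_pages(path)
    nch <- length(pages) %/% 9L
    if (!is.null(meta) && !is.na(meta$n_channels) && meta$n_channels != nch &&
        meta$n_channels * 9 == length(pages)) nch <- meta$n_channels
    for (ci in seq_len(nch))
      frames[[ci]] <- simplify2array(pages[(ci - 1) * 9 + 1:9])
  }
  config <- if (!is.null(meta$config)) {
    ch <- meta$config$channels
    chl <- if (is.data.frame(ch)) lapply(seq_len(nrow(ch)), function(i) as.list(ch[i, ]))
           else ch
    optical_config(meta$config$na, meta$config$n_immersion, chl,
                   meta$config$pixel_nm, meta$config$image_px, meta$config$sa_waves)
  } else NULL
  structure(list(frames = lapply(frames, function(f) f * 1.0),
                 config = config, protocol = NULL,
                 sidecar = meta, seed = if (!is.null(meta)) meta$seed else NA),
            class = "sim_stack")
}

# --- minimal float32 multi-page TIFF writer ----------------------------

#' Write real matrices as an IEEE float32 multi-page TIFF
#'
#' Uncompressed, little-endian, one strip per page; readable by
#' `tiff::readTIFF` and standard TIFF libraries.
#'
#' @param pages A matrix or list of equal-size matrices.
#' @param path Output path.
#' @export
write_float_tiff <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); wr2(42L)
  n_tags <- 10L
  ifd_size <- 2 + n_tags * 12 + 4
  data_size <- 4 * h * w
  # layout: header(8) | per page: pixel data then IFD
  offset_first_ifd <- 8 + data_size
  wr4(offset_first_ifd)
  tag <- function(id, type, count, value) { wr2(id); wr2(type); wr4(count); wr4(value) }
  for (p in seq_along(pages)) {
    m <- pages[[p]]
    stopifnot(nrow(m) == h, ncol(m) == w)
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")  # row-major
    # IFD
    tag_list <- function(next_ifd, data_offset) {
      wr2(n_tags)
      tag(256L, 3L, 1L, w)            # ImageWidth
      tag(257L, 3L, 1L, h)            # ImageLength
      tag(258L, 3L, 1L, 32L)          # BitsPerSample
      tag(259L, 3L, 1L, 1L)           # Compression: none
      tag(262L, 3L, 1L, 1L)           # Photometric: BlackIsZero
      tag(273L, 4L, 1L, data_offset)  # StripOffsets
      tag(277L, 3L, 1L, 1L)           # SamplesPerPixel
      tag(278L, 3L, 1L, h)            # RowsPerStrip
      tag(279L, 4L, 1L, data_size)    # StripByteCounts
      tag(339L, 3L, 1L, 3L)           # SampleFormat: IEEE float
      wr4(next_ifd)
    }
    data_offset <- 8 + (p - 1) * (data_size + ifd_size)
    next_ifd <- if (p < length(pages))
      8 + p * (data_size + ifd_size) + data_size else 0L
    tag_list(next_ifd, data_offset)
  }
  invisible(path)
}

#' Write / read a reconstruction as float32 TIFF
#' @param recon A `sim_recon` (or plain matrix).
#' @param path Path.
#' @export
write_recon <- function(recon, path) {
  img <- if (inherits(recon, "sim_recon")) recon$image else recon
  write_float_tiff(img, path)
  if (inherits(recon, "sim_recon"))
    jsonlite::write_json(list(format = "simscope-recon-v1",
                              pixel_nm = recon$pixel_nm,
                              params = recon$params),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  invisible(path)
}

#' @rdname write_recon
#' @export
read_recon <- function(path) {
  img <- tiff::readTIFF(path)
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE) else NULL
  structure(list(image = img, support = NULL,
                 pixel_nm = if (!is.null(meta)) meta$pixel_nm else NA,
                 params = if (!is.null(meta)) meta$params else NULL),
            class = "sim_recon")
}

# --- run configuration --------------------------------------------------

run_config_keys <- c("na", "n_immersion", "channels", "pixel_nm", "image_px",
                     "sa_waves", "pattern_fraction", "orientations_deg",
                     "reference_ex_nm", "modulation_depth", "mode", "noise",
                     "recon", "seed")
noise_keys <- c("peak_signal", "read_noise_sd", "background", "gain")

#' Read and validate a run configuration (YAML or JSON)
#'
#' The schema mirrors [optical_config()], [interferometer_geometry()],
#' [noise_model()] and [recon_options()]; unknown keys are rejected.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return List with `config`, `geometry`, `noise`, `options`, `mode`, `seed`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), run_config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$noise)) {
    un <- setdiff(names(raw$noise), noise_keys)
    if (length(un)) stop("unknown noise key(s): ", paste(un, collapse = ", "))
  }
  ch <- raw$channels
  chl <- if (is.data.frame(ch)) lapply(seq_len(nrow(ch)), function(i) as.list(ch[i, ]))
         else if (is.list(ch)) ch else list(list(ex_nm = 488, em_nm = 515))
  cfg <- optical_config(na = raw$na %||% 1.2,
                        n_immersion = raw$n_immersion %||% 1.33,
                        channels = chl,
                        pixel_nm = raw$pixel_nm %||% 60,
                        image_px = raw$image_px %||% 256,
                        sa_waves = raw$sa_waves %||% 0)
  geom <- interferometer_geometry(
    pattern_fraction = raw$pattern_fraction %||% 0.95,
    orientations_deg = raw$orientations_deg %||% c(0, 120, 240),
    reference_ex_nm = raw$reference_ex_nm,
    modulation_depth = raw$modulation_depth %||% 0.8)
  nz <- raw$noise %||% list()
  noise <- noise_model(peak_signal = nz$peak_signal %||% 200,
                       read_noise_sd = nz$read_noise_sd %||% 1,
                       background = nz$background %||% 2,
                       gain = nz$gain %||% 1)
  ro <- raw$recon %||% list()
  opts <- do.call(recon_options, ro)
  list(config = cfg, geometry = geom, noise = noise, options = opts,
       mode = raw$mode %||% "sequential", seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
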