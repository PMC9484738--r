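# Convolution-model ultrasound RF simulation: random scatterer field,
# separable Gaussian-cosine point spread function, bilinear deposition and
# additive Gaussian noise at a prescribed SNR.

#' Linear-array transducer specification
#'
#' @param fc Center frequency, Hz.
#' @param fbw Fractional bandwidth at -6 dB of the amplitude spectrum.
#' @param fs RF sampling frequency, Hz (must exceed `2 fc (1 + fbw)`).
#' @param beamwidth_mm Lateral -6 dB beamwidth at the focus, mm.
#' @param aperture_mm Array aperture, mm.
#' @param n_lines Number of A-lines across the aperture.
#' @param line_pitch_mm Line spacing, mm (default `aperture_mm / n_lines`).
#' @param c_m_s Speed of sound used for sample/depth conversion, m/s.
#' @return A `transducer_spec` object.
#' @export
transducer_spec <- function(fc = 6.6e6, fbw = 0.5, fs = 40e6, beamwidth_mm = 1,
                            aperture_mm = 38, n_lines = 128,
                            line_pitch_mm = aperture_mm / n_lines,
                            c_m_s = 1540) {
  if (fs <= 2 * fc * (1 + fbw))
    stop("sampling frequency must exceed 2 fc (1 + fbw)")
  if (beamwidth_mm <= 0) stop("beamwidth must be positive")
  structure(list(fc = fc, fbw = fbw, fs = fs, beamwidth_mm = beamwidth_mm,
                 aperture_mm = aperture_mm, n_lines = n_lines,
                 line_pitch_mm = line_pitch_mm, c_m_s = c_m_s),
            class = "transducer_spec")
}

#' @export
print.transducer_spec <- function(x, ...) {
  cat(sprintf("Linear array: fc = %.3g MHz, %g%% bandwidth (-6 dB), fs = %.3g MHz\n",
              x$fc / 1e6, 100 * x$fbw, x$fs / 1e6))
  cat(sprintf("  %d lines / %g mm aperture (pitch %.3g mm), beamwidth %.3g mm\n",
              x$n_lines, x$aperture_mm, x$line_pitch_mm, x$beamwidth_mm))
  invisible(x)
}

# axial sample spacing in mm (two-way travel)
axial_sample_mm <- function(spec) spec$c_m_s / 2 / spec$fs * 1000

#' Point spread function of the transducer
#'
#' Separable kernel: axially a cosine at `fc` under a Gaussian envelope
#' whose amplitude spectrum has -6 dB full width `fbw * fc`; laterally a
#' Gaussian with -6 dB full width equal to the beamwidth. Truncated at
#' +/- 3 sigma and peak-normalised.
#'
#' @param spec A [transducer_spec()].
#' @return Matrix (axial samples x lateral lines) with attributes `axial`
#'   and `lateral` holding the two 1-D profiles.
#' @export
make_psf <- function(spec) {
  stopifnot(inherits(spec, "transducer_spec"))
  sigma_t <- sqrt(2 * log(2)) / (pi * spec$fbw * spec$fc)
  dt <- 1 / spec$fs
  nt <- ceiling(3 * sigma_t / dt)
  tt <- (-nt:nt) * dt
  axial <- cos(2 * pi * spec$fc * tt) * exp(-tt^2 / (2 * sigma_t^2))
  sigma_x <- spec$beamwidth_mm / (2 * sqrt(2 * log(2)))
  nx <- ceiling(3 * sigma_x / spec$line_pitch_mm)
  xx <- (-nx:nx) * spec$line_pitch_mm
  lateral <- exp(-xx^2 / (2 * sigma_x^2))
  k <- outer(axial, lateral)
  k <- k / max(abs(k))
  attr(k, "axial") <- axial / max(abs(axial))
  attr(k, "lateral") <- lateral / max(abs(lateral))
  k
}

#' Random scatterer field
#'
#' Uniformly distributed scatterer positions with standard-normal
#' amplitudes over a rectangular extent, at a density given per resolution
#' cell (beamwidth times pulse spatial length).
#'
#' @param extent_mm `c(lateral, axial)` extent, mm.
#' @param density_per_cell Mean scatterers per resolution cell (>= 1).
#' @param seed Integer seed for reproducibility.
#' @param spec [transducer_spec()] defining the resolution cell.
#' @return A `scatterer_field`: data.frame `lat_mm`, `ax_mm`, `amp` with
#'   the extent stored as an attribute.
#' @export
make_scatterer_field <- function(extent_mm, density_per_cell = 10, seed = 1,
                                 spec = transducer_spec()) {
  if (any(extent_mm <= 0)) stop("extent must have positive area")
  if (density_per_cell < 1) stop("density_per_cell must be >= 1")
  set.seed(as.integer(seed))
  sigma_t <- sqrt(2 * log(2)) / (pi * spec$fbw * spec$fc)
  pulse_mm <- 2.355 * sigma_t * spec$c_m_s / 2 * 1000  # FWHM, one-way depth
  cell_mm2 <- spec$beamwidth_mm * pulse_mm
  n <- round(density_per_cell * prod(extent_mm) / cell_mm2)
  out <- data.frame(lat_mm = stats::runif(n, 0, extent_mm[1]),
                    ax_mm = stats::runif(n, 0, extent_mm[2]),
                    amp = stats::rnorm(n))
  structure(out, extent_mm = extent_mm, class = c("scatterer_field", "data.frame"))
}

# Bilinear interpolation of a gridded map at arbitrary points. Grid node i
# sits at (i - 0.5) * spacing; points outside are clamped to the edge.
bilinear_at <- function(map, spacing, ax_mm, lat_mm) {
  nr <- nrow(map); nc <- ncol(map)
  ri <- ax_mm / spacing[1] + 0.5
  ci <- lat_mm / spacing[2] + 0.5
  clamped <- ri < 1 | ri > nr | ci < 1 | ci > nc
  ri <- pmin(pmax(ri, 1), nr)
  ci <- pmin(pmax(ci, 1), nc)
  r0 <- pmin(floor(ri), nr - 1); c0 <- pmin(floor(ci), nc - 1)
  fr <- ri - r0; fc <- ci - c0
  v <- map[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    map[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    map[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    map[cbind(r0 + 1, c0 + 1)] * fr * fc
  attr(v, "n_clamped") <- sum(clamped)
  v
}

#' Displace scatterers by interpolated displacement maps
#'
#' Each scatterer is moved by the bilinearly interpolated displacement at
#' its position; amplitudes are preserved. Scatterers outside the map
#' domain use the nearest edge value (their count is reported via the
#' `"n_clamped"` attribute).
#'
#' @param field A `scatterer_field`.
#' @param disp_axial_mm,disp_lateral_mm Displacement maps (rows = axial,
#'   columns = lateral), mm, covering the field extent.
#' @param spacing_mm Map pixel size `c(axial, lateral)`, mm.
#' @return The displaced `scatterer_field`.
#' @export
displace_scatterers <- function(field, disp_axial_mm, disp_lateral_mm,
                                spacing_mm) {
  stopifnot(inherits(field, "scatterer_field"))
  ua <- bilinear_at(disp_axial_mm, spacing_mm, field$ax_mm, field$lat_mm)
  ul <- bilinear_at(disp_lateral_mm, spacing_mm, field$ax_mm, field$lat_mm)
  out <- field
  out$ax_mm <- field$ax_mm + as.numeric(ua)
  out$lat_mm <- field$lat_mm + as.numeric(ul)
  attr(out, "extent_mm") <- attr(field, "extent_mm")
  attr(out, "n_clamped") <- attr(ua, "n_clamped") + attr(ul, "n_clamped")
  out
}

# separable 2-D convolution by shift-and-add (kernels are short)
conv_separable <- function(img, kax, klat) {
  nr <- nrow(img); nc <- ncol(img)
  ha <- (length(kax) - 1) / 2
  out <- matrix(0, nr, nc)
  for (i in seq_along(kax)) {
    sh <- i - 1 - ha
    src <- seq_len(nr) - sh
    ok <- src >= 1 & src <= nr
    out[ok, ] <- out[ok, ] + kax[i] * img[src[ok], ]
  }
  img <- out
  hl <- (length(klat) - 1) / 2
  out <- matrix(0, nr, nc)
  for (j in seq_along(klat)) {
    sh <- j - 1 - hl
    src <- seq_len(nc) - sh
    ok <- src >= 1 & src <= nc
    out[, ok] <- out[, ok] + klat[j] * img[, src[ok]]
  }
  out
}

#' Synthesize one RF frame from a scatterer field
#'
#' Each scatterer contributes the separable point spread function (axial
#' Gaussian-cosine, lateral Gaussian, truncated at +/- 3 sigma) evaluated
#' at its exact continuous position — equivalent to convolving the
#' continuous object field with the PSF and sampling, without gridding
#' error. Gaussian noise is then added at the requested SNR (relative to
#' the clean-frame rms).
#'
#' @param field A `scatterer_field`.
#' @param spec A [transducer_spec()].
#' @param snr_db Signal-to-noise ratio, dB (`Inf` for noise-free).
#' @param seed Integer seed for the noise.
#' @param depth_mm Imaged depth; defaults to the axial extent of the field.
#' @param noise_floor_rms Noise rms used when the field is empty (no signal
#'   to reference the SNR to).
#' @return Matrix of RF samples (samples x lines) with attributes
#'   `sample_mm`, `line_pitch_mm`.
#' @export
synthesize_rf <- function(field, spec, snr_db = Inf, seed = 1,
                          depth_mm = NULL, noise_floor_rms = 1) {
  stopifnot(inherits(field, "scatterer_field"), inherits(spec, "transducer_spec"))
  extent <- attr(field, "extent_mm")
  if (is.null(depth_mm)) depth_mm <- extent[2]
  dz <- axial_sample_mm(spec)
  ns <- floor(depth_mm / dz)
  nl <- min(spec$n_lines, floor(extent[1] / spec$line_pitch_mm))
  sigma_t <- sqrt(2 * log(2)) / (pi * spec$fbw * spec$fc)
  sigma_ax_mm <- sigma_t * spec$c_m_s / 2 * 1000
  k_rad_per_mm <- 4 * pi * spec$fc / (spec$c_m_s * 1000)   # two-way travel
  sigma_lat_mm <- spec$beamwidth_mm / (2 * sqrt(2 * log(2)))
  rf <- render_rf_cpp(field$ax_mm, field$lat_mm, field$amp, ns, nl,
                      dz, spec$line_pitch_mm, sigma_ax_mm, k_rad_per_mm,
                      sigma_lat_mm)
  if (is.finite(snr_db)) {
    set.seed(as.integer(seed))
    sig_rms <- sqrt(mean(rf^2))
    sd_n <- if (sig_rms > 0) sig_rms * 10^(-snr_db / 20) else noise_floor_rms
    rf <- rf + matrix(stats::rnorm(length(rf), sd = sd_n), ns, nl)
  }
  attr(rf, "sample_mm") <- dz
  attr(rf, "line_pitch_mm") <- spec$line_pitch_mm
  rf
}

# Displacement movies (axial, lateral, mm) on the strain grid, derived from
# a strain series by spatial integration: axial displacement is toward the
# transducer (negative deeper coordinate) below the contacting surface,
# lateral displacement expands outward from the centerline.
displacement_from_strains <- function(series) {
  d <- dim(series$axial)
  sp <- series$pixel_spacing_mm
  nt <- d[3]
  ua <- array(0, dim = d); ul <- array(0, dim = d)
  for (k in seq_len(nt)) {
    ez <- series$axial[, , k]          # compression-positive
    ex <- series$lateral[, , k]        # expansion-positive
    # midpoint rule: displacement at a pixel center integrates half its own strain
    ua[, , k] <- -(apply(ez, 2, cumsum) - ez / 2) * sp[1]
    half <- ncol(ex) / 2
    cums <- (t(apply(ex, 1, cumsum)) - ex / 2) * sp[2]
    center <- (cums[, max(1, floor(half))] + cums[, ceiling(half)]) / 2
    ul[, , k] <- cums - center
  }
  list(axial = ua, lateral = ul)
}

#' Simulate an RF frame series for a creep phantom
#'
#' Builds displacement movies from the phantom strain series, generates one
#' scatterer field, and synthesizes a reference (uncompressed) frame plus
#' one frame per strain sample with independent noise realisations.
#'
#' @param series A `strain_series` from [generate_strain_series()].
#' @param spec A [transducer_spec()].
#' @param snr_db Per-frame RF SNR, dB.
#' @param seed Integer seed (drives the scatterer field and all noise).
#' @param density_per_cell Scatterer density per resolution cell.
#' @return An `rf_series`: list with `frames` (samples x lines x frames,
#'   frame 1 being the uncompressed reference), `times` (of frames 2..),
#'   `spec`, `snr_db`, and grid metadata.
#' @export
simulate_rf_series <- function(series, spec = transducer_spec(), snr_db = 40,
                               seed = 1, density_per_cell = 10) {
  stopifnot(inherits(series, "strain_series"))
  d <- dim(series$axial)
  extent <- c(d[2] * series$pixel_spacing_mm[2], d[1] * series$pixel_spacing_mm[1])
  field <- make_scatterer_field(extent, density_per_cell, seed = seed, spec = spec)
  disp <- displacement_from_strains(series)
  nt <- d[3]
  ref <- synthesize_rf(field, spec, snr_db, seed = seed + 1, depth_mm = extent[2])
  frames <- array(0, dim = c(dim(ref), nt + 1))
  frames[, , 1] <- ref
  for (k in seq_len(nt)) {
    fk <- displace_scatterers(field, disp$axial[, , k], disp$lateral[, , k],
                              series$pixel_spacing_mm)
    frames[, , k + 1] <- synthesize_rf(fk, spec, snr_db, seed = seed + 1 + k,
                                       depth_mm = extent[2])
  }
  structure(list(frames = frames, times = series$times, spec = spec,
                 snr_db = snr_db, sample_mm = attr(ref, "sample_mm"),
                 line_pitch_mm = attr(ref, "line_pitch_mm"),
                 source_geometry = series$geometry,
                 source_truth = series$truth,
                 sigma0_pa = series$sigma0_pa, SV_m1 = series$SV_m1),
            class = "rf_series")
}

#' @export
print.rf_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("RF frame series: %d samples x %d lines x %d frames (frame 1 = reference)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  SNR %.3g dB, sample %.4g mm, pitch %.4g mm\n",
              x$snr_db, x$sample_mm, x$line_pitch_mm))
  invisible(x)
}
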