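# Two-step displacement estimation (integer dynamic programming followed by
# Horn-Schunck subsample refinement) and smoothed least-squares strain.

shift_rows <- function(M, by) {
  nr <- nrow(M)
  src <- pmin(pmax(seq_len(nr) - by, 1), nr)
  M[src, , drop = FALSE]
}

shift_cols <- function(M, by) {
  nc <- ncol(M)
  src <- pmin(pmax(seq_len(nc) - by, 1), nc)
  M[, src, drop = FALSE]
}

#' Integer displacement by regularized dynamic programming
#'
#' Per A-line dynamic programming over integer (axial, lateral) sample
#' offsets, minimizing a mean-absolute-difference data term over a small
#' window plus an L1 continuity penalty between neighboring samples along
#' the line; displacement continuity across lines is propagated
#' sequentially through a penalty against the previous line's solution.
#'
#' @param pre_frame,post_frame RF frames (samples x lines) sharing geometry.
#' @param search_range `c(axial, lateral)` maximum absolute integer offsets
#'   (axial must be positive, lateral non-negative).
#' @param regularization_weight Weight of the along-line continuity term.
#' @param halfwin Half-width of the data-term window, samples.
#' @param prev_weight Weight of the previous-line continuity term.
#' @return List with integer matrices `da` (samples), `dl` (lines) and
#'   `quality` (data-term residual along the chosen path). The convention
#'   is `post[x + d] = pre[x]`.
#' @export
dp_integer_displacement <- function(pre_frame, post_frame, search_range,
                                    regularization_weight = 0.4,
                                    halfwin = 5, prev_weight = 0.1) {
  stopifnot(is.matrix(pre_frame), all(dim(pre_frame) == dim(post_frame)))
  if (length(search_range) == 1) search_range <- c(search_range, 0)
  if (search_range[1] <= 0 || search_range[2] < 0)
    stop("search_range must be positive (axial) and non-negative (lateral)")
  scale <- stats::sd(pre_frame)
  if (scale == 0) scale <- 1
  res <- dp_pair_cpp(pre_frame / scale, post_frame / scale,
                     as.integer(search_range[1]), as.integer(search_range[2]),
                     regularization_weight, as.integer(halfwin), prev_weight)
  structure(res, class = "displacement_field")
}

#' Horn-Schunck subsample displacement refinement
#'
#' Classical brightness-constancy plus smoothness optical flow between a
#' reference frame and the motion-compensated (integer-warped) moving
#' frame. Returns the residual sub-sample displacements, clamped to one
#' sample/line in magnitude.
#'
#' @param pre_frame Reference frame.
#' @param motion_compensated_post Moving frame already warped by the
#'   integer displacement field.
#' @param smoothness_lambda Smoothness weight (the classical alpha^2).
#' @param n_iter Maximum Jacobi iterations.
#' @param tol Mean-absolute-update stopping threshold.
#' @return List with matrices `axial`, `lateral` (residual displacement in
#'   samples/lines) and the logical `converged` (FALSE carries a warning
#'   flag, not an error).
#' @export
hs_refine <- function(pre_frame, motion_compensated_post,
                      smoothness_lambda = 0.25, n_iter = 100, tol = 1e-6) {
  stopifnot(all(dim(pre_frame) == dim(motion_compensated_post)))
  sc <- stats::sd(pre_frame)
  if (sc == 0) sc <- 1
  I1 <- pre_frame / sc
  I2 <- motion_compensated_post / sc
  gz <- function(M) (shift_rows(M, -1) - shift_rows(M, 1)) / 2
  gx <- function(M) (shift_cols(M, -1) - shift_cols(M, 1)) / 2
  Ez <- (gz(I1) + gz(I2)) / 2
  Ex <- (gx(I1) + gx(I2)) / 2
  Et <- I2 - I1
  D <- smoothness_lambda + Ez^2 + Ex^2
  u <- matrix(0, nrow(I1), ncol(I1))
  v <- u
  nbr <- function(M)
    (shift_rows(M, 1) + shift_rows(M, -1) + shift_cols(M, 1) + shift_cols(M, -1)) / 6 +
    (shift_rows(shift_cols(M, 1), 1) + shift_rows(shift_cols(M, 1), -1) +
       shift_rows(shift_cols(M, -1), 1) + shift_rows(shift_cols(M, -1), -1)) / 12
  converged <- FALSE
  for (it in seq_len(n_iter)) {
    ub <- nbr(u)
    vb <- nbr(v)
    P <- (Ez * ub + Ex * vb + Et) / D
    un <- ub - Ez * P
    vn <- vb - Ex * P
    delta <- mean(abs(un - u)) + mean(abs(vn - v))
    u <- un
    v <- vn
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(axial = pmin(pmax(u, -1), 1), lateral = pmin(pmax(v, -1), 1),
       converged = converged)
}

# Warp the moving frame by the integer displacement field:
# out[x] = post[x + d(x)], indices clamped at the frame edges.
warp_integer <- function(post_frame, da, dl) {
  nr <- nrow(post_frame)
  nc <- ncol(post_frame)
  ri <- pmin(pmax(row(post_frame) + da, 1), nr)
  ci <- pmin(pmax(col(post_frame) + dl, 1), nc)
  matrix(post_frame[cbind(as.vector(ri), as.vector(ci))], nr, nc)
}

#' Combine integer and subsample displacements into millimetres
#'
#' Element-wise sum of the integer and residual sub-sample fields,
#' converted to mm: axial samples via `c / (2 fs)`, lateral lines via the
#' line pitch.
#'
#' @param integer_field Output of [dp_integer_displacement()].
#' @param subsample_field Output of [hs_refine()].
#' @param spec A [transducer_spec()].
#' @return List of matrices `axial_mm`, `lateral_mm`.
#' @export
total_displacement <- function(integer_field, subsample_field, spec) {
  if (!all(dim(integer_field$da) == dim(subsample_field$axial)))
    stop("integer and subsample fields must share their grid")
  list(axial_mm = (integer_field$da + subsample_field$axial) * axial_sample_mm(spec),
       lateral_mm = (integer_field$dl + subsample_field$lateral) * spec$line_pitch_mm)
}

# Moving least-squares slope of `u` vs the coordinate along dimension 1
# (rows), window of kernel_len samples spaced `spacing` apart. Edge rows are
# filled with the nearest interior estimate.
lsq_slope_rows <- function(u, kernel_len, spacing) {
  k <- (kernel_len - 1) / 2
  w <- (-k:k) / (sum((-k:k)^2) * spacing)
  nr <- nrow(u)
  out <- matrix(0, nr, ncol(u))
  for (j in seq_along(w)) out <- out + w[j] * shift_rows(u, -(j - 1 - k))
  if (nr > 2 * k) {
    out[seq_len(k), ] <- rep(out[k + 1, ], each = k)
    out[(nr - k + 1):nr, ] <- rep(out[nr - k, ], each = k)
  }
  out
}

# Scalar random-walk Kalman filter along dimension 1, vectorised over
# columns. Gains depend only on (q, r) and are precomputed.
kalman_rows <- function(z, process_noise, measurement_noise) {
  nr <- nrow(z)
  P <- 1e3 * measurement_noise
  gains <- numeric(nr)
  for (s in seq_len(nr)) {
    Pp <- P + process_noise
    gains[s] <- Pp / (Pp + measurement_noise)
    P <- (1 - gains[s]) * Pp
  }
  x <- z[1, ]
  out <- z
  out[1, ] <- x
  for (s in 2:nr) {
    x <- x + gains[s] * (z[s, ] - x)
    out[s, ] <- x
  }
  out
}

# Box average along rows with zero padding and count normalisation, so
# edges are local means rather than replicated values.
nbox_rows <- function(M, half) {
  if (half < 1) return(M)
  nr <- nrow(M)
  out <- matrix(0, nr, ncol(M))
  cnt <- matrix(0, nr, ncol(M))
  for (s in -half:half) {
    src <- seq_len(nr) + s
    ok <- src >= 1 & src <= nr
    out[ok, ] <- out[ok, ] + M[src[ok], ]
    cnt[ok, ] <- cnt[ok, ] + 1
  }
  out / cnt
}

# 3-point median across lines (columns), suppressing isolated line blunders.
median3_cols <- function(M) {
  A <- M[, pmax(seq_len(ncol(M)) - 1, 1)]
  C <- M[, pmin(seq_len(ncol(M)) + 1, ncol(M))]
  pmax(pmin(A, M), pmin(pmax(A, M), C))
}

#' Strain images from a displacement field
#'
#' Per column (axial) and per row (lateral), the strain is the slope of a
#' moving least-squares linear fit of displacement versus depth/width over
#' `kernel_len` points, smoothed by a scalar random-walk Kalman filter.
#' The filter runs along the fitting direction by default; for lateral
#' strain it can instead run along depth (`kalman_along = "axial"`), which
#' avoids the short-memory transient of filtering across the few dozen
#' image lines.
#'
#' @param disp Displacement field: list with `axial_mm` and `lateral_mm`
#'   matrices (samples x lines).
#' @param spec A [transducer_spec()] (for the grid spacings).
#' @param kernel_len `c(axial, lateral)` window lengths (odd, >= 3).
#' @param process_noise,measurement_noise Kalman noise variances.
#' @param kalman_along `"fit"` (along the fitting direction) or `"axial"`
#'   (always along depth).
#' @return List of matrices `axial`, `lateral`: signed strains
#'   (d displacement / d coordinate).
#' @export
strain_from_displacement <- function(disp, spec, kernel_len = c(49, 5),
                                     process_noise = 1e-4,
                                     measurement_noise = 1e-2,
                                     kalman_along = c("fit", "axial")) {
  kalman_along <- match.arg(kalman_along)
  if (length(kernel_len) == 1) kernel_len <- rep(kernel_len, 2)
  if (any(kernel_len %% 2 != 1) || any(kernel_len < 3))
    stop("kernel_len must be odd and >= 3")
  if (kernel_len[1] > nrow(disp$axial_mm) || kernel_len[2] > ncol(disp$axial_mm))
    stop("kernel_len exceeds the image size")
  ez <- lsq_slope_rows(disp$axial_mm, kernel_len[1], axial_sample_mm(spec))
  ez <- kalman_rows(ez, process_noise, measurement_noise)
  ex <- t(lsq_slope_rows(t(disp$lateral_mm), kernel_len[2], spec$line_pitch_mm))
  ex <- if (kalman_along == "fit")
    t(kalman_rows(t(ex), process_noise, measurement_noise))
  else kalman_rows(ex, process_noise, measurement_noise)
  list(axial = ez, lateral = ex)
}

#' Track an RF frame series into a strain-field series
#'
#' Applies the two-step scheme (integer dynamic programming, then
#' Horn-Schunck refinement of the motion-compensated pair) between
#' consecutive frames, accumulates the displacements, converts each frame's
#' accumulated displacement to axial/lateral strain images, and returns a
#' `strain_series` on an axially decimated grid. Axial strains are reported
#' compression-positive, lateral strains expansion-positive.
#'
#' @param rf An `rf_series` from [simulate_rf_series()].
#' @param search_first `c(axial, lateral)` integer search range for the
#'   first (reference to first loaded) pair; defaults to 3% of the depth.
#' @param search_later Search range for subsequent consecutive pairs, whose
#'   inter-frame motion is sub-sample.
#' @param regularization_weight,prev_weight,halfwin DP parameters.
#' @param hs_lambda,hs_iter Horn-Schunck parameters.
#' @param kernel_len,process_noise,measurement_noise Strain-estimation
#'   parameters (see [strain_from_displacement()]).
#' @param lateral_smooth_half `c(axial, lateral)` half-widths of the box
#'   average applied to the accumulated lateral displacement before its
#'   slope is taken (lateral speckle tracking is far noisier than axial;
#'   the lateral motion field is smooth at the tissue scale).
#' @param decimate_axial Keep every this-many RF samples in the output
#'   strain grid.
#' @return A `strain_series` (mask carried over from the source phantom
#'   geometry when available).
#' @export
track_rf_series <- function(rf, search_first = NULL, search_later = c(3, 1),
                            regularization_weight = 0.4, prev_weight = 0.1,
                            halfwin = 5, hs_lambda = 0.25, hs_iter = 200,
                            kernel_len = c(81, 15), process_noise = 1e-4,
                            measurement_noise = 1e-2,
                            lateral_smooth_half = c(120, 2),
                            decimate_axial = 8, anchor_every = 10,
                            bandpass = TRUE) {
  stopifnot(inherits(rf, "rf_series"))
  d <- dim(rf$frames)
  ns <- d[1]; nl <- d[2]; nf <- d[3]
  spec <- rf$spec
  if (is.null(search_first))
    search_first <- c(max(4, ceiling(0.045 * ns)), 2)
  frames_bp <- rf$frames
  if (bandpass) {
    # matched axial filtering for the subsample stage: correlate each
    # A-line with the pulse so out-of-band noise does not reach the
    # optical flow. The integer stage keeps the broadband frames, whose
    # wide envelope spectrum protects the dynamic program from
    # wavelength-hopping ambiguity.
    psf <- make_psf(spec)
    kax <- attr(psf, "axial")
    kax <- kax / sqrt(sum(kax^2))
    h <- (length(kax) - 1) / 2
    for (k in seq_len(nf)) {
      M <- rf$frames[, , k]
      out <- matrix(0, ns, nl)
      for (j in seq_along(kax)) {
        src <- seq_len(ns) - (j - 1 - h)
        ok <- src >= 1 & src <= ns
        out[ok, ] <- out[ok, ] + kax[j] * M[src[ok], ]
      }
      frames_bp[, , k] <- out
    }
  }
  # first-order corrections of the central-difference gradient attenuation,
  # which otherwise inflates the optical flow: axially evaluated at the RF
  # carrier, laterally as the gradient-energy-weighted average over the
  # speckle's lateral (beam) spectrum
  wfc <- 2 * pi * spec$fc / spec$fs
  sinc_fc <- sin(wfc) / wfc
  sig_x <- spec$beamwidth_mm / (2 * sqrt(2 * log(2)))
  pitch <- spec$line_pitch_mm
  wgt <- function(w) exp(-sig_x^2 * w^2) * w^2
  sinc_lat <- stats::integrate(function(w) wgt(w) * sin(w * pitch) / (w * pitch),
                               0, 30 / sig_x)$value /
    stats::integrate(wgt, 0, 30 / sig_x)$value
  track_pair <- function(i_pre, i_post, sr) {
    dpf <- dp_integer_displacement(rf$frames[, , i_pre], rf$frames[, , i_post],
                                   sr, regularization_weight,
                                   halfwin = halfwin, prev_weight = prev_weight)
    da <- median3_cols(dpf$da)
    dl <- median3_cols(dpf$dl)
    postw <- warp_integer(frames_bp[, , i_post], da, dl)
    hs <- hs_refine(frames_bp[, , i_pre], postw, hs_lambda, hs_iter, tol = 1e-7)
    list(ax = (da + hs$axial * sinc_fc) * axial_sample_mm(spec),
         lat = (dl + hs$lateral * sinc_lat) * spec$line_pitch_mm)
  }
  ua <- matrix(0, ns, nl)
  ul <- matrix(0, ns, nl)
  anchor_idx <- 1L
  anchor_ul <- ul
  rows <- seq(ceiling(decimate_axial / 2), ns, by = decimate_axial)
  ax_out <- array(0, dim = c(length(rows), nl, nf - 1))
  lat_out <- array(0, dim = c(length(rows), nl, nf - 1))
  for (k in 2:nf) {
    sr <- if (k == 2) search_first else search_later
    d1 <- track_pair(k - 1, k, sr)
    ua <- ua + d1$ax
    ul <- ul + d1$lat
    # periodic re-anchoring of the lateral accumulation: measure the
    # displacement from the last anchor frame directly, so lateral
    # accumulation noise does not random-walk over the whole record. The
    # axial path stays consecutive (its per-pair noise is far smaller and
    # re-anchoring would inject keyframe decorrelation into the
    # time-constant fits).
    if (anchor_every > 0 &&
        (k - anchor_idx >= anchor_every || k == nf) && k > 2) {
      sr_anchor <- c(max(4, ceiling(search_later[1] * 2)), search_later[2])
      dd <- track_pair(anchor_idx, k, sr_anchor)
      ul <- anchor_ul + dd$lat
      anchor_idx <- k
      anchor_ul <- ul
    } else if (k == 2) {
      anchor_idx <- 2L
      anchor_ul <- ul
    }
    ul_s <- nbox_rows(ul, lateral_smooth_half[1])
    if (lateral_smooth_half[2] >= 1)
      ul_s <- t(nbox_rows(t(ul_s), lateral_smooth_half[2]))
    st <- strain_from_displacement(list(axial_mm = ua, lateral_mm = ul_s), spec,
                                   kernel_len, process_noise, measurement_noise,
                                   kalman_along = "axial")
    ax_out[, , k - 1] <- -st$axial[rows, ]   # compression-positive
    lat_out[, , k - 1] <- st$lateral[rows, ] # expansion-positive
  }
  spacing <- c(axial_sample_mm(spec) * decimate_axial, spec$line_pitch_mm)
  # region unaffected by kernel edge fill, displacement clamping and
  # scatterer washout at the deep edge
  lat_margin <- (kernel_len[2] - 1) / 2 + lateral_smooth_half[2] + 3
  top_margin <- ceiling(((kernel_len[1] - 1) / 2 + 12) / decimate_axial) + 1
  bot_margin <- top_margin +
    ceiling((search_first[1] + (kernel_len[1] - 1) / 2) / decimate_axial)
  geom <- rf$source_geometry
  mask <- if (!is.null(geom)) {
    ax_mm <- (seq_along(rows) - 0.5) * spacing[1]
    lat_mm <- (seq_len(nl) - 0.5) * spacing[2]
    outer(ax_mm, lat_mm, function(z, x)
      ((x - geom$center_mm[1]) / geom$semi_axis_lateral_mm)^2 +
        ((z - geom$center_mm[2]) / geom$semi_axis_axial_mm)^2 <= 1)
  } else matrix(TRUE, length(rows), nl)
  out <- new_strain_series(rf$times, ax_out, lat_out, mask, spacing,
                           sigma0_pa = rf$sigma0_pa, SV_m1 = rf$SV_m1,
                           geometry = geom, truth = rf$source_truth)
  out$valid_margin <- list(top = top_margin, bottom = bot_margin,
                           left = lat_margin, right = lat_margin)
  if (!is.null(geom)) {
    # partial-volume (mixing) weights of the inclusion under the strain
    # estimator: push the mask indicator, as a unit strain field, through
    # the same linear smoothing/slope chain. A measured region curve is
    # then mix * inclusion + (1 - mix) * background, which the scalar
    # estimators invert.
    ax_full <- (seq_len(ns) - 0.5) * axial_sample_mm(spec)
    lat_full <- (seq_len(nl) - 0.5) * spec$line_pitch_mm
    ind <- outer(ax_full, lat_full, function(z, x)
      ((x - geom$center_mm[1]) / geom$semi_axis_lateral_mm)^2 +
        ((z - geom$center_mm[2]) / geom$semi_axis_axial_mm)^2 <= 1) * 1
    ua_ind <- -(apply(ind, 2, cumsum) - ind / 2) * axial_sample_mm(spec)
    ul_ind <- (t(apply(ind, 1, cumsum)) - ind / 2) * spec$line_pitch_mm
    ul_ind <- nbox_rows(ul_ind, lateral_smooth_half[1])
    if (lateral_smooth_half[2] >= 1)
      ul_ind <- t(nbox_rows(t(ul_ind), lateral_smooth_half[2]))
    stm <- strain_from_displacement(list(axial_mm = ua_ind, lateral_mm = ul_ind),
                                    spec, kernel_len, process_noise,
                                    measurement_noise, kalman_along = "axial")
    out$mix <- list(axial = -stm$axial[rows, ], lateral = stm$lateral[rows, ])
  }
  out
}
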