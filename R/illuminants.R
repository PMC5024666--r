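# Synthesis of the D67 target metamer and the directional comparison-illuminant
# series from a simulated multichannel LED basis. Every emitted spectrum is a
# nonnegative combination of the channel spectra; metamer fitting is a
# smoothness-penalized nonnegative least-squares problem.

#' Simulated multichannel LED basis
#'
#' Gaussian channel profiles with unit peak on the canonical grid, standing in
#' for the (unpublished) channel spectra of a 13-channel tunable luminaire.
#'
#' @param n number of channels (>= 3).
#' @param peaks channel peak wavelengths in nm, strictly increasing; default
#'   equally spaced 410-690 nm.
#' @param fwhm full width at half maximum in nm.
#' @return Object of class `led_basis`: list(channels, peaks_nm, fwhm_nm, B)
#'   where B is the 31 x n matrix of channel spectra.
#' @export
make_led_basis <- function(n = 13, peaks = seq(410, 690, length.out = n),
                           fwhm = 30) {
  if (n < 3) stop("need at least 3 channels to span chromaticity space")
  if (length(peaks) != n) stop("length(peaks) must equal n")
  if (any(diff(peaks) <= 0)) stop("channel peaks must be strictly increasing")
  grid <- canonical_grid()
  if (any(peaks < min(grid)) || any(peaks > max(grid))) {
    stop("channel peaks must lie within the canonical grid")
  }
  if (fwhm <= 0) stop("fwhm must be positive")
  sd_nm <- fwhm / (2 * sqrt(2 * log(2)))
  B <- vapply(peaks, function(p) exp(-0.5 * ((grid - p) / sd_nm)^2),
              numeric(length(grid)))
  channels <- lapply(seq_len(n), function(j) spectrum(B[, j], role = "channel"))
  structure(list(channels = channels, peaks_nm = peaks, fwhm_nm = fwhm, B = B),
            class = "led_basis")
}

# Second-difference operator on the canonical grid (penalizes spectral
# curvature of the synthesized spectrum).
.second_diff_operator <- function(n) {
  D <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) D[i, i:(i + 2)] <- c(1, -2, 1)
  D
}

#' Fit nonnegative channel weights to a target spectrum
#'
#' Solves w = argmin ||B w - s||^2 + lambda ||D2 (B w)||^2 subject to w >= 0,
#' where D2 is the second-difference operator, via nonnegative least squares
#' on the stacked system. This is the spectrally smooth metamer-fitting
#' quadratic program.
#'
#' @param target a [spectrum()] on the canonical grid.
#' @param basis a [make_led_basis()] object.
#' @param smoothness penalty weight lambda >= 0 (relative to unit-normalized
#'   spectra).
#' @return list(weights, fitted (spectrum), rms, chromaticity_error_uv).
#' @export
fit_weights <- function(target, basis, smoothness = 1e-3) {
  stopifnot(is_spectrum(target), inherits(basis, "led_basis"))
  if (smoothness < 0) stop("smoothness must be nonnegative")
  s <- target$values
  if (all(s == 0)) {
    w <- rep(0, ncol(basis$B))
    fitted <- spectrum(rep(0, length(s)))
    return(list(weights = w, fitted = fitted, rms = 0,
                chromaticity_error_uv = 0))
  }
  scale <- max(s)
  B <- basis$B
  D2 <- .second_diff_operator(nrow(B))
  A <- rbind(B, sqrt(smoothness) * (D2 %*% B))
  b <- c(s / scale, rep(0, nrow(D2)))
  sol <- pracma::lsqnonneg(A, b)
  if (is.null(sol$x) || any(!is.finite(sol$x))) {
    stop("nonnegative least-squares solver failed: ",
         paste(utils::capture.output(utils::str(sol)), collapse = " "))
  }
  w <- sol$x * scale
  fit_vals <- as.numeric(B %*% w)
  fitted <- spectrum(fit_vals, role = "illuminant")
  uv_t <- xy_to_uv1960(xyz_to_xy(spectrum_to_xyz(target)))
  uv_f <- xy_to_uv1960(xyz_to_xy(spectrum_to_xyz(fitted)))
  list(weights = w, fitted = fitted,
       rms = sqrt(mean((fit_vals - s)^2)),
       chromaticity_error_uv = sqrt(sum((uv_t - uv_f)^2)))
}

#' Fit nonnegative channel weights to target tristimulus values
#'
#' Chromaticity/luminance metamer synthesis: finds the spectrally smoothest
#' nonnegative channel combination whose tristimulus values match `target_xyz`.
#' The tristimulus match is enforced by a large quadratic penalty.
#'
#' @param target_xyz numeric c(X, Y, Z).
#' @param basis a [make_led_basis()] object.
#' @param smoothness curvature penalty weight.
#' @param match_weight penalty weight on the tristimulus match.
#' @return list(weights, fitted, xyz_error, chromaticity_error_uv).
#' @export
fit_weights_xyz <- function(target_xyz, basis, smoothness = 1e-3,
                            match_weight = 1e4) {
  stopifnot(inherits(basis, "led_basis"))
  B <- basis$B
  cmf <- cie1931_cmf()
  M <- t(cmf) * 10  # 3 x 31, spectrum -> XYZ
  scale <- target_xyz[[2]]
  if (scale <= 0) stop("target luminance must be positive")
  D2 <- .second_diff_operator(nrow(B))
  A <- rbind(sqrt(match_weight) * (M %*% B) / scale,
             sqrt(smoothness) * (D2 %*% B))
  b <- c(sqrt(match_weight) * as.numeric(target_xyz) / scale,
         rep(0, nrow(D2)))
  sol <- pracma::lsqnonneg(A, b)
  if (is.null(sol$x) || any(!is.finite(sol$x))) {
    stop("nonnegative least-squares solver failed in tristimulus fit")
  }
  w <- sol$x
  fitted <- spectrum(as.numeric(B %*% w), role = "illuminant")
  xyz_f <- spectrum_to_xyz(fitted)
  uv_t <- xy_to_uv1960(xyz_to_xy(as.numeric(target_xyz)))
  uv_f <- xy_to_uv1960(xyz_to_xy(xyz_f))
  list(weights = w, fitted = fitted,
       xyz_error = sqrt(sum((xyz_f - as.numeric(target_xyz))^2)) / scale,
       chromaticity_error_uv = sqrt(sum((uv_t - uv_f)^2)))
}

#' Scale a spectrum to match a reference luminance
#'
#' @param s illuminant [spectrum()] with positive Y.
#' @param reference illuminant [spectrum()] with positive Y.
#' @return `s` scaled so its Y equals the reference's; chromaticity unchanged.
#' @export
match_luminance <- function(s, reference) {
  check_same_grid(s, reference)
  Ys <- spectrum_to_xyz(s)[["Y"]]
  Yr <- spectrum_to_xyz(reference)[["Y"]]
  if (Ys <= 0) stop("cannot luminance-match a zero-luminance spectrum")
  if (Yr <= 0) stop("reference spectrum has nonpositive luminance")
  spectrum(s$values * Yr / Ys, role = "illuminant")
}

# CIELUV colour difference between two chromaticities at equal luminance,
# with the target illumination as reference white (so the target maps to
# L* = 100, u* = v* = 0 and dE reduces to the chromatic terms).
.de_from_target <- function(xy, target_xy) {
  white <- xy_to_xyz(target_xy, Y = 100)
  delta_e_luv(xyz_to_luv(xy_to_xyz(xy, Y = 100), white),
              xyz_to_luv(white, white))
}

#' Comparison chromaticity at a given colour difference from the target
#'
#' Blue and yellow directions move along the Planckian locus from 6700 K
#' (blue toward higher correlated colour temperature, yellow toward lower);
#' red and green move along the iso-CCT line through 6700 K (green above the
#' locus toward larger v, red below). The point is located by bisection on
#' the path parameter so that the luminance-matched CIELUV colour difference
#' from the target equals `de`.
#'
#' @param direction one of "blue", "yellow", "red", "green".
#' @param de target CIELUV colour difference (>= 0).
#' @param target_xy chromaticity of the target illumination; default the
#'   daylight-model D67 chromaticity.
#' @param tol placement tolerance in colour-difference units.
#' @return Named numeric c(x, y).
#' @export
chromaticity_at_delta_e <- function(direction = c("blue", "yellow", "red", "green"),
                                    de, target_xy = NULL, tol = 0.05) {
  direction <- match.arg(direction)
  if (de < 0) stop("de must be nonnegative")
  if (is.null(target_xy)) {
    target_xy <- xyz_to_xy(spectrum_to_xyz(daylight_spectrum(6700)))
  }
  if (de == 0) return(c(x = target_xy[[1]], y = target_xy[[2]]))
  uv0 <- xy_to_uv1960(target_xy)
  point_at <- function(t) {
    if (direction %in% c("blue", "yellow")) {
      # parametrize by reciprocal temperature for even spacing along the locus
      mired0 <- 1e6 / 6700
      mired <- if (direction == "blue") mired0 - t else mired0 + t
      T_k <- 1e6 / mired
      p <- planckian_uv(T_k)
      # shift so the path passes through the target chromaticity at t = 0
      p + (uv0 - planckian_uv(6700))
    } else {
      # normal at the target's own CCT: the straight normal line through the
      # target is then an iso-CCT line, so every comparison keeps the
      # target's correlated colour temperature
      n <- iso_cct_direction(cct_of_uv(uv0))
      if (direction == "red") n <- -n
      uv0 + t * n
    }
  }
  t_max <- if (direction == "blue") {
    1e6 / 6700 - 1e6 / 19000
  } else if (direction == "yellow") {
    1e6 / 1100 - 1e6 / 6700
  } else 0.2
  f <- function(t) .de_from_target(uv1960_to_xy(point_at(t)), target_xy) - de
  if (f(t_max) < 0) {
    stop("colour difference ", de, " unreachable within the ", direction,
         " path domain")
  }
  r <- stats::uniroot(f, c(0, t_max), tol = 1e-10)
  xy <- uv1960_to_xy(point_at(r$root))
  if (abs(f(r$root)) > tol) {
    stop("placement failed to reach tolerance ", tol, " for de = ", de)
  }
  c(x = xy[[1]], y = xy[[2]])
}

# Snap weights to the 16-bit lattice of [0, w_max].
.quantize_weights <- function(w, w_max, levels = 2^16) {
  if (w_max <= 0) stop("w_max must be positive")
  round(pmin(w, w_max) / w_max * (levels - 1)) / (levels - 1) * w_max
}

#' Generate one chromatic direction's comparison-illuminant series
#'
#' Synthesizes the target (a D67 metamer fit to the daylight-model spectrum)
#' and 51 comparison illuminants at nominal colour differences 0..50 from it,
#' each a spectrally smooth nonnegative channel combination at the chromaticity
#' from [chromaticity_at_delta_e()], luminance-matched to the target. The
#' achieved colour difference of each synthesized (post-fit, post-quantization)
#' spectrum is recorded.
#'
#' @param direction one of "blue", "yellow", "red", "green".
#' @param basis a [make_led_basis()] object.
#' @param n_steps number of series members (nominal 0..n_steps-1).
#' @param quantize snap channel weights to the 16-bit hardware lattice.
#' @param smoothness curvature penalty passed to the fit.
#' @return Object of class `comparison_series`: list(direction, target,
#'   comparisons, nominal_de, achieved_de, weights, table) where table is a
#'   data.frame(index, nominal_de, achieved_de, x, y, Y, cct).
#' @export
generate_series <- function(direction = c("blue", "yellow", "red", "green"),
                            basis = make_led_basis(), n_steps = 51,
                            quantize = TRUE, smoothness = 1e-3) {
  direction <- match.arg(direction)
  d67 <- daylight_spectrum(6700)
  target_fit <- fit_weights(d67, basis, smoothness = smoothness)
  target <- target_fit$fitted
  target_xyz <- spectrum_to_xyz(target)
  target_xy <- xyz_to_xy(target_xyz)
  white <- xy_to_xyz(target_xy, Y = 100)
  luv_target <- xyz_to_luv(white, white)

  nominal <- seq_len(n_steps) - 1
  raw <- lapply(nominal, function(k) {
    xy <- chromaticity_at_delta_e(direction, k, target_xy = target_xy)
    fit_weights_xyz(xy_to_xyz(xy, Y = target_xyz[["Y"]]), basis,
                    smoothness = smoothness)
  })
  w_max <- max(vapply(raw, function(r) max(r$weights), numeric(1)),
               max(target_fit$weights))
  comparisons <- vector("list", n_steps)
  weights <- matrix(NA_real_, n_steps, ncol(basis$B))
  achieved <- numeric(n_steps)
  rows <- vector("list", n_steps)
  for (i in seq_len(n_steps)) {
    w <- raw[[i]]$weights
    if (quantize) w <- .quantize_weights(w, w_max)
    sp <- spectrum(as.numeric(basis$B %*% w), role = "illuminant")
    sp <- match_luminance(sp, target)
    xyz <- spectrum_to_xyz(sp)
    xy <- xyz_to_xy(xyz)
    achieved[i] <- delta_e_luv(
      xyz_to_luv(xy_to_xyz(xy, Y = 100), white), luv_target)
    comparisons[[i]] <- sp
    weights[i, ] <- w
    cct <- tryCatch(cct_of_uv(xy_to_uv1960(xy)), error = function(e) NA_real_)
    rows[[i]] <- data.frame(index = i - 1, nominal_de = nominal[i],
                            achieved_de = achieved[i],
                            x = xy[[1]], y = xy[[2]], Y = xyz[["Y"]],
                            cct = cct)
  }
  structure(list(direction = direction, target = target,
                 comparisons = comparisons, nominal_de = nominal,
                 achieved_de = achieved, weights = weights,
                 quantized = quantize,
                 mean_abs_deviation = mean(abs(achieved - nominal)),
                 table = do.call(rbind, rows)),
            class = "comparison_series")
}

#' @export
print.comparison_series <- function(x, ...) {
  cat("<comparison_series>", x$direction, "|", length(x$comparisons),
      "comparisons | achieved dE",
      sprintf("%.2f..%.2f | mean |achieved-nominal| = %.3f\n",
              min(x$achieved_de), max(x$achieved_de), x$mean_abs_deviation))
  invisible(x)
}

#' Write a comparison series to a directory
#'
#' Emits one spectrum CSV per comparison plus `series.csv` (columns: index,
#' nominal_de, achieved_de, x, y, Y, cct) and `target.csv`.
#'
#' @param series a [generate_series()] object.
#' @param dir output directory (created if missing).
#' @export
write_series <- function(series, dir) {
  stopifnot(inherits(series, "comparison_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(series$table, file.path(dir, "series.csv"),
                   row.names = FALSE)
  write_spectrum_csv(series$target, file.path(dir, "target.csv"))
  for (i in seq_along(series$comparisons)) {
    write_spectrum_csv(series$comparisons[[i]],
                       file.path(dir, sprintf("comparison_%02d.csv", i - 1)))
  }
  invisible(dir)
}
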