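# Spectral-to-colorimetric conversions, Planckian-locus geometry and
# colour-difference metrics. Everything downstream (illuminant series,
# rendering, observers, S-CIELAB) is built on these.

# Package-local cache for derived tables (fine-grid CMFs, locus table).
.cache <- new.env(parent = emptyenv())

#' Tristimulus values of a spectrum
#'
#' Riemann sum of the spectrum against the CIE 1931 2-degree colour-matching
#' functions on the canonical grid. Absolute scale is arbitrary (relative
#' colorimetry); Y is relative luminance.
#'
#' @param s a [spectrum()].
#' @param cmfs colour-matching functions, 31 x 3 matrix on the canonical grid.
#' @return Named numeric vector c(X, Y, Z).
#' @export
spectrum_to_xyz <- function(s, cmfs = cie1931_cmf()) {
  stopifnot(is_spectrum(s))
  if (nrow(cmfs) != length(s$wavelengths)) {
    stop("grid mismatch: spectrum has ", length(s$wavelengths),
         " bands, colour-matching functions have ", nrow(cmfs), " rows")
  }
  xyz <- as.numeric(crossprod(cmfs, s$values)) * 10  # d(lambda) = 10 nm
  names(xyz) <- c("X", "Y", "Z")
  xyz
}

#' Chromaticity coordinates of tristimulus values
#'
#' @param xyz numeric c(X, Y, Z) with positive sum.
#' @return Named numeric vector c(x, y).
#' @export
xyz_to_xy <- function(xyz) {
  s <- sum(xyz)
  if (!is.finite(s) || s <= 0) {
    stop("cannot project to chromaticity: X + Y + Z = ", s)
  }
  c(x = xyz[[1]] / s, y = xyz[[2]] / s)
}

#' Tristimulus values from chromaticity at a given luminance
#'
#' @param xy numeric c(x, y), y > 0.
#' @param Y luminance.
#' @return Named numeric vector c(X, Y, Z).
#' @export
xy_to_xyz <- function(xy, Y = 1) {
  x <- xy[[1]]; y <- xy[[2]]
  if (y <= 0) stop("chromaticity y must be positive")
  c(X = x * Y / y, Y = Y, Z = (1 - x - y) * Y / y)
}

#' CIE 1960 uniform-chromaticity-scale coordinates
#'
#' u = 4x / (-2x + 12y + 3), v = 6y / (-2x + 12y + 3). Note v = (2/3) v' of
#' the 1976 diagram.
#'
#' @param xy numeric c(x, y).
#' @return Named numeric vector c(u, v).
#' @export
xy_to_uv1960 <- function(xy) {
  x <- xy[[1]]; y <- xy[[2]]
  d <- -2 * x + 12 * y + 3
  if (d <= 0) stop("uv projection undefined: -2x + 12y + 3 = ", d)
  c(u = 4 * x / d, v = 6 * y / d)
}

#' Inverse of [xy_to_uv1960()]
#'
#' @param uv numeric c(u, v).
#' @return Named numeric vector c(x, y).
#' @export
uv1960_to_xy <- function(uv) {
  u <- uv[[1]]; v <- uv[[2]]
  d <- 2 * u - 8 * v + 4
  if (d <= 0) stop("xy back-projection undefined: 2u - 8v + 4 = ", d)
  c(x = 3 * u / d, y = 2 * v / d)
}

# CIE L* companding function.
.lstar_f <- function(t) {
  ifelse(t > (6 / 29)^3, t^(1 / 3), t * (29 / 6)^2 / 3 + 4 / 29)
}

#' CIELUV coordinates of tristimulus values
#'
#' @param xyz numeric c(X, Y, Z).
#' @param white reference-white tristimulus values, Y of white defines L* = 100.
#' @return Object of class `luv`: list(Lstar, ustar, vstar, white).
#' @export
xyz_to_luv <- function(xyz, white) {
  up <- function(p) 4 * p[[1]] / (p[[1]] + 15 * p[[2]] + 3 * p[[3]])
  vp <- function(p) 9 * p[[2]] / (p[[1]] + 15 * p[[2]] + 3 * p[[3]])
  L <- 116 * .lstar_f(xyz[[2]] / white[[2]]) - 16
  structure(list(Lstar = L,
                 ustar = 13 * L * (up(xyz) - up(white)),
                 vstar = 13 * L * (vp(xyz) - vp(white)),
                 white = as.numeric(white)),
            class = "luv")
}

#' CIELUV colour difference
#'
#' Euclidean distance in (L*, u*, v*). Both colours must share the same
#' reference white.
#'
#' @param a,b objects from [xyz_to_luv()].
#' @return Nonnegative scalar.
#' @export
delta_e_luv <- function(a, b) {
  stopifnot(inherits(a, "luv"), inherits(b, "luv"))
  if (max(abs(a$white - b$white)) > 1e-9 * max(abs(a$white))) {
    stop("CIELUV colours have different reference whites")
  }
  sqrt((a$Lstar - b$Lstar)^2 + (a$ustar - b$ustar)^2 + (a$vstar - b$vstar)^2)
}

# Colour-matching functions interpolated to a 1 nm grid (spline), cached.
.fine_cmfs <- function() {
  if (is.null(.cache$fine_cmfs)) {
    grid <- canonical_grid()
    wl <- seq(400, 700, by = 1)
    cmf <- cie1931_cmf()
    fine <- vapply(1:3, function(j) {
      pmax(stats::spline(grid, cmf[, j], xout = wl)$y, 0)
    }, numeric(length(wl)))
    .cache$fine_cmfs <- list(wl = wl, cmf = fine)
  }
  .cache$fine_cmfs
}

#' Chromaticity of a Planckian (blackbody) radiator
#'
#' Integrates Planck's law against the colour-matching functions on a 1 nm
#' grid over the canonical wavelength support.
#'
#' @param T_k temperature in kelvin, in \[1000, 20000\].
#' @return Named numeric c(u, v) in the CIE 1960 diagram.
#' @export
planckian_uv <- function(T_k) {
  if (T_k < 1000 || T_k > 20000) {
    stop("Planckian locus temperature out of range [1000, 20000] K: ", T_k)
  }
  f <- .fine_cmfs()
  lam <- f$wl * 1e-9
  c2 <- 1.4388e-2  # m K
  rad <- 1 / (lam^5 * (exp(c2 / (lam * T_k)) - 1))
  xyz <- as.numeric(crossprod(f$cmf, rad))
  xy_to_uv1960(xyz_to_xy(xyz))
}

# Dense locus table for CCT search, cached.
.locus_table <- function() {
  if (is.null(.cache$locus)) {
    T_grid <- seq(1000, 20000, by = 10)
    uv <- t(vapply(T_grid, planckian_uv, numeric(2)))
    .cache$locus <- list(T = T_grid, u = uv[, 1], v = uv[, 2])
  }
  .cache$locus
}

#' Correlated colour temperature of a chromaticity
#'
#' Temperature of the nearest Planckian-locus point in the 1960 uv diagram:
#' coarse grid search at 10 K followed by golden-section refinement to 0.1 K.
#'
#' @param uv numeric c(u, v).
#' @param max_dist maximum allowed uv distance from the locus (default 0.05).
#' @return Temperature in kelvin.
#' @export
cct_of_uv <- function(uv, max_dist = 0.05) {
  loc <- .locus_table()
  d2 <- (loc$u - uv[[1]])^2 + (loc$v - uv[[2]])^2
  i <- which.min(d2)
  lo <- loc$T[max(i - 1, 1)]
  hi <- loc$T[min(i + 1, length(loc$T))]
  dist_at <- function(T_k) {
    p <- planckian_uv(T_k)
    sqrt((p[1] - uv[[1]])^2 + (p[2] - uv[[2]])^2)
  }
  opt <- stats::optimize(dist_at, c(lo, hi), tol = 0.1)
  if (opt$objective > max_dist) {
    stop("chromaticity is not near the Planckian locus (uv distance ",
         signif(opt$objective, 3), " > ", max_dist, ")")
  }
  opt$minimum
}

#' CIE daylight spectrum at a correlated colour temperature
#'
#' Daylight-model spectrum S0 + M1 S1 + M2 S2 on the canonical grid, with the
#' daylight chromaticity polynomial for xD and the quadratic for yD.
#'
#' @param cct correlated colour temperature in kelvin, in \[4000, 25000\].
#' @return A [spectrum()] (role illuminant), unnormalized model units.
#' @export
daylight_spectrum <- function(cct) {
  if (cct < 4000 || cct > 25000) {
    stop("daylight model domain is [4000, 25000] K: ", cct)
  }
  T_k <- cct
  xD <- if (T_k <= 7000) {
    -4.6070e9 / T_k^3 + 2.9678e6 / T_k^2 + 0.09911e3 / T_k + 0.244063
  } else {
    -2.0064e9 / T_k^3 + 1.9018e6 / T_k^2 + 0.24748e3 / T_k + 0.237040
  }
  yD <- -3.000 * xD^2 + 2.870 * xD - 0.275
  M <- 0.0241 + 0.2562 * xD - 0.7341 * yD
  M1 <- (-1.3515 - 1.7703 * xD + 5.9114 * yD) / M
  M2 <- (0.0300 - 31.4424 * xD + 30.0717 * yD) / M
  comp <- cie_daylight_components()
  spectrum(comp[, "S0"] + M1 * comp[, "S1"] + M2 * comp[, "S2"],
           role = "illuminant")
}

#' Unit normal to the Planckian locus in the 1960 uv diagram
#'
#' Tangent by central finite difference (10 K); the normal's positive sense
#' points above the locus, toward larger v (the "green" side).
#'
#' @param T_k temperature in kelvin.
#' @return Unit numeric c(u, v) vector.
#' @export
iso_cct_direction <- function(T_k) {
  h <- 10
  p1 <- planckian_uv(T_k - h)
  p2 <- planckian_uv(T_k + h)
  tg <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  n <- c(-tg[2], tg[1])
  if (n[2] < 0) n <- -n
  n / sqrt(sum(n^2))
}

#' Mean CIELUV colour difference of one just-noticeable difference
#'
#' Scales each MacAdam ellipse to `k_sd` standard deviations, samples its
#' boundary, converts the centre and boundary chromaticities to CIELUV at
#' equal luminance (reference white: illuminant C at the same luminance, the
#' adapting field of the original measurements) and averages the resulting
#' colour differences over boundary points and ellipses. With the luminance
#' held fixed only the chromatic terms contribute.
#'
#' @param ellipses data.frame as returned by [macadam_ellipses()].
#' @param k_sd scale factor in standard deviations (default 1.96).
#' @param n_points boundary samples per ellipse.
#' @return Mean CIELUV colour difference (scalar).
#' @export
jnd_in_delta_e <- function(ellipses = macadam_ellipses(), k_sd = 1.96,
                           n_points = 64) {
  if (is.null(ellipses) || nrow(ellipses) == 0) stop("empty ellipse set")
  if (k_sd < 0) stop("k_sd must be nonnegative")
  Y <- 100
  white <- xy_to_xyz(.illuminant_c_xy, Y = Y)
  theta <- seq(0, 2 * pi, length.out = n_points + 1)[seq_len(n_points)]
  per_ellipse <- vapply(seq_len(nrow(ellipses)), function(i) {
    e <- ellipses[i, ]
    ang <- e$theta_deg * pi / 180
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    offs <- R %*% rbind(e$a_1e3 * 1e-3 * cos(theta),
                        e$b_1e3 * 1e-3 * sin(theta)) * k_sd
    center <- xyz_to_luv(xy_to_xyz(c(e$x, e$y), Y = Y), white)
    des <- vapply(seq_len(n_points), function(j) {
      p <- c(e$x + offs[1, j], e$y + offs[2, j])
      delta_e_luv(xyz_to_luv(xy_to_xyz(p, Y = Y), white), center)
    }, numeric(1))
    mean(des)
  }, numeric(1))
  mean(per_ellipse)
}
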