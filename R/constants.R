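# Embedded standard colorimetric reference data, all resampled/tabulated on the
# canonical wavelength grid 400-700 nm in 10 nm steps (31 bands).

#' Canonical wavelength grid
#'
#' All spectra in the package live on this grid: 400 to 700 nm in 10 nm steps,
#' 31 samples, matching a 31-plane hyperspectral image representation.
#'
#' @return Numeric vector of 31 wavelengths in nm.
#' @export
canonical_grid <- function() seq(400, 700, by = 10)

# CIE 1931 2-degree standard colorimetric observer, 10 nm tabulation 400-700 nm.
# Columns: xbar, ybar, zbar.
.cie1931_cmf <- matrix(c(
  # xbar    ybar    zbar
  0.0143, 0.0004, 0.0679,  # 400
  0.0435, 0.0012, 0.2074,  # 410
  0.1344, 0.0040, 0.6456,  # 420
  0.2839, 0.0116, 1.3856,  # 430
  0.3483, 0.0230, 1.7471,  # 440
  0.3362, 0.0380, 1.7721,  # 450
  0.2908, 0.0600, 1.6692,  # 460
  0.1954, 0.0910, 1.2876,  # 470
  0.0956, 0.1390, 0.8130,  # 480
  0.0320, 0.2080, 0.4652,  # 490
  0.0049, 0.3230, 0.2720,  # 500
  0.0093, 0.5030, 0.1582,  # 510
  0.0633, 0.7100, 0.0782,  # 520
  0.1655, 0.8620, 0.0422,  # 530
  0.2904, 0.9540, 0.0203,  # 540
  0.4334, 0.9950, 0.0087,  # 550
  0.5945, 0.9950, 0.0039,  # 560
  0.7621, 0.9520, 0.0021,  # 570
  0.9163, 0.8700, 0.0017,  # 580
  1.0263, 0.7570, 0.0011,  # 590
  1.0622, 0.6310, 0.0008,  # 600
  1.0026, 0.5030, 0.0003,  # 610
  0.8544, 0.3810, 0.0002,  # 620
  0.6424, 0.2650, 0.0000,  # 630
  0.4479, 0.1750, 0.0000,  # 640
  0.2835, 0.1070, 0.0000,  # 650
  0.1649, 0.0610, 0.0000,  # 660
  0.0874, 0.0320, 0.0000,  # 670
  0.0468, 0.0170, 0.0000,  # 680
  0.0227, 0.0082, 0.0000,  # 690
  0.0114, 0.0041, 0.0000   # 700
), ncol = 3, byrow = TRUE,
  dimnames = list(NULL, c("xbar", "ybar", "zbar")))

#' CIE 1931 2-degree colour-matching functions
#'
#' @return 31 x 3 matrix (columns xbar, ybar, zbar) on the canonical grid.
#' @export
cie1931_cmf <- function() .cie1931_cmf

# CIE daylight model components S0, S1, S2, 10 nm tabulation 400-700 nm.
.cie_daylight_components <- matrix(c(
  #  S0      S1     S2
   94.80,  43.40, -1.10,  # 400
  104.80,  46.30, -0.50,  # 410
  105.90,  43.90, -0.70,  # 420
   96.80,  37.10, -1.20,  # 430
  113.90,  36.70, -2.60,  # 440
  125.60,  35.90, -2.90,  # 450
  125.50,  32.60, -2.80,  # 460
  121.30,  27.90, -2.60,  # 470
  121.30,  24.30, -2.60,  # 480
  113.50,  20.10, -1.80,  # 490
  113.10,  16.20, -1.50,  # 500
  110.80,  13.20, -1.30,  # 510
  106.50,   8.60, -1.20,  # 520
  108.80,   6.10, -1.00,  # 530
  105.30,   4.20, -0.50,  # 540
  104.40,   1.90, -0.30,  # 550
  100.00,   0.00,  0.00,  # 560
   96.00,  -1.60,  0.20,  # 570
   95.10,  -3.50,  0.50,  # 580
   89.10,  -3.50,  2.10,  # 590
   90.50,  -5.80,  3.20,  # 600
   90.30,  -7.20,  4.10,  # 610
   88.40,  -8.60,  4.70,  # 620
   84.00,  -9.50,  5.10,  # 630
   85.10, -10.90,  6.70,  # 640
   81.90, -10.70,  7.30,  # 650
   82.60, -12.00,  8.60,  # 660
   84.90, -14.00,  9.80,  # 670
   81.30, -13.60, 10.20,  # 680
   71.90, -12.00,  8.30,  # 690
   74.30, -13.30,  9.60   # 700
), ncol = 3, byrow = TRUE,
  dimnames = list(NULL, c("S0", "S1", "S2")))

#' CIE daylight basis components
#'
#' @return 31 x 3 matrix (columns S0, S1, S2) on the canonical grid.
#' @export
cie_daylight_components <- function() .cie_daylight_components

# Stockman-Sharpe 2-degree cone fundamentals (linear energy units, unity peak),
# 10 nm resampling transcribed to ~2-3 significant figures. Only relative
# values enter any computation (cone-excitation images).
.ss2_cone_fundamentals <- matrix(c(
  #  L       M       S
  0.0020,  0.0030, 0.0560,  # 400
  0.0080,  0.0120, 0.2220,  # 410
  0.0260,  0.0390, 0.6580,  # 420
  0.0520,  0.0800, 0.9400,  # 430
  0.0830,  0.1280, 0.9840,  # 440
  0.1180,  0.1850, 0.8730,  # 450
  0.1700,  0.2540, 0.7010,  # 460
  0.2450,  0.3500, 0.4780,  # 470
  0.3440,  0.4700, 0.3000,  # 480
  0.4630,  0.6100, 0.1720,  # 490
  0.6050,  0.7550, 0.0930,  # 500
  0.7550,  0.8850, 0.0460,  # 510
  0.8800,  0.9650, 0.0220,  # 520
  0.9550,  0.9970, 0.0100,  # 530
  0.9900,  1.0000, 0.0046,  # 540
  1.0000,  0.9600, 0.0021,  # 550
  0.9980,  0.8750, 0.0010,  # 560
  0.9950,  0.7550, 0.0005,  # 570
  0.9450,  0.6100, 0.00025, # 580
  0.8600,  0.4600, 0.00012, # 590
  0.7400,  0.3250, 0.00006, # 600
  0.5950,  0.2150, 0.00003, # 610
  0.4500,  0.1350, 0.00001, # 620
  0.3150,  0.0810, 0.0,     # 630
  0.2060,  0.0470, 0.0,     # 640
  0.1290,  0.0260, 0.0,     # 650
  0.0760,  0.0140, 0.0,     # 660
  0.0430,  0.0074, 0.0,     # 670
  0.0230,  0.0039, 0.0,     # 680
  0.0120,  0.0020, 0.0,     # 690
  0.0063,  0.0010, 0.0      # 700
), ncol = 3, byrow = TRUE,
  dimnames = list(NULL, c("L", "M", "S")))

#' Stockman-Sharpe 2-degree cone fundamentals
#'
#' Linear energy sensitivities normalized to unity peak, resampled to the
#' canonical 10 nm grid (approximate transcription; relative values only).
#'
#' @return 31 x 3 matrix (columns L, M, S) on the canonical grid.
#' @export
cone_fundamentals <- function() .ss2_cone_fundamentals

# MacAdam (1942) chromaticity-discrimination ellipses: standard 25-ellipse set.
# Centers in CIE 1931 xy; semi-axes a >= b in units of 1e-3 xy at one standard
# deviation; orientation theta in degrees (angle of the major axis from the
# positive x-axis).
.macadam_ellipses <- data.frame(
  x = c(0.160, 0.187, 0.253, 0.150, 0.131, 0.212, 0.258, 0.152, 0.280, 0.380,
        0.160, 0.228, 0.305, 0.385, 0.472, 0.527, 0.475, 0.510, 0.596, 0.344,
        0.390, 0.441, 0.278, 0.300, 0.365),
  y = c(0.057, 0.118, 0.125, 0.680, 0.521, 0.550, 0.450, 0.365, 0.385, 0.498,
        0.200, 0.250, 0.323, 0.393, 0.399, 0.350, 0.300, 0.236, 0.283, 0.284,
        0.237, 0.198, 0.223, 0.163, 0.153),
  a_1e3 = c(0.85, 2.20, 2.50, 9.60, 4.70, 5.80, 5.00, 3.80, 4.00, 4.40,
            2.10, 3.10, 2.30, 3.80, 3.20, 2.60, 2.90, 2.40, 2.60, 2.30,
            2.50, 2.80, 2.40, 2.90, 3.60),
  b_1e3 = c(0.35, 0.55, 0.50, 2.30, 2.00, 2.30, 2.00, 1.90, 1.50, 1.20,
            0.95, 0.90, 0.90, 1.60, 1.40, 1.30, 1.10, 1.20, 1.30, 0.90,
            1.00, 0.95, 0.55, 0.60, 0.95),
  theta_deg = c(62.5, 77.0, 55.5, 105.0, 112.5, 100.0, 92.0, 110.0, 75.5, 70.0,
                104.0, 72.0, 58.0, 65.5, 51.0, 20.0, 28.5, 29.5, 13.0, 60.0,
                47.0, 34.5, 57.5, 54.0, 40.0)
)

#' MacAdam (1942) chromaticity-discrimination ellipses
#'
#' The standard 25-ellipse set. Semi-axes are one standard deviation of the
#' underlying colour-matching scatter, in units of 1e-3 xy.
#'
#' @return data.frame with columns x, y, a_1e3, b_1e3, theta_deg.
#' @export
macadam_ellipses <- function() .macadam_ellipses

# Illuminant C chromaticity: adapting field of the original ellipse measurements.
.illuminant_c_xy <- c(x = 0.3101, y = 0.3162)

# sRGB (IEC 61966-2-1) linear-RGB <-> XYZ (D65) matrices; rows map XYZ -> RGB.
.xyz_to_srgb_mat <- matrix(c(
   3.2404542, -1.5371385, -0.4985314,
  -0.9692660,  1.8760108,  0.0415560,
   0.0556434, -0.2040259,  1.0572252
), nrow = 3, byrow = TRUE)

# S-CIELAB opponent-colour transform (luminance, red-green, blue-yellow),
# rows map XYZ -> opponent.
.scielab_opponent_mat <- matrix(c(
   0.279,  0.720, -0.107,
  -0.449,  0.290, -0.077,
   0.086, -0.590,  0.501
), nrow = 3, byrow = TRUE)

# S-CIELAB spatial kernels: per-channel sums of Gaussians; 'halfwidth' is the
# spread in degrees of visual angle, 'weight' the component amplitude.
.scielab_kernels <- list(
  lum = list(weights = c(0.921, 0.105, -0.108),
             halfwidths = c(0.0283, 0.133, 4.336)),
  rg  = list(weights = c(0.531, 0.330),
             halfwidths = c(0.0392, 0.494)),
  by  = list(weights = c(0.488, 0.371),
             halfwidths = c(0.0536, 0.386))
)
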