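# Mondrian surface ensembles and a flat diffuse renderer. Scenes are
# collections of overlapping axis-aligned rectangles drawing from a set of 16
# reflectances; rendering multiplies the illuminant into each pixel's surface
# reflectance (no interreflections, shading or geometry).

#' Default set of 16 surface reflectances
#'
#' A synthetic ensemble of smooth reflectances (sums of 2-3 Gaussians in
#' wavelength) spanning the hue circle plus near-neutrals, standing in for
#' the preselected surfaces of a printed Mondrian poster. Labels classify
#' each member by the hue family it reflects most, which the ensemble-variant
#' sampling biases use.
#'
#' @return Object of class `reflectance_set`: list(surfaces = list of 16
#'   [spectrum()], labels = character 16, R = 16 x 31 matrix).
#' @export
default_reflectance_set <- function() {
  grid <- canonical_grid()
  g <- function(mu, sd, amp) amp * exp(-0.5 * ((grid - mu) / sd)^2)
  base <- 0.04
  specs <- list(
    red1    = base + g(650, 45, 0.62) + g(440, 25, 0.06),
    red2    = base + g(620, 35, 0.50),
    orange  = base + g(600, 50, 0.58),
    yellow1 = base + 0.65 / (1 + exp(-(grid - 560) / 18)),
    yellow2 = base + 0.50 / (1 + exp(-(grid - 540) / 22)),
    green1  = base + g(540, 40, 0.55),
    green2  = base + g(520, 30, 0.42) + g(680, 30, 0.05),
    green3  = base + g(555, 55, 0.60),
    cyan    = base + g(490, 35, 0.48),
    blue1   = base + g(455, 30, 0.55) + g(680, 40, 0.04),
    blue2   = base + g(470, 40, 0.45),
    purple  = base + g(430, 30, 0.45) + g(670, 45, 0.30),
    neutral1 = rep(0.80, length(grid)),
    neutral2 = rep(0.55, length(grid)),
    neutral3 = rep(0.30, length(grid)),
    neutral4 = rep(0.12, length(grid))
  )
  surfaces <- lapply(specs, function(v) spectrum(pmin(v, 0.95),
                                                 role = "reflectance"))
  labels <- c("red", "red", "red", "yellow", "yellow", "green", "green",
              "green", "blue", "blue", "blue", "red", "neutral", "neutral",
              "neutral", "neutral")
  R <- t(vapply(surfaces, function(s) s$values, numeric(length(grid))))
  structure(list(surfaces = surfaces, labels = labels, R = R),
            class = "reflectance_set")
}

#' Load a reflectance set from a CSV file
#'
#' Expected columns: `wavelength_nm` plus one column per surface; exactly 16
#' surface columns.
#'
#' @param path CSV path.
#' @param labels optional hue-family labels, one per surface.
#' @return A `reflectance_set`.
#' @export
read_reflectance_set <- function(path, labels = NULL) {
  d <- utils::read.csv(path)
  if (!"wavelength_nm" %in% names(d)) stop("missing wavelength_nm column")
  cols <- setdiff(names(d), "wavelength_nm")
  if (length(cols) != 16) {
    stop("a reflectance set has exactly 16 surfaces, found ", length(cols))
  }
  surfaces <- lapply(cols, function(nm) {
    resample_spectrum(d$wavelength_nm, d[[nm]], role = "reflectance")
  })
  names(surfaces) <- cols
  if (is.null(labels)) labels <- cols
  R <- t(vapply(surfaces, function(s) s$values,
                numeric(length(canonical_grid()))))
  structure(list(surfaces = surfaces, labels = labels, R = R),
            class = "reflectance_set")
}

#' Per-surface sampling weights for an ensemble variant
#'
#' "neutral" samples all 16 surfaces uniformly; "reddish_blue" doubles the
#' weight on red- and blue-reflecting members; "yellowish_green" doubles the
#' weight on yellow- and green-reflecting members.
#'
#' @param set a `reflectance_set`.
#' @param variant one of "neutral", "reddish_blue", "yellowish_green".
#' @return Numeric weight vector of length 16.
#' @export
ensemble_bias <- function(set, variant = c("neutral", "reddish_blue",
                                           "yellowish_green")) {
  variant <- match.arg(variant)
  w <- rep(1, length(set$labels))
  if (variant == "reddish_blue") {
    w[set$labels %in% c("red", "blue")] <- 2
  } else if (variant == "yellowish_green") {
    w[set$labels %in% c("yellow", "green")] <- 2
  }
  w
}

#' Generate a Mondrian scene of overlapping rectangles
#'
#' Randomly places `n_rects` overlapping rectangles (uniform position, uniform
#' width/height in `size_range`), each painted with a surface drawn from the
#' reflectance set with probability proportional to `bias`. Later rectangles
#' overpaint earlier ones. If the canvas is not fully covered after `n_rects`
#' placements, placement continues until it is (warning past 2 x n_rects).
#'
#' @param dims canvas c(height, width) in pixels.
#' @param n_rects nominal number of rectangles.
#' @param set a `reflectance_set`.
#' @param bias per-surface sampling weights (nonnegative, not all zero).
#' @param size_range rectangle side range in pixels.
#' @return Object of class `mondrian_scene`: list(dims, rects, owner, set)
#'   where owner is the dims matrix of 1-based surface indices per pixel.
#' @export
generate_mondrian <- function(dims = c(256, 256), n_rects = 2000,
                              set = default_reflectance_set(),
                              bias = rep(1, 16),
                              size_range = c(4, 64)) {
  if (any(bias < 0) || all(bias == 0)) {
    stop("bias weights must be nonnegative and not all zero")
  }
  H <- dims[1]; W <- dims[2]
  owner <- matrix(0L, H, W)
  prob <- bias / sum(bias)
  rects <- vector("list", n_rects)
  placed <- 0
  warned <- FALSE
  while (placed < n_rects || any(owner == 0L)) {
    placed <- placed + 1
    if (!warned && placed > 2 * n_rects) {
      warning("canvas not covered after ", 2 * n_rects,
              " rectangles; continuing")
      warned <- TRUE
    }
    w <- sample(size_range[1]:size_range[2], 1)
    h <- sample(size_range[1]:size_range[2], 1)
    x0 <- sample.int(W, 1) - sample.int(w, 1)  # may start off-canvas
    y0 <- sample.int(H, 1) - sample.int(h, 1)
    xs <- max(x0, 1):min(x0 + w - 1, W)
    ys <- max(y0, 1):min(y0 + h - 1, H)
    idx <- sample.int(length(set$labels), 1, prob = prob)
    if (length(xs) > 0 && length(ys) > 0) owner[ys, xs] <- idx
    rects[[placed]] <- c(x0 = x0, y0 = y0, width = w, height = h,
                         surface = idx)
  }
  structure(list(dims = c(H, W), rects = do.call(rbind, rects[seq_len(placed)]),
                 owner = owner, set = set),
            class = "mondrian_scene")
}

#' @export
print.mondrian_scene <- function(x, ...) {
  cat("<mondrian_scene>", paste(x$dims, collapse = "x"), "px |",
      nrow(x$rects), "rects |",
      length(unique(as.vector(x$owner))), "surfaces visible\n")
  invisible(x)
}

#' Pixel area share of each surface in a scene
#'
#' @param scene a `mondrian_scene`.
#' @return Numeric vector of length 16 summing to 1.
#' @export
surface_shares <- function(scene) {
  tab <- tabulate(as.vector(scene$owner), nbins = length(scene$set$labels))
  tab / sum(tab)
}

#' Render a scene under an illuminant (flat diffuse model)
#'
#' Each pixel's spectrum is the bandwise product of its surface reflectance
#' and the illuminant: a 31-plane hyperspectral image with no interreflections
#' or shading.
#'
#' @param scene a `mondrian_scene`.
#' @param illum an illuminant [spectrum()].
#' @return Object of class `msimage`: H x W x 31 array with attribute
#'   `wavelengths`.
#' @export
render_flat <- function(scene, illum) {
  stopifnot(inherits(scene, "mondrian_scene"), is_spectrum(illum))
  E <- matrix(illum$values, nrow = length(scene$owner),
              ncol = length(illum$values), byrow = TRUE)
  px <- scene$set$R[as.vector(scene$owner), , drop = FALSE] * E
  img <- array(px, dim = c(scene$dims, length(illum$values)))
  attr(img, "wavelengths") <- canonical_grid()
  class(img) <- c("msimage", class(img))
  img
}

# Flatten an H x W x K image to (H*W) x K.
.flatten_image <- function(img) {
  d <- dim(img)
  matrix(img, nrow = d[1] * d[2], ncol = d[3])
}

#' Per-pixel tristimulus values of a multispectral image
#'
#' @param img an `msimage`.
#' @return (H*W) x 3 matrix of XYZ.
#' @export
image_xyz <- function(img) {
  .flatten_image(img) %*% cie1931_cmf() * 10
}

#' Mean chromaticity of a multispectral image
#'
#' Chromaticity of the mean pixel tristimulus values (average first, then
#' project).
#'
#' @param img an `msimage`.
#' @return Named numeric c(x, y).
#' @export
mean_chromaticity <- function(img) {
  xyz <- colMeans(image_xyz(img))
  if (sum(xyz) <= 0) stop("cannot compute chromaticity of an all-black image")
  xyz_to_xy(xyz)
}

#' Select the candidate scene whose rendered mean chromaticity matches a target
#'
#' Renders each candidate under `illum` and returns the one minimizing the
#' Euclidean xy distance of its mean chromaticity to `target_xy`; ties break
#' to the lowest index.
#'
#' @param candidates list of `mondrian_scene`.
#' @param target_xy numeric c(x, y).
#' @param illum illuminant [spectrum()].
#' @return The selected `mondrian_scene`, with attribute `xy_distance`.
#' @export
select_scene <- function(candidates, target_xy, illum) {
  if (length(candidates) == 0) stop("no candidate scenes")
  d <- vapply(candidates, function(sc) {
    xy <- mean_chromaticity(render_flat(sc, illum))
    sqrt(sum((xy - target_xy)^2))
  }, numeric(1))
  best <- which.min(d)
  out <- candidates[[best]]
  attr(out, "xy_distance") <- d[best]
  out
}

#' Cone-excitation image
#'
#' Per-pixel inner products of the spectral image with the L, M and S cone
#' fundamentals.
#'
#' @param img an `msimage`.
#' @param fundamentals 31 x 3 matrix on the canonical grid.
#' @return H x W x 3 array of cone excitations.
#' @export
to_lms <- function(img, fundamentals = cone_fundamentals()) {
  d <- dim(img)
  if (d[3] != nrow(fundamentals)) {
    stop("grid mismatch: image has ", d[3], " bands, fundamentals have ",
         nrow(fundamentals), " rows")
  }
  lms <- .flatten_image(img) %*% fundamentals * 10
  array(lms, dim = c(d[1], d[2], 3))
}

# Per-pixel linear sRGB of a multispectral image (relative units).
.image_linear_srgb <- function(img) {
  xyz <- image_xyz(img)
  xyz %*% t(.xyz_to_srgb_mat)
}

#' Scale a collection of images into the display gamut
#'
#' Applies one common multiplicative factor to every image so that the maximum
#' linear display-primary value across the whole collection is 1; relative
#' ratios between images are preserved.
#'
#' @param images list of `msimage`.
#' @return list(images, factor).
#' @export
scale_to_gamut <- function(images) {
  if (length(images) == 0) stop("empty image collection")
  m <- max(vapply(images, function(im) max(.image_linear_srgb(im)),
                  numeric(1)))
  if (m <= 0) stop("all-zero image collection")
  f <- 1 / m
  scaled <- lapply(images, function(im) {
    out <- im * f
    attr(out, "wavelengths") <- attr(im, "wavelengths")
    class(out) <- class(im)
    out
  })
  list(images = scaled, factor = f)
}

# sRGB transfer function (IEC 61966-2-1), linear in [0,1] -> encoded [0,1].
.srgb_gamma <- function(v) {
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

#' Tone-map a collection of images for display
#'
#' Caps luminance at four times the mean luminance of the reference image
#' (chromaticity preserved for capped pixels), converts to linear sRGB, scales
#' all images by one common factor to fill the gamut, and applies the sRGB
#' transfer function.
#'
#' @param images list of `msimage`.
#' @param reference index of the image defining the luminance cap.
#' @return list of H x W x 3 arrays of 8-bit sRGB values (0-255), plus
#'   attribute `n_truncated` on each (count of luminance-capped pixels).
#' @export
tone_map_for_display <- function(images, reference = 1) {
  if (length(images) == 0) stop("empty image collection")
  xyzs <- lapply(images, image_xyz)
  cap <- 4 * mean(xyzs[[reference]][, 2])
  capped <- lapply(xyzs, function(xyz) {
    over <- xyz[, 2] > cap
    if (any(over)) {
      sc <- cap / xyz[over, 2]
      xyz[over, ] <- xyz[over, , drop = FALSE] * sc
    }
    attr(xyz, "n_truncated") <- sum(over)
    xyz
  })
  rgbs <- lapply(capped, function(xyz) xyz %*% t(.xyz_to_srgb_mat))
  m <- max(vapply(rgbs, max, numeric(1)))
  if (m <= 0) stop("all-zero image collection")
  out <- vector("list", length(images))
  for (i in seq_along(images)) {
    lin <- pmax(rgbs[[i]] / m, 0)
    enc <- round(.srgb_gamma(lin) * 255)
    d <- dim(images[[i]])
    arr <- array(enc, dim = c(d[1], d[2], 3))
    attr(arr, "n_truncated") <- attr(capped[[i]], "n_truncated")
    out[[i]] <- arr
  }
  out
}
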