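# S-CIELAB spatial colour-difference metric: per-pixel XYZ -> opponent
# channels (luminance, red-green, blue-yellow) -> per-channel spatial
# filtering with sums of Gaussians scaled by viewing resolution -> back to
# XYZ -> CIELAB -> pixelwise colour difference. For uniform fields the
# filters are transparent (unit DC gain) and the metric reduces to CIELAB.

#' S-CIELAB configuration
#'
#' @param ppd pixels per degree of visual angle (> 0).
#' @param white reference-white tristimulus values for the CIELAB conversion.
#' @param support kernel truncation half-support in degrees.
#' @return list(ppd, white, support).
#' @export
scielab_config <- function(ppd = 17, white = xy_to_xyz(c(0.3127, 0.3290), Y = 1),
                           support = 0.5) {
  if (ppd <= 0) stop("ppd must be positive")
  list(ppd = ppd, white = as.numeric(white), support = support)
}

#' CIELAB coordinates of tristimulus values
#'
#' @param xyz numeric c(X, Y, Z) or n x 3 matrix.
#' @param white reference white.
#' @return Matching vector/matrix of (L*, a*, b*).
#' @export
xyz_to_lab <- function(xyz, white) {
  m <- if (is.matrix(xyz)) xyz else matrix(xyz, 1)
  fr <- .lstar_f(pmax(sweep(m, 2, as.numeric(white), "/"), 0))
  out <- cbind(L = 116 * fr[, 2] - 16,
               a = 500 * (fr[, 1] - fr[, 2]),
               b = 200 * (fr[, 2] - fr[, 3]))
  if (is.matrix(xyz)) out else out[1, ]
}

# 1-D Gaussian kernel with given full width at half maximum (pixels),
# truncated at +/- half_support pixels, normalized to unit sum.
.gauss_kernel <- function(fwhm_px, half_support_px) {
  sd <- fwhm_px / (2 * sqrt(2 * log(2)))
  r <- max(1, min(half_support_px, ceiling(4 * sd)))
  x <- -r:r
  k <- exp(-0.5 * (x / sd)^2)
  k / sum(k)
}

# Symmetric-padded separable convolution of a matrix with a 1-D kernel
# applied along both dimensions.
.conv_sep <- function(m, k) {
  r <- (length(k) - 1) / 2
  pad_idx <- function(n) c(pmin(r:1, n), 1:n, n + 1 - pmin(1:r, n))
  conv_cols <- function(mm) {
    p <- mm[pad_idx(nrow(mm)), , drop = FALSE]
    out <- stats::filter(p, k, sides = 2)
    out[(r + 1):(r + nrow(mm)), , drop = FALSE]
  }
  if (r == 0) return(m)
  t(conv_cols(t(conv_cols(m))))
}

# Filter one opponent-channel plane with its sum-of-Gaussians kernel.
.filter_channel <- function(plane, params, ppd, support) {
  half_support_px <- ceiling(support * ppd)
  w <- params$weights
  acc <- 0
  for (i in seq_along(w)) {
    k <- .gauss_kernel(params$halfwidths[i] * ppd, half_support_px)
    acc <- acc + w[i] * .conv_sep(plane, k)
  }
  acc / sum(w)  # unit DC gain
}

# Spatially filtered XYZ planes of a multispectral image.
.scielab_filter_xyz <- function(img, cfg) {
  d <- dim(img)
  xyz <- image_xyz(img)
  opp <- xyz %*% t(.scielab_opponent_mat)
  planes <- lapply(1:3, function(j) matrix(opp[, j], d[1], d[2]))
  names(planes) <- c("lum", "rg", "by")
  filt <- lapply(names(planes), function(ch) {
    .filter_channel(planes[[ch]], .scielab_kernels[[ch]], cfg$ppd,
                    cfg$support)
  })
  opp_f <- cbind(as.vector(filt[[1]]), as.vector(filt[[2]]),
                 as.vector(filt[[3]]))
  pmax(opp_f %*% t(solve(.scielab_opponent_mat)), 0)
}

#' Per-pixel S-CIELAB colour-difference map of two images
#'
#' @param img_a,img_b `msimage` objects of identical dimensions.
#' @param cfg a [scielab_config()]; its white should be on the luminance
#'   scale of the images (see `white_from`).
#' @param white_from if "images", the reference white is taken as the mean
#'   filtered tristimulus values of `img_a` scaled to the maximum image
#'   luminance; if "config", `cfg$white` is used as given.
#' @return H x W matrix of colour differences.
#' @export
scielab_map <- function(img_a, img_b, cfg = scielab_config(),
                        white_from = c("images", "config")) {
  white_from <- match.arg(white_from)
  da <- dim(img_a); db <- dim(img_b)
  if (!all(da == db)) {
    stop("image dimension mismatch: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  }
  fa <- .scielab_filter_xyz(img_a, cfg)
  fb <- .scielab_filter_xyz(img_b, cfg)
  white <- if (white_from == "images") {
    xy <- xyz_to_xy(colMeans(fa))
    xy_to_xyz(xy, Y = max(fa[, 2], fb[, 2]))
  } else cfg$white
  la <- xyz_to_lab(fa, white)
  lb <- xyz_to_lab(fb, white)
  matrix(sqrt(rowSums((la - lb)^2)), da[1], da[2])
}

#' Mean of an S-CIELAB difference map
#'
#' @param map matrix from [scielab_map()].
#' @return Arithmetic mean.
#' @export
mean_scielab <- function(map) {
  if (length(map) == 0) stop("empty map")
  mean(map)
}

#' Mean S-CIELAB image difference at threshold
#'
#' For each chromatic direction, renders the scene under the target and under
#' the comparisons bracketing the direction's threshold colour difference,
#' computes the mean S-CIELAB difference from the target image at both levels
#' and interpolates linearly to the threshold. Rows with invalid thresholds
#' are skipped with a warning.
#'
#' @param series_list named list of `comparison_series`.
#' @param thresholds named numeric vector of per-direction thresholds
#'   (achieved colour-difference units).
#' @param scene a `mondrian_scene`.
#' @param cfg a [scielab_config()].
#' @return data.frame(direction, threshold, mean_scielab) with attribute
#'   `dispersion` = max/min ratio of the metric across rows.
#' @export
threshold_image_difference <- function(series_list, thresholds, scene,
                                       cfg = scielab_config()) {
  rows <- list()
  for (d in names(series_list)) {
    thr <- thresholds[[d]]
    se <- series_list[[d]]
    if (is.null(thr) || !is.finite(thr) || thr < min(se$achieved_de) ||
        thr > max(se$achieved_de)) {
      warning("skipping direction ", d, ": threshold ", thr,
              " invalid or outside the series range")
      next
    }
    target_img <- render_flat(scene, se$target)
    i_hi <- which(se$achieved_de >= thr)[1]
    i_lo <- max(i_hi - 1, 1)
    m_at <- function(i) {
      mean_scielab(scielab_map(target_img,
                               render_flat(scene, se$comparisons[[i]]), cfg))
    }
    m <- if (i_lo == i_hi) m_at(i_hi) else {
      d0 <- se$achieved_de[i_lo]; d1 <- se$achieved_de[i_hi]
      w <- if (d1 > d0) (thr - d0) / (d1 - d0) else 0.5
      (1 - w) * m_at(i_lo) + w * m_at(i_hi)
    }
    rows[[d]] <- data.frame(direction = d, threshold = thr, mean_scielab = m)
  }
  if (length(rows) == 0) stop("no direction had a usable threshold")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dispersion") <- max(out$mean_scielab) / min(out$mean_scielab)
  out
}
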