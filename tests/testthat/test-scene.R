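test_that("the default reflectance set has 16 valid labelled surfaces", {
  rs <- default_reflectance_set()
  expect_s3_class(rs, "reflectance_set")
  expect_length(rs$surfaces, 16)
  expect_length(rs$labels, 16)
  expect_identical(dim(rs$R), c(16L, 31L))
  expect_true(all(rs$R >= 0 & rs$R <= 1))
  expect_setequal(unique(rs$labels),
                  c("red", "yellow", "green", "blue", "neutral"))
})

test_that("reflectance sets round trip through CSV", {
  rs <- default_reflectance_set()
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  d <- data.frame(wavelength_nm = canonical_grid())
  for (nm in names(rs$surfaces)) d[[nm]] <- rs$surfaces[[nm]]$values
  utils::write.csv(d, f, row.names = FALSE)
  rs2 <- read_reflectance_set(f, labels = rs$labels)
  expect_equal(rs2$R, rs$R, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("ensemble biases double the intended hue families", {
  rs <- default_reflectance_set()
  expect_identical(ensemble_bias(rs, "neutral"), rep(1, 16))
  rb <- ensemble_bias(rs, "reddish_blue")
  expect_true(all(rb[rs$labels %in% c("red", "blue")] == 2))
  expect_true(all(rb[!rs$labels %in% c("red", "blue")] == 1))
  yg <- ensemble_bias(rs, "yellowish_green")
  expect_true(all(yg[rs$labels %in% c("yellow", "green")] == 2))
})

test_that("generated scenes are fully covered by valid surface indices", {
  sc <- fx_scene()
  expect_true(all(sc$owner >= 1 & sc$owner <= 16))
  expect_identical(dim(sc$owner), c(48L, 48L))
  sh <- surface_shares(sc)
  expect_length(sh, 16)
  expect_equal(sum(sh), 1)
  expect_error(generate_mondrian(c(8, 8), n_rects = 5, bias = rep(0, 16)),
               "not all zero")
})

test_that("sampling bias shifts the expected surface shares", {
  rs <- default_reflectance_set()
  set.seed(99)
  share_of <- function(variant) {
    s <- replicate(30, {
      sc <- generate_mondrian(c(32, 32), n_rects = 150, set = rs,
                              bias = ensemble_bias(rs, variant))
      sum(surface_shares(sc)[rs$labels %in% c("red", "blue")])
    })
    mean(s)
  }
  expect_gt(share_of("reddish_blue"), share_of("neutral") + 0.05)
})

test_that("the flat renderer multiplies reflectance into the illuminant", {
  sc <- fx_scene()
  illum <- fx_target()
  img <- render_flat(sc, illum)
  expect_s3_class(img, "msimage")
  expect_identical(dim(img), c(48L, 48L, 31L))
  i <- 17; j <- 31
  expect_equal(as.numeric(img[i, j, ]),
               sc$set$R[sc$owner[i, j], ] * illum$values,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("mean chromaticity matches a hand-computed two-surface oracle", {
  rs <- default_reflectance_set()
  sc <- fx_scene()
  sc$owner[, ] <- 13L          # neutral1
  sc$owner[, 1:24] <- 1L       # half red1
  illum <- fx_target()
  img <- render_flat(sc, illum)
  # oracle: direct sums, no package colorimetry helpers
  cmf <- cie1931_cmf()
  xyz_a <- colSums(cmf * (rs$R[1, ] * illum$values)) * 10
  xyz_b <- colSums(cmf * (rs$R[13, ] * illum$values)) * 10
  m <- 0.5 * xyz_a + 0.5 * xyz_b
  oracle <- m[1:2] / sum(m)
  expect_equal(unname(mean_chromaticity(img)), unname(oracle),
               tolerance = 1e-12)
})

test_that("scene selection returns the closest candidate", {
  rs <- default_reflectance_set()
  illum <- fx_target()
  mono <- function(idx) {
    sc <- fx_scene()
    sc$owner[, ] <- idx
    sc
  }
  candidates <- list(mono(1L), mono(13L), mono(9L))
  target_xy <- mean_chromaticity(render_flat(candidates[[2]], illum))
  best <- select_scene(candidates, target_xy, illum)
  expect_identical(best$owner[1, 1], 13L)
  expect_equal(attr(best, "xy_distance"), 0)
  expect_error(select_scene(list(), c(0.3, 0.3), illum), "no candidate")
})

test_that("cone images agree with direct per-pixel products", {
  sc <- fx_scene()
  img <- render_flat(sc, fx_target())
  lms <- to_lms(img)
  expect_identical(dim(lms), c(48L, 48L, 3L))
  f <- cone_fundamentals()
  expect_equal(as.numeric(lms[3, 5, ]),
               as.numeric(crossprod(f, img[3, 5, ])) * 10, tolerance = 1e-12)
  expect_error(to_lms(img, fundamentals = f[1:10, ]), "grid mismatch")
})

test_that("gamut scaling preserves ratios and display mapping is 8-bit", {
  sc <- fx_scene()
  imgs <- list(render_flat(sc, fx_target()),
               render_flat(sc, fx_series("blue")$comparisons[[40]]))
  sg <- scale_to_gamut(imgs)
  expect_equal(sg$images[[2]][2, 2, 5] / sg$images[[1]][2, 2, 5],
               imgs[[2]][2, 2, 5] / imgs[[1]][2, 2, 5], tolerance = 1e-12)
  expect_lte(max(illumdisc:::.image_linear_srgb(sg$images[[1]])), 1 + 1e-9)
  disp <- tone_map_for_display(imgs)
  for (d in disp) {
    expect_true(all(d >= 0 & d <= 255))
    expect_identical(dim(d), c(48L, 48L, 3L))
    expect_false(is.null(attr(d, "n_truncated")))
  }
})
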