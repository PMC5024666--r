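test_that("xyz_to_lab matches hand-computed CIELAB values", {
  white <- c(95.047, 100, 108.883)
  lab_w <- xyz_to_lab(white, white)
  expect_equal(unname(lab_w), c(100, 0, 0), tolerance = 1e-9)
  # mid grey: Y/Yn = 0.18 -> L* = 116 * 0.18^(1/3) - 16
  lab_g <- xyz_to_lab(white * 0.18, white)
  expect_equal(lab_g[["L"]], 116 * 0.18^(1 / 3) - 16, tolerance = 1e-9)
  expect_equal(lab_g[["a"]], 0, tolerance = 1e-9)
  # matrix input returns one row per colour
  m <- xyz_to_lab(rbind(white, white * 0.18), white)
  expect_identical(dim(m), c(2L, 3L))
})

test_that("the spatial filters have unit DC gain", {
  plane <- matrix(3.7, 20, 20)
  for (ch in c("lum", "rg", "by")) {
    f <- illumdisc:::.filter_channel(plane,
                                     illumdisc:::.scielab_kernels[[ch]],
                                     ppd = 17, support = 0.5)
    expect_equal(max(abs(f - 3.7)), 0, tolerance = 1e-9, label = ch)
  }
})

test_that("identical images give an exactly zero difference map", {
  img <- render_flat(fx_scene(), fx_target())
  m <- scielab_map(img, img)
  expect_identical(dim(m), c(48L, 48L))
  expect_equal(max(abs(m)), 0)
})

test_that("uniform fields reduce the metric to plain CIELAB", {
  sc <- fx_scene()
  sc$owner[, ] <- 13L
  se <- fx_series("yellow")
  a <- render_flat(sc, se$target)
  b <- render_flat(sc, se$comparisons[[25]])
  m <- scielab_map(a, b)
  expect_equal(max(m) - min(m), 0, tolerance = 1e-9)  # spatially constant
  # oracle: CIELAB difference of the two uniform colours, same white rule
  fa <- image_xyz(a); fb <- image_xyz(b)
  white <- xy_to_xyz(xyz_to_xy(colMeans(fa)), Y = max(fa[, 2], fb[, 2]))
  oracle <- sqrt(sum((xyz_to_lab(fa[1, ], white) -
                        xyz_to_lab(fb[1, ], white))^2))
  expect_equal(mean(m), oracle, tolerance = 1e-6)
})

test_that("at low resolution the filters approach the identity", {
  # with well under one pixel per degree the kernels collapse to deltas and
  # the metric approaches unfiltered per-pixel CIELAB
  sc <- fx_scene()
  se <- fx_series("red")
  a <- render_flat(sc, se$target)
  b <- render_flat(sc, se$comparisons[[30]])
  cfg <- scielab_config(ppd = 0.05)
  m <- scielab_map(a, b, cfg)
  fa <- image_xyz(a); fb <- image_xyz(b)
  white <- xy_to_xyz(xyz_to_xy(colMeans(fa)), Y = max(fa[, 2], fb[, 2]))
  plain <- sqrt(rowSums((xyz_to_lab(fa, white) - xyz_to_lab(fb, white))^2))
  expect_equal(mean(m), mean(plain), tolerance = 0.02)
})

test_that("strong spatial pooling erases a phase-flipped checkerboard", {
  # two images that differ only by the phase of a one-pixel checkerboard
  # become indistinguishable once the kernels span many checker periods
  sc <- fx_scene()
  checker <- outer(1:48, 1:48, function(i, j) (i + j) %% 2 == 0)
  sc$owner[, ] <- 14L
  sc$owner[checker] <- 13L
  sc2 <- sc
  sc2$owner[, ] <- 14L
  sc2$owner[!checker] <- 13L  # phase-flipped checkerboard
  illum <- fx_target()
  a <- render_flat(sc, illum)
  b <- render_flat(sc2, illum)
  pooled <- mean_scielab(scielab_map(a, b, scielab_config(ppd = 60)))
  unpooled <- mean_scielab(scielab_map(a, b, scielab_config(ppd = 0.05)))
  expect_lt(pooled, 0.2 * unpooled)
})

test_that("map inputs are validated", {
  img <- render_flat(fx_scene(), fx_target())
  small <- render_flat({
    set.seed(5); generate_mondrian(c(8, 8), n_rects = 30)
  }, fx_target())
  expect_error(scielab_map(img, small), "dimension mismatch")
  expect_error(scielab_config(ppd = 0), "positive")
  expect_error(mean_scielab(matrix(numeric(0), 0, 0)), "empty")
})

test_that("threshold-level image differences interpolate the series", {
  sc <- fx_scene()
  series_list <- list(blue = fx_series("blue"), red = fx_series("red"))
  cfg <- scielab_config()
  thr <- c(blue = 10, red = 20)
  out <- threshold_image_difference(series_list, thr, sc, cfg)
  expect_identical(nrow(out), 2L)
  expect_true(all(out$mean_scielab > 0))
  expect_equal(attr(out, "dispersion"),
               max(out$mean_scielab) / min(out$mean_scielab))
  # the metric at a larger threshold on the same direction is larger
  out2 <- threshold_image_difference(series_list["blue"], c(blue = 30), sc,
                                     cfg)
  expect_gt(out2$mean_scielab, out$mean_scielab[out$direction == "blue"])
  # invalid thresholds are skipped with a warning; none usable is an error
  expect_warning(
    both <- threshold_image_difference(series_list, c(blue = 10, red = NA),
                                       sc, cfg),
    "skipping")
  expect_identical(nrow(both), 1L)
  expect_error(suppressWarnings(
    threshold_image_difference(series_list, c(blue = NA, red = 99), sc, cfg)),
    "no direction")
})
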