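test_that("the metamer fit matches an exhaustive 2-channel grid search", {
  basis2 <- make_led_basis(n = 3, peaks = c(450, 550, 650))
  w_true <- c(0.3, 0.7)
  target_vals <- as.numeric(basis2$B[, 1:2] %*% w_true)
  # restrict to the first two channels for the oracle
  basis_pair <- basis2
  basis_pair$B <- basis2$B[, 1:2]
  fit <- fit_weights(spectrum(target_vals), basis_pair, smoothness = 1e-3)
  oracle <- grid_search_2ch(target_vals, basis_pair, 1e-3)
  expect_equal(fit$weights, oracle, tolerance = 1e-3)
})

test_that("in-span targets are reconstructed to near-zero chromaticity error", {
  basis <- fx_basis()
  set.seed(7)
  w_true <- runif(13, 0.1, 1)
  target <- spectrum(as.numeric(basis$B %*% w_true))
  fit <- fit_weights(target, basis, smoothness = 0)
  expect_lt(fit$chromaticity_error_uv, 1e-6)
  expect_equal(fit$weights, w_true, tolerance = 1e-6)
})

test_that("the D67 target fit lands on the daylight chromaticity", {
  basis <- fx_basis()
  fit <- fit_weights(daylight_spectrum(6700), basis)
  expect_lt(fit$chromaticity_error_uv, 1e-3)
  expect_true(all(fit$weights >= 0))
})

test_that("the tristimulus fit hits an arbitrary target chromaticity", {
  basis <- fx_basis()
  xyz <- xy_to_xyz(c(0.33, 0.36), Y = 50)
  fit <- fit_weights_xyz(xyz, basis)
  expect_lt(fit$chromaticity_error_uv, 1e-5)
  expect_lt(fit$xyz_error, 1e-4)
  expect_true(all(fit$weights >= 0))
})

test_that("degenerate fit inputs are handled", {
  basis <- fx_basis()
  z <- fit_weights(spectrum(rep(0, 31)), basis)
  expect_identical(z$weights, rep(0, 13))
  expect_identical(z$rms, 0)
  expect_error(fit_weights_xyz(c(1, 0, 1), basis), "positive")
  expect_error(make_led_basis(n = 2), "at least 3")
  expect_error(make_led_basis(peaks = c(500, 450, rep(600, 11))), "increasing")
})

test_that("luminance matching equates Y without moving chromaticity", {
  a <- daylight_spectrum(5500)
  b <- daylight_spectrum(8000)
  m <- match_luminance(a, b)
  expect_equal(spectrum_to_xyz(m)[["Y"]], spectrum_to_xyz(b)[["Y"]],
               tolerance = 1e-9)
  expect_equal(xyz_to_xy(spectrum_to_xyz(m)), xyz_to_xy(spectrum_to_xyz(a)),
               tolerance = 1e-12)
})

test_that("comparison chromaticities land at the requested colour difference", {
  target_xy <- xyz_to_xy(spectrum_to_xyz(daylight_spectrum(6700)))
  for (d in c("blue", "yellow", "red", "green")) {
    xy <- chromaticity_at_delta_e(d, 20, target_xy = target_xy)
    expect_equal(illumdisc:::.de_from_target(xy, target_xy), 20,
                 tolerance = 1e-6, label = d)
  }
  xy0 <- chromaticity_at_delta_e("blue", 0, target_xy = target_xy)
  expect_equal(unname(xy0), unname(target_xy))
  expect_error(chromaticity_at_delta_e("red", -1), "nonnegative")
})

test_that("blue raises CCT, yellow lowers it, red/green hold it", {
  target_xy <- xyz_to_xy(spectrum_to_xyz(daylight_spectrum(6700)))
  cct0 <- cct_of_uv(xy_to_uv1960(target_xy))
  cct_at <- function(d) {
    cct_of_uv(xy_to_uv1960(chromaticity_at_delta_e(d, 30,
                                                   target_xy = target_xy)))
  }
  expect_gt(cct_at("blue"), cct0 + 100)
  expect_lt(cct_at("yellow"), cct0 - 100)
  expect_equal(cct_at("red"), cct0, tolerance = 20)
  expect_equal(cct_at("green"), cct0, tolerance = 20)
  # red moves below the locus (smaller v), green above
  v0 <- xy_to_uv1960(target_xy)[["v"]]
  expect_lt(xy_to_uv1960(chromaticity_at_delta_e("red", 30,
                                                 target_xy = target_xy))[["v"]], v0)
  expect_gt(xy_to_uv1960(chromaticity_at_delta_e("green", 30,
                                                 target_xy = target_xy))[["v"]], v0)
})

test_that("each series has 51 monotone, luminance-matched comparisons", {
  for (d in c("blue", "yellow", "red", "green")) {
    se <- fx_series(d)
    expect_length(se$comparisons, 51)
    expect_equal(se$nominal_de, as.numeric(0:50))
    expect_true(all(diff(se$achieved_de) > 0), label = paste(d, "monotone"))
    expect_lte(se$achieved_de[1], 0.5)
    expect_gte(se$achieved_de[51], 45)
    expect_lte(se$achieved_de[51], 55)
    Y_t <- spectrum_to_xyz(se$target)[["Y"]]
    Ys <- vapply(se$comparisons, function(s) spectrum_to_xyz(s)[["Y"]],
                 numeric(1))
    expect_equal(Ys, rep(Y_t, 51), tolerance = 1e-9)
  }
})

test_that("achieved colour differences track the nominal levels closely", {
  for (d in c("blue", "yellow", "red", "green")) {
    se <- fx_series(d)
    expect_lt(se$mean_abs_deviation, 0.5, label = d)
  }
})

test_that("series weights are nonnegative and quantization snaps to a lattice", {
  se <- fx_series("blue")
  expect_true(all(se$weights >= 0))
  w_max <- max(se$weights)
  # every weight is an integer multiple of the lattice step
  steps <- se$weights / (w_max / (2^16 - 1))
  expect_equal(steps, round(steps), tolerance = 1e-6)
  q <- illumdisc:::.quantize_weights(c(0, 0.5, 1), w_max = 1)
  expect_identical(q[1], 0)
  expect_identical(q[3], 1)
  expect_equal(q[2], 0.5, tolerance = 1 / 2^15)  # within one lattice step
})

test_that("series spectra stay within the locus geometry of their direction", {
  # blue/yellow: near the Planckian locus; red/green: constant CCT
  dist_to_locus <- function(uv) {
    cct <- cct_of_uv(uv)
    sqrt(sum((planckian_uv(cct) - uv)^2))
  }
  for (d in c("blue", "yellow")) {
    tab <- fx_series(d)$table
    dists <- vapply(seq_len(nrow(tab)), function(i) {
      dist_to_locus(xy_to_uv1960(c(tab$x[i], tab$y[i])))
    }, numeric(1))
    expect_lt(max(dists), 0.004, label = d)
  }
  for (d in c("red", "green")) {
    tab <- fx_series(d)$table
    expect_true(all(abs(tab$cct - 6700) <= 20), label = d)
  }
})
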