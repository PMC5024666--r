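test_that("the Weibull percent-correct function matches hand computation", {
  obs <- weibull_observer(alpha = 10, beta = 3)
  expect_equal(p_correct(0, obs), 0.5)
  # at de = alpha with zero lapse: 0.5 + 0.5 (1 - e^-1)
  expect_equal(p_correct(10, obs), 0.5 + 0.5 * (1 - exp(-1)), tolerance = 1e-12)
  lap <- weibull_observer(10, 3, lapse = 0.04)
  expect_equal(p_correct(1e6, lap), 0.96, tolerance = 1e-9)
  expect_true(all(diff(p_correct(seq(0, 40, 0.5), obs)) >= 0))
  expect_error(weibull_observer(-1, 2), "alpha")
  expect_error(weibull_observer(10, 2, lapse = 0.2), "lapse")
})

test_that("a Weibull observer's simulated hit rate matches its function", {
  obs <- weibull_observer(10, 3)
  set.seed(11)
  for (de in c(0, 8, 15)) {
    p_hat <- mean(simulate_trials(obs, 20000, de = de))
    expect_equal(p_hat, p_correct(de, obs), tolerance = 0.015, label = de)
  }
})

test_that("scene summaries match a direct rendered-image computation", {
  sc <- fx_scene()
  se <- fx_series("blue")
  ss <- scene_summaries(sc, se, strategy = "global_mean")
  # oracle: render the full image and average the pixel tristimulus values
  img <- render_flat(sc, se$comparisons[[30]])
  xyz <- colMeans(image_xyz(img))
  white <- colMeans(image_xyz(render_flat(sc, se$target)))
  luv <- xyz_to_luv(xyz, white)
  expect_equal(as.numeric(ss$comparisons[30, ]),
               c(luv$Lstar, luv$ustar, luv$vstar), tolerance = 1e-9)
  # the target summary sits at the white point
  expect_equal(ss$target, c(100, 0, 0), tolerance = 1e-9)
})

test_that("single-surface summaries track only the chosen surface", {
  sc <- fx_scene()
  se <- fx_series("yellow")
  s4 <- scene_summaries(sc, se, strategy = "single_surface",
                        tracked_surface = 4)
  cmf <- cie1931_cmf()
  xyz <- as.numeric(crossprod(cmf, sc$set$R[4, ] *
                                se$comparisons[[10]]$values)) * 10
  luv <- xyz_to_luv(xyz, s4$white)
  expect_equal(as.numeric(s4$comparisons[10, ]),
               c(luv$Lstar, luv$ustar, luv$vstar), tolerance = 1e-9)
})

test_that("the mechanistic decision rule matches a slow-loop oracle", {
  obs <- mechanistic_observer("global_mean", noise_sd = 4)
  target <- c(100, 0, 0)
  comp <- c(100, 6, -3)
  set.seed(21)
  p_fast <- mean(simulate_trials(obs, 40000, target_summary = target,
                                 comparison_summary = comp))
  # independent scalar re-implementation of the same decision rule
  set.seed(22)
  n <- 40000
  hits <- logical(n)
  for (i in seq_len(n)) {
    ref <- target + rnorm(3, sd = 4)
    ct <- target + rnorm(3, sd = 4)
    cc <- comp + rnorm(3, sd = 4)
    hits[i] <- sum((ct - ref)^2) < sum((cc - ref)^2)
  }
  se_mc <- sqrt(0.25 / n)
  expect_lt(abs(p_fast - mean(hits)), 6 * se_mc)
})

test_that("mechanistic responses anchor at chance and saturate without noise", {
  obs <- mechanistic_observer("global_mean", noise_sd = 3)
  set.seed(31)
  p0 <- mean(simulate_trials(obs, 20000, target_summary = c(100, 0, 0),
                             comparison_summary = c(100, 0, 0)))
  expect_equal(p0, 0.5, tolerance = 0.02)
  noiseless <- mechanistic_observer("global_mean", noise_sd = 0)
  expect_true(all(simulate_trials(noiseless, 100,
                                  target_summary = c(100, 0, 0),
                                  comparison_summary = c(100, 2, 0))))
  set.seed(32)
  p_tie <- mean(simulate_trials(noiseless, 20000,
                                target_summary = c(100, 0, 0),
                                comparison_summary = c(100, 0, 0)))
  expect_equal(p_tie, 0.5, tolerance = 0.02)
})

test_that("observer inputs are validated", {
  obs <- weibull_observer(10, 3)
  mech <- mechanistic_observer()
  expect_error(simulate_trials(obs, 10), "colour difference")
  expect_error(simulate_trials(mech, 10), "summaries")
  expect_error(simulate_trials(mech, 10, target_summary = c(1, 2, 3),
                               comparison_summary = c(1, 2)), "mismatch")
  expect_error(mechanistic_observer(noise_sd = -1))
})

test_that("the effective threshold of a Weibull observer inverts its function", {
  obs <- weibull_observer(10, 3)
  se <- fx_series("green")
  set.seed(41)
  thr <- effective_threshold(obs, se, n_per_level = 3000)
  expected <- threshold_at(list(alpha = 10, beta = 3, lapse = 0, guess = 0.5))
  expect_equal(thr, expected, tolerance = 0.08)
})

test_that("the effective threshold grows with internal noise", {
  sc <- fx_scene()
  se <- fx_series("blue")
  set.seed(42)
  thr <- vapply(c(2, 6), function(s) {
    effective_threshold(mechanistic_observer("global_mean", noise_sd = s),
                        se, scene = sc, n_per_level = 1500)
  }, numeric(1))
  expect_gt(thr[2], thr[1])
})

test_that("an undiscriminable series yields an unbounded threshold", {
  sc <- fx_scene()
  se <- fx_series("blue")
  blind <- mechanistic_observer("global_mean", noise_sd = 1e6)
  set.seed(43)
  thr <- effective_threshold(blind, se, scene = sc, n_per_level = 200)
  expect_true(is.na(thr))
  expect_true(isTRUE(attr(thr, "unbounded")))
})
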