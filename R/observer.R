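# Simulated observers for the three-interval illumination-discrimination task.
# A Weibull observer responds directly from the comparison's colour difference;
# mechanistic observers form a noisy CIELUV summary of each interval's image
# and pick the interval nearest the reference.

#' Weibull simulated observer
#'
#' Percent correct follows a cumulative Weibull in colour difference with
#' guess rate fixed at 0.5 (two-alternative task).
#'
#' @param alpha colour-difference scale parameter (> 0); with zero lapse this
#'   is the 81.6%-correct point.
#' @param beta slope parameter (> 0).
#' @param lapse lapse rate in \[0, 0.05\].
#' @return Object of class `weibull_observer`.
#' @export
weibull_observer <- function(alpha, beta, lapse = 0) {
  stopifnot(alpha > 0, beta > 0, lapse >= 0, lapse <= 0.05)
  structure(list(alpha = alpha, beta = beta, lapse = lapse, guess = 0.5),
            class = c("weibull_observer", "observer"))
}

#' Mechanistic simulated observer
#'
#' Summarizes each interval's image either by its mean CIELUV coordinates
#' ("global_mean") or by the CIELUV coordinates of one tracked surface
#' ("single_surface"), perturbs each summary by isotropic Gaussian internal
#' noise, and answers with the candidate interval whose noisy summary lies
#' nearer the noisy reference summary.
#'
#' @param strategy "global_mean" or "single_surface".
#' @param noise_sd internal noise standard deviation, CIELUV units per
#'   interval (>= 0).
#' @param tracked_surface surface index (single_surface only).
#' @return Object of class `mechanistic_observer`.
#' @export
mechanistic_observer <- function(strategy = c("global_mean", "single_surface"),
                                 noise_sd = 3, tracked_surface = 1) {
  strategy <- match.arg(strategy)
  stopifnot(noise_sd >= 0)
  structure(list(strategy = strategy, noise_sd = noise_sd,
                 tracked_surface = tracked_surface),
            class = c("mechanistic_observer", "observer"))
}

#' Probability of a correct response for a Weibull observer
#'
#' p(de) = 0.5 + (0.5 - lapse) (1 - exp(-(de/alpha)^beta)).
#'
#' @param de colour difference (>= 0), vectorized.
#' @param obs a [weibull_observer()].
#' @return Probabilities in \[0.5, 1 - lapse\].
#' @export
p_correct <- function(de, obs) {
  stopifnot(inherits(obs, "weibull_observer"), all(de >= 0))
  0.5 + (0.5 - obs$lapse) * (1 - exp(-(de / obs$alpha)^obs$beta))
}

#' CIELUV summaries of a scene under a comparison-illuminant series
#'
#' Precomputes the decision-variable summary of the rendered scene under the
#' target and under every comparison illuminant. For the flat renderer the
#' mean image tristimulus values equal the area-share-weighted sum of the
#' per-surface tristimulus values, so no per-pixel rendering is needed.
#' The reference white is the scene's mean tristimulus values under the
#' target illumination (the adapting context of the task).
#'
#' @param scene a `mondrian_scene`.
#' @param series a `comparison_series`.
#' @param strategy "global_mean" or "single_surface".
#' @param tracked_surface surface index for single_surface.
#' @return list(target = numeric 3 (L*, u*, v*), comparisons = n x 3 matrix).
#' @export
scene_summaries <- function(scene, series,
                            strategy = c("global_mean", "single_surface"),
                            tracked_surface = 1) {
  strategy <- match.arg(strategy)
  shares <- surface_shares(scene)
  R <- scene$set$R
  cmf <- cie1931_cmf()
  surf_xyz <- function(illum) (R * rep(illum$values, each = nrow(R))) %*% cmf * 10
  summ_xyz <- function(illum) {
    sx <- surf_xyz(illum)
    if (strategy == "global_mean") as.numeric(crossprod(shares, sx))
    else as.numeric(sx[tracked_surface, ])
  }
  white <- as.numeric(crossprod(surface_shares(scene),
                                surf_xyz(series$target)))
  as_luv_vec <- function(xyz) {
    l <- xyz_to_luv(xyz, white)
    c(l$Lstar, l$ustar, l$vstar)
  }
  comps <- t(vapply(series$comparisons, function(s) as_luv_vec(summ_xyz(s)),
                    numeric(3)))
  list(target = as_luv_vec(summ_xyz(series$target)), comparisons = comps,
       white = white)
}

#' Simulate a batch of three-interval trials at one stimulus level
#'
#' The reference interval shows the scene under the target illumination; of
#' the two candidate intervals one repeats the target and the other shows the
#' comparison. A mechanistic observer adds isotropic Gaussian noise to each
#' interval's summary and picks the candidate nearest the noisy reference;
#' a Weibull observer responds correct with probability [p_correct()] of the
#' achieved colour difference.
#'
#' @param obs an observer.
#' @param n number of trials.
#' @param de achieved colour difference (Weibull observer).
#' @param target_summary,comparison_summary CIELUV summaries (mechanistic).
#' @return Logical vector of length n (TRUE = correct).
#' @export
simulate_trials <- function(obs, n, de = NULL, target_summary = NULL,
                            comparison_summary = NULL) {
  if (inherits(obs, "weibull_observer")) {
    if (is.null(de)) stop("Weibull observer needs the colour difference de")
    return(stats::runif(n) < p_correct(de, obs))
  }
  stopifnot(inherits(obs, "mechanistic_observer"))
  if (is.null(target_summary) || is.null(comparison_summary)) {
    stop("mechanistic observer needs target and comparison summaries")
  }
  if (length(target_summary) != length(comparison_summary)) {
    stop("summary dimension mismatch")
  }
  k <- length(target_summary)
  sd <- obs$noise_sd
  ref <- matrix(target_summary, n, k, byrow = TRUE) +
    matrix(stats::rnorm(n * k, sd = sd), n, k)
  cand_t <- matrix(target_summary, n, k, byrow = TRUE) +
    matrix(stats::rnorm(n * k, sd = sd), n, k)
  cand_c <- matrix(comparison_summary, n, k, byrow = TRUE) +
    matrix(stats::rnorm(n * k, sd = sd), n, k)
  d_t <- rowSums((cand_t - ref)^2)
  d_c <- rowSums((cand_c - ref)^2)
  correct <- d_t < d_c
  ties <- d_t == d_c  # identical stimuli with zero noise: chance
  if (any(ties)) correct[ties] <- stats::runif(sum(ties)) < 0.5
  correct
}

#' Simulate one trial
#'
#' @inheritParams simulate_trials
#' @return TRUE if the response is correct.
#' @export
simulate_trial <- function(obs, de = NULL, target_summary = NULL,
                           comparison_summary = NULL) {
  simulate_trials(obs, 1, de = de, target_summary = target_summary,
                  comparison_summary = comparison_summary)[1]
}

#' Ground-truth discrimination threshold of an observer on a series
#'
#' Estimates percent correct at every series level by dense simulation,
#' enforces monotonicity by isotonic regression, and interpolates the level
#' (in achieved colour difference) at which percent correct crosses 70.71%.
#'
#' @param obs an observer.
#' @param series a `comparison_series`.
#' @param scene a `mondrian_scene` (mechanistic observers).
#' @param n_per_level simulated trials per level.
#' @param criterion percent-correct criterion.
#' @return Threshold in colour-difference units, or NA with attribute
#'   `unbounded = TRUE` if the criterion is never crossed in range.
#' @export
effective_threshold <- function(obs, series, scene = NULL,
                                n_per_level = 10000, criterion = 0.7071) {
  de <- series$achieved_de
  if (inherits(obs, "weibull_observer")) {
    p <- vapply(de, function(d) mean(simulate_trials(obs, n_per_level, de = d)),
                numeric(1))
  } else {
    if (is.null(scene)) stop("mechanistic observer needs a scene")
    ss <- scene_summaries(scene, series, strategy = obs$strategy,
                          tracked_surface = obs$tracked_surface)
    p <- vapply(seq_along(de), function(i) {
      mean(simulate_trials(obs, n_per_level, target_summary = ss$target,
                           comparison_summary = ss$comparisons[i, ]))
    }, numeric(1))
  }
  ord <- order(de)
  iso <- stats::isoreg(de[ord], p[ord])
  p_mono <- iso$yf
  de_s <- de[ord]
  if (max(p_mono) < criterion) {
    out <- NA_real_
    attr(out, "unbounded") <- TRUE
    return(out)
  }
  i <- which(p_mono >= criterion)[1]
  if (i == 1) return(de_s[1])
  # linear interpolation between the bracketing levels
  p0 <- p_mono[i - 1]; p1 <- p_mono[i]
  if (p1 == p0) return(de_s[i])
  de_s[i - 1] + (criterion - p0) / (p1 - p0) * (de_s[i] - de_s[i - 1])
}
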