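# Threshold extraction: aggregate all trials of a chromatic direction, sort by
# achieved colour difference, bin by 10, fit a cumulative Weibull by binomial
# maximum likelihood (guess fixed at 0.5, lapse in [0, 0.05]) and invert at
# 70.71% correct.

#' Bin trial records by colour difference
#'
#' Stable sort by achieved colour difference (chronological tie-break), then
#' consecutive bins of `bin_size` trials with the remainder in the last bin.
#'
#' @param records data.frame with columns achieved_de and response (0/1).
#' @param bin_size trials per bin.
#' @return data.frame(mean_de, n_trials, n_correct), mean_de nondecreasing.
#' @export
bin_trials <- function(records, bin_size = 10) {
  if (is.null(records) || nrow(records) == 0) stop("no trials to bin")
  ord <- order(records$achieved_de)  # stable: ties keep chronological order
  de <- records$achieved_de[ord]
  resp <- records$response[ord]
  n <- length(de)
  bin <- ceiling(seq_len(n) / bin_size)
  data.frame(
    mean_de = as.numeric(tapply(de, bin, mean)),
    n_trials = as.integer(tapply(resp, bin, length)),
    n_correct = as.integer(tapply(resp, bin, sum))
  )
}

# Negative binomial log-likelihood of the Weibull psychometric function.
.weibull_nll <- function(par, b) {
  alpha <- exp(par[1]); beta <- exp(par[2]); lapse <- par[3]
  p <- 0.5 + (0.5 - lapse) * (1 - exp(-(b$mean_de / alpha)^beta))
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  -sum(b$n_correct * log(p) + (b$n_trials - b$n_correct) * log(1 - p))
}

#' Fit a cumulative Weibull to binned data by maximum likelihood
#'
#' Maximizes the binomial log-likelihood of
#' p(de) = 0.5 + (0.5 - lapse)(1 - exp(-(de/alpha)^beta)) over alpha > 0,
#' beta > 0, lapse in \[0, 0.05\], from a multi-start grid (8 log-spaced
#' alphas spanning the data range, beta in 1/2/4, lapse in 0/0.025).
#' Degenerate data never raise: the fit is returned with `valid = FALSE`
#' when the inverted threshold leaves the (1, 50) stimulus range.
#'
#' @param b binned data from [bin_trials()].
#' @param criterion percent-correct level defining the reported threshold.
#' @return Object of class `psychometric_fit`: list(alpha, beta, lapse,
#'   guess = 0.5, threshold, valid, loglik).
#' @export
fit_weibull <- function(b, criterion = 0.7071) {
  if (nrow(b) < 2) stop("need at least 2 bins to fit")
  de_pos <- b$mean_de[b$mean_de > 0]
  lo <- if (length(de_pos)) max(min(de_pos), 0.5) else 0.5
  hi <- max(max(b$mean_de), lo * 2)
  alphas <- exp(seq(log(lo), log(hi * 1.5), length.out = 8))
  best <- NULL
  for (a in alphas) for (be in c(1, 2, 4)) for (la in c(0, 0.025)) {
    fit <- tryCatch(
      stats::optim(c(log(a), log(be), la), .weibull_nll, b = b,
                   method = "L-BFGS-B",
                   lower = c(log(1e-3), log(0.1), 0),
                   upper = c(log(1e4), log(20), 0.05)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("Weibull fit failed from every start")
  alpha <- exp(best$par[1]); beta <- exp(best$par[2]); lapse <- best$par[3]
  thr <- tryCatch(
    threshold_at(list(alpha = alpha, beta = beta, lapse = lapse, guess = 0.5),
                 criterion),
    error = function(e) Inf)
  structure(list(alpha = alpha, beta = beta, lapse = lapse, guess = 0.5,
                 threshold = thr,
                 valid = is.finite(thr) && thr > 1 && thr < 50,
                 loglik = -best$value),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> alpha=%.3g beta=%.3g lapse=%.3g | threshold=%.3g (%s)\n",
    x$alpha, x$beta, x$lapse, x$threshold,
    if (x$valid) "valid" else "invalid"))
  invisible(x)
}

#' Invert a Weibull fit at a percent-correct criterion
#'
#' Closed form: de = alpha (-ln(1 - (c - 0.5)/(0.5 - lapse)))^(1/beta).
#'
#' @param fit list with alpha, beta, lapse, guess.
#' @param criterion percent correct, in (guess, 1 - lapse).
#' @return Colour difference at the criterion.
#' @export
threshold_at <- function(fit, criterion = 0.7071) {
  g <- if (is.null(fit$guess)) 0.5 else fit$guess
  if (criterion <= g || criterion >= 1 - fit$lapse) {
    stop("criterion ", criterion, " outside the attainable range (",
         g, ", ", 1 - fit$lapse, ")")
  }
  fit$alpha * (-log(1 - (criterion - g) / (0.5 - fit$lapse)))^(1 / fit$beta)
}

#' Aggregate per-block fits into observer and group threshold tables
#'
#' Per observer and direction, the threshold is the mean across blocks. An
#' observer with any invalid block-by-direction fit is flagged excluded (but
#' kept in the table for auditability); the group summary (mean, SEM, n) uses
#' non-excluded observers only.
#'
#' @param fits data.frame with columns observer, direction, block, threshold,
#'   valid.
#' @return list(observer_thresholds, group_summary, excluded).
#' @export
aggregate_observer <- function(fits) {
  stopifnot(all(c("observer", "direction", "block", "threshold", "valid")
                %in% names(fits)))
  bad <- unique(fits$observer[!fits$valid])
  obs_tab <- stats::aggregate(threshold ~ observer + direction, data = fits,
                              FUN = mean)
  obs_tab$excluded <- obs_tab$observer %in% bad
  keep <- obs_tab[!obs_tab$excluded, ]
  if (nrow(keep) == 0) stop("every observer was excluded")
  grp <- do.call(rbind, lapply(split(keep, keep$direction), function(d) {
    data.frame(direction = d$direction[1],
               mean = mean(d$threshold),
               sem = stats::sd(d$threshold) / sqrt(nrow(d)),
               n = nrow(d))
  }))
  rownames(grp) <- NULL
  list(observer_thresholds = obs_tab, group_summary = grp, excluded = bad)
}

#' Bonferroni-adjusted significance level
#'
#' @param n_comparisons number of comparisons in the family (>= 1).
#' @param family_alpha family-wise alpha.
#' @return family_alpha / n_comparisons.
#' @export
bonferroni_alpha <- function(n_comparisons, family_alpha = 0.05) {
  if (n_comparisons < 1) stop("need at least one comparison")
  family_alpha / n_comparisons
}
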