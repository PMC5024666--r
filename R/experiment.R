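# Orchestration: configuration presets, scene construction by candidate
# selection, the full synthetic experiment (observers x blocks x interleaved
# staircases -> binning -> Weibull fits -> group summary), and the
# surface-ensemble manipulation.

#' Mean-chromaticity targets of the three scene variants
#'
#' @return Named list of xy targets for neutral, reddish_blue and
#'   yellowish_green ensembles.
#' @export
variant_targets <- function() {
  list(neutral = c(0.323, 0.357),
       reddish_blue = c(0.361, 0.339),
       yellowish_green = c(0.399, 0.425))
}

#' Experiment configuration
#'
#' The two dialect presets encode the procedural differences that affect
#' computation: the real-scene dialect runs one block per observer with
#' staircase levels down to 0; the simulated-scene dialect runs two blocks
#' with minimum level 1. Interval timings are metadata only (simulated
#' observers are timing-blind).
#'
#' @param seed root seed; all stage randomness derives from it.
#' @param dialect "simulated" or "real".
#' @param variant scene ensemble variant.
#' @param observer an observer object.
#' @param n_observers number of simulated observers.
#' @param blocks blocks per observer (default by dialect).
#' @param directions chromatic directions to run.
#' @param dims scene canvas in pixels.
#' @param n_candidates candidate scenes for mean-chromaticity selection.
#' @param n_rects rectangles per candidate scene.
#' @param basis LED basis used for illuminant synthesis.
#' @param reflectances a `reflectance_set`.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(seed,
                              dialect = c("simulated", "real"),
                              variant = c("neutral", "reddish_blue",
                                          "yellowish_green"),
                              observer = weibull_observer(10, 3),
                              n_observers = 10,
                              blocks = NULL,
                              directions = c("blue", "yellow", "red", "green"),
                              dims = c(128, 128),
                              n_candidates = 20,
                              n_rects = 2000,
                              basis = make_led_basis(),
                              reflectances = default_reflectance_set()) {
  dialect <- match.arg(dialect)
  variant <- match.arg(variant)
  if (missing(seed)) stop("a seed is mandatory")
  min_level <- if (dialect == "real") 0 else 1
  if (is.null(blocks)) blocks <- if (dialect == "real") 1 else 2
  structure(list(
    seed = as.integer(seed), dialect = dialect, variant = variant,
    observer = observer, n_observers = n_observers, blocks = blocks,
    directions = directions, dims = dims, n_candidates = n_candidates,
    n_rects = n_rects, basis = basis, reflectances = reflectances,
    staircase = staircase_config(min_level = min_level),
    interval_ms = if (dialect == "real") c(target = 2000, candidate = 500,
                                           gap = 400)
                  else c(target = 2000, candidate = 670, gap = 400)),
    class = "experiment_config")
}

# Named substream seeds derived from one root seed (kept below 2^31).
.stage_seed <- function(root, stage, k = 0) {
  offs <- c(scene = 104729L, staircase = 224737L, observer = 350377L)
  (as.integer(root) + offs[[stage]] + 1009L * as.integer(k)) %% .Machine$integer.max
}

#' Build the experiment's scene by candidate selection
#'
#' Generates candidate Mondrian scenes with the variant's sampling bias and
#' selects the one whose mean chromaticity under the target illumination is
#' closest to the variant's target chromaticity.
#'
#' @param cfg an [experiment_config()].
#' @param target_illum target illuminant; default the D67 metamer is fit from
#'   the configured basis.
#' @return A `mondrian_scene`.
#' @export
make_scene <- function(cfg, target_illum = NULL) {
  if (is.null(target_illum)) {
    target_illum <- fit_weights(daylight_spectrum(6700), cfg$basis)$fitted
  }
  set.seed(.stage_seed(cfg$seed, "scene"))
  bias <- ensemble_bias(cfg$reflectances, cfg$variant)
  candidates <- lapply(seq_len(cfg$n_candidates), function(i) {
    generate_mondrian(cfg$dims, n_rects = cfg$n_rects,
                      set = cfg$reflectances, bias = bias)
  })
  select_scene(candidates, variant_targets()[[cfg$variant]], target_illum)
}

#' Run the full synthetic experiment
#'
#' Generates the four comparison series, builds the scene, runs every
#' observer through the configured number of blocks of twelve interleaved
#' staircases, bins and fits each direction's trials, and aggregates
#' thresholds. Deterministic given the config seed.
#'
#' @param cfg an [experiment_config()].
#' @param series_list optional precomputed series (they are deterministic
#'   given the basis, so recomputation is pure cost).
#' @param scene optional precomputed scene.
#' @return list(config, series_list, scene, trials, fits, thresholds,
#'   group_summary, excluded).
#' @export
run_experiment <- function(cfg, series_list = NULL, scene = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (is.null(series_list)) {
    series_list <- lapply(stats::setNames(cfg$directions, cfg$directions),
                          function(d) generate_series(d, cfg$basis))
  }
  if (is.null(scene)) scene <- make_scene(cfg, series_list[[1]]$target)
  trials <- list()
  fit_rows <- list()
  for (o in seq_len(cfg$n_observers)) {
    for (b in seq_len(cfg$blocks)) {
      set.seed(.stage_seed(cfg$seed, "staircase",
                           k = (o - 1) * cfg$blocks + b))
      rec <- run_block(series_list, cfg$observer, cfg$staircase,
                       scene = scene)
      rec$observer <- o
      rec$block <- b
      trials[[length(trials) + 1]] <- rec
      for (d in cfg$directions) {
        f <- fit_weibull(bin_trials(rec[rec$direction == d, ]))
        fit_rows[[length(fit_rows) + 1]] <- data.frame(
          observer = o, block = b, direction = d,
          alpha = f$alpha, beta = f$beta, lapse = f$lapse,
          threshold = f$threshold, valid = f$valid)
      }
    }
  }
  trials <- do.call(rbind, trials)
  fits <- do.call(rbind, fit_rows)
  agg <- aggregate_observer(fits)
  list(config = cfg, series_list = series_list, scene = scene,
       trials = trials, fits = fits,
       thresholds = agg$observer_thresholds,
       group_summary = agg$group_summary,
       excluded = agg$excluded)
}

#' Write an experiment bundle to a directory
#'
#' Emits trials.csv, thresholds.csv (per block), observer_thresholds.csv,
#' group_summary.csv and one series table per direction.
#'
#' @param bundle result of [run_experiment()].
#' @param dir output directory.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$fits, file.path(dir, "thresholds.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$thresholds,
                   file.path(dir, "observer_thresholds.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$group_summary, file.path(dir, "group_summary.csv"),
                   row.names = FALSE)
  for (d in names(bundle$series_list)) {
    utils::write.csv(bundle$series_list[[d]]$table,
                     file.path(dir, paste0("series_", d, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Surface-ensemble manipulation: thresholds per scene variant
#'
#' Runs the full pipeline once per scene variant with a common mechanistic
#' observer and returns the scene x direction threshold matrix together with
#' per-direction interaction contrasts (threshold differences relative to the
#' neutral scene).
#'
#' @param cfg an [experiment_config()] whose observer is mechanistic.
#' @param variants scene variants to run.
#' @return list(thresholds = data.frame(variant, direction, mean, sem, n),
#'   contrasts = data.frame of per-direction differences vs neutral).
#' @export
replicate_scene_effect <- function(cfg,
                                   variants = c("neutral", "reddish_blue",
                                                "yellowish_green")) {
  if (!inherits(cfg$observer, "mechanistic_observer")) {
    stop("the ensemble manipulation requires a mechanistic observer ",
         "(a Weibull observer never sees the scene)")
  }
  series_list <- lapply(stats::setNames(cfg$directions, cfg$directions),
                        function(d) generate_series(d, cfg$basis))
  rows <- list()
  for (v in variants) {
    vcfg <- cfg
    vcfg$variant <- v
    bundle <- run_experiment(vcfg, series_list = series_list)
    g <- bundle$group_summary
    g$variant <- v
    rows[[v]] <- g
  }
  thr <- do.call(rbind, rows)
  rownames(thr) <- NULL
  contrasts <- NULL
  if ("neutral" %in% variants) {
    base <- thr[thr$variant == "neutral", c("direction", "mean")]
    names(base)[2] <- "neutral_mean"
    contrasts <- merge(thr[thr$variant != "neutral", ], base,
                       by = "direction")
    contrasts$delta_vs_neutral <- contrasts$mean - contrasts$neutral_mean
  }
  list(thresholds = thr, contrasts = contrasts)
}
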