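# The adaptive 1-up-2-down procedure: step schedule 15/10/5/3/1 advancing at
# each of the first four reversals, termination at the sixth reversal or 50
# trials, twelve interleaved tracks (three per chromatic direction).

#' Staircase configuration
#'
#' @param start_ranges list of three integer ranges for the random starting
#'   level of the three staircases per direction.
#' @param steps step-size schedule; entry k applies after k-1 reversals
#'   (frozen from the fifth reversal on).
#' @param max_trials per-staircase trial cap.
#' @param reversal_limit reversals at which a staircase terminates.
#' @param min_level,max_level level range (nominal colour-difference units);
#'   min_level 0 in the real-scene dialect, 1 in the simulated-scene dialect.
#' @return Object of class `staircase_config`.
#' @export
staircase_config <- function(start_ranges = list(11:20, 21:30, 31:40),
                             steps = c(15, 10, 5, 3, 1),
                             max_trials = 50, reversal_limit = 6,
                             min_level = 0, max_level = 50) {
  stopifnot(length(steps) == 5, length(start_ranges) == 3,
            min_level < max_level)
  for (r in start_ranges) {
    if (min(r) < min_level || max(r) > max_level) {
      stop("start range outside level range")
    }
  }
  structure(list(start_ranges = start_ranges, steps = steps,
                 max_trials = max_trials, reversal_limit = reversal_limit,
                 min_level = min_level, max_level = max_level),
            class = "staircase_config")
}

#' Initialize a staircase at a starting level
#'
#' @param start_level integer starting level.
#' @param config a [staircase_config()].
#' @return Object of class `staircase_state`.
#' @export
staircase_init <- function(start_level, config = staircase_config()) {
  stopifnot(start_level >= config$min_level, start_level <= config$max_level)
  structure(list(level = as.integer(start_level), consec_correct = 0L,
                 reversals = 0L, trials = 0L, last_direction = 0L,
                 done = FALSE, config = config,
                 history = list()),
            class = "staircase_state")
}

#' Update a staircase with one response
#'
#' Two consecutive correct responses move the level down by the current step
#' (and reset the counter); one incorrect response moves it up. A reversal is
#' logged when the induced movement direction differs from the previous
#' nonzero movement; movements clamped to no level change do not count. The
#' step size advances through the schedule at each of the first four
#' reversals. The staircase terminates at the sixth reversal or the fiftieth
#' trial.
#'
#' @param state a `staircase_state`.
#' @param correct logical response.
#' @return The updated `staircase_state`.
#' @export
staircase_update <- function(state, correct) {
  if (state$done) stop("staircase is finished; no further updates allowed")
  cfg <- state$config
  state$trials <- state$trials + 1L
  state$history[[state$trials]] <- c(level = state$level,
                                     correct = as.integer(correct))
  move <- 0L
  if (correct) {
    state$consec_correct <- state$consec_correct + 1L
    if (state$consec_correct == 2L) {
      move <- -1L
      state$consec_correct <- 0L
    }
  } else {
    move <- 1L
    state$consec_correct <- 0L
  }
  if (move != 0L) {
    step <- cfg$steps[min(state$reversals, 4L) + 1L]
    new_level <- max(cfg$min_level,
                     min(cfg$max_level, state$level + move * step))
    if (new_level != state$level) {
      if (state$last_direction != 0L && move != state$last_direction) {
        state$reversals <- state$reversals + 1L
      }
      state$last_direction <- move
      state$level <- as.integer(new_level)
    }
  }
  if (state$reversals >= cfg$reversal_limit ||
      state$trials >= cfg$max_trials) {
    state$done <- TRUE
  }
  state
}

#' Run one block of twelve interleaved staircases
#'
#' Three staircases per chromatic direction, starting levels drawn from the
#' configured ranges, interleaved by uniform random choice among unfinished
#' staircases. Each trial looks up the achieved colour difference of the
#' staircase's current nominal level in the direction's comparison series and
#' queries the observer.
#'
#' @param series_list named list of `comparison_series`, one per direction.
#' @param observer an observer object.
#' @param config a [staircase_config()].
#' @param scene a `mondrian_scene` (required for mechanistic observers).
#' @return data.frame of trial records: direction, staircase_id, trial_index,
#'   nominal_de, achieved_de, response (1 = correct).
#' @export
run_block <- function(series_list, observer, config = staircase_config(),
                      scene = NULL) {
  dirs <- names(series_list)
  stopifnot(length(dirs) >= 1, !is.null(dirs))
  summaries <- NULL
  if (inherits(observer, "mechanistic_observer")) {
    if (is.null(scene)) stop("mechanistic observer requires a scene")
    summaries <- lapply(series_list, function(se) {
      scene_summaries(scene, se, strategy = observer$strategy,
                      tracked_surface = observer$tracked_surface)
    })
  }
  tracks <- list()
  for (d in dirs) {
    for (j in 1:3) {
      start <- sample(config$start_ranges[[j]], 1)
      tracks[[paste0(d, "_", j)]] <- list(
        direction = d, id = paste0(d, "_", j),
        state = staircase_init(start, config))
    }
  }
  rec <- list()
  t_idx <- 0
  repeat {
    open <- which(!vapply(tracks, function(tr) tr$state$done, logical(1)))
    if (length(open) == 0) break
    k <- if (length(open) == 1) open else sample(open, 1)
    tr <- tracks[[k]]
    level <- tr$state$level
    se <- series_list[[tr$direction]]
    # series index: nominal level k is entry k+1
    idx <- level + 1L
    if (idx < 1L || idx > length(se$achieved_de)) {
      stop("staircase level ", level, " outside the series range")
    }
    de <- se$achieved_de[idx]
    correct <- if (inherits(observer, "weibull_observer")) {
      simulate_trial(observer, de = de)
    } else {
      ss <- summaries[[tr$direction]]
      simulate_trial(observer, target_summary = ss$target,
                     comparison_summary = ss$comparisons[idx, ])
    }
    tracks[[k]]$state <- staircase_update(tr$state, correct)
    t_idx <- t_idx + 1
    rec[[t_idx]] <- data.frame(direction = tr$direction,
                               staircase_id = tr$id,
                               trial_index = t_idx,
                               nominal_de = level,
                               achieved_de = de,
                               response = as.integer(correct))
  }
  out <- do.call(rbind, rec)
  attr(out, "states") <- lapply(tracks, function(tr) tr$state)
  out
}
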