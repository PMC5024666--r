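# Shared fixtures, memoized across test files: the LED basis, the four
# comparison series and a small Mondrian scene are expensive enough that
# recomputing them per test would dominate the suite's runtime.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, make) {
  if (is.null(.fx[[key]])) .fx[[key]] <- make()
  .fx[[key]]
}

fx_basis <- function() fx_memo("basis", make_led_basis)

fx_target <- function() {
  fx_memo("target", function() {
    fit_weights(daylight_spectrum(6700), fx_basis())$fitted
  })
}

fx_series <- function(direction) {
  fx_memo(paste0("series_", direction), function() {
    generate_series(direction, fx_basis())
  })
}

fx_all_series <- function() {
  dirs <- c("blue", "yellow", "red", "green")
  stats::setNames(lapply(dirs, fx_series), dirs)
}

# A small but fully covered scene on the default 16-surface ensemble.
fx_scene <- function() {
  fx_memo("scene", function() {
    set.seed(424242)
    generate_mondrian(c(48, 48), n_rects = 400)
  })
}

# Bernoulli trial records at a constant percent correct over given levels.
make_records <- function(de, p, seed = 1) {
  set.seed(seed)
  data.frame(achieved_de = de, response = as.integer(stats::runif(length(de)) < p))
}
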