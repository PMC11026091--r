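# Shared fixtures, built once per test run and cached.

.fix_env <- new.env(parent = emptyenv())

# small rendered experiment: 3 channels (1 empty) x 40 frames
small_experiment <- function() {
  if (is.null(.fix_env$small)) {
    set.seed(7)
    sp <- sim_params(seed = 7)
    .fix_env$small <- simulate_experiment(sp, n_channels = 3, n_frames = 40,
                                          n_empty = 1)
  }
  .fix_env$small
}

# the small experiment run through the full pipeline
small_pipeline <- function() {
  if (is.null(.fix_env$small_pipe)) {
    ex <- small_experiment()
    .fix_env$small_pipe <- suppressWarnings(run_pipeline(list(phase = ex$phase)))
  }
  .fix_env$small_pipe
}

# the end-to-end fixture: 5 occupied channels (+1 empty template) x 300
# frames at the default easy-contrast render
acceptance_fixture <- function() {
  if (is.null(.fix_env$accept)) {
    set.seed(101)
    sp <- sim_params(seed = 101)
    ex <- simulate_experiment(sp, n_channels = 6, n_frames = 300, n_empty = 1)
    res <- suppressWarnings(run_pipeline(list(phase = ex$phase)))
    .fix_env$accept <- list(ex = ex, res = res,
                            cal = list(pixel_size = sp$pixel_size,
                                       frame_interval = sp$frame_interval))
  }
  .fix_env$accept
}
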