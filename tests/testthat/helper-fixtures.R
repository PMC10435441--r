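# Shared fixtures, built lazily once per test session.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# short, quiet run for signal-level tests
short_run <- function(seed = 1, ...) {
  generate_run(run_profile(duration_s = 600, film_onset_s = 240, ...),
               seed = seed)
}

# the acceptance-scale cohort: 24 runs, ~22 min, default profile
acceptance_runs <- function() {
  fixture("acceptance_runs", function() {
    lapply(1:24, function(i) generate_run(run_profile(), seed = i))
  })
}

expect_close <- function(x, y, tol) expect_lt(abs(x - y), tol)
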