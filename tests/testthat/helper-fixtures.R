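# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small but fully structured recording: 40 neurons, 2 min dark + 3 trials
small_dataset <- function() cached("small", generate_dataset(
  simulation_config(n_neurons = 40, sa_duration_s = 120, n_trials = 3,
                    noise_sd = 0.05, seed = 7)))

small_epochs <- function() cached("small_ep", {
  d <- small_dataset()
  segment_epochs(d$stimulus_log, d$frame_rate_hz, ncol(d$traces), d$sa_end_frame)
})

# low-noise recording for recovery tests
lownoise_dataset <- function() cached("lownoise", generate_dataset(
  simulation_config(n_neurons = 60, sa_duration_s = 400, n_trials = 2,
                    noise_sd = 0.01, assembly_event_rate_hz = 0.03, seed = 11)))

# all-neurons-active fixture rendered as a movie (detection tests)
movie_fixture <- function() cached("movie", {
  d <- generate_dataset(simulation_config(
    n_neurons = 30, sa_duration_s = 240, n_trials = 1, noise_sd = 0.02,
    sa_member_fraction = 1, n_sa_assemblies = 6,
    assembly_event_rate_hz = 0.05, seed = 5))
  mv <- suppressWarnings(generate_movie(d, frames = seq_len(d$sa_end_frame),
                                        seed = 3))
  mv$dataset <- d
  mv
})

# random orthonormal basis, N x K
random_basis <- function(n, k, seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(n * k), n, k)))
}
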