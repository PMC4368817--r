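# Shared fixtures, built lazily and memoized so expensive forward solves run
# once per test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# the study conditions used throughout: default schedule, Bateman rates with
# a ~3 min intravascular peak and slow clearance, wall ramp with 60 s delay
# and 300 s rise to 0.008 um^2/s
default_pk <- function() pk_params(k_a = 0.02, k_e = 0.0005)

default_wall <- function(t_ep = 1030)
  wall_permeability(t_ep = t_ep, t_del = t_ep + 60, t_sat = t_ep + 360,
                    d_sat = 0.008)

noiseless_ep_dataset <- function() {
  fixture("noiseless_ep", function() {
    sch <- make_schedule()
    truth <- ground_truth(default_pk(), default_wall(sch$t_ep), d_tiss = 30,
                          background = 100, noise_cv = 0, gain = 2.5,
                          seed = 11L)
    simulate_trace(sch, truth)
  })
}

noiseless_control_dataset <- function() {
  fixture("noiseless_control", function() {
    sch <- make_schedule()
    truth <- ground_truth(default_pk(), wall = NULL, d_tiss = 30,
                          background = 100, noise_cv = 0, gain = 2.5,
                          seed = 11L)
    simulate_trace(sch, truth)
  })
}

normalized_ep_trace <- function() {
  fixture("normalized_ep_trace", function()
    normalize_trace(subtract_background(noiseless_ep_dataset()$trace)))
}

ep_fit_context <- function() {
  fixture("ep_fit_context", function() {
    pk_hat <- fit_pk(normalized_ep_trace())
    fit_context(pk_hat, t_fd = 300, t_ep = 1030, d_tiss = 30)
  })
}

# reduced-budget GA settings for desk-scale test runs; the search space and
# operators are the defaults, only the population/generation budget shrinks
quick_ga <- function(seed = 1L, pop = 24L, gens = 40L, stall = 12L)
  ga_config(pop_size = pop, generations = gens, seed = seed,
            stall_generations = stall)
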