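# Shared fixtures. Expensive objects (a full synthetic flight) are built once
# per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

test_rig <- function() cached("rig", function() standard_rig(center = c(0.3, 0, 0.35)))

test_flight <- function() cached("flight", function() {
  simulate_flight(flight_sim_config(seed = 1L))
})

# a fast flight for tests that only need structure, not realism
small_flight <- function() cached("small_flight", function() {
  simulate_flight(flight_sim_config(n_wingbeats = 2, wingbeat_frequency = 5,
                                    seed = 1L))
})

# constant-acceleration truth track
ca_track <- function(n = 120, frame_rate = 240,
                     p0 = c(0.1, -0.2, 0.3), v0 = c(1, -0.5, 0.8),
                     a0 = c(2, 1, -3)) {
  t <- (seq_len(n) - 1) / frame_rate
  list(t = t,
       pos = cbind(p0[1] + v0[1] * t + a0[1] * t^2 / 2,
                   p0[2] + v0[2] * t + a0[2] * t^2 / 2,
                   p0[3] + v0[3] * t + a0[3] * t^2 / 2),
       vel = cbind(v0[1] + a0[1] * t, v0[2] + a0[2] * t, v0[3] + a0[3] * t),
       acc = matrix(a0, n, 3, byrow = TRUE))
}

# straight-line trajectory with given constant velocity
straight_trajectory <- function(v, n = 120, frame_rate = 240) {
  t <- (seq_len(n) - 1) / frame_rate
  pos <- cbind(v[1] * t, v[2] * t, v[3] * t)
  smoothed_trajectory(pos, matrix(v, n, 3, byrow = TRUE),
                      matrix(0, n, 3), frame_rate)
}

star_tree7 <- function() ape::read.tree(
  text = "(A:1,B:1,C:1,D:1,E:1,F:1,G:1);")

# default metric table with all SDs set to zero (degenerate-variance cases)
.default_metric_table_zero_sd <- function() {
  tab <- cohort_design()$metric_table
  tab$canopy_sd <- 0
  tab$understory_sd <- 0
  tab
}
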