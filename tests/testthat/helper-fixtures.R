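# Shared fixtures: the published parameter estimates used as simulation
# ground truth, plus small trajectory builders.

table2_truth <- function() {
  allo_params(a0 = 0.03, b = 0.12, E = 0.37, E_h = 3.11, t_opt = 26.33)
}

# trajectory moving at a constant speed (mm/s) along +x
straight_trajectory <- function(speed_mm_s, duration = 10, dt = 1 / 38) {
  t <- seq(0, duration, by = dt)
  data.frame(t = t, x = speed_mm_s * t, y = 0)
}

# trajectory realising a prescribed per-frame speed series (dt = 1 s)
trajectory_from_speeds <- function(speeds, dt = 1) {
  x <- cumsum(c(0, speeds * dt))
  data.frame(t = seq_along(x) - 1, x = x, y = 0)
}

small_design <- function(n = 42) {
  study_design(n_individuals = n, n_species = 4)
}
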