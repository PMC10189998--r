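#' Study design for the synthetic-data generator
#'
#' Defaults emulate the experimental design the analysis assumes: 125
#' individuals of 8 species spanning 10-303 mg, measured one individual per
#' session across a 14-level temperature gradient from 8 to 32 degC with 3
#' records per temperature level per pass.
#'
#' @param n_individuals Total individuals (default 125).
#' @param n_species Number of species / log-spaced size classes (default 8).
#' @param mass_range `c(min, max)` body mass in mg (default `c(10, 303)`).
#' @param temperature_levels Chamber temperatures in degC (default 14 evenly
#'   spaced values from 8 to 32).
#' @param records_per_level Consecutive records taken per temperature level
#'   before moving to the next (default 3).
#' @return List of class `study_design`.
#' @export
study_design <- function(n_individuals = 125, n_species = 8,
                         mass_range = c(10, 303),
                         temperature_levels = seq(8, 32, length.out = 14),
                         records_per_level = 3) {
  stopifnot(n_individuals >= n_species, all(mass_range > 0),
            mass_range[1] < mass_range[2],
            all(temperature_levels >= 0 & temperature_levels <= 60),
            records_per_level >= 1)
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_species = as.integer(n_species),
    mass_range = mass_range,
    temperature_levels = temperature_levels,
    records_per_level = as.integer(records_per_level)
  ), class = "study_design")
}

#' Noise model for synthetic speed observations
#'
#' @param kind `"lognormal"` (multiplicative, keeps speeds positive; the
#'   default) or `"gaussian"` (additive).
#' @param sigma Dispersion: sdlog of the multiplicative factor for lognormal
#'   noise (default 0.30), or the additive sd in m/s for gaussian noise.
#' @param species_effect_sd Standard deviation (m/s) of an additive
#'   per-species offset; default 0 (no species-specific effect beyond mass).
#' @return List of class `noise_model`.
#' @export
noise_model <- function(kind = c("lognormal", "gaussian"), sigma = 0.30,
                        species_effect_sd = 0) {
  kind <- match.arg(kind)
  stopifnot(sigma >= 0, species_effect_sd >= 0)
  structure(list(kind = kind, sigma = sigma,
                 species_effect_sd = species_effect_sd),
            class = "noise_model")
}

#' Table-2-style default ground truth
#'
#' The combined-model parameter vector used as the generator's default truth:
#' a0 = 0.03 m/s, b = 0.12, E = 0.37 eV, E_h = 3.11 eV, t_opt = 26.33 degC.
#'
#' @return An [allo_params()] vector.
#' @export
default_truth <- function() {
  allo_params(a0 = 0.03, b = 0.12, E = 0.37, E_h = 3.11, t_opt = 26.33)
}

with_local_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a per-individual speed table from the combined model
#'
#' Assigns species to log-spaced mass classes spanning the design's mass
#' range, jitters individual masses log-uniformly within class, walks the
#' temperature levels in blocks of `records_per_level`, and draws each
#' observed speed around the model expectation `eval_allo_tpc(truth, M, T)`
#' under the noise model. For lognormal noise the observation is
#' `expectation * exp(N(0, sigma^2))`, so the conditional *mean* of generated
#' speeds is `expectation * exp(sigma^2 / 2)`, not the expectation itself.
#'
#' @param design A [study_design()].
#' @param truth An [allo_params()] ground-truth vector (default
#'   [default_truth()]).
#' @param noise A [noise_model()].
#' @param seed Integer seed; identical inputs give byte-identical tables.
#' @return Data.frame with `individual_id`, `species`, `habitat_group`,
#'   `mass` (mg), `temperature` (degC), `speed` (m/s).
#' @examples
#' head(generate_speed_dataset(study_design(), seed = 1))
#' @export
generate_speed_dataset <- function(design = study_design(),
                                   truth = default_truth(),
                                   noise = noise_model(), seed = 1) {
  stopifnot(inherits(design, "study_design"), inherits(noise, "noise_model"))
  with_local_seed(seed, {
    n <- design$n_individuals
    ns <- design$n_species
    # temperature schedule: each level repeated records_per_level times,
    # cycled until every individual has a session
    sched <- rep(design$temperature_levels, each = design$records_per_level)
    temperature <- rep_len(sched, n)
    species_idx <- rep_len(seq_len(ns), n)
    # log-spaced mass-class boundaries; individual masses log-uniform in class
    bounds <- exp(seq(log(design$mass_range[1]), log(design$mass_range[2]),
                      length.out = ns + 1))
    lo <- bounds[species_idx]
    hi <- bounds[species_idx + 1]
    mass <- exp(stats::runif(n, log(lo), log(hi)))
    species <- sprintf("sp%02d", species_idx)
    habitat_pool <- rep_len(c("forest", "open", "riparian"), ns)
    habitat_group <- habitat_pool[species_idx]
    expected <- eval_allo_tpc(truth, mass, temperature)
    sp_shift <- if (noise$species_effect_sd > 0) {
      stats::rnorm(ns, 0, noise$species_effect_sd)[species_idx]
    } else 0
    speed <- if (noise$kind == "lognormal") {
      expected * exp(stats::rnorm(n, 0, noise$sigma)) + sp_shift
    } else {
      expected + stats::rnorm(n, 0, noise$sigma) + sp_shift
    }
    speed <- pmax(speed, 0)
    data.frame(
      individual_id = sprintf("ind%03d", seq_len(n)),
      species = species,
      habitat_group = habitat_group,
      mass = mass,
      temperature = temperature,
      speed = speed,
      stringsAsFactors = FALSE
    )
  })
}

#' Random-walk configuration for synthetic arena trajectories
#'
#' @param arena_radius Arena radius in mm (default 245, i.e. a 490 mm
#'   diameter circular arena).
#' @param frame_rate Frames per second (default 38).
#' @param duration Recording length in seconds (default 3600, one hour).
#' @param move_to_pause_prob Per-frame probability of stopping a movement
#'   bout (default 0.005, mean bout length ~5 s).
#' @param pause_to_move_prob Per-frame probability of resuming movement
#'   (default 0.02, mean pause ~1.3 s).
#' @param turning_sd Wrapped-normal heading increment sd per frame while
#'   moving (rad, default 0.3).
#' @param within_bout_speed_cv Coefficient of variation of per-frame speeds
#'   inside a bout (default 0.2).
#' @param pause_jitter_max Maximum jitter speed while paused, in mm/s
#'   (default 0.25; stays below the 0.3 mm/s stop threshold, emulating the
#'   sub-threshold position noise of inactive animals).
#' @return List of class `walk_config`.
#' @export
walk_config <- function(arena_radius = 245, frame_rate = 38, duration = 3600,
                        move_to_pause_prob = 0.005, pause_to_move_prob = 0.02,
                        turning_sd = 0.3, within_bout_speed_cv = 0.2,
                        pause_jitter_max = 0.25) {
  stopifnot(arena_radius > 0, frame_rate > 0, duration > 0,
            move_to_pause_prob >= 0, move_to_pause_prob <= 1,
            pause_to_move_prob >= 0, pause_to_move_prob <= 1,
            turning_sd >= 0, within_bout_speed_cv >= 0, pause_jitter_max >= 0)
  structure(list(
    arena_radius = arena_radius, frame_rate = frame_rate, duration = duration,
    move_to_pause_prob = move_to_pause_prob,
    pause_to_move_prob = pause_to_move_prob,
    turning_sd = turning_sd, within_bout_speed_cv = within_bout_speed_cv,
    pause_jitter_max = pause_jitter_max
  ), class = "walk_config")
}

# Two-state (move/pause) sequence as alternating geometric run lengths; the
# initial state is drawn from the chain's stationary distribution.
simulate_states <- function(n_frames, p_stop, p_go) {
  states <- logical(0)
  moving <- if (p_stop + p_go > 0) {
    stats::runif(1) < p_go / (p_stop + p_go)
  } else TRUE
  while (length(states) < n_frames) {
    p <- if (moving) p_stop else p_go
    run <- if (p <= 0) n_frames - length(states) else stats::rgeom(1, p) + 1L
    run <- min(run, n_frames - length(states))
    states <- c(states, rep(moving, run))
    moving <- !moving
  }
  states
}

#' Generate one synthetic arena trajectory
#'
#' Two-state correlated random walk standing in for the camera pipeline's
#' output: while "moving", per-frame speeds are lognormal around
#' `target_speed` (mean-calibrated) and the heading performs a wrapped-normal
#' random walk; while "paused", the position jitters at sub-threshold speeds.
#' The walk reflects off the circular arena wall.
#'
#' @param cfg A [walk_config()].
#' @param target_speed Intended within-bout mean speed in m/s (> 0).
#' @param seed Integer seed.
#' @return Trajectory data.frame (`t` s, `x` mm, `y` mm) with every point
#'   inside the arena.
#' @export
generate_trajectory <- function(cfg = walk_config(), target_speed, seed = 1) {
  stopifnot(inherits(cfg, "walk_config"), target_speed > 0)
  v_mm <- target_speed * 1000
  dt <- 1 / cfg$frame_rate
  if (v_mm * dt >= 2 * cfg$arena_radius) {
    stop("target_speed crosses the arena in under two frames; reduce it")
  }
  n_steps <- max(1L, as.integer(round(cfg$duration * cfg$frame_rate)))
  with_local_seed(seed, {
    moving <- simulate_states(n_steps, cfg$move_to_pause_prob,
                              cfg$pause_to_move_prob)
    # mean-calibrated lognormal per-frame speeds within bouts
    cv <- cfg$within_bout_speed_cv
    sdlog <- sqrt(log(1 + cv^2))
    speed <- numeric(n_steps)
    nm <- sum(moving)
    speed[moving] <- v_mm * exp(stats::rnorm(nm, -sdlog^2 / 2, sdlog))
    speed[!moving] <- stats::runif(n_steps - nm, 0, cfg$pause_jitter_max)
    step_len <- speed * dt
    dhead <- numeric(n_steps)
    dhead[moving] <- stats::rnorm(nm, 0, cfg$turning_sd)
    dhead[!moving] <- stats::runif(n_steps - nm, -pi, pi)
    heading <- cumsum(c(stats::runif(1, 0, 2 * pi), dhead))[-1]
    R <- cfg$arena_radius
    x <- numeric(n_steps + 1)
    y <- numeric(n_steps + 1)
    # start away from the wall
    r0 <- sqrt(stats::runif(1)) * R * 0.5
    a0 <- stats::runif(1, 0, 2 * pi)
    x[1] <- r0 * cos(a0)
    y[1] <- r0 * sin(a0)
    off <- 0
    for (i in seq_len(n_steps)) {
      h <- heading[i] + off
      xi <- x[i] + step_len[i] * cos(h)
      yi <- y[i] + step_len[i] * sin(h)
      r <- sqrt(xi^2 + yi^2)
      if (r > R) {
        # mirror the overshoot back across the wall and reflect the heading
        # about the tangent so the walk leaves the wall
        psi <- atan2(yi, xi)
        scale <- (2 * R - r) / r
        xi <- xi * scale
        yi <- yi * scale
        off <- off + (2 * psi + pi - 2 * h)
      }
      x[i + 1] <- xi
      y[i + 1] <- yi
    }
    data.frame(t = seq(0, by = dt, length.out = n_steps + 1), x = x, y = y)
  })
}

#' Generate a full synthetic study: trajectories plus metadata
#'
#' Draws a speed table with [generate_speed_dataset()] and, for every
#' individual, a trajectory whose within-bout speed targets that individual's
#' drawn speed, so that running the filter pipeline and then [fit_allo_tpc()]
#' approximately recovers the generating parameters.
#'
#' @param design A [study_design()].
#' @param truth An [allo_params()] truth vector.
#' @param noise A [noise_model()].
#' @param walk_cfg A [walk_config()].
#' @param seed Integer seed (drives both the speed draws and the walks).
#' @param out_dir Optional directory; when given, writes one `<id>.csv`
#'   trajectory file per individual plus `metadata.csv`, and returns the
#'   paths invisibly. Default NULL returns everything in memory.
#' @return List with `trajectories` (named list of data.frames), `metadata`
#'   (columns `id`, `species`, `habitat_group`, `mass_mg`, `temperature_C`)
#'   and `target_speeds` (the drawn speeds the walks aim for).
#' @export
generate_study <- function(design = study_design(), truth = default_truth(),
                           noise = noise_model(), walk_cfg = walk_config(),
                           seed = 1, out_dir = NULL) {
  speeds <- generate_speed_dataset(design, truth, noise, seed = seed)
  trajs <- lapply(seq_len(nrow(speeds)), function(i) {
    generate_trajectory(walk_cfg, target_speed = speeds$speed[i],
                        seed = seed + 7919L * i)
  })
  names(trajs) <- speeds$individual_id
  metadata <- data.frame(
    id = speeds$individual_id,
    species = speeds$species,
    habitat_group = speeds$habitat_group,
    mass_mg = speeds$mass,
    temperature_C = speeds$temperature,
    stringsAsFactors = FALSE
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(trajs)) {
      tr <- trajs[[id]]
      utils::write.csv(cbind(id = id, tr), file.path(out_dir, paste0(id, ".csv")),
                       row.names = FALSE)
    }
    utils::write.csv(metadata, file.path(out_dir, "metadata.csv"),
                     row.names = FALSE)
  }
  list(trajectories = trajs, metadata = metadata,
       target_speeds = speeds$speed)
}
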