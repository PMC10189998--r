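#' Speed-threshold filter configuration
#'
#' Hysteresis thresholds (mm/s) separating active movement from the spurious
#' sub-millimetre position jitter that image tracking records for inactive
#' animals: a movement bout starts when the per-frame speed reaches `v_start`
#' and stops when it falls below `v_stop`.
#'
#' @param v_start Start threshold in mm/s (default 0.6).
#' @param v_stop Stop threshold in mm/s (default 0.3); must not exceed
#'   `v_start`.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(v_start = 0.6, v_stop = 0.3) {
  if (v_start <= 0 || v_stop <= 0) stop("thresholds must be positive")
  if (v_stop > v_start) {
    stop("v_stop (", v_stop, ") must not exceed v_start (", v_start, ")")
  }
  structure(list(v_start = v_start, v_stop = v_stop), class = "filter_config")
}

validate_trajectory <- function(traj) {
  req <- c("t", "x", "y")
  miss <- setdiff(req, names(traj))
  if (length(miss)) stop("trajectory lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(traj) == 0) stop("trajectory is empty")
  if (any(!is.finite(traj$x)) || any(!is.finite(traj$y)) || any(!is.finite(traj$t))) {
    stop("trajectory contains non-finite coordinates or timestamps")
  }
  dt <- diff(traj$t)
  if (any(dt <= 0)) {
    i <- which(dt <= 0)[1]
    stop("timestamps not strictly increasing at row ", i + 1,
         " (t = ", traj$t[i + 1], ")")
  }
  invisible(traj)
}

#' Per-frame speeds of a trajectory
#'
#' Speed between consecutive frames: Euclidean displacement (mm) divided by
#' the timestamp difference (s). The series has one fewer entry than the
#' trajectory; entry i belongs to the step from frame i to frame i+1.
#'
#' @param traj Data.frame with columns `t` (s, strictly increasing), `x`, `y`
#'   (mm).
#' @param smooth_window Optional centred moving-average window (in frames,
#'   odd) applied to the speed series; 0 (default) disables smoothing.
#' @return Data.frame with `t_mid` (s) and `speed` (mm/s); zero rows for a
#'   single-point trajectory.
#' @examples
#' compute_speeds(data.frame(t = c(0, 1), x = c(0, 3), y = c(0, 4)))
#' @export
compute_speeds <- function(traj, smooth_window = 0) {
  validate_trajectory(traj)
  if (nrow(traj) < 2) {
    return(data.frame(t_mid = numeric(0), speed = numeric(0)))
  }
  dt <- diff(traj$t)
  dist <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  speed <- dist / dt
  if (smooth_window > 1) {
    k <- as.integer(smooth_window)
    if (k %% 2 == 0) stop("smooth_window must be odd")
    speed <- stats::filter(speed, rep(1 / k, k), sides = 2)
    speed <- as.numeric(speed)
    # edges keep the raw values where the window does not fit
    raw <- dist / dt
    speed[is.na(speed)] <- raw[is.na(speed)]
  }
  data.frame(t_mid = traj$t[-nrow(traj)] + dt / 2, speed = speed)
}

#' Segment a speed series into movement bouts (hysteresis rule)
#'
#' A bout opens at the first frame whose speed reaches `v_start` while no bout
#' is open, and closes immediately before the first later frame whose speed
#' falls below `v_stop`; a bout still open at the end of the series closes at
#' the end. The two-threshold rule prevents flicker when speeds hover near a
#' single cutoff.
#'
#' @param speeds Data.frame from [compute_speeds()] (or a bare numeric vector
#'   of speeds in mm/s).
#' @param cfg A [filter_config()].
#' @return Data.frame with one row per bout: `start` (first speed-series index
#'   in the bout, 1-based, inclusive) and `stop` (exclusive). Bouts are
#'   ordered and non-overlapping.
#' @examples
#' segment_bouts(c(0.7, 0.5, 0.4, 0.2, 0.7, 0.1), filter_config())
#' @export
segment_bouts <- function(speeds, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  v <- if (is.data.frame(speeds)) speeds$speed else as.numeric(speeds)
  if (any(!is.finite(v))) stop("speeds must be finite")
  if (any(v < 0)) stop("speeds must be non-negative")
  n <- length(v)
  starts <- integer(0)
  stops <- integer(0)
  open <- FALSE
  start_i <- 0L
  for (i in seq_len(n)) {
    if (!open) {
      if (v[i] >= cfg$v_start) {
        open <- TRUE
        start_i <- i
      }
    } else if (v[i] < cfg$v_stop) {
      starts <- c(starts, start_i)
      stops <- c(stops, i)
      open <- FALSE
    }
  }
  if (open) {
    starts <- c(starts, start_i)
    stops <- c(stops, n + 1L)
  }
  data.frame(start = starts, stop = stops)
}

#' Exploratory speed of one individual
#'
#' Pools all movement bouts of a trajectory: total within-bout path length
#' divided by total within-bout duration, converted from mm/s to m/s. Frames
#' outside bouts (tracking jitter of inactive animals) contribute nothing.
#' An individual that never starts a bout gets `NA`, never zero.
#'
#' @param traj Trajectory data.frame (`t`, `x`, `y`).
#' @param bouts Bout table from [segment_bouts()]; computed from `traj` and
#'   `cfg` when NULL.
#' @param cfg A [filter_config()], used when `bouts` is NULL.
#' @param trim Optional `c(start, end)` window in seconds; only frames with
#'   `t` inside the window are used. Default NULL (whole recording).
#' @param smooth_window Passed to [compute_speeds()].
#' @return Exploratory speed in m/s, or `NA_real_` when no bout occurs.
#' @export
exploratory_speed <- function(traj, bouts = NULL, cfg = filter_config(),
                              trim = NULL, smooth_window = 0) {
  validate_trajectory(traj)
  if (!is.null(trim)) {
    traj <- traj[traj$t >= trim[1] & traj$t <= trim[2], , drop = FALSE]
    if (nrow(traj) < 2) return(NA_real_)
    bouts <- NULL
  }
  if (nrow(traj) < 2) return(NA_real_)
  dt <- diff(traj$t)
  dist <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  if (is.null(bouts)) {
    speeds <- compute_speeds(traj, smooth_window = smooth_window)
    bouts <- segment_bouts(speeds, cfg)
  }
  if (nrow(bouts) == 0) return(NA_real_)
  idx <- unlist(mapply(function(s, e) s:(e - 1L), bouts$start, bouts$stop,
                       SIMPLIFY = FALSE))
  total_dist <- sum(dist[idx])
  total_dur <- sum(dt[idx])
  (total_dist / total_dur) / 1000
}

#' Read a trajectory CSV
#'
#' Expected columns: `id`, `t` (s), `x` (mm), `y` (mm), with a header row.
#'
#' @param path File path.
#' @return Validated trajectory data.frame with attribute `individual_id`.
#' @export
read_trajectory_csv <- function(path) {
  traj <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "t", "x", "y")
  miss <- setdiff(req, names(traj))
  if (length(miss)) stop(path, " lacks columns: ", paste(miss, collapse = ", "))
  out <- traj[, c("t", "x", "y")]
  validate_trajectory(out)
  attr(out, "individual_id") <- as.character(traj$id[1])
  out
}

#' Read an individual-metadata CSV
#'
#' Expected columns: `id`, `species`, `habitat_group`, `mass_mg`,
#' `temperature_C` (header required).
#'
#' @param path File path.
#' @return Data.frame with those columns.
#' @export
read_metadata_csv <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "species", "mass_mg", "temperature_C")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop(path, " lacks columns: ", paste(miss, collapse = ", "))
  if (any(meta$mass_mg <= 0)) stop("mass_mg must be > 0")
  meta
}

#' Exploratory speed for a set of individuals
#'
#' Runs the filter pipeline ([compute_speeds()] -> [segment_bouts()] ->
#' [exploratory_speed()]) for every individual and joins the metadata,
#' producing the per-individual record table the model fits consume.
#'
#' @param trajectories Named list of trajectory data.frames (names are
#'   individual ids), or a directory path containing `<id>.csv` files.
#' @param metadata Metadata data.frame (see [read_metadata_csv()]) or a CSV
#'   path.
#' @param cfg A [filter_config()].
#' @param trim,smooth_window Passed to [exploratory_speed()].
#' @return Data.frame with `individual_id`, `species`, `habitat_group` (if
#'   present), `mass` (mg), `temperature` (degC), `speed` (m/s; NA when the
#'   individual never moved above threshold).
#' @export
track_individuals <- function(trajectories, metadata, cfg = filter_config(),
                              trim = NULL, smooth_window = 0) {
  if (is.character(metadata)) metadata <- read_metadata_csv(metadata)
  if (is.character(trajectories)) {
    files <- list.files(trajectories, pattern = "\\.csv$", full.names = TRUE)
    files <- files[basename(files) != "metadata.csv"]
    trajs <- lapply(files, read_trajectory_csv)
    names(trajs) <- vapply(trajs, attr, "", "individual_id")
    trajectories <- trajs
  }
  ids <- as.character(metadata$id)
  speed <- vapply(ids, function(id) {
    traj <- trajectories[[id]]
    if (is.null(traj)) return(NA_real_)
    exploratory_speed(traj, cfg = cfg, trim = trim,
                      smooth_window = smooth_window)
  }, numeric(1))
  out <- data.frame(
    individual_id = ids,
    species = metadata$species,
    mass = metadata$mass_mg,
    temperature = metadata$temperature_C,
    speed = unname(speed),
    stringsAsFactors = FALSE
  )
  if ("habitat_group" %in% names(metadata)) {
    out$habitat_group <- metadata$habitat_group
    out <- out[, c("individual_id", "species", "habitat_group",
                   "mass", "temperature", "speed")]
  }
  rownames(out) <- NULL
  out
}
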