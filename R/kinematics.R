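# Kinematic event detection and performance-variable extraction.
#
# All quantities are derived from RAW positions by first-order forward
# finite differences; no smoothing is ever applied, because low-pass
# filtering at the cutoffs usual in movement science (10-15 Hz) would erase
# the ~15 ms collision transient that the contact detector relies on.
#
# Index convention: the speed attributed to sample i is the finite
# difference over the interval arriving at i, ||x[i] - x[i-1]|| * rate, and
# the acceleration attributed to sample i is the change in that speed,
# (speed[i] - speed[i-1]) * rate.  With this arrival alignment the
# deceleration caused by an impact between samples c and c+1 first appears
# at acceleration sample c+1, and the contact rule's trailing "- dt" lands
# on c, the last frame before impact.

#' Kinematic detection configuration
#'
#' @param sampling_rate Hz.
#' @param cube_motion_threshold Cube speed (m/s) above which the cube counts
#'   as moving (default 0.04, strict inequality).
#' @param contact_ratio_threshold Fraction of the window's peak deceleration
#'   that defines contact (default 0.4, strict inequality).
#' @param onset_speed_fraction Fraction of the strike-segment peak speed used
#'   to locate the strike before the onset walk-back (default 0.05).
#' @param cube_stop_threshold Cube speed (m/s) below which the cube counts
#'   as stopped (default 0.04, symmetric with the motion threshold).
#' @return A list of class `kinematic_config`.
#' @export
kinematic_config <- function(sampling_rate = 250,
                             cube_motion_threshold = 0.04,
                             contact_ratio_threshold = 0.4,
                             onset_speed_fraction = 0.05,
                             cube_stop_threshold = 0.04) {
  stopifnot(sampling_rate > 0, cube_motion_threshold > 0,
            contact_ratio_threshold > 0, contact_ratio_threshold < 1,
            onset_speed_fraction >= 0, onset_speed_fraction < 1,
            cube_stop_threshold > 0)
  structure(list(sampling_rate = sampling_rate,
                 cube_motion_threshold = cube_motion_threshold,
                 contact_ratio_threshold = contact_ratio_threshold,
                 onset_speed_fraction = onset_speed_fraction,
                 cube_stop_threshold = cube_stop_threshold),
            class = "kinematic_config")
}

kin_error <- function(reason, msg) {
  stop(structure(class = c("strikekin_kin_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), reason = reason)))
}

#' Finite-difference speed of a position series
#'
#' First-order forward difference: `speed[i] = ||position[i+1] -
#' position[i]|| * rate` (Euclidean norm for a multi-column series, absolute
#' difference for a vector). No smoothing is applied. The result has one
#' element fewer than the input.
#'
#' @param position Numeric vector (1D) or matrix with one row per sample.
#' @param sampling_rate Hz.
#' @return Numeric vector of speeds, length `nrow(position) - 1`.
#' @examples
#' finite_diff_speed(c(0, 0.004, 0.008), 250)
#' @export
finite_diff_speed <- function(position, sampling_rate) {
  if (is.null(dim(position))) position <- matrix(position, ncol = 1)
  if (nrow(position) < 2) {
    kin_error("insufficient_data", "need at least 2 samples to differentiate")
  }
  d <- diff(position)
  sqrt(rowSums(d^2)) * sampling_rate
}

# Arrival-aligned speed: element i is the speed with which sample i was
# reached; element 1 is NA.
speed_at <- function(position, sampling_rate) {
  c(NA_real_, finite_diff_speed(position, sampling_rate))
}

#' Detect the onset of cube motion and the pre-motion speed minimum
#'
#' Motion onset is the first sample whose cube speed strictly exceeds the
#' motion threshold. `t_minCS` is the latest sample, between `from` and the
#' onset, at which the cube speed attains its minimum over that window --
#' the minimal cube speed immediately preceding the cube's motion.
#'
#' @param cube_speed Arrival-aligned cube speed series (element i = speed
#'   reaching sample i; element 1 may be NA).
#' @param config A [kinematic_config()].
#' @param from First index considered for the pre-motion minimum (when
#'   composing the contact window this is the fingertip peak-speed sample).
#' @return List with integer sample indices `onset` and `i_min_cs`.
#' @export
detect_cube_motion <- function(cube_speed, config = kinematic_config(),
                               from = 2L) {
  moving <- which(cube_speed > config$cube_motion_threshold)
  if (length(moving) == 0) {
    kin_error("cube_never_moved", "cube speed never exceeds motion threshold")
  }
  onset <- moving[1]
  from <- max(2L, from)
  if (onset < from) {
    kin_error("cube_moved_early",
              "cube motion onset precedes the search window")
  }
  win <- cube_speed[from:onset]
  i_min <- from - 1L + max(which(win == min(win, na.rm = TRUE)))
  list(onset = onset, i_min_cs = i_min)
}

#' Detect the fingertip-cube contact sample
#'
#' Within the window from the fingertip's peak speed (`i_max_fs`) to the
#' minimal pre-motion cube speed (`i_min_cs`), the fingertip acceleration is
#' normalized by the window's most negative value; contact is the sample one
#' step (`dt`) before the first normalized value strictly exceeding the
#' contact ratio threshold. The window minimum itself normalizes to 1, so a
#' crossing always exists when any deceleration is present.
#'
#' @param fingertip_speed Arrival-aligned fingertip speed series.
#' @param i_max_fs,i_min_cs Sample indices bounding the search window.
#' @param config A [kinematic_config()].
#' @return Integer sample index of contact.
#' @export
detect_contact <- function(fingertip_speed, i_max_fs, i_min_cs,
                           config = kinematic_config()) {
  if (i_min_cs < i_max_fs) {
    kin_error("empty_window", "contact window [t_maxFS, t_minCS] is empty")
  }
  idx <- i_max_fs:i_min_cs
  accel <- (fingertip_speed[idx] - fingertip_speed[idx - 1L]) *
    config$sampling_rate
  m <- min(accel, na.rm = TRUE)
  if (!is.finite(m) || m >= 0) {
    kin_error("no_deceleration", "no fingertip deceleration in contact window")
  }
  norm <- accel / m
  hit <- which(norm > config$contact_ratio_threshold)[1]
  idx[hit] - 1L
}

#' Detect strike onset
#'
#' Locates the strike as the first sample, after the last direction reversal
#' toward the cube preceding contact, whose fingertip speed exceeds
#' `onset_speed_fraction` of the strike-segment peak speed; the onset is
#' then walked back to the sample preceding that contiguous run of
#' toward-cube motion (the reversal extremum, where the fingertip is still
#' stationary). The walk-back removes the threshold's dependence on
#' the steepness of the speed profile's rise; on noisy recordings the
#' fraction still guards against drift being mistaken for the strike.
#'
#' @param axial_velocity Arrival-aligned signed fingertip velocity along the
#'   gutter axis (positive toward the cube).
#' @param fingertip_speed Arrival-aligned fingertip speed series.
#' @param i_contact Contact sample index.
#' @param config A [kinematic_config()].
#' @return Integer sample index of strike onset.
#' @export
detect_strike_onset <- function(axial_velocity, fingertip_speed, i_contact,
                                config = kinematic_config()) {
  toward <- axial_velocity > 0
  toward[is.na(toward)] <- FALSE
  upto <- seq_len(i_contact)
  rev_cand <- which(toward[upto][-1] & !toward[upto][-i_contact]) + 1L
  peak <- max(fingertip_speed[upto], na.rm = TRUE)
  if (peak <= 0) kin_error("stationary", "fingertip never moves")
  thr <- config$onset_speed_fraction * peak
  if (length(rev_cand) == 0) {
    # no arming reversal: fall back to the first sample exceeding the
    # speed fraction
    hit <- which(fingertip_speed[upto] > thr)[1]
    if (is.na(hit)) kin_error("no_onset", "no sample exceeds onset threshold")
    return(hit)
  }
  r <- rev_cand[length(rev_cand)]
  hit <- which(fingertip_speed > thr & seq_along(fingertip_speed) >= r)[1]
  if (is.na(hit) || hit > i_contact) {
    kin_error("no_onset", "no post-reversal sample exceeds onset threshold")
  }
  while (hit > r && toward[hit - 1L]) hit <- hit - 1L
  # onset is the last stationary sample (the reversal extremum itself):
  # motion toward the cube happens in the interval (onset, onset + 1]
  max(hit - 1L, 1L)
}

#' Extract performance variables from one trial
#'
#' Runs the full event-detection chain (peak fingertip speed, cube motion
#' onset and pre-motion minimum, contact, strike onset, cube stop) and
#' derives the performance variables: strike duration `D` (onset to
#' contact), strike amplitude `A` (3D chord between the fingertip positions
#' at onset and contact, reported in mm), impact speed `IS` (fingertip speed
#' at contact), the cube stop position (front-edge travel, m) and the
#' signed spatial error as a percentage of the target distance.
#'
#' @param trajectory A `strike_trajectory` (see [synthesize_trial()]).
#' @param condition One row of [build_condition_grid()].
#' @param config A [kinematic_config()]; its sampling rate is overridden by
#'   the trajectory's.
#' @return One-row data.frame with the trial-table schema
#'   (`ground_truth = FALSE`); detected event times (s) are attached as
#'   attribute `"events"`. Detection failures signal a condition of class
#'   `strikekin_kin_error` whose `reason` field codes the exclusion.
#' @export
extract_trial <- function(trajectory, condition,
                          config = kinematic_config()) {
  config$sampling_rate <- trajectory$sampling_rate
  rate <- config$sampling_rate
  dt <- 1 / rate
  xyz <- trajectory$fingertip_xyz
  fs <- speed_at(xyz, rate)
  cs <- speed_at(trajectory$cube_axis_position, rate)
  vx <- c(NA_real_, diff(xyz[, 1]) * rate)

  i_max_fs <- which.max(fs)
  cube_ev <- detect_cube_motion(cs, config, from = i_max_fs)
  i_contact <- detect_contact(fs, i_max_fs, cube_ev$i_min_cs, config)
  i_onset <- detect_strike_onset(vx, fs, i_contact, config)

  post <- which(cs < config$cube_stop_threshold &
                  seq_along(cs) > cube_ev$onset)
  if (length(post) == 0) {
    kin_error("cube_never_stopped", "cube speed never drops below threshold")
  }
  i_stop <- post[1]

  if (!(i_onset < i_max_fs && i_max_fs <= i_contact + 1L &&
        i_contact + 1L <= cube_ev$i_min_cs &&
        cube_ev$i_min_cs <= i_stop)) {
    kin_error("event_order", "detected events violate temporal ordering")
  }

  D <- (i_contact - i_onset) * dt
  A_m <- sqrt(sum((xyz[i_contact, ] - xyz[i_onset, ])^2))
  IS <- fs[i_contact]
  stop_m <- trajectory$cube_axis_position[i_stop]
  d <- condition$target_distance_m

  rec <- data.frame(
    demand_rank = condition$demand_rank,
    surface = condition$surface,
    mu_k = condition$mu_k,
    slope_deg = condition$slope_deg,
    target_distance_m = d,
    optimal_speed_mps = condition$optimal_speed_mps,
    A_mm = A_m * 1000,
    D_s = D,
    IS_mps = IS,
    stop_m = stop_m,
    spatial_error_pct = 100 * (stop_m - d) / d,
    ground_truth = FALSE,
    stringsAsFactors = FALSE
  )
  t0 <- trajectory$time[1]
  attr(rec, "events") <- list(
    t_onset = t0 + (i_onset - 1L) * dt,
    t_maxFS = t0 + (i_max_fs - 1L) * dt,
    t_contact = t0 + (i_contact - 1L) * dt,
    t_minCS = t0 + (cube_ev$i_min_cs - 1L) * dt,
    t_cube_stop = t0 + (i_stop - 1L) * dt,
    onset_speed_fraction = config$onset_speed_fraction
  )
  rec
}

#' Extract a whole cohort's trajectories
#'
#' Applies [extract_trial()] to every trajectory of a synthetic cohort.
#' Trials whose event detection fails are excluded and returned with their
#' reason code, mirroring the exclusion bookkeeping of motion-capture
#' studies.
#'
#' @param cohort A `strike_cohort` from [generate_cohort()] with
#'   trajectories kept.
#' @param config A [kinematic_config()].
#' @return List with `trials` (extracted trial table, one row per retained
#'   trial, carrying `trial_id`, `participant_id`, `archetype`,
#'   `coordination_group` from the cohort) and `exclusions` (data.frame of
#'   `trial_id`, `reason`).
#' @export
extract_cohort <- function(cohort, config = kinematic_config()) {
  stopifnot(inherits(cohort, "strike_cohort"))
  if (is.null(cohort$trajectories)) {
    stop("cohort was generated with keep_trajectories = FALSE")
  }
  ids <- cohort$trials$trial_id
  out <- vector("list", length(ids))
  excl <- list()
  for (i in seq_along(ids)) {
    gt <- cohort$trials[i, ]
    cond <- cohort$conditions[cohort$conditions$demand_rank ==
                                gt$demand_rank, ]
    rec <- tryCatch(
      extract_trial(cohort$trajectories[[ids[i]]], cond, config),
      strikekin_kin_error = function(e) e
    )
    if (inherits(rec, "strikekin_kin_error")) {
      excl[[length(excl) + 1L]] <-
        data.frame(trial_id = ids[i], reason = rec$reason,
                   stringsAsFactors = FALSE)
    } else {
      rec$trial_id <- gt$trial_id
      rec$participant_id <- gt$participant_id
      rec$archetype <- gt$archetype
      rec$coordination_group <- gt$coordination_group
      out[[i]] <- rec
    }
  }
  trials <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  front <- c("trial_id", "participant_id", "archetype", "coordination_group")
  trials <- trials[, c(front, setdiff(names(trials), front))]
  rownames(trials) <- NULL
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(trial_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  list(trials = trials, exclusions = exclusions)
}
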