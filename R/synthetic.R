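# Synthetic motion-capture generator.
#
# Emulates the study conditions: cohorts of participants x 12 conditions x
# 10 repetitions, 250 Hz fingertip (3D) and cube (1D, along the gutter axis)
# position series with arming / strike / collision / slide phases. Three
# strategy archetypes are distinguished by the sign of the coupling between
# strike duration and impact speed.

#' Reference impact speed anchoring the archetype scaling rules (m/s)
#'
#' Archetype baselines are the expected duration/amplitude at this impact
#' speed; roughly the cohort-average intended impact speed (mean optimal
#' cube speed over the 12 conditions divided by a typical speed-transfer
#' ratio).
#' @keywords internal
IS_REF <- 1.8

#' Strategy archetype definitions
#'
#' An archetype fixes the affine scaling rules that generate strike duration
#' `D` and amplitude `A` from the intended impact speed `IS`:
#' `D = baseline_duration + d_vs_is_slope * (IS - IS_REF) + noise` and
#' `A = baseline_amplitude + a_vs_is_slope * (IS - IS_REF) + noise`.
#'
#' * `inverse_duration_amplitude`: duration shrinks as impact speed grows
#'   (negative duration coupling), amplitude grows moderately.
#' * `temporal_invariance`: duration is unchanged across demand; speed is
#'   modulated almost purely through amplitude.
#' * `late_impulse`: both duration and amplitude grow with impact speed,
#'   producing a shallow approach and a late acceleration burst.
#'
#' Default slopes and baselines follow the cluster-mean regression slopes
#' and typical movement scales reported for this task (duration slopes of
#' about -0.03 / 0 / +0.023 s per m/s; amplitude slopes of about 31 / 63 /
#' 71 mm per m/s; baselines of 125-145 mm and 150-170 ms).
#'
#' @param name One of `"inverse_duration_amplitude"`, `"temporal_invariance"`,
#'   `"late_impulse"`.
#' @return A list of class `strategy_archetype` with fields `name`,
#'   `d_vs_is_slope` (s per m/s), `a_vs_is_slope` (m per m/s, positive),
#'   `baseline_duration` (s), `baseline_amplitude` (m).
#' @examples
#' strategy_archetype("late_impulse")
#' @export
strategy_archetype <- function(name = c("inverse_duration_amplitude",
                                        "temporal_invariance",
                                        "late_impulse")) {
  name <- match.arg(name)
  defs <- list(
    inverse_duration_amplitude = list(
      d_vs_is_slope = -0.030, a_vs_is_slope = 0.030,
      baseline_duration = 0.150, baseline_amplitude = 0.135),
    temporal_invariance = list(
      d_vs_is_slope = 0.000, a_vs_is_slope = 0.063,
      baseline_duration = 0.160, baseline_amplitude = 0.143),
    late_impulse = list(
      d_vs_is_slope = 0.023, a_vs_is_slope = 0.071,
      baseline_duration = 0.170, baseline_amplitude = 0.125)
  )
  out <- c(list(name = name), defs[[name]])
  stopifnot(out$a_vs_is_slope > 0)
  class(out) <- "strategy_archetype"
  out
}

#' Participant generative profile
#'
#' @param participant_id Identifier string.
#' @param archetype A [strategy_archetype()] (or its name).
#' @param kappa Speed-transfer ratio: cube launch speed / fingertip impact
#'   speed, in (0, 1].
#' @param planning_noise_sd Trial-level Gaussian noise on the intended
#'   impact speed (m/s).
#' @param execution_noise_sd_frac Trial-level relative noise on duration and
#'   amplitude, as a fraction of the archetype baselines.
#' @param coordination_group `"wrist"` or `"forearm"`; inert for trajectory
#'   generation, used by the strategy-by-coordination contingency analysis.
#' @return A list of class `participant_profile`.
#' @export
participant_profile <- function(participant_id, archetype,
                                kappa = 0.92,
                                planning_noise_sd = 0.15,
                                execution_noise_sd_frac = 0.18,
                                coordination_group = c("wrist", "forearm")) {
  if (is.character(archetype)) archetype <- strategy_archetype(archetype)
  coordination_group <- match.arg(coordination_group)
  stopifnot(kappa > 0, kappa <= 1,
            planning_noise_sd >= 0, execution_noise_sd_frac >= 0)
  structure(list(participant_id = participant_id, archetype = archetype,
                 kappa = kappa, planning_noise_sd = planning_noise_sd,
                 execution_noise_sd_frac = execution_noise_sd_frac,
                 coordination_group = coordination_group),
            class = "participant_profile")
}

#' Shape exponent of the power-law strike speed profile
#'
#' The strike speed profile family is `v(u) = IS * u^s` on normalized time
#' `u` in `[0, 1]`. Its displacement integral is `D * IS / (s + 1)`, so the
#' exponent that makes the profile traverse amplitude `A` in duration `D`
#' ending at speed `IS` is `s = D * IS / A - 1`. Large `s` means a shallow
#' approach with a late impulse; `s = 1` is a linear ramp.
#'
#' @param A Strike amplitude (m), with `0 < A < D * IS`.
#' @param D Strike duration (s).
#' @param IS Impact speed (m/s).
#' @return The positive shape exponent.
#' @examples
#' strike_shape_exponent(0.1, 0.2, 2.0) # 3
#' @export
strike_shape_exponent <- function(A, D, IS) {
  stopifnot(length(A) == 1, length(D) == 1, length(IS) == 1)
  if (A <= 0) stop("strike amplitude A must be positive")
  if (A >= D * IS) {
    stop("infeasible profile: A must be smaller than D * IS")
  }
  D * IS / A - 1
}

# Discrete analogue of strike_shape_exponent: exponent s such that the
# sampled interval speeds w_j = IS * (j/n)^s, j = 1..n, sum to A / dt
# exactly.  Keeps the sampled trajectory's chord amplitude and terminal
# finite-difference speed exactly equal to the ground truth.
solve_discrete_shape <- function(A, n, IS, dt) {
  j <- seq_len(n) / n
  f <- function(s) IS * dt * sum(j^s) - A
  lo <- 0.05; hi <- 8
  if (f(lo) < 0 || f(hi) > 0) stop("infeasible profile: A outside [IS*dt, IS*D]")
  stats::uniroot(f, c(lo, hi), tol = 1e-13)$root
}

#' Synthesize one trial
#'
#' Draws `(A, D, IS)` from the participant's archetype rules, then builds a
#' sampled trajectory with five phases: rest at the cube face, a cosine
#' arming excursion of amplitude `A` away from the cube, a short hold, the
#' power-law strike reaching `IS` over duration `D`, a 4-sample (16 ms)
#' linear fingertip deceleration at the collision, and the cube's frictional
#' slide. The cube stays in contact-lag for one sample after impact, then
#' follows the exact constant-deceleration parabola with launch speed
#' `kappa * IS`, so its total travel equals
#' `stopping_distance(kappa * IS, alpha, mu_k)` exactly.
#'
#' Randomness comes from R's global RNG; seed it (or use
#' [generate_cohort()]) for reproducibility.
#'
#' @param profile A [participant_profile()].
#' @param condition One row of [build_condition_grid()].
#' @param sampling_rate Hz (default 250).
#' @param max_retry Resampling attempts for infeasible `(A, D, IS)` draws.
#' @return A list with elements `trajectory` (class `strike_trajectory`:
#'   `sampling_rate`, `time`, `fingertip_xyz` n x 3 matrix, `cube_axis_position`)
#'   and `record` (one-row data.frame of ground-truth performance variables).
#' @export
synthesize_trial <- function(profile, condition, sampling_rate = 250,
                             max_retry = 25L) {
  stopifnot(inherits(profile, "participant_profile"))
  arch <- profile$archetype
  dt <- 1 / sampling_rate
  v_opt <- condition$optimal_speed_mps
  decel <- cube_deceleration(condition$slope_deg, condition$mu_k)

  draw <- NULL
  for (try in seq_len(max_retry)) {
    IS <- v_opt / profile$kappa +
      stats::rnorm(1, 0, profile$planning_noise_sd)
    D <- arch$baseline_duration + arch$d_vs_is_slope * (IS - IS_REF) +
      stats::rnorm(1, 0, profile$execution_noise_sd_frac * arch$baseline_duration)
    A <- arch$baseline_amplitude + arch$a_vs_is_slope * (IS - IS_REF) +
      stats::rnorm(1, 0, profile$execution_noise_sd_frac * arch$baseline_amplitude)
    n <- round(D * sampling_rate)
    # keep the shape exponent in a physiological band (~0.08 to 6): extreme
    # exponents produce strikes that are flat to machine precision at onset
    if (IS > 0.2 && n >= 8 && A > IS * n * dt / 7 && A < 0.93 * IS * n * dt) {
      draw <- list(IS = IS, A = A, n = n)
      break
    }
  }
  if (is.null(draw)) {
    stop("could not draw a feasible (A, D, IS) triple within retry budget")
  }
  IS <- draw$IS; A <- draw$A; n <- draw$n
  D <- n * dt # ground-truth duration snapped to the sampling grid

  s <- solve_discrete_shape(A, n, IS, dt)

  n_rest <- 25L
  n_arm <- round(0.4 * sampling_rate)
  n_hold <- 12L

  # fingertip gutter-axis position, one value per phase sample
  arm <- -A * (1 - cos(pi * seq_len(n_arm) / n_arm)) / 2
  strike_w <- IS * (seq_len(n) / n)^s
  strike <- -A + cumsum(strike_w * dt)
  strike[n] <- 0 # land exactly on the cube face (root solve is ~1e-12 off)
  coll <- cumsum(c(0.75, 0.5, 0.25, 0) * IS * dt)

  launch <- profile$kappa * IS
  slide_T <- launch / decel
  n_slide <- ceiling(slide_T * sampling_rate) + 25L
  tau <- pmin(seq_len(n_slide) * dt, slide_T) # hold at the vertex once stopped
  stop_m <- launch^2 / (2 * decel)
  cube_slide <- launch * tau - decel * tau^2 / 2

  fx <- c(rep(0, n_rest), arm, rep(-A, n_hold), strike,
          coll, rep(coll[4], n_slide))
  # cube: at rest until impact, one-sample contact lag, then the parabola
  i_impact <- n_rest + n_arm + n_hold + n
  n_total <- length(fx)
  cube <- c(rep(0, i_impact + 1L), cube_slide)
  length(cube) <- n_total
  cube[is.na(cube)] <- stop_m

  time <- (seq_len(n_total) - 1L) * dt
  traj <- structure(list(sampling_rate = sampling_rate, time = time,
                         fingertip_xyz = cbind(x = fx, y = 0, z = 0),
                         cube_axis_position = cube),
                    class = "strike_trajectory")

  record <- data.frame(
    participant_id = profile$participant_id,
    archetype = arch$name,
    coordination_group = profile$coordination_group,
    demand_rank = condition$demand_rank,
    surface = condition$surface,
    mu_k = condition$mu_k,
    slope_deg = condition$slope_deg,
    target_distance_m = condition$target_distance_m,
    optimal_speed_mps = v_opt,
    A_mm = A * 1000,
    D_s = D,
    IS_mps = IS,
    stop_m = stop_m,
    spatial_error_pct = 100 * (stop_m - condition$target_distance_m) /
      condition$target_distance_m,
    ground_truth = TRUE,
    stringsAsFactors = FALSE
  )
  list(trajectory = traj, record = record)
}

#' @export
print.strike_trajectory <- function(x, ...) {
  cat(sprintf("<strike_trajectory: %d samples @ %g Hz (%.2f s)>\n",
              length(x$time), x$sampling_rate, max(x$time)))
  invisible(x)
}

#' Cohort configuration
#'
#' @param n_per_archetype Named or unnamed integer vector of length 3:
#'   participants per archetype, in the order inverse_duration_amplitude,
#'   temporal_invariance, late_impulse. Default 11 each (a 33-participant
#'   cohort).
#' @param repetitions Trials per condition (default 10, i.e. 120 trials per
#'   participant over the 12-condition grid).
#' @param kappa_range Per-participant speed-transfer ratio is drawn
#'   uniformly from this interval.
#' @param planning_noise_sd,execution_noise_sd_frac Trial-level noise, see
#'   [participant_profile()].
#' @param p_wrist Probability that a participant belongs to the wrist
#'   coordination group (default 14/33, the observed margin).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_archetype = c(11L, 11L, 11L),
                          repetitions = 10L,
                          kappa_range = c(0.85, 0.98),
                          planning_noise_sd = 0.15,
                          execution_noise_sd_frac = 0.18,
                          p_wrist = 14 / 33) {
  stopifnot(length(n_per_archetype) == 3, all(n_per_archetype >= 0),
            sum(n_per_archetype) > 0, repetitions >= 1,
            length(kappa_range) == 2, kappa_range[1] > 0,
            kappa_range[2] <= 1, kappa_range[1] <= kappa_range[2],
            planning_noise_sd >= 0, execution_noise_sd_frac >= 0)
  structure(list(n_per_archetype = as.integer(n_per_archetype),
                 repetitions = as.integer(repetitions),
                 kappa_range = kappa_range,
                 planning_noise_sd = planning_noise_sd,
                 execution_noise_sd_frac = execution_noise_sd_frac,
                 p_wrist = p_wrist),
            class = "cohort_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic cohort
#'
#' Draws participant profiles (archetype, transfer ratio, coordination
#' group) and synthesizes every trial of the 12-condition x
#' `repetitions` design. Reproducible: the same `seed` yields an identical
#' trial table and trajectories; the caller's RNG state is left untouched.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed controlling every random draw.
#' @param keep_trajectories Keep the sampled trajectories (needed for
#'   kinematic extraction; ~30 kB per trial) or only the ground-truth trial
#'   table.
#' @param sampling_rate Hz.
#' @return A list of class `strike_cohort`: `trials` (ground-truth trial
#'   table, one row per trial), `trajectories` (named list keyed by
#'   `trial_id`, or NULL), `profiles`, `conditions` (the demand grid),
#'   `seed`.
#' @examples
#' coh <- generate_cohort(cohort_config(c(1, 1, 1), repetitions = 2), seed = 7)
#' table(coh$trials$archetype)
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L,
                            keep_trajectories = TRUE, sampling_rate = 250) {
  stopifnot(inherits(config, "cohort_config"))
  grid <- build_condition_grid()
  with_seed(seed, {
    arch_names <- rep(c("inverse_duration_amplitude", "temporal_invariance",
                        "late_impulse"), config$n_per_archetype)
    n_part <- length(arch_names)
    ids <- sprintf("P%02d", seq_len(n_part))
    profiles <- lapply(seq_len(n_part), function(i) {
      participant_profile(
        ids[i], arch_names[i],
        kappa = stats::runif(1, config$kappa_range[1], config$kappa_range[2]),
        planning_noise_sd = config$planning_noise_sd,
        execution_noise_sd_frac = config$execution_noise_sd_frac,
        coordination_group = if (stats::runif(1) < config$p_wrist)
          "wrist" else "forearm")
    })
    names(profiles) <- ids

    rows <- vector("list", n_part * nrow(grid) * config$repetitions)
    trajs <- if (keep_trajectories) vector("list", length(rows)) else NULL
    k <- 0L
    for (p in profiles) {
      for (ci in seq_len(nrow(grid))) {
        for (rep_i in seq_len(config$repetitions)) {
          k <- k + 1L
          tr <- synthesize_trial(p, grid[ci, ], sampling_rate = sampling_rate)
          rec <- tr$record
          rec$trial_id <- sprintf("%s_c%02d_r%02d", p$participant_id,
                                  grid$demand_rank[ci], rep_i)
          rows[[k]] <- rec
          if (keep_trajectories) trajs[[k]] <- tr$trajectory
        }
      }
    }
    trials <- do.call(rbind, rows)
    trials <- trials[, c("trial_id", setdiff(names(trials), "trial_id"))]
    rownames(trials) <- NULL
    if (keep_trajectories) names(trajs) <- trials$trial_id
    structure(list(trials = trials, trajectories = trajs,
                   profiles = profiles, conditions = grid, seed = seed),
              class = "strike_cohort")
  })
}

#' @export
print.strike_cohort <- function(x, ...) {
  cat(sprintf(
    "<strike_cohort: %d participants, %d trials%s, seed %d>\n",
    length(x$profiles), nrow(x$trials),
    if (is.null(x$trajectories)) "" else " (+trajectories)", x$seed))
  invisible(x)
}
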