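# Frictional sliding physics on an inclined gutter.
#
# A cube launched with speed v0 along a surface of slope alpha and kinetic
# friction coefficient mu_k decelerates at a = g * [sin(alpha) + mu_k *
# cos(alpha)] (magnitude, m/s^2) and travels v0^2 / (2 a) before stopping.
# Inverting gives the launch speed that stops the cube exactly at a target
# distance d -- the "optimal cube speed" used throughout as the scalar
# task-demand axis.

#' Standard gravity used by the sliding model (m/s^2)
#' @keywords internal
GRAVITY <- 9.81

#' Kinetic friction coefficients of the two gutter surfaces
#'
#' Aluminum: 0.37; balsa wood: 0.47.
#' @keywords internal
SURFACE_MU <- c(aluminum = 0.37, balsa = 0.47)

deg2rad <- function(deg) deg * pi / 180

#' Deceleration of the sliding cube
#'
#' Magnitude of the constant deceleration of a cube sliding uphill-positive
#' on a surface of slope `alpha` with kinetic friction `mu_k`:
#' `g * (sin(alpha) + mu_k * cos(alpha))`.
#'
#' @param alpha Surface slope in degrees; positive slopes rise away from the
#'   strike point (uphill is more demanding).
#' @param mu_k Dimensionless kinetic friction coefficient (> 0).
#' @return Deceleration in m/s^2 (strictly positive unless both `alpha` and
#'   `mu_k` are zero).
#' @examples
#' cube_deceleration(0, 0.47)
#' cube_deceleration(-10, 0.37)
#' @export
cube_deceleration <- function(alpha, mu_k) {
  stopifnot(is.numeric(alpha), is.numeric(mu_k), mu_k >= 0)
  a <- deg2rad(alpha)
  f <- sin(a) + mu_k * cos(a)
  if (any(f < 0)) {
    stop("cube does not stop on this slope: sin(alpha) + mu_k*cos(alpha) < 0")
  }
  GRAVITY * f
}

#' Launch speed that stops the cube exactly at the target distance
#'
#' `sqrt(2 g d [sin(alpha) + mu_k cos(alpha)])`: the initial sliding speed
#' for which the cube's front edge comes to rest at distance `d`. Monotone
#' increasing in `d`, `mu_k` and (over the experimental range) `alpha`, so it
#' orders the experimental conditions along a single task-demand continuum.
#'
#' @inheritParams cube_deceleration
#' @param d Target distance in metres (>= 0).
#' @return Speed in m/s.
#' @examples
#' optimal_cube_speed(0.25, -10, 0.37) # least demanding condition, ~0.97
#' optimal_cube_speed(0.50, +10, 0.47) # most demanding condition, ~2.50
#' @export
optimal_cube_speed <- function(d, alpha, mu_k) {
  stopifnot(is.numeric(d))
  if (any(d < 0)) stop("target distance d must be non-negative")
  sqrt(2 * d * cube_deceleration(alpha, mu_k))
}

#' Distance travelled by the cube before friction stops it
#'
#' Exact algebraic inverse of [optimal_cube_speed()]: a cube launched at `v0`
#' slides `v0^2 / (2 * cube_deceleration(alpha, mu_k))` metres.
#'
#' @inheritParams cube_deceleration
#' @param v0 Initial cube speed in m/s (>= 0).
#' @return Stopping distance in metres.
#' @export
stopping_distance <- function(v0, alpha, mu_k) {
  stopifnot(is.numeric(v0))
  if (any(v0 < 0)) stop("initial speed v0 must be non-negative")
  v0^2 / (2 * cube_deceleration(alpha, mu_k))
}

#' The 12-condition task-demand grid
#'
#' Cartesian product of two target distances (0.25, 0.50 m), two surfaces
#' (aluminum mu_k = 0.37, balsa mu_k = 0.47) and three slopes (-10, 0, +10
#' degrees), ranked by ascending optimal cube speed (`demand_rank` 1 is the
#' least demanding condition). Ties (none with these constants) would be
#' broken by (d, mu_k, alpha) lexicographic order.
#'
#' @return A data.frame with one row per condition and columns
#'   `demand_rank`, `surface`, `mu_k`, `slope_deg`, `target_distance_m`,
#'   `optimal_speed_mps`.
#' @examples
#' head(build_condition_grid())
#' @export
build_condition_grid <- function() {
  grid <- expand.grid(
    target_distance_m = c(0.25, 0.50),
    surface = c("aluminum", "balsa"),
    slope_deg = c(-10, 0, 10),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$mu_k <- unname(SURFACE_MU[grid$surface])
  grid$optimal_speed_mps <- optimal_cube_speed(
    grid$target_distance_m, grid$slope_deg, grid$mu_k
  )
  ord <- order(grid$optimal_speed_mps, grid$target_distance_m,
               grid$mu_k, grid$slope_deg)
  grid <- grid[ord, ]
  grid$demand_rank <- seq_len(nrow(grid))
  rownames(grid) <- NULL
  grid[, c("demand_rank", "surface", "mu_k", "slope_deg",
           "target_distance_m", "optimal_speed_mps")]
}
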