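## Locomotion: overdamped (Stokes-regime) rigid-body dynamics.  Each
## cell's flagella exert a tangential thrust on the colony; the normal
## beating mode pushes the colony toward its anterior pole with an
## azimuthal component that spins it about the swimming axis
## (counterclockwise as seen from behind).  Translational and rotational
## mobilities are folded into the parameter units, so "forces" are in
## um/s and "torques" in rad/s; the two are linked through the rigid-
## sphere mobility ratio, omega = 3/(4 R) * (r_hat x f) summed over
## cells.  Gravity adds a constant sinking velocity and, because the
## colony is bottom-heavy, a righting angular velocity
## righting_rate * sin(psi) that turns the anterior pole upward.

#' Locomotion parameters
#'
#' Usually produced by [calibrate_locomotion()]; the direct constructor
#' is provided for tests and custom configurations.
#'
#' @param per_cell_thrust_normal thrust magnitude scale (um/s per unit
#'   cell weight).
#' @param reverse_thrust_ratio ratio of reverse-mode to normal-mode
#'   per-cell thrust at equal beat frequency, in (0, 1\] (reverse-mode
#'   streamlines are slower).
#' @param azimuthal_tilt tilt of the per-cell thrust away from the
#'   meridian (degrees); sets the axial rotation rate.
#' @param sinking_speed passive sinking speed (um/s).
#' @param righting_rate bottom-heaviness reorientation rate (1/s).
#' @param rotational_diffusion rotational diffusivity (rad^2/s) of the
#'   orientation noise; balances the righting torque so that dark-adapted
#'   swimmers populate all heading sectors.
#' @param reverse_freq_ratio reverse/normal beat-frequency ratio by which
#'   the reverse-mode thrust additionally scales.
#' @return an object of class `locomotion_params`.
#' @export
locomotion_params <- function(per_cell_thrust_normal = 1,
                              reverse_thrust_ratio = 0.45,
                              azimuthal_tilt = 40,
                              sinking_speed = 220,
                              righting_rate = 1.218,
                              rotational_diffusion = 0.6,
                              reverse_freq_ratio = 40 / 22) {
  stop_if_not(reverse_thrust_ratio > 0 && reverse_thrust_ratio <= 1,
              "reverse_thrust_ratio must lie in (0, 1]")
  stop_if_not(per_cell_thrust_normal > 0, "thrust scale must be positive")
  stop_if_not(sinking_speed >= 0 && righting_rate >= 0 &&
                rotational_diffusion >= 0,
              "rates must be non-negative")
  structure(as.list(environment()), class = "locomotion_params")
}

## effective reverse-mode thrust factor (signed magnitude relative to
## normal mode)
reverse_factor <- function(params) {
  params$reverse_thrust_ratio * params$reverse_freq_ratio
}

#' Calibrate locomotion parameters against a spheroid's geometry
#'
#' Deterministic three-step calibration: (1) the thrust scale is set so
#' the all-normal axial swimming speed equals the spheroid's intrinsic
#' speed; (2) the azimuthal tilt is set so the axial rotation period
#' equals the spheroid's rotation period (closed form through the
#' mobility ratio); (3) the reverse thrust ratio is set so that full
#' reversal of the responsive anterior hemisphere cancels the net axial
#' thrust -- the photophobic configuration then leaves the colony
#' sinking passively, which reproduces the observed ~0.45 mm drop over
#' the ~2 s photophobic phase.  The righting rate is set so a horizontal
#' colony reorients to within 10 degrees of vertical in 2 s.
#'
#' @param spheroid a [build_spheroid()] object.
#' @param kinetics a [kinetics_params()] object (supplies the beat
#'   frequencies and the responsive-cap boundary).
#' @param rotational_diffusion rotational diffusivity (rad^2/s).
#' @param righting_time time for a horizontal colony to right itself to
#'   within `righting_angle` of vertical (s).
#' @param righting_angle residual angle from vertical after
#'   `righting_time` (degrees).
#' @return a calibrated [locomotion_params()] object.
#' @export
#' @examples
#' sph <- build_spheroid(200, seed = 1)
#' calibrate_locomotion(sph)
calibrate_locomotion <- function(spheroid, kinetics = kinetics_params(),
                                 rotational_diffusion = 0.6,
                                 righting_time = 2, righting_angle = 10) {
  cells <- spheroid$cells
  R <- spheroid$radius
  v0 <- spheroid$intrinsic_speed
  Trot <- spheroid$rotation_period

  sin_th <- sqrt(pmax(0, 1 - cells$pz^2))
  S <- sum(cells$weight * sin_th)

  ## (2) tilt: |omega_z| = 3/(4R) * C * sin(beta) * S = 2 pi / Trot and
  ##     axial speed  =            C * cos(beta) * S = v0
  tanb <- (2 * pi / Trot) * (4 * R / 3) / v0
  beta <- atan(tanb)

  ## (1) thrust scale
  C <- v0 / (cos(beta) * S)

  ## (3) reverse ratio: responsive (anterior) axial thrust, reversed at
  ##     factor q, balances the posterior normal thrust exactly
  resp <- cells$arc_fraction <= kinetics$responsive_arc_fraction
  S_ant <- sum(cells$weight[resp] * sin_th[resp])
  S_post <- S - S_ant
  q_eff <- S_post / S_ant
  fr <- kinetics$reverse_beat_freq / kinetics$normal_beat_freq
  r <- q_eff / fr
  stop_if_not(r > 0 && r <= 1,
              "calibrated reverse_thrust_ratio left (0, 1]")

  ## righting rate from the pendulum-like relaxation d psi/dt = -k sin psi
  k <- log(tan(pi / 4) / tan(deg2rad(righting_angle) / 2)) / righting_time

  locomotion_params(per_cell_thrust_normal = C,
                    reverse_thrust_ratio = r,
                    azimuthal_tilt = rad2deg(beta),
                    sinking_speed = spheroid$sinking_speed,
                    righting_rate = k,
                    rotational_diffusion = rotational_diffusion,
                    reverse_freq_ratio = fr)
}

## Precompute the per-cell thrust machinery for a spheroid: unit thrust
## directions (tilted off the meridian), the moment arms r_hat x dir, and
## the per-cell magnitudes.
thrust_model <- function(spheroid, params) {
  cells <- spheroid$cells
  beta <- deg2rad(params$azimuthal_tilt)
  Tm <- cbind(cells$tx, cells$ty, cells$tz)
  Az <- cbind(cells$ax, cells$ay, cells$az)
  Rh <- cbind(cells$px, cells$py, cells$pz)
  dir <- cos(beta) * Tm - sin(beta) * Az
  cr <- cbind(Rh[, 2] * dir[, 3] - Rh[, 3] * dir[, 2],
              Rh[, 3] * dir[, 1] - Rh[, 1] * dir[, 3],
              Rh[, 1] * dir[, 2] - Rh[, 2] * dir[, 1])
  list(dir = dir, moment = cr,
       mag = params$per_cell_thrust_normal * cells$weight,
       mobility = 3 / (4 * spheroid$radius),
       q_eff = reverse_factor(params),
       cos_beta = cos(beta))
}

## Signed per-cell thrust factor for a state vector: +1 normal / latent,
## -q_eff reversed, linear interpolation across the transitions.
mode_thrust_factor <- function(states, params, kinetics) {
  q <- reverse_factor(params)
  f <- rep(1, length(states$mode))
  tt <- kinetics$transition_time
  s <- pmin(1, pmax(0, 1 - states$timer / tt))
  i <- states$mode == 3L                       # normal -> reversed
  f[i] <- 1 + s[i] * (-q - 1)
  f[states$mode == 4L] <- -q
  i <- states$mode == 5L                       # reversed -> normal
  f[i] <- -q + s[i] * (1 + q)
  f
}

#' Thrust of a single cell
#'
#' Body-frame thrust vector of one cell given its beating-mode state.
#' Normal-mode thrust points along the cell's meridional thrust
#' direction tilted by the azimuthal tilt (propelling the colony toward
#' the anterior while spinning it counterclockwise as seen from behind);
#' reverse-mode thrust is exactly opposite, scaled by
#' `reverse_thrust_ratio` times the beat-frequency ratio; transition
#' modes interpolate linearly.
#'
#' @param cell one row of a spheroid's `cells` data frame.
#' @param state a single-cell [cell_states()] object.
#' @param params a [locomotion_params()] object.
#' @param kinetics a [kinetics_params()] object.
#' @return body-frame thrust 3-vector (um/s contribution).
#' @export
cell_thrust <- function(cell, state, params, kinetics = kinetics_params()) {
  beta <- deg2rad(params$azimuthal_tilt)
  dir <- cos(beta) * c(cell$tx, cell$ty, cell$tz) -
    sin(beta) * c(cell$ax, cell$ay, cell$az)
  f <- mode_thrust_factor(state, params, kinetics)
  params$per_cell_thrust_normal * cell$weight * f * dir
}

#' Net wrench of all flagellar thrusts
#'
#' Sums per-cell thrusts into a mobility-scaled body-frame force
#' (um/s) and torque (rad/s).
#'
#' @param spheroid a [build_spheroid()] object.
#' @param states a [cell_states()] object with one state per cell.
#' @param params a [locomotion_params()] object.
#' @param kinetics a [kinetics_params()] object.
#' @return a list with elements `force` and `torque` (body frame).
#' @export
net_wrench <- function(spheroid, states, params,
                       kinetics = kinetics_params()) {
  stop_if_not(length(states$mode) == nrow(spheroid$cells),
              "one cell state per cell is required")
  tm <- thrust_model(spheroid, params)
  f <- tm$mag * mode_thrust_factor(states, params, kinetics)
  list(force = as.numeric(crossprod(tm$dir, f)),
       torque = tm$mobility * as.numeric(crossprod(tm$moment, f)))
}

#' Gravity wrench
#'
#' Lab-frame sinking velocity plus the bottom-heaviness righting angular
#' velocity `righting_rate * (axis x up)`, which rotates the anterior
#' pole toward the vertical at rate `righting_rate * sin(psi)`.
#'
#' @param spheroid a [build_spheroid()] object (uses its orientation).
#' @param params a [locomotion_params()] object.
#' @return a list with lab-frame `force` (um/s) and `torque` (rad/s).
#' @export
gravity_wrench <- function(spheroid, params) {
  axis <- as.numeric(spheroid$orientation %*% c(0, 0, 1))
  ## axis x z_hat = (axis_y, -axis_x, 0): rotates the axis toward +z
  torque <- params$righting_rate * c(axis[2], -axis[1], 0)
  list(force = c(0, 0, -params$sinking_speed), torque = torque)
}

#' Advance the spheroid pose by one Euler step
#'
#' Overdamped update: velocities are instantaneous functions of the
#' wrench (no inertia).  The position advances by `force * dt` (um
#' converted to the mm lab frame) and the orientation by the rotation
#' `exp([torque dt]_x)`, re-orthonormalized.
#'
#' @param spheroid a [build_spheroid()] object.
#' @param total lab-frame wrench (list with `force` um/s, `torque`
#'   rad/s).
#' @param dt time step (s), at most 10 ms.
#' @return the spheroid with updated `position` and `orientation`.
#' @export
step_dynamics <- function(spheroid, total, dt) {
  stop_if_not(dt > 0 && dt <= 0.010 + 1e-12,
              "dt must be positive and at most 10 ms")
  spheroid$position <- spheroid$position + total$force * dt * 1e-3
  w <- total$torque
  ang <- sqrt(sum(w^2)) * dt
  if (ang > 0) {
    spheroid$orientation <-
      orthonormalize(rot_axis_angle(w, ang) %*% spheroid$orientation)
  }
  spheroid
}

#' Surface-slip profile over a polar band
#'
#' Proxy for the fluid streamlines along the colony surface: the mean
#' tangential (meridional) thrust of the cells in a polar-angle band,
#' with the anterior-to-posterior fluid direction counted positive.
#' Normally beating regions give positive slip; fully reversed regions
#' give negative slip whose magnitude is reduced by the effective
#' reverse thrust factor.
#'
#' @param spheroid a [build_spheroid()] object.
#' @param states a [cell_states()] object.
#' @param region polar-angle band `c(min, max)` in degrees from the
#'   anterior pole.
#' @param params a [locomotion_params()] object.
#' @param kinetics a [kinetics_params()] object.
#' @return signed mean slip (um/s); positive = anterior to posterior.
#' @export
surface_slip_profile <- function(spheroid, states, region,
                                 params, kinetics = kinetics_params()) {
  th <- spheroid$cells$arc_fraction * 180
  sel <- th >= region[1] & th <= region[2]
  stop_if_not(any(sel), "no cells in the requested region")
  f <- mode_thrust_factor(states, params, kinetics)
  beta <- deg2rad(params$azimuthal_tilt)
  mean(params$per_cell_thrust_normal * spheroid$cells$weight[sel] *
         f[sel] * cos(beta))
}
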