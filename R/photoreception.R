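## Photoreception: per-cell perceived light intensity.  The eyespot makes
## the photoreceptor directionally sensitive; the angular sensitivity is
## modelled as the four-level step function realized physically by a
## rotating stack of three neutral-density filters with mirror-symmetric
## sector cutouts (100 / 74 / 55 / 23 % at half-angles 14 / 25 / 55 deg).
## Light intensities are irradiances in umol m-2 s-1 of green light.

#' Rotating filter stack
#'
#' Three stacked neutral-density filters with sector cutouts.  A ray at
#' angle `theta` from the stack axis passes every filter whose cutout
#' half-angle exceeds `theta` unattenuated, and is attenuated by the
#' transmissivity of every filter it does not clear.  Rotated at
#' `rotation_rate` revolutions per second the stack converts a constant
#' beam into a periodic pulse train with one peak per revolution.
#'
#' @param filter_transmissivities per-filter transmissivities (fractions).
#' @param cutout_half_angles per-filter cutout half-angles (degrees),
#'   strictly increasing.
#' @param rotation_rate rotation rate in revolutions per second.
#' @return an object of class `filter_stack`.
#' @export
#' @examples
#' filter_stack()   # the standard three-filter stack, 0.83 rps
filter_stack <- function(filter_transmissivities = c(0.744, 0.744, 0.4077),
                         cutout_half_angles = c(14, 25, 55),
                         rotation_rate = 0.83) {
  stop_if_not(length(filter_transmissivities) == length(cutout_half_angles),
              "one cutout half-angle per filter is required")
  stop_if_not(length(filter_transmissivities) >= 1, "empty filter list")
  stop_if_not(all(filter_transmissivities > 0 & filter_transmissivities < 1),
              "transmissivities must lie in (0, 1)")
  stop_if_not(all(diff(cutout_half_angles) > 0) &&
                all(cutout_half_angles > 0 & cutout_half_angles < 180),
              "cutout half-angles must be strictly increasing in (0, 180)")
  stop_if_not(rotation_rate > 0, "rotation_rate must be positive")
  structure(list(filter_transmissivities = filter_transmissivities,
                 cutout_half_angles = cutout_half_angles,
                 rotation_rate = rotation_rate),
            class = "filter_stack")
}

#' Transmissivity of a filter stack at a given angle
#'
#' Product of the transmissivities of all filters whose cutout does not
#' cover the angle; inside the innermost cutout the stack transmits
#' fully.
#'
#' @param stack a [filter_stack()].
#' @param angle angle from the stack axis (degrees, in \[0, 180\]);
#'   vectorized.
#' @return transmitted fraction(s) in (0, 1\].
#' @export
#' @examples
#' stacked_transmissivity(filter_stack(), 40)   # 0.744^2, printed as 55%
#' stacked_transmissivity(filter_stack(), 90)   # 0.744^2 * 0.4077, ~23%
stacked_transmissivity <- function(stack, angle) {
  stop_if_not(all(angle >= 0 & angle <= 180), "angle must lie in [0, 180]")
  vapply(angle, function(a) {
    covered <- a >= stack$cutout_half_angles
    prod(stack$filter_transmissivities[covered])
  }, numeric(1))
}

#' Piecewise eye directivity
#'
#' Angular sensitivity of the eye as a decreasing step function of the
#' angle between the eye axis and the direction toward the light source.
#' By default the levels are the exact products of the standard filter
#' stack (1, 0.744, 0.5535, 0.2257), which round to the reported
#' 100/74/55/23 %.
#'
#' @param sector_half_angles sector boundaries (degrees), strictly
#'   increasing.
#' @param levels sensitivity levels, one more than there are boundaries,
#'   strictly decreasing in (0, 1].
#' @return an object of class `directivity`.
#' @export
directivity <- function(sector_half_angles = c(14, 25, 55),
                        levels = cumprod(c(1, 0.744, 0.744, 0.4077))) {
  stop_if_not(length(levels) == length(sector_half_angles) + 1,
              "need one more level than sector boundaries")
  stop_if_not(all(diff(sector_half_angles) > 0) &&
                all(sector_half_angles > 0 & sector_half_angles < 180),
              "sector half-angles must be strictly increasing in (0, 180)")
  stop_if_not(all(diff(levels) < 0) && all(levels > 0 & levels <= 1),
              "levels must be strictly decreasing in (0, 1]")
  structure(list(sector_half_angles = sector_half_angles, levels = levels),
            class = "directivity")
}

#' Directivity value at an angle
#'
#' @param angle angle between the eye axis and the direction toward the
#'   source (degrees, in \[0, 180\]); vectorized.
#' @param d a [directivity()].
#' @return sensitivity fraction(s); symmetric in the sign of the angle.
#' @export
#' @examples
#' directivity_value(c(0, 20, 120), directivity())
directivity_value <- function(angle, d = directivity()) {
  angle <- abs(angle)
  stop_if_not(all(angle >= 0 & angle <= 180), "angle must lie in [0, 180]")
  k <- findInterval(angle, d$sector_half_angles)
  unname(d$levels[k + 1])
}

#' Fit sector cutouts to a target directivity curve
#'
#' Given the transmissivities of the available filters (applied in order)
#' and a sampled, non-increasing target curve on \[0, 180\] degrees, finds
#' the increasing cutout half-angles whose piecewise-constant stack
#' transmissivity minimizes the mean absolute error against the target.
#' The optimum is found exactly by dynamic programming over the sample
#' grid (the candidate breakpoints are the sample angles).
#'
#' @param target data frame with columns `angle` (degrees, increasing)
#'   and `value` (fractions).
#' @param available_transmissivities per-filter transmissivities.
#' @param rotation_rate rotation rate for the returned stack (rev/s).
#' @return a [filter_stack()] with fitted `cutout_half_angles`, carrying
#'   the achieved mean absolute error in attribute `"mae"`.
#' @export
#' @examples
#' tgt <- target_directivity_curve()
#' design_filter_stack(tgt, c(0.744, 0.744, 0.4077))
design_filter_stack <- function(target, available_transmissivities,
                                rotation_rate = 0.83) {
  stop_if_not(length(available_transmissivities) >= 1, "empty filter list")
  stop_if_not(is.data.frame(target) &&
                all(c("angle", "value") %in% names(target)),
              "target must have columns angle and value")
  th <- target$angle
  tv <- target$value
  o <- order(th); th <- th[o]; tv <- tv[o]
  m <- length(available_transmissivities)
  levels <- cumprod(c(1, available_transmissivities))
  n <- length(th)

  ## cumulative absolute errors for each level
  cum <- sapply(levels, function(L) cumsum(abs(tv - L)))  # n x (m+1)
  cum <- rbind(0, cum)                                    # index shift

  ## D[k, j]: best error for samples 1..j using levels 0..k-1, with the
  ## k-th breakpoint placed immediately after sample j.
  D <- matrix(Inf, m + 1, n + 1)
  B <- matrix(NA_integer_, m + 1, n + 1)
  D[1, ] <- cum[, 1]
  for (k in 2:(m + 1)) {
    ## D[k, j] = min_{i <= j} D[k-1, i] + (cum[j+1, k] - cum[i+1, k])
    best <- Inf; arg <- NA_integer_
    for (j in 0:n) {
      cand <- D[k - 1, j + 1] - cum[j + 1, k]
      if (cand < best) { best <- cand; arg <- j }
      D[k, j + 1] <- best + cum[j + 1, k]
      B[k, j + 1] <- arg
    }
  }
  ## total error with all m+1 levels over all n samples:
  j <- n
  cuts <- numeric(m)
  for (k in (m + 1):2) {
    i <- B[k, j + 1]
    ## breakpoint between sample i and i+1: the cut half-angle is the
    ## first angle of the darker segment (exact recovery on step targets)
    cuts[k - 1] <- if (i >= n) th[n] + diff(range(th)) / n
                   else th[i + 1]
    j <- i
  }
  ## enforce strict increase for degenerate (empty-segment) solutions
  for (k in seq_len(m)[-1])
    if (cuts[k] <= cuts[k - 1]) cuts[k] <- cuts[k - 1] + 1e-6
  out <- filter_stack(available_transmissivities, cuts, rotation_rate)
  attr(out, "mae") <- D[m + 1, n + 1] / n
  out
}

#' Smooth stand-in target directivity
#'
#' A cardioid-like angular sensitivity with the same floor as the
#' four-level step model, provided for exercising
#' [design_filter_stack()]: `D(theta) = max(cos(theta), floor)`.
#'
#' @param angles sample angles (degrees).
#' @param floor sensitivity floor.
#' @return data frame with columns `angle`, `value`.
#' @export
target_directivity_curve <- function(angles = 0:180, floor = 0.23) {
  data.frame(angle = angles,
             value = pmax(cos(deg2rad(angles)), floor))
}

#' Pulse train produced by a rotating filter stack
#'
#' Intensity time series seen through the rotating stack: period
#' `1 / rotation_rate`, one peak (full transmission through the cutout
#' gap) per revolution, minimum equal to the product of all filter
#' transmissivities.
#'
#' @param stack a [filter_stack()].
#' @param duration series duration (s).
#' @param dt sampling interval (s).
#' @param peak_intensity intensity at full transmission
#'   (umol m-2 s-1).
#' @return data frame with columns `t` (s) and `intensity`.
#' @export
#' @examples
#' head(pulse_train(filter_stack(), duration = 2.5, dt = 0.1,
#'                  peak_intensity = 28))
pulse_train <- function(stack, duration, dt, peak_intensity) {
  stop_if_not(duration > 0 && dt > 0, "duration and dt must be positive")
  t <- seq(0, duration, by = dt)
  ang <- (360 * stack$rotation_rate * t) %% 360
  ang <- pmin(ang, 360 - ang)
  data.frame(t = t,
             intensity = peak_intensity * stacked_transmissivity(stack, ang))
}

## ---------------------------------------------------------------------
## Light schedules

#' Light schedules
#'
#' A light schedule couples a propagation direction (lab-frame unit
#' vector pointing *away* from the source) with a non-negative intensity
#' as a function of time.  `light_constant` is always on,
#' `light_step` switches on at `t_on` (a dark-light switch), and
#' `light_pulsed` runs a rotating-filter pulse train from `t_on`.
#'
#' @param intensity irradiance when on (umol m-2 s-1).
#' @param direction propagation direction (lab frame); normalized
#'   internally.
#' @param t_on switch-on time (s).
#' @param label free-text label.
#' @param stack a [filter_stack()] for `light_pulsed`.
#' @param peak_intensity peak irradiance of the pulse train.
#' @return an object of class `light_schedule` with fields `direction`,
#'   `intensity_of_time` (a function of time) and `label`.
#' @export
#' @examples
#' sch <- light_step(2.1)
#' schedule_intensity(sch, c(-1, 0, 1))
light_constant <- function(intensity, direction = c(0, 0, -1),
                           label = "constant") {
  stop_if_not(intensity >= 0, "intensity must be non-negative")
  new_light_schedule(function(t) rep_len(intensity, length(t)),
                     direction, label)
}

#' @rdname light_constant
#' @export
light_step <- function(intensity, t_on = 0, direction = c(0, 0, -1),
                       label = "dark-light switch") {
  stop_if_not(intensity >= 0, "intensity must be non-negative")
  new_light_schedule(function(t) ifelse(t >= t_on, intensity, 0),
                     direction, label)
}

#' @rdname light_constant
#' @export
light_pulsed <- function(stack = filter_stack(), peak_intensity = 28,
                         t_on = 0, direction = c(0, 0, -1),
                         label = "rotating-filter pulse train") {
  stop_if_not(peak_intensity >= 0, "peak_intensity must be non-negative")
  force(stack); force(t_on)
  f <- function(t) {
    ang <- (360 * stack$rotation_rate * (t - t_on)) %% 360
    ang <- pmin(ang, 360 - ang)
    ifelse(t >= t_on,
           peak_intensity * stacked_transmissivity(stack, ang), 0)
  }
  new_light_schedule(f, direction, label)
}

#' @rdname light_constant
#' @export
light_off <- function(direction = c(0, 0, -1), label = "darkness") {
  new_light_schedule(function(t) rep_len(0, length(t)), direction, label)
}

new_light_schedule <- function(intensity_of_time, direction, label) {
  d <- direction / sqrt(sum(direction^2))
  structure(list(direction = d, intensity_of_time = intensity_of_time,
                 label = label),
            class = "light_schedule")
}

#' Incident intensity of a schedule at given times
#'
#' @param schedule a light schedule.
#' @param t times (s).
#' @return irradiance(s).
#' @export
schedule_intensity <- function(schedule, t) schedule$intensity_of_time(t)

## ---------------------------------------------------------------------

#' Perceived intensity of one somatic cell
#'
#' Incident intensity scaled by the eye directivity at the angle between
#' the cell's lab-frame eye axis and the direction toward the source, and
#' by the cell's eyespot area relative to the anterior eyespot area
#' (photon capture proportional to eyespot area).  Blind cells perceive
#' nothing.
#'
#' @param cell one row of a spheroid's `cells` data frame.
#' @param spheroid_orientation body-to-lab rotation matrix.
#' @param schedule a light schedule.
#' @param t time (s).
#' @param anterior_diameter eyespot diameter used as the area reference
#'   (um).
#' @param d a [directivity()].
#' @return perceived irradiance (umol m-2 s-1).
#' @export
perceived_intensity <- function(cell, spheroid_orientation, schedule, t,
                                anterior_diameter = 3.6,
                                d = directivity()) {
  if (cell$eyespot_diameter <= 0) return(0)
  eye_lab <- as.numeric(spheroid_orientation %*%
                          c(cell$ex, cell$ey, cell$ez))
  toward_source <- -schedule$direction
  ang <- angle_between_deg(eye_lab, toward_source)
  incident <- schedule$intensity_of_time(t)
  incident * directivity_value(ang, d) *
    (cell$eyespot_diameter / anterior_diameter)^2
}

#' Photoresponse strength of a perceived intensity
#'
#' Saturable (Michaelis-Menten) dose-response:
#' `min(1, (1 + K / I_sat) * I / (I + K))`.  The scaling makes the
#' response reach exactly 1 at `I_sat = 0.16` umol m-2 s-1 and stay
#' saturated above it (no further gain up to the highest intensities
#' tested, ~457 umol m-2 s-1), while remaining positive for any
#' positive input.  The half-saturation constant `K = 0.002` places the
#' partial-response regime where it is observed: the perceived
#' intensities reaching anterior cells at a dim (two decades below
#' saturation) incident stimulus elicit roughly a third of the full
#' response, reproducing the weak (~70% residual speed) photophobic
#' reaction at dim light.  The ineffectiveness of the very dimmest
#' stimuli is handled separately by the detection floor in
#' [kinetics_params()] (`step_up_min`), not by this curve.
#'
#' @param perceived perceived irradiance (umol m-2 s-1); vectorized.
#' @param saturation irradiance at which the response reaches 1.
#' @param half_sat half-saturation constant (umol m-2 s-1).
#' @return response fraction(s) in \[0, 1\].
#' @export
#' @examples
#' response_strength(c(0, 0.016, 0.16, 457))
response_strength <- function(perceived, saturation = 0.16,
                              half_sat = 0.002) {
  stop_if_not(all(perceived >= 0), "perceived intensity must be >= 0")
  pmin(1, (1 + half_sat / saturation) * perceived / (perceived + half_sat))
}
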