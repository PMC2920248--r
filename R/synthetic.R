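## Synthetic track sets with known, controllable structure, emulating
## the statistical shape of the tracking data: roughly 1 mm/s swimmers
## whose speed depends on heading (faster downward than upward), a
## transient photophobic deceleration with passive sinking after the
## dark-light switch, reorientation toward the source afterwards, and
## additive positional noise.  Velocity noise is deliberately omitted so
## that in the zero-noise limit every constructed parameter is recovered
## exactly by the analysis pipeline.

#' Parameters of the synthetic track generator
#'
#' Defaults mirror the measured values: 0.88 mm/s upward and 1.06 mm/s
#' horizontal dark swimming speed, a 1.5-fold faster descent, a
#' photophobic drop to 40% of the pre-switch speed lasting 2 s with a
#' 0.45-mm sinking excursion.
#'
#' @param n_tracks number of tracks.
#' @param v_up,v_down,v_horizontal dark swimming speed by heading
#'   (mm/s).
#' @param photophobic_drop_fraction post-switch speed as a fraction of
#'   the pre-switch speed during the photophobic phase.
#' @param photophobic_duration length of the photophobic phase (s).
#' @param sinking_drop total vertical drop inserted during the
#'   photophobic phase (mm).
#' @param heading_bias von Mises-Fisher concentration of pre-switch
#'   headings toward the light source; 0 = isotropic.
#' @param position_noise_sd SD of additive Gaussian positional noise
#'   (mm).
#' @param seed integer seed.
#' @return an object of class `track_generator_params`.
#' @export
track_generator_params <- function(n_tracks = 65,
                                   v_up = 0.88, v_down = 1.32,
                                   v_horizontal = 1.06,
                                   photophobic_drop_fraction = 0.4,
                                   photophobic_duration = 2,
                                   sinking_drop = 0.45,
                                   heading_bias = 0,
                                   position_noise_sd = 0.005,
                                   seed = 1L) {
  stop_if_not(all(c(v_up, v_down, v_horizontal) > 0),
              "speeds must be positive")
  stop_if_not(photophobic_drop_fraction > 0 &&
                photophobic_drop_fraction <= 1,
              "photophobic_drop_fraction must lie in (0, 1]")
  stop_if_not(position_noise_sd >= 0, "noise must be non-negative")
  stop_if_not(n_tracks >= 1, "n_tracks must be at least 1")
  structure(as.list(environment()), class = "track_generator_params")
}

## von Mises-Fisher sample of n unit vectors about `axis`
rvmf <- function(n, axis, kappa) {
  if (kappa <= 0) return(random_unit_vectors(n))
  u <- stats::runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  ## orthonormal frame around axis
  a <- axis / sqrt(sum(axis^2))
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * a) * a; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  t(sapply(seq_len(n), function(i)
    w[i] * a + s[i] * (cos(phi[i]) * e1 + sin(phi[i]) * e2)))
}

## dark swimming speed (mm/s) as a function of the vertical heading
## component, piecewise linear through (up, horizontal, down)
dark_speed_of_heading <- function(uz, params) {
  ifelse(uz >= 0,
         params$v_horizontal + uz * (params$v_up - params$v_horizontal),
         params$v_horizontal - uz * (params$v_down - params$v_horizontal))
}

#' Generate synthetic tracks around a dark-light switch
#'
#' Piecewise-constant-velocity tracks sampled at the chamber's sampling
#' interval: each track swims with a heading drawn from the configured
#' distribution at the heading-dependent dark speed; at the switch
#' (t = 0) its speed drops to `photophobic_drop_fraction` of the
#' pre-switch speed, with the vertical velocity set to deliver
#' `sinking_drop` over `photophobic_duration` (vertical chamber only);
#' afterwards it swims toward the light source at its pre-switch speed.
#' Gaussian positional noise is added throughout.  Tracks are generated
#' in an unbounded copy of the chamber geometry so that constructed
#' quantities are recovered exactly in the zero-noise limit.
#'
#' @param params a [track_generator_params()] object.
#' @param config a [chamber_config()]; supplies geometry, light axis and
#'   sampling interval.
#' @param t_start,t_end track extent around the switch at t = 0 (s).
#' @return a `volvox_tracks` data frame with `switch_time = 0`.
#' @export
#' @examples
#' tr <- generate_tracks(track_generator_params(n_tracks = 5,
#'                                              position_noise_sd = 0))
#' relative_speed_curve(tr)
generate_tracks <- function(params, config = chamber_config(),
                            t_start = -2, t_end = 5) {
  set.seed(as.integer(params$seed))
  n <- params$n_tracks
  dims <- config$internal_dimensions
  clamped <- config$orientation == "HORIZONTAL_B"
  toward <- -config$light$direction
  t <- seq(t_start, t_end, by = config$sampling_dt)

  heading <- rvmf(n, toward, params$heading_bias)
  if (clamped) {                       # flat chamber: headings in-plane
    heading[, 3] <- 0
    nrm <- sqrt(rowSums(heading^2))
    nrm[nrm == 0] <- 1
    heading <- heading / nrm
  }
  v_dark <- if (clamped) rep(params$v_horizontal, n)
            else dark_speed_of_heading(heading[, 3], params)

  start <- cbind(stats::runif(n, 0, dims[1]),
                 stats::runif(n, 0, dims[2]),
                 stats::runif(n, 0, dims[3]))
  f <- params$photophobic_drop_fraction
  dur <- params$photophobic_duration

  rows <- lapply(seq_len(n), function(i) {
    u <- heading[i, ]
    v0 <- v_dark[i] * u
    sp1 <- f * v_dark[i]
    if (clamped) {
      v1 <- sp1 * u
    } else {
      vz <- -params$sinking_drop / dur
      hmag2 <- sp1^2 - vz^2
      if (hmag2 <= 0) {                # drop alone exceeds the slowed
        v1 <- c(0, 0, -sp1)            # speed: sink straight down
      } else {
        h <- u; h[3] <- 0
        hn <- sqrt(sum(h^2))
        hdir <- if (hn < 1e-12) c(1, 0, 0) else h / hn
        v1 <- sqrt(hmag2) * hdir + c(0, 0, vz)
      }
    }
    v2 <- v_dark[i] * toward
    pos <- matrix(NA_real_, length(t), 3)
    for (j in seq_along(t)) {
      tj <- t[j]
      p <- if (tj <= 0) start[i, ] + v0 * tj
           else if (tj <= dur) start[i, ] + v1 * tj
           else start[i, ] + v1 * dur + v2 * (tj - dur)
      pos[j, ] <- p
    }
    if (params$position_noise_sd > 0)
      pos <- pos + stats::rnorm(length(pos), 0, params$position_noise_sd)
    if (clamped) pos[, 3] <- start[i, 3]
    data.frame(spheroid_id = i, t = t,
               x = pos[, 1], y = pos[, 2], z = pos[, 3])
  })
  df <- do.call(rbind, rows)
  df$light_on <- as.integer(df$t >= 0)
  structure(df,
            class = c("volvox_tracks", "data.frame"),
            sampling_dt = config$sampling_dt,
            switch_time = 0,
            config = config,
            z_clamped = clamped)
}

#' Generate a synthetic pulse-response series
#'
#' A response that stays at its suppressed baseline for
#' `initial_suppression` seconds and then oscillates at the stimulus
#' period with minima lagging the reference intensity peaks (at t = 0
#' mod `period`) by `lag`, plus additive Gaussian noise.
#'
#' @param lag lag of the response minima behind the intensity peaks (s).
#' @param period stimulus period (s).
#' @param amplitude oscillation amplitude (response units).
#' @param initial_suppression initial flat-minimal phase (s).
#' @param noise_sd additive noise SD.
#' @param seed integer seed.
#' @param duration,dt series extent and sampling (s).
#' @param baseline minimal response level.
#' @return data frame with columns `t` and `value`, attribute
#'   `"period"`.
#' @export
#' @examples
#' ps <- generate_pulse_response(lag = 0.3, period = 1.2, amplitude = 1,
#'                               initial_suppression = 2.5,
#'                               noise_sd = 0, seed = 1)
#' estimate_response_lag(ps$t, ps$value, period = 1.2, skip = 2.5)
generate_pulse_response <- function(lag, period, amplitude,
                                    initial_suppression = 2.5,
                                    noise_sd = 0, seed = 1L,
                                    duration = 20, dt = 0.01,
                                    baseline = 0.1) {
  stop_if_not(period > 0, "period must be positive")
  set.seed(as.integer(seed))
  t <- seq(0, duration, by = dt)
  v <- ifelse(t < initial_suppression,
              baseline,
              baseline + amplitude *
                (1 - cos(2 * pi * (t - lag) / period)) / 2)
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
  structure(data.frame(t = t, value = v), period = period)
}
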