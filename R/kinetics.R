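## Photoresponse kinetics: each somatic cell converts its perceived
## intensity history into a flagellar beating mode.  A sufficient step-up
## in perceived intensity (relative to a short running-mean baseline)
## triggers, after a sampled latency of ~100 ms, a ~30 ms transition into
## the reverse beating mode, which persists for 2-3 s under sustained
## light before the cell adapts back to normal beating.  Once a cell has
## completed one full photophobic cycle it is "entrained": subsequent
## reversals are cut short as soon as the perceived intensity steps back
## down, which lets the population follow a periodic stimulus.

MODE_LEVELS <- c("NORMAL", "LATENT", "TRANSITION_TO_REVERSE",
                 "REVERSED", "TRANSITION_TO_NORMAL")

#' Photoresponse kinetics parameters
#'
#' Defaults follow the measured reaction kinetics: reversal latency
#' 100 +/- 25 ms after a dark-light switch, 30 ms mode transition,
#' reversal persisting 2-3 s, and beat frequencies of 22 Hz (normal) and
#' 40 Hz (reverse).
#'
#' @param latency_mean,latency_sd mean and SD of the reversal latency (s);
#'   latencies are sampled from a normal truncated below at `latency_min`.
#' @param latency_min lower truncation of the latency distribution (s).
#' @param transition_time duration of the switch between beating modes (s).
#' @param reversal_duration persistence of the reverse mode under
#'   sustained light (s).  Cell-level persistence is 2-3 s; the default
#'   2.0 s is the low end of that range, matching the ~2 s
#'   organism-level photophobic phase during which the colony sinks
#'   ~0.45 mm at 220 um/s.
#' @param normal_beat_freq,reverse_beat_freq beat frequencies (Hz).
#' @param step_up_threshold relative intensity increase (against the
#'   running-mean baseline) that triggers a response.
#' @param step_up_min photoreceptor detection floor: absolute perceived
#'   step (umol m-2 s-1) below which a step-up is invisible however
#'   large its relative size.  Models the photon-noise limit that makes
#'   the dimmest stimuli ineffective.
#' @param baseline_tau time constant of the adaptation baseline (s).
#' @param responsive_arc_fraction cells whose arc distance from the
#'   anterior pole exceeds this fraction never respond, reflecting the
#'   anterior-posterior photoresponse gradient (only anterior-hemisphere
#'   cells show an effective light response).
#' @param dark_adaptation_factor multiplier in \[0, 1\] applied to the
#'   response probability after dark adaptation (see
#'   [dark_adaptation_factor()]).
#' @return an object of class `kinetics_params`.
#' @export
kinetics_params <- function(latency_mean = 0.100, latency_sd = 0.025,
                            latency_min = 0.010,
                            transition_time = 0.030,
                            reversal_duration = 2.0,
                            normal_beat_freq = 22,
                            reverse_beat_freq = 40,
                            step_up_threshold = 0.2,
                            step_up_min = 5e-4,
                            baseline_tau = 0.5,
                            responsive_arc_fraction = 0.5,
                            dark_adaptation_factor = 1) {
  stop_if_not(latency_mean > 0 && latency_sd >= 0 && latency_min > 0 &&
                transition_time > 0 && reversal_duration > 0,
              "all times must be positive")
  stop_if_not(normal_beat_freq > 0 && reverse_beat_freq > 0,
              "beat frequencies must be positive")
  stop_if_not(step_up_threshold > 0, "step_up_threshold must be positive")
  stop_if_not(dark_adaptation_factor >= 0 && dark_adaptation_factor <= 1,
              "dark_adaptation_factor must lie in [0, 1]")
  structure(as.list(environment()), class = "kinetics_params")
}

#' Initialize cell beating-mode states
#'
#' @param n number of cells.
#' @return an object of class `cell_states` holding, per cell, the mode
#'   (`NORMAL`, `LATENT`, `TRANSITION_TO_REVERSE`, `REVERSED`,
#'   `TRANSITION_TO_NORMAL`), the stage timer, the adaptation baseline,
#'   the trigger arming flag, the entrainment flag and the last perceived
#'   intensity.
#' @export
cell_states <- function(n) {
  structure(list(mode = rep(1L, n),
                 timer = numeric(n),
                 baseline = numeric(n),
                 armed = rep(TRUE, n),
                 entrained = rep(FALSE, n),
                 last_perceived = numeric(n)),
            class = "cell_states")
}

## sample latencies from a truncated normal (rejection; the truncation at
## latency_min = 10 ms removes a ~0.02 % tail at the default parameters)
sample_latency <- function(n, params) {
  if (n == 0L) return(numeric(0))
  if (params$latency_sd == 0) return(rep(params$latency_mean, n))
  out <- stats::rnorm(n, params$latency_mean, params$latency_sd)
  bad <- out < params$latency_min
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), params$latency_mean,
                             params$latency_sd)
    bad <- out < params$latency_min
  }
  out
}

#' Advance cell beating-mode states by one time step
#'
#' Vectorized over cells.  A relative step-up in perceived intensity
#' beyond `step_up_threshold` (against the running-mean baseline) while a
#' cell beats normally starts the latency stage with probability
#' `response_strength(perceived) * dark_adaptation_factor`; the cell then
#' passes through the transition into the reverse mode, which persists
#' for `reversal_duration` under sustained light.  The first reversal of
#' a cell always runs its full course; afterwards ("entrained") a step-
#' down in perceived intensity ends the reversal immediately via the
#' return transition.  Constant perceived intensity leaves normally
#' beating cells unchanged.
#'
#' @param states a [cell_states()] object.
#' @param perceived perceived irradiance per cell (umol m-2 s-1).
#' @param dt time step (s); must not exceed 10 ms so stage transitions
#'   are resolved.
#' @param params a [kinetics_params()] object.
#' @return the advanced `cell_states` object.
#' @export
update_cell_states <- function(states, perceived, dt, params) {
  stop_if_not(dt > 0 && dt <= 0.010 + 1e-12,
              "dt must be positive and at most 10 ms")
  n <- length(states$mode)
  stop_if_not(length(perceived) == n,
              "one perceived intensity per cell is required")
  eps <- 1e-9
  base <- states$baseline
  rel_up <- (perceived - base) / pmax(base, eps)
  rel_down <- (base - perceived) / pmax(base, eps)
  thr <- params$step_up_threshold

  mode <- states$mode
  timer <- states$timer
  entrained <- states$entrained
  armed <- states$armed

  ## trigger on the rising edge only: the cell must have re-armed (seen
  ## the relative step fall below threshold) since its last trigger,
  ## and the absolute step must clear the detection floor
  edge <- armed & rel_up > thr & (perceived - base) > params$step_up_min
  armed <- ifelse(rel_up <= thr, TRUE, armed & !edge)

  fire <- edge & mode == 1L
  if (any(fire)) {
    p_resp <- response_strength(perceived[fire]) *
      params$dark_adaptation_factor
    go <- stats::runif(sum(fire)) < p_resp
    idx <- which(fire)[go]
    if (length(idx)) {
      mode[idx] <- 2L
      timer[idx] <- sample_latency(length(idx), params)
    }
  }

  ## stage progression (evaluated on the pre-update stage)
  lat <- mode == 2L
  timer[lat] <- timer[lat] - dt
  done <- lat & timer <= 0
  mode[done] <- 3L
  timer[done] <- params$transition_time + timer[done]

  t2r <- mode == 3L & !done
  timer[t2r] <- timer[t2r] - dt
  d2 <- t2r & timer <= 0
  mode[d2] <- 4L
  timer[d2] <- params$reversal_duration + timer[d2]

  rev <- mode == 4L & !d2
  cut <- rev & entrained & rel_down > thr
  timer[rev] <- timer[rev] - dt
  expired <- rev & !cut & timer <= 0
  entrained[expired] <- TRUE
  stop_rev <- cut | expired
  mode[stop_rev] <- 5L
  timer[stop_rev] <- ifelse(cut[stop_rev], params$transition_time,
                            params$transition_time + timer[stop_rev])

  t2n <- mode == 5L & !stop_rev
  timer[t2n] <- timer[t2n] - dt
  d3 <- t2n & timer <= 0
  mode[d3] <- 1L
  timer[d3] <- 0

  states$mode <- mode
  states$timer <- timer
  states$baseline <- base + (dt / params$baseline_tau) * (perceived - base)
  states$armed <- armed
  states$entrained <- entrained
  states$last_perceived <- perceived
  states
}

#' Advance a single cell state
#'
#' Scalar convenience wrapper around [update_cell_states()].
#'
#' @inheritParams update_cell_states
#' @param state single-cell `cell_states` object (length 1).
#' @param perceived perceived irradiance (scalar).
#' @return the advanced single-cell state.
#' @export
update_cell_state <- function(state, perceived, dt,
                              params = kinetics_params()) {
  update_cell_states(state, perceived, dt, params)
}

#' Mode labels of a state object
#'
#' @param states a [cell_states()] object.
#' @return character vector of mode names.
#' @export
state_modes <- function(states) MODE_LEVELS[states$mode]

#' Beat period of a beating mode
#'
#' @param mode `"NORMAL"` or `"REVERSED"`.
#' @param params a [kinetics_params()] object.
#' @return stroke period in seconds (1/22 Hz ~ 45 ms normal, 1/40 Hz =
#'   25 ms reverse at the defaults).
#' @export
beat_period <- function(mode, params = kinetics_params()) {
  switch(mode,
         NORMAL = 1 / params$normal_beat_freq,
         REVERSED = 1 / params$reverse_beat_freq,
         stop("beat period is undefined for transition modes",
              call. = FALSE))
}

## ---------------------------------------------------------------------
## Dark adaptation

#' Dark-adaptation efficiency table
#'
#' Phototactic efficiency after a dark period, measured as the fraction
#' of spheroids reaching the chamber area nearest the light source.  The
#' default anchors are the study-condition measurements binned over
#' 10-min dark periods (anchored at bin midpoints); efficiency declines
#' from 1.0 (light-adapted) to ~0.62 after 80-90 min, with no further
#' significant decrease beyond one hour.  One adjacent-bin inversion
#' (within its reported SDs) is pooled by isotonic regression so the
#' tabulated trend is non-increasing.
#'
#' @param dark_minutes anchor dark periods (min).
#' @param efficiency efficiency fractions at the anchors.
#' @param monotone pool adjacent increases (pool-adjacent-violators)?
#' @return an object of class `dark_adaptation`.
#' @export
dark_adaptation <- function(dark_minutes = c(0, 5, 15, 25, 35, 45,
                                             55, 65, 75, 85),
                            efficiency = c(1, 0.973, 0.865, 0.877, 0.845,
                                           0.815, 0.672, 0.652, 0.638,
                                           0.619),
                            monotone = TRUE) {
  stop_if_not(length(dark_minutes) == length(efficiency),
              "anchors and efficiencies must have equal length")
  stop_if_not(all(diff(dark_minutes) > 0), "anchors must be increasing")
  stop_if_not(efficiency[1] == 1, "efficiency at zero dark time must be 1")
  eff <- efficiency
  if (monotone) {
    iso <- stats::isoreg(dark_minutes, -efficiency)
    eff <- -iso$yf
  }
  structure(list(dark_minutes = dark_minutes, efficiency = eff,
                 raw_efficiency = efficiency),
            class = "dark_adaptation")
}

#' Dark-adaptation factor
#'
#' Linear interpolation between the table anchors, constant beyond the
#' last anchor (darkness longer than ~1 h causes no further decrease).
#'
#' @param dark_minutes length of the dark period before stimulation
#'   (min); vectorized.
#' @param da a [dark_adaptation()] table.
#' @return efficiency fraction(s) in (0, 1\].
#' @export
#' @examples
#' dark_adaptation_factor(c(0, 55, 85, 200))
dark_adaptation_factor <- function(dark_minutes, da = dark_adaptation()) {
  stop_if_not(all(dark_minutes >= 0), "dark period must be non-negative")
  stats::approx(da$dark_minutes, da$efficiency, xout = dark_minutes,
                rule = 2)$y
}

#' Hydrodynamic lag bounds
#'
#' Under periodic stimulation the minimum of the fluid streamlines lags
#' the intensity peaks by a total lag that includes the cellular reaction
#' time; subtracting the reaction-time window gives the time the reversed
#' flagella need to bring the surrounding fluid to its minimum.
#'
#' @param total_lag observed lag between intensity peak and streamline
#'   minimum (s).
#' @param latency_window two-element reaction-time window (s), lower then
#'   upper.
#' @return two-element vector: bounds on the hydrodynamic lag (s).
#' @export
#' @examples
#' hydrodynamic_lag_bounds(0.300, c(0.100, 0.160))   # 0.140 to 0.200 s
hydrodynamic_lag_bounds <- function(total_lag, latency_window) {
  stop_if_not(length(latency_window) == 2 &&
                latency_window[1] <= latency_window[2],
              "latency_window must be (lower, upper)")
  stop_if_not(total_lag > latency_window[2],
              "total_lag must exceed the upper latency bound")
  c(total_lag - latency_window[2], total_lag - latency_window[1])
}
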