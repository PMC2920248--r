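## Virtual assays.  A 10 x 10 x 1 mm observation chamber is mounted
## either vertically (setup A: light from above, parallel to gravity;
## six areas stacked along the light axis) or horizontally (setup B:
## light from the side, perpendicular to gravity; three areas).  Colony
## trajectories are integrated with the full per-cell model and sampled
## every 0.1 s, the unit of exchange with the analysis pipeline.

#' Observation-chamber configuration
#'
#' @param orientation `"VERTICAL_A"` (light from above, six areas along
#'   the vertical light axis, area 1 on top) or `"HORIZONTAL_B"` (flat
#'   chamber, light from the side, three areas, area 1 nearest the
#'   source; the 1-mm gap hides sinking).
#' @param n_spheroids number of colonies.
#' @param duration recorded duration after the light switch (s).
#' @param light a light schedule (defaults to a saturating dark-light
#'   switch at t = 0 along the setup's light axis).
#' @param sampling_dt trajectory sampling interval (s).
#' @param burn_in dark swimming time before t = 0 used to randomize
#'   positions and headings with the model's own dynamics (s).
#' @return an object of class `chamber_config` with the internal chamber
#'   dimensions (mm), the light propagation axis and the area partition.
#' @export
chamber_config <- function(orientation = c("VERTICAL_A", "HORIZONTAL_B"),
                           n_spheroids = if (orientation == "VERTICAL_A")
                             40 else 65,
                           duration = 60,
                           light = NULL,
                           sampling_dt = 0.1,
                           burn_in = 10) {
  orientation <- match.arg(orientation)
  if (orientation == "VERTICAL_A") {
    dims <- c(x = 10, y = 1, z = 10)
    propagation <- c(0, 0, -1)       # from above, parallel to gravity
    n_areas <- 6L
  } else {
    dims <- c(x = 10, y = 10, z = 1)
    propagation <- c(1, 0, 0)        # from the x = 0 side
    n_areas <- 3L
  }
  if (is.null(light)) light <- light_step(2.1, direction = propagation)
  stop_if_not(n_spheroids >= 1, "n_spheroids must be at least 1")
  structure(list(orientation = orientation,
                 internal_dimensions = dims,
                 n_areas = n_areas,
                 light = light,
                 n_spheroids = as.integer(n_spheroids),
                 duration = duration,
                 sampling_dt = sampling_dt,
                 burn_in = burn_in),
            class = "chamber_config")
}

## distance of positions along the light propagation axis, measured from
## the chamber face nearest the source; used for the area partition
light_axis_depth <- function(config, xyz) {
  p <- config$light$direction
  d <- xyz %*% p
  face <- sum(pmin(p * config$internal_dimensions, 0))
  as.numeric(d) - face
}

## area index (1 = nearest the source) for an n x 3 position matrix
area_index_of <- function(config, xyz) {
  span <- sum(abs(config$light$direction * config$internal_dimensions))
  depth <- light_axis_depth(config, xyz)
  idx <- 1L + pmin(config$n_areas - 1L,
                   floor(depth / span * config$n_areas))
  as.integer(pmax(1L, idx))
}

## uniform random rotation matrix
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-6) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

## ---------------------------------------------------------------------
## Core integrator for one colony.  Positions in mm, dt in s.  The RNG
## state of the caller drives all stochastic elements (latency sampling,
## response Bernoulli draws, rotational diffusion).
## Positions are held fixed before `move_from` (the dark burn-in then
## randomizes headings through the rotational dynamics while the
## colonies keep their seeded, uniformly distributed positions).
simulate_one <- function(spheroid, schedule, loco, kin,
                         dims_mm, t_start, t_end, dt = 0.01,
                         sampling_dt = 0.1, record_from = t_start,
                         move_from = t_start,
                         position = NULL, orientation = NULL) {
  cells <- spheroid$cells
  n <- nrow(cells)
  tm <- thrust_model(spheroid, loco)
  E <- t(cbind(cells$ex, cells$ey, cells$ez))        # 3 x n eye axes
  d0 <- spheroid$gradient$anterior_eyespot_diameter
  resp_gain <- (cells$eyespot_diameter / d0)^2 *
    (cells$arc_fraction <= kin$responsive_arc_fraction)
  dvty <- directivity()
  cos_bounds <- rev(cos(deg2rad(dvty$sector_half_angles)))
  lev <- rev(dvty$levels)

  pos <- if (is.null(position)) dims_mm / 2 else position
  Q <- if (is.null(orientation)) diag(3) else orientation
  st <- cell_states(n)
  rad_mm <- spheroid$radius * 1e-3
  lo <- rep(rad_mm, 3); hi <- dims_mm - rad_mm
  toward <- -schedule$direction
  s_sink <- loco$sinking_speed
  k_right <- loco$righting_rate
  sig_rot <- sqrt(2 * loco$rotational_diffusion / dt)

  n_steps <- round((t_end - t_start) / dt)
  every <- max(1L, round(sampling_dt / dt))
  keep <- which((seq_len(n_steps + 1L) - 1L) %% every == 0 &
                  t_start + (seq_len(n_steps + 1L) - 1L) * dt >=
                  record_from - 1e-9)
  out_t <- numeric(length(keep)); out_p <- matrix(0, length(keep), 3)
  out_i <- 1L

  for (step in 0:n_steps) {
    t <- t_start + step * dt
    if (out_i <= length(keep) && (step + 1L) == keep[out_i]) {
      out_t[out_i] <- t
      out_p[out_i, ] <- pos
      out_i <- out_i + 1L
    }
    if (step == n_steps) break

    I <- schedule$intensity_of_time(t)
    if (I > 0 || any(st$baseline > 0)) {
      eye_lab <- Q %*% E
      cosang <- toward %*% eye_lab                   # 1 x n
      j <- findInterval(cosang, cos_bounds)
      perceived <- I * lev[j + 1L] * resp_gain
    } else {
      perceived <- numeric(n)
    }
    st <- update_cell_states(st, perceived, dt, kin)

    mf <- tm$mag * mode_thrust_factor(st, loco, kin)
    Fb <- as.numeric(crossprod(tm$dir, mf))
    Tb <- tm$mobility * as.numeric(crossprod(tm$moment, mf))

    axis <- Q[, 3]
    v <- Q %*% Fb
    v[3] <- v[3] - s_sink
    ## orientation noise: angular-velocity SD sqrt(2 D / dt) gives angle
    ## increments with SD sqrt(2 D dt)
    w <- Q %*% Tb + k_right * c(axis[2], -axis[1], 0) +
      sig_rot * stats::rnorm(3)
    ang <- sqrt(sum(w^2)) * dt
    if (ang > 1e-12) Q <- rot_axis_angle(w, ang) %*% Q
    if (step %% 40L == 0L) Q <- orthonormalize(Q)
    if (t >= move_from - 1e-9)
      pos <- pmin(pmax(pos + as.numeric(v) * dt * 1e-3, lo), hi)
  }
  list(t = out_t, pos = out_p)
}

## assemble per-colony samples into the tidy track table
make_tracks <- function(res_list, config, schedule, switch_time = 0) {
  df <- do.call(rbind, lapply(seq_along(res_list), function(i) {
    r <- res_list[[i]]
    data.frame(spheroid_id = i, t = r$t,
               x = r$pos[, 1], y = r$pos[, 2], z = r$pos[, 3])
  }))
  df$light_on <- as.integer(schedule_intensity(schedule, df$t) > 0)
  structure(df,
            class = c("volvox_tracks", "data.frame"),
            sampling_dt = config$sampling_dt,
            switch_time = switch_time,
            config = config,
            z_clamped = config$orientation == "HORIZONTAL_B")
}

#' Simulate a photoaccumulation assay
#'
#' Colonies start at uniform random positions and orientations, swim in
#' darkness for the burn-in, then the configured light schedule switches
#' on at t = 0.  Trajectories are recorded from t = 0 at the sampling
#' interval.
#'
#' @param config a [chamber_config()].
#' @param spheroid_template a [build_spheroid()] object used for every
#'   colony.
#' @param seed integer seed; identical configurations and seeds give
#'   identical track sets.
#' @param loco optional pre-calibrated [locomotion_params()].
#' @param kinetics a [kinetics_params()] object.
#' @return a `volvox_tracks` data frame (columns `spheroid_id`, `t`,
#'   `x`, `y`, `z`, `light_on`) with the chamber configuration attached
#'   as attributes.
#' @export
run_photoaccumulation <- function(config, spheroid_template, seed = 1L,
                                  loco = NULL,
                                  kinetics = kinetics_params()) {
  set.seed(as.integer(seed))
  if (is.null(loco))
    loco <- calibrate_locomotion(spheroid_template, kinetics)
  dims <- config$internal_dimensions
  rad <- spheroid_template$radius * 1e-3
  res <- lapply(seq_len(config$n_spheroids), function(i) {
    p0 <- stats::runif(3, rad, dims - rad)
    simulate_one(spheroid_template, config$light, loco, kinetics,
                 dims, t_start = -config$burn_in, t_end = config$duration,
                 sampling_dt = config$sampling_dt, record_from = 0,
                 move_from = 0,
                 position = p0, orientation = random_rotation())
  })
  make_tracks(res, config, config$light)
}

#' Simulate a dark-light switch tracking experiment
#'
#' As [run_photoaccumulation()], but records from 2 s before the switch
#' so that pre-switch headings and speeds are available, and runs for
#' `post` seconds after the switch.
#'
#' @inheritParams run_photoaccumulation
#' @param intensity irradiance after the switch (umol m-2 s-1).
#' @param pre,post recorded time before/after the switch (s).
#' @return a `volvox_tracks` data frame with `switch_time = 0`.
#' @export
run_dark_light_switch <- function(config, spheroid_template, intensity,
                                  seed = 1L, pre = 2, post = 5,
                                  loco = NULL,
                                  kinetics = kinetics_params()) {
  set.seed(as.integer(seed))
  if (is.null(loco))
    loco <- calibrate_locomotion(spheroid_template, kinetics)
  schedule <- light_step(intensity,
                         direction = config$light$direction)
  dims <- config$internal_dimensions
  rad <- spheroid_template$radius * 1e-3
  res <- lapply(seq_len(config$n_spheroids), function(i) {
    p0 <- stats::runif(3, rad, dims - rad)
    simulate_one(spheroid_template, schedule, loco, kinetics,
                 dims, t_start = -config$burn_in, t_end = post,
                 sampling_dt = config$sampling_dt, record_from = -pre,
                 move_from = -pre,
                 position = p0, orientation = random_rotation())
  })
  make_tracks(res, config, schedule)
}

#' Pulsed stimulation of an immobilized colony
#'
#' The colony is held in place (as when trapped between slide and cover
#' glass) with its body axis perpendicular to the light, while a
#' rotating filter stack modulates the incident intensity.  The surface
#' slip (streamline proxy) of anterior polar-angle regions is recorded
#' at every integration step.
#'
#' @param spheroid_template a [build_spheroid()] object.
#' @param stack a [filter_stack()].
#' @param duration stimulation time (s); after `light_off_at` (if
#'   finite) the light is switched off to probe the return to normal
#'   beating.
#' @param seed integer seed.
#' @param peak_intensity pulse-train peak irradiance.
#' @param regions named list of polar-angle bands (degrees from the
#'   anterior pole).
#' @param light_off_at time at which the pulse train stops (s), default
#'   never.
#' @param dt integration and recording step (s).
#' @param loco optional pre-calibrated [locomotion_params()].
#' @param kinetics a [kinetics_params()] object.
#' @return data frame with columns `t`, `intensity`, one slip column per
#'   region (um/s), and attribute `"period"` (stimulus period, s).
#' @export
run_pulsed_stimulation <- function(spheroid_template,
                                   stack = filter_stack(),
                                   duration = 20, seed = 1L,
                                   peak_intensity = 28,
                                   regions = list(r1 = c(0, 20),
                                                  r2 = c(20, 40),
                                                  r3 = c(40, 60)),
                                   light_off_at = Inf,
                                   dt = 0.01,
                                   loco = NULL,
                                   kinetics = kinetics_params()) {
  set.seed(as.integer(seed))
  if (is.null(loco))
    loco <- calibrate_locomotion(spheroid_template, kinetics)
  base <- light_pulsed(stack, peak_intensity, t_on = 0,
                       direction = c(1, 0, 0))
  f_int <- function(t) ifelse(t < light_off_at,
                              base$intensity_of_time(t), 0)
  schedule <- new_light_schedule(f_int, c(1, 0, 0), "pulsed")

  cells <- spheroid_template$cells
  n <- nrow(cells)
  E <- t(cbind(cells$ex, cells$ey, cells$ez))
  d0 <- spheroid_template$gradient$anterior_eyespot_diameter
  resp_gain <- (cells$eyespot_diameter / d0)^2 *
    (cells$arc_fraction <= kinetics$responsive_arc_fraction)
  dvty <- directivity()
  cos_bounds <- rev(cos(deg2rad(dvty$sector_half_angles)))
  lev <- rev(dvty$levels)
  toward <- -schedule$direction
  cosang <- as.numeric(toward %*% E)                # pose is fixed
  dir_val <- lev[findInterval(cosang, cos_bounds) + 1L]
  gain <- dir_val * resp_gain

  th <- cells$arc_fraction * 180
  region_sel <- lapply(regions, function(rg) th >= rg[1] & th <= rg[2])
  beta <- deg2rad(loco$azimuthal_tilt)
  slip_base <- loco$per_cell_thrust_normal * cells$weight * cos(beta)

  st <- cell_states(n)
  n_steps <- round(duration / dt)
  out <- matrix(0, n_steps + 1L, 2 + length(regions))
  for (step in 0:n_steps) {
    t <- step * dt
    I <- f_int(t)
    st_f <- mode_thrust_factor(st, loco, kinetics)
    out[step + 1L, ] <- c(t, I, vapply(region_sel, function(sel)
      mean(slip_base[sel] * st_f[sel]), numeric(1)))
    if (step == n_steps) break
    st <- update_cell_states(st, I * gain, dt, kinetics)
  }
  res <- as.data.frame(out)
  names(res) <- c("t", "intensity", names(regions))
  attr(res, "period") <- 1 / stack$rotation_rate
  res
}

#' Write / read tracks as a plain-text table
#'
#' Tab-separated table with `# key value` header lines preserving the
#' sampling interval, switch time and chamber geometry.
#'
#' @param tracks a `volvox_tracks` data frame.
#' @param path file path.
#' @return `write_tracks` returns `path` invisibly; `read_tracks`
#'   returns a `volvox_tracks` data frame.
#' @export
write_tracks <- function(tracks, path) {
  cfg <- attr(tracks, "config")
  hdr <- c(sampling_dt = attr(tracks, "sampling_dt"),
           switch_time = attr(tracks, "switch_time"),
           n_areas = cfg$n_areas,
           dim_x = cfg$internal_dimensions[["x"]],
           dim_y = cfg$internal_dimensions[["y"]],
           dim_z = cfg$internal_dimensions[["z"]],
           prop_x = cfg$light$direction[1],
           prop_y = cfg$light$direction[2],
           prop_z = cfg$light$direction[3],
           z_clamped = as.numeric(isTRUE(attr(tracks, "z_clamped"))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s %.17g", names(hdr), hdr), con)
  utils::write.table(as.data.frame(tracks), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^# ", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr_lines), " "))
  hdr <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  df <- utils::read.table(text = lines[!startsWith(lines, "# ")],
                          header = TRUE, sep = "\t")
  prop <- c(hdr[["prop_x"]], hdr[["prop_y"]], hdr[["prop_z"]])
  cfg <- list(orientation = if (hdr[["z_clamped"]] > 0) "HORIZONTAL_B"
              else "VERTICAL_A",
              internal_dimensions = c(x = hdr[["dim_x"]],
                                      y = hdr[["dim_y"]],
                                      z = hdr[["dim_z"]]),
              n_areas = as.integer(hdr[["n_areas"]]),
              light = new_light_schedule(function(t) rep_len(NA_real_,
                                                             length(t)),
                                         prop, "from file"),
              sampling_dt = hdr[["sampling_dt"]])
  class(cfg) <- "chamber_config"
  structure(df,
            class = c("volvox_tracks", "data.frame"),
            sampling_dt = hdr[["sampling_dt"]],
            switch_time = hdr[["switch_time"]],
            config = cfg,
            z_clamped = hdr[["z_clamped"]] > 0)
}
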