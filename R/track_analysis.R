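## Quantification of track sets: photoaccumulation index over chamber
## areas, heading-sector assignment, relative and absolute speed curves
## around a dark-light switch, sinking depth, and the phase lag of a
## periodic response.  Works on any `volvox_tracks` table: simulated,
## synthetic, or read from file.

## positions of every spheroid at one sample time (rows ordered by id)
positions_at <- function(tracks, t) {
  dt <- attr(tracks, "sampling_dt")
  sel <- abs(tracks$t - t) < dt / 2
  stop_if_not(any(sel), sprintf("no samples at t = %g", t))
  p <- tracks[sel, c("spheroid_id", "x", "y", "z")]
  p[order(p$spheroid_id), ]
}

#' Photoaccumulation index
#'
#' `PI = (B - A) * 100 / (100 - A)` where `A` is the percentage of
#' colonies inside the area at the switch time and `B` the percentage at
#' time `t`.  `PI` is 100 when every colony has accumulated in the area,
#' 0 when occupancy equals the baseline, and negative when colonies
#' left the area.  Times before the switch return 0 by definition.
#'
#' @param tracks a `volvox_tracks` data frame whose attributes carry the
#'   chamber partition.
#' @param area_index area number, 1 = nearest the light source.
#' @param t evaluation time (s); vectorized.
#' @return PI value(s) (dimensionless percentage, at most 100).
#' @export
photoaccumulation_index <- function(tracks, area_index, t) {
  cfg <- attr(tracks, "config")
  stop_if_not(!is.null(cfg), "tracks carry no chamber configuration")
  stop_if_not(area_index >= 1 && area_index <= cfg$n_areas,
              "area_index outside the chamber partition")
  sw <- attr(tracks, "switch_time")
  p0 <- positions_at(tracks, sw)
  a0 <- area_index_of(cfg, as.matrix(p0[, c("x", "y", "z")]))
  A <- 100 * mean(a0 == area_index)
  if (A >= 100)
    stop("baseline occupancy is 100%: PI is undefined", call. = FALSE)
  vapply(t, function(ti) {
    if (ti < sw) return(0)
    p1 <- positions_at(tracks, ti)
    a1 <- area_index_of(cfg, as.matrix(p1[, c("x", "y", "z")]))
    B <- 100 * mean(a1 == area_index)
    (B - A) * 100 / (100 - A)
  }, numeric(1))
}

#' Photoaccumulation-index curve
#'
#' @inheritParams photoaccumulation_index
#' @param times evaluation times; defaults to every sample time from the
#'   switch onward.
#' @return data frame with columns `area_index`, `t`, `pi` and the
#'   baseline occupancy attribute `"A_percent"`.
#' @export
pi_curve <- function(tracks, area_index = 1, times = NULL) {
  sw <- attr(tracks, "switch_time")
  if (is.null(times))
    times <- sort(unique(tracks$t[tracks$t >= sw]))
  pi <- photoaccumulation_index(tracks, area_index, times)
  cfg <- attr(tracks, "config")
  p0 <- positions_at(tracks, sw)
  a0 <- area_index_of(cfg, as.matrix(p0[, c("x", "y", "z")]))
  structure(data.frame(area_index = area_index, t = times, pi = pi),
            A_percent = 100 * mean(a0 == area_index))
}

#' Heading sectors relative to the light source
#'
#' The heading of each colony immediately before the switch is the line
#' from its position 1 s before the switch to its position at the
#' switch.  The angle between this line and the direction toward the
#' light source, in \[0, 180\] degrees, is binned into nine equal 20-degree
#' sectors labelled `a` (toward the source) through `i` (away from it);
#' bins are half-open at the lower edge and the final bin includes 180.
#'
#' @param tracks a `volvox_tracks` data frame with a switch time.
#' @return factor of sector labels (levels `a` to `i`), one per colony,
#'   `NA` (with a warning) for colonies with zero pre-switch
#'   displacement.
#' @export
assign_sector <- function(tracks) {
  sw <- attr(tracks, "switch_time")
  toward <- -attr(tracks, "config")$light$direction
  p0 <- positions_at(tracks, sw - 1)
  p1 <- positions_at(tracks, sw)
  d <- as.matrix(p1[, c("x", "y", "z")]) -
    as.matrix(p0[, c("x", "y", "z")])
  nrm <- sqrt(rowSums(d^2))
  if (any(nrm == 0))
    warning("zero pre-switch displacement: heading undefined")
  cosang <- (d %*% toward) / ifelse(nrm == 0, NA, nrm)
  theta <- rad2deg(acos(pmin(1, pmax(-1, cosang))))
  k <- pmin(8L, as.integer(floor(theta / 20)))
  factor(letters[k + 1L], levels = letters[1:9])
}

## chord speeds (mm/s) at offsets -1..4 around the switch; offset k >= 1
## uses the chord [k-1, k]; offsets -1 and 0 both report the pre-switch
## chord [-1, 0], which serves as the normalization window
chord_speeds <- function(tracks, offsets = -1:4) {
  sw <- attr(tracks, "switch_time")
  ids <- sort(unique(tracks$spheroid_id))
  need <- sort(unique(c(sw - 1, sw + 0:max(offsets, 1))))
  pos <- lapply(need, function(ti) {
    p <- tracks[abs(tracks$t - ti) < attr(tracks, "sampling_dt") / 2,
                c("spheroid_id", "x", "y", "z")]
    p[match(ids, p$spheroid_id), c("x", "y", "z")]
  })
  names(pos) <- sprintf("%.3f", need)
  at <- function(ti) as.matrix(pos[[sprintf("%.3f", ti)]])
  sp <- sapply(offsets, function(k) {
    kk <- max(k, 0)
    d <- at(sw + kk) - at(sw + kk - 1)
    sqrt(rowSums(d^2))
  })
  if (is.null(dim(sp))) sp <- matrix(sp, nrow = 1)
  colnames(sp) <- offsets
  rownames(sp) <- ids
  sp
}

#' Relative swimming-speed curve around a dark-light switch
#'
#' Speeds are chord lengths of 1-s displacement windows at offsets -1 to
#' +4 s around the switch, each track normalized by its pre-switch
#' window (set to 100%), then averaged over all tracks or per heading
#' sector.  Tracks lacking the full window (or with zero pre-switch
#' speed) are excluded with a warning.
#'
#' @param tracks a `volvox_tracks` data frame with a switch time.
#' @param group `"all"` or `"sector"`.
#' @return data frame with columns `sector` (`"all"` or `a`-`i`),
#'   `offset` (s), `mean`, `sd` (percent of pre-switch speed) and `n`.
#' @export
relative_speed_curve <- function(tracks, group = c("all", "sector")) {
  group <- match.arg(group)
  sp <- chord_speeds(tracks)
  ok <- stats::complete.cases(sp) & sp[, "0"] > 0
  if (!all(ok)) warning(sum(!ok), " track(s) lack the full window")
  if (!any(ok)) {
    warning("no usable tracks")
    return(data.frame(sector = character(), offset = numeric(),
                      mean = numeric(), sd = numeric(), n = integer()))
  }
  rel <- 100 * sp[ok, , drop = FALSE] / sp[ok, "0"]
  grp <- if (group == "sector") {
    as.character(assign_sector(tracks))[ok]
  } else rep("all", sum(ok))
  out <- do.call(rbind, lapply(split(seq_along(grp), grp), function(i) {
    data.frame(sector = grp[i[1]], offset = as.numeric(colnames(rel)),
               mean = colMeans(rel[i, , drop = FALSE]),
               sd = apply(rel[i, , drop = FALSE], 2, stats::sd),
               n = length(i))
  }))
  rownames(out) <- NULL
  out
}

#' Absolute swimming speed by heading sector
#'
#' Unnormalized chord speeds (mm/s) at offsets -1 to +4 s, averaged per
#' pre-switch heading sector.  The pre-switch (offset 0) column gives
#' the sector-dependence of the dark swimming speed; the ratio of the
#' downward sector `i` to the upward sector `a` measures how much
#' faster colonies swim toward the bottom than toward the top.
#'
#' @param tracks a `volvox_tracks` data frame with a switch time.
#' @return data frame with columns `sector`, `offset`, `mean` (mm/s),
#'   `sd` and `n`.
#' @export
absolute_speed_by_sector <- function(tracks) {
  sp <- chord_speeds(tracks)
  ok <- stats::complete.cases(sp)
  sec <- as.character(assign_sector(tracks))
  ok <- ok & !is.na(sec)
  grp <- sec[ok]
  rel <- sp[ok, , drop = FALSE]
  out <- do.call(rbind, lapply(split(seq_along(grp), grp), function(i) {
    data.frame(sector = grp[i[1]], offset = as.numeric(colnames(rel)),
               mean = colMeans(rel[i, , drop = FALSE]),
               sd = apply(rel[i, , drop = FALSE], 2, stats::sd),
               n = length(i))
  }))
  rownames(out) <- NULL
  out
}

#' Sinking depth after a dark-light switch
#'
#' Maximum drop of the vertical coordinate below its switch-time value
#' within the first `window` seconds after the switch, per colony.
#' Tracks from a horizontal chamber (clamped vertical coordinate) return
#' 0 and are flagged.
#'
#' @param tracks a `volvox_tracks` data frame with a switch time.
#' @param window post-switch search window (s).
#' @return numeric vector of depths (mm), one per colony, with
#'   attribute `"z_clamped"`.
#' @export
sinking_depth <- function(tracks, window = 3) {
  sw <- attr(tracks, "switch_time")
  clamped <- isTRUE(attr(tracks, "z_clamped"))
  ids <- sort(unique(tracks$spheroid_id))
  if (clamped)
    return(structure(stats::setNames(rep(0, length(ids)), ids),
                     z_clamped = TRUE))
  z0 <- positions_at(tracks, sw)$z
  depth <- vapply(seq_along(ids), function(i) {
    sel <- tracks$spheroid_id == ids[i] &
      tracks$t > sw & tracks$t <= sw + window
    max(0, z0[i] - min(tracks$z[sel]))
  }, numeric(1))
  structure(stats::setNames(depth, ids), z_clamped = FALSE)
}

#' Phase lag of a periodic response behind a pulse train
#'
#' Fits the first Fourier component of the (detrended) response at the
#' stimulus period and returns the lag of the response *minima* behind
#' the intensity peaks (taken at t = 0 mod period).
#'
#' @param t sample times (s).
#' @param value response values.
#' @param period stimulus period (s).
#' @param skip initial time to exclude (s), e.g. the suppressed phase.
#' @return lag in seconds, in \[0, period).
#' @export
estimate_response_lag <- function(t, value, period, skip = 0) {
  sel <- t >= skip
  stop_if_not(sum(sel) > 4, "too few samples to estimate a lag")
  tt <- t[sel]; v <- value[sel] - mean(value[sel])
  C <- sum(v * cos(2 * pi * tt / period))
  S <- sum(v * sin(2 * pi * tt / period))
  (atan2(-S, -C) / (2 * pi) * period) %% period
}
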