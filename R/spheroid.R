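## Spheroid morphology: a rigid spherical colony whose surface carries a
## monolayer of biflagellate somatic cells.  The colony is polarized along
## its swimming (posterior -> anterior) axis: anterior cells are larger,
## more widely spaced, and carry the largest eyespots; posterior cells are
## small, densely packed, and within a cap around the posterior pole they
## have no eyespot at all.  Internal daughter colonies make the posterior
## hemisphere denser, shifting the center of mass behind the geometric
## center ("bottom-heaviness").
##
## Conventions: body frame has the anterior pole on +z; body-frame lengths
## are in micrometres, lab-frame positions in millimetres, times in
## seconds.

#' Morphological gradient parameters of a polarized spheroid
#'
#' Defaults follow the measured anterior-posterior gradients of
#' *Volvox rousseletii*: anterior eyespots of ~3.6 um diameter whose
#' surface area is ~80-fold that of the last eyespot-bearing posterior
#' cells, cell spacing ~2.3-fold wider at the anterior pole, and
#' protoplast surface area ~1.8-fold larger anteriorly.
#'
#' @param anterior_eyespot_diameter eyespot diameter at the anterior pole
#'   (um).
#' @param posterior_area_ratio ratio of anterior eyespot surface area to
#'   the eyespot area at the edge of the blind posterior cap.
#' @param spacing_ratio ratio of anterior to posterior cell-to-cell
#'   spacing.
#' @param protoplast_area_ratio ratio of anterior to posterior protoplast
#'   surface area (used as the per-cell thrust weight gradient).
#' @param blind_cap_angle polar angle (degrees, measured from the
#'   posterior pole) within which cells carry no eyespot.
#' @return an object of class `gradient_params`.
#' @export
#' @examples
#' gradient_params()
gradient_params <- function(anterior_eyespot_diameter = 3.6,
                            posterior_area_ratio = 80,
                            spacing_ratio = 2.3,
                            protoplast_area_ratio = 1.8,
                            blind_cap_angle = 30) {
  stop_if_not(anterior_eyespot_diameter > 0,
              "anterior_eyespot_diameter must be positive")
  stop_if_not(posterior_area_ratio >= 1 && spacing_ratio >= 1 &&
                protoplast_area_ratio >= 1,
              "gradient ratios must be >= 1")
  stop_if_not(blind_cap_angle >= 0 && blind_cap_angle < 180,
              "blind_cap_angle must be in [0, 180)")
  structure(list(anterior_eyespot_diameter = anterior_eyespot_diameter,
                 posterior_area_ratio = posterior_area_ratio,
                 spacing_ratio = spacing_ratio,
                 protoplast_area_ratio = protoplast_area_ratio,
                 blind_cap_angle = blind_cap_angle),
            class = "gradient_params")
}

#' Eyespot diameter along the anterior-posterior axis
#'
#' The eyespot diameter decreases linearly with arc distance from the
#' anterior pole, reaching the diameter implied by the anterior/posterior
#' eyespot *area* ratio at the edge of the blind cap, and is zero inside
#' the blind cap (posterior cells are essentially blind).
#'
#' @param arc_distance_from_anterior arc distance from the anterior pole
#'   as a fraction of half the great circle (0 = anterior pole,
#'   1 = posterior pole).
#' @param gradient a [gradient_params()] object.
#' @return eyespot diameter (um), vectorized over
#'   `arc_distance_from_anterior`.
#' @export
#' @examples
#' eyespot_diameter_at(0, gradient_params())    # 3.6 um at the anterior pole
#' eyespot_diameter_at(1, gradient_params())    # blind posterior pole
eyespot_diameter_at <- function(arc_distance_from_anterior,
                                gradient = gradient_params()) {
  x <- arc_distance_from_anterior
  stop_if_not(all(x >= 0 & x <= 1), "arc distance must lie in [0, 1]")
  d0 <- gradient$anterior_eyespot_diameter
  x_blind <- 1 - gradient$blind_cap_angle / 180
  d_edge <- d0 / sqrt(gradient$posterior_area_ratio)
  d <- ifelse(x > x_blind, 0,
              d0 - (d0 - d_edge) * x / x_blind)
  unname(d)
}

## Inverse CDF of the polar cell-placement density.  Cell number density
## rho(c) ~ (1 + (s - 1) c)^2 in the cap-area coordinate
## c = (1 - cos(theta)) / 2 (0 at the anterior pole), which makes the
## local cell spacing (~ rho^-1/2) decrease by exactly `s` from anterior
## pole to posterior pole.
.placement_quantile <- function(u, spacing_ratio) {
  s <- spacing_ratio
  if (abs(s - 1) < 1e-12) return(u)
  (((1 + (s^3 - 1) * u)^(1 / 3)) - 1) / (s - 1)
}

#' Build a polarized spheroid
#'
#' Places `n_cells` somatic cells on the unit sphere using a generalized
#' spiral (Fibonacci) lattice whose polar coordinate is warped to realize
#' the anterior-posterior spacing gradient, then assigns per-cell eyespot
#' diameters, eye axes, flagellar thrust directions and thrust weights.
#' The center-of-mass offset is computed by direct mass summation over
#' the somatic shell plus a posterior daughter-colony point mass.
#'
#' @param n_cells number of somatic cells (>= 8); large spheroids carry
#'   ~5000.
#' @param radius colony radius in um.
#' @param gradient a [gradient_params()] object.
#' @param seed integer seed fixing the (single) random azimuthal phase of
#'   the lattice; identical inputs give bitwise-identical spheroids.
#' @param eye_tilt tilt of each eye axis away from the outward surface
#'   normal toward the posterior pole (degrees).  The tilt reflects the
#'   observation that eyespots face toward the posterior pole; its
#'   magnitude is a model assumption.
#' @param daughter_mass_fraction fraction of total colony mass in
#'   daughter colonies, modelled as a point mass halfway between center
#'   and posterior pole.
#' @param rotation_period target axial rotation period (s); the colony
#'   rotates counterclockwise as seen from behind roughly once every 1-3 s.
#' @param intrinsic_speed flagellar propulsion speed through still water
#'   (um/s) before subtracting sinking.
#' @param sinking_speed passive sinking speed (um/s).
#' @return an object of class `spheroid`: a list with scalar fields
#'   (`radius`, `position` (mm, lab), `orientation` (body->lab rotation),
#'   `com_offset` (um, negative = posterior), `sinking_speed`,
#'   `intrinsic_speed`, `rotation_period`, `eye_tilt`, `gradient`) and a
#'   data frame `cells` with one row per cell: body-frame surface
#'   position (`px,py,pz`), eye axis (`ex,ey,ez`), meridional thrust
#'   direction (`tx,ty,tz`, toward the anterior), azimuthal tangent
#'   (`ax,ay,az`), `eyespot_diameter` (um), `arc_fraction` and the
#'   protoplast-size thrust weight `weight`.
#' @export
#' @examples
#' sph <- build_spheroid(500, seed = 1)
#' sph
build_spheroid <- function(n_cells, radius = 250,
                           gradient = gradient_params(), seed = 1L,
                           eye_tilt = 30,
                           daughter_mass_fraction = 0.2,
                           rotation_period = 2,
                           intrinsic_speed = 1100,
                           sinking_speed = 220) {
  stop_if_not(is.numeric(n_cells) && n_cells >= 8,
              "n_cells must be at least 8")
  stop_if_not(radius > 0, "radius must be positive")
  stop_if_not(daughter_mass_fraction >= 0 && daughter_mass_fraction < 1,
              "daughter_mass_fraction must be in [0, 1)")
  n_cells <- as.integer(n_cells)

  set.seed(as.integer(seed))
  phi0 <- stats::runif(1, 0, 2 * pi)

  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n_cells) - 1
  u <- (i + 0.5) / n_cells
  cc <- .placement_quantile(u, gradient$spacing_ratio)
  cos_th <- 1 - 2 * cc                   # +1 anterior pole, -1 posterior
  sin_th <- sqrt(pmax(0, 1 - cos_th^2))
  phi <- (phi0 + i * golden) %% (2 * pi)

  px <- sin_th * cos(phi)
  py <- sin_th * sin(phi)
  pz <- cos_th

  ## tangent frame: meridional unit vector pointing toward the anterior
  ## (+z) pole, and the eastward azimuthal unit vector.
  ## m = (z_hat - cos_th * n) / sin_th
  tx <- -cos_th * cos(phi); ty <- -cos_th * sin(phi); tz <- sin_th
  ax <- -sin(phi); ay <- cos(phi); az <- rep(0, n_cells)

  arc_fraction <- acos(pmin(1, pmax(-1, cos_th))) / pi
  eyespot <- eyespot_diameter_at(arc_fraction, gradient)

  ## eye axis: outward normal tilted toward the posterior pole by eye_tilt
  tau <- deg2rad(eye_tilt)
  ex <- cos(tau) * px - sin(tau) * tx
  ey <- cos(tau) * py - sin(tau) * ty
  ez <- cos(tau) * pz - sin(tau) * tz

  ## Per-cell thrust weight: protoplast-size gradient (larger anterior
  ## cells carry longer, stronger flagella) divided by the local cell-
  ## packing density (crowded posterior cells interfere and contribute
  ## less each), so the propulsive surface force density follows the
  ## protoplast gradient.
  g1 <- gradient$protoplast_area_ratio
  s <- gradient$spacing_ratio
  packing <- (1 + (s - 1) * cc)^2
  weight <- (g1 - (g1 - 1) * arc_fraction) / packing
  weight <- weight / mean(weight)

  cells <- data.frame(index = seq_len(n_cells),
                      px = px, py = py, pz = pz,
                      ex = ex, ey = ey, ez = ez,
                      tx = tx, ty = ty, tz = tz,
                      ax = ax, ay = ay, az = az,
                      eyespot_diameter = eyespot,
                      arc_fraction = arc_fraction,
                      weight = weight)

  ## center of mass: equal-mass somatic shell plus daughter point mass at
  ## -radius / 2 on the body axis.
  delta <- daughter_mass_fraction
  com_offset <- (1 - delta) * radius * mean(pz) + delta * (-radius / 2)

  structure(list(radius = radius,
                 cells = cells,
                 position = c(0, 0, 0),
                 orientation = diag(3),
                 com_offset = com_offset,
                 daughter_mass_fraction = delta,
                 sinking_speed = sinking_speed,
                 intrinsic_speed = intrinsic_speed,
                 rotation_period = rotation_period,
                 eye_tilt = eye_tilt,
                 gradient = gradient,
                 seed = as.integer(seed)),
            class = "spheroid")
}

#' Center-of-mass asymmetry of a spheroid
#'
#' Returns the signed offset of the center of mass along the body axis
#' (um).  Negative values mean the center of mass is shifted toward the
#' posterior pole, the bottom-heavy configuration that makes unpowered
#' colonies sink posterior-pole first and passively rights swimmers
#' anterior-pole up.
#'
#' @param spheroid a [build_spheroid()] object.
#' @return signed center-of-mass offset (um).
#' @export
mass_asymmetry <- function(spheroid) {
  stop_if_not(inherits(spheroid, "spheroid"), "not a spheroid")
  spheroid$com_offset
}

#' @export
print.spheroid <- function(x, ...) {
  cat("<spheroid> ", nrow(x$cells), " somatic cells, radius ",
      x$radius, " um\n", sep = "")
  cat("  com offset ", signif(x$com_offset, 3),
      " um; intrinsic speed ", x$intrinsic_speed,
      " um/s; sinking ", x$sinking_speed, " um/s\n", sep = "")
  cat("  eyespots: ", signif(max(x$cells$eyespot_diameter), 3),
      " um (anterior) to 0 inside the blind cap (",
      sum(x$cells$eyespot_diameter == 0), " blind cells)\n", sep = "")
  invisible(x)
}

#' Write / read a spheroid as a plain-text table
#'
#' The file holds `# key value` header lines with the scalar parameters
#' followed by a tab-separated table of per-cell geometry.
#'
#' @param spheroid a [build_spheroid()] object.
#' @param path file path.
#' @return `write_spheroid` returns `path` invisibly; `read_spheroid`
#'   returns a `spheroid` object.
#' @export
write_spheroid <- function(spheroid, path) {
  hdr <- c(radius = spheroid$radius,
           com_offset = spheroid$com_offset,
           daughter_mass_fraction = spheroid$daughter_mass_fraction,
           sinking_speed = spheroid$sinking_speed,
           intrinsic_speed = spheroid$intrinsic_speed,
           rotation_period = spheroid$rotation_period,
           eye_tilt = spheroid$eye_tilt,
           seed = spheroid$seed,
           anterior_eyespot_diameter =
             spheroid$gradient$anterior_eyespot_diameter,
           posterior_area_ratio = spheroid$gradient$posterior_area_ratio,
           spacing_ratio = spheroid$gradient$spacing_ratio,
           protoplast_area_ratio = spheroid$gradient$protoplast_area_ratio,
           blind_cap_angle = spheroid$gradient$blind_cap_angle)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s %.17g", names(hdr), hdr), con)
  utils::write.table(spheroid$cells, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_spheroid
#' @export
read_spheroid <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^# ", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr_lines), " "))
  hdr <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  cells <- utils::read.table(text = lines[!startsWith(lines, "# ")],
                             header = TRUE, sep = "\t")
  grad <- gradient_params(hdr[["anterior_eyespot_diameter"]],
                          hdr[["posterior_area_ratio"]],
                          hdr[["spacing_ratio"]],
                          hdr[["protoplast_area_ratio"]],
                          hdr[["blind_cap_angle"]])
  structure(list(radius = hdr[["radius"]],
                 cells = cells,
                 position = c(0, 0, 0),
                 orientation = diag(3),
                 com_offset = hdr[["com_offset"]],
                 daughter_mass_fraction = hdr[["daughter_mass_fraction"]],
                 sinking_speed = hdr[["sinking_speed"]],
                 intrinsic_speed = hdr[["intrinsic_speed"]],
                 rotation_period = hdr[["rotation_period"]],
                 eye_tilt = hdr[["eye_tilt"]],
                 gradient = grad,
                 seed = as.integer(hdr[["seed"]])),
            class = "spheroid")
}
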