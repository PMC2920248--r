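test_that("calibration closes on speed, rotation and reversal balance", {
  sph <- fixture_spheroid()
  loco <- fixture_locomotion()
  kin <- kinetics_params()
  st <- cell_states(nrow(sph$cells))

  w <- net_wrench(sph, st, loco, kin)
  # all-normal: propulsion along +z at the intrinsic speed
  expect_equal(w$force[3], sph$intrinsic_speed, tolerance = 1e-9)
  expect_lt(sqrt(sum(w$force[1:2]^2)), 0.02 * sph$intrinsic_speed)
  # axial rotation at the configured period, counterclockwise as seen
  # from behind (negative z angular velocity in this convention)
  expect_equal(2 * pi / abs(w$torque[3]), sph$rotation_period,
               tolerance = 1e-9)
  expect_lt(w$torque[3], 0)

  # upward and downward free-swimming speeds and their ratio
  v_up <- w$force[3] - loco$sinking_speed
  v_down <- w$force[3] + loco$sinking_speed
  expect_equal(v_up, 880, tolerance = 1e-9)
  expect_equal(v_down / v_up, 1.5, tolerance = 0.02)

  # full anterior reversal cancels the axial thrust (photophobic phase:
  # the colony then sinks passively)
  st_rev <- states_with_anterior(sph, 4L)
  w_rev <- net_wrench(sph, st_rev, loco, kin)
  expect_lt(abs(w_rev$force[3]), 1e-6 * sph$intrinsic_speed)

  expect_true(loco$reverse_thrust_ratio > 0 &&
                loco$reverse_thrust_ratio <= 1)
})

test_that("net wrench equals independent brute-force summation", {
  sph <- build_spheroid(20, seed = 13)
  loco <- calibrate_locomotion(sph)
  kin <- kinetics_params()
  set.seed(8)
  st <- cell_states(20)
  st$mode <- sample(c(1L, 4L), 20, replace = TRUE)
  w <- net_wrench(sph, st, loco, kin)

  beta <- loco$azimuthal_tilt * pi / 180
  q <- loco$reverse_thrust_ratio * loco$reverse_freq_ratio
  f_tot <- c(0, 0, 0); t_tot <- c(0, 0, 0)
  for (i in 1:20) {
    cl <- sph$cells[i, ]
    dir <- cos(beta) * c(cl$tx, cl$ty, cl$tz) -
      sin(beta) * c(cl$ax, cl$ay, cl$az)
    fac <- if (st$mode[i] == 4L) -q else 1
    f <- loco$per_cell_thrust_normal * cl$weight * fac * dir
    r <- c(cl$px, cl$py, cl$pz)
    f_tot <- f_tot + f
    t_tot <- t_tot + 3 / (4 * sph$radius) *
      c(r[2] * f[3] - r[3] * f[2],
        r[3] * f[1] - r[1] * f[3],
        r[1] * f[2] - r[2] * f[1])
  }
  expect_equal(w$force, f_tot, tolerance = 1e-12)
  expect_equal(w$torque, t_tot, tolerance = 1e-12)
  expect_error(net_wrench(sph, cell_states(5), loco, kin), "per cell")
})

test_that("cell thrust reverses and interpolates with the beating mode", {
  sph <- fixture_spheroid()
  loco <- fixture_locomotion()
  kin <- kinetics_params()
  cl <- sph$cells[5, ]
  st_n <- cell_states(1)
  f_n <- cell_thrust(cl, st_n, loco, kin)
  st_r <- cell_states(1); st_r$mode <- 4L
  f_r <- cell_thrust(cl, st_r, loco, kin)
  q <- loco$reverse_thrust_ratio * loco$reverse_freq_ratio
  expect_equal(f_r, -q * f_n, tolerance = 1e-12)
  # halfway through the transition the thrust is the midpoint
  st_t <- cell_states(1); st_t$mode <- 3L
  st_t$timer <- kin$transition_time / 2
  expect_equal(cell_thrust(cl, st_t, loco, kin), (f_n + f_r) / 2,
               tolerance = 1e-12)
})

test_that("gravity wrench rights the colony anterior-up while sinking", {
  sph <- fixture_spheroid()
  loco <- fixture_locomotion()
  g0 <- gravity_wrench(sph, loco)
  expect_equal(g0$force, c(0, 0, -loco$sinking_speed))
  expect_equal(g0$torque, c(0, 0, 0))          # axis vertical: no torque

  sph_h <- sph
  sph_h$orientation <- matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3)
  g1 <- gravity_wrench(sph_h, loco)
  expect_equal(sqrt(sum(g1$torque^2)), loco$righting_rate,
               tolerance = 1e-12)              # horizontal: maximal

  # unpowered colony reorients to anterior-up terminal orientation and
  # sinks posterior-first
  sph_h$position <- c(5, 5, 5)
  for (i in 1:600) {
    g <- gravity_wrench(sph_h, loco)
    sph_h <- step_dynamics(sph_h, g, 0.01)
  }
  axis <- as.numeric(sph_h$orientation %*% c(0, 0, 1))
  expect_gt(axis[3], 0.99)                     # anterior pole up
  expect_lt(sph_h$position[3], 5)              # sank
})

test_that("righting reaches within 10 degrees of vertical in 2 s", {
  sph <- fixture_spheroid()
  loco <- fixture_locomotion()
  sph$orientation <- matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3)
  for (i in 1:200) {
    g <- gravity_wrench(sph, loco)
    sph <- step_dynamics(sph, g, 0.01)
  }
  axis <- as.numeric(sph$orientation %*% c(0, 0, 1))
  psi <- acos(axis[3]) * 180 / pi
  expect_lt(psi, 10 + 0.5)
})

test_that("pose updates follow the wrench in closed form", {
  sph <- fixture_spheroid()
  z0 <- sph$position
  sph1 <- step_dynamics(sph, list(force = c(0, 0, 0),
                                  torque = c(0, 0, 0)), 0.01)
  expect_equal(sph1$position, z0)
  expect_equal(sph1$orientation, sph$orientation)

  # constant axial force F for time T displaces by F * T
  sph2 <- sph
  for (i in 1:100)
    sph2 <- step_dynamics(sph2, list(force = c(0, 0, 500),
                                     torque = c(0, 0, 0)), 0.01)
  expect_equal(sph2$position[3] - z0[3], 500 * 1 * 1e-3, tolerance = 1e-9)

  # photophobic phase: axial thrust zeroed, 2 s of passive sinking
  sph3 <- sph
  for (i in 1:205)
    sph3 <- step_dynamics(sph3, list(force = c(0, 0, -220),
                                     torque = c(0, 0, 0)), 0.01)
  expect_equal(z0[3] - sph3$position[3], 0.45, tolerance = 0.01)
  expect_error(step_dynamics(sph, list(force = 1:3, torque = 1:3), 0.1),
               "10 ms")
})

test_that("axial thrust is never backward for reachable states", {
  # the colony only has a forward gear: any mix of normal and (at most
  # fully) reversed responsive cells leaves the axial thrust >= 0
  sph <- fixture_spheroid()
  loco <- fixture_locomotion()
  kin <- kinetics_params()
  resp <- which(sph$cells$arc_fraction <= kin$responsive_arc_fraction)
  set.seed(17)
  for (rep in 1:25) {
    st <- cell_states(nrow(sph$cells))
    sub <- sample(resp, sample(length(resp), 1))
    st$mode[sub] <- sample(c(3L, 4L, 5L), length(sub), replace = TRUE)
    st$timer[st$mode != 1L] <- stats::runif(sum(st$mode != 1L), 0,
                                            kin$transition_time)
    w <- net_wrench(sph, st, loco, kin)
    expect_gte(w$force[3], -1e-9)
  }
})

test_that("surface slip reverses sign only where cells are reversed", {
  sph <- fixture_spheroid()
  loco <- fixture_locomotion()
  kin <- kinetics_params()
  st <- cell_states(nrow(sph$cells))
  s_ant <- surface_slip_profile(sph, st, c(0, 60), loco, kin)
  expect_gt(s_ant, 0)                      # anterior-to-posterior flow

  st_rev <- states_with_anterior(sph, 4L)
  s_rev <- surface_slip_profile(sph, st_rev, c(0, 60), loco, kin)
  q <- loco$reverse_thrust_ratio * loco$reverse_freq_ratio
  expect_lt(s_rev, 0)                      # reversed flow...
  expect_equal(-s_rev / s_ant, q, tolerance = 1e-9)
  expect_lt(-s_rev, s_ant)                 # ... of smaller magnitude

  # posterior band unchanged during the anterior reversal
  s_post0 <- surface_slip_profile(sph, st, c(120, 180), loco, kin)
  s_post1 <- surface_slip_profile(sph, st_rev, c(120, 180), loco, kin)
  expect_equal(s_post0, s_post1)
  expect_gt(s_post1, 0)
  expect_error(surface_slip_profile(sph, st, c(179.9, 180), loco, kin),
               "no cells")
})
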