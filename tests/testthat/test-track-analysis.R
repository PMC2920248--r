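# The analysis operations are checked against synthetic tracks whose
# ground truth is constructed, plus direct formula cases.

test_that("the photoaccumulation index formula and its bounds hold", {
  # direct formula cases via a hand-built track table: 10 colonies, the
  # first k of which sit in area 1 (top slab) at each time
  mk <- function(n_in0, n_in1) {
    cfg <- chamber_config("VERTICAL_A", n_spheroids = 10)
    z0 <- c(rep(9.5, n_in0), rep(1, 10 - n_in0))
    z1 <- c(rep(9.5, n_in1), rep(1, 10 - n_in1))
    df <- data.frame(spheroid_id = rep(1:10, 2),
                     t = rep(c(0, 5), each = 10),
                     x = 5, y = 0.5, z = c(z0, z1), light_on = 1L)
    structure(df, class = c("volvox_tracks", "data.frame"),
              sampling_dt = 0.1, switch_time = 0, config = cfg,
              z_clamped = FALSE)
  }
  expect_equal(photoaccumulation_index(mk(2, 6), 1, 5), 50)  # A=20, B=60
  expect_equal(photoaccumulation_index(mk(3, 3), 1, 5), 0)   # B = A
  expect_equal(photoaccumulation_index(mk(0, 10), 1, 5), 100)
  expect_equal(photoaccumulation_index(mk(2, 6), 1, -1), 0)  # pre-switch
  expect_error(photoaccumulation_index(mk(10, 10), 1, 5), "undefined")

  # bounds: PI <= 100 and PI = 0 at the switch for arbitrary track sets
  for (s in 1:3) {
    tr <- generate_tracks(track_generator_params(n_tracks = 30, seed = s),
                          t_start = -1, t_end = 4)
    pc <- pi_curve(tr, 1)
    expect_true(all(pc$pi <= 100))
    expect_equal(pc$pi[pc$t == 0], 0)
  }
})

test_that("every heading maps to exactly one 20-degree sector", {
  cfg <- chamber_config("VERTICAL_A")
  mk_track <- function(theta_deg) {
    # heading at angle theta from the toward-source direction (up)
    u <- c(sin(theta_deg * pi / 180), 0, cos(theta_deg * pi / 180))
    t <- seq(-1, 0, by = 0.1)
    df <- data.frame(spheroid_id = 1L, t = t,
                     x = 5 + u[1] * (t + 1), y = 0.5 + u[2] * (t + 1),
                     z = 5 + u[3] * (t + 1), light_on = 0L)
    structure(df, class = c("volvox_tracks", "data.frame"),
              sampling_dt = 0.1, switch_time = 0, config = cfg,
              z_clamped = FALSE)
  }
  expect_equal(as.character(assign_sector(mk_track(0))), "a")
  expect_equal(as.character(assign_sector(mk_track(179))), "i")
  expect_equal(as.character(assign_sector(mk_track(90))), "e")
  expect_equal(as.character(assign_sector(mk_track(180))), "i")
  expect_equal(as.character(assign_sector(mk_track(19.99))), "a")
  expect_equal(as.character(assign_sector(mk_track(20.01))), "b")
  # totality over a fine sweep
  secs <- vapply(seq(0, 180, by = 2.5),
                 function(a) as.character(assign_sector(mk_track(a))),
                 character(1))
  expect_true(!anyNA(secs))
  expect_setequal(unique(secs), letters[1:9])
})

test_that("constant-velocity tracks give a flat 100% speed curve", {
  p <- track_generator_params(n_tracks = 10, photophobic_drop_fraction = 1,
                              sinking_drop = 0, position_noise_sd = 0,
                              seed = 3)
  tr <- generate_tracks(p)
  rc <- relative_speed_curve(tr)
  expect_equal(rc$mean, rep(100, 6), tolerance = 1e-9)
  expect_equal(rc$n, rep(10, 6))
})

test_that("a constructed 50% speed drop is recovered exactly", {
  p <- track_generator_params(n_tracks = 12,
                              photophobic_drop_fraction = 0.5,
                              photophobic_duration = 2,
                              position_noise_sd = 0, seed = 4)
  tr <- generate_tracks(p)
  rc <- relative_speed_curve(tr)
  v <- function(k) rc$mean[rc$offset == k]
  expect_equal(v(-1), 100, tolerance = 1e-9)
  expect_equal(v(0), 100, tolerance = 1e-9)
  expect_equal(v(1), 50, tolerance = 1e-9)
  expect_equal(v(2), 50, tolerance = 1e-9)
  expect_equal(v(3), 100, tolerance = 1e-9)
  # per-track normalization is exact for every included track
  sd0 <- rc$sd[rc$offset == 0]
  expect_lt(sd0, 1e-9)
})

test_that("sinking depth recovers the constructed drop", {
  p <- track_generator_params(n_tracks = 8, sinking_drop = 0.45,
                              position_noise_sd = 0, seed = 5)
  tr <- generate_tracks(p)
  expect_equal(unname(mean(sinking_depth(tr))), 0.45, tolerance = 1e-9)

  # monotonically rising track: depth 0
  cfg <- chamber_config("VERTICAL_A")
  t <- seq(-1, 4, by = 0.1)
  df <- data.frame(spheroid_id = 1L, t = t, x = 5, y = 0.5,
                   z = 2 + 0.5 * (t + 1), light_on = 1L)
  up <- structure(df, class = c("volvox_tracks", "data.frame"),
                  sampling_dt = 0.1, switch_time = 0, config = cfg,
                  z_clamped = FALSE)
  expect_equal(as.vector(sinking_depth(up)), 0)

  # clamped (horizontal) chambers flag the zero result
  pB <- track_generator_params(n_tracks = 4, position_noise_sd = 0,
                               seed = 6)
  trB <- generate_tracks(pB, chamber_config("HORIZONTAL_B"))
  dB <- sinking_depth(trB)
  expect_true(all(dB == 0))
  expect_true(attr(dB, "z_clamped"))
})

test_that("sector-wise speeds recover the constructed down/up ratio", {
  for (ratio in c(1.5, 2)) {
    p <- track_generator_params(n_tracks = 600, v_up = 0.88,
                                v_down = 0.88 * ratio,
                                v_horizontal = 1.06,
                                position_noise_sd = 0, seed = 7)
    tr <- generate_tracks(p)
    ab <- absolute_speed_by_sector(tr)
    pre <- ab[ab$offset == 0, ]
    r <- pre$mean[pre$sector == "i"] / pre$mean[pre$sector == "a"]
    expect_equal(r, ratio, tolerance = 0.03)
  }
  # isotropic tracks with equal speeds everywhere: ratio 1
  p1 <- track_generator_params(n_tracks = 300, v_up = 1, v_down = 1,
                               v_horizontal = 1, position_noise_sd = 0,
                               seed = 8)
  ab1 <- absolute_speed_by_sector(generate_tracks(p1))
  pre1 <- ab1[ab1$offset == 0, ]
  expect_equal(pre1$mean[pre1$sector == "i"] /
                 pre1$mean[pre1$sector == "a"], 1, tolerance = 1e-9)
})

test_that("the pulse-response lag estimator is exact on clean series", {
  ps <- generate_pulse_response(lag = 0.3, period = 1.2, amplitude = 1,
                                initial_suppression = 2.4, noise_sd = 0,
                                seed = 1)
  lag <- estimate_response_lag(ps$t, ps$value, period = 1.2, skip = 2.4)
  expect_equal(lag, 0.3, tolerance = 0.02)
})
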