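# Chamber assays use small colony counts and short durations: the
# checks here are structural (sampling, containment, determinism) and
# qualitative (photophobic slowdown and recovery, entrainment); the
# calibrated quantitative behavior is covered by the acceptance tests.

# track columns without the configuration attributes
track_cols <- function(tr) {
  data.frame(unclass(tr)[c("spheroid_id", "t", "x", "y", "z",
                           "light_on")])
}

test_that("tracks are sampled on the 0.1-s grid inside the chamber", {
  sph <- fixture_spheroid()
  cfg <- chamber_config("VERTICAL_A", n_spheroids = 3, duration = 4,
                        burn_in = 2)
  tr <- run_photoaccumulation(cfg, sph, seed = 4,
                              loco = fixture_locomotion())
  expect_true(all(abs(tr$t / 0.1 - round(tr$t / 0.1)) < 1e-9))
  expect_equal(sort(unique(tr$spheroid_id)), 1:3)
  dims <- cfg$internal_dimensions
  expect_true(all(tr$x >= 0 & tr$x <= dims[1]))
  expect_true(all(tr$y >= 0 & tr$y <= dims[2]))
  expect_true(all(tr$z >= 0 & tr$z <= dims[3]))
  expect_equal(nrow(tr), 3 * (4 / 0.1 + 1))

  tr2 <- run_photoaccumulation(cfg, sph, seed = 4,
                               loco = fixture_locomotion())
  expect_identical(track_cols(tr), track_cols(tr2))
  tr3 <- run_photoaccumulation(cfg, sph, seed = 5,
                               loco = fixture_locomotion())
  expect_false(identical(tr$x, tr3$x))
})

test_that("track tables round-trip through the plain-text format", {
  sph <- fixture_spheroid()
  cfg <- chamber_config("VERTICAL_A", n_spheroids = 2, duration = 2,
                        burn_in = 1)
  tr <- run_dark_light_switch(cfg, sph, intensity = 2.1, seed = 2,
                              pre = 1, post = 2,
                              loco = fixture_locomotion())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tracks(tr, path)
  back <- read_tracks(path)
  expect_equal(track_cols(back), track_cols(tr), tolerance = 1e-12)
  expect_equal(attr(back, "switch_time"), attr(tr, "switch_time"))
  expect_equal(attr(back, "config")$n_areas, 6L)
})

test_that("a dark-light switch causes a transient slowdown and recovery", {
  sph <- fixture_spheroid()
  cfg <- chamber_config("VERTICAL_A", n_spheroids = 12, duration = 10,
                        burn_in = 6)
  tr <- run_dark_light_switch(cfg, sph, intensity = 2.1, seed = 21,
                              loco = fixture_locomotion())
  rc <- relative_speed_curve(tr)
  v <- function(k) rc$mean[rc$offset == k]
  expect_equal(v(0), 100)
  expect_lt(v(1), 60)            # strong photophobic deceleration
  expect_gt(v(4), v(1) + 20)     # clear recovery under way by 3-4 s

  # dim light elicits the partial response (~70% residual speed)
  tr_lo <- run_dark_light_switch(cfg, sph, intensity = 0.016, seed = 21,
                                 loco = fixture_locomotion())
  rc_lo <- relative_speed_curve(tr_lo)
  v_lo1 <- rc_lo$mean[rc_lo$offset == 1]
  expect_gt(v_lo1, v(1))         # weaker slowdown than at high intensity
  expect_true(v_lo1 > 55 && v_lo1 < 90)
})

test_that("setup A accumulates toward the light for all effective intensities", {
  sph <- fixture_spheroid()
  loco <- fixture_locomotion()
  for (intensity in c(0.016, 2.1, 457)) {
    pis <- sapply(1:3, function(s) {
      cfg <- chamber_config("VERTICAL_A", n_spheroids = 8, duration = 30,
                            light = light_step(intensity,
                                               direction = c(0, 0, -1)))
      tr <- run_photoaccumulation(cfg, sph, seed = 100 + s, loco = loco)
      photoaccumulation_index(tr, 1, 30)
    })
    expect_true(all(pis > 0),
                label = sprintf("positive PI at %g umol m-2 s-1",
                                intensity))
  }
})

test_that("very dim light in setup B is indistinguishable from darkness", {
  sph <- fixture_spheroid()
  loco <- fixture_locomotion()
  cfg_dim <- chamber_config("HORIZONTAL_B", n_spheroids = 20,
                            duration = 30,
                            light = light_step(0.0016,
                                               direction = c(1, 0, 0)))
  cfg_dark <- chamber_config("HORIZONTAL_B", n_spheroids = 20,
                             duration = 30,
                             light = light_off(direction = c(1, 0, 0)))
  pi_dim <- sapply(1:3, function(s)
    photoaccumulation_index(run_photoaccumulation(cfg_dim, sph,
                                                  seed = 200 + s,
                                                  loco = loco), 1, 30))
  pi_dark <- sapply(1:3, function(s)
    photoaccumulation_index(run_photoaccumulation(cfg_dark, sph,
                                                  seed = 300 + s,
                                                  loco = loco), 1, 30))
  expect_lt(abs(mean(pi_dim) - mean(pi_dark)), 25)
  expect_lt(abs(mean(pi_dim)), 25)
})

test_that("pulsed stimulation suppresses slip, entrains, and releases", {
  sph <- fixture_spheroid()
  res <- run_pulsed_stimulation(sph, duration = 16, seed = 6,
                                light_off_at = 12,
                                loco = fixture_locomotion())
  period <- attr(res, "period")
  s_dark <- res$r1[res$t < 0.05][1]          # pre-stimulus slip

  # initial response: slip minimal for ~2 s despite intervening peaks
  early <- res$t > 0.5 & res$t < 1.9
  expect_lt(mean(res$r1[early]), 0)
  expect_lt(max(res$r1[early]), 0.25 * s_dark)

  # entrained phase: slip oscillates at the stimulus period
  late <- res$t >= 5 & res$t < 10
  sl <- res$r1[late]
  expect_gt(max(sl), 0.8 * s_dark)
  expect_lt(min(sl), 0.25 * s_dark)
  shift <- round(period / 0.01)
  idx <- which(late)
  expect_gt(stats::cor(res$r1[idx[1:300]], res$r1[idx[1:300] + shift]),
            0.9)

  # all three anterior regions behave alike
  expect_gt(stats::cor(res$r1[idx], res$r2[idx]), 0.9)
  expect_gt(stats::cor(res$r1[idx], res$r3[idx]), 0.9)

  # light off: slip returns to the maximal normal-mode level and stays
  off <- res$t > 13
  expect_true(all(res$r1[off] > 0.9 * s_dark))
})
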