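# Shared fixtures: one moderately sized spheroid with its calibrated
# locomotion, built once per test run.

fixture_spheroid <- local({
  sph <- NULL
  function() {
    if (is.null(sph)) sph <<- build_spheroid(200, seed = 42)
    sph
  }
})

fixture_locomotion <- local({
  loco <- NULL
  function() {
    if (is.null(loco)) loco <<- calibrate_locomotion(fixture_spheroid())
    loco
  }
})

# all-cells state vector with the responsive anterior hemisphere set to
# a given mode
states_with_anterior <- function(spheroid, mode_code,
                                 cap_fraction = 0.5) {
  st <- cell_states(nrow(spheroid$cells))
  st$mode[spheroid$cells$arc_fraction <= cap_fraction] <- mode_code
  st
}
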