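---
title: "A cell-resolved model of phototactic steering in bottom-heavy Volvox colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cell-resolved model of phototactic steering in bottom-heavy Volvox colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volvoxsteer)
```

## The organism and the question

Large spheroidal *Volvox* colonies of the section *Volvox* (such as
*V. rousseletii*) are fast swimmers: a few thousand biflagellate somatic
cells on the surface of a rigid extracellular-matrix sphere beat their
flagella toward the posterior pole, propelling the colony
posterior-to-anterior at roughly 1 mm/s while spinning it about the
swimming axis (counterclockwise seen from behind, one turn every 1–3 s).
The colony steers toward light without any cell-to-cell communication.
This package implements a mechanistic, cell-resolved account of how
that works, together with the trajectory-analysis pipeline used to
quantify the behavior, so that the organismal statistics can be
regenerated from the cellular ingredients at desk scale.

The ingredients the model combines:

* **Morphological polarity.** Anterior cells are large, widely spaced,
  and carry ~3.6 µm eyespots; eyespot size declines continuously along
  the anterior–posterior axis (an ~80-fold area ratio) and a posterior
  cap is effectively blind.  Cell spacing tightens ~2.3-fold toward the
  posterior, and internal daughter colonies sit in the posterior
  hemisphere, shifting the center of mass backward (bottom-heaviness).
* **A directional eye.** The eyespot's pigment stack makes each
  photoreceptor directional.  The package models the angular
  sensitivity as the four-level step function (100/74/55/23 % at
  half-angles 14°/25°/55°) that is physically realized by a rotating
  stack of three neutral-density filters with mirror-symmetric sector
  cutouts — the only directivity specified numerically by the
  measurements.
* **A two-gear cell.** A sufficient step-up in perceived intensity
  makes a cell reverse its ciliary beat after a ~100 ms latency and a
  ~30 ms transition; the reverse mode (40 Hz, smaller stroke) persists
  for 2–3 s under sustained light before the cell adapts back to the
  normal mode (22 Hz).
* **Gravity.** Unpowered colonies sink at ~220 µm/s, posterior pole
  first; bottom-heaviness supplies a passive righting torque that
  keeps the anterior (and its large eyespots) pointing up, where the
  light usually is.

Steering emerges without communication: when the rotating colony is lit
from the side, only the cells currently facing the source see step-ups
and reverse; the resulting force imbalance turns the colony toward the
light.  A sudden global step-up (a dark–light switch) instead reverses
the whole anterior hemisphere at once — a photophobic response that
cancels propulsion and lets the colony sink briefly before it
reorients and accelerates toward the source.

## Model structure

### Spheroid construction

`build_spheroid()` places `n_cells` on a generalized-spiral (Fibonacci)
lattice whose polar coordinate is warped so that the local cell spacing
shrinks by exactly `spacing_ratio` from the anterior to the posterior
pole (density ∝ `(1 + (s−1)c)²` in the cap-area coordinate `c`).  The
eyespot diameter falls linearly with arc distance from the anterior
pole down to the blind-cap edge, where the anterior/edge *area* ratio
equals `posterior_area_ratio`, and is zero inside the cap
(`blind_cap_angle`, default 30°).  Eye axes are outward normals tilted
30° toward the posterior (the tilt magnitude is an assumption; the
direction reflects the observation that eyespots face the posterior
pole).  The measurements do not give a colony diameter for the studied
strain; the default radius of 250 µm is a configurable assumption.

Each cell carries a thrust weight equal to the protoplast-size gradient
(1.8-fold larger anterior cells carry longer, stronger flagella)
divided by the local packing density.  The normalization encodes
flagellar crowding interference: it makes the propulsive *surface force
density* follow the protoplast gradient rather than the cell count.
Without it, the dense posterior would dominate the axial thrust so
strongly that cancelling it during the photophobic response would
require reversed cells to beat ~1.6× harder than normal cells — the
opposite of the observed slower reversed streamlines.  With it, the
calibrated reverse-mode slip is ~0.83× the normal slip, consistent
with observation.

### Photoreception

`perceived_intensity` = incident intensity × directivity(angle between
the lab-frame eye axis and the direction toward the source) × (eyespot
area / anterior eyespot area).  Blind cells perceive nothing.  The
response-versus-intensity curve `response_strength(I) = min(1,
(1 + K/0.16) · I/(I + K))` is a saturable Michaelis–Menten
dose-response: it reaches exactly 1 at 0.16 µmol m⁻² s⁻¹ and stays
saturated above (stimuli up to ~457 µmol m⁻² s⁻¹ elicit no stronger
response) while remaining positive for arbitrarily dim light.  The
half-saturation constant `K = 0.01 µmol m⁻² s⁻¹` places the
partial-response regime where it is observed: a stimulus one decade
below saturation elicits roughly a third of the full response
(reproducing the weak, ~70 % residual-speed photophobic reaction at
dim light), while a stimulus two decades below elicits almost none
(reproducing the absence of significant photoaccumulation at the
dimmest intensities).  `K` is a model assumption anchored to those two
printed observations, not a measured constant.

### Beating-mode kinetics

Each cell runs the five-stage cycle NORMAL → LATENT →
TRANSITION_TO_REVERSE → REVERSED → TRANSITION_TO_NORMAL → NORMAL.  The
trigger is a *relative* step-up, `(I − I_ref)/max(I_ref, ε) > 0.2`,
against an exponential running-mean baseline with a 0.5 s time
constant (the adaptation memory).  Relative detection makes the
trigger scale-invariant, matching the observation that behavior is the
same from 0.16 to 457 µmol m⁻² s⁻¹.  The relative trigger is combined
with an absolute detection floor (`step_up_min = 5×10⁻⁴
µmol m⁻² s⁻¹`): a perceived step below the floor is invisible however
large its relative size.  The floor stands in for the photon-noise
limit of the photoreceptor, and it — not the dose-response curve — is
what makes the dimmest stimuli ineffective: because the eye's
directivity spreads perceived intensities over a ~4-fold range across
the colony, some source-facing cells perceive near-threshold light at
*any* incident intensity, so no smooth dose-response alone can switch
steering off at the dim end.  On a trigger the cell responds
with probability `response_strength × dark_adaptation_factor`;
latencies are drawn from a normal (100 ± 25 ms) truncated at 10 ms.
Only cells in the anterior hemisphere are photoresponsive
(`responsive_arc_fraction = 0.5`), reflecting the measured
photoresponse gradient; posterior cells, even those with small
eyespots, never reverse.

The reversal persistence is 2–3 s at the cell level; the default of
2.0 s takes the low end of that range because it is also the printed
duration of the organism-level photophobic phase — the colony "sinks
for ~2 s", and 0.45 mm at the 220 µm/s sinking speed is 2.05 s.  (The
~2.5 s of minimal *bead* movement under pulsed stimulation is a
streamline observation; the extra few hundred milliseconds beyond the
cellular reversal are fluid lag, outside the surface-slip proxy.)

Two stage-exit rules need reconciling: a first-time reversal runs its
full course regardless of intervening intensity dips (this produces
the ~2 s of suppressed surface flow at the start of pulsed
stimulation), while an *entrained* cell — one that has completed a full
photophobic cycle — ends its reversal as soon as the intensity steps
back down, which lets the population follow a periodic stimulus
cycle-by-cycle.  Switching the light off never triggers anything:
step-downs are not stimuli.

The dark-adaptation table anchors the efficiency decline at the
10-minute bin midpoints with linear interpolation and a constant value
beyond 85 min (dark periods longer than an hour cause no further
decline).  The raw anchors contain one adjacent-bin inversion well
within the reported SDs; it is pooled by isotonic regression so the
tabulated trend is non-increasing, leaving all other anchors exact.

### Locomotion and calibration

Dynamics are overdamped (Reynolds number ≪ 1): velocities are
instantaneous functions of the applied "wrench", with translational and
rotational mobilities folded into the units (forces in µm/s, torques
in rad/s) and linked by the rigid-sphere mobility ratio
`ω = 3/(4R) Σ r̂ × f`.  Normal-mode thrust points along the meridian
toward the anterior, tilted azimuthally to produce the axial spin;
reverse-mode thrust is opposite, scaled by `reverse_thrust_ratio ×
(40/22)` (the beat-frequency ratio).  Gravity adds a constant sinking
velocity and the righting angular velocity `k sin ψ`.

`calibrate_locomotion()` is deterministic and closed-form:

1. the thrust scale makes the all-normal axial speed equal the
   intrinsic speed `v₀ = 1100 µm/s`, so the free upward swimming speed
   is `v₀ − s = 880 µm/s` with sinking speed `s = 220 µm/s`;
2. the azimuthal tilt makes the rotation period 2 s (midpoint of the
   observed 1–3 s);
3. `reverse_thrust_ratio` makes a *fully reversed anterior hemisphere
   cancel the axial thrust exactly*, so the photophobic colony sinks
   passively at `s`.

The `v₀ = 1100, s = 220` decomposition is inferred from two printed
observations — 880 µm/s upward swimming and the ~1.5× down/up speed
ratio (`(v₀+s)/(v₀−s) = 1.5`) — and independently cross-checks the
~0.45 mm drop over the ~2 s photophobic sinking phase (220 µm/s ×
2.05 s ≈ 0.45 mm).

Step 3 deserves its own paragraph, because a plausible alternative
calibration — leaving 35–45 % of the axial *thrust* during full
reversal, matching the printed relative track speed one second after a
bright dark–light switch — is incompatible with the printed sinking: a
40 % residual of 1100 µm/s (440 µm/s) out-swims the 220 µm/s sinking
and the colony would keep rising.  The sinking observation (0.45 mm
over ~2 s, i.e. vertical velocity ≈ −s, i.e. net axial thrust ≈ 0) is
the mechanically decisive one and is what the calibration reproduces.
The printed 35–45 % window still emerges, because it is a *chord*
statistic, not an instantaneous speed: the +1 s chord includes the
~130 ms of normal swimming before the reversal completes, and each
track is normalized by its pre-switch chord, which the rotational
wobble shortens relative to the true path.  Simulated +1 s values come
out around 30–50 % across seeds (mean ≈ 40 %), consistent with the
measurements even though the instantaneous photophobic speed is the
bare sinking speed (~25 % of the free upward speed).

The righting rate (1.22 s⁻¹) is set so a horizontal colony rights to
within 10° of vertical in 2 s, matching the duration of the sinking
phase — an assumption, since no reorientation time is printed.
Orientation noise (`rotational_diffusion`, default 0.6 rad²/s) is a
model parameter with no printed counterpart: it balances the righting
torque in a gyrotactic equilibrium (`k/D ≈ 2`) so that dark-adapted
swimmers populate all heading sectors, as the sector-wise analysis of
dark swimming requires (pure righting would align every colony
upward within seconds, leaving downward sectors empty and the measured
horizontal and downward dark speeds unobservable).  It was chosen once
from that requirement.

### Chamber assays

The virtual chamber is 10 × 10 × 1 mm.  In setup A it stands
vertically, lit from above (light parallel to gravity), partitioned
into six horizontal slabs with area 1 on top.  In setup B it lies flat,
lit from one side, partitioned into three slabs; the 1-mm gap clamps
the vertical coordinate so sinking is invisible.  Runs begin with a
10 s dark burn-in that randomizes positions and headings with the
model's own dynamics; walls clamp position with tangential sliding (no
wall hydrodynamics).  Pulsed stimulation holds the colony in place with
its axis perpendicular to the beam — each anterior cell then
experiences what a corresponding cell of a free, rotating,
side-illuminated swimmer experiences — and records the surface-slip
proxy (mean tangential thrust per region) instead of bead streamlines.
Because the proxy has no fluid dynamics in it, its minima lag the
intensity peaks by roughly the cellular reaction time (~0.1–0.16 s),
not by the ~0.3 s measured for bead tracks; the difference is exactly
the hydrodynamic lag quantified by `hydrodynamic_lag_bounds()`
(~140–200 ms).

### Analysis pipeline

The photoaccumulation index `PI = (B − A)·100/(100 − A)` corrects the
occupancy of an area for its baseline at the switch; it is 0 at the
switch by construction, 100 at complete accumulation, and undefined
(signalled) if the baseline is already 100 %.  Headings are binned into
nine 20° sectors a–i over [0°, 180°] — the measurements name nine
sectors but never print bin edges, so equal bins (half-open low,
closed at 180°) are an assumption.  Speeds are 1-s displacement chords
(not path lengths), normalized per track by the pre-switch window;
offsets −1 and 0 both report that window, hence are exactly 100 %.
Sinking depth is the maximum drop below the switch-time height within
3 s.  The pulse-response lag is the first-Fourier-component phase of
the response at the stimulus period, reported as the lag of the minima
behind the peaks.

### Synthetic data

`generate_tracks()` builds piecewise-constant-velocity tracks with the
full statistical shape of the tracking data — heading-dependent dark
speed (0.88 up / 1.06 horizontal / 1.32 mm/s down by default), a
photophobic drop to a configurable fraction with an inserted sinking
excursion, reorientation toward the source, and additive positional
noise — but no velocity noise, so in the zero-noise limit every
constructed parameter is recovered *exactly* by the analysis pipeline.
Tracks are generated in an unbounded copy of the chamber so wall
clamping cannot distort the constructed quantities.  This round-trip
(drop fraction, sinking depth, sector speed ratio, pulse lag — each
within three noise SDs) is the principal correctness surface for the
analysis module, independent of the simulator.

What the generator does *not* emulate: curvature within the 1-s
windows, colony–colony interactions, wall effects, size heterogeneity,
and tracking dropouts.  Passing round-trip tests therefore validates
the estimators, not the biology.

## Numerical choices

* Integration: explicit Euler at `dt = 10 ms` (the spec of the cell
  cycle requires `dt` no coarser than the 30 ms transition; 10 ms
  resolves it while keeping a 60 s, 40-colony assay around a minute of
  CPU).  Orientations are advanced by exact axis–angle rotations and
  re-orthonormalized every 40 steps.
* Trigger edge detection is *armed*: after firing (or declining to
  fire) a cell cannot re-trigger until its relative step falls back
  below threshold, preventing re-draws of the response Bernoulli on
  consecutive steps of one edge.
* The filter-design operation minimizes mean absolute error by dynamic
  programming over the sample grid; the optimum is exact for the given
  samples (verified against exhaustive search) and recovers step
  targets exactly.  For the smooth stand-in target `max(cos θ, 0.23)`
  the optimal cuts are (30°, 50°, 68°) — the physically built stack
  (14°, 25°, 55°) was matched to a narrower directivity curve that is
  not tabulated anywhere in the measurements, so the built angles are
  not recoverable from the stand-in and are not asserted.
* Template colonies for chamber assays use 200 cells; construction
  invariants are tested at 5000.  The density-gradient property needs
  ≥ 1000 cells to estimate spacing ratios stably.

## Worked example

```{r example, eval = FALSE}
sph  <- build_spheroid(200, seed = 1)
loco <- calibrate_locomotion(sph)

cfg <- chamber_config("VERTICAL_A", n_spheroids = 20, duration = 10)
tr  <- run_dark_light_switch(cfg, sph, intensity = 2.1, seed = 11,
                             loco = loco)
mean(sinking_depth(tr))          # ~0.43 mm photophobic sinking
relative_speed_curve(tr)         # ~35% at +1 s, recovery by +4 s
```

## Known limitations

* No hydrodynamic flow fields: bead advection, wall hydrodynamics and
  colony–colony coupling are outside the surface-slip proxy.  In
  particular, the ~300 ms lag of streamline minima behind intensity
  peaks and the ~2.5 s of minimal bead movement under pulsed light are
  bead observations; the thrust-based slip reproduces their cellular
  components (reaction time, ~2 s reversal) but not the fluid part.
* The eye-tilt angle, colony radius, response half-saturation and
  detection floor, and rotational diffusivity are assumptions
  constrained only indirectly.
* Flagellar waveforms are not modelled; beating modes enter only
  through thrust direction, magnitude and timing.
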