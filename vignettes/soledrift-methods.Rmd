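---
title: "Methods: otolith back-calculation and the larval dispersal IBM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: otolith back-calculation and the larval dispersal IBM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the scientific and numerical choices behind
`soledrift`: the two models it implements, the parameters that matter,
what the synthetic-data generators do and do not emulate, and the
decisions taken where more than one defensible convention existed.

## 1. The otolith ageing model

A juvenile sole otolith read for daily increments yields up to three
counts per fish: larval rings (hatch check to start of metamorphosis),
metamorphosis rings, and post-settlement rings up to the otolith edge.
Larval rings are only readable in a minority of otoliths, so the model
follows the survey convention: each station derives a mean larval count
from its readable otoliths, and every fish of that station uses its
individual larval count when present, the station mean otherwise
(`estimate_ages()`). Thus

* `PLD = larval + metamorphosis` (days; the pelagic larval duration,
  hatch to settlement),
* `age at capture = PLD + post-settlement`,
* `hatching date = sampling date − age at capture`,
* `settlement date = hatching date + PLD`.

**Real-valued ages, one rounding step.** Station means make ages
fractional (e.g. 136.7 d). Ages stay real-valued through every
computation; rounding to whole days happens once, at calendar
subtraction, half away from zero (`round_half_up`). This convention
reproduces exactly the published station-mean hatching dates wherever the
printed rounded means are internally consistent; on other stations
day-level ±1 discrepancies are expected because the original analysis
averaged individual dates rather than back-calculating from rounded
means. The settlement identity `hatch + round(PLD) = settlement` is
enforced in preference to `sampling − round(age − PLD)`, which can differ
by a day through double rounding.

**Stations with no readable larval rings** borrow the pooled mean over
the same country and year, flagged in the output (`borrow_pooled`
argument). The alternative — dropping such stations — discards otherwise
complete metamorphosis and post-settlement counts.

**Overwintering stations.** Fish sampled after an overwintering period
(age approaching 1+) have unreliable increment records: increments become
too narrow to resolve and deposition may pause over winter. Their ages
are computed and carried, but flagged `unreliable` and excluded from
back-calculation, summaries and distributions by default
(`exclude_overwinter = FALSE` restores them).

**Optional yolk-sac offset.** Increments only deposit consistently after
first feeding, so otolith PLDs may undercount the true pelagic phase by
one to two weeks. `yolk_sac_offset` (days, default 0) adds a constant to
every PLD; the default takes the counts at face value.

**Week convention.** Arrival curves bin settlement dates by ISO-8601 week
number — the only self-documenting, reproducible definition — with a
`jan1` alternative (7-day blocks from January 1) for comparison against
analyses that used it. Interior empty weeks are carried as zero bins;
frequencies always sum to 1.

**Group comparisons** (`compare_groups()`) delegate to
`stats::kruskal.test`, `wilcox.test`, `t.test` and
`pairwise.wilcox.test`; these steps are routine and carry no bespoke
logic. The two-group method is the rank-sum (Mann–Whitney) test: the
year and country contrasts it serves compare independent samples, for
which the signed-rank test would be mis-specified.

## 2. The dispersal individual-based model

Four stages — egg, yolk-sac, first-feeding and metamorphosing larvae —
each parameterized by duration, mortality and vertical behaviour
(`default_stage_parameters()`).

**Durations** follow `a·T^b` days at local sea-surface temperature `T`.
The shipped coefficients are *provisional*: no published per-stage values
were available, so `a = (70, 50, 300, 140)` with `b = −1` was fixed once
such that durations at the 10 °C spawning-peak temperature are
7 / 5 / 30 / 14 days — summing to 49 d for the complete pelagic phase and
44 d excluding the yolk sac, the long-term means reported for the
reference hindcast. Everything is overridable per stage via
`simulation_config()` or YAML; a `"short"` set (every `a` × 0.8) supports
the shorter-PLD sensitivity analysis (`sensitivity_short_pld()`).

**Mortality** is `0.0004·T^3.0293` d⁻¹ for eggs and yolk-sac larvae
(≈ 0.428 d⁻¹ at 10 °C) and 0.035 d⁻¹ for the feeding stages. Two modes:
deterministic survival weights (default — each super-individual's weight
decays as `exp(−m Δt)`; reproducible, minimal variance) or stochastic
Bernoulli culling. The reference description does not state which was
used; weights were chosen as the lower-variance default.

**Behaviour.** First-feeding larvae migrate on the day/night cycle
(−0.001 m s⁻¹ by day, +0.003 m s⁻¹ by night); metamorphosing larvae ride
the tide (+0.001 rising, −0.003 falling — selective tidal stream
transport). Eggs and yolk-sac larvae "stay in the upper water column";
no velocity being stated for this, it is implemented as confinement: they
swim up at 0.001 m s⁻¹ only when below a configurable surface layer
(default 10 m) and are otherwise passive. Day is 06:00–18:00 local by
default; tidal phase comes from the provider (idealized M2, 12.42 h).

**Transport.** Horizontal advection uses fixed-step RK4 (default
Δt = 600 s, matching the 10-minute resolution of the reference
hydrodynamics; explicit Euler available). No horizontal random walk is
applied: vertical shear acting on vertically dispersed particles is the
dominant horizontal spreading mechanism in this shelf sea, so horizontal
diffusion is deliberately neglected. Vertical displacement combines the
behaviour velocity with the Visser-corrected random walk

`z' = z + K'(z)Δt + R·sqrt(2 K(z + ½K'(z)Δt) Δt / r)`,

with `R ~ U(−1, 1)` (variance `r = 1/3`), reflective at surface and
bottom. The drift term `K'Δt` and midpoint evaluation of `K` prevent the
spurious accumulation of particles in low-diffusivity water that a naive
walk produces; the test suite verifies the well-mixed condition (an
initially uniform ensemble stays uniform under parabolic `K`,
chi-squared goodness of fit p > 0.01 at 10⁴ particles × 10⁴ steps). A
step is refused when `Δt > 1/max|K''|`, the scheme's consistency bound,
with the bound named in the error.

**Development** accumulates fractionally: `dev += Δt/duration(T_local)`
per step, with the over-shoot remainder converted through the next
stage's duration at the same temperature, so stage traversal at constant
`T` equals `a·T^b` to within one timestep and halving Δt changes it by
less than one step.

**Spawning phenology.** Per ground, the peak is the first day of the
year whose spatial-mean surface temperature reaches 10 °C; release spans
peak ± 50 days (101 days). The within-window shape is not stated in the
reference description; a Gaussian centred on the peak (σ = 25 d,
truncated at ±50 d) was chosen so release genuinely *peaks* at the
trigger day, with a uniform alternative by config. Daily quantities are
normalized to `total_eggs × egg_share` *after* truncation/clipping, so
the egg budget is conserved exactly. If the window would start before
day 1 it is clipped at the year start with a warning. Egg shares per
ground default to equal sixths — the source distribution map is not
tabulated numerically — and are configurable.

**Super-individuals.** `n_particles` per ground (default 10⁴), each
carrying `total_eggs × share / n_particles` eggs, allocated to release
days proportionally to the daily egg quantity (largest-remainder
rounding) and released at uniform-random positions inside the ground
polygon at noon.

**Settlement.** When a metamorphosing larva completes development it
settles if its position lies inside a nursery polygon with local
bathymetry shallower than the nursery's `max_depth` (20 m default),
otherwise it is lost. The end-of-stage rule is the default; a
`during_mtl` alternative settles on first nursery entry at any point of
the metamorphosing stage. Overlapping nursery polygons resolve to the
first declared match, with a warning. Particles advected out of the
domain are lost; particles advected onto dry land are reflected once
(kept at their previous position) and lost on a second grounding.

**Accounting.** At every step, released = pelagic + settled + lost +
dead; the invariant is tested live on a running simulation.

## 3. The flow-field interface and the idealized provider

The simulator sees hydrodynamics only through a closure list: velocity,
surface temperature, eddy diffusivity and its vertical derivative,
bathymetry, tidal phase, day/night. `generate_ideal_field()` implements
it analytically: a steady eastward along-coast residual current (the
large-scale anticlockwise shelf circulation sets this drift direction),
a sinusoidal M2 tidal current, seasonal sinusoidal SST with a weak
latitudinal gradient (defaults cross 10 °C in early April), a parabolic
`K(z)` profile vanishing at surface and bottom over local bathymetry,
and bathymetry deepening linearly offshore. Any provider implementing
the same closures — e.g. one interpolating archived hydrodynamic model
output — can be substituted without touching the simulator; running
against real current archives is exactly such a substitution and is out
of scope here.

## 4. Synthetic data: what it emulates, what it does not

`generate_otolith_dataset()` draws, per fish, a hatch date (April 1 –
May 15), integer larval and metamorphosis durations (Normal(23.2, 2.7²)
and Normal(11.2, 3.5²) days, truncated positive, rounded to whole
increments), a growth rate (station means defaulting to 0.53–0.65
mm d⁻¹, individual SD 0.07) and a station capture date (August 15 –
October 15). Settlement follows by construction; standard length is
growth × age; otolith radius inverts `SL = 24.1 + 57.74·OR` plus noise.
These moments are the published summary statistics of the observed
cohorts — the individual-level source data are not redistributable — so
the generator reproduces the *marginal* structure of a real reading
table, with exact per-fish ground truth attached.

With `reading_noise_sd = 0` the full pipeline recovers every hatch and
settlement date exactly (the package's primary round-trip property). By
default every fish carries an individual larval count so that round trip
is total; lowering `larval_ring_fraction` emulates the realistic
sparse-larval-reading situation, in which station-mean substitution
makes individual dates approximate by design.

What the generator does **not** emulate: reader disagreement structure
(a single symmetric noise term stands for it), correlation between
growth rate and phase durations, within-station capture-date spread,
winter deposition gaps, and any real hydrography. Passing tests
therefore demonstrate the correctness of the *computations*, not the
field accuracy of the parameter values.

Scenario fixtures (`scenario_fixture()`) provide constructed-outcome
simulations: `straight_to_nursery` (steady flow, constant 12 °C, no
diffusion — every particle settles in the target nursery),
`two_source_mixing` (two grounds whose spawning triggers are offset
~3 weeks by a strong meridional SST gradient — bimodal arrival curve),
and `cold_year` (seasonal cycle delayed 20 days — spawning peak shifts
exactly 20 days).

## 5. Validation statistics

Curves are aligned on the union week axis, zero-filled. The overlap
coefficient `Σ min(obs, pred)` was chosen as the quantitative proxy for
the visual curve comparisons of the source analysis: it is simple,
symmetric, in [0, 1], and 1 iff the curves coincide. Peak lag is
predicted minus observed modal week; modal ties break toward the earlier
week and are flagged, and the lag is reported absent under a tie rather
than invented. Long-term averaging takes the per-week mean of yearly
normalized curves and renormalizes; at desk scale the "long-term" mode
averages the simulated years present in the observations (the reference
analysis averaged a 21-year hindcast, which requires the real
hydrodynamic archive). Natal-ground decomposition is reported on the
predicted side only; the natal origin of an observed juvenile is
unknown.

PLD comparisons report predicted means both including and excluding the
yolk-sac stage, because otolith increments usually start at first
feeding; the headline difference is observed minus predicted-excluding-
yolk-sac.

## 6. Degenerate inputs and edge rules

* Empty reading files parse to empty datasets; invalid rows are dropped
  with row-level diagnostics, never silently.
* `-`/`NA` in tables mean *absent*, never zero.
* Zero ages back-calculate to the sampling date itself; `age = 0` makes
  growth rate undefined (absent, not infinite).
* OLS on fewer than 3 pairs, or with all radii identical, errors; the
  age–length smoother requires ≥ 10 fish spanning > 30 days and refuses
  prediction outside the observed age range.
* A temperature series never reaching 10 °C yields an empty spawning
  schedule plus a warning, not an error.
* `stage_duration` and egg mortality are undefined at `T ≤ 0` and error.
* Arrival binning of an empty set errors; a simulation with zero eggs
  returns a well-formed empty result.

## 7. Problem sizes

Defaults were chosen so a full check runs on a laptop: the test suite
uses 10–250 fish per station (10⁴ for moment checks, 10³ for the
round-trip certificate), 30–100 super-individuals per scenario ground at
Δt = 1800 s over ≤ 170 simulated days, and the well-mixed-condition
ensemble at 10⁴ particles × 10⁴ steps (screening size 3 × 10³ × 1.5 ×
10³ in the unit test). Production runs would raise `n_particles` to the
10⁴ default and plug in a real flow-field provider; nothing else
changes.

## 8. Known limitations

* The stage-duration coefficients are calibrated placeholders, not
  fitted values; conclusions about absolute timing inherit their
  uncertainty.
* The idealized field has no baroclinic structure, no wind events, no
  storm variability; interannual variability enters only through the
  spawning trigger.
* Temperature driving development is the *surface* temperature at the
  particle position, as in the reference parameterization; vertically
  resolved temperature would require a 3-D provider.
* Weekly binning makes sub-week lags invisible; the overlap coefficient
  conflates timing and shape mismatch.
* Back-calculation assumes strictly daily, uninterrupted increment
  deposition; overwintered fish violate this, which is why they are
  excluded rather than corrected.
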