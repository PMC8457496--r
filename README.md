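# soledrift

Otolith-based ageing and biophysical dispersal modelling for juvenile
common sole (*Solea solea* L.) in the southern North Sea.

Common sole spawns offshore in spring; its eggs and larvae drift for
roughly a month before the metamorphosing larvae settle in shallow
(< 20 m) coastal nurseries. Two independent windows exist on that hidden
pelagic phase. The daily growth increments of juvenile otoliths record,
ring by ring, the larval phase, the metamorphosis and the post-settlement
period, so hatching and settlement dates can be back-calculated from a
fish captured months later. And a biophysical individual-based model
(IBM) can simulate the same journey forward: eggs released on
temperature-triggered spawning schedules, transported by currents, aging
through temperature-dependent stages, and arriving at the nurseries.
`soledrift` implements both windows and the machinery to confront them,
for fisheries scientists validating dispersal models against otolith
microstructure (and vice versa).

## What is implemented

**Observed side (otolith pipeline).** For each fish with increment
counts: pelagic larval duration `PLD = larval + metamorphosis` days
(individual larval counts where the rings were readable, otherwise the
station-mean count), age at capture `= PLD + post-settlement` days,
hatching date `= sampling date − age`, settlement date
`= hatching date + PLD`, absolute growth rate `SL / age` (mm d⁻¹), the
linear somatic/otolith growth check `SL = β₀ + β₁·OR + ε` (OLS) and a
penalized-smooth age–length key `OR = α + f(A) + ε` (GAM). Back-calculated
settlement dates are binned by ISO week into normalized arrival curves.

**Predicted side (dispersal IBM).** Four stages — egg (EGG), yolk-sac
(YSL), first-feeding (FFL) and metamorphosing (MTL) larvae — each with:
duration `a·T^b` days at temperature `T`; mortality `0.0004·T^3.0293` d⁻¹
(EGG, YSL) or 0.035 d⁻¹ (FFL, MTL); and vertical behaviour — surface
keeping (EGG, YSL), diel migration at −0.001 / +0.003 m s⁻¹ day/night
(FFL), tidally synchronized migration at +0.001 / −0.003 m s⁻¹
rising/falling tide (MTL). Spawning at each ground peaks on the first day
its mean surface temperature reaches 10 °C, spanning peak ± 50 days, with
1.89 × 10¹³ eggs per year spread over the grounds as super-individuals.
Transport combines RK4 horizontal advection with a Visser-corrected
vertical random walk

    z' = z + K'(z) Δt + R · sqrt(2 K(z + ½K'(z)Δt) Δt / r)

on a pluggable flow-field interface; an idealized analytic field
(residual along-coast current, M2 tide, seasonal SST, parabolic
diffusivity) ships with the package.

**Validation layer.** Weekly arrival curves from both sides are compared
by overlap coefficient `Σ min(obs, pred)` and modal-week lag, year by
year and against multi-year averages, plus observed-versus-realized PLD
summaries in both yolk-sac conventions.

## Worked example

```r
library(soledrift)

# observed side: synthetic otolith cohort with known ground truth
syn <- generate_otolith_dataset(otolith_gen_config(n_fish = 30, rng_seed = 1))
rep <- run_observed_pipeline(syn$dataset)
rep
#> observed-side pipeline report
#>   90 fish aged over 3 stations; 0 station(s) excluded
#>  station year  n age_mean pld_mean settlement_date hatch_date
#>  SYN-BE1 2014 30    129.0 34.10000      2014-05-28 2014-04-24
#>  SYN-BE2 2014 30    134.8 34.63333      2014-05-30 2014-04-25
#>  SYN-NL1 2014 30    148.0 34.56667      2014-05-29 2014-04-24

# predicted side: dispersal under seasonal forcing
sc  <- scenario_fixture("cold_year", n_particles = 100)
sim <- simulate_dispersal(sc$config, sc$providers$baseline,
                          sc$grounds, sc$nurseries)
sim
#> sole larval dispersal simulation
#>   released 100 particles: 100 settled, 0 lost, 0 dead, 0 still pelagic
#>   realized PLD (excl. yolk sac): 34.5 +/- 4.0 days

# confrontation
compare_distributions(rep$distributions[["BE_2014"]],
                      predicted_arrival_distribution(sim))
#> arrival-curve comparison
#>   peak lag (predicted - observed): -3 week(s)
#>   overlap coefficient: 0.325
#>   shared week range: 19-25

compare_pld(rep$ages$pld, sim)
#> PLD comparison (days)
#>   observed:            34.4 +/- 4.0 (n = 90)
#>   predicted excl. YSL: 34.5 +/- 4.0 (n = 100)
#>   predicted incl. YSL: 39.2 +/- 4.8
#>   observed - predicted (excl. YSL): -0.1 days
```

The station table is the per-location summary a survey would publish:
mean age at capture (days), mean PLD, and the back-calculated mean
settlement and hatching dates. The simulation settles every particle
(steady flow into a wide nursery), realizes a ~34-day pelagic phase
excluding the yolk sac at spring temperatures, and arrives in ISO weeks
18–25 (May–June). The comparison quantifies what the plots would show: a
3-week offset between modal weeks here, 32% overlap of the two
normalized curves, and near-identical mean PLDs.

Fixture tables transcribed from the underlying field study are packaged
and validated (`load_fixtures()`): 402 fish over 11 station-years, 154
otoliths read, 31 with countable larval rings.

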