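# hydrocap

Soil–plant hydraulic simulation with plant water storage capacitance.

Trees do not draw all of their transpiration stream from the soil in real
time: water stored in sapwood and other tissues ("plant water storage")
discharges into the xylem when tension rises and refills overnight. How
much that storage actually helps depends on how stomata are regulated.
`hydrocap` is an R package for exploring that interaction. It is aimed at
plant ecophysiologists and ecohydrologists who want a transparent,
testable implementation of a classic resistor–capacitor
soil–plant-atmosphere model together with the field-data pipelines used to
parameterize and evaluate it.

## The model in brief

Water flows from a cylinder of accessible soil through a single long root
and a single big leaf, driven by water-potential gradients (Ohm's-law
analogy). The pieces:

* **Soil**: Brooks–Corey retention θ(ψ) and conductivity
  K(ψ) = K_s (ψ_e/ψ)^(2+3λ); steady radial flow to the root via the matric
  flux potential Φ(ψ) = ∫K dψ, so
  Q_soil = 2πL [Φ(ψ_bulk) − Φ(ψ_sri)] / ln(r_b/r_root).
* **Xylem**: whole-plant conductance K_x0 with a power-law vulnerability
  decline below the onset potential h_x0, handled through the integrated
  conductance so segment fluxes are exact.
* **Storage**: a linear pressure–volume compartment, full at 0 MPa and
  empty at −4.5 MPa (constant capacitance C = V_max/4.5), exchanging with
  the xylem node through conductance k_exchange:
  Q_cap = k_exchange (ψ_cap − ψ_x).
* **Closure**: at every time step, transpiration E = Q_soil + Q_cap; the
  xylem potential ψ_x that balances the node is solved by the damped
  fixed-point iteration (tolerance 5×10⁻⁵ MPa) and both reservoirs are
  updated.

Two stomatal strategies limit transpiration: a **fixed threshold**
(isohydric; the leaf is held at ψ_lim = −1.7 MPa, as observed in spruce)
and a **flexible** rule (anisohydric; stomata close where
E/(−Ψ_leaf + 0.2 MPa) peaks along the rising daily trajectory, as observed
in beech). Calibrated species presets (beech, spruce, and their average)
ship with the package.

Beyond the simulator, the package implements the accompanying data
pipelines: whole-plant-conductance and vulnerability calibration from
leaf campaigns (`estimate_Kx0()`, `select_envelope()`, `fit_L_hx0()`),
capacitance estimation from root-segment drydowns
(`capacitance_from_drydown()`), sap-flow vs. root-water-uptake lag
analysis (`rwu_series()`, `wet_day_mask()`, `daily_peak_times()`,
`fit_timing_distribution()`, `mean_lag()`), and ground-truthed synthetic
generators for all three observation kinds (`gen_campaign()`,
`gen_diel()`, `gen_drydown()`).

## Worked example

One day of half-sine evaporative demand (peak 0.3 cm³ s⁻¹) on the
average-tree preset, with storage sized to 50% of the daily demand
integral, wet soil, and no stomatal limitation:

```r
library(hydrocap)

sys <- hydraulic_system(soil_params(), plant_preset("average"),
                        storage_from_fraction(0.5))
traj <- run_simulation(sinusoidal_demand(), sys, strategy_spec("none"),
                       init_psi_soil = -0.1)
daily_summary(traj)
#>   day  E_total Q_soil_total Q_cap_total t_peak_E t_peak_Q_soil t_peak_Q_cap
#> 1   0 8250.579     8158.711      91.868        6         6.433        2.383
#>   lag_E_Q_soil min_psi_leaf
#> 1        0.433       -0.697
```

Reading this: the tree transpired 8251 cm³ (exactly the demand — wet soil,
no regulation), of which almost all was ultimately root uptake because the
storage discharged early in the morning (Q_cap peak at 02:23) and refilled
overnight (its net daily contribution, 92 cm³, is ~1% of the total). Peak
root uptake lagged peak transpiration by 0.43 h — the storage-induced lag
that sap-flow studies measure — and the leaf never fell below −0.70 MPa.

The strategy comparison across drying soil:

```r
res <- sensitivity_grid(fractions = 0.2, psi0 = seq(0, -2, by = -0.05))
crossover_potential(res)   # ~ -0.8 MPa
```

Under wet soil the flexible strategy transpires less (it closes earlier in
the day, the more so the larger the capacitance); under drying soil it
overtakes the fixed-threshold strategy, with the crossover near −0.8 MPa
initial soil water potential.

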