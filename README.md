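# phoenixsim

Kinetic simulation of the **Phoenix Rising pathway** — the signaling
relay by which apoptotic cells secrete prostaglandin E2 (PGE2) and
stimulate proliferation of the cells around them. The pathway matters in
two opposite directions: it helps damaged normal tissue repopulate after
injury, and it helps tumors regrow after radiotherapy kills only part of
the cell population.

The package is for systems biologists and radiation biologists who want
to simulate, perturb and calibrate this pathway: run the 48-h
post-irradiation protocol for MEF and 4T1 cells, knock out caspases in
silico, clamp NFκB, titrate a COX2 inhibitor, silence iPLA2, and ask
which rate constants the secreted PGE2 actually depends on.

## The model

Ten species, seventeen reactions, deterministic mass-action/enzyme
kinetics (concentrations in µM, time in minutes):

* **Inputs:** activated caspase-3 (C3\*), activated caspase-7 (C7\*) and
  NFκB accumulate at zero-order rates k₁, k₃ (switched on 24 h after
  irradiation by a Heaviside gate) and k₉ (from t = 0).
* **iPLA2 axis:** constitutive synthesis k₋₅ and first-order decay k₅ of
  iPLA2; Michaelis–Menten cleavage by C3\*/C7\* (k₂/K₂, k₄/K₄) into
  active iPLA2\*, which releases arachidonic acid (AA) at rate
  v₆ = k₆·[iPLA2\*].
* **COX2 axis:** NFκB drives COX2 transcription through a Hill law
  (k₁₀, K₁₀, n = 2); translation k₁₂; COX2 converts AA to PGH2 with
  competitive inhibition by PGE2 (K_i14) and by an exogenous drug of
  strength α; PGES (constant, 0.5 µM) converts PGH2 to PGE2 with
  competitive inhibition by AA (K_i16).
* **Volumes:** AA and PGE2 are medium-referenced; their source fluxes are
  diluted by 1/β with β = V_t/V_c = 5000.

Reported PGE2 converts at 3.525×10⁵ pg·mL⁻¹ per µM. The full rate-law
and mass-balance account, parameter table and numerical choices are in
the methods vignette (`vignettes/phoenix-rising-model.Rmd`).

## Worked example

```r
library(phoenixsim)

# 48-h radiation protocol for wild-type MEF cells at 10 Gy:
# unirradiated steady state -> irradiated trajectory
tr <- run_protocol(preset_condition("mef_10gy"))
tr
#> Trajectory: wild-type MEF (10 Gy), 289 time points over [0, 2880] min
#>   final [PGE2] = 0.005109 uM (1800.9 pg/mL)

# the pre-irradiation steady state it started from
round(relax_to_steady_state(preset_condition("mef_0gy")), 6)
#>   c3star   c7star     nfkb    ipla2 ipla2star cox2_mrna     cox2       aa
#> 0.000200 0.006000 0.100000 1.213525  0.286475  0.001277 0.095741 0.174672
#>     pgh2     pge2
#> 0.055698 0.001100

# compare all six standard conditions with the measured PGE2 panel
validate_against_table1()
#>       condition measured_pg_per_ml simulated_pg_per_ml rel_diff_pct
#> 1  c3ko_mef_0gy                335                 333         0.57
#> 2 c3ko_mef_10gy                525                 525         0.04
#> 3       mef_0gy                398                 388         2.59
#> 4      mef_10gy               1730                1801         4.10
#> 5       4t1_0gy                285                 285         0.09
#> 6      4t1_10gy               2100                1910         9.07
#> max relative difference: 9.07% -> PASS

# which of the 25 rate/equilibrium constants move 48-h PGE2 by >25%
# under a twofold perturbation?
sensitive_constants(sensitivity_scan())
#> [1] "k_minus5" "k6"       "k7"       "k17"
```

Reading: irradiated wild-type MEF cells secrete ~1801 pg/mL PGE2 at
48 h, up from 388 pg/mL without radiation, and the simulated panel stays
within 9% of measurement across both cell lines, both doses and the
caspase-3 knockout. The secreted output is controlled almost entirely by
the arachidonic-acid supply (iPLA2 synthesis k₋₅, release rate k₆,
active-enzyme lifetime 1/k₇) and the PGE2 lifetime 1/k₁₇.

A command-line interface wraps the same functions:

```sh
exec/phoenixsim simulate --preset 4t1_10gy --out-csv traj.csv
exec/phoenixsim scan --param alpha --values 0,1,2,5 --preset mef_10gy
exec/phoenixsim validate
```

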