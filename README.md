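# seepaom

Reaction-transport modelling and methane budgets for cold-seep
sediments.

## What it does, and for whom

In methane-seep sediments, anaerobic oxidation of methane (AOM)
removes most of the methane rising toward the seafloor. Sulfate-driven
AOM (S-AOM) dominates in the sulfate–methane transition zone (SMTZ),
but below it — in the methanic zone — buried reactive iron and
manganese oxides can keep oxidising methane (Fe-AOM, Mn-AOM).
`seepaom` is for biogeochemists who want to quantify that partition
from depth-resolved porewater and solid-phase profiles of a single
core.

The quantitative core is a 1-D steady-state reaction-transport model
for six dissolved species (SO₄²⁻, CH₄, DIC, Ca²⁺, Mg²⁺, Fe²⁺) and two
solid iron phases (reactive Fe oxides, Fe carbonate):

    0 = d/dz(φ Ds dC/dz) − d(φ v C)/dz + φ α(z)(C₀ − C) + R_C      (solutes)
    0 = −d((1−φ) w S)/dz + R_S                                      (solids)

with bimolecular AOM kinetics (S-AOM: k·[CH₄][SO₄]; Fe-AOM:
k·[CH₄][FeOx] gated off in sulfate-replete sediment), methane supplied
by bubble dissolution in a free-gas zone, bubble-driven nonlocal
irrigation, Monod-gated organoclastic sulfate reduction, and
threshold carbonate precipitation. Mn-AOM is estimated without a Mn
state variable, from the measured Mn²⁺ gradient via Fick's first law
(J = φ·Ds·|dC/dz|) and the 4:1 Mn(IV):CH₄ stoichiometry — an explicit
minimum estimate. Depth-integrated rates (µmol CH₄ cm⁻² yr⁻¹) are
partitioned into percentage fractions of total methane removal.

Everything is driven from data frames and returns tibbles; results
have `tidy()`/`glance()` methods and `autoplot()`/`plot_profiles()`
figures. A synthetic-profile generator reproduces the published
concentration anchors of a deep-water seep core so the whole pipeline
is testable without the (unpublished) raw data table.

## A worked example

```r
library(seepaom)

# 1. synthetic observations at the published anchor values (noise-free)
obs <- generate_anchor_profiles(anchor_spec(seed = 1), sigma_scale = 0)

# 2. zonation from the sulfate and methane profiles
zonate(obs)
#> <zonation> SRZ 0-130, SMTZ 130-228.592, methanic 228.592-430 cmbsf

# 3. solve the shipped reference scenario on a 1-cm grid
ms <- solve_steady_state(reference_scenario())
depth_integrate(ms, "S-AOM", c(0, 430))     # 18.34  umol CH4 cm-2 yr-1
depth_integrate(ms, "Fe-AOM", c(230, 430))  # 0.322  umol CH4 cm-2 yr-1
max(ms$rates[ms$z >= 230, "Fe-AOM"])        # 0.0207 umol CH4 cm-3 yr-1

# 4. Mn-AOM from the Mn2+ gradient over 250-350 cmbsf
site <- reference_scenario()$site
phi <- porosity_profile(site, 300)$phi
ds <- tortuosity_correct(diffusion_coefficient("Mn2", site$temperature),
                         phi)
fl <- fick_flux(obs$porewater$Mn2, c(250, 350), Ds = ds, phi = phi,
                minimum_estimate = TRUE)
mn_aom_from_flux(fl)
#> # A tibble: 1 x 3
#>    J_mn rate_ch4 minimum_estimate
#> 1 0.671    0.168 TRUE

# 5. the budget partition
budget_summary(ms, zonate(obs), fl)$partition
#> # A tibble: 3 x 4
#>   pathway   rate fraction_raw fraction
#> 1 S-AOM   18.3         97.4       97
#> 2 Fe-AOM   0.327        1.74       1.7
#> 3 Mn-AOM   0.168        0.890      0.9
```

Reading the numbers: sulfate-driven AOM removes ~18 µmol CH₄ cm⁻²
yr⁻¹ over the whole core (~97 % of removal), iron-driven AOM ~0.3
µmol cm⁻² yr⁻¹ in the methanic zone, and the Mn²⁺ gradient implies at
least ~0.2 µmol cm⁻² yr⁻¹ more — metal-driven pathways together take
a small but resolvable share of seep methane. The one-command version
of the same workflow (plus calibration, sensitivity analysis and a
Spearman correlation matrix) is

```r
res <- run_pipeline(pipeline_config(seeds = list(simulate = 1,
                                                 calibrate = 1)),
                    out_dir = "seep-run")
```

A thin command-line wrapper with the same stages as subcommands ships
in `inst/cli/seepaom`.

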