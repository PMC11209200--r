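# fugascreen

Environmental fate and hazard screening of nematicidal plant volatiles
against synthetic nematicides.

Plant-parasitic nematode control still leans on synthetic nematicides
(oxamyl, metam sodium, and the newer fluazaindolizine, fluensulfone and
fluopyram) that carry real risks for aquatic life and mammals. Volatile
phytochemicals — terpenes, phenylpropanoids, organosulfur compounds, and
beta-keto acid/fatty acid derivatives — are candidate bionematicides with
potentially safer profiles. `fugascreen` implements the desk-screening
pipeline used to compare them: curated physicochemical properties →
partition-parameter estimation → equilibrium multimedia fate modelling →
GHS acute-toxicity classification → an integrated exposure-by-hazard
report. It ships a 25-compound reference dataset (20 volatiles, 5
nematicides) compiled from public databases.

## The model

**Level I Mackay fugacity model.** A fixed emission E (default 100,000 kg)
enters a closed evaluative world of seven compartments at equilibrium at
25 °C. Each compartment has a fugacity capacity Z (mol m⁻³ Pa⁻¹):

    Z_air   = 1/(RT)                          Z_water = 1/H
    Z_soil  = Z_water · (ρ/1000) · foc · Koc  (likewise sediment, suspended)
    Z_biota = Z_water · (ρ/1000) · L · Kow
    Z_aero  = Z_air · 6×10⁶ / P_L,  P_L = VP / F,  F = exp(6.79(1 − Tm/T))

At a single equilibrium fugacity f = n / Σ(Z·V) with n = 1000·E/M, the
predicted environmental distribution (PED) of compartment c is
100·Z_c·V_c / Σ(Z·V). Missing parameters are filled by the Seth relation
Koc = 0.35·Kow and by Henry's law H = P·M/S.

**Hazard classification.** Acute oral/dermal LD₅₀ values map to GHS
categories 1–5 (oral cut-offs 5/50/300/2000/5000 mg/kg; dermal
50/200/1000/2000) and to the six-band toxicity-class scheme, with
left-open right-closed intervals and `>` qualifiers promoted past their
bound. Aquatic hazard is summarised as the minimum of fish LC₅₀, algae
EC₅₀ and *Daphnia magna* EC₅₀.

## Worked example

```r
library(fugascreen)
d <- bundled_dataset()
distribute(d$compounds[d$compounds$name == "Fluopyram", ])
#> Level I distribution: Fluopyram (658066-35-4)
#>   fugacity 1.477e-11 Pa over 2.52e+05 mol
#>   aerosols                0.0 %
#>   air                     0.0 %
#>   biota                   0.0 %
#>   sediment                1.3 %
#>   soil                   59.3 %
#>   suspended_particles     0.0 %
#>   water                  39.3 %
```

Fluopyram partitions mostly to soil (59.3%) and water (39.3%): unlike the
older nematicides (> 99% water), it is predicted to stay where it is
applied — but more than a third of the emitted mass still reaches water,
where its *Daphnia* EC₅₀ is 55.5 mg/L. The full pipeline:

```r
ped <- batch_distribute(d$compounds, reference = d$ped_reference)
hz  <- classify_hazard_table(d$mamm_tox)
rep <- screen_compounds(ped, d$ecotox, hz, d$compounds)
subset(rep$rows, name == "Oxamyl")$flags
#> [1] "water_affine;aquatic_concern;mammalian_concern"
```

Rows whose published distribution cannot be reproduced from the published
inputs (internal unit inconsistencies in the source data) are flagged
`non_reconstructable` instead of silently reported. `reconcile_henry()`
shows why: six compounds print an H that disagrees ~100-fold (or worse)
with VP·M/S from the same row:

```r
rec <- reconcile_henry(d$compounds)
print(subset(rec, henry_consistency == "discrepant")[,
  c("name", "henry_printed", "henry_derived", "discrepancy_ratio")],
  digits = 3)
#>                    name henry_printed henry_derived discrepancy_ratio
#> 8             3-Octanol         3.209      3.21e-02             100.0
#> 10         2-Undecanone         0.114      1.14e+01              99.7
#> 14 Dipropyl trisulphide         0.209      2.08e+01              99.7
#> 17         Benzaldehyde         2.031      1.53e-04           13301.4
#> 21       cis-Ascaridole         0.760      6.35e-03             119.7
#> 23              Carvone         0.105      1.06e+01             100.7
```

A command-line interface mirrors the pipeline
(`Rscript inst/cli/fugascreen ped|classify|screen|synth ...`).

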