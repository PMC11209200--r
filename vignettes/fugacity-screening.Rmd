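---
title: "Multimedia fate and hazard screening of nematicidal volatiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimedia fate and hazard screening of nematicidal volatiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fugascreen)
```

## The screening problem

Candidate bionematicides — volatile terpenes, phenylpropanoids,
organosulfur compounds and fatty-acid derivatives — are compared with
synthetic nematicides on two axes: where an emitted mass ends up
(exposure), and how toxic the compound is to non-target organisms where it
ends up (hazard). `fugascreen` implements both axes and their crossing as
a transparent, fully configurable rule engine over a packaged 25-compound
dataset.

## The Level I model and its assumptions

The fate engine is an equilibrium (Level I) Mackay fugacity model: a fixed
emission into a closed, well-mixed evaluative world; no degradation,
advection or inter-media transfer kinetics. Equilibrium means a single
fugacity $f$ across all compartments, so the mass fraction in compartment
$c$ is $Z_c V_c / \sum_j Z_j V_j$ — independent of the emission mass,
which only scales $f$. This is a *screening* model: it ranks affinities,
it does not predict concentrations in a real landscape.

Fugacity capacities follow the standard forms (air $1/RT$; water $1/H$;
organic-carbon-mediated sorption $Z_{water}\,(\rho/1000)\,f_{oc}\,K_{oc}$
for soil, sediment and suspended particles; lipid partitioning
$Z_{water}\,(\rho/1000)\,L\,K_{ow}$ for biota; the empirical
$Z_{air}\,6\times10^6/P_L$ association for aerosols). For solids the
aerosol term uses the subcooled-liquid vapour pressure $P_L = VP/F$ with
$F = \exp\!\big(6.79\,(1 - T_m/T)\big)$; 6.79 is the conventional
entropy-of-fusion default and no compound-specific value is supported.
When a compound has no usable vapour pressure the aerosol capacity is set
to zero rather than undefined.

### The evaluative world

The defaults (see `default_environment()`) are the standard Level I unit
world: volumes $10^{14}$ (air), $2\times10^{11}$ (water), $9\times10^9$
(soil), $10^8$ (sediment), $10^6$ (suspended particles), $2\times10^5$
(biota), $2\times10^3$ m$^3$ (aerosols); organic-carbon fractions
0.02 / 0.04 / 0.2 for soil / sediment / suspended; solids densities
2400 / 2400 / 1500 / 1000 / 2000 kg m$^{-3}$; biota lipid fraction 0.05;
$T = 298.15$ K, $R = 8.314$ Pa m$^3$ mol$^{-1}$ K$^{-1}$, emission
100,000 kg. These constants were fixed once, before any comparison with
the reference distribution table, on the grounds that they are the
documented defaults of the classic Level I calculator; the package's
acceptance tests then confirm they reproduce the reference table for all
of its internally consistent rows. Any constant can be overridden via a
JSON configuration (`read_environment()`); YAML is deliberately not
supported to avoid a dependency outside the declared stack.

## Parameter estimation and the reconciliation policy

Three parameters are derivable when missing:

* $K_{oc} = 0.35\,K_{ow}$ (Seth relation) — used whenever the table has no
  printed Koc; `signif3()` reproduces the 3-significant-figure
  presentation of published tables.
* $H = P\,M/S$ with $S$ in mg/L $\equiv$ g/m$^3$.
* $F$ from the melting point as above; $F = 1$ for liquids.

The packaged property table contains rows whose printed $H$ disagrees
with $P\,M/S$ computed from the same row by two orders of magnitude
(3-octanol, 2-undecanone, dipropyl trisulphide, carvone, cis-ascaridole;
benzaldehyde by four orders). `reconcile_henry()` quantifies the
disagreement as $\max(H_{printed}/H_{derived},\,H_{derived}/H_{printed})$
and flags rows beyond a 3-fold tolerance. The default policy is
**printed-first** (use the printed $H$ when present): hand-validation
showed the reference distribution table is reproduced from printed values
for the majority of rows. The alternative **derived-first** policy is a
one-argument switch, and the batch engine records, per row, whether
switching policy would reproduce the reference (see below).

## Non-reconstructable rows

`batch_distribute(..., reference = )` compares each computed distribution
with a reference table at ±0.5 percentage points per compartment. A row
that fails under the policy in use is flagged `non_reconstructable`; if
the *other* Henry policy reproduces it, a supplementary
`derived_h_reproduces_reference` flag records that the row is recoverable
— this is the case for carvone, 2-undecanone and dipropyl trisulphide,
whose printed $H$ is exactly the ~100-fold-off member of each pair. Eight
further rows cannot be reproduced under either policy; their source
inputs are internally inconsistent in ways the data alone cannot resolve,
so they are flagged rather than matched or corrected. One related
expectation in the acceptance suite is intentionally left failing: it
asserts (following its source document) that 2-decanone's printed and
derived $H$ disagree ~100-fold, but the packaged table shows them to
agree within 0.3%.

## Hazard classification conventions

All classifiers use left-open, right-closed intervals, following the
explicit "$5 < LD_{50} \le 50$" style of the six-band scheme; prose
formulations like "below 5" are read to the same convention, so a
boundary value classifies into the more severe class. A `>` qualifier
means the true value exceeds the bound, so it classifies as if
infinitesimally above it (`>2000` dermal → category 5). Two deliberate
choices:

* **Oral values above 5000 mg/kg** fall outside the five GHS categories;
  the default maps them to category 5 (least severe) so that summary
  statements over whole tables remain total, with
  `above_5000 = "unclassified"` available for strict GHS reporting.
* **Dermal values printed as exactly 2000** classify as category 4 under
  the convention. Published summaries sometimes treat these as "above
  2000" (category 5); the classification table annotates qualifier-borne
  bounds so both readings stay auditable, and the package does not force
  agreement.

## The screening rules

The exposure-by-hazard crossing is rule-transparent, not a score:
`water_affine` / `air_disperser` / `soil_affine` fire at ≥ 50% of mass in
the compartment; `aquatic_concern` = water-affine **and** minimum aquatic
threshold < 10 mg/L; `mammalian_concern` = GHS oral category ≤ 2. The
thresholds reproduce the qualitative groupings of the comparative study
they were designed around and are echoed verbatim into every report, so a
report is reproducible from its own payload. Missing endpoints yield
`insufficient_data:` markers, never a silent pass. Fold-difference
comparisons are reported at full precision plus a nearest-10 rounding
(the "ca. N-fold" convention); a `>` bound in the numerator yields an
"at least N-fold" qualifier.

## The synthetic generator

`generate_compound_set()` draws internally consistent records:
partition-relevant properties ($H$, $K_{oc}$, $S$) are log-uniform within
profile bounds — they span many orders of magnitude in real tables —
while molar mass is uniform on [100, 500] g/mol. $H$ is sampled directly
and the vapour pressure back-solved as $VP = H\,S/M$, so synthetic rows
never exhibit the printed-vs-derived inconsistency of the real table;
$\log K_{ow}$ is set Seth-consistently from the sampled $K_{oc}$. The
three single-compartment profiles have bounds chosen so the expected
dominant compartment holds essentially by construction under the default
world (verified ≥ 95% in tests). Every fifth record omits its stored $H$
to keep the derivation path exercised, and endpoint batches always carry
at least one `>` qualifier.

`generate_endpoint_tables()` draws endpoints log-normally around
per-class medians (natural-log scale dispersion, default 0.2), emulating
the class structure of real screening tables — synthetic pesticides sit
orders of magnitude below phytochemicals on invertebrate EC$_{50}$. What
a green test establishes is therefore *pipeline correctness* (parameter
recovery, label fidelity, qualifier handling), not realism of any
particular compound: the generator is mechanism-targeted, it does not fit
the empirical property distribution, does not correlate endpoints across
trophic groups, and has no missing-data structure beyond the designed
gaps.

## Numerical choices

* Percentages are kept at full precision internally; presentation rounds
  half-up to one decimal (`round_percent()`), since base R's half-to-even
  rounding does not match published tables.
* Qualifier promotion uses a relative epsilon of $10^{-12}$ above the
  bound — far below any printed precision.
* Conservation is exact by construction; tests assert $10^{-9}$ relative
  on the sum and $10^{-12}$ against an independently coded oracle.
* Dominant-compartment ties resolve in the fixed compartment order
  (aerosols, air, biota, sediment, soil, suspended particles, water).

## Known limitations

Level I only: no persistence, reaction or advection, so air-dispersing
volatiles look "safe" partly because degradation is outside the model.
Identity is by CAS number; no structures, no QSAR. Ecotoxicity and
mammalian values marked as model predictions in the source data are
stored verbatim and never recomputed. The packaged carvone solubility
(27 mg/L) is far below common literature values; it is kept as printed
and inherited by every downstream number for that compound.
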