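# eetmorph

Rod-shaped cyanobacteria change shape when their environment changes —
and because mediated extracellular electron transfer (EET) under
mass-transfer limitation depends on cell geometry, a measured change in
EET rate between two cultures may reflect nothing more than a change in
cell morphology. `eetmorph` separates the two: it quantifies how much
of an observed EET-rate difference is attributable to morphology
(through the mass-transfer coefficient *k* and the cell surface area
*A*) and how much to physiology or metabolism (through the
bulk-to-surface mediator concentration difference). It is aimed at
researchers running ferricyanide-assay comparisons of cyanobacterial
cultures (e.g. in biophotovoltaics work) who need to know whether an
environmental treatment altered the EET pathway or merely the cells.

## The model

Under mass-transfer limitation the per-cell ferricyanide reduction rate
follows Fick's law,

    r = k · A · ([Fe³⁺]_b − [Fe³⁺]_s),

with *k* the liquid-to-cell mass-transfer coefficient, *A* the
geometric outer-membrane area, and the bracket the bulk-to-surface
concentration difference Δc. Each factor is obtained independently:

* **A** from spherocylinder stereology of projected dimensions:
  `A = πDL`, `V = π/4·D²(L − D/3)`, fed by moment-ellipse morphometry
  of fluorescence images (binarisation, 8-connected labelling, axes =
  4·√eigenvalues of the pixel covariance) with quality-control filters
  and count-weighted population statistics.
* **k** from the suspended-microorganism correlation
  `k = 2·D_AB/d_p + 0.31·(D_AB²·|ρ_p − ρ_c|·g/μ_c)^{1/3}`, valid for
  1 µm < d_p < 600 µm, with the cell length as characteristic
  dimension.
* **r** from the OLS slope of the assay concentration–time course,
  normalised per cell.
* **Δc = r/(kA)** by inversion, with first-order error propagation.

Fractional test-vs-control differences compose as
`(1+Δr) = (1+Δk)(1+ΔA)(1+ΔΔc)`, and the **morphology effect ratio**

    MER = 1 / (1 + exp(−|Δ(k·A)| / |Δ(Δc)|))

condenses the comparison to one number in (0.5, 1): above 0.7311
(the value at unit ratio) morphology dominates the rate difference,
below it physiology/metabolism does. A decoupled derivative
`∂r/∂L = [A·(−2D_AB/L²) + k·πD]·Δc` separates the two opposing effects
of elongation (area gain vs boundary-layer loss). Gompertz growth
fitting, OD750/chlorophyll conversions and a synthetic-data generator
(populations, rendered images, assay traces, growth curves, all with
known ground truth) complete the pipeline.

## Worked example

```r
library(eetmorph)

# mass-transfer coefficient at the exponential-phase mean length
mt <- mass_transfer_coefficient(3.7)
mt
#> <mass_transfer_result> k = 0.000423 m/s (diffusive 0.0004022 +
#>   gravitational 2.08e-05) at d_p = 3.7 um

# population area regression on 3000 synthetic cells, evaluated at 3.7 um
pop <- sample_population(n_cells = 3000, seed = 1)
reg <- bin_regress(cell_dims(pop$length_um, pop$width_um), "area")
predict_mean_property(reg, 3.7)
#>   length_um predicted  ci95_lo  ci95_hi uncertainty extrapolated
#> 1       3.7  13.98193 13.87639 14.08748   0.1055447        FALSE

# assay slope -> per-cell rate -> concentration difference
s <- simulate_assay(true_rate_mol_cell_s = 2.5e-20,
                    cell_conc_per_ml = 6.78e8, noise_sd_mM = 0.005, seed = 2)
r <- reduction_rate(s)$rate_mol_cell_s   # 2.604e-20 mol cell^-1 s^-1
conc_difference(r, mt$k_ms, 14.0e-12)$delta_c_molm3
#> 4.397e-06  (mol m^-3)

# the verdict for a test-vs-control comparison
morphology_effect_ratio(dkA = 0.12, ddc = -0.05)
#> $mer [1] 0.9168 ; $dominance "morphology"
```

The k value says diffusion through the boundary layer dominates
transport (the gravitational term is 20x smaller); the regression puts
the mean cell area near 14 µm² with a ±0.11 µm² confidence half-width;
the inverted Δc of ~4.4e-6 mol m⁻³ is the diffusive driving force; and
an MER of 0.92 means the k·A (morphology) channel changed much more
than the physiology channel, so the rate difference is mostly shape.

`run_pipeline()` chains all of this from three CSV inputs (per-cell
dimensions, assay readings, assay metadata) to snapshot/MER tables and
a JSON report; `inst/cli/eetmorph.R` exposes the same steps as shell
verbs (`simulate`, `stereology`, `assay-rate`, `growth-fit`,
`mass-transfer`, `mer`, `run`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

builds two synthetic cultures with different morphologies, derives
their k and A through the package, pins the physiology channel to the
same fractional magnitude as the morphology channel, and reports the
resulting morphology effect ratio.
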