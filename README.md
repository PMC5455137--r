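# pdoflux

Constraint-based phenotype prediction for anaerobic, glycerol-fermenting
bacteria that produce 1,3-propanediol (PDO) — the *Clostridium*-type
metabolism where an oxidative branch (glycerol → pyruvate → acids/H₂, making
ATP and NADH) balances a reductive, NADH-consuming branch (glycerol →
3-hydroxypropanal → PDO). The package is for modelers who have (or want to
prototype against) a genome-scale metabolic model of such an organism and
need the full analysis chain: flux prediction under biologically validated
objectives, feasible ranges, knockout screens, growth-coupling structure,
and omics consistency checks.

## What it computes

Given a stoichiometric model (`S v = 0`, bounds `v_min ≤ v ≤ v_max`),
`solve_fba()` predicts a flux distribution under one of three objectives:

* `lp_biomass` — maximize the growth rate μ (linear programming);
* `yield_per_flux` — maximize `μ / Σ v²`, biomass yield per enzyme usage,
  the validated objective for substrate-**limited** growth;
* `weighted` — maximize `μ / (w Σ v² + (1 − w) v_ATP²)`, `w ∈ (0,1)`
  (default calibration `w = 0.04` for glycerol **excess**), which also
  penalizes ATP production and captures sub-optimal growth.

The fractional objectives are solved to global optimality by Dinkelbach
iteration over convex quadratic subproblems. Around the core solver the
package provides: an allosteric logistic upper bound on acetate secretion as
a function of glycerol uptake (`acetate_upper_bound()`); flux variability
analysis with the objective relaxed by 5% (`fva()`, `yield_ranges()`);
ROOM knockout prediction and single/double enzyme-deletion screens
(`room()`, `single_deletion_screen()`, `double_deletion_screen()`);
flux-coupling classification of reactions and enzymes relative to growth
and blocked-metabolite detection (`flux_coupling()`,
`find_blocked_metabolites()`); qualitative proteome/transcriptome
consistency scoring (`compare_expression()`); biomass-composition
perturbation screens and glucose–glycerol co-fermentation yield surfaces
(`perturbation_screen()`, `cofermentation_surface()`,
`minimal_conversion_ratio()`); SBML and tabular model I/O (`load_model()`,
`write_model()`); and a staged, manifest-writing pipeline
(`run_pipeline()`). Synthetic fixtures (`toy_glycerol_model()`,
`random_model()`) make every stage runnable with no external files.

## Worked example

```r
library(pdoflux)

m <- toy_glycerol_model()        # balanced ~30-reaction anaerobic network
cond <- culture_condition(c(EX_glyc = 10), acetate_constraint = TRUE,
                          fix_uptake = TRUE)

f <- solve_fba(m, cond, objective_spec("yield_per_flux"))
glance(f)
#> # A tibble: 1 × 4
#>   objective_value status  n_reactions n_active
#>             <dbl> <chr>         <int>    <int>
#> 1        0.000258 optimal          30       28

yield_ranges(m, cond, objective_spec("yield_per_flux"),
             products = c("BIOMASS", "EX_pdo", "EX_h2"),
             substrate = "EX_glyc")
#> # A tibble: 3 × 5
#>   product y_point  y_min  y_max uptake
#>   <chr>     <dbl>  <dbl>  <dbl>  <dbl>
#> 1 BIOMASS  0.0161 0.0156 0.0161     10
#> 2 EX_h2    0.754  0.754  0.773      10
#> 3 EX_pdo   0.106  0.101  0.106     10
```

At a fixed glycerol uptake of 10 mmol gDW⁻¹ h⁻¹ the yield-per-enzyme-usage
objective predicts growth at μ ≈ 0.16 h⁻¹ (`y_point` is per unit uptake)
**with** PDO secretion — 0.106 mol PDO per mol glycerol, feasible range
0.101–0.106 at 5% objective relaxation — whereas plain biomass maximization
on the same model predicts no PDO at all. Electron overflow leaves as
hydrogen (0.754 mol/mol). A double lactate-dehydrogenase knockout is
predicted phenotypically silent here, because the wild type carries no
lactate flux:

```r
r <- room(m, cond, deletions = c("1.1.1.27", "1.1.1.28"), wild_reference = f)
glance(r)
#> # A tibble: 1 × 4
#>   deletions         n_changed viable status
#>   <chr>                 <int> <lgl>  <chr>
#> 1 1.1.1.27+1.1.1.28         0 TRUE   optimal
```

Result objects have `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
companions (robustness scans, flux ranges, perturbation correlations,
co-fermentation surfaces).

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance quantities from
scratch — the logistic acetate-secretion bound evaluated at zero glycerol
uptake and at its large-uptake saturation — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
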