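---
title: "Constraint-based phenotype prediction for PDO-producing anaerobes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based phenotype prediction for PDO-producing anaerobes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdoflux)
```

## The modeling problem

Anaerobic bacteria such as glycerol-fermenting *Clostridium* convert glycerol
through two coupled branches. The oxidative branch runs glycerol to pyruvate
and onward to acetate, butyrate, lactate, ethanol, formate and hydrogen,
producing ATP and the reducing equivalent NADH. The reductive branch
dehydrates glycerol to 3-hydroxypropanal and reduces it to 1,3-propanediol
(PDO), consuming NADH. Because the cell is anaerobic, the substrate is both
electron donor and acceptor, and the split between the branches is set by the
redox and energy balance.

`pdoflux` predicts steady-state flux phenotypes of such networks from a
genome-scale metabolic model: a stoichiometric matrix \(S\), flux bounds, and
gene/enzyme annotations. A flux distribution \(v\) is feasible when
\(S v = 0\) and \(v^{min} \le v \le v^{max}\); a phenotype is the optimizer
of an objective over that polytope.

## The three objectives

* **`lp_biomass`** maximizes the growth rate \(\mu\) (the biomass reaction
  flux) by linear programming. On fermentative networks that can vent
  electrons as hydrogen and formate, this objective uses the substrate almost
  purely as an electron donor and predicts **no PDO at all** — a vertex
  artifact that disagrees with experiments.
* **`yield_per_flux`** maximizes \(\mu / \sum_i v_i^2\), formalizing the
  hypothesis that substrate-limited cells maximize biomass yield while
  minimizing total enzyme usage (squared flux is the usual proxy). The
  spread-out optimum routes part of the glycerol through the short reductive
  branch: PDO production appears.
* **`weighted`** maximizes
  \(\mu / \left(w \sum_i v_i^2 + (1 - w)\, v_{ATP}^2\right)\) with
  \(w \in (0,1)\), where \(v_{ATP}\) sums the flux of the designated
  ATP-producing reactions in their ATP-forming direction. Small \(w\)
  additionally penalizes ATP production and reproduces the *sub-optimal*
  growth observed under substrate excess; \(w = 0.04\) is the calibration
  for glycerol excess, and `calibrate_weight()` re-estimates it from
  experimental yield tables.

### How the fractional programs are solved

Both non-linear objectives have a linear numerator and a convex denominator,
so maximizing the ratio is a concave–convex fractional program. We solve it
by Dinkelbach iteration: each subproblem
\(\max_v\, \mu - \lambda D(v)\) is a strictly convex quadratic program
(solved with `quadprog`), and the iteration on \(\lambda\) converges to the
**global** optimum. The ATP term \(\sum_j \max(\sigma_j v_j, 0)\) is handled
exactly with auxiliary variables \(p_j \ge \sigma_j v_j,\ p_j \ge 0\), whose
quadratic coupling \((\sum_j p_j)^2\) stays convex. This is a deliberate
design choice over multi-start local NLP: on every toy network where a dense
grid or analytic optimum is available, the two agree, but Dinkelbach carries
a global guarantee and needs no random starts. Multi-start SLSQP, tried
first, stalled at inferior local optima on exactly the networks that matter
(it reported a PDO-free local optimum where the global optimum produces
PDO).

A degenerate case is worth knowing: with no fixed demand (no maintenance
ATP, uptake given as a *bound* rather than a flux), \(\mu/\sum v^2\) grows
without bound as \(v \to 0\), because halving all fluxes halves the numerator
but quarters the denominator. Models should anchor the scale with a non-zero
NGAM or a fixed substrate uptake (`culture_condition(..., fix_uptake =
TRUE)`); the robustness scans "as a function of uptake flux" always fix it.

## The allosteric acetate bound

Acetate secretion in glycerol cultures saturates with the uptake flux. The
bound is logistic,
\[
v_{ac} \le \frac{v_{max} v_0 e^{r u}}{v_{max} + v_0\,(e^{r u} - 1)},
\]
with \(v_0 = 0.158\) and \(v_{max} = 11.5\) mmol gDW\(^{-1}\) h\(^{-1}\) and
rate \(r = 0.0859\) g h mmol\(^{-1}\); \(u\) is the glycerol uptake
magnitude. The published sources print two rate constants (0.0859 in the
bound's equation, 0.0879 in the surrounding text); the equation's value is
the default and both are accepted by `acetate_params()`. The sign convention
is chosen so the bound **rises** from \(v_0\) toward \(v_{max}\) as uptake
grows, which matches the printed initial/maximum values and the physiology.
The implementation evaluates the algebraically equivalent form
\(v_{max} / (1 + (v_{max}/v_0 - 1) e^{-r u})\), which cannot overflow and
stays monotone in floating point. The constraint applies to glycerol
cultures only; keep it off for other carbon sources.

## Variability, coupling, knockouts

**FVA.** Feasible flux ranges are computed per reaction with the objective
held within 5% of its optimum (`Z >= 0.95 Z*` for maximized objectives). For
the fractional objectives this constraint is rewritten as
\(\mu - 0.95\,Z^* D(v) \ge 0\), which is *convex*, so the linear FVA
subproblems (solved with SLSQP) have no spurious local optima. The
relaxation applies to all objectives, linear included.

**Flux coupling.** Ratio extremes \(v_j / v_{target}\) over the polytope are
computed with the Charnes–Cooper substitution (two LPs per reaction; an
unbounded LP reports an infinite ratio). Classes: `blocked`; `full` (fixed
non-zero ratio); `partial` (ratio bounded away from zero); `directional`;
`uncoupled`. Reversible reactions are classified on \(|v_j|\), since
expression prediction cares about activity, not direction. The sources do
not pin down which implication "directionally coupled" denotes; this package
adopts the flux-coupling-finder convention that a non-zero \(v_j\) implies a
non-zero target flux, tested by fixing the target to zero and checking
whether the reaction can still run. Enzymes aggregate their reactions'
classes by strongest coupling, and are `blocked` only when every catalyzed
reaction is blocked.

**Blocked metabolites** are detected per metabolite by adding a temporary
sink and maximizing its flux — an LP-per-metabolite formulation with the
same result set as the binary-MILP original, but deterministic and simpler.
Note that on small closed toys, conserved cofactor pools (ferredoxin,
NAD(H), adenine phosphates) are correctly reported blocked for net
production.

**ROOM.** Knockouts map to reactions through EC annotations: a reaction
closes only when *all* of its isozyme ECs are deleted. The mutant phenotype
minimizes the number of reactions pushed outside the wild-type band
\(v_{wild} \pm (\delta |v_{wild}| + \varepsilon)\), \(\delta = 0.05\),
\(\varepsilon = 0.001\), as a mixed-binary program solved by branch and
bound with big-M constants taken from each reaction's own bounds. The wild
reference defaults to the `yield_per_flux` solution, the validated objective
for substrate-limited cultures. Mutant FVA ranges (when requested) fix the
on/off optimum within a 5% relaxation of the integral count — an
interpretation, since the sources do not state which constraint holds during
mutant range computation. Ties among equal-count solutions return the
incumbent found first by the deterministic search order.

## Screens

**Biomass-composition perturbation.** Each perturbable biomass precursor
coefficient (consumed species minus the ATP/water maintenance currency) is
drawn from a normal with mean at nominal and standard deviation 30% of
nominal. Draws with any non-positive coefficient are excluded, not redrawn,
so the retained count follows \(n\,\Phi(1/\mathrm{rsd})^k\). After
perturbation the precursor coefficients are renormalized by molar mass so
one unit of biomass flux still produces 1 gDW — without this, yields are not
comparable across samples; growth-associated ATP stays fixed per gDW.
Pearson correlations are computed against the dimensionless multipliers.
(The published exclusion bookkeeping — 965 of 10,000 at 52 coefficients — is
~4x the closed-form normal-tail expectation; the sampler here follows the
stated normal model, and the tests check the closed form, not the printed
count.)

**Co-fermentation.** The yield surface reports the FVA maximum of PDO
secretion divided by glycerol uptake over a glucose x glycerol uptake grid;
`minimal_conversion_ratio()` bisects for the smallest glucose/glycerol
uptake ratio achieving complete conversion (\(Y_{PDO} \ge 1 -\) tol). With
`objective = NULL` the surface is the pure stoichiometric capability,
otherwise the relaxed-objective constraint applies.

**Omics comparison** is qualitative and EC-keyed: an expressed enzyme is
"predicted" when any reaction it catalyzes carries flux above `tol_zero`
(1e-6, shared with the solver); structurally blocked enzymes are excluded;
dashes in partial ECs match by prefix; expression lists are taken as given,
with no abundance thresholds.

## The synthetic world

`toy_glycerol_model()` builds an ~30-reaction anaerobic glycerol network
with every internal reaction atom- and charge-balanced (carriers carried in
full: NAD(H), ATP/ADP, and ferredoxin as a two-electron pseudo-element
`Fd`). Defaults: GAM 40 mmol ATP gDW\(^{-1}\), NGAM 5 mmol ATP gDW\(^{-1}\)
h\(^{-1}\) (the maintenance reaction is fixed at this rate), uptake bound 10
mmol gDW\(^{-1}\) h\(^{-1}\), all byproduct branches present, textbook
integer stoichiometry, and a biomass equation lumped into three
pseudo-precursors (carbon skeleton, nitrogen compound, lipid; 300/550/150 mg
per gDW) so the perturbation screen is exercisable at toy scale. At uptake
10 the toy grows at \(\mu \approx 0.16\ h^{-1}\) under the fractional
objective — a realistic magnitude for anaerobic glycerol growth.

The toy reproduces the qualitative regimes that motivate the objective
choices: LP predicts zero PDO; the fractional objective predicts PDO; under
forced excess uptake the ATP-penalized objective reverses the ferredoxin:NAD
reductase and lowers the hydrogen/reduced-ferredoxin formation ratio
\(\alpha_{H_2/Fd}\). It does **not** emulate the numerics of a real
891-reaction reconstruction: yields, coupling class counts and omics rates
on the toy are properties of the toy. A green test establishes the
algorithms, not the biology of any particular strain.

`random_model()` generates connected, trivially mass-balanced test beds for
oracle-equivalence tests (vertex enumeration stays exact at that size), and
`synthetic_expression()` derives noisy expressed-enzyme lists from a flux
state to exercise the omics comparison.

## Numerical choices

* LP/MILP: a dense two-phase bounded-variable simplex with Bland's-rule
  fallback (no LP solver package is available in the target environment);
  branch and bound prunes on the integral on/off count. Verified against an
  independent solver on hundreds of random instances during development and
  against in-suite vertex-enumeration oracles at test time.
* `tol_zero` and `tol_balance` are 1e-6 (mmol gDW\(^{-1}\) h\(^{-1}\));
  formula balance tolerance 1e-4 atoms; Dinkelbach fixed-point tolerance
  1e-12 relative.
* Degenerate denominator at \(v = 0\): the ratio objective is defined as 0
  when \(\mu = 0\).
* All stochastic code (sampling, random test beds, noisy expression) runs
  under explicit seeds; rerunning a pipeline config reproduces outputs
  bit-identically.

## A worked call

```{r example, eval = FALSE}
m <- toy_glycerol_model()
cond <- culture_condition(c(EX_glyc = 10), acetate_constraint = TRUE,
                          fix_uptake = TRUE)
f <- solve_fba(m, cond, objective_spec("yield_per_flux"))
glance(f)
yield_ranges(m, cond, objective_spec("yield_per_flux"),
             products = c("BIOMASS", "EX_pdo", "EX_h2"),
             substrate = "EX_glyc")
```

## Known limitations

* The simplex is dense and suited to networks up to a few hundred reactions;
  genome-scale models load and validate fine, but whole-model coupling or
  double-deletion screens at that size are offline jobs.
* Relaxed-objective FVA for fractional objectives relies on the convex
  reformulation; if a future objective lacks one, ranges would only be
  locally valid.
* Thermodynamic loop handling is a post-hoc check (`loopless_check()`), not
  a loopless solve: it certifies a given flux distribution, it does not
  forbid loops during optimization.
* Charge balancing trusts the formulas and charges in the model file; no
  pH-dependent protonation is computed.
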