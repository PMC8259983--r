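---
title: "Growth-coupled ME models and coenzyme activity coupling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-coupled ME models and coenzyme activity coupling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modeling choices, parameters and numerical
machinery behind `meallocate`, in the spirit of a methods section: what the
model assumes, which knobs matter, and where the implementation makes a
decision the mathematics alone does not force.

## 1. The μ-parametric model

A metabolism-and-expression (ME) model extends a stoichiometric network
with the machinery that expresses it. At steady state, every macromolecule
pool is diluted by growth, so the formation flux of each machine must cover
a μ-dependent multiple of the flux that machine carries. We encode each
such constraint as a *pseudo-species*: the formation reaction produces one
unit of it and each coupled flux consumes the μ-dependent coefficient. The
entire problem then stays a single homogeneous system `S(μ) v = 0` with
bounds, and the biomass dilution flux pinned to μ.

Every coefficient is stored as the rational form
`a + b·μ + c/μ + d·μ²`. The `1/μ` term appears only in the mRNA
degradation coupling; the `μ²` term only in the synthetase coupling
`(1 + μ/k_eff,tRNA)(μ/k_eff,charging)`, which is the product of two
μ-linear factors. Coupling rows are equalities, not inequalities: machinery
is made exactly as needed. (A consequence worth knowing: solutions never
"overbuild" machinery, and redundant formation routes are resolved by the
minimum-norm rule below.)

Two structural conventions follow the established ME formulations:

* **Peptides are materially balanced** (translation produces them, complex
  formation consumes them), while mRNA, tRNA and complex species are
  bookkeeping entities whose economy lives entirely in their coupling
  rows. Complex formation deposits the complex's protein mass (g/mmol)
  into a `protein_biomass` pool, which the summary reaction
  `protein_biomass_to_biomass` converts into biomass; biomass dilution
  drains that pool at rate μ.
* **The unmodeled-protein fraction** `f` scales the summary stoichiometry
  to `1/(1-f)` grams of modeled protein per gram of biomass credit: the
  dummy share of the proteome must be synthesized (at full ribosomal and
  amino-acid cost) without contributing catalysis. Default `f = 0`.

## 2. Coenzyme activity coupling

Prosthetic groups are consumed stoichiometrically by complex formation, so
their synthesis is forced by mass balance. Coenzymes are not: the
charged/uncharged cycle closes on itself. The activity coupling multiplies
the uncharged coenzyme's coefficient by `(1 + μ/k_activity)` in every
reaction where it is a reactant, forcing a fraction `μ/k_activity` of each
use to be replaced by fresh synthesis — a deliberately rough first-order
stand-in for the true kinetics, chosen so that computed coenzyme demands
are *relatively* comparable across conditions rather than quantitatively
exact. The companion coupling row equates the coenzyme's external supply
(biosynthesis, or uptake in an auxotroph) with `Σ (μ/k_activity)·usage`.
The row keeps the native stoichiometric entries of all non-cycle
producers, which is what makes it remain valid when a knockout replaces
biosynthesis with uptake; for a prototroph it reduces exactly to the
formation/usage balance. The multiplier applies multiplicatively to
non-unit coefficients (a reaction cycling three carrier units pays three
times the synthesis tax) and to the forward-consuming direction only;
reversible charging reactions must be split first. With the coupling in
place the static biomass-constituent demand is set to zero — coenzyme
synthesis is driven by activity, not by a fixed recipe.

Because `μ/k_activity ≈ 1e-4` at realistic growth rates, the coupling is
perturbative by design: it barely moves the growth optimum (the package
verifies convergence to the uncoupled optimum as `k_activity → ∞`) while
making coenzyme synthesis demands strictly positive wherever the coenzyme
works. One practical consequence: *knocking out* a coenzyme's biosynthesis
suppresses growth to a small residual rather than exactly zero, because at
low μ the forced-synthesis flux falls below any double-precision
feasibility tolerance. `make_auxotroph()` therefore validates auxotrophy
against a threshold (`min_growth = 0.05 /h`) sitting above that resolution
floor and far below prototrophic growth.

## 3. Parameters

| parameter | default | units | role |
|---|---|---|---|
| `kappa_tau` | 4.5 | 1/h | slope of the RNA-to-protein growth relation in all expression couplings |
| `r0` | 0.087 | — | its intercept; sets the μ→0 machinery floor |
| `c_ribo` | 10000 | aa·ribosome⁻¹·h-scale | ribosome capacity scale; with `kappa_tau` it sets the ribosomal proteome fraction |
| `c_mRNA` | 1000 | nt·mRNA⁻¹-scale | mRNA economy scale |
| `k_eff_default` | 65·3600 | 1/h | turnover of expression machinery and transport (65 1/s) |
| `k_eff_overrides` | per reaction | 1/h | metabolic turnovers; the toy's high-turnover oxidative step uses 1500 1/s |
| `k_deg_default` | 8 | 1/h | mRNA degradation rate (≈5 min half-life) |
| `k_activity_default` | 1e4 | 1/h | coenzyme pseudo-kinetic rate |
| `unmodeled_protein_fraction` | 0 | — | dummy proteome share |

Rates quoted per second are converted once at load time (`per_second()`);
everything internal is 1/h. `kappa_tau` and `r0` are treated as constants
even though the RNA-to-protein ratio is really a nonlinear function of
growth rate — that is the form the constraint block takes, and the
parameters are exposed for any alternative calibration.

## 4. The LP backend

ME matrices are notoriously ill-scaled: metabolic fluxes sit at
mmol/gDW/h while machinery formation fluxes sit five orders of magnitude
lower, and the reference implementations resort to quad-precision solvers.
This package stays in double precision (tolerance defaults are chosen
accordingly: bisection `tol = 1e-6`, LP feasibility `1e-7`) and gets its
robustness from structure instead:

1. **Column equilibration.** Two passes of geometric-mean scaling put all
   matrix entries near unit magnitude.
2. **Null-space reduction.** The equality block (stoichiometric rows plus
   fixed bounds) is eliminated analytically by a pivoted QR: an
   independent row subset, a least-norm particular solution `x0` (by
   triangular solve on the QR factors — never normal equations), a
   consistency check on the dropped rows, and an orthonormal null-space
   basis `N`. The deliberately redundant coupling rows (each coenzyme row
   is an exact combination of the inflated mass balances) disappear here;
   the rank tolerance is tight (1e-10) so that genuinely distinct but
   nearly parallel rows are never dropped — every returned point is
   re-verified against the *full* original system.
3. **Reduced QP.** What remains is `min ‖x0 + N z‖²` under bound
   constraints in a space of dimension ≈ (reactions − rank), typically
   ~10. Solved by the dual active-set method (`quadprog`), with bound
   rows unit-normalized. The minimizer is the unique minimum-norm flux
   vector, which makes reported fluxes deterministic among alternate LP
   optima (chosen over an L1 "parsimonious" rule, which itself needs an
   LP solver; both are equally arbitrary biologically, and the L2 point is
   unique).
4. **Degeneracy escape.** Active-set methods can declare a feasible,
   highly degenerate system inconsistent. The solver retries with every
   bound relaxed by a ladder of tiny slacks *expressed in original units*
   (1e-12 … 1e-9, deterministically jittered to break ties), and accepts a
   point only if its true bound violation and equality residual pass the
   feasibility tolerance in original units. Verdicts are never taken from
   the solver's exit status alone.

`feasible_at_mu(model, 0)` deserves a note: the mRNA degradation
coefficient carries `1/μ`, so the matrix cannot be evaluated at zero, yet
the model is always feasible there. The assembler therefore rescales any
row containing an active `1/μ` term by μ — the exact limiting constraint,
which forces the coupled translation flux to zero — only for the μ = 0
feasibility check. `evaluate_at_mu()` keeps the honest singularity error.

Growth maximization is bisection on feasibility over `[mu_lo, mu_hi]`
(defaults 0 and 4 /h), which is exact because feasibility is monotone in μ
for these models — every coupling only tightens as μ grows (property-tested
on all shipped fixtures). The returned `mu_opt` is the last feasible point;
the bracket and solve count are reported. A feasibility boundary detected
through a 1e-7 tolerance carries that much fuzz, which is why tolerances
below ~1e-7 buy no additional accuracy in double precision.

## 5. Demand accounting and normalizations

Amino-acid demand is the translation-flux-weighted composition sum;
prosthetic demand the formation-flux-weighted prosthetic stoichiometry;
coenzyme demand the flux of one designated reaction in the coenzyme's
single direct biosynthetic pathway. Demands below `1e-8` mmol/gDW/h are
clamped to zero before normalization: that threshold sits above the
double-precision backend's flux noise floor (~1e-9) and three decades
below any genuine demand in the shipped networks.

Two normalizations are provided. `per_growth` (divide by μ) is the
convention for comparing against a static biomass objective function.
`per_protein_biomass` (divide by the summary-reaction flux, g
protein/gDW/h) is the convention for cross-condition composition analysis,
since amino-acid and prosthetic demands track total protein content.
Neither is ideal for coenzymes — their usage is not a function of protein
abundance — but no third normalization is invented; both are reported and
the caveat stands.

## 6. What the toy generator emulates — and what it does not

`generate_toy_me_model()` emits a complete ME network whose *structure*
mirrors the phenomena the analysis stack is built to expose:

* a fermentative route (NAD-cycled, net 0.8 precursor per substrate after
  redox balancing) versus a respiratory route (quinone-cycled,
  heme-dependent, O2-consuming, net 2.0) — so aerobic growth is faster,
  respiratory cofactors are conditionally essential, and per-protein NAD
  demand is higher anaerobically;
* nutrient exchanges in all four element classes with alternatives,
  non-catabolizable decoys, and a cofactor-heavy carbon source cycling
  three NAD per substrate (a planted composition outlier);
* per-gene transcription-unit/mRNA/peptide/complex chains with ribosome
  and RNA polymerase expressed through their own chains (the
  self-replicating-machinery recursion is real, with a finite ribosomal
  growth ceiling);
* a folate pair whose dependent amino acid has a cheap folate-hungry route
  and an expensive folate-light backup, producing the route-switch phase
  structure under limitation;
* a structural protein that carries the bulk of the proteome, so the
  biomass demand `v_summary = μ` is satisfiable while catalytic masses
  stay at their coupled minima.

Nitrogen is supplied at three times the other base uptakes so that carbon
limits growth on the base media; with nitrogen binding, the solver may
satisfy the optimum with any redox-feasible carbon mix and the
respiratory/fermentative contrast blurs. Peptide lengths (250–450 aa;
ribosome 2000; RNA polymerase 1000), amino-acid compositions (every
peptide contains every amino acid) and metabolic turnovers (log-uniform
10–60 1/s) are drawn from the single seed, which fully determines the
model down to its serialized bytes.

What the toy does *not* emulate: mass/charge balance (degradation and some
summaries are deliberately lossy), realistic pathway lengths and
promiscuity, metal cofactors, regulation, and the sheer redundancy of a
genome-scale reconstruction. Passing tests therefore certify the
*machinery* — constraint assembly, optimization, accounting, statistics —
and the qualitative condition-dependence designed into the toy, not
quantitative agreement with any organism.

## 7. Statistical stages

The condition × component demand table flows through:

* **PCA** (`prcomp`), z-scored by default because demands span orders of
  magnitude; covariance PCA via `standardize = FALSE`. PC1's sign is fixed
  so aerobic conditions score negative (signs are otherwise arbitrary),
  and the PC2–growth rank correlation is reported as Spearman's ρ
  (Pearson alongside).
* **Outlier calling**: per-component z-scores, `|z| > 3`, with the log2
  fold change against the component mean; zero-variance components are
  skipped.
* **Ward clustering** (`hclust`, `ward.D2`) after removing outlier
  conditions and dividing each component by its maximum (absorbing
  scale). The cluster count maximizes the gap statistic
  (`cluster::clusGap`, uniform reference over the data's bounding box,
  B = 50, seeded) under the original one-standard-error rule
  (`maxSE`, "Tibs2001SEmax") — the raw argmax of the gap curve
  over-segments because the curve keeps creeping upward.
* **Cluster characterization**: two-sided Wilcoxon rank-sum
  (`wilcox.test`, exact where applicable) of in-cluster versus
  out-of-cluster demands, retaining components at `p < 1e-5` and
  `|log2fc| > 0.15`. No multiple-testing correction by default — the fixed
  stringent threshold takes its place — but `p_adjust_method` exists.
  Singleton clusters are skipped (the rank test is degenerate).
* **Conditional essentiality**: a cofactor is required wherever its
  clamped demand is positive.

## 8. Limitation analysis choices

`limitation_profile()` caps uptake at fractions 1.00…0.05 (step 0.05, 20
points) of the uptake observed at unconstrained maximum growth; the cap is
an upper bound on uptake magnitude, so the model may always take less.
`protein_allocation()` computes each complex's steady-state mass as
formation flux × deposited grams / μ and splits multi-subsystem complexes
across their catalyzed reactions' subsystems in proportion to usage flux
(machinery and structural protein fall back to their own subsystem
annotation). `flux_response_summary()` reports growth-normalized,
series-max-normalized fluxes, ranks by standard deviation, merges series
identical within 1e-6 ("perfect correlation" — exact Pearson r = 1 is
numerically fragile) and drops series whose normalized flux never exceeds
1e-6, which would otherwise be solver noise amplified to full scale.

## 9. Problem sizes used in the shipped analyses

The default toy network has ~110 reactions and ~100 active constraint
rows; a growth maximization is ~24 feasibility solves; the full scan is 22
conditions; limitation profiles are 20 points × 3 auxotrophs; statistical
recovery runs use 24–27 synthetic conditions with 20 seeds for the
clustering study. These sizes were chosen so the entire pipeline — and its
brute-force oracles, like the 1 mh⁻¹-step grid scan behind the bisection
check — completes in about a minute each, which is what makes
property-based testing of every stage practical.

## 10. Known limitations

* Double precision bounds the achievable optimality gap at ~1e-7 in μ;
  reproducing reference pipelines run at 1e-13 requires a quad-precision
  LP solver, which is out of scope here.
* Coupling equalities assume machinery is never produced in excess;
  regulatory overcapacity is not representable.
* The coenzyme coupling is a single global first-order rate; per-reaction
  overrides exist (`k_activity_overrides`) but no kinetics are fitted.
* The minimum-norm flux selection, while deterministic, is one point of
  the optimal face; flux-level conclusions at exact alternate optima
  should be drawn from quantities the constraints pin down (growth,
  coupled demands), not from individual free fluxes.
* Auxotrophy of coenzymes is resolved only above the coupling-resolution
  floor (§2).
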