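---
title: "Constraint-based simulation and fold-change omics integration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based simulation and fold-change omics integration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxkit)
```

This vignette is the package's account of its methods: the models and
statistics it implements, the numerical machinery underneath, the
parameters that matter, and the design choices made where the design was
genuinely open. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The feasible flux space and its modifiers

All simulation operates on

$$\Omega_k = \{\, v \in \mathbb{R}^J : \textstyle\sum_j S_{ij} v_{j} = 0
\;\forall i,\; l_{jk} \le v_{jk} \le u_{jk} \,\}$$

for condition $k$, with fluxes in mmol/gCDW/h. Three kinds of
modification produce a condition-specific $\Omega_k$:

* **Measured fluxes.** A measured exchange (or growth) rate with mean
  $\mu$ and standard deviation $\sigma$ becomes the interval
  $[\mu-\sigma,\, \mu+\sigma]$ (`buildMeasuredBounds()`). For triplicate,
  approximately normal measurements this interval carries better than
  90% confidence; the standard deviations are used *only* here, never as
  regression weights downstream.
* **Gene deletions.** `deleteGenes()` closes ($l=u=0$) every reaction
  whose GPR boolean tree evaluates false with deleted genes false and all
  others true. An empty GPR means "no gene association" and evaluates
  true: such reactions can never be disabled by gene removal. This
  convention matters for pseudo-reactions (biomass, ATP hydrolysis,
  transport without annotated genes).
* **Condition configuration.** `applyCondition()` activates exactly one
  of the three biomass variants (cellobiose, cellulose, no-cellulosome)
  and closes the others; sets the NGAM value as the lower bound of the
  ATP-hydrolysis pseudo-reaction; installs GAM into the active biomass
  reaction; closes all exchange uptakes except the medium's allowed set
  and all secretions except the allowed set; and, for growth on
  cellulose, opens the glucose-equivalent cellodextrin pseudo-reactions
  (detected structurally as `n glceq_e -> celln_e`).

**GAM installation mechanics.** GAM is a stoichiometric coefficient, not
a bound: the ATP-hydrolysis stoichiometry (taken from the model's NGAM
pseudo-reaction, typically `atp + h2o -> adp + pi + h`) is rescaled
inside the biomass column so that forming one gram of biomass hydrolyses
exactly `gam` mmol of ATP, replacing whatever coefficient the model
shipped with. Doing it through the hydrolysis stoichiometry keeps the
water/proton bookkeeping consistent in models that track them.

## Simulation methods

**FBA** (`fba()`) maximises $c \cdot v$ over $\Omega_k$. Only the
objective *value* is part of the contract: at degenerate optima the flux
vector depends on pivoting order, so downstream analyses that need a
vector use pFBA. Infeasibility and unboundedness are reported as errors,
the latter naming a reaction in an unbounded direction.

**Quadratic pFBA** (`pfba()`) returns the unique minimiser of
$\sum_j v_j^2$ over $\Omega_k$ — the entire program, with no
growth-maximisation pre-step. The measured bounds are expected to pin
the exchange fluxes; making the quadratic program the whole formulation
keeps the method a pure projection of the data onto the stoichiometry.
Because the objective is strictly convex the solution is unique, and the
solver is deterministic, so repeated solves agree to numerical
precision. A side effect worth knowing: minimum-norm solutions carry no
internal cycles (adding any null-space cycle vector strictly increases
the norm), so pFBA fluxes are loop-free without integer constraints.

**FVA** (`fva()`) minimises and maximises each flux over $\Omega_k$.
With `loopless = TRUE` the classic mixed-integer exclusion of
thermodynamically infeasible cycles is added: each *internal* reaction
$j$ (not an exchange, biomass variant, or the ATP-hydrolysis
pseudo-reaction) gets a binary direction variable $a_j$ and a potential
$G_j$ with

$$v_j \le 1000\,a_j,\qquad v_j \ge -1000\,(1-a_j),$$
$$a_j = 1 \Rightarrow G_j \in [-1000,-1],\qquad
  a_j = 0 \Rightarrow G_j \in [1,1000],$$

and $N^\top G = 0$ for $N$ a basis of the null space of the internal
stoichiometric matrix. Any internal cycle would need all its potentials
to drop in the direction of flux while summing to zero around the cycle
— impossible — so loop flux is excluded while every acyclic distribution
survives. The big-M of 1000 matches the global flux bound. The
**FVA center** $(v_{\min}+v_{\max})/2$ is the scalar summary used for
fold changes; it indicates an upward or downward shift of the feasible
range but is a heuristic — it need not itself be a feasible flux, and it
cannot distinguish all range permutations.

**Blocked reactions** (`findBlockedReactions()`) are computed with every
exchange opened to $[-1000, 1000]$ — the most permissive boundary, hence
the smallest blocked set — and flagged when both FVA extremes are zero
within $10^{-6}$. The set is invariant to the exchange bound magnitude
(exposed as the `mag` argument precisely so the tests can verify that).

## Numerical machinery

The package solves its linear programs with a dense bounded-variable
two-phase primal simplex (`lpSolve2()`), written for the model sizes
this package targets in testing (tens of reactions): Bland's
smallest-index rule for entering and leaving variables guarantees
termination on the heavily degenerate bases that measured-bound
conditions produce, and a fresh basis solve per iteration favours
numerical transparency over speed. Reduced-cost and pivot tolerances are
$10^{-9}$; reported constraint checks use $10^{-6}$.

The pFBA quadratic program is solved by a primal active-set method
specialised to the minimum-norm objective (`qpMinNorm`): with any
working set of active bounds, "minimise $\|v\|^2$ subject to $Sv=0$ and
fixed actives" is solved *exactly* by a pseudoinverse, so the active-set
loop needs no general QP factorisation, handles rank-deficient
stoichiometries natively, and is untroubled by the many pinned
($l = u$) variables that measured conditions create. Its solutions are
cross-checked in the test suite against an independent QP implementation
(quadprog) on random instances.

Loopless FVA solves its mixed-integer programs by depth-first
branch-and-bound on the binary direction variables, with the simplex as
relaxation solver, branching on the most fractional binary and exploring
the relaxation-rounded branch first. On the fixture scale the
relaxations are nearly integral and the trees are shallow.

Determinism throughout: no solver uses randomisation, so identical
inputs give identical outputs across runs and platforms at these
problem sizes.

## Maintenance-parameter training

Each measured condition contributes the point (measured growth rate,
maximum ATP-hydrolysis flux), where the maximum is computed with the
measured exchange bounds applied, growth pinned to its measured
interval, the biomass GAM coefficient zeroed and the NGAM bound
released (`maxATPYield()`). Zeroing GAM during training is what lets the
regression slope absorb the growth-proportional ATP demand; the
alternative (leaving the shipped coefficient in place) is exposed as
`zeroGAM = FALSE`. `fitMaintenance()` then runs plain unweighted OLS of
ATP flux (y) on growth rate (x): slope = GAM, intercept = NGAM, with
$r^2$ reported. Growth is deliberately the regressor — the slope must
have units of mmol ATP per gCDW — and the orientation is asserted by the
exact-recovery tests against planted parameters.

Outliers are **caller-designated** flags, not auto-detected: no
principled threshold exists at $n \approx 8$ points per condition class,
so exclusion is an explicit analyst decision recorded in the fit object.
Duplicating a point re-weights it (plain OLS semantics) — documented and
tested rather than hidden.

`validateGrowth()` closes the loop: per condition it installs the fitted
class parameters (batch, chemostat-cellobiose, chemostat-cellulose),
bounds the measured exchanges, leaves growth free, maximises it, and
reports the paired table with the squared Pearson correlation.
Infeasible conditions become failed rows, not fatal errors, because one
inconsistent measurement should not abort a validation campaign.

## The fold-change integration protocol

Measured side: gene-level log2 fold changes map to reactions as the
plain mean over the reaction's GPR genes with nonzero measured FC
(`mapGeneFoldChanges()`), deliberately ignoring AND/OR structure — the
protocol compares *signs*, and inventing min/max enzyme-complex
semantics would add assumptions the sign comparison does not need.
Unmeasured genes and genes measured at exactly zero both drop out of the
mean but are distinguished in the report (`n_unmeasured` vs `n_zero`).
A significance column in gene FC input is accepted but unused by
default: the consistency definition only requires FC ≠ 0.

Simulated side: pFBA fluxes and FVA centers are normalised by the
magnitude of the designated carbon-source uptake of their own condition
and method (the pFBA uptake flux for pFBA FCs, the uptake interval
center for FVA FCs), floored, and differenced in log2 space. The
flooring function with $\epsilon = 10^{-4}$ keeps vanishing normalised
fluxes from exploding the log; exact zero maps to $+\epsilon$ — the
continuous extension of the positive branch — so "zero in both
conditions" cleanly yields FC = 0, and every floored zero is flagged in
the report. Negative normalised fluxes are handled on the magnitude
scale ($\log_2|a| - \log_2|b|$); a sign flip between conditions is
flagged `sign_reversal`, and flagged simulated FCs are excluded both as
sign witnesses for consistency and from the correlations, because a
reversal is a directionality change, not a magnitude change, and
coercing it onto a log-ratio axis would be meaningless. In the package's
own use the normalised fluxes of interest are non-negative, so the
branch exists for robustness rather than routine use.

A reaction is **consistent** when its measured FC is strictly nonzero
and shares a sign with at least one simulated FC; Pearson correlations
(pFBA-based and FVA-based) are computed over the consistent set only.
`runFoldChangeProtocol()` wires the pipeline end to end and emits the
full record table plus a two-column reaction/FC table for map viewers.

## Phenotype screening

`mutantGrowthPercent()` compares maximum growth of wild type and mutant
under the identical condition; below 20% of wild type (the conventional
lethality threshold, exposed as a parameter) the mutant is called
lethal. `rescueScreen()` opens each supplement's uptake — default
magnitude 1000 mmol/gCDW/h, i.e. effectively unconstrained, since a
rescue experiment adds the compound in excess — and reports growth
relative to the *unsupplemented* wild type, which is why rescue
percentages above 100% are possible and meaningful.
`reactionDeletionScan()` closes every not-yet-disabled reaction on top
of a base mutant and returns those pushing growth below the threshold,
with per-reaction infeasibility recorded as zero growth. Uptake is left
free within the medium caps rather than pinned to measured rates: a
lethality call should reflect what the network *could* do on that
medium, not one measured operating point.

## Synthetic fixtures: what they emulate and what they do not

`toyModel(includeRedox = TRUE)` encodes, at minimal scale, the
redox topology that makes these organisms interesting: glycolysis
produces NADH and ATP; pyruvate-ferredoxin oxidoreductase produces
reduced ferredoxin; an ethanol branch consumes NADH; an acetate branch
yields ATP; a bifurcating hydrogenase (NADH + ferredoxin), a
bidirectional NADPH hydrogenase and a ferredoxin-only hydrogenase
dispose of electrons as H2; a ferredoxin:NADP oxidoreductase supplies
NADPH; and a sulfate-reduction-style pathway behind a closed uptake
provides an external electron acceptor. The two hydrogenases share a
maturase gene in their GPRs, so deleting that single gene silences both
— the GPR subtlety that makes *hydG*-style genotypes non-trivial.
Deleting the maturase plus the ferredoxin hydrogenase is lethal by redox
imbalance and rescued by sulfate, and these phenotypes are hand-derivable
from the stoichiometry (the wild-type optimum of 20/3 and mutant optimum
of 16/3 are closed-form LP solutions, frozen in the tests).

`maintenanceDataset()` plants known GAM/NGAM by choosing, for each
requested growth rate, the substrate uptake whose ATP yield equals
`gam*mu + ngam` plus optional Gaussian noise; at zero noise the training
pipeline must recover the parameters to machine precision, which is the
strongest possible correctness check on the whole chain
(condition → bounds → LP → regression). `omicsDataset()` plants gene
fold changes equal to the simulated pFBA fold changes on reactions with
private single-gene GPRs, so at zero noise the protocol must return
exactly the planted consistent set with a pFBA Pearson correlation of 1.
The redox toy has no internal cycles (hydrogen is only produced
internally, never consumed), so plain and loopless FVA coincide on it
and the generator's protocol configuration uses the plain variant; the
cycle fixture (`includeCycle = TRUE`) exists precisely to exercise the
loopless machinery, which the simulation tests do.

What the fixtures do **not** emulate: quantitative realism of any real
organism's fluxes, proteome-scale gene counts, measurement error
structure beyond i.i.d. Gaussian noise, or thermodynamic/kinetic
constraints. Passing the planted-truth tests therefore demonstrates that
the algorithms are implemented correctly, not that the biological
conclusions drawn from any particular dataset are right.

Problem sizes used by the tests and the acceptance script — toy models
of 12–25 reactions, 8 training points per maintenance fit, 50 seeded
noisy replicates, 1000 random records for the sign-table oracle — were
chosen so the full suite exercises every code path, including the
mixed-integer one, in well under a minute of solver time.

## Degenerate inputs and edge policies

* Reactions with missing formulas or charges are *unscorable* in balance
  checking, never failures: deposited models legitimately carry generic
  biomass species. Exchange reactions are skipped by convention.
* Proton/water auto-correction (`balanceWithWaterProtons()`) solves the
  3×2 linear system exactly (protons cancel the charge delta, water the
  oxygen delta, hydrogen must then close); any residual outside H/O/charge
  is an explicit "uncorrectable" error carrying the deltas.
* A fitted negative NGAM is physically suspect and warns but is still
  returned — masking it would hide a data problem.
* A single validation condition yields an absent $r^2$, not a number.
* FBA on a model whose wild type cannot grow refuses to compute percent
  of wild type (the reference is undefined) rather than returning 0/0.

## Known limitations

* Dense linear algebra bounds practical model size to a few hundred
  reactions; the design favours transparency and determinism at fixture
  scale over large-model performance.
* The FVA center is a coarse interval summary; correlations based on it
  are expected to be weaker than pFBA-based ones, and the package makes
  no attempt to quantify range overlap.
* No thermodynamic (ΔG-based) or kinetic constraints are integrated;
  loop exclusion is purely topological.
* Escher-style visualisation is out of scope: the package emits the
  two-column reaction/FC table such viewers consume, nothing more.
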