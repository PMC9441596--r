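---
title: "Amino-acid-resolved enzyme-constrained flux balance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amino-acid-resolved enzyme-constrained flux balance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Standard flux balance analysis (FBA) predicts steady-state fluxes $v_j$
(mmol gDW$^{-1}$ h$^{-1}$) of a stoichiometric network by solving

$$\max \sum_j c_j v_j \quad \text{s.t.} \quad \sum_j s_{ij} v_j = 0
\;\;\forall i, \qquad v_j^{\min} \le v_j \le v_j^{\max},$$

with the biomass reaction as objective. Enzyme-constrained models of the
GECKO family additionally limit every catalyzed flux by its enzyme's
capacity, $v_j \le k_{cat,jk}\,[E_k]$, by inserting enzyme
pseudo-metabolites $E_k$ (consumed at $1/k_{cat}$ by the reactions they
catalyze), one draw reaction per enzyme spending protein-pool mass at
$MW_k/1000$ g mmol$^{-1}$, and a pool exchange whose upper bound
$\sigma f P_{total}$ (g gDW$^{-1}$) caps the total metabolic enzyme mass:

$$\sum_k MW_k\, e_k \le \sigma f P_{total},$$

where $e_k$ is the enzyme source flux (mmol gDW$^{-1}$), $P_{total}$ the
total cellular protein fraction (0.5 g gDW$^{-1}$ by default), $f$ the
modeled proteome fraction and $\sigma$ the average in-vivo saturation.

This package resolves that aggregate budget into the twenty proteinogenic
amino acids. Each draw reaction is replaced by a source reaction

$$\sum_{l=1}^{20} \xi_{kl}\, A_l \rightarrow e_k\, E_k,$$

where $\xi$ is the $K \times 20$ composition matrix built from the
protein sequences ($\xi_{kl}$ = gram of amino acid $l$ per mmol of protein
$k$), and twenty irreversible drain reactions $E_{pool} \rightarrow A_l$
route pool mass 1:1 into amino-acid pseudo-metabolites. Summing the
amino-acid mass balances $\sum_k \xi_{kl} e_k = a_l$ over $l$ recovers the
pool budget exactly, because each row of $\xi$ sums to $MW_k/1000$. Two
consequences are used as permanent invariants:

* **growth equivalence** — the rewired model has exactly the parent
  model's optimum (the per-enzyme mass cost is unchanged), and
* **mass closure** — in every feasible solution
  $\sum_l a_l$ equals the pool exchange flux.

The drain fluxes $a_l$ (g gDW$^{-1}$) are the amino-acid mass
requirements of the expressed metabolic proteome; normalized they form
the model's amino-acid distribution.

## Composition-matrix conventions

* **Residue masses, not free amino acids.** $\xi$ and $MW_k$ use the
  polymerized (water-free) residue masses, computed from the residue
  molecular formulas with average atomic masses (C 12.011, H 1.008,
  N 14.007, O 15.999, S 32.06) and rounded once to three decimals. This
  makes the amino-acid-resolved pool inequality algebraically identical
  to the aggregate one; using free-chain masses instead would inflate
  every protein by up to one water (18.015 g mol$^{-1}$).
  `proteinMW(..., terminalWater = TRUE)` exposes the free-chain mass for
  reporting, but it must never enter the pool accounting.
* **Canonical ordering.** All 20-vectors and matrix columns are ordered
  alphabetically by one-letter code; the ordering is fixed package-wide.
* **Non-canonical residues** (B, J, X, Z, U, O) are rejected by default;
  a lenient mode drops them with a warning. Silent acceptance would
  corrupt the mass budget, so strictness is the default.
* **Subunit stoichiometry.** Rows of $\xi$ are per polypeptide. Where a
  draw reaction's MW coefficient disagrees with the row sum by more than
  0.5% (annotation drift, complex stoichiometry), the row sum wins with a
  warning, keeping the mass balances internally consistent. Copy-number
  scaling, when needed, is applied by supplying a rescaled FASTA or
  composition table.
* **Missing sequences** are an error by default; the lenient fallback
  assigns the mean relative composition of the present proteins scaled to
  the parent draw reaction's molecular weight, and says so.

## Optimization machinery

Every problem in the package is of the form $\min c^\top v$ subject to
$S v = 0$ and box bounds, solved by a dense bounded-variable two-phase
primal simplex with Bland's anti-cycling rule. The solver is
deterministic — repeated calls yield bit-identical solutions — which the
test suite exploits by comparing optima against exhaustive vertex
enumeration at $10^{-8}$ relative tolerance. Reduced-cost and pivot
tolerances are $10^{-9}$ and $10^{-11}$; problems here have tens of rows,
where a dense implementation is the simplest correct choice.

Secondary objectives are lexicographic: the parsimonious profile fixes
biomass at the optimum (relative tolerance $10^{-9}$) and minimizes the
total absolute flux by variable splitting; the chemostat solver first
minimizes the pool exchange flux at fixed growth, then breaks remaining
ties by the flux-sum minimization. Enzyme draws, drains and the pool
exchange are included in the flux sum by default (`includePseudo`
toggles this).

Drain variability ranges are computed at a 99% growth-optimality
threshold (inequality on biomass by default; an equality toggle exists
because alternative optima can persist at 100%). The "mean flux" used
for normalization is the interval midpoint $(\max + \min)/2$ — symmetric
and available without an extra solve; midpoints below $10^{-9}$
g gDW$^{-1}$ are numerically zero and yield an `NA` sentinel rather than
an infinite ratio. The same sentinel-and-exclude policy applies to all
relative deviations with zero denominators.

The uniform-composition control replaces every row of $\xi$ by
$MW_k/1000$ times one fixed distribution. Then every drain is a fixed
share of the pool flux, so all relative variabilities coincide; when the
pool is the only binding constraint, growth is proportional to pool flux
and the common value equals the optimality slack,
$0.01/0.995 \approx 1.005\%$ at the 99% threshold. The package's
acceptance script recomputes exactly this number. Note that the control
value reflects the slack only in enzyme-limited models; if a substrate
uptake bound co-binds, the common variability is larger than the slack
(the two-enzyme reference toy with uptake bound 10 gives about 3.4%).

## Species-distribution fitting

A species distribution $p$ (relative mass fractions) is enforced as
proportionality couplings $a_l = p_l T$ with a free auxiliary total $T$,
which keeps the problem linear; maximizing growth under these couplings
defines the reference growth state. Infeasibility — more precisely, a
zero maximal growth in maintenance-free toys — is a legitimate, reported
outcome when the distribution is unattainable (e.g. an amino acid absent
from every enzyme).

The minimally-different profile at a demanded growth rate minimizes
$\sum_l (a_l - p_l T)^2$ with $T = \sum_l a_l$, a convex quadratic over
the flux polytope. The Hessian is positive semidefinite and singular
(the objective touches only the drains and $T$), so the QP is solved
with a $10^{-12}$ diagonal ridge; the reported distance is recomputed
from the unridged objective at the solution, and the fit is validated
against a dense grid search on two-enzyme toys. The distance is measured
in mass units (g gDW$^{-1}$); it is zero exactly when the hard-constrained
model is feasible at that growth level, which the test suite
cross-validates over growth grids. Scan grids default to steps of 0.05
from 0.1 up to the ratio of unconstrained to reference growth.

## Nutrient sampling

Viability of a candidate source is judged by swapping it in for the
reference source of its elemental class (others untouched) and requiring
a maximal growth of at least $10^{-4}$ (configurable). Conditions draw
one source per class uniformly with replacement under one master seed —
the combinatorial space is far larger than any sample, so collisions are
immaterial. Per condition, all class-member exchanges are closed and the
selected sources opened to a large finite bound (1000 mmol gDW$^{-1}$
h$^{-1}$) rather than truly unbounded, keeping all LPs bounded. Closing
only annotated class members (not, say, CO$_2$ outgassing) makes the
exchange classification table part of the model input.

## The synthetic generator

Toy models are parallel-route networks: one substrate, $K$ enzymatic
routes $S \to y_k P$ with turnover $k_{cat,k}$, a biomass sink, and the
full GECKO bookkeeping (draw reactions at $MW_k/1000$, capped pool
exchange). Biomass flux is used directly as the growth rate — no
maintenance terms — so optima have closed forms and exhaustive vertex
enumeration over the route fluxes (at most two non-trivial constraints:
total uptake and pool mass) provides an independent oracle. Optional
nitrogen/phosphorus/sulphur pseudo-nutrients are consumed by biomass at
stoichiometry 0.01 with ample bounds: they never move the optimum but
give the sampling machinery real elemental classes, including
deliberately unusable (dead-end) sources.

Random models draw $k_{cat}$ log-uniformly from $10$ to $10^4$ h$^{-1}$
(a realistic span for metabolic enzymes), sequence lengths uniformly
from 50 to 500 with uniform residue usage (which exercises every drain
with high probability at $K \ge 3$), yields uniformly from 0.2 to 2, and
pool bounds log-uniformly from $10^{-3}$ to $10^{-1}$ g gDW$^{-1}$ so
that both uptake-limited and enzyme-limited regimes occur. The default
test run checks growth equivalence on 1000 such models and
oracle agreement on a subset; these sizes keep the whole suite under
half a minute while covering 1 to 6 routes.

What the toys do **not** emulate: genome-scale topology (thousands of
reactions, compartments, cofactor coupling), realistic $k_{cat}$
distributions, isoenzyme/complex structure, and maintenance energies.
Passing tests therefore demonstrate the correctness of the construction,
the optimizers and the bookkeeping — not predictive accuracy on real
organisms, which requires an externally supplied enzyme-constrained
genome-scale model and proteome FASTA via `readEcModelSBML()` /
`readProteome()`.

## Chemostat sweeps

Growth-rate-dependent protein availability enters as a table or callable
$P_{total}(\mu)$ (monotone piecewise-linear interpolation with flat
extrapolation); the growth-rate-dependent pool bound is
$\sigma f\,P_{total}(\mu)$. The regression producing such a curve for a
real organism is configuration input, not something the package re-fits.
The critical growth rate is the first grid point whose pool slack falls
below $10^{-8}$ g gDW$^{-1}$. Condition files (YAML bound overrides and
blocked reactions) express medium changes such as anaerobic
re-parameterizations generically; nothing organism-specific is
hardcoded.

## Known limitations

* Dense linear algebra limits practical model size to a few hundred
  reactions; genome-scale models would need a sparse LP backend behind
  the same interfaces.
* The QP fit measures distance in mass units via the auxiliary-total
  linearization; a distance on normalized fractions is non-convex and
  deliberately avoided.
* Proportional profile couplings are the literal reading of
  "distribution as flux constraints"; per-drain equality bounds would be
  an alternative with different infeasibility behavior.
* The SBML layer covers the fbc-v2 subset these models need (verified
  against an external constraint-based toolchain), not the full
  specification.
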