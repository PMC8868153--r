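---
title: "Simulating organic pig-breeding programs: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating organic pig-breeding programs: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgpigsim)
```

`orgpigsim` simulates closed pig-breeding programs for organic production
over half-year reproductive cycles and compares two designs: a
self-contained organic nucleus (**OS**, organic sires) and an organic line
sired from a conventional nucleus (**CS**, conventional sires). This
vignette explains the model, the choices made where the design was open,
and what the simulation does and does not emulate.

## The genetic architecture

Ten dam-line traits are simulated jointly: growth to 30 kg and from 30 to
100 kg (GR30, GR100, g/day), lean meat percentage (LMP), leg/back strength
(ST, points), feed efficiency (FE, feed units per kg gain), live piglets at
day 5 (LP5), slaughter loss (SL, kg), sow longevity (LG, %), piglet
mortality (PM, %) and number of functional teats (NFT). The packaged
parameter file (`inst/extdata/trait_parameters.yaml`) carries, per trait,
the additive, environmental and phenotypic variances (which satisfy
$\sigma^2_a + \sigma^2_e = \sigma^2_p$ row by row), the genetic and
phenotypic correlation triangles, and the economic values of four breeding
goals: a conventional goal (CBG), the current organic goal (curOBG) and two
alternative organic goals from farmer preferences (altOBG, altOBG+; only
the last weights PM and NFT).

The genetic covariance matrix is assembled as
$G_{ij} = r_{g,ij}\sqrt{\sigma^2_{a,i}\sigma^2_{a,j}}$, the phenotypic one
analogously from $r_p$ and $\sigma^2_p$. Environmental correlations are
never tabulated in this parameter set, so the environmental covariance is
defined by difference on the covariance scale, $R = P - G$ — the only
derivation consistent with the variance identities. Because rounded
published correlations can yield indefinite matrices, `trait_panel()`
validates that $G$ and $R$ admit Cholesky factors and otherwise projects
them to the nearest correlation matrix (variances preserved), aborting if
any correlation would move by more than 0.05 — results that far from the
tabulated architecture would no longer describe it. For this parameter set
both matrices are positive definite as assembled (smallest eigenvalues
about 0.004 and 0.007) and no repair occurs.

PM and NFT are labelled maternal traits in the source parameter set, but
the evaluation model has direct additive effects only; both are simulated
as direct, female-recorded traits and no maternal-effect covariance is
modelled.

## Breeding goals as aggregate genotypes

A goal is an economic-value vector $v$ (EUR per trait unit); an animal's
aggregate genotype is $H = v'a$ with $a$ its breeding-value vector. The
genetic correlation between two goals is the standard selection-index
quantity

$$ r_{H_1 H_2} = \frac{v_1' G v_2}{\sqrt{(v_1' G v_1)(v_2' G v_2)}}, $$

which `goal_correlation()` computes. From the packaged panel the six
pairwise correlations are 0.83 (CBG–curOBG), 0.76, 0.72, 0.87
(curOBG–altOBG), 0.69 (curOBG–altOBG+) and 0.83 — selection on any one
goal drags the others along only partially. Traits with zero economic
value stay in the index (contributing nothing) and in the evaluation model
(contributing correlated information).

## Sampling true breeding values and phenotypes

Base-population animals get $a = L r$ with $LL' = G$ and $r$ standard
normal; offspring get the parent average plus a Mendelian-sampling
deviation,

$$ a_i = \tfrac12 (a_{sire} + a_{dam}) +
   \sqrt{\tfrac12\left(1 - \tfrac{F_{sire}+F_{dam}}{2}\right)}\; L r_i , $$

so the deviation *variance* is $\tfrac12(1-\bar F)G$, the standard result
for inbred parents. A widely used printed form of this recursion applies
the factor $\tfrac12(1-\bar F)$ to $Lr$ directly, which would square it on
the variance scale and shrink genetic variance unrealistically; the
package defaults to the square-root scale and keeps the linear form as the
config switch `mendelian_scale = "linear"` for sensitivity runs.
Phenotypes are $y = a + Cr$ with $CC' = R$.

Recording follows the biology: GR30, GR100, ST and FE are observed on
candidates of both sexes; LP5, LG, PM and NFT only on females (recorded
when the female first reaches candidate age, a proxy for first parity —
the design gives no timing); LMP and SL only on candidates culled without
ever being selected, recorded at culling and available to evaluations from
the *next* step (a record produced by culling cannot influence the
decision that culled the animal). Litters, permanent-environment effects
and non-normality of the count-like traits are not modelled; the variance
components are used as tabulated, Gaussian throughout.

## Pedigree and evaluation

Inbreeding coefficients use the Meuwissen–Luo scheme (compiled, extended
incrementally as litters are appended); the sparse inverse numerator
relationship matrix uses Henderson's rules with inbreeding-adjusted
Mendelian-sampling variances; unknown parents are draws from the
unrelated, non-inbred base (no genetic groups — the design starts from an
unrelated base population). In CS scenarios one joint pedigree spans both
lines, so the relationship matrix links conventional sires to organic
offspring; `line` is a label, not a genetic barrier.

Breeding values are estimated by multivariate pedigree BLUP,
$y = Xb + Za + e$ with fixed time-step effects per trait,
$\mathrm{var}(a) = G \otimes A$ and $\mathrm{var}(e) = R \otimes I$.
Missing traits are handled exactly: each animal's residual contribution
inverts the observed-trait submatrix of $R$ for its missing pattern. The
assembled system is solved directly by sparse Cholesky (CHOLMOD) with a
fill-reducing permutation; the relative residual is verified against the
`solver_tol` contract (default $10^{-8}$) and a failure is an error, so
the "iterative tolerance" semantics are preserved with a direct method
that is faster at these problem sizes. Evaluations are re-run from scratch
at every selection step on all records accumulated so far — the only
ordering under which evaluations can drive selection. For speed the
evaluation pedigree is pruned to animals that are phenotyped or have
offspring (a set closed under ancestry); pruned animals carry no
information and are never selection candidates. Animals without records
still receive EBVs through the relationship matrix, and a record-free
non-parent's EBV equals its parent average (a property the tests check).

## The two scheme designs

Time advances in half-year steps (one female reproductive cycle), 20 steps
(10 years) by default, with overlapping generations: males occupy four age
classes and are candidates at ages 1–2 years (steps 2–4), females five
classes and ages 1–2.5 years (steps 2–5). "Each generation" in the scheme
description is implemented as "each time step": only per-cycle mating
makes the per-generation birth counts consistent with 20 steps of
overlapping generations. Selected parents may be re-selected while still
inside their window. Founders fill every age class at the per-step
selection quota, all phenotyped, unrelated, F = 0. Each selected dam
produces one litter of exactly 10 piglets, 5 of each sex (the average
litter of 10 with a 1:1 ratio, taken literally; an odd litter size
alternates the extra piglet's sex); all piglets survive to adulthood — no
mortality process anywhere. Animals are culled when they age out of their
last class.

- **OS**: 10 sires and 100 dams truncation-selected per step among organic
  candidates on the configured organic-goal index; balanced random mating
  (each sire serves an equal share of the shuffled dams); both sexes of the
  1000 newborns phenotyped at the configured intensity (20% or 100%),
  drawn uniformly at random, litter-blind.
- **CS**: a conventional nucleus (10 sires, 100 dams, all phenotyped,
  selected on CBG) plus an organic line: its 10 sires are the best
  *unselected* conventional male candidates ranked by the organic goal
  (the two sire sets are disjoint by construction), its 50 dams the best
  organic female candidates on the same goal. Of the 500 organic newborns
  per step only females are phenotyped (at the intensity); organic males
  are slaughtered at candidate age and never enter selection. The organic
  dam line uses half the conventional dam quota, reflecting the smaller
  organic population.

Whether a conventional male may sire the organic line in consecutive steps
is not constrained (allowed while eligible); within one step the
not-selected rule excludes dual use.

## Endpoints

Genetic gain: per trait, the OLS slope over years 4–10 of the yearly
slaughter-cohort mean TBV (cohort = organic animals born that year; for CS,
males plus never-retained females), priced by the **curOBG** economic
values regardless of the goal that drove selection, so all scenarios are
compared on one scale; totals are the per-trait sum, and a per-trait
variant in additive-SD units divides the slope by $\sigma_a$.

Inbreeding: the OLS slope over years 4–10 of mean F among living organic
animals, times the realized generation interval $L$ (mean parent age at
offspring birth over the window), in percent per generation. The published
comparison table's last column (generational gain per 1% inbreeding) is
reproduced cell-for-cell by converting the annual gain to the half-year
cycle before dividing, i.e. $(\Delta G/2)/\Delta F$; `scenario_table()`
follows that arithmetic. `inbreeding_rate(relative = TRUE)` instead
divides the slope by $1-\bar F$, the relative rate that idealized formulas
like Wright's $\Delta F = 1/(8N_m) + 1/(8N_f)$ predict; with mean F around
0.08 by mid-run the absolute slope underreads the relative rate by roughly
8%, which matters when checking the mating engine against the closed form.

## What the tests run, and what that shows

The simulator is its own data generator, so the test suite validates each
layer against independent oracles (recursive-kinship pedigrees, dense
mixed-model solves, Monte-Carlo covariance recovery, Wright's closed form
under random selection with discrete one-step candidate windows) and then
checks the qualitative study findings on a scaled-down sweep: all 12
scenarios (2 schemes × 20%/100% phenotyping × 3 organic goals) at 10
replicates with 4 sires, 16 organic dams (8 in CS), litters of 4, and the
full 20-step horizon. At that scale the suite checks *orderings*: CS gains
insensitive to the organic goal and intensity, OS gains goal-dependent and
increasing with intensity, and OS at 20% phenotyping accumulating
inbreeding much more slowly than at 100%. The full-size design (10 sires,
100 dams, litters of 10, 100 replicates) reproduces the published
magnitudes and is run with `experiment_plan()` +
`run_experiment()`; it is a long-running computation and is intentionally
not part of the routine suite. Scaled populations have smaller effective
sizes, so their absolute inbreeding rates sit above the full-scale
figures; the orderings, not the magnitudes, are the scaled check.

Because phenotyping is the only observation process simulated, passing
tests say nothing about real-data complications the design explicitly sets
aside: genotype-by-environment interaction between organic and
conventional systems (genes are assumed to act identically in both),
recording costs, maternal effects, mortality, or non-Gaussian trait
distributions.

## Numerical choices

- Truncation selection breaks index ties by lower animal id —
  deterministic replays matter more than unbiasedness at ties, which are
  measure-zero with continuous indices.
- All randomness in a replicate flows through one seeded R stream;
  replicate $r$ of scenario $s$ derives an independent seed below
  $2^{31}$ from the base seed, so sweeps are reproducible and
  order-independent.
- Positive-definite repair bound 0.05 on the correlation scale (above).
- Solver: direct sparse Cholesky with a one-shot ridge retry
  ($10^{-8}\times$ mean diagonal) for confounded fixed levels; residual
  checked against `solver_tol`.
- Degenerate configurations ($R = 0$, $h^2 \to 0$) are supported for
  testing limits: a zero covariance yields a zero Cholesky factor, and the
  shrinkage limit drives all EBVs to zero.
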