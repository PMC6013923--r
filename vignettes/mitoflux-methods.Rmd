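---
title: "Modelling enterocyte mitochondrial fluxes under dietary lipid interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling enterocyte mitochondrial fluxes under dietary lipid interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the modelling approach

Enterocytes are the first cells to see dietary nutrients, and their
mitochondria must switch between carbohydrate oxidation and fatty-acid
β-oxidation as the diet changes. `mitoflux` asks a constraint-based
question about that switch: given only reaction stoichiometry, flux
bounds, and the steady-state assumption, how does the *space* of feasible
mitochondrial flux distributions shift when the diet changes in lipid
type (marine omega-3 fatty acids replacing plant fatty acids) or lipid
load (an increasing lipid/carbohydrate ratio)?

A constraint-based model needs no kinetic parameters. The network is a
stoichiometric matrix $S$ (metabolites × reactions); a steady-state flux
vector $v$ satisfies

$$ S\,v = 0, \qquad lb \le v \le ub , $$

and flux balance analysis (FBA) maximizes an objective $c^\top v$ — here
the cytosolic ATP demand — over that polytope by linear programming.
Because the optimal vertex is rarely unique, the package characterizes
the *distribution* of feasible fluxes by sampling the polytope with
artificial centering hit-and-run (ACHR) and then compares per-reaction
flux distributions across diets with one-way ANOVA and Tukey–Kramer post
hoc letters.

## The reduced enterocyte network

`build_fixture_model()` constructs a three-compartment network — luminal
`u`, cytosolic `c`, mitochondrial matrix `m` — of roughly 106 metabolites
and 108 reactions. The cytosolic compartment also stands for the
mitochondrial intermembrane space, because the outer membrane is freely
permeable to small metabolites; protons pumped by the respiratory chain
therefore land in `c`. The pathway content is:

* per-species luminal exchange and hydrolysis of **uniform
  triacylglycerides** (each dietary fatty acid enters as a TAG of three
  identical chains), free fatty-acid and glycerol absorption;
* ATP-dependent acyl-CoA activation and the **carnitine shuttle**
  (Cpt1a → Slc25a20 translocase → Cpt2);
* lumped matrix **β-oxidation** per species (`FAOXC140` … `FAOXC226`);
* lumped **glycolysis**, lactate fermentation, glycerol utilization via
  glycerol kinase and the cytosolic NAD-linked glycerol-3-phosphate
  dehydrogenase;
* **pyruvate dehydrogenase** (`PDHm`) and the full TCA cycle (`CSm`,
  `ACONTm`, `ICDHxm`, `AKGDm`, `SUCOASm`, `SUCD1m`, `FUMm`, `MDHm`);
* malate–aspartate and glycerol-phosphate **redox shuttles**;
* proton-pumping **electron transport** lumps, ATP synthase, and a
  cytosolic ATP demand reaction that serves as the FBA objective.

Every metabolite carries a fully protonated elemental formula and every
non-boundary reaction balances C, H, N, O, P and S exactly
(`check_elemental_balance()`); free protons `h_c`/`h_m` are explicit
species, so the proton-motive bookkeeping is closed rather than implied.

### β-oxidation stoichiometry

Complete oxidation of a C$_n$:$d$ acyl-CoA runs $n/2-1$ cycles and yields
$n/2$ acetyl-CoA, one NADH per cycle, and one FADH$_2$ per cycle *except*
where a pre-existing double bond lets the isomerase bypass the
FAD-dependent dehydrogenation: FADH$_2 = (n/2-1) - d$. This simplification
keeps PUFA handling linear in the familiar cofactors. The NADPH-consuming
2,4-dienoyl-CoA reductase steps required for even-numbered double bonds
are **not** modelled, and DHA is oxidized entirely in the matrix without
peroxisomal pre-shortening (all fatty acids are assumed importable into
mitochondria). Both are deliberate deviations from full biochemistry,
chosen so that each dietary species maps onto exactly one lumped
`FAOXCnnd` reaction. Each species' reaction is tagged to its *dietary*
fatty acid: long-chain intermediates are not routed through shorter
species' reactions, so `FAOXC160` reads as oxidation of dietary palmitate
only.

### Proton stoichiometry and closed-form ATP yields

The respiratory stoichiometries are configurable
(`fixture_config()`), with textbook defaults: 10 H⁺ pumped per NADH
(complexes I+III+IV, 4+4+2), 6 H⁺ per FADH$_2$-equivalent (III+IV), and
4 H⁺ consumed per cytosolic ATP (3 at the synthase + 1 for
phosphate/adenine-nucleotide transport), i.e. P/O ratios of 2.5 and 1.5.

Because chemical protons are explicit, the maximal yield is fixed by the
matrix proton balance. With NADH$_m$ and FADH$_2$ tallies and the
chemical H⁺$_m$ production $H^{chem}$ of the dehydrogenases and
H⁺-symporting carriers, the synthase flux $A$ satisfies
$h_{ATP} A = (h_{NADH}+1)\,\mathrm{NADH} + h_{FADH_2}\,\mathrm{FADH_2} -
H^{chem}$, and total ATP adds the substrate-level contributions. At the
default stoichiometries this gives **31.5 ATP per glucose** and
**330.5 ATP per mole palmitate-TAG** — close to, but not identical with,
the textbook 32/~106-per-chain numbers, because the explicit symport
costs and chemical protons do not cancel exactly. The test suite computes
these closed forms in an independent proton-ledger oracle and requires
the LP to match them; an early version of that ledger routed glycerol
through the mitochondrial G3P shuttle and the LP found the better (and
physiological) route through the reversible cytosolic NAD-linked G3P
dehydrogenase, which is the route the frozen oracle now uses.

Two structural facts about the reduced network are worth knowing. The
phosphate exchange can never carry net flux (phosphorus has no net sink),
and the free-proton exchange is likewise forced to zero because the
proton books close internally; `check_model_integrity()` reports both as
blocked, alongside the deliberately closed biosynthetic drain
`DM_accoa_m` that stands in for the phospholipid/heme branches of the
full curated model. CO₂ transport is secretion-only, since the
network only ever produces CO₂.

## From a printed diet table to uptake bounds

`builtin_diets()` transcribes the printed composition table for seven
diets: three isocaloric high-fat diets differing in fish-oil fraction
(FISH0/15/44) and four diets of increasing lipid/carbohydrate ratio
(FAT10/20/30/45). For each fatty-acid species $f$ with profile $p_f$
(g per 100 g lipid),

$$ \text{bound}_f \;=\; a \cdot
   \frac{I \cdot \ell \cdot p_f / 100}{M_{TAG,f}} \cdot
   \frac{1000}{m_{dry} \cdot 24}
   \quad \text{mmol g}^{-1}\text{h}^{-1}, $$

with $I$ the food intake (g/day), $\ell$ the lipid mass fraction,
$M_{TAG,f} = 3M_f + M_{glycerol} - 3M_{water}$, $a$ the absorption
fraction and $m_{dry}$ the intestinal dry mass; glucose converts
analogously with 180.16 g/mol. The bounds are uptake **ceilings**
(applied as negative lower bounds on the `EX_` reactions), not forced
uptakes — they are maximal potential intake rates.

The intake and tissue parameters are not printed in the composition
table, so the package ships explicit defaults chosen once as realistic
murine values: 2.5 g/day for the energy-dense fish-oil diets, 4.0 g/day
for the lipid/carbohydrate series, 0.25 g small-intestinal dry mass,
complete absorption, 24 h/day. They are package assumptions, configurable
through `physiology_params()`; publication-grade runs should supply
measured values. For the fish-oil diets this yields nine constrained
exchanges (glucose + 8 fatty-acid TAGs); the FAT diets lack the two
marine species, so seven of the nine are constrained.

## Sampling the steady-state polytope

`achr_sample()` implements ACHR: warm-up points are stored as columns of
a matrix $W$ with running center $s$; each iteration draws a random
column $y$, moves along $u = (y-s)/\lVert y-s\rVert$ by a uniform draw on
the feasible chord, substitutes the new point into $W$ at a random column
and updates $s$ incrementally; every `steps_per_point`-th iterate is
recorded. Defaults follow the reference study protocol: 2000 recorded points
with 500 iterations between points. The pipeline's reduced scale
(500 points, 100 steps) keeps a full seven-diet run in the minutes range
and is what the shipped tests and the acceptance script use; the full
protocol sits behind `study_config(full_scale = TRUE)`.

Design choices that the algorithm description leaves open:

* **Exact equalities.** Sampling runs in an orthonormal basis of the
  null space of $S$ (restricted to non-fixed reactions), so $S v = 0$
  holds to machine precision along the whole chain instead of drifting.
* **Objective handling.** The study's simulations used maximal ATP
  production as objective while sampling characterized the flux space;
  the default reconciles the two by constraining the ATP demand to at
  least 99% of its FBA maximum before sampling
  (`optimality_fraction = 0.99`), with `optimality_fraction = 0`
  sampling the unconstrained polytope as a first-class alternative.
* **Interior start and implicit equalities.** A hit-and-run chain
  started at an LP vertex stalls: almost every direction leaves the
  polytope immediately. The warm-up chain therefore starts from the
  average of the FBA solution and a handful of random-objective
  vertices. Diet constraints also *force* whole pathway chains to zero
  (e.g. the EPA/DHA chains under the FAT diets), making the polytope
  lower-dimensional than the null space; a structural bound-propagation
  pass pins chains whose metabolites have no producer, and any residual
  face-touching directions at the trial interior point are settled by
  targeted flux-variability LPs — zero-range reactions are pinned,
  otherwise the extreme vertices are folded into the average. Without
  this the chain would make vanishing steps and mix pathologically.
* **Numerics.** Chord endpoints are excluded by a relative inset of
  1e-10 to avoid sticking to faces; recorded points are validated
  against $\lVert S v\rVert_\infty < 10^{-6}$ and bounds within
  $10^{-9}$, with tiny overshoots re-projected onto the box and anything
  persistent raised as an error. The warm-up count defaults to twice the
  polytope dimension (capped at 5000, never below dimension + 1). All
  randomness flows through a single integer seed; identical
  `(model, config, seed)` reproduce bit-identical sample sets.
* **Direction normalization.** Whether $y - s$ is normalized only
  reparameterizes the chord; it does not change the sampled
  distribution. The implementation normalizes.

The linear programs behind FBA, flux variability and the interior-point
construction are solved by the package's own dense bounded-variable
two-phase revised simplex (Dantzig pricing with a Bland's-rule fallback
once a degeneracy streak is detected, and a fresh basis solve per
iteration). Flux-balance problems are small but extremely degenerate —
the steady-state right-hand side is identically zero — and the test
suite cross-checks objective values against an independent
HiGHS-based oracle through the system Python at $10^{-6}$.

## Cross-diet statistics

For each reported reaction the per-diet sampled fluxes are compared by
one-way ANOVA followed by Tukey–Kramer honestly-significant-difference
comparisons (exact for unequal group sizes), and a compact letter display
is built by insert-and-absorb on the significance matrix: groups sharing
a letter do not differ at level α, groups sharing none do; ties are
broken by group order as supplied. Letters are keyed to the comparison of
means, while the boxplot view reports medians and quartiles
(linear-interpolation convention, R's type 7 — the convention is stated
because different software disagrees here).

Sampled fluxes are treated as independent observations, replicating the original
study procedure. They are not independent — the chain is a Markov
process — so effective significance is inflated; `compare_groups()`
exposes a `thin` factor for sensitivity checks, and the distributional
diagnostics in the test suite thin the chain (50 steps between records)
before applying a Kolmogorov–Smirnov test, which assumes independent
draws. With 500-point samples per diet the letter separations reported by
the pipeline are far from the decision boundary, so the inflation does
not change any reported direction.

## What the fixture does and does not show

The fixture is a reduced, fully documented stand-in for the full
curated enterocyte mitochondrial model (127 genes, 178
metabolites, 311 reactions). It reproduces the analysis *mechanics* —
diet-to-bound conversion, integrity checks, optimality-constrained ACHR
sampling, post hoc letters — and the qualitative dietary responses:
increasing lipid/carbohydrate ratio strictly decreases the sampled PDHm
median while every dietary β-oxidation flux increases, and increasing
fish-oil fraction increases EPA/DHA oxidation while PDHm and dietary
palmitate oxidation decrease, the latter pattern markedly subtler than
the lipid-load response — the same contrast the full model shows.
Passing tests on the fixture do **not** establish quantitative flux
values for real enterocytes: the fixture's absolute fluxes depend on the
assumed intake and dry-mass parameters, its pathway lumping, and the
closed biosynthetic drain. The tabular loader (`load_model(...,
"tabular")`) reads the supplementary-style reaction-table dialect of curated models,
so the same pipeline runs against the full model when those files are
available; the printed composition counts (24 luminal / 54 cytosolic /
80 mitochondrial / 91 transport / 62 exchange reactions) can only be
verified against them.

## Known limitations

* Gene rules are carried and serialized (JSON, SBML L3 FBC, tabular) but
  expression data are not integrated into bounds; the transcriptomic
  side of the original study is out of scope.
* No thermodynamic constraints; reversibility is encoded solely by the
  sign of the lower bound.
* Degenerate FBA optima mean individual flux values of a returned
  solution are not contract-stable; only the objective value is.
* ANOVA on MCMC samples (above) inflates significance; directions, not
  p values, are the robust output.
* The uniform-TAG convention and complete-absorption default overstate
  how much of each fatty acid reaches β-oxidation; both are explicit,
  configurable assumptions.
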