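# mitoflux

Constraint-based analysis of small-intestinal enterocyte mitochondrial
metabolism under dietary lipid interventions.

Enterocyte mitochondria must trade carbohydrate oxidation against
fatty-acid β-oxidation as the diet changes. `mitoflux` models that
trade-off without kinetic parameters: a three-compartment metabolic
network (luminal `u`, cytosolic `c`, mitochondrial matrix `m`) is
described by its stoichiometric matrix *S* and flux bounds, a
steady-state flux vector *v* satisfies

    S v = 0,   lb ≤ v ≤ ub,

and maximal ATP production (the cytosolic ATP demand `DM_atp_c`) is the
linear-programming objective. Because optimal flux vectors are highly
degenerate, the package characterizes the whole solution space: the
steady-state flux polytope is sampled with **artificial centering
hit-and-run (ACHR)** — optionally restricted to ≥ 99% of the ATP optimum
— and per-reaction flux distributions are compared across diets with
one-way ANOVA plus **Tukey–Kramer** post hoc letters.

The package is aimed at researchers in nutritional systems biology who
want a fully testable, self-contained version of this workflow. It ships
a reduced, elementally balanced enterocyte mitochondrial network
(TCA cycle, per-species β-oxidation of eight dietary fatty acids supplied
as uniform triacylglycerides, carnitine shuttle, oxidative
phosphorylation with explicit proton bookkeeping), the printed
compositions of seven experimental mouse diets — three isocaloric
fish-oil diets (FISH0/15/44) and four diets of increasing
lipid/carbohydrate ratio (FAT10/20/30/45) — and the conversion from a
diet table to exchange-reaction uptake ceilings in mmol g⁻¹ h⁻¹. Models
are read and written as native JSON, SBML Level 3 FBC, and a tabular
reaction-list dialect compatible with COBRA-style spreadsheet exports.

## Worked example

```r
library(mitoflux)

model <- build_fixture_model()
model
#> Metabolic model 'mitoflux_fixture'
#>   metabolites: 106  reactions: 108  genes: 67
#>   objective: DM_atp_c

# maximal ATP per mole glucose: feed 1 mmol g-1 h-1 glucose, nothing else
ex <- reaction_ids(model)[is_exchange(model)]
glc_only <- set_bounds(model, ex, lower = 0)
glc_only <- set_bounds(glc_only, c("EX_o2_u", "EX_h2o_u", "EX_pi_u", "EX_h_u"),
                       lower = -1000)
glc_only <- set_bounds(glc_only, "EX_glc__D_u", lower = -1)
fba_max_atp(glc_only)
#> Flux balance solution (optimal)
#>   objective DM_atp_c = 31.5 mmol g-1 h-1  (max |S v| = 2.49e-14)
```

31.5 ATP per glucose is the closed-form yield implied by the fixture's
proton stoichiometry (10 H⁺/NADH, 6 H⁺/FADH₂, 4 H⁺/ATP with explicit
chemical protons; see the methods vignette). Now compare the lowest- and
highest-fat diets end to end — constrain, sample, test:

```r
cfg <- study_config(diets = c("FAT10", "FAT45"), seed = 3)
cfg$sampler$n_points <- 200; cfg$sampler$steps_per_point <- 50
res <- run_study(cfg)

res$comparisons[["PDHm"]]
#> Cross-diet comparison of PDHm (one-way ANOVA F = 346118626, p = 0; Tukey-Kramer letters at alpha = 0.05)
#>   group   n median    q1    q3  mean letters
#> 1 FAT10 200  4.838 4.838 4.839 4.838       a
#> 2 FAT45 200  2.697 2.696 2.698 2.697       b

res$comparisons[["FAOXC160"]]
#> Cross-diet comparison of FAOXC160 (one-way ANOVA F = 43161861, p = 0; Tukey-Kramer letters at alpha = 0.05)
#>   group   n  median      q1      q3    mean letters
#> 1 FAT10 200 0.02561 0.02535 0.02579 0.02556       a
#> 2 FAT45 200 0.22770 0.22740 0.22790 0.22760       b
```

Read: moving from 10 to 45 fat-energy% cuts the sampled median flux
through pyruvate dehydrogenase (`PDHm`) from 4.84 to 2.70
mmol g⁻¹ h⁻¹ — less glucose arrives, so less carbohydrate-derived
acetyl-CoA enters the TCA cycle — while β-oxidation of dietary palmitate
(`FAOXC160`) rises about nine-fold; distinct letters mean the two diets
differ at α = 0.05. `run_study()` writes per-diet sample matrices,
a flux report with letters, and a manifest (seeds, configuration,
versions) sufficient to reproduce the run bit-for-bit;
`study_config(full_scale = TRUE)` switches from the reduced default
(500 points, 100 steps) to the full protocol (2000 points, 500 steps
between points). A thin CLI over the same functions lives in
`inst/cli/mitoflux` (`build-fixture`, `diets`, `constrain`, `check`,
`fba`, `sample`, `run`).

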