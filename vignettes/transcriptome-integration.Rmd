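---
title: "Transcriptome-integrated metabolic modeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome-integrated metabolic modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tigsmm)
```

## The modeling problem

A genome-scale metabolic model (GSMM) encodes an organism's metabolism as
a stoichiometric matrix $S$ (metabolites $\times$ reactions), flux bounds
$lb_i \le v_i \le ub_i$ (mmol gDW$^{-1}$ h$^{-1}$), and gene-protein-reaction
(GPR) boolean rules linking reactions to the genes encoding their enzymes.
Flux balance analysis (FBA) predicts a flux state by linear programming:

$$\max\; v_{biomass} \quad \text{s.t.}\quad S v = 0,\; lb \le v \le ub,$$

where the biomass pseudo-reaction drains precursors in measured
proportions and its flux is the growth rate (h$^{-1}$). Plain FBA ignores
condition-specific regulation. The GIMME family of methods repairs this by
penalizing flux through reactions whose associated genes are weakly
expressed in the condition of interest, yielding a context-specific
("transcriptome-integrated") flux state. This package implements that
pipeline end to end for the typical fungal-culture design — two carbon
sources (glucose, sucrose) under a light regime, FPKM expression tables,
and gene-level differential statistics — together with the reporter
metabolite statistic used to summarize which parts of the network respond
transcriptionally.

## The GIMME linear program

Expression is mapped onto reactions as $x_i$ and compared with a
threshold $x_{threshold}$. The penalty coefficient for each reaction is

$$c_i = \begin{cases} x_{threshold} - x_i & x_i < x_{threshold} \\
0 & \text{otherwise,}\end{cases}$$

and the context-specific state solves

$$\min \sum_i c_i\,|v_i| \quad\text{s.t.}\quad S v = 0,\;
lb \le v \le ub,\; v_{biomass} \ge f\,\mu^*,$$

where $\mu^*$ is the FBA growth maximum from a first phase. The optimum's
objective value is the *inconsistency score*: how much "expression says
off" flux the network is still forced to carry to grow. The absolute
value is handled exactly by splitting every flux into nonnegative forward
and reverse parts, which is valid because every $c_i \ge 0$; no integer
programming is involved.

Design choices worth recording:

* **Growth fraction `f`.** Descriptions of this approach are ambiguous
  between pinning growth at the full FBA maximum and requiring only a
  fraction of it. We expose it as `gimme_config(growth_fraction = )`,
  default 0.90 (the common GIMME practice), with 1.0 used in our
  replication profile. Everything downstream (active sets, Venn counts)
  can shift at the margin between the two; the knob is one number in the
  run config so the choice is always visible in the manifest.
* **Expression mapping.** The default rule scores a reaction by the
  maximum FPKM over its GPR genes, following the assumption that a
  reaction is available as soon as one associated gene is expressed. A
  GPR-aware alternative (complex `and` $\to$ min, isozyme `or` $\to$ max)
  is available; it is never larger than the max rule, a property the test
  suite checks.
* **Missing evidence.** Reactions without a GPR, and reactions whose
  genes are absent from the profile, are *unscored* and get $c_i = 0$.
  Treating missing as zero expression would inject penalties without
  evidence.
* **Threshold population.** The percentile (default P50) is taken over
  the FPKM values of the model's metabolic genes present in the profile,
  per condition; an all-genes option exists for sensitivity analysis.
  Percentiles interpolate linearly between order statistics, so
  P50 of $\{1,2,3,4\}$ is 2.5.
* **Strict vs non-strict bounds.** The flux bounds are treated as
  non-strict inequalities, as is universal in LP practice.
* **Active calls.** A reaction is *active* when $|v_i|$ exceeds
  `zero_tolerance` (default $10^{-6}$), separating LP round-off from
  biological activity. Alternate optima are a fact of FBA-type models;
  tests therefore assert objective values and invariants, never full
  flux vectors, and borderline active counts can legitimately shift
  between equally optimal vertices.

## Linear programming machinery

The package solves its LPs with a self-contained bounded-variable
two-phase primal simplex (Bland's smallest-index rule, dense algebra).
Metabolic steady-state systems are small here but heavily degenerate and
often rank-deficient, which is exactly where naive tableau
implementations stall or crash; Bland's rule guarantees termination.
Flux bounds use the conventional $\pm 1000$ finite proxy for
"unbounded"; genuinely infinite bounds are replaced internally by
$\pm 10^6$ and an optimum touching that proxy with a nonzero objective
coefficient is reported as status `"unbounded"` rather than as a number.

Correctness is anchored by an independent oracle:
`enumerate_vertices_oracle()` (and `gimme_oracle()`) enumerate all basic
feasible points of the flux polytope by choosing, for every subset of
$n - \mathrm{rank}(S)$ variables, a nonbasic value from
$\{lb_i, ub_i\}$ — extended with $0$ for reversible reactions when the
objective is the piecewise-linear GIMME score, since
$\sum c_i |v_i|$ is linear on each orthant and its minimum therefore
sits at a vertex of the polytope refined by the $v_i = 0$ hyperplanes.
This enumeration is combinatorial and restricted to models with at most
12 reactions; the acceptance suite checks simplex-vs-oracle agreement to
$10^{-6}$ on 200 seeded random models (the problem size was chosen so
the whole comparison runs in well under a minute).

## Reporter metabolites

Given gene-level two-sided p-values with directions (an input — the
differential-expression call itself is out of scope), each gene gets a
distinct-directional Z-score: the one-tailed p in the direction of
interest is $p/2$ if the gene moved that way and $1 - p/2$ otherwise,
and $Z_g = \Phi^{-1}(1 - p_{dir})$ (p-values clamped to
$[10^{-300}, 1 - 10^{-16}]$, with the inversion done on the upper tail
to retain precision for extreme p). For a metabolite $m$ whose touching
reactions carry $k$ scored genes $G(m)$,

$$Z_{raw}(m) = \frac{1}{\sqrt{k}} \sum_{g \in G(m)} Z_g, \qquad
Z_{corr}(m) = \frac{Z_{raw}(m) - \mu_k}{\sigma_k}, \qquad
p_{up}(m) = 1 - \Phi(Z_{corr}(m)),$$

where $(\mu_k, \sigma_k)$ are the moments of $Z_{raw}$ over random
size-$k$ gene sets drawn from the scored universe. The background is
enumerated exhaustively when $\binom{n}{k} \le 10^5$ and otherwise
sampled (default $10^4$ subsets, seed-driven; $\sigma$ floored at
$10^{-12}$ so constant universes yield $Z_{corr} = 0$, not NaN). The
down-direction is the exact mirror (per-gene $Z$ negated, background
mirrored), so both directions come from one pass. Significance is the
plain $p < 0.05$ rule per direction, without multiplicity correction,
and no currency metabolites are excluded by default — both choices
match how reporter lists are conventionally read in this literature.
Neighborhoods are *gene* sets (the union of GPR leaves over reactions
with nonzero stoichiometry for the metabolite), the sampling unit of the
original reporter algorithm.

## Synthetic data: what it emulates and what it does not

The generators define the study conditions for every desk-scale result:

* `make_textbook_model()` is a fixed 6-metabolite, 10-reaction,
  4-gene fixture with two parallel unit-yield paths under different
  genes and a half-yield bypass — the smallest network on which GIMME
  rerouting is observable and hand-checkable (penalize both parallel
  paths, require half of maximal growth: all flux must move to the
  bypass at inconsistency 0; block the alternatives and force 10 units
  through a penalty-5 reaction: the score is exactly 50).
* `generate_model()` draws feasibility-by-construction networks: a
  substrate-to-biomass backbone guarantees growth $> 0$ without
  rejection sampling, then parallel isozyme-like duplicates and forward
  branches (yields in $[0.5, 1]$) are added with random GPRs.
* `generate_fpkm()` draws log-normal FPKM (meanlog 2, sdlog 1.2 —
  a bulk-RNA-seq-like spread with a median around 7 FPKM); planted
  low-expression reactions have their genes drawn from the bottom 5% of
  the same distribution, so they land below any median-style threshold
  with near certainty.
* `generate_gene_stats()` draws null genes from Uniform(0,1) with
  random directions, and genes around designated "hot" metabolites from
  a scaled Beta(0.5, 1) (median $\approx 0.002$) with a shared "up"
  direction.

All generators take a seed, restore the global RNG state afterwards, and
are bit-reproducible. What these fixtures deliberately do **not**
emulate: genome-scale network topology (hubs, cofactor coupling, ~10%
blocked reactions), between-condition correlation of expression, and the
dependency structure of real differential statistics. Passing tests on
synthetic data therefore demonstrate algorithmic correctness and
statistical calibration, not biological fidelity on any particular
organism's reconstruction; real-model results additionally depend on the
quality of the deposited GSMM and transcriptome.

## Worked example

```{r example, eval = FALSE}
m <- make_textbook_model()
census(m)

m10 <- apply_uptake(m, list(uptake_constraint("EX_A", 10)),
                    open_nutrients = "EX_N")
solve_fba(m10)$objective_value        # 10: unit yield times uptake

pen <- setNames(rep(0, 10), m$reactions$id)
pen[c("R_hi", "R_lo")] <- 5
g <- solve_gimme(m10, pen, gimme_config(growth_fraction = 0.5))
g$inconsistency_score                  # 0: flux rerouted to the bypass
g$fluxes[["R_byp"]]                    # 10
```

## Numerical conventions and limitations

* Steady-state residual tolerance $10^{-6}$; bound violation tolerance
  $10^{-9}$; simplex pivot tolerance $10^{-9}$.
* Bounds absent from model files default to $(-1000, 1000)$ for
  reversible and $(0, 1000)$ for irreversible reactions.
* SBML support covers Level 3 Version 1 with FBC v2 (bounds as
  parameters, GPR as `fbc:geneProductAssociation`, the active objective
  as the biomass designation); reaction kind and subsystem ride in
  COBRA-style notes. `.mat`/`.xlsx` model files are out of scope.
* The vertex oracles are exponential and guard at 12 reactions; they
  are test instruments, not production solvers.
* Degenerate alternate optima mean flux *vectors* are not unique;
  only objective values, active/inactive calls at the tolerance, and
  invariants are stable quantities.
* Reporter p-values are calibrated marginally (the acceptance suite
  verifies a 5% false-positive rate under the null within $\pm 2$
  points); overlapping neighborhoods make metabolite calls correlated,
  as in the original algorithm.
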