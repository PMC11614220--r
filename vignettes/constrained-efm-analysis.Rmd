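---
title: "Constrained elementary flux mode analysis of tumour metabolism and stroma formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained elementary flux mode analysis of tumour metabolism and stroma formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromaefm)
```

## The question and the modelling frame

Cancer cells ferment glucose to lactate even under oxygen (aerobic
glycolysis, the Warburg effect) and consume glutamine far in excess of
their nitrogen needs. Around them, the tumoral stroma accumulates
collagen, inflammation markers (IL1-beta, TNF-alpha) and the angiogenic
growth factor VEGF-A. This package asks, with a constraint-based metabolic
model, whether these phenotypes can be carried by *single minimal
pathways*: steady-state flux distributions that simultaneously ferment
glucose, consume glutamine, grow, and export collagen and stroma markers.

The frame is classical constraint-based modelling. A network of `r`
reactions over `m` internal metabolites is summarized by its stoichiometric
matrix $N \in \mathbb{R}^{m\times r}$; a flux vector $\nu$ is admissible at
steady state when

$$N\,\nu = 0, \qquad \nu_i \ge 0 \text{ for irreversible } i.$$

An **Elementary Flux Mode** (EFM) is an admissible $\nu$ of minimal
support: no other admissible flux uses a strict subset of its active
reactions. EFMs are the extreme rays of the flux cone, unique up to
positive scaling, and they are verified here with the stoichiometric rank
test: $\nu$ is elementary iff
$\operatorname{rank} N_{\cdot,\operatorname{supp}(\nu)} =
|\operatorname{supp}(\nu)| - 1$.

## The model

`synthetic_stroma_model()` is a 73-reaction, three-compartment core model
of a proliferating human cell, assembled in two layers:

1. `synthetic_core_model()` — central carbon and nitrogen metabolism:
   lumped glycolysis, lactate fermentation, the TCA cycle with reversible
   isocitrate dehydrogenase (so reductive carboxylation towards lipogenic
   citrate is available), oxidative phosphorylation with pseudo-metabolites
   for the proton gradient (`DPH`, `DPSI`) and protonmotive force (`PMFm`),
   the malate–aspartate shuttle, glutaminolysis, serine synthesis and the
   cytosolic folate cycle, amino-acid degradation for arginine, cysteine
   and the conflated pools TIV (Thr/Ile/Val) and YFLKW (Tyr/Phe/Leu/Lys/Trp),
   a lumped nucleotide-synthesis reaction that converts glutamine to
   glutamate, and a biomass reaction.
2. `build_stroma_extension()` — the stroma layer: collagen assembled as
   100-residue bricks (33% glycine, 50% of an equiprobable X–Y pool,
   8.5% proline, 8.5% hydroxyproline; 100 bricks per collagen polypeptide),
   protein-synthesis reactions for IL1-beta, TNF-alpha and VEGF-A whose
   coefficients are residue counts divided by protein length (so the
   protein coefficient is the inverse of its length), a lumping block that
   requires one inflammation marker *and* the growth factor before stroma
   is formed, and transport/metabolism for the amino acids the core lacks
   (proline, histidine, alanine, asparagine).

The core network is explicitly a **synthetic stand-in** for the published
core model of central human metabolism this analysis style was developed
on; that model's full reaction list is not redistributable here. The
stand-in preserves the features the method depends on — compartments,
pseudo-metabolites, conflated pools, Warburg-compatible routes,
folate-cycle variability, glutamine-to-glutamate conversion through
nucleotide synthesis — at roughly half the size. Counts derived from it
(reactions, metabolites, compressed sizes, score ranges) are properties of
the stand-in, not of the published model.

Two deliberate unit conventions matter:

* **Biomass quantum.** One unit of the biomass reaction represents a
  cell-growth quantum and therefore draws one to two orders of magnitude
  more precursor material (and 1200 ATP) than one secreted protein
  molecule. This matters because the analysis constrains collagen and
  stroma production *rates* to exceed the biomass rate: with a
  molecule-sized biomass unit no elementary mode can satisfy that ordering,
  while with a growth-quantum unit the joint modes exist.
* **No free ATP sink.** Maintenance ATP consumption is folded into the
  biomass coefficient instead of a standalone ATP hydrolysis reaction. A
  free ATP sink makes pure glucose-to-lactate cycles self-contained
  elementary modes, which decouples glycolysis from biosynthesis in every
  EFM; folding maintenance into biomass keeps glycolytic throughput
  stoichiometrically tied to growth and stroma production, which is the
  coupling under study.

Elemental balancing is not enforced (the published models in this family
also fail strict stoichiometric-consistency checks); the network is a flux
topology, not an atom map.

## Constraints

`default_constraint_set()` encodes four constraint classes derived from
NCI-60 exometabolomic exchange-flux statistics (packaged as
`table1_constants()`, fmol/cell/h, uptake negative):

* **Hard activity** — glucose uptake, lactate secretion and glutamine
  uptake must carry flux, and biomass production must be active (the three
  followed functions — proliferation, collagen formation, stroma response —
  are all demanded; activity of the latter two follows from the linear
  constraints below).
* **Forbidden directions** — for each metabolite observed only consumed
  ("−") the secretion direction is forbidden, for each observed only
  secreted ("+") the uptake direction is forbidden; zero flux stays
  allowed. Bidirectional ("+/−") metabolites are unconstrained.
* **Strict linear inequalities** — collagen production above biomass
  production, stroma production above biomass production.
* **Support cap** — strictly fewer than 60 active reactions, counted on
  the network the sampler runs on (the compressed network).

Strictness cannot be expressed in an LP, so strict constraints carry a
margin `eps` (1e-6 of the normalized flux scale in `satisfies()`; the
activation threshold inside the sampler's LPs is 1e-4 on the
sum-normalized polytope, where active fluxes are orders of magnitude
larger).

## Compression

`compress()` removes blocked reactions (zero maximal absolute flux under
steady state, irreversibility and a |v| <= 1000 box, established by
flux-variability LPs with a nullspace prescreen) and merges *enzyme
subsets*: groups of reactions whose rows in a kernel basis of $N$ are
proportional (cosine similarity above 1 − 1e-9) and whose fluxes are hence
in fixed ratio in every steady state. Subset detection runs on the
*unsplit* network: splitting reversible reactions first would add
two-cycle kernel vectors that mask row proportionality. Reversible
splitting happens inside the EFM machinery instead, where the spurious
two-cycles are excluded combinatorially. Compression maps losslessly back
through `decompress()`, and compressing a compressed network is the
identity.

## EFM computation

Small networks (up to ~32 columns after splitting) are enumerated
exhaustively with the double description method (`enumerate_efms_exhaustive()`),
and an independent brute-force oracle (`brute_force_efms()`) checks every
support subset for a one-dimensional, sign-consistent kernel; both agree on
all seeded toy fixtures.

The full model is beyond exhaustive enumeration, and the constraint set
makes naive sampling hopeless: almost every vertex of the constrained flux
polytope is a superposition of two or more EFMs each of which individually
violates some constraint. `sample_constrained_efms()` therefore works in
seeded randomized rounds:

1. **Vertex rounds** solve an LP with a mixed-sign random objective over
   the constrained polytope normalized by $\sum_i \nu_i = 1$ (optionally
   forcing a random direction active), giving a vertex with small support.
2. **Sub-cone enumeration**: within the candidate support the flux cone has
   a low-dimensional kernel, so all of its elementary rays are enumerated
   by double description and classified against the constraint set; rank
   test and `satisfies()` gate acceptance.
3. **Neighborhood rounds** re-seed the search from the supports of found
   modes *and* of near-miss rays (rays violating at most two constraints),
   dropping a few support members and adding a few random directions, so
   genuine pathway swaps (serine import vs. synthesis, IL1-beta vs.
   TNF-alpha, formate import vs. export) are explored.

Every returned mode is steady-state, rank-test elementary, constraint
satisfying, and deduplicated by support; given a seed the sample is
deterministic, and different seeds extend it. On toy networks the sampler
is provably complete because it falls back to exhaustive enumeration below
the size threshold. A natural alternative design is a support-minimizing
mixed-integer program with Boolean activity indicators and no-good cuts;
the sampler here deliberately delivers the same output contract —
constrained EFMs in batches, rediscovery prevented by visited-support
caching — with linear programming and combinatorial enumeration only,
which keeps the solver stack to small, dependable dense-LP routines and
makes every accepted candidate independently verifiable by the rank test.

### Linear programming backends

All LPs are small and dense. The primary backend is the two-phase tableau
simplex from the recommended package `boot` (vertex solutions, which the
sampler needs); the cross-check backend is `quadprog` with a small
quadratic regularization and a support-restricted polishing loop. Both are
wrapped with row/column equilibration — stoichiometric coefficients span
1e-3 (protein synthesis) to 1e2 (collagen condensation, biomass ATP) and
the unscaled tableau otherwise degenerates numerically. Any non-optimal
simplex verdict is confirmed against the quadratic backend before being
believed, and bound-fixed variables are substituted out of every problem.

## Scoring against exometabolomic data

`regress_mode()` regresses the measured mean exchange fluxes (fmol/cell/h)
on the mode's exchange values by ordinary least squares with intercept,
restricted to metabolites with usable numbers and nonzero mode flux. This
direction makes the RMSE carry data units and the score invariant under
positive rescaling of the mode (EFMs are rays, so scale is meaningless);
the opposite regression direction is available via the `direction`
argument for sensitivity analysis. Metabolites without usable numbers
(pyruvate: uncalibrated; formate, histidine: missing) never enter a
regression even when the mode carries flux there. $R^2$ is
$1 - SS_{res}/SS_{tot}$ and may be negative for terrible fits; RMSE is the
root *mean* squared residual. `rank_modes()` orders by descending $R^2$
with RMSE and index as tie-breaks; `per_line_first_places()` repeats the
ranking against each cell line's individual fluxes.

Exchange fluxes are always reported uptake-negative, regardless of how an
exchange reaction is written in the model file: the accessor
`exchange_flux()` normalizes through the boundary species' production
rate, which also works on compressed networks where exchange reactions sit
inside merged subsets. Model ids are resolved through a user-editable
alias table (`default_exchange_aliases()`), since id conventions differ
between model files.

## Baselines

`pfba()` is a two-stage LP: maximize the summed production flux of
biomass, collagen assembly and stroma recruitment subject to the same hard
/ forbidden / linear constraints (no support cap) and a per-flux bound
(default 15), then fix the optimum and minimize total split flux. Stage-2
optima can be degenerate — the two backends may return different flux
vectors of equal objective and total flux — so ratio and score quantities
derived from a pFBA solution are compared across both backends.
`is_essential()` knocks a reaction out and tests feasibility of the same
polytope. `flux_sample()` is an artificial-centering hit-and-run walk in
nullspace coordinates over the box-bounded constrained polytope (warm-up
1000 steps; thinning targets a chain of 100 steps per kept sample, capped
at 1e6 total steps; directions drawn towards previously visited points
relative to the running mean). Chain maxima fluctuate noticeably across
seeds, so large-sample summaries are best taken over several independently
seeded chains.

## Synthetic data generators

`generate_cell_lines()` draws per-line exchange fluxes
Normal(mean, sd) from the packaged table, with optional sign enforcement by
redraw (at most 100 attempts, then clipping to zero — a truncated-normal
emulation that keeps the distribution shape), plus a synthetic cancer-type
label cycling over nine types. `generate_planted_efm_data()` produces
parameter-recovery data: each line is a uniform positive scaling of one
mode's exchange vector plus Gaussian noise. `generate_toy_network()` makes
chain, diamond, cycle and random fixtures whose EFM sets the brute-force
oracle can enumerate; random fixtures embed a guaranteed
substrate-to-product path so at least one EFM always exists.

These generators emulate the *structure* of cell-line exometabolomics
(means, dispersions, sign categories, a planted low-rank signal), not its
biology: real lines correlate across metabolites, deviate from normality,
and carry tissue-specific signatures. A passing recovery test shows the
ranking machinery identifies a planted generating mode under the stated
noise; it does not show that real cell lines are generated by single EFMs.

## Problem sizes and tolerances

The packaged analyses run at sizes chosen to finish in minutes on one
core: EFM samples of 50–150 modes (the sampler typically saturates near
the model's constrained-EFM diversity before the cap), hit-and-run samples
of 1e3–5e4 points, 60 synthetic cell lines, toy oracles at 11–13
reactions. Key numerical settings: support membership and kernel rank use
a relative 1e-9 threshold on singular values; steady-state verification
uses 1e-6 relative; kernel-row proportionality 1 − 1e-9 in cosine;
blocked-reaction box 1000; strictness margins as above. Sub-cone
enumeration is guarded (kernel dimension at most 10, at most 2000
intermediate rays) so no round can blow up combinatorially.

## Known limitations

* The packaged network is a stand-in; absolute score levels, counts and
  ratios are not those of the published model this analysis style comes
  from. The acceptance tests that compare against published values accept
  user-supplied paths to the original supplementary files and fail
  otherwise, by design.
* The sampler is sound but has no completeness guarantee above toy scale;
  the sample it saturates at underestimates the true constrained-EFM count.
* Flux-sampling maxima depend on chain length and thinning; they are
  reported for fixed seeds and sizes, not as converged extremes.
* The steady-state assumption ignores all kinetics and regulation;
  "pathways" here are stoichiometric capabilities, not measured states.
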