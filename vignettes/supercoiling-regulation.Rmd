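---
title: "Evolving gene regulation through the transcription-supercoiling coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving gene regulation through the transcription-supercoiling coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tscevo)
```

## The model

Bacterial DNA is kept negatively supercoiled, and the supercoiling density
at a promoter modulates how easily the double helix opens, hence how
strongly the gene is transcribed. Transcription in turn perturbs local
supercoiling: under the twin-domain picture, a transcribing polymerase
pushes positive supercoils downstream and leaves negative supercoils
upstream. On a gene-dense chromosome this couples the expression levels of
neighboring genes.

`tscevo` implements this coupling at the whole-genome scale. An individual
is a circular chromosome of `n` point-like genes (half-open intervals
`[begin, begin + length)` on a circle of `L` bp), each typed, oriented and
non-overlapping. The effect of gene `j`'s transcription on the
supercoiling at gene `i`'s promoter is

\[ \frac{\partial\sigma_i}{\partial e_j}
   = \eta \cdot c \cdot \max\!\left(1 - \frac{d(i,j)}{d_{max}},\, 0\right), \]

where `d(i, j)` is the shortest circular distance from `i`'s promoter to
`j`'s middle (the average polymerase position), `c` is a torsional drag
coefficient, and the sign `η` follows the twin-domain rules: an upstream
gene on the same strand contributes positive supercoiling (+1), an
upstream gene on the opposite strand negative supercoiling (−1), with
both signs reversed downstream. Exact antipodal ties (distance `L/2`)
get a zero coefficient; they are unreachable at the default parameters,
where `d_max` is far below `L/2`.

Local supercoiling sums the basal level, an environmental shift and the
coupling:
\(\sigma_i = \sigma_{basal} + \delta\sigma_{env} + \sum_j
\partial\sigma_i/\partial e_j \, e_j\).
Promoter opening follows a sigmoid
\(U_i = 1/(1 + e^{(\sigma_i - \sigma_{1/2})/\epsilon})\)
and expression an exponential
\(e_i = e^{m (U_i - 1)}\), bounded in \([e^{-m}, 1]\).
A gene is *activated* when its expression exceeds
\(e_{1/2} = (e^{-m} + 1)/2\), strictly.

The phenotype of a genome in an environment is the vector of expression
levels solving this self-referential system. `solve_expression()` computes
it by synchronous substitution from the uniform start `e_1/2`, with
knocked-out genes pinned to exactly zero at every step.

### Parameters

All constants live in `sim_params()` and default to averaged *E. coli*
values:

| parameter | default | meaning |
|---|---|---|
| `gene_length` | 1,000 bp | gene footprint on the circle |
| `intergene` | 125 bp | initial intergenic spacing |
| `d_max` | 5,000 bp | supercoiling transmission distance |
| `sigma_basal` | −0.066 | basal supercoiling density |
| `c` | 0.03 | torsional drag (coupling magnitude) |
| `sigma_half` | −0.042 | promoter opening threshold |
| `epsilon` | 0.005 | opening sigmoid width |
| `m` | 2.5 | inverse effective thermal energy |
| `delta_sigma_A` / `delta_sigma_B` | +0.01 / −0.01 | environmental shifts |
| `lam` | 2 | inversions per offspring (Poisson) |
| `pop_size` | 100 | individuals per population |
| `k_selection` | 50 | selection intensity |

The selection intensity `k` has no literature value; the default of 50
makes fitness differences meaningful at the gap scale the model produces
(squared errors of order 10⁻²–1) without collapsing the population onto a
single genotype in one generation. It is exposed in every entry point.

## Numerical behavior of the fixed-point solver

The substitution map is strongly nonlinear: its Jacobian entries scale
with \(m\,U(1-U)/\epsilon \cdot c\), which at the crossover can exceed 1
by an order of magnitude. Three regimes occur on real genomes, and the
solver handles each explicitly:

* **Contracting** (most genomes, all well-evolved ones): plain
  substitution converges in tens of iterations.
* **Oscillating**: strongly coupled convergent pairs make the update
  overshoot in alternating directions (a period-2 cycle of the map).
  The solver detects the failure to improve, estimates the dominant
  eigenvalue of the damped map from the alignment of successive steps,
  and re-damps near the optimum; a halving ladder and a pinned
  conservative damping stage (w = 0.2) back this up. Damping moves the
  iterate along the same update direction, so it never changes the fixed
  point, only the path.
* **Slow or orbiting**: strong divergent-pair feedback yields
  near-unit eigenvalues (slow geometric tails), which a verified
  Steffensen extrapolation along the last step shortcuts. In roughly 1%
  of *random* genomes the damped dynamics instead settles on a limit
  cycle around an unstable fixed point — no damping converges. Since the
  model defines the phenotype as a *solution of the equation system*,
  the solver then switches to a Newton iteration on the fixed-point
  equations (analytic Jacobian, backtracking line search), which finds
  that equilibrium directly. Every returned state is verified: the
  `converged` flag means the max-norm self-consistency residual is below
  `solver_tol` (default 1e−10).

Setting `damping < 1` disables all adaptation and runs a plain fixed
damped iteration — useful for methodological comparisons. Non-convergence
within `solver_max_iter` (default 40,000) is always surfaced as a warning
and a `converged = FALSE` flag, never silently.

The system can be genuinely multistable — a convergent gene pair is a
toggle switch, and that is part of the biology the model is built to
show. The reported phenotype is therefore *defined* by the iteration's
starting point: all genes at `e_1/2`, which respects the genome's
symmetries (mirror and rotation invariance are tested to 1e−12).

## The evolutionary simulation

Populations of `pop_size` clonal founders evolve in non-overlapping
generations under two environments applied to every individual:
relaxation (`A`, `δσ = +0.01`) and increased negative supercoiling
(`B`, `δσ = −0.01`). Genes are typed `A`, `B` or `AB`; per-type mean
expressions are compared with targets (type `A`: maximal in environment
A, minimal in B; type `B` the reverse; `AB` maximal in both), and the
fitness is `exp(-k * g)` with `g` the sum of the six squared deviations.
Reproducers are drawn multinomially with replacement, proportional to
fitness; each offspring undergoes a Poisson(λ)-distributed number of
genomic inversions.

Inversions pick two endpoints uniformly over the non-coding positions
(per-bp, so longer intergenes receive proportionally more breakpoints),
then mirror the enclosed genes within the segment, flipping their
orientations while conserving their relative spacing. Gene counts,
lengths, total genome length and total intergenic length are all
invariant; endpoints are cuts between base pairs and may touch a gene
boundary without splitting the gene, which keeps every inversion exactly
reversible. On a circle, inverting an arc or its complement differ only
by a mirror-rotation with identical dynamics, so the non-wrapping arc is
inverted without loss of generality.

One seed fully determines a replicate: the founder genome, every
selection draw, every mutation count and every endpoint come from a
single random stream consumed in a fixed order (selection, then
per-offspring inversion count, then endpoints).

## Analysis toolkit

* `activation_counts()` — genes above `e_1/2` per type and environment.
* `environment_sweep()` — per-type mean expression across a grid of
  `δσ_env`, with the neighbor-less closed form and a random-genome
  average as baselines. The default grid (−0.02 … +0.02 in steps of
  0.001) brackets both environments symmetrically.
* `census_pairs()` — every circular adjacency read twice, once per focal
  gene; classified convergent / divergent / focal-upstream /
  focal-downstream, stratified by the two gene types, with the
  transcription-generated supercoiling contribution of the focal gene at
  the target's promoter split into positive and negative totals per
  environment.
* `census_triplets()` — the `n` consecutive gene triples, quotiented by
  read-direction symmetry (central gene kept forward), 216 raw classes
  → 108 canonical ones.
* `minimal_subnetwork_size()` — smallest odd number of contiguous genes
  around a focal gene whose isolated evaluation reproduces the focal
  gene's full-genome activation state. Subnetworks are evaluated as
  *linear* arrangements with the original arc distances: wrapping the
  extracted genes into a smaller circle would create interactions that do
  not exist in the full genome. If no odd size below `n` matches, `n` is
  reported.
* `knockout_switches()` / `build_effective_graph()` / `graph_stats()` —
  re-solving with one gene's transcription pinned to zero, recording
  which genes switch activation state in either environment; the union
  over knockouts is a directed graph (at most one edge per ordered pair,
  labeled activation / inhibition / mixed), summarized by weakly
  connected component sizes and per-type in/out degrees.
* `random_genome_baseline()` — the same statistics over freshly drawn
  random genomes, the null the knockout analyses are compared against.

## What the generator emulates, and what it does not

`random_genome()` reproduces the initial individuals of the evolutionary
runs: equal gene counts per type in uniformly random order, fair-coin
orientations, equal spacing at the initial intergenic distance. This is a
model organism, not a real chromosome: genes carry no sequence, lengths
are uniform, there are no topological barriers, no polymerase particles,
no stochastic expression noise, and mRNA and protein levels are conflated
with transcription rates. Tests passing on these genomes validate the
model's internal logic — conservation laws, symmetry, solver
self-consistency, the directional effect of selection — not quantitative
agreement with any real transcriptome.

## Problem sizes used in the test suite

The reference experiments run 30 populations for 10⁶ generations; that
scale is far outside a test suite. The suite exercises the full default
genome (60 genes, L = 67,500 bp) throughout, checks solver
self-consistency on 100 random genomes, inversion conservation over 10⁴
events, and the selection response on 5 replicates × 5,000 generations at
the full default parameters — enough for fitness to rise by many orders
of magnitude and for `AB` genes to approach full activation, while the
slower differentiation of `A` genes (the paper-scale outcome of ~10⁶
generations) is only partially developed at that horizon. The acceptance
script runs 3 replicates × 3,000 generations for the same reason.

## Known limitations

* For multistable genomes the reported equilibrium depends on the
  documented initial state; no attempt is made to enumerate attractors.
* The Newton stage guarantees a self-consistent equilibrium for genomes
  whose substitution dynamics cycles, but if the underlying system had no
  solution the solver would report `converged = FALSE`; no such genome
  has been observed.
* Checkpointing restores the best genome, not the full population state;
  bit-exact resumption of an interrupted run is only available by
  re-running the replicate from its seed.
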