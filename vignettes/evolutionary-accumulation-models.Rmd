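---
title: "Evolutionary accumulation models on genotype lattices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary accumulation models on genotype lattices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoaccum)
```

## The modelling problem

Cross-sectional studies of tumours (and of any system accumulating
discrete, irreversible traits) give one binary genotype per independent
individual: which events — mutations, CGH regions, pathway hits — are
present, with no ordering or timing information. Accumulation models
recover the dependency structure under three assumptions: events are
gained one at a time; once gained they are never lost; and individuals are
replicate runs of the same constrained process. Under these assumptions
the state space is the lattice of subsets of the n events, transitions
only add single events, and the wild type (WT, no events) is the common
origin.

`evoaccum` implements the five standard families under one set of
containers and one genotype convention (bit masks; canonical order = by
number of events, then bit-pattern value; labels "WT" or comma-joined
event names).

## Model semantics

**DAG families.** OT, CBN, OncoBN and H-ESBCN place a directed acyclic
graph over the events plus a virtual root (implicit; never part of a
genotype). An event may be gained only when its parents satisfy its
relation: SINGLE/AND — all parents present; OR — at least one; XOR —
exactly one. OT restricts to trees with SINGLE relations; CBN allows AND;
OncoBN allows AND or OR but one type per model (its conjunctive and
disjunctive forms); H-ESBCN allows all three. `validate_model()` returns
all violations of these rules as descriptions rather than throwing, so a
GUI or script can report every problem at once.

**Timed vs untimed.** CBN and H-ESBCN attach an exponential gain *rate*
to each event; MHN is also timed, with gain rate
`exp(theta[e,e] + sum(theta[e,i], i in g))` — a baseline hazard times
pairwise multiplicative promoting/inhibiting effects, with no DAG at all.
OT and OncoBN are untimed: each parameter is the conditional probability
that the event is present *by observation time* given its dependency is
met, and the genotype distribution is the Bayesian-network product. This
treatment of OT edge weights (the Oncotree convention) makes OT exactly
the tree-restricted case of conjunctive OncoBN, and both share one code
path.

**XOR and reachability.** XOR is enforced at the moment the child is
gained; a second XOR parent may be gained afterwards. So with roots A, B
and C = XOR(A, B), the genotype {A, B, C} is reachable via A → C → B even
though a static check of C's constraint inside {A, B, C} fails, while
{A, B} is an absorbing dead end. Reachability is therefore defined by
breadth-first closure over transitions (`reachable_genotypes()`), which
is authoritative; for monotone relations (SINGLE/AND/OR) it provably
coincides with the static predicate, and the test suite checks this
equivalence on random DAGs.

## The timed observation model

The observation time is an independent Exponential(s) clock, s =
`sampling_rate`, default 1 — the convention of the CBN/MHN literature;
rates are only identified relative to this clock, which is why
`fit_cbn_rates()` fixes s = 1. Scaling all rates and s by the same
constant leaves the distribution invariant (tested). The observed-genotype
distribution is computed two independent ways:

- a **lattice dynamic program** in canonical order: with R(g) the total
  exit rate, reach-probability rho(WT) = 1,
  rho(h) = sum over predecessors g of rho(g) q(g,h)/(s + R(g)), and
  P(g) = rho(g) s/(s + R(g));
- the **linear system** p = s e_WT' (sI − Q)^{-1} over the reachable
  states.

Both are exposed via `observation_distribution(..., method = )` and must
agree to 1e-9; the acceptance checks also compare them against a third,
purely stochastic route (Gillespie simulation). Jump-chain transition
probabilities use competing-risks normalisation Q[g,h]/(−Q[g,g]);
absorbing rows are all-zero rather than identity so path enumeration
terminates cleanly (the matrix writer documents this convention). "Rate is
zero" means exactly zero — rates come from parameters, not arithmetic — so
no tolerance is applied when deciding reachability.

## Evolutionary paths

A path is a WT-to-absorbing sequence of single-event gains; its
probability is the product of jump-chain step probabilities, i.e. the
probability of that event *order* conditional on full progression, with
the observation clock excluded — this keeps the path probabilities summing
to 1 and matches the usual "probability of an evolutionary path" notion.
Untimed models define no dynamics, so we adopt and document a convention:
the step probability of event e at genotype g is param(e) normalised over
all currently satisfiable absent events. Absorbing states may be proper
subsets of the full event set (XOR dead ends; MHN with strong inhibition
still has all-positive rates, so only the full genotype absorbs there).
Enumeration is depth-first with a configurable cap (default 1e6 paths)
that errors rather than silently truncating; `top_paths()` gives the
deterministic head (probability descending, ties lexicographic).

## Sampling and observational error

`sample_genotypes()` draws i.i.d. individuals from any genotype
distribution; `gillespie_sample()` instead simulates the generative story
(exponential waiting times, competing risks, censoring at the observation
time) and serves as the independent oracle — the two are required to be
statistically indistinguishable (chi-square, and total-variation distance
below 0.02 at N = 1e5).

Observational (genotyping) error is a single symmetric per-cell flip
probability epsilon in [0, 0.5], applied independently to every cell —
the simplest model consistent with user-specified genotyping error levels;
asymmetric false-positive/false-negative rates and per-event rates are
deliberate non-goals. `noisy_distribution()` is the exact convolution with
the flip kernel, computed one bit at a time in O(n 2^n); epsilon = 0 is
the identity and epsilon = 0.5 maps every distribution to the uniform.
Internal "model error" of the kind some CBN implementations estimate is
not implemented; only observational noise.

## Fitting

**OT** (`fit_ot`): marginal and pairwise frequencies with a pseudocount of
0.5 on every cell of each 2×2 table; Desper-style edge weights
w(i→j) = 2 log p_ij − log(p_i + p_j) − log p_i − log p_j, with the root
treated as an event present in every individual; maximum-weight branching
by a hand-implemented Chu-Liu/Edmonds algorithm (verified against
brute-force enumeration of all arborescences in the tests); edge
probabilities p(child|parent) = p_{c∧p}/p_p clipped into (0,1). The exact
weight and regularisation vary across the OT literature; this choice is
standard and isolated in one function. Constant columns are rejected with
instructions to remove them.

**MHN** (`fit_mhn`): exact marginal likelihood of the observed genotypes
on the full 2^n lattice, penalised by lambda * sum |theta_ij| over
off-diagonals, maximised by proximal gradient (ISTA): analytic gradients
through the lattice dynamic program (forward-mode product rule over the
reach-probabilities, checked against finite differences), soft-thresholding
of the off-diagonals, backtracking line search, convergence when the
relative change of the penalised objective drops below 1e-8 (cap 500
iterations; non-convergence is flagged in the diagnostics, not thrown).
The objective trace is recorded and is non-increasing by construction.
Initialisation: diagonal at the per-event closed form log(f/(1−f)) (the
exact single-event MLE, since P(mutated) = r/(1+r) at rate r), off-diagonals
0. A `diagonal_only` option fits the independent-rates submodel, which is
also how the CBN/MHN equivalence (empty DAG ≡ diagonal theta) is verified:
with free off-diagonals a small-n MHN at zero penalty is over-parameterised
and the comparison would be ill-posed.

**CBN rates** (`fit_cbn_rates`): BFGS over log-rates of the
observed-genotype likelihood with the DAG fixed and s = 1. Genotypes
incompatible with the DAG have probability zero, so by default the
likelihood is evaluated through the flip kernel with a small epsilon =
0.001, keeping it finite; epsilon is exposed and can be set to 0 when all
observed genotypes are reachable. Every fit's reported log-likelihood is
re-computable through the public prediction path
(`model_log_likelihood()`), and the tests assert this round trip.

## Random models and what the simulations show

`random_dag_model()` draws a random topological order and adds edges
downward (density 0.3 by default; OT draws one parent per node, giving a
random rooted tree); `random_mhn()` draws the diagonal uniformly on
[−3, 3] and off-diagonals on [−2, 2] with sparsity 0.5. Rate defaults
[0.5, 2] and probability defaults [0.1, 0.9] keep the expected number of
events per individual moderate. These generators define the study
conditions for every property test and the acceptance script.

Synthetic data emulate the models' own generative assumptions — i.i.d.
individuals, homogeneous constraints, symmetric genotyping error. Real
tumour data violate several of these (sampling biases, intra-tumour
heterogeneity, event loss, asymmetric error), so passing tests certify the
implementation, not the adequacy of any family for a given dataset.

Problem sizes used throughout the suite and the acceptance script — 200
random models per family at n ≤ 6, Gillespie samples of 1e5, recovery
fits at N = 1e4 — are desk-scale choices that keep each check in seconds
while leaving standard errors well below the asserted tolerances.

## Limitations

- n is capped at 12: all structures are dense over the 2^n lattice by
  design (exactness over scalability).
- Structure learning is provided only for OT; CBN is rate-estimation under
  a fixed DAG, and H-ESBCN / OncoBN are simulate/predict-only.
- No transition probabilities at a fixed finite time t (no matrix
  exponentials): only the jump chain and the exponentially censored
  observation distribution.
- No event loss, back-mutation, latent states, missing data, or
  per-patient sampling times.
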