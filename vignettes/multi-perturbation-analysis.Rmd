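---
title: "Multi-perturbation lesion analysis: models, estimators and the bundled ground-truth network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-perturbation lesion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netlesion)
```

## The problem

Classical lesion inference silences one neural element at a time and reads a
causal contribution off the resulting behavioural deficit. That logic fails
whenever function is carried by coalitions of interacting elements: an
element can be critical yet replaceable (its single lesion shows nothing), or
a second lesion can *restore* a deficit produced by a first one — the
paradoxical-lesion, or Sprague, effect. `netlesion` implements the
multi-perturbation alternative on recurrent artificial neural networks whose
ground truth is fully known: every node and connection can be severed in any
combination, and causal contributions are estimated from the performance of
all (sampled) lesion combinations rather than single-site lesions.

The package provides five analysis layers over a common network model:

* **SPA** — single-element perturbation analysis: lesion one element, compare
  the score distribution against the intact one.
* **MSA** — multi-perturbation Shapley value analysis: treat elements as
  players in a coalition game and estimate each element's Shapley value.
* **PCIA** — pairwise causal interaction analysis: joint and conditioned
  Shapley values per element pair, an interaction term, and detection of
  paradoxical-lesion pairs.
* **FC/IFC** — functional connectivity of node time series and the impact of
  each lesion on it.
* **Inference** — mean-shift bootstrap hypothesis tests with Bonferroni
  correction, percentile bootstrap CIs, and rank-sum control comparisons.

## The network model

A genome is a set of node genes and connection genes. Each non-input node
carries a bias $b$, a response multiplier $r$, an aggregation function (at
least `sum` and `max` are registered) and an activation function (`sigmoid`,
`identity`, `tanh`, `relu`). Connections carry a weight and an enabled flag;
disabled connections are pseudogenes and are removed by `prune_disabled()`
before analysis. The update is synchronous with a one-step delay:

$$a_n(t) = \phi_n\!\left(b_n + r_n \cdot
  \mathrm{agg}_n\{\, w_{m \to n}\, x_m \,\}\right),$$

where $x_m$ is the current stimulus for input sources and the previous
activation for recurrent sources; a node whose surviving incoming set is
empty aggregates 0 and emits $\phi(b)$. Synchronous updating is the simplest
reproducible contract that supports self-loops; nothing in the analyses
depends on a finer schedule. The sigmoid is the plain logistic — for
$|z| \gtrsim 37$ the double-precision value is exactly 0 or 1, so no
explicit clamping is needed.

A lesion is a severed connection: a masked connection passes zero, exactly
like a disabled gene. Node lesions sever all incoming *and* outgoing enabled
connections (a `scope` argument restricts this if a study wants
outgoing-only lesions). The chosen action at each timestep is the output
node with maximal activation, ties broken by the lowest id — determinism
matters more than the tie rule itself.

## The coalition game and the Shapley value

For an element set $N$ the characteristic function is
$v(S) = $ mean score of the network with every element outside $S$ lesioned;
$v(N)$ is intact performance. The marginal importance of element $i$ to a
coalition $S \not\ni i$ is $\Delta_i(S) = v(S \cup \{i\}) - v(S)$ and the
Shapley value averages it over all orderings:

$$\gamma_i = \frac{1}{n!} \sum_{R} \Delta_i(S_i(R)),$$

with $S_i(R)$ the set preceding $i$ in ordering $R$. `exact_shapley()`
evaluates the algebraically equal subset-weighted form
$\sum_{S \subseteq N \setminus i} \frac{|S|!\,(n-|S|-1)!}{n!} \Delta_i(S)$
over the full $2^n$ lattice (capped at $n = 12$); `sampled_shapley()` draws
orderings uniformly with replacement and walks each prefix chain, which
costs at most $n + 1$ coalition evaluations per ordering thanks to the
coalition cache.

Two design rules make the estimator exact where it can be:

* **Frozen replicate streams.** A stochastic game's value at coalition $S$
  is the mean of `plays_per_eval` episodes whose noise streams derive
  deterministically from (seed, $S$, replicate). Revisiting a coalition
  returns the identical value, so each sampled ordering telescopes exactly:
  $\sum_i \Delta_i(S_i(R)) = v(N) - v(\emptyset)$, and efficiency holds
  per permutation, not just in expectation.
* **Cache delegation.** Compound and conditioned games (below) map their
  subsets onto base-game subsets, so an entire PCIA shares one coalition
  cache.

Efficiency is reported as $\sum_i \gamma_i = v(N) - v(\emptyset)$; the
fully-lesioned baseline $v(\emptyset)$ is generally positive, and
`cmd_msa()`'s manifest reports the raw sum, $v(N)$, $v(\emptyset)$ and the
residual so either convention can be audited. On the bundled fixture the
baseline is in fact *maximal*: with every connection severed, the rewarded
output's bias makes it the default winner, so a fully-lesioned network
plays the target action on every step and $\sum_i \gamma_i$ is slightly
negative. This is a deliberate property of a lesion-tolerant design — the
intact machinery (distractor, "no action" unit) can only degrade a policy
that is already optimal by default — and a concrete reminder that Shapley
totals are relative to the empty-coalition baseline, not to zero.

## PCIA and the Sprague condition

For a pair $(i, j)$, three Shapley values are computed on games derived from
the same base game: the joint value $\gamma_{(ij)}$ of the fused compound
element (intact iff both are intact), and the conditioned values
$\gamma(i,\bar{j})$ and $\gamma(j,\bar{i})$, each computed on the pool
$N \setminus \{j\}$ (resp. $\{i\}$) with the partner permanently lesioned
and all other elements participating as usual. The interaction term

$$I_{i,j} = \gamma_{(ij)} - \gamma(i,\bar{j}) - \gamma(j,\bar{i})$$

is positive for net-synergy and negative for net-redundancy (these are
behavioural, not information-theoretic, notions). Pairs are screened by
excluding interactions within $\pm k$ SD of the mean (default $k = 2$,
population SD over the unique off-diagonal entries; an entry exactly at the
mean is never retained, which keeps the $k = 0$ boundary meaningful). For
each ordered direction of a surviving pair, a paradoxical-lesion edge
$i \to j$ is emitted iff

$$\gamma(i,\bar{j}) < 0 \quad\text{and}\quad I_{i,j} + \gamma(i,\bar{j}) > 0,$$

i.e. $i$ hinders performance while $j$ is lesioned, yet the pair's joint
contribution exceeds $j$'s own conditioned contribution.

**Estimator choice.** The Sprague condition compares quantities that can be
an order of magnitude smaller than the interaction itself (on the bundled
fixture, $\gamma_{(ij)} - \gamma(i,\bar{j})$ is roughly +12 score units
against an interaction of ~1600). Permutation sampling at the protocol
budget of 100 orderings has Monte-Carlo noise of the same size, which would
make edge detection a coin flip. For games of up to 13 elements the package
therefore enumerates the pair games exactly — since all pair games share the
base cache, enumeration costs no more than sampling, which visits nearly the
whole subset lattice anyway. Beyond 13 elements PCIA falls back to sampling
with a configurable budget (default 100 per estimate).

## Functional connectivity and IFC

FC is the Pearson correlation matrix of the non-input nodes' activity over a
single episode; the lesioned network is run on the *same* stimulus as the
intact reference so that all FC change is attributable to the lesion.
Zero-variance (silenced) series get correlation 0 and a flag rather than
`NA`, keeping matrices comparable. The impact on functional connectivity is
the absolute element-wise sum of the FC difference over the full matrix
(both triangles; the diagonal difference is zero). The degenerate-fill rule
has a visible consequence: lesions that silence a node to a constant zero
out whole FC rows and therefore produce large IFC values even when
behaviour is untouched — which is precisely the dissociation between IFC
and Shapley values that the FC layer is meant to expose.

## Statistical inference

`bootstrap_p()` implements a mean-shift bootstrap: the sample is shifted so
its mean equals the null mean, resampled with replacement `n_boot` times
(default 10000), and the p-value is the add-one-corrected fraction of
bootstrap means at least as extreme as the observed mean (two-sided by
default; the floor is $1/(n_{boot}+1)$). Shapley values are tested against a
null mean of 0, lesioned score distributions against the intact mean.
Multiple comparisons use Bonferroni correction only
(`alpha / n_tests`). Control comparisons (intact versus noise-fed or
weight-shuffled networks) use the tie-corrected Mann-Whitney U test. The
test's type-I error is calibrated at the protocol's sample size: with null
datasets of 512 values (the 512-trial convention) the empirical rejection
rate at $\alpha = 0.05$ is ~0.05, while at $n \approx 30$ the mean-shift
scheme is mildly anti-conservative (~0.065) — a property worth knowing
before applying it to small samples.

## The bundled ground-truth fixture

`make_motif_genome()` returns a 13-node network (inputs $-1..-4$, outputs
$0..5$, hidden $6, 7, 9$) built around an inhibitory self-loop motif:

* Channel $-1$ carries a slowly decaying oscillation $s(t)$; channel $-4$
  carries $1 - s(t)$ plus Gaussian noise (sd 0.05) — an anticorrelated
  drive pair. Remaining channels are iid Uniform[0, 1] distractors.
* Output 0 ("no action") has bias $-0.9$ and receives the positive drive
  $(-4 \to 0)$ (weight 2) and the negative self-loop $(0 \to 0)$ (weight
  $-4$). Intact, it hovers suppressed around 0.4; with the self-loop cut it
  follows the drive up to ~0.75 and dominates the readout.
* Output 4 (the rewarded action) is driven by $(-1 \to 4)$ and by two steep
  hidden detectors of node 0's state: unit 6 fires in the
  suppressed-but-driven regime ($a_0 > 0.33$) and unit 7 in the silenced
  regime ($a_0 < 0.22$, firing fully when its input is severed). Output 2
  is a noise-driven distractor that keeps the task from saturating.
* Hidden unit 9 is a coincidence detector on channels $-1$ and $-4$: under
  the anticorrelated stimulus their sum is ~1 and the unit is silent; under
  unstructured input it fires and suppresses output 4. This is what makes
  the noise-as-input control score below the intact network.
* Outputs 1, 3, 5 are inert (bias $-4$); two disabled connection genes act
  as pseudogenes for the pruning path.

The behavioural contract this fixture satisfies (all via simulation, see
`test-toytask.R` and `test-acceptance.R`): intact $\geq 0.8$ of maximum;
masking $(0\to 0)$ alone $\leq 0.3$; masking both $(0 \to 0)$ and
$(-4 \to 0)$ restores $\geq 0.8$; masking $(-4 \to 0)$ alone, or lesioning
node 0 entirely, stays within 5% of intact. The first three clauses are the
paradoxical-lesion effect; the contrast between clause two and the node-0
lesion is the SPA blind spot that MSA resolves.

### Why node 0 aggregates by summation

With `max` aggregation over weighted inputs, a negative-weight self-loop can
never influence a node that also receives a non-negative drive: the maximum
of a positive product and a negative product is always the former. An
inhibitory self-loop motif therefore requires summation at the motif centre,
and the fixture uses it; `max` aggregation remains available and tested for
other nodes and genomes.

### Design tensions behind the weights

The weights are fixed constants chosen once (recorded in the genome and its
JSON fixture) to satisfy the contract, and two tensions shaped them. First,
the contract caps the full-network benefit of the drive-given-self-loop at
5% of maximum, yet the Sprague edge condition needs exactly that benefit,
averaged over coalitions, to be positive — the fixture resolves this with
the unit-7 rescue path, which substitutes for the drive in the full network
but is absent from enough coalitions to leave a positive average. Second, a
strong self-loop makes intact node 0's activity oscillatory (rich dynamics,
hence a large FC impact when released), but pushes its activity peaks toward
output 4's winning threshold, injecting coalition noise; raising output 4's
bias and widening the distractor's range buys the headroom for the strong
self-loop. Alternative weightings satisfying the same contract exist; only
orderings and ratios, never absolute scores, are meaningful.

### What the fixture does and does not emulate

It reproduces the statistical structure the analyses assume: anticorrelated
driving inputs, winner-take-all action readout, a performance score with
trial-to-trial noise, one strongly synergistic pair with a directional
paradoxical-lesion effect, near-null elements, and controls (noise-as-input,
weight-shuffled) that score below intact. It does not emulate a real game's
reward structure (lives, waves), frame preprocessing, learned
representations, or plasticity; passing tests on the fixture show the
estimators and detection machinery are correct, not that any particular real
network has these properties.

## Protocol constants and problem sizes

Defaults follow the study protocol: 512 trials of 16 plays per lesion
experiment, 1000 MSA permutations, 100 PCIA permutations per estimate,
10000 bootstrap resamples, $\alpha = 0.05$, $\pm 2$ SD interaction
screening. The test-suite and the acceptance script scale the simulation
sizes down (32-trial / 4-play protocols, 200 MSA permutations, exact PCIA
over the 2^11-subset lattice, 2000-resample bootstraps except where the CI
width itself is measured), sizes chosen so the full suite completes in a few
minutes on one CPU while every qualitative result remains stable across
seeds.

## Known limitations

* The fixture's element set is small enough for exact enumeration, so the
  sampled-PCIA path is validated on canonical and random games rather than
  on the fixture itself.
* A weight-shuffled control occasionally lands on a functional wiring
  (roughly 1 in 4 shuffles); control comparisons should average several
  shuffles, as the tests do.
* The mean-shift bootstrap is anti-conservative below $n \approx 100$;
  use the protocol-sized distributions it was designed for.
* Node silencing inflates IFC through the degenerate-row rule; comparisons
  of IFC across lesions of different kinds (silencing versus releasing)
  should keep this in mind.

## A worked pipeline

```{r pipeline, eval = FALSE}
g <- make_motif_genome()
cfg <- run_config(n_permutations = 200, n_trials = 32, plays = 4,
                  n_boot = 2000, seed = 1, out = "motif-results")
cmd_spa(cfg)    # spa.tsv: (0->0) most deleterious, node-0 lesion silent
cmd_msa(cfg)    # msa.tsv: gamma ranks; rank_comparison.tsv: SPA vs MSA
cmd_pcia(cfg)   # interaction_matrix.tsv, sprague_edges.tsv
cmd_fc(cfg, msa_table = file.path("motif-results", "msa.tsv"))
```
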