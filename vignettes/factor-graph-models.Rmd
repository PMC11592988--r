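---
title: "Building and constraining Forney-style factor graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and constraining Forney-style factor graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffgraph)
```

## The model class

ffgraph represents a factorized generative model

$$p(s) = \prod_{a \in V(G)} f_a(s_a)$$

as a Forney-style factor graph (FFG): a bipartite graph whose factor nodes
are the functions $f_a$ and whose variable nodes connect the factors that
share them. A group of factors, once its internal variables are marginalized
out, interacts with the rest of the graph only through its boundary-crossing
variables — its Markov blanket. "Closing the box" around such a group is what
makes models composable: any previously defined graph can stand in as a
single node of a larger graph, and `ffgraph` records that nesting in a
context tree alongside the flat bipartite structure.

Two departures from the textbook FFG drawing are deliberate:

* **Variables are nodes, not edges.** The classical drawing treats a
  variable as an edge and therefore limits it to two endpoints, inserting
  equality factors when a variable is shared more widely. Realistic models
  (state-space chains, parameter sharing across time steps) routinely attach
  one variable to many factors, so the data model stores a variable once
  with arbitrary degree. The equality-node expansion survives as a rendering
  option (`to_dot(g, strict_ffg = TRUE)`).
* **Constants are never deduplicated.** Each statement that mentions a
  literal creates a fresh constant variable node. `theta ~ Beta(1, 1)`
  therefore creates one factor and three variables — `theta` plus two
  constants — which keeps the graph a faithful record of the statements
  that produced it.

## Statement semantics

Models are written against a recording builder rather than through operator
overloading: the host language has no user-definable `~`, and the semantics,
not the surface syntax, is the contract. The core operation is

```{r, eval = FALSE}
tilde(m, "y", fg_call("Normal", fg_ref("x"), fg_call("exp", fg_ref("u"))))
```

which materializes `y ~ Normal(x, exp(u))`. The builder implements:

* **Compound unrolling.** Nested calls are lifted into anonymous
  intermediates named `<lhs>_tmp_<k>` (a per-context counter starting at 0,
  so names are deterministic and collision-free), innermost-first and
  left-to-right; the final primitive statement binds the original left-hand
  side.
* **Deterministic folding.** A deterministic node type whose arguments are
  all known at construction time (literals, or references to constant nodes)
  is evaluated immediately and its result bound in the context — no nodes are
  created. With at least one random or data argument the relation is kept in
  the graph as a deterministic factor. Folding happens per primitive
  statement, so known subexpressions of a compound statement collapse while
  the random remainder materializes.
* **`:=` as an alias.** The deterministic-assignment relation runs through
  exactly the same operation as `~`; the relation flag is recorded for
  rendering only.
* **Vector variables on first touch.** `at(x, k)` addresses element `k`
  (0-based, matching the serialization format — the one place the package
  departs from R's 1-based convention, chosen so that indices mean the same
  thing in the builder, the JSON documents and the DOT output);
  `get_or_create_indexed()` creates missing elements as random variables, so
  a transition and the observation it explains can be introduced on one
  line.
* **Keyword aliasing.** `Normal(mean = , var = )`,
  `Normal(mean = , precision = )`, `Normal(xi = , var = )` and
  `Normal(nu = , tau = )` resolve to the four concrete parameterizations
  (`NormalMeanVariance`, ..., `NormalWeightedMeanPrecision`) with arguments
  reordered per rule. A positional `Normal(m, v)` stays generic. Alias rules
  are data, so backends can register their own.

Submodel invocation supplies all but one interface by keyword; the missing
interface is detected by set difference (never positionally) and bound to the
left-hand side of the invoking statement. Each invocation increments a
per-parent counter, giving contexts stable paths such as `hgf/gcv_lm:1/gcv:0`.

## The variational-constraints plugin

Payloads attached by one plugin are invisible to every other plugin; the
variational-constraints plugin stores functional-form tags on variables and
the resolved local factorization on the graph.

A factorization constraint (FC) such as $q(x, y, z) = q(x)\,q(y)\,q(z)$
refines the Bethe family, in which each factor carries a joint belief
$q_a(s_a)$ over all its interfaces and each variable an edge belief $q_i$.
Resolution works per factor: every applicable FC induces a partition of the
factor's interfaces (mentioned interfaces grouped by FC block, all
unmentioned interfaces in one remaining cell), and the resolved partition is
the coarsest common refinement — the lattice meet — of the Bethe default and
all induced partitions. Two consequences worth spelling out:

* a mean-field FC over named variables isolates those variables in every
  factor they touch, even when anonymous intermediates sit between them;
* two FCs conflict only if one separates a pair of variables the other
  holds together; compatible overlaps are merged silently.

Constraint scopes are model-name paths: a constraint declared for scope
`gcv` applies in every invocation of `gcv`, wherever it is nested and
whatever its invocation counter. Constraints may mention data-bound
variables (their beliefs are clamped by the engine), but naming a
construction-time constant is an error: beliefs range over latent and
observed quantities, not over literals. Functional-form constraints
(`q(x) :: Beta`) tag single variables with a registered family.

## The reference engine

The engine exists to make every produced graph executable and testable at
desk scale, with exactness where exactness is checkable:

* **Enumeration** (`brute_force()`) clamps data and constant nodes,
  enumerates the joint latent state space (capped at $10^7$ states) in log
  space, and returns marginals and the log evidence. It is the oracle the
  rest of the engine is tested against.
* **Sum-product** (`sum_product()`) runs a two-pass leaf-to-root-to-leaf
  schedule on acyclic graphs (exact; per-message normalizers are accumulated
  so the log evidence is recovered) and damped flooding (damping 0.5,
  synchronous sweeps) on cyclic graphs, where it is the usual loopy
  approximation: convergence is reported, not guaranteed.
* **Bethe free energy** (`bethe_free_energy()`) is assembled as
  $$F = \sum_a \sum_{s_a} q_a \log\frac{q_a}{f_a} \;+\; \sum_i (d_i - 1)\, H[q_i],$$
  with $d_i$ the latent degree of variable $i$. The degree multiplicity on
  the edge-entropy term follows from the counting correction in the Bethe
  family ($q_i$ appears once per incident factor and must be discounted
  $d_i - 1$ times); the tree identity $F = -\log Z$ at converged beliefs,
  checked against enumeration, pins the convention down. Belief mass on a
  zero-probability cell yields `+Inf` with a `SupportMismatch` diagnostic
  rather than `NaN`.
* **Constraint checks** (`check_constraints()`) verify the normalization and
  block-marginalization conditions that make a belief set a valid
  distribution.
* **Conjugate coordinate ascent** (`cbfe_coordinate_ascent()`) covers the
  three closed-form families: Beta–Bernoulli, Gaussian mean with known
  precision, and the Normal–Gamma mean field. The free energy is evaluated
  after every update; the trace must be non-increasing (violations beyond
  1e-9 are reported as diagnostics, never silently accepted). Anything
  outside these families raises `NotSupported` — there is no general-purpose
  continuous message approximation here by design.
* **Gaussian-chain smoothing** (`ssm_smooth()`) is the conjugate reduction
  of the hierarchical state-space model: with noise variances and the
  observation precision treated as known, the joint (drift, state) chain is
  linear-Gaussian, and Kalman filtering with Rauch–Tung–Striebel smoothing
  gives exact marginals plus the log evidence via the prediction-error
  decomposition. It is validated against a direct joint-precision-matrix
  solve in the tests.

## The synthetic experiment and its defaults

`generate_ssm_data()` draws from

$$d_t = d_{t-1} + \varepsilon_d, \qquad
  x_t = x_{t-1} + d_t + \varepsilon_s, \qquad
  y_t = x_t + \varepsilon_o,$$

a random walk with drift whose drift is itself a random walk. Hyperparameter
defaults are the package's own choices, since the graphical presentation of
this model customarily omits them: drift-increment variance 0.01 (a slowly
wandering trend), state-noise variance 0.1, observation precision drawn once
from Gamma(shape 2, rate 2) (mean precision 1, i.e. observation noise of the
same order as the signal), and standard-normal initial states. All are
configurable through `ssm_params()`. The draw order is fixed, so a seed
pins the dataset bit-for-bit.

What the generator emulates is the dependence structure — hierarchical
drift, additive Gaussian noise, an unknown but time-constant observation
precision. What it does not emulate: heavy-tailed or heteroscedastic
observation noise, missing observations, or model misspecification. Tests
passing on this data show the machinery is self-consistent (builder,
constraints and inference agree with independent oracles); they do not show
robustness on real data.

The bundled experiment uses 100 time points. Inference on the materialized
graph proper would require nonlinear continuous message passing (the
observation precision is Gamma, making the model non-Gaussian jointly);
that is out of scope, so the reference inference runs on the conjugate
reduction with the drawn precision treated as known and is judged by drift
RMSE against the generating series. Under the default parameters the RMSE
(about 0.12 at seed 1) sits far below three observation-noise standard
deviations, reproducing the qualitative recovery result.

## Numerical choices and degenerate inputs

* Messages are normalized after every update with log-scale accumulators;
  uniform fallback replaces an all-zero message (possible with zero table
  entries) instead of dividing by zero.
* Enumeration works in shifted log space, so widely scaled tables do not
  overflow.
* `0 log 0` is taken as 0 throughout entropies and KL divergences; KL raises
  `SupportMismatch` when the candidate has mass where the reference has
  none.
* An empty constraint set resolves to the pure Bethe default (one joint
  block per factor); scope patterns matching no context produce a
  warning-level diagnostic, not an error, so constraint documents can be
  written before the model is final.
* Coordinate ascent stops when the free energy improves by less than `tol`
  (default 1e-12 nats) or at `max_iters`; for the conjugate families one
  sweep is already exact, and the trace makes that visible.
* The coin model is handled along two independent routes — grid enumeration
  (201 midpoints, avoiding the endpoints where a Beta density may diverge)
  and parametric conjugate updates — which cross-validate each other in the
  tests.

## Design choices where the design was open

* FCs are restricted to a single scope; a constraint spanning variables of
  different submodels is not expressible, and scope resolution logs a
  diagnostic on unmatched patterns instead of guessing.
* `new`-style auto-creation applies to indexed names only; a bare scalar
  name on a right-hand side must already be bound, which catches typos that
  silent scalar creation would hide.
* The interface order of `gcv` is `(y, x, z, kappa, omega)`; order is
  non-semantic since submodels are invoked by keyword.
* The hierarchical Gaussian filter's top layer defaults to a plain Gaussian
  random walk, and the neural building blocks use `tanh` as activation; both
  live in the model zoo, not in the language.
* Problem sizes in the test suite (up to 8 variables and domain 4 for random
  graphs, 200 seeded replicates, T = 100 for the state-space experiment) are
  chosen so the whole suite runs in well under a minute while still
  exercising every code path against an exact oracle.

## Known limitations

* Discrete inference only, plus the listed conjugate families; the nonlinear
  controlled-variance models materialize as graphs but are not numerically
  inferable here.
* Flooding on cyclic graphs inherits loopy BP's failure modes (oscillation,
  bias at strong coupling); damping mitigates, the convergence flag reports.
* The enumeration cap makes the oracle unusable beyond ~$10^7$ joint states;
  that is intentional — it is a reference, not a production engine.
* Graphs are mutable environments; copying a graph means serializing and
  re-parsing (`from_json(to_json(g))`), which is also the supported way to
  snapshot one.
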