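---
title: "Pareto MCTS for multi-objective molecule generation: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pareto MCTS for multi-objective molecule generation: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paretomcts)
```

## The decision process

Token-by-token molecule generation is a Markov decision process. A state is
the pair (protein sequence, molecule fragment `a_1⋯a_τ`); an action appends
one vocabulary symbol; the episode ends when the reserved terminal symbol
`$` is emitted. Rewards are sparse: only a completed molecule is scored, with
one value per objective. An autoregressive policy — in production an
external pretrained SMILES model behind `external_policy()`, in tests a
`tabular_policy()` — supplies the prior `P(a | C)` over next tokens given
the context `C`.

The search engine makes three structural assumptions:

* the policy's distribution is a valid probability vector over a fixed
  vocabulary (validated on every call, tolerance `1e-6`);
* every objective can be evaluated on a terminal token string, with
  unparsable strings signalled as a condition rather than a value;
* objectives are comparable only through Pareto dominance — no weights, no
  scalarisation.

## Dominance, the pool, and the reward

All metrics are oriented so that larger is better before any comparison:
minimise-type metrics (synthetic accessibility) are negated, and the LogP
objective is the 0/1 indicator of the closed druggable window
`[-0.4, 5.6]`. With that orientation, `x` weakly dominates `y` when
`x ≥ y` componentwise and strictly when some component is larger;
`pareto_front()` returns the rows not strictly dominated by any other.

A single global pool archives every generated molecule whose metric vector
is not strictly dominated by a current member; admission evicts members the
newcomer strictly dominates, and molecules are deduplicated by canonical
token string. The reward of a candidate with metrics `h` is computed
*against the pool before it is offered*:

$$ r_i = \frac{1}{N_P} \sum_{k=1}^{N_P} \mathbb{1}\!\left[h_i \ge h_i^k\right] $$

so each component is the fraction of archived molecules the candidate
matches or beats in that dimension — scale-free and weightless. Two edge
conventions are deliberate:

* **Empty pool.** The formula divides by `N_P`; at `N_P = 0` we return the
  all-ones vector: the first molecule vacuously beats an empty front and
  should be reinforced maximally.
* **Tie handling.** The indicator uses `≥`, so a candidate equal to an
  archived molecule in a dimension is credited for it. The strict variant
  (`>`) would zero the reward of every re-discovered front member, which
  destabilises the search around plateaus; with `≥`, equal vectors also
  coexist in the pool, since equality never strictly dominates.
* **Self-comparison.** Rewards are computed before the pool update; scoring
  a molecule against a pool that already contains it would inflate `r`.

## The search loop

Each token decision runs `iterations` simulations (default 150) of the
classic four steps from a fresh root:

1. **Selection.** For every child, the vectorial score
   $U_p(a) = W_a / N_a + c\,P(a|C)\,\sqrt{N}/(1 + N_a)$ is computed; the
   scalar exploration bonus is added to every component. The next node is
   drawn uniformly at random from the Pareto front of the children's
   scores. At `N_a = 0` the exploitation term `W_a/N_a` is `0/0`; we use the
   zero vector, the standard PUCT convention that lets the prior term rank
   unvisited children.
2. **Expansion.** A reached leaf gets one child per legal token,
   initialized to `{N_a = 0, W_a = 0, prior = P(a|C)}`. Expansion is
   idempotent.
3. **Rollout.** The fragment is completed greedily (argmax of the policy)
   until `$` or the depth cap. Depth-capped rollouts are flagged incomplete
   and treated as invalid molecules.
4. **Backup.** The reward vector is added along the selected path:
   `N_a ← N_a + 1`, `W_a ← W_a + r`, up to the root — so `W_a/N_a` is the
   empirical mean reward of passing through `a`.

Invalid molecules — unparsable strings, depth-capped rollouts, and the
empty molecule `"$"` — receive the zero reward vector, are backed up
normally, and never enter the pool: failure is penalised without aborting
the search.

### Numerical and structural choices

* **Legal actions at the depth cap.** `max_depth` bounds the number of
  non-terminal tokens. A fragment at the cap has exactly one legal action,
  the terminal symbol, with its prior renormalised to 1. Without this the
  deepest layer of molecules would be unreachable by the tree while still
  being counted by the enumeration oracle.
* **Move rule.** After the simulation budget, the engine commits the
  most-visited child — the robust PUCT move statistic — with ties broken by
  larger mean-reward sum `Σ W_a/N_a`, then lexicographic token order, so
  runs are fully deterministic given a seed.
* **Fresh tree per decision.** The tree is rebuilt for each token position
  rather than re-rooted. Subtree reuse is a pure efficiency device; a fresh
  tree keeps the per-decision budget accounting exact (`root N = IT`) and
  the visit-conservation invariant trivial to audit. The global pool, which
  carries all cross-decision knowledge, persists regardless.
* **Tie-breaks elsewhere.** Greedy rollouts resolve argmax ties by first
  vocabulary index; uniform front draws use R's RNG, seeded once per
  generation run, so equal seeds give byte-identical outputs.
* **Collecting `n` candidates.** The pool may be shared across `n`
  independent runs (default, seeds derived as `seed + 0:(n-1)`) or kept
  private per run — both behaviours are exposed because either reading of
  "collect 10 molecules per target" is defensible.

## Multi-target fusion

For `m` protein targets sharing one vocabulary, per-target predictions are
mean-pooled: $f(P_1,\dots,P_m)(a) = \frac{1}{m}\sum_i P_i(a|C_i)$. The
fusion preserves normalisation, is order-invariant, bounds the fused
probability by the member extremes, and keeps any token unanimously ranked
first. Because the multi-target selection score differs from the
single-target one only in the prior term, plugging the fused prior into the
ordinary ParetoPUCT score reproduces the multi-target criterion exactly —
an algebraic identity the test suite checks to `1e-12`. All multi-target
logic therefore lives in `fused_policy()`; the search engine is
target-count agnostic.

## Objectives

The default chemistry profile is QED (maximise), SA score (minimise,
1 = easy to 10 = hard), NP-likeness (maximise, roughly −5 to 5) and the LogP
window indicator. Descriptors are computed by RDKit's reference
implementations (including the SA and NP contribution scorers) through a
batch python bridge; values are cached per session and the RDKit version is
recorded in result metadata, since the contribution-based scorers can drift
across releases. Binding affinity enters through a smina-compatible docking
adapter that negates the reported best energy (higher = better,
kcal·mol⁻¹); docking is strictly optional and activates only when an
executable and receptor are configured, with misconfiguration caught at
setup rather than mid-search. Surrogate token-count objectives stand in for
docking wherever the pipeline must run without chemistry.

## What the toy MDP does and does not show

The synthetic fixture — vocabulary `{A, B, $}`, at most three letters,
conflicting objectives (countA, countB) — has 15 terminal strings, so the
true Pareto front is computable by brute force and every search property is
checkable exactly: front recovery under a uniform prior (2,000 iterations,
ten seeds), the single-objective reduction to scalar PUCT (token-for-token
against an independent reference implementation), visit conservation and
reward bounds, and the value of exploration under a deliberately deceptive
prior (0.9 mass on a misleading token), where `c = 1` recovers strictly
more of the front than the pure-exploitation limit `c = 0`. The
exploitation-only failure mode is structural: a child whose reward vector
is still zero is strictly dominated by any sibling with positive mean
reward and is never revisited without the exploration bonus.

These tests validate the *search machinery*, not chemistry. The toy space
is tiny, its objectives are smooth functions of token counts, and its
policy is unconditioned on the protein; real chemical space is vastly
larger, SMILES validity is brittle, and descriptor landscapes are rugged.
Passing the toy suite shows the engine orders, archives, and explores
correctly — it does not certify discovery performance with a real
pretrained policy, which additionally depends on model quality and docking
fidelity.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `c` | 1.0 | exploration constant scaling the prior bonus (unitless); 0 = pure exploitation |
| `iterations` | 150 | simulations per token decision |
| `max_depth` | 100 | maximum non-terminal tokens per molecule |
| `seed` | 1 | RNG seed; recorded in every run log |
| `n_molecules` | 1 | candidates collected per target |
| `share_pool` | TRUE | one archive across the `n` runs |

The iteration default matches the per-token budget used in comparable
MCTS-guided generation work; `c` is exposed rather than fixed because the
right balance depends on the policy's calibration. Problem sizes used by
the shipped checks (2,000-iteration toy searches, 200-vector front
comparisons, 150-iteration reduction runs) were chosen so the complete
suite audits every invariant on an ordinary workstation in well under a
minute.

## Known limitations

* No transposition tables, virtual loss, or parallel search; the engine is
  single-threaded by design.
* Descriptor scoring shells out to python per batch; per-molecule calls
  inside a chemistry-objective search are cached but still subprocess-bound,
  so real chemistry runs want a persistent policy/scorer service behind the
  adapter.
* The pool is unbounded; with many objectives (`d ≳ 5`) non-dominated sets
  grow quickly and pool updates are `O(N_P)` per candidate.
* The docking adapter trusts the external program's output format
  (smina-style affinity tables) and does not manage 3D conformer
  generation.
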