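# paretomcts

Multi-objective Pareto Monte Carlo Tree Search for target-aware,
atom-by-atom molecule generation.

## The problem

De novo drug design is inherently multi-objective: a useful ligand must bind
its protein target *and* be drug-like, synthesizable, and within a sensible
lipophilicity window — demands that routinely conflict. Generative models
conditioned on a protein can propose binders, but greedy or beam decoding of
an autoregressive policy optimizes none of these properties explicitly and is
easily trapped in local optima of chemical space.

`paretomcts` treats token-by-token molecule generation as a Markov decision
process and searches it with a Pareto Monte Carlo Tree Search: a pluggable
next-token policy (a pretrained SMILES model behind an adapter, or a shipped
tabular toy policy for testing) guides the tree, while a **global Pareto
pool** archives every generated molecule not strictly dominated in the vector
of property objectives. It is aimed at computational chemists and
method developers who want a transparent, fully testable search engine around
whatever policy and objective set they bring.

## The method

All objectives are oriented "higher is better" (minimise-type metrics are
negated; the LogP objective is the indicator of the druggable Ghose window
`[-0.4, 5.6]`). For a rollout molecule with property vector
*h* = (h₁, …, h_d), the reward against a pool of N_P archived molecules is
per-dimension, scale-free:

    r_i = (1/N_P) Σ_k  1[ h_i ≥ h_i^k ],   i = 1…d

Each tree node stores a visit count N_a and a cumulative reward **vector**
W_a, updated by the backup N_a ← N_a + 1, W_a ← W_a + **r**. Child selection
uses the vectorial **ParetoPUCT** score

    U_p(a) = W_a / N_a + c · P(a|C) · √N / (1 + N_a)

where P(a|C) is the policy prior given the protein context and fragment, and
c trades exploration against exploitation. Because U_p is a vector, the
chosen child is drawn uniformly at random from the Pareto front of the
children's scores. For multi-target design, per-target policies are fused by
mean pooling, P(a) = (1/m) Σᵢ Pᵢ(a|Cᵢ), which is exactly equivalent to the
multi-target selection criterion.

Post-hoc evaluation covers uniqueness across targets (deduplicated-union
ratio), best-molecule selection by largest reward-vector sum,
Pareto-dominance reports against reference drugs, and QED / SA / NP-likeness /
Crippen LogP descriptors computed with RDKit's reference implementations
through a batch python bridge. A smina-compatible docking adapter (negated
binding energy, higher = better) is available when an executable and receptor
are configured; nothing in the package requires it.

## Worked example

The enumerable toy MDP (tokens `A`/`B`, terminal `$`, conflicting objectives
countA vs countB, maximum 3 letters) makes the search auditable end to end:

```r
library(paretomcts)

mdp    <- toy_mdp(c("A", "B"), max_len = 3)
policy <- uniform_policy(mdp$vocabulary)
config <- search_config(c = 1, iterations = 500, max_depth = 3, seed = 1, d = 2)

run <- generate_molecule("MKVLAAGRS", policy, mdp$objectives, config)
glance(run)
#> # A tibble: 1 × 7
#>   status tokens n_tokens pool_size exploration_c iterations  seed
#>   <chr>  <chr>     <int>     <int>         <dbl>      <int> <int>
#> 1 ok     ABA$          4         8             1        500     1

tidy(run)          # the global Pareto pool
#> # A tibble: 8 × 6
#>   tokens countA countB r_countA r_countB iteration
#>   <chr>   <dbl>  <dbl>    <dbl>    <dbl>     <int>
#> 1 ABB$        1      2    0.5      1           100
#> 2 ABA$        2      1    1        0.5         121
#> 3 AAA$        3      0    1        0           123
#> # … 5 more rows

select_best(run$pool)$tokens
#> [1] "ABA$"
```

The pool holds exactly the eight terminal strings whose count vectors
(3,0), (2,1), (1,2), (0,3) form the true Pareto front — the same set
`brute_force_front(mdp)` computes by exhaustive enumeration — and the
generated molecule `ABA$` lies on it. `autoplot(run)` draws the archived
front with the generated molecule highlighted.

Chemistry scoring works on any SMILES list:

```r
score_properties(c("c1ccccc1", "CC(=O)Oc1ccccc1C(O)=O"))
#> # A tibble: 2 × 7
#>   smiles                canonical             valid  logp   qed    sa     np
#> 1 c1ccccc1              c1ccccc1              TRUE   1.69 0.443  1    -0.154
#> 2 CC(=O)Oc1ccccc1C(O)=O CC(=O)Oc1ccccc1C(=O)O TRUE   1.31 0.550  1.58  0.122
```

A thin command-line front end (`inst/cli/paretomcts.R`) wraps generation,
SMILES-list evaluation and batch uniqueness behind YAML run configurations.

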