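---
title: "Clone-structured cognitive graphs: model, learning and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone-structured cognitive graphs: model, learning and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cscg)
```

## The model

A *cloned hidden Markov model* is an HMM whose emission matrix is a fixed
0/1 block structure: each hidden state ("clone") deterministically emits
exactly one observation symbol, and every symbol `j` owns a contiguous
block `C(j)` of clones. Higher-order temporal structure that a first-order
model on symbols cannot express is absorbed by letting several clones of
the same symbol specialize to different temporal contexts. The
clone-structured cognitive graph (CSCG) augments this with actions: an
agent's experience is the stream
$(x_1, a_1), (x_2, a_2), \dots, (x_{N-1}, a_{N-1}), x_N$ and the joint
density is

$$P(x_{1:N}, a_{1:N-1}) \;=\; \sum_{z_1 \in C(x_1)} \cdots \sum_{z_N \in C(x_N)}
P(z_1) \prod_{n=1}^{N-1} P(z_{n+1}, a_n \mid z_n).$$

The parameters are a prior $\pi$ over the $H$ clones and the transition
tensor $T(i,k,j) = P(z_{n+1}=j, a_n=k \mid z_n=i)$, stored densely as an
`H x nActions x H` array (desk-scale state counts, a few hundred, make
dense storage trivial). Summing the tensor over actions recovers a
standard cloned-HMM transition matrix.

Because emissions are deterministic, the forward and backward recursions
only touch the $M_{x_n} \times M_{x_{n+1}}$ clone blocks of consecutive
symbols: the cost of learning grows with the clone count, never with the
alphabet size. `eStep()` reports the number of block cells visited
(`blockOps`) so this contract is testable.

## Learning

`emFit()` is Baum–Welch specialized to the block structure. Messages are
rescaled at every step and log-scales accumulated, so 50,000-step walks do
not underflow (the model description is silent on scaling; any positive
per-step rescaling cancels in the posterior ratios). Smoothing adds a
pseudocount $\kappa$ to the expected counts, which keeps every transition
possible at test time and acts as a Dirichlet-MAP prior; the penalized
objective (data log-likelihood plus $\kappa \sum \log T + \kappa \sum \log
\pi$) is non-decreasing across iterations and is what the tests assert.

### The two estimators

The M-step can normalize the smoothed counts in two ways, exposed as
`actionNorm`:

* `"joint"` — $T(i,k,j) = (\kappa + c_{ikj}) / \sum_{k'j'} (\kappa +
  c_{ik'j'})$, which also learns the action marginal $P(a\mid z)$. This is
  the update the model equations imply.
* `"conditional"` (default) — per-action row normalization
  $P(z'|z,a) = (\kappa + c_{ikj}) / \sum_{j'}(\kappa + c_{ikj'})$, with an
  action factor uniform over the actions observed at that state so the
  stored tensor remains a valid joint distribution.

The two coincide for a single action, and both are exact EM for their
respective likelihoods. They differ in inference dynamics: under the joint
estimator the forward messages weigh states by how well they predict the
*action* taken, which opens a self-reinforcing channel for clones to
specialize on spurious action statistics. Empirically this matters a great
deal for consolidation: on the 6×8 aliased-room benchmark (50,000 steps,
20 clones per symbol, $\kappa = 2\cdot 10^{-3}$) the joint estimator
plateaus near 120 distinct decoded states, while the conditional estimator
reaches the high 40s — the regime in which the room's 48 locations are
each represented by (nearly) one clone. The conditional estimator is the
default; the joint one remains available and is used in the
parameter-recovery tests, where the generator's action marginal must be
estimated.

EM cannot merge a *locked* pair of duplicate clones — two clones of the
same symbol with identical outgoing rows whose incoming edges are
deterministic per context constitute an exact fixed point — and,
symmetrically, it cannot split clones whose differentiation requires a
long coordinated move with no local gradient. Three remedies are used,
each documented where a pipeline relies on it:

* **Random restarts** (`emFit(nRestarts = )`): fresh initializations, best
  final penalized log-likelihood wins. Used where redundant clones are
  likelihood-neutral (stochastic worlds such as the modular graph), so
  only restart luck decides between observationally equivalent optima.
  The aliased-room benchmark needs no restarts but does need patience:
  the last redundant clones take on the order of 1,500 EM iterations to
  consolidate, so its pipeline runs EM to a 1e-9 relative tolerance with a
  2,000-iteration cap.
* **Two-phase smoothing schedules**: a weak-pseudocount phase
  (`kappa/100`) learns the structure before the working pseudocount's
  merging pressure is applied. Used by the overlapping-rooms and
  multi-environment pipelines, where strong early smoothing otherwise
  merges look-alike regions before their contexts can separate them.
* **Sequence-memorizing initialization** (`memorizeInit()`, or
  `fitCSCG(init = "memorize")`): the o-th occurrence of a symbol starts in
  clone `o mod M`, transitions counted hard, then EM generalizes. Used for
  prototypical-route and lap data, where the optimal solution is a set of
  memorized context chains that random-start EM provably cannot reach:
  the four-lap corridor requires 48 clones to differentiate with zero
  local gradient, and every random start converges to the merged
  one-clone-per-symbol loop. Memorize-then-generalize is also how the
  replay literature describes acquisition of such sequences.

### Viterbi training and pruning

`viterbiTrain()` performs hard EM with zero pseudocount: decode the MAP
clone path, count realized transitions, renormalize, repeat until the
decoded paths are stable. It removes the soft redundancy that smoothing
leaves behind and marks clones never visited by any decoded path;
`pruneClones()` drops them (keeping one placeholder per symbol so the
alphabet does not shift) without changing decoded-path likelihoods.
`fitCSCG()` packages the standard two-phase schedule — smoothed EM, then
zero-pseudocount Viterbi refinement warm-started from it.

### Emission relearning (schema transfer)

`learnEmission()` freezes the transition tensor and fits a dense
state-by-symbol emission matrix by EM, starting from uniform rows. This is
how a learned room graph is reused in a new room with the same layout but
different observations: once every location has been visited the emission
rows converge to (near) one-hot and next-symbol prediction becomes
perfect. The transition tensor is bit-identical before and after, which
the tests check literally.

### Online EM

`onlineEMUpdate()` implements the adaptive variant: expected counts of
each batch are folded into a running statistic
$A^{(b)} = \lambda A^{(b-1)} + (1-\lambda) \sum_{n \in b} \xi(n)$ with
$\lambda \in (0,1)$, and the tensor is re-estimated from $A^{(b)}$. A
single batch from zero statistics reproduces the batch M-step exactly
(the $1-\lambda$ factor cancels in the normalization). The default batch
length used in examples is 1,000 steps — the model description leaves it
open.

## Inference

All queries run on the same trained model. `filterPosterior()` and
`smoothPosterior()` return exact per-step posteriors over all clones,
under hard evidence or *soft evidence* — a per-step likelihood vector over
symbols; one-hot soft evidence reproduces hard evidence exactly, and when
actions are missing they are integrated out. `viterbiDecode()` breaks ties
toward the lowest state index so decodes are reproducible.

`correctErrors()` models a corrupted stream by giving the received symbol
likelihood $1-p$ and spreading $p$ uniformly over the other $E-1$ symbols,
then outputs the MAP symbol from a forward-only (online) pass — past
evidence only. By default the pass starts from a uniform state
distribution rather than the trained prior: retrieval begins unlocalized,
and a prior concentrated on wherever the training walks happened to start
would overrule clean evidence during the first steps and produce false
corrections. The model used for retrieval is the smoothed EM model itself
(its in-training pseudocount dilutes transitions by a fraction of a
percent); applying `smoothModel()` post hoc at a comparable `kappa` would
add `kappa * nActions * H` of uniform mass per row — orders of magnitude
more — and wash out the predictions. A smoothed correction variant exists
but is not the canonical procedure. `sampleCSCG()` and `replayObservation()` are ancestral sampling
from the learned conditionals, the generative reading of replay.

For multi-environment models, `environmentCloneSets()` assigns each used
clone to the environment whose training walk gives it the most forward
mass, and `environmentPosterior()` reports per-step environment-identity
posteriors by summing filtered mass over each set.

### Remapping metrics and training levels

The five-environment model trains with the two-phase smoothing schedule
for a 500-iteration budget; on this task (each room a permutation of 25
unique symbols) the log-likelihood effectively converges within the first
hundred iterations, so the budget is generous. The "partially trained"
model of the remapping comparison stops after 10 iterations — about a
tenth of the iterations within which training effectively converges —
where clones are still shared across environments.

### Remapping metrics

"Activity" always means posterior probability. The active-clone set of a
trace is every clone whose activation reaches 0.01 at some step (the
sources plot shaded activations without a printed threshold; 0.01 is this
package's choice). Global vs partial remapping is quantified as the mean
pairwise Jaccard overlap of active sets across environments; rate
remapping softens evidence as $(1-\varepsilon)\,\text{onehot} +
\varepsilon/E$ with $\varepsilon = 0.3$ by default (the mechanism is
prescribed, the value is ours). Because softening scales
near-deterministic activations by about $1-\varepsilon$, support
preservation is checked at the dilution-adjusted threshold
$(1-\varepsilon)\cdot 0.01$.

### The lap-track model

The four-lap corridor (start symbol, four repetitions of 1..12, reward) is
trained to the hard fixed point and then given a *small inference-time*
pseudocount (`smoothModel()`, default $10^{-5}$) for the event-specific-
representation analyses. The size matters: each lap transition carries an
expected count of one in the 50-symbol training sequence, so a pseudocount
of $10^{-2}$ would dilute the reward prediction to well below the
near-certainty the trained model should have, while $10^{-5}$ keeps it
above 0.99 and still lets same-position clones of other laps carry small
positive activation.

## Planning

`planPath()` treats planning as inference: clamp a start clone (or belief)
and a goal (clone or observation symbol), sweep forward to find the
minimal horizon at which the goal has positive support, extract actions
backward by max-product with ties to the lowest action id. Support lives
on the *planning graph*: transitions above a per-row floor of
$10\kappa/\text{(row count mass)}$, computable because the M-step records
each row's count mass — without the floor, smoothing makes every goal
trivially "feasible". Zero-pseudocount (Viterbi-refined) models keep every
positive edge. `executeAndReplan()` runs a plan in a grid environment;
rejected actions remove the failed edge and trigger replanning from the
current clone.

## Hierarchy

`transitionGraph()` converts the action-marginalized tensor over the used
clones into a weighted directed graph; `detectCommunities()` partitions it
with the map equation (InfoMap, via igraph — delegating this standard step
to an established library is deliberate; the tests depend only on the
partition). For reversible worlds — every grid move can be undone — the
`directed = FALSE` option symmetrizes the flow first; on the multi-room
maze the directed map equation splits rooms into finer chunks, while the
symmetrized one recovers the clean chunks-then-rooms-then-hyper-rooms
progression, so the maze pipeline detects three undirected levels. `buildHierarchy()` alternates detection and community
collapse (edge weights summed, self-loops removed) into a multi-level
map; `hierarchicalPlan()` refines top-down, restricting each level's
search to the communities selected above. Search effort is compared by
BFS node-expansion counters (`planningEffort()`); path *length*
comparisons against flat search assert a ≤1.5× bound on the mean ratio
(individual pairs can detour further when the top-level hop-count path
commits to a longer corridor) and direction on effort, because an optimal
flat path can never be longer than a hierarchical one; reported step
savings for hierarchical planning are therefore read as search effort,
which the expansion counters measure directly.

## Environments

`envs`-module generators are pure functions of their seed:

* `makeRoom()` — rectangular rooms with randomly placed aliased symbols;
  the aliased-room benchmark uses 6×8 cells and an 18-symbol alphabet with
  20 clones per symbol (360 states), which is the 360-state configuration
  the distinct-state count is reported for. A `uniformInterior` variant
  reproduces the severely aliased empty-room setting.
* `makeOverlappingRooms()` — two 8×6 rooms over 15 symbols sharing a 3×3
  corner patch, plus a disjoint, non-adjacent confounder copy of the patch
  on the top edge of room 1. The confounder is deliberately *not* placed
  in the opposite corner: a corner placement gives it a wall pattern
  complementary to the overlap patch's, which makes merging confounder and
  overlap clones cost no likelihood at all (every action from a merged
  clone stays deterministic) — the wrong merge then becomes statistically
  indistinguishable from the right one.
* `makeHierarchicalMaze()` — 4×4 rooms of 5×5 cells (room size shown but
  not stated in the sources; exposed as a parameter), observations drawn
  from 1..12, bridge cells carrying symbol 13. Four hyper-rooms are built
  in structurally: all adjacent room pairs within a 2×2 quadrant are
  bridged, adjacent quadrants are connected by exactly one bridge. Each
  room's 25 observations are a near-balanced random multiset of the 12
  symbols (two of each plus one random extra) instead of iid draws: iid
  placement routinely pushes one symbol's global cell count above the
  40-clone capacity the experiment allocates, which forces cross-room
  clone merges that no amount of training can undo.
* `makeModularGraph()` — a reconstruction of the classic three-community
  graph: three 5-node clusters in a ring, every node degree 4, cluster
  labels aliased so observations do not identify communities. The exact
  inter-cluster wiring is shown only graphically in the sources; this
  construction fixes a standard form and is documented as such.
* `makeLapTrack()`, `makeRouteEnvironment()` — the lap corridor and the
  route worlds (figure-eight T-maze, odor sequences, stochastic routes
  with the overlap segment 4-5-11-12-13-5-17). Route geometry beyond the
  stated overlaps is reconstructed qualitatively.
* `makeRemappingSet()` — five 5×5 rooms (fresh permutations of 25 symbols)
  or five closed-loop rectangular tracks over a 6-symbol alphabet (four
  corner symbols, horizontal/vertical arms); ring dimensions are this
  package's choice of "geometrical shapes".
* `randomWalk()` samples uniformly among legal moves (never off the grid
  or into walls), `corruptSequence()` flips symbols with probability `p`
  uniformly over the other symbols.

Action ids on grids are 1 = up, 2 = right, 3 = down, 4 = left (the agent's
proprioception is opaque to the model — actions are just tokens).

## What the synthetic data do and do not show

The generators emulate the *statistical* structure of the original
experiments: aliased observations, prototypical routes, shared alphabets
across environments, corrupted streams. They do not emulate continuous
space, sensor noise models beyond symbol replacement, or any
neurophysiology; "activation" is posterior probability, not firing rate.
Tests passing on these worlds demonstrate that the algorithms recover the
generative structure they were built for — not that they would do so on
behavioural or neural recordings.

## Problem sizes and numerical choices

The test suite and the experiment harness run at the study conditions
where those are stated (50,000-step walks, 20 clones, $\kappa$ values as
given) and at deliberately reduced scale elsewhere; the hierarchical maze
is trained on a 120,000-step walk with a single restart, and the route
world on 400 trials rather than 5,000 — enough for the branch statistics
to stabilize. EM stops on a relative penalized-loglik change below `tol` or
at `maxIter` (both exposed; fixed iteration counts reproduce the original
schedules). Viterbi ties go to the lowest state index, planning ties to
the lowest action id. Degenerate inputs have defined behaviour: impossible
sequences yield `-Inf` log-likelihood rather than errors, all-zero
count statistics with $\kappa = 0$ raise a degenerate-statistics error,
and rows of never-visited states keep their previous values.

## Known limitations

* Clone counts are fixed up front; there is no structure search over
  allocations.
* The conditional estimator fixes the action factor to be uniform over
  observed actions; models of deliberate (non-uniform) policies should use
  `actionNorm = "joint"`.
* Locked duplicate clones (identical futures, context-split pasts) are
  exact EM fixed points; only restarts escape them, so minimal-state
  recovery is stochastic rather than guaranteed per seed.
* The multi-room maze is the hardest learning problem in the package:
  coincidentally identical symbol patches in different rooms make
  spurious cross-room merges nearly likelihood-free, and escaping them
  needs restart volume far beyond a desk-scale budget (the original
  experiment used 1,000 restarts). At a handful of restarts the learned
  model reaches ~0.99 held-out prediction accuracy but its community
  structure does not yet respect room boundaries everywhere; the
  abstraction machinery itself recovers chunks, the 16 rooms and the 4
  hyper-rooms exactly on a perfectly learned model.
* Continuous observations and factored action spaces are out of scope.
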