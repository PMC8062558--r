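# cscg

Learning, inference and planning with **clone-structured cognitive graphs
(CSCGs)** — a probabilistic sequence model of hippocampal cognitive maps.

## The problem

An agent wandering a world receives a stream of discrete observations and
emits a stream of discrete actions. Observations are *aliased*: many
places look identical, so no first-order model over observations can
represent the world's layout. A CSCG resolves aliasing with *cloning*:
each observation symbol owns a block of hidden states ("clones") that all
emit that symbol deterministically, and learning assigns different clones
of the same symbol to different temporal contexts. The joint model over
observations `x` and actions `a` is

    P(x_1..N, a_1..N-1) = sum over clone paths of
        P(z_1) * prod_n P(z_{n+1}, a_n | z_n),    z_n in C(x_n)

parameterized by a prior over the `H` clones and a transition tensor
`T[i, k, j] = P(z' = j, a = k | z = i)`. From random walks alone, EM on
this model recovers the latent graph of rooms and mazes; message passing
on the learned graph then supports localization under noisy evidence,
error correction, sampling/replay, goal-directed planning, and — via
community detection on the transition graph — hierarchical abstraction.
The package reproduces, end to end, the phenomena this model family is
known for: spatial map learning from aliased walks, transitive stitching
of overlapping rooms, schema transfer to new rooms, splitter cells and
lap-specific coding, remapping across environments, and multi-level
planning. It is aimed at computational-neuroscience and probabilistic-
modelling researchers.

## A worked example

Learn a 4 x 5 room with 12 aliased symbols from a random walk, then plan:

```r
library(cscg)

env  <- makeRoom(4, 5, nObs = 12, seed = 11)
walk <- randomWalk(env, 8000, seed = 12)
model <- fitCSCG(walk$seq, clonesPerObs = 10, nObs = 12, nActions = 4,
                 kappa = 1e-2, maxIter = 600, tol = 1e-9, seed = 11)

length(modelMeta(model)$usedStates)
#> [1] 20
```

All 20 cells of the room are represented by exactly one clone each — the
minimal latent map. Map cells to clones and plan a corner-to-corner route:

```r
cm <- positionCloneMap(model, walk)
pl <- planPath(model, cm[1], cm[20], goalType = "clone")
pl$horizon
#> [1] 7
pl$actions
#> [1] 2 2 2 3 2 3 3
```

Seven actions (2 = right, 3 = down: four rights and three downs) — the
true grid distance between opposite corners of a 4 x 5 room. The room's
transition graph has one node per location:

```r
g <- transitionGraph(model)
igraph::vcount(g)
#> [1] 20
```

Filtering, smoothing, decoding, error correction, sampling and the
experiment harness (`runExperiment("aliased_room", ...)` etc.) are
documented in the methods vignette (`vignettes/cscg-methods.Rmd`).

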