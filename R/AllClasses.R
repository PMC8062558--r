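#' @import methods
NULL

#' Clone allocation: mapping observation symbols to clone-state blocks
#'
#' A `CloneAllocation` fixes how the hidden state space of a clone-structured
#' model is laid out: each observation symbol `s` (1..E) owns a contiguous
#' block of `clonesPerObs[s]` hidden states ("clones"), symbol-major, so that
#' the clones of symbol 1 come first, then those of symbol 2, and so on. The
#' total state count is `H = sum(clonesPerObs)`.
#'
#' @slot clonesPerObs integer vector of per-symbol clone counts, all >= 1.
#' @slot offsets integer vector; `offsets[s]` is the 1-based index of the
#'   first clone of symbol `s`.
#' @slot nObs number of observation symbols E.
#' @slot nStates total number of hidden states H.
#'
#' @seealso [CloneAllocation()], [cloneRange()], [symbolOf()]
#' @export
setClass("CloneAllocation",
  representation(clonesPerObs = "integer", offsets = "integer",
                 nObs = "integer", nStates = "integer"),
  validity = function(object) {
    m <- object@clonesPerObs
    if (length(m) < 1L) return("at least one observation symbol is required")
    if (any(is.na(m)) || any(m < 1L)) return("all clone counts must be >= 1")
    if (object@nObs != length(m)) return("nObs does not match clonesPerObs")
    if (object@nStates != sum(m)) return("nStates must equal sum(clonesPerObs)")
    off <- cumsum(c(1L, m[-length(m)]))
    if (!identical(object@offsets, as.integer(off)))
      return("offsets are inconsistent with clonesPerObs")
    TRUE
  })

#' Action-observation sequence
#'
#' The experience stream of an agent: observations `x_1, ..., x_N` with the
#' actions `a_1, ..., a_{N-1}` taken between consecutive observations. Actions
#' may be absent (length 0), in which case the sequence is treated as coming
#' from an action-free cloned HMM (equivalently a single-action model).
#'
#' @slot observations integer vector of symbol ids in 1..nObs.
#' @slot actions integer vector of action ids in 1..nActions, length N-1 or 0.
#' @slot nObs declared observation alphabet size.
#' @slot nActions declared action alphabet size.
#' @export
setClass("AOSequence",
  representation(observations = "integer", actions = "integer",
                 nObs = "integer", nActions = "integer"),
  validity = function(object) {
    x <- object@observations; a <- object@actions
    if (length(x) < 1L) return("empty observation sequence")
    if (any(is.na(x)) || any(x < 1L) || any(x > object@nObs))
      return("observations outside the declared alphabet")
    if (length(a) > 0L) {
      if (length(a) != length(x) - 1L)
        return("length(actions) must be length(observations) - 1")
      if (any(is.na(a)) || any(a < 1L) || any(a > object@nActions))
        return("actions outside the declared alphabet")
    }
    TRUE
  })

#' Clone-structured cognitive graph model
#'
#' A CSCG is an action-augmented cloned HMM: a prior `pi` over H hidden
#' states together with a transition tensor `T` with entries
#' `T[i, k, j] = P(z' = j, a = k | z = i)`, so each row block `T[i, , ]`
#' is a joint distribution over (action, next state). Emissions are
#' deterministic through the clone allocation (`emissionMode = "clone"`), or,
#' for schema transfer, an explicit row-stochastic state-by-symbol matrix
#' (`emissionMode = "dense"`).
#'
#' @slot allocation a [CloneAllocation-class].
#' @slot nActions number of actions N_a.
#' @slot prior numeric prior over the H states, sums to 1.
#' @slot transitions numeric array of dim `c(H, nActions, H)`.
#' @slot emission numeric matrix `H x E` (dense mode) or `0 x 0`.
#' @slot emissionMode `"clone"` or `"dense"`.
#' @slot metadata list of provenance: seed, pseudocount, loglik trace,
#'   M-step row count masses, etc.
#' @export
setClass("CSCGModel",
  representation(allocation = "CloneAllocation", nActions = "integer",
                 prior = "numeric", transitions = "array",
                 emission = "matrix", emissionMode = "character",
                 metadata = "list"),
  validity = function(object) {
    H <- object@allocation@nStates
    if (object@nActions < 1L) return("nActions must be >= 1")
    if (length(object@prior) != H) return("prior has wrong length")
    if (any(object@prior < 0)) return("prior has negative entries")
    if (abs(sum(object@prior) - 1) > 1e-8) return("prior must sum to 1")
    d <- dim(object@transitions)
    if (!identical(d, c(H, as.integer(object@nActions), H)))
      return("transitions must have dim c(H, nActions, H)")
    if (any(object@transitions < 0)) return("negative transition entries")
    rs <- rowSums(matrix(object@transitions, nrow = H))
    if (any(abs(rs - 1) > 1e-8))
      return("each T[i, , ] must sum to 1 over (action, next state)")
    if (!object@emissionMode %in% c("clone", "dense"))
      return("emissionMode must be 'clone' or 'dense'")
    if (object@emissionMode == "dense") {
      if (!identical(dim(object@emission), c(H, object@allocation@nObs)))
        return("dense emission must be H x nObs")
      if (any(object@emission < 0)) return("negative emission entries")
      if (any(abs(rowSums(object@emission) - 1) > 1e-8))
        return("dense emission rows must sum to 1")
    }
    TRUE
  })

#' Grid environment
#'
#' A rectangular room whose cells carry observation symbols; 0 marks a
#' wall/blocked cell. Actions are 1 = up, 2 = right, 3 = down, 4 = left
#' (row-major coordinates, row 1 at the top).
#'
#' @slot grid integer matrix of symbols (0 = wall).
#' @slot nObs observation alphabet size.
#' @slot name environment name.
#' @slot seed generator seed.
#' @slot info list of annotations (patch coordinates, room labels, ...).
#' @export
setClass("GridEnvironment",
  representation(grid = "matrix", nObs = "integer", name = "character",
                 seed = "integer", info = "list"),
  validity = function(object) {
    g <- object@grid
    if (!is.numeric(g) && !is.integer(g)) return("grid must be numeric")
    if (!any(g != 0)) return("at least one non-wall cell is required")
    if (any(g < 0)) return("grid symbols must be >= 0 (0 = wall)")
    if (any(g > object@nObs)) return("grid symbol exceeds declared alphabet")
    TRUE
  })

#' Route graph environment
#'
#' A set of positions with observation symbols and per-position successor
#' sets (optionally stochastic), plus designated route start nodes. Used for
#' prototypical-route experiments (figure-eight mazes, odor sequences,
#' stochastic routes). Terminal nodes have no successors; a sampled trial
#' runs from a route start to a terminal.
#'
#' @slot obs integer observation symbol per node.
#' @slot successors list of integer vectors (successor node ids).
#' @slot probs list of numeric vectors (successor probabilities, sum to 1).
#' @slot routeStarts integer vector of start node ids, one per route.
#' @slot nObs observation alphabet size.
#' @slot name environment name.
#' @slot seed generator seed.
#' @slot info list of annotations (overlap node ids, route membership, ...).
#' @export
setClass("RouteGraph",
  representation(obs = "integer", successors = "list", probs = "list",
                 routeStarts = "integer", nObs = "integer",
                 name = "character", seed = "integer", info = "list"),
  validity = function(object) {
    n <- length(object@obs)
    if (length(object@successors) != n || length(object@probs) != n)
      return("successors/probs must have one entry per node")
    for (i in seq_len(n)) {
      s <- object@successors[[i]]; p <- object@probs[[i]]
      if (length(s) != length(p)) return("successor/prob length mismatch")
      if (length(s) > 0L) {
        if (any(s < 1L | s > n)) return("successor id out of range")
        if (abs(sum(p) - 1) > 1e-8) return("successor probabilities must sum to 1")
      }
    }
    if (any(object@routeStarts < 1L | object@routeStarts > n))
      return("route start out of range")
    TRUE
  })

#' Per-step clone activation trace
#'
#' Posterior probability over all H clones at every step of a sequence,
#' either filtered (forward messages only) or smoothed (forward-backward).
#'
#' @slot probs numeric matrix H x N; each column sums to 1.
#' @slot mode `"filtered"` or `"smoothed"`.
#' @slot logLik log-likelihood of the evidence under the model.
#' @export
setClass("CloneActivation",
  representation(probs = "matrix", mode = "character", logLik = "numeric"),
  validity = function(object) {
    if (!object@mode %in% c("filtered", "smoothed"))
      return("mode must be 'filtered' or 'smoothed'")
    cs <- colSums(object@probs)
    if (any(abs(cs - 1) > 1e-6)) return("activation columns must sum to 1")
    TRUE
  })

#' Hierarchical map: clone graph, community partitions, collapsed graphs
#'
#' Level 0 is the learned clone transition graph; each higher level collapses
#' the communities of the level below into single nodes (edge weights summed
#' over cross-community edges).
#'
#' @slot graph level-0 igraph (directed, weighted; vertex attribute `symbol`).
#' @slot partitions list of integer membership vectors, one per level.
#' @slot levelGraphs list of igraphs; `levelGraphs[[l]]` is the collapsed
#'   graph whose nodes are the level-l communities.
#' @slot info list (quality scores, node id maps).
#' @export
setClass("HierarchicalMap",
  representation(graph = "ANY", partitions = "list", levelGraphs = "list",
                 info = "list"))
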