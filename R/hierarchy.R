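#' @include plan.R
NULL

#' Learned transition graph of a CSCG
#'
#' Treats the action-marginalized transition matrix as a weighted directed
#' graph over the clones actually in use: nodes are the used states
#' (annotated with the symbol they emit), and an edge i -> j exists when
#' `sum_a T[i, a, j]` exceeds a floor that strips pseudocount-only weights
#' (per-row `10 * kappa / row count mass` by default, or an explicit
#' `floor`).
#'
#' @param model a trained [CSCGModel-class].
#' @param floor explicit edge floor (NULL uses the pseudocount-derived one).
#' @param used integer ids of states to include; defaults to
#'   `modelMeta(model)$usedStates` (from [viterbiTrain()]) or, failing
#'   that, states with positive M-step row mass, or all states.
#' @return a directed weighted `igraph`; vertex attributes `name` (the
#'   state id as character) and `symbol`.
#' @export
transitionGraph <- function(model, floor = NULL, used = NULL) {
  H <- nStates(model)
  if (is.null(used)) {
    used <- model@metadata$usedStates
    if (is.null(used)) {
      rc <- model@metadata$rowCounts
      used <- if (!is.null(rc)) which(rc > 1e-9) else seq_len(H)
    }
  }
  used <- sort(unique(as.integer(used)))
  if (length(model@metadata$loglikTrace) == 0L &&
      is.null(model@metadata$usedStates))
    warning("model looks untrained; the graph may be degenerate",
            call. = FALSE)
  W <- marginalTransitions(model)[used, used, drop = FALSE]
  fl <- .planningFloor(model, floor)[used]
  keep <- which(W > fl, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(used), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(used))
  g <- igraph::set_vertex_attr(g, "symbol", value = symbolOf(model, used))
  if (nrow(keep))
    g <- igraph::add_edges(g, rbind(keep[, 1L], keep[, 2L]),
                           weight = W[keep])
  g
}

#' Community detection on a clone graph
#'
#' Partitions a directed weighted transition graph with the map-equation
#' (InfoMap) algorithm — the flow-based objective that discovers rooms and
#' hyper-rooms in learned cognitive maps. Deterministic given `seed`.
#'
#' @param graph an `igraph` (e.g. from [transitionGraph()]).
#' @param seed integer seed.
#' @param directed treat edge directions as flow (`TRUE`, default) or
#'   symmetrize first (`FALSE`). For reversible worlds (every move can be
#'   undone) the symmetrized map equation matches the walk's reversible
#'   flow and yields coarser, room-like modules.
#' @return list with `membership` (integer community per vertex, named by
#'   vertex name), `nCommunities`, and `codelength` (the map-equation value;
#'   lower is better).
#' @export
detectCommunities <- function(graph, seed = 1L, directed = TRUE) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  if (!directed)
    graph <- igraph::as_undirected(graph, mode = "collapse",
                                   edge.attr.comb = list(weight = "sum"))
  cl <- withr::with_seed(as.integer(seed),
    igraph::cluster_infomap(graph,
      e.weights = if ("weight" %in% igraph::edge_attr_names(graph))
        igraph::E(graph)$weight else NULL))
  memb <- igraph::membership(cl)
  list(membership = memb, nCommunities = length(unique(memb)),
       codelength = igraph::code_len(cl))
}

# collapse communities into single nodes; edge weights are summed over the
# underlying cross-community edges, self-loops removed
.collapseGraph <- function(graph, membership) {
  ids <- as.integer(membership)
  g2 <- igraph::contract(graph, ids, vertex.attr.comb = list(name = "ignore"))
  g2 <- igraph::set_vertex_attr(g2, "name",
                                value = as.character(seq_len(max(ids))))
  igraph::simplify(g2, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(weight = "sum"))
}

#' Build a multi-level hierarchical map
#'
#' Alternates community detection and community collapse: level-0 is the
#' clone transition graph, level-1 nodes are its communities (rooms),
#' level-2 nodes the communities of the collapsed room graph (hyper-rooms),
#' and so on up to the requested depth.
#'
#' @param model a trained [CSCGModel-class] (or an `igraph` used directly
#'   as the level-0 graph).
#' @param levels number of abstraction levels above the clones (>= 1;
#'   `levels = 2` gives the clones / rooms / hyper-rooms three-level map).
#' @param floor,used passed to [transitionGraph()] when `model` is a model.
#' @param seed seed for community detection.
#' @param directed passed to [detectCommunities()].
#' @return a [HierarchicalMap-class].
#' @export
buildHierarchy <- function(model, levels = 2L, floor = NULL, used = NULL,
                           seed = 1L, directed = TRUE) {
  g0 <- if (is(model, "CSCGModel")) transitionGraph(model, floor, used)
        else model
  if (levels < 1L) stop("levels must be >= 1")
  partitions <- list()
  levelGraphs <- list()
  quality <- numeric(0)
  g <- g0
  for (l in seq_len(levels)) {
    cm <- detectCommunities(g, seed = seed + l - 1L, directed = directed)
    partitions[[l]] <- cm$membership
    quality <- c(quality, cm$codelength)
    g <- .collapseGraph(g, cm$membership)
    levelGraphs[[l]] <- g
  }
  new("HierarchicalMap", graph = g0, partitions = partitions,
      levelGraphs = levelGraphs, info = list(codelength = quality))
}

setMethod("show", "HierarchicalMap", function(object) {
  cat("HierarchicalMap:", igraph::vcount(object@graph), "clones;",
      paste(vapply(object@partitions, function(p) length(unique(p)), 1L),
            collapse = " / "),
      "communities per level\n")
})

#' Replace the level-1 partition of a hierarchy
#'
#' Rebuilds the collapsed graphs and re-detects all higher-level
#' communities after substituting a level-1 membership vector (e.g. a
#' surrogate partition). Used to measure how much a room-respecting
#' partition helps hierarchical planning.
#'
#' @param hier a [HierarchicalMap-class].
#' @param membership integer membership vector over level-0 nodes.
#' @param seed seed for re-detecting higher levels.
#' @param directed passed to [detectCommunities()].
#' @return a new [HierarchicalMap-class].
#' @export
rebuildHierarchy <- function(hier, membership, seed = 1L, directed = TRUE) {
  levels <- length(hier@partitions)
  partitions <- list(membership)
  g <- .collapseGraph(hier@graph, membership)
  levelGraphs <- list(g)
  if (levels > 1L) for (l in 2:levels) {
    cm <- detectCommunities(g, seed = seed + l - 1L, directed = directed)
    partitions[[l]] <- cm$membership
    g <- .collapseGraph(g, cm$membership)
    levelGraphs[[l]] <- g
  }
  new("HierarchicalMap", graph = hier@graph, partitions = partitions,
      levelGraphs = levelGraphs, info = list(surrogate = TRUE))
}

#' Surrogate community partition
#'
#' Randomly permutes the community assignment over nodes while preserving
#' every community's size — a partition with the same granularity that no
#' longer respects the graph's structural boundaries.
#'
#' @param partition membership vector (as returned in
#'   `detectCommunities()$membership`).
#' @param seed integer seed.
#' @return permuted membership vector (names preserved in order).
#' @export
surrogatePartition <- function(partition, seed = 1L) {
  memb <- as.integer(partition)
  out <- withr::with_seed(as.integer(seed),
                          memb[sample.int(length(memb))])
  names(out) <- names(partition)
  out
}

# unweighted BFS with an expansion counter (hop metric = plan steps)
.bfsGraph <- function(adjList, from, to) {
  n <- length(adjList)
  dist <- rep(NA_integer_, n)
  pred <- integer(n)
  dist[from] <- 0L
  queue <- from
  expansions <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    expansions <- expansions + 1L
    if (v == to) break
    for (u in adjList[[v]]) {
      if (is.na(dist[u])) {
        dist[u] <- dist[v] + 1L
        pred[u] <- v
        queue <- c(queue, u)
      }
    }
  }
  path <- NULL
  if (!is.na(dist[to])) {
    path <- to
    while (path[1L] != from) path <- c(pred[path[1L]], path)
  }
  list(path = path, dist = dist[to], expansions = expansions)
}

.adjListOf <- function(graph) {
  lapply(igraph::as_adj_list(graph, mode = "out"), as.integer)
}

# top-down refinement shared by hierarchicalPlan and planningEffort
.hierSearch <- function(hier, start, goal) {
  g0 <- hier@graph
  v0 <- igraph::V(g0)$name
  s0 <- match(as.character(start), v0)
  t0 <- match(as.character(goal), v0)
  if (is.na(s0) || is.na(t0)) stop("start or goal clone not in the graph")
  L <- length(hier@partitions)
  # community chain for start/goal at every level
  sC <- integer(L); tC <- integer(L)
  si <- s0; ti <- t0
  for (l in seq_len(L)) {
    sC[l] <- as.integer(hier@partitions[[l]][si])
    tC[l] <- as.integer(hier@partitions[[l]][ti])
    if (l < L) {
      nm <- igraph::V(hier@levelGraphs[[l]])$name
      si <- match(as.character(sC[l]), nm)
      ti <- match(as.character(tC[l]), nm)
    }
  }
  expansions <- 0L
  # top level: search the whole collapsed graph
  gl <- hier@levelGraphs[[L]]
  nm <- igraph::V(gl)$name
  bf <- .bfsGraph(.adjListOf(gl), match(as.character(sC[L]), nm),
                  match(as.character(tC[L]), nm))
  expansions <- expansions + bf$expansions
  if (is.null(bf$path))
    stop(errorCondition("goal community unreachable at the top level",
                        class = "cscg_infeasible_goal"))
  allowed <- nm[bf$path]
  # refine downwards, restricting each level to the allowed communities
  if (L > 1L) for (l in (L - 1L):1L) {
    gl <- hier@levelGraphs[[l]]
    nm <- igraph::V(gl)$name
    keep <- which(as.character(hier@partitions[[l + 1L]]) %in% allowed)
    sub <- igraph::induced_subgraph(gl, keep)
    snm <- igraph::V(sub)$name
    bf <- .bfsGraph(.adjListOf(sub), match(as.character(sC[l]), snm),
                    match(as.character(tC[l]), snm))
    expansions <- expansions + bf$expansions
    if (is.null(bf$path))
      stop(errorCondition("goal unreachable within the allowed communities",
                          class = "cscg_infeasible_goal"))
    allowed <- snm[bf$path]
  }
  # level 0: clones restricted to the allowed level-1 communities
  keep <- which(as.character(hier@partitions[[1L]]) %in% allowed)
  sub <- igraph::induced_subgraph(g0, keep)
  snm <- igraph::V(sub)$name
  bf <- .bfsGraph(.adjListOf(sub), match(as.character(start), snm),
                  match(as.character(goal), snm))
  expansions <- expansions + bf$expansions
  if (is.null(bf$path))
    stop(errorCondition("goal clone unreachable within allowed communities",
                        class = "cscg_infeasible_goal"))
  list(path = as.integer(snm[bf$path]), expansions = expansions)
}

#' Hierarchical planning over a multi-level map
#'
#' Plans top-down: shortest community path at the highest level, then the
#' shortest path at each lower level restricted to the communities selected
#' above, down to a concrete clone path. The returned path is a valid walk
#' in the level-0 graph ending at the goal.
#'
#' @param hier a [HierarchicalMap-class].
#' @param start,goal level-0 clone ids.
#' @return integer vector of clone ids from `start` to `goal`.
#' @export
hierarchicalPlan <- function(hier, start, goal) {
  .hierSearch(hier, start, goal)$path
}

#' Search effort of hierarchical vs flat planning
#'
#' Counts node expansions (BFS dequeues) of a flat search on the full
#' level-0 graph versus the hierarchical top-down search, for the same
#' start/goal pair.
#'
#' @param hier a [HierarchicalMap-class].
#' @param start,goal level-0 clone ids.
#' @return list with `flat`, `hierarchical` (expansion counts),
#'   `flatLength` and `hierLength` (path lengths in steps).
#' @export
planningEffort <- function(hier, start, goal) {
  g0 <- hier@graph
  v0 <- igraph::V(g0)$name
  bf <- .bfsGraph(.adjListOf(g0), match(as.character(start), v0),
                  match(as.character(goal), v0))
  hs <- .hierSearch(hier, start, goal)
  list(flat = bf$expansions, hierarchical = hs$expansions,
       flatLength = as.integer(bf$dist),
       hierLength = length(hs$path) - 1L)
}

#' Export a graph as edge-list TSV
#'
#' Columns `src`, `dst`, `weight` (vertex names).
#'
#' @param graph an `igraph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGraphTSV <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  w <- if ("weight" %in% igraph::edge_attr_names(graph))
    igraph::E(graph)$weight else rep(1, nrow(el))
  df <- data.frame(src = el[, 1L], dst = el[, 2L], weight = w)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
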