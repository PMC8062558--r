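#' @include sequence.R
NULL

# Grid action convention: 1 = up (-row), 2 = right (+col), 3 = down (+row),
# 4 = left (-col); row-major coordinates with row 1 at the top.
.GRID_MOVES <- matrix(c(-1L, 0L, 0L, 1L, 1L, 0L, 0L, -1L), nrow = 4L,
                      byrow = TRUE)

.gridEnv <- function(grid, nObs, name, seed, info = list()) {
  storage.mode(grid) <- "integer"
  new("GridEnvironment", grid = grid, nObs = as.integer(nObs),
      name = name, seed = as.integer(seed), info = info)
}

#' @describeIn nObservations alphabet size of a grid environment
#' @export
setMethod("nObservations", "GridEnvironment", function(x) x@nObs)

#' @describeIn nObservations alphabet size of a route graph
#' @export
setMethod("nObservations", "RouteGraph", function(x) x@nObs)

setMethod("show", "GridEnvironment", function(object) {
  cat("GridEnvironment '", object@name, "': ", nrow(object@grid), " x ",
      ncol(object@grid), " grid, ", object@nObs, " symbols, ",
      sum(object@grid != 0L), " open cells\n", sep = "")
})

setMethod("show", "RouteGraph", function(object) {
  cat("RouteGraph '", object@name, "': ", length(object@obs), " nodes, ",
      object@nObs, " symbols, ", length(object@routeStarts), " routes\n",
      sep = "")
})

#' Generate an aliased room
#'
#' A rectangular room whose cells carry observation symbols drawn uniformly
#' at random from an alphabet much smaller than the number of cells, so that
#' instantaneous observations do not identify locations (aliasing). Every
#' symbol is used at least once when the room has enough cells. With
#' `uniformInterior = TRUE` all non-border cells share symbol 1 and border
#' cells draw from the remaining symbols — the severely aliased
#' uniform-interior variant.
#'
#' @param height,width room dimensions (>= 1).
#' @param nObs observation alphabet size.
#' @param seed integer seed; the same seed reproduces the grid exactly.
#' @param uniformInterior logical.
#' @return a [GridEnvironment-class].
#' @export
makeRoom <- function(height, width, nObs, seed = 1L,
                     uniformInterior = FALSE) {
  nc <- height * width
  if (nObs < 1L || height < 1L || width < 1L) stop("invalid dimensions")
  if (nObs > nc) stop("more symbols than cells")
  g <- withr::with_seed(as.integer(seed), {
    if (uniformInterior) {
      g <- matrix(1L, height, width)
      border <- which(row(g) == 1L | row(g) == height |
                      col(g) == 1L | col(g) == width)
      if (nObs > 1L) {
        syms <- 2:nObs
        fill <- sample(syms, length(border), replace = TRUE)
        # guarantee coverage of the border alphabet when feasible
        if (length(border) >= length(syms))
          fill[sample.int(length(border), length(syms))] <- sample(syms)
        g[border] <- fill
      }
      g
    } else {
      fill <- sample.int(nObs, nc, replace = TRUE)
      fill[sample.int(nc, nObs)] <- sample.int(nObs)  # coverage
      matrix(fill, height, width)
    }
  })
  .gridEnv(g, nObs, sprintf("room_%dx%d", height, width), seed,
           info = list(uniformInterior = uniformInterior))
}

#' Generate two overlapping rooms with a confounder patch
#'
#' Two 8 x 6 rooms over a shared 15-symbol alphabet that share an identical
#' 3 x 3 corner patch (bottom-right corner of room 1 equals the top-left
#' corner of room 2). Room 1 additionally contains a second, disjoint and
#' non-adjacent copy of the same patch (the confounder) in its opposite
#' corner, so that merging locations by local appearance alone would be
#' wrong.
#'
#' @param seed integer seed.
#' @return list with `room1`, `room2` ([GridEnvironment-class]) and
#'   `annotations` (row/col index lists for `overlap1`, `overlap2`,
#'   `confounder`).
#' @export
makeOverlappingRooms <- function(seed = 1L) {
  h <- 8L; w <- 6L; E <- 15L
  res <- withr::with_seed(as.integer(seed), {
    mk <- function() {
      f <- sample.int(E, h * w, replace = TRUE)
      f[sample.int(h * w, E)] <- sample.int(E)
      matrix(f, h, w)
    }
    g1 <- mk(); g2 <- mk()
    list(g1 = g1, g2 = g2)
  })
  ov1 <- list(rows = 6:8, cols = 4:6)     # room 1 bottom-right corner
  ov2 <- list(rows = 1:3, cols = 1:3)     # room 2 top-left corner
  # confounder: top edge of room 1, disjoint and non-adjacent to the
  # overlap. Deliberately NOT at the opposite corner: a corner placement
  # has the wall pattern complementary to the overlap patch, which makes
  # merging the confounder with the overlap cost no likelihood (every
  # action from a merged clone stays deterministic), so the wrong merge
  # becomes indistinguishable from the right one. A mid-edge confounder
  # breaks that degeneracy.
  cf <- list(rows = 1:3, cols = 2:4)
  g1 <- res$g1; g2 <- res$g2
  patch <- g1[ov1$rows, ov1$cols]
  g2[ov2$rows, ov2$cols] <- patch
  g1[cf$rows, cf$cols] <- patch
  list(room1 = .gridEnv(g1, E, "overlap_room1", seed,
                        info = list(overlap = ov1, confounder = cf)),
       room2 = .gridEnv(g2, E, "overlap_room2", seed,
                        info = list(overlap = ov2)),
       annotations = list(overlap1 = ov1, overlap2 = ov2, confounder = cf))
}

#' Generate the hierarchical multi-room maze
#'
#' `roomsPerSide^2` rooms of `roomSize x roomSize` cells tiled in a square,
#' with observations drawn uniformly from 1..12 (with repetition) and rooms
#' connected by single-cell bridges carrying the dedicated symbol 13. With
#' an even `roomsPerSide` the rooms are grouped into four quadrant
#' "hyper-rooms": all adjacent room pairs inside a quadrant are bridged,
#' while each pair of adjacent quadrants is connected by exactly one bridge,
#' giving the maze a three-level hierarchy (cells, rooms, hyper-rooms).
#'
#' @param seed integer seed.
#' @param roomsPerSide rooms along each side (default 4).
#' @param roomSize cells along each side of a room (default 5).
#' @return a [GridEnvironment-class]; `x@info$roomLabels` is a matrix giving
#'   each cell's room id (0 for walls and bridges), `x@info$quadrant` the
#'   hyper-room of each room, and `x@info$bridgedPairs` the bridged room
#'   pairs.
#' @export
makeHierarchicalMaze <- function(seed = 1L, roomsPerSide = 4L,
                                 roomSize = 5L) {
  if (roomsPerSide < 2L) stop("roomsPerSide must be >= 2")
  R <- roomsPerSide; S <- roomSize
  G <- R * S + (R - 1L)
  grid <- matrix(0L, G, G)
  labels <- matrix(0L, G, G)
  roomId <- function(r, c) (r - 1L) * R + c
  # each room draws a near-balanced random multiset of the 12 symbols
  # (random placement, aliased within and across rooms); balancing keeps
  # every symbol's global cell count safely below the clone capacity a
  # 40-clone model provides
  roomCells <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(R * R), function(i) {
      base <- rep(seq_len(12L), (S * S) %/% 12L)
      extra <- sample.int(12L, S * S - length(base))
      sample(c(base, extra))
    })
  })
  for (r in seq_len(R)) for (c in seq_len(R)) {
    rr <- (r - 1L) * (S + 1L) + seq_len(S)
    cc <- (c - 1L) * (S + 1L) + seq_len(S)
    grid[rr, cc] <- matrix(roomCells[[roomId(r, c)]], S, S)
    labels[rr, cc] <- roomId(r, c)
  }
  # quadrant (hyper-room) lookup by room id
  quadOf <- integer(R * R)
  for (r in seq_len(R)) for (c in seq_len(R))
    quadOf[roomId(r, c)] <- if (R %% 2L == 0L)
      2L * ((r - 1L) %/% (R %/% 2L)) + (c - 1L) %/% (R %/% 2L) + 1L else 1L
  mid <- (S + 1L) %/% 2L
  bridged <- list()
  crossUsed <- character(0)
  addBridge <- function(pos) { grid[pos[1L], pos[2L]] <<- 13L }
  for (r in seq_len(R)) for (c in seq_len(R)) {
    id <- roomId(r, c)
    if (c < R) {  # horizontal neighbour
      id2 <- roomId(r, c + 1L)
      key <- paste(sort(c(quadOf[id], quadOf[id2])), collapse = "-")
      same <- quadOf[id] == quadOf[id2]
      if (same || !(key %in% crossUsed)) {
        addBridge(c((r - 1L) * (S + 1L) + mid, c * (S + 1L)))
        bridged[[length(bridged) + 1L]] <- c(id, id2)
        if (!same) crossUsed <- c(crossUsed, key)
      }
    }
    if (r < R) {  # vertical neighbour
      id2 <- roomId(r + 1L, c)
      key <- paste(sort(c(quadOf[id], quadOf[id2])), collapse = "-")
      same <- quadOf[id] == quadOf[id2]
      if (same || !(key %in% crossUsed)) {
        addBridge(c(r * (S + 1L), (c - 1L) * (S + 1L) + mid))
        bridged[[length(bridged) + 1L]] <- c(id, id2)
        if (!same) crossUsed <- c(crossUsed, key)
      }
    }
  }
  .gridEnv(grid, 13L, sprintf("hmaze_%dx%d", R, R), seed,
           info = list(roomLabels = labels, quadrant = quadOf,
                       bridgedPairs = bridged, roomSize = S,
                       roomsPerSide = R))
}

#' Generate the aliased modular graph
#'
#' A 15-node graph of three 5-node clusters arranged in a ring, every node
#' of degree 4: the three internal nodes of a cluster connect to all other
#' nodes of their cluster, the two boundary nodes connect to the internal
#' nodes of their cluster and to one boundary node of a neighbouring
#' cluster (boundary nodes of the same cluster are not linked). This is a
#' reconstruction of the classic community-structured graph used in
#' statistical-learning studies. Observation labels are aliased: the same
#' five symbols are reused in every cluster (order permuted per cluster), so
#' observations alone do not reveal the communities.
#'
#' @param seed integer seed (permutes the labels).
#' @return a [RouteGraph-class]; `x@info$communities` holds the ground-truth
#'   cluster of each node.
#' @export
makeModularGraph <- function(seed = 1L) {
  edges <- list()
  addE <- function(a, b) { edges[[length(edges) + 1L]] <<- c(a, b) }
  base <- function(k) (k - 1L) * 5L  # cluster k occupies base+1..base+5
  for (k in 1:3) {
    b <- base(k)
    # node 1 and 5 are boundary; 2,3,4 internal (clique among all but 1-5)
    for (i in 1:5) for (j in 1:5) if (i < j && !(i == 1L && j == 5L))
      addE(b + i, b + j)
  }
  # ring: boundary node 5 of cluster k links boundary node 1 of cluster k+1
  addE(base(1) + 5L, base(2) + 1L)
  addE(base(2) + 5L, base(3) + 1L)
  addE(base(3) + 5L, base(1) + 1L)
  adj <- vector("list", 15L)
  for (e in edges) {
    adj[[e[1L]]] <- c(adj[[e[1L]]], e[2L])
    adj[[e[2L]]] <- c(adj[[e[2L]]], e[1L])
  }
  obs <- withr::with_seed(as.integer(seed),
                          unlist(lapply(1:3, function(k) sample.int(5L))))
  new("RouteGraph", obs = as.integer(obs),
      successors = lapply(adj, as.integer),
      probs = lapply(adj, function(s) rep(1 / length(s), length(s))),
      routeStarts = 1L, nObs = 5L, name = "modular_graph",
      seed = as.integer(seed),
      info = list(communities = rep(1:3, each = 5L)))
}

#' Generate the four-lap track sequence
#'
#' The lap-running task: one start symbol, four repetitions of the corridor
#' sequence 1..12, and a final goal/reward symbol, all under a single
#' "advance" action (50 symbols in total). `elongation > 0` builds a test
#' sequence in which the corridor symbol at position 6 of every lap is
#' repeated `elongation` extra times — the elongated maze is never part of
#' the training data.
#'
#' @param elongation extra repeats of the elongation position per lap (>= 0).
#' @return list with `train` (an [AOSequence-class]; the canonical 50-symbol
#'   sequence), `test` (the elongated sequence; equals `train` when
#'   `elongation = 0`), and `annotations` (`lap` and `position` per step of
#'   each sequence; start symbol 13 is position 0 / lap 0, reward symbol 14
#'   is position 13 / lap 5).
#' @export
makeLapTrack <- function(elongation = 0L) {
  stopifnot(elongation >= 0)
  startSym <- 13L; rewardSym <- 14L
  lapSeq <- function(extra) {
    pos <- seq_len(12L)
    reps <- rep(1L, 12L); reps[6L] <- 1L + extra
    list(obs = rep(pos, times = reps), pos = rep(pos, times = reps))
  }
  build <- function(extra) {
    obs <- startSym; lap <- 0L; pos <- 0L
    for (l in 1:4) {
      ls <- lapSeq(extra)
      obs <- c(obs, ls$obs)
      lap <- c(lap, rep(l, length(ls$obs)))
      pos <- c(pos, ls$pos)
    }
    obs <- c(obs, rewardSym); lap <- c(lap, 5L); pos <- c(pos, 13L)
    list(seq = AOSequence(obs, actions = rep(1L, length(obs) - 1L),
                          nObs = 14L, nActions = 1L),
         lap = lap, position = pos)
  }
  tr <- build(0L)
  te <- if (elongation > 0L) build(as.integer(elongation)) else tr
  list(train = tr$seq, test = te$seq,
       annotations = list(train = list(lap = tr$lap, position = tr$position),
                          test = list(lap = te$lap, position = te$position)))
}

# build a RouteGraph from a list of routes; each route is a list of segments
# where a segment is either a plain obs vector (a chain) or a list of
# alternative obs vectors (a uniform stochastic branch)
.buildRoutes <- function(routes, nObs, name, seed, overlapObs = NULL) {
  obs <- integer(0)
  succ <- list(); prob <- list()
  starts <- integer(0)
  routeNodes <- list()
  overlapNodes <- list()
  addNode <- function(o) {
    obs[length(obs) + 1L] <<- o
    succ[[length(obs)]] <<- integer(0)
    prob[[length(obs)]] <<- numeric(0)
    length(obs)
  }
  link <- function(a, b, p = 1) {
    succ[[a]] <<- c(succ[[a]], b)
    prob[[a]] <<- c(prob[[a]], p)
  }
  for (ri in seq_along(routes)) {
    segs <- routes[[ri]]$segments
    nodesOfRoute <- integer(0)
    tails <- integer(0)   # nodes whose successors are the next segment head
    for (seg in segs) {
      if (is.list(seg)) {  # stochastic branch: alternatives, uniform choice
        heads <- integer(0); newTails <- integer(0)
        for (alt in seg) {
          ids <- vapply(alt, addNode, integer(1))
          if (length(ids) > 1L) for (i in seq_len(length(ids) - 1L))
            link(ids[i], ids[i + 1L])
          heads <- c(heads, ids[1L])
          newTails <- c(newTails, ids[length(ids)])
          nodesOfRoute <- c(nodesOfRoute, ids)
        }
        if (length(tails) == 0L) starts <- c(starts, heads[1L])
        for (t in tails) for (h in heads) link(t, h, 1 / length(heads))
        tails <- newTails
      } else {
        ids <- vapply(seg, addNode, integer(1))
        if (length(ids) > 1L) for (i in seq_len(length(ids) - 1L))
          link(ids[i], ids[i + 1L])
        if (length(tails) == 0L) starts <- c(starts, ids[1L])
        for (t in tails) link(t, ids[1L])
        tails <- ids[length(ids)]
        nodesOfRoute <- c(nodesOfRoute, ids)
      }
    }
    routeNodes[[ri]] <- nodesOfRoute
    if (!is.null(routes[[ri]]$overlapSegment))
      overlapNodes[[ri]] <- nodesOfRoute[routes[[ri]]$overlapSegment]
  }
  new("RouteGraph", obs = obs, successors = succ, probs = prob,
      routeStarts = starts, nObs = as.integer(nObs), name = name,
      seed = as.integer(seed),
      info = list(routeNodes = routeNodes, overlapNodes = overlapNodes,
                  overlapObs = overlapObs))
}

#' Generate prototypical-route environments
#'
#' Three route-structured worlds in which two routes share an overlapping
#' observation segment:
#' \describe{
#'   \item{`tmaze_fig8`}{a figure-eight T maze: left-turn and right-turn
#'     trials traverse an identical central stem (observations 1-2-3) before
#'     diverging into distinct return arms.}
#'   \item{`odor_sequences`}{two deterministic symbol sequences sharing a
#'     middle subsequence.}
#'   \item{`stochastic_routes`}{two routes with stochastic pre-segments that
#'     overlap in the seven-location middle segment with observations
#'     4-5-11-12-13-5-17 before diverging to a shared destination.}
#' }
#' Ground truth keeps one node chain per route (identical observations in
#' the overlap), so sampled trials always respect their route's successor
#' sets. All routes use the single "advance" action.
#'
#' @param kind one of `"tmaze_fig8"`, `"odor_sequences"`,
#'   `"stochastic_routes"`.
#' @param seed integer seed (recorded; the layouts themselves are fixed).
#' @return a [RouteGraph-class]; `x@info$overlapObs` lists the shared
#'   observation segment and `x@info$overlapNodes` the per-route node ids of
#'   that segment.
#' @export
makeRouteEnvironment <- function(kind = c("tmaze_fig8", "odor_sequences",
                                          "stochastic_routes"),
                                 seed = 1L) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("unknown route environment kind"))
  if (kind == "tmaze_fig8") {
    stem <- c(1L, 2L, 3L)
    routes <- list(
      list(segments = list(stem, c(4L, 5L, 6L, 7L)),
           overlapSegment = seq_along(stem)),
      list(segments = list(stem, c(8L, 9L, 10L, 11L)),
           overlapSegment = seq_along(stem)))
    .buildRoutes(routes, 11L, "tmaze_fig8", seed, overlapObs = stem)
  } else if (kind == "odor_sequences") {
    mid <- c(3L, 9L, 10L)
    routes <- list(
      list(segments = list(c(1L, 2L), mid, c(4L)),
           overlapSegment = 2L + seq_along(mid)),
      list(segments = list(c(5L, 6L), mid, c(7L)),
           overlapSegment = 2L + seq_along(mid)))
    .buildRoutes(routes, 10L, "odor_sequences", seed, overlapObs = mid)
  } else {
    ov <- c(4L, 5L, 11L, 12L, 13L, 5L, 17L)
    routes <- list(
      list(segments = list(c(1L), list(c(2L, 3L), c(7L, 8L)), ov,
                           c(6L, 9L, 20L)),
           overlapSegment = 5L + seq_along(ov)),
      list(segments = list(c(14L), list(c(15L, 16L), c(18L, 19L)), ov,
                           c(10L, 3L, 20L)),
           overlapSegment = 5L + seq_along(ov)))
    .buildRoutes(routes, 20L, "stochastic_routes", seed, overlapObs = ov)
  }
}

#' Generate a remapping environment set
#'
#' Five environments sharing one observation alphabet, used to study place
#' field reorganization across environments. `kind = "rooms"`: five 5 x 5
#' rooms, each a fresh random permutation of symbols 1..25 (every symbol
#' used exactly once per room). `kind = "mazes"`: five closed-loop
#' rectangular tracks of distinct dimensions over a 6-symbol alphabet —
#' four corner symbols (1 = top-left, 2 = top-right, 3 = bottom-right,
#' 4 = bottom-left), 5 for horizontal arms and 6 for vertical arms.
#'
#' @param kind `"rooms"` or `"mazes"`.
#' @param seed integer seed.
#' @return list of five [GridEnvironment-class] objects.
#' @export
makeRemappingSet <- function(kind = c("rooms", "mazes"), seed = 1L) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("unknown remapping set kind"))
  if (kind == "rooms") {
    perms <- withr::with_seed(as.integer(seed),
                              lapply(1:5, function(i) sample.int(25L)))
    lapply(1:5, function(i)
      .gridEnv(matrix(perms[[i]], 5L, 5L), 25L,
               sprintf("remap_room%d", i), seed))
  } else {
    dims <- list(c(3L, 4L), c(3L, 6L), c(4L, 4L), c(4L, 6L), c(5L, 5L))
    lapply(seq_along(dims), function(i) {
      h <- dims[[i]][1L]; w <- dims[[i]][2L]
      g <- matrix(0L, h, w)
      g[1L, ] <- 5L; g[h, ] <- 5L          # horizontal arms
      g[, 1L] <- 6L; g[, w] <- 6L          # vertical arms
      g[1L, 1L] <- 1L; g[1L, w] <- 2L      # corners
      g[h, w] <- 3L; g[h, 1L] <- 4L
      .gridEnv(g, 6L, sprintf("remap_maze%d", i), seed)
    })
  }
}

# legal-move table: for each open cell, the legal actions and target cells
.legalMoves <- function(env) {
  g <- env@grid
  h <- nrow(g); w <- ncol(g)
  open <- which(g != 0L)
  moves <- vector("list", h * w)
  for (cell in open) {
    r <- (cell - 1L) %% h + 1L
    c <- (cell - 1L) %/% h + 1L
    acts <- integer(0); tgts <- integer(0)
    for (a in 1:4) {
      r2 <- r + .GRID_MOVES[a, 1L]; c2 <- c + .GRID_MOVES[a, 2L]
      if (r2 >= 1L && r2 <= h && c2 >= 1L && c2 <= w &&
          g[r2, c2] != 0L) {
        acts <- c(acts, a)
        tgts <- c(tgts, (c2 - 1L) * h + r2)
      }
    }
    moves[[cell]] <- list(actions = acts, targets = tgts)
  }
  moves
}

#' Random walk in an environment
#'
#' On a [GridEnvironment-class]: at every step an action is sampled
#' uniformly among the moves that stay inside the room and off walls; the
#' action taken and the observation of the resulting cell are recorded. On a
#' [RouteGraph-class]: successors are followed according to their
#' probabilities; when a terminal node is reached a new trial starts at a
#' route start sampled uniformly (a continuous stream of trials).
#'
#' @param env a [GridEnvironment-class] or [RouteGraph-class].
#' @param nSteps number of actions (the walk has `nSteps + 1` observations).
#' @param seed integer seed; walks are bitwise reproducible.
#' @param start starting cell as `c(row, col)` (grid) or node id (routes);
#'   `NULL` samples uniformly over open cells / route starts.
#' @return list with `seq` (an [AOSequence-class]) and `positions` (cell
#'   indices or node ids visited, length `nSteps + 1`).
#' @export
randomWalk <- function(env, nSteps, seed = 1L, start = NULL) {
  stopifnot(nSteps >= 1)
  if (is(env, "GridEnvironment")) {
    g <- env@grid
    h <- nrow(g)
    moves <- .legalMoves(env)
    withr::with_seed(as.integer(seed), {
      cell <- if (is.null(start)) {
        open <- which(g != 0L)
        open[sample.int(length(open), 1L)]
      } else {
        (start[2L] - 1L) * h + start[1L]
      }
      if (g[cell] == 0L) stop("start cell is a wall")
      if (length(moves[[cell]]$actions) == 0L)
        stop("no legal move from the start cell")
      pos <- integer(nSteps + 1L); acts <- integer(nSteps)
      obs <- integer(nSteps + 1L)
      pos[1L] <- cell; obs[1L] <- g[cell]
      for (n in seq_len(nSteps)) {
        mv <- moves[[cell]]
        k <- if (length(mv$actions) == 1L) 1L
             else sample.int(length(mv$actions), 1L)
        acts[n] <- mv$actions[k]
        cell <- mv$targets[k]
        pos[n + 1L] <- cell
        obs[n + 1L] <- g[cell]
      }
      list(seq = AOSequence(obs, actions = acts, nObs = env@nObs,
                            nActions = 4L),
           positions = pos)
    })
  } else if (is(env, "RouteGraph")) {
    withr::with_seed(as.integer(seed), {
      node <- if (is.null(start)) {
        env@routeStarts[sample.int(length(env@routeStarts), 1L)]
      } else as.integer(start)
      pos <- integer(nSteps + 1L); obs <- integer(nSteps + 1L)
      pos[1L] <- node; obs[1L] <- env@obs[node]
      for (n in seq_len(nSteps)) {
        s <- env@successors[[node]]
        if (length(s) == 0L) {  # terminal: new trial
          node <- env@routeStarts[sample.int(length(env@routeStarts), 1L)]
        } else if (length(s) == 1L) {
          node <- s[1L]
        } else {
          node <- s[sample.int(length(s), 1L, prob = env@probs[[node]])]
        }
        pos[n + 1L] <- node
        obs[n + 1L] <- env@obs[node]
      }
      list(seq = AOSequence(obs, actions = rep(1L, nSteps), nObs = env@nObs,
                            nActions = 1L),
           positions = pos)
    })
  } else stop("unsupported environment type")
}

#' Sample complete trials along a route
#'
#' Draws `nPaths` start-to-terminal trials from a [RouteGraph-class],
#' following successor probabilities. Useful for training on prototypical
#' routes (each trial is an independent sequence).
#'
#' @param env a [RouteGraph-class].
#' @param nPaths number of trials.
#' @param seed integer seed.
#' @param route route index (into `env@routeStarts`); `NULL` alternates over
#'   routes.
#' @param maxLen safety cap on trial length.
#' @return list of [AOSequence-class]; attribute `"nodes"` of each element
#'   holds the visited node ids.
#' @export
sampleRoutePaths <- function(env, nPaths, seed = 1L, route = NULL,
                             maxLen = 1000L) {
  stopifnot(is(env, "RouteGraph"))
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(nPaths), function(p) {
      ri <- if (is.null(route)) (p - 1L) %% length(env@routeStarts) + 1L
            else route
      node <- env@routeStarts[ri]
      nodes <- node
      while (length(env@successors[[node]]) > 0L &&
             length(nodes) < maxLen) {
        s <- env@successors[[node]]
        node <- if (length(s) == 1L) s[1L]
                else s[sample.int(length(s), 1L, prob = env@probs[[node]])]
        nodes <- c(nodes, node)
      }
      sq <- AOSequence(env@obs[nodes],
                       actions = rep(1L, length(nodes) - 1L),
                       nObs = env@nObs, nActions = 1L)
      attr(sq, "nodes") <- nodes
      attr(sq, "route") <- ri
      sq
    })
  })
}

#' Corrupt an observation sequence
#'
#' Each symbol is independently replaced with probability `p` by a uniform
#' draw over the other `E - 1` symbols (so every corrupted position really
#' differs from the original).
#'
#' @param seq an [AOSequence-class].
#' @param p corruption probability in `[0, 1)`.
#' @param seed integer seed.
#' @return list with `seq` (the corrupted [AOSequence-class]) and `mask`
#'   (logical vector of replaced positions).
#' @export
corruptSequence <- function(seq, p, seed = 1L) {
  stopifnot(is(seq, "AOSequence"))
  if (!(p >= 0 && p < 1)) stop("corruption probability must be in [0, 1)")
  E <- seq@nObs
  x <- seq@observations
  withr::with_seed(as.integer(seed), {
    mask <- stats::runif(length(x)) < p
    if (any(mask)) {
      repl <- vapply(x[mask], function(s) {
        others <- setdiff(seq_len(E), s)
        others[sample.int(E - 1L, 1L)]
      }, integer(1))
      x[mask] <- repl
    }
    list(seq = AOSequence(x, actions = if (length(seq@actions)) seq@actions
                          else NULL,
                          nObs = E, nActions = seq@nActions),
         mask = mask)
  })
}

#' Write an environment as JSON
#'
#' Grid environments: `{"name", "grid": [[int]], "wall": 0, "n_obs",
#' "seed"}` (rows of the grid). Route graphs: a node list with `obs` and
#' `successors` (`to`/`p` pairs) plus `route_starts`.
#'
#' @param env a [GridEnvironment-class] or [RouteGraph-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEnvironment <- function(env, path) {
  doc <- if (is(env, "GridEnvironment")) {
    list(type = "grid", name = env@name,
         grid = unname(split(env@grid, row(env@grid))), wall = 0L,
         n_obs = env@nObs, seed = env@seed)
  } else if (is(env, "RouteGraph")) {
    list(type = "routes", name = env@name, n_obs = env@nObs,
         seed = env@seed,
         nodes = lapply(seq_along(env@obs), function(i)
           list(obs = env@obs[i],
                successors = if (length(env@successors[[i]]))
                  lapply(seq_along(env@successors[[i]]), function(k)
                    list(to = env@successors[[i]][k],
                         p = env@probs[[i]][k]))
                else list())),
         route_starts = env@routeStarts)
  } else stop("unsupported environment type")
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}

#' Read an environment from JSON
#'
#' @param path file written by [writeEnvironment()].
#' @return a [GridEnvironment-class] or [RouteGraph-class].
#' @export
readEnvironment <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (identical(doc$type, "grid")) {
    g <- do.call(rbind, lapply(doc$grid, unlist))
    .gridEnv(g, doc$n_obs, doc$name, doc$seed)
  } else if (identical(doc$type, "routes")) {
    n <- length(doc$nodes)
    obs <- vapply(doc$nodes, function(x) as.integer(x$obs), integer(1))
    succ <- lapply(doc$nodes, function(x)
      vapply(x$successors, function(s) as.integer(s$to), integer(1)))
    prob <- lapply(doc$nodes, function(x)
      vapply(x$successors, function(s) as.numeric(s$p), numeric(1)))
    new("RouteGraph", obs = obs, successors = succ, probs = prob,
        routeStarts = as.integer(unlist(doc$route_starts)),
        nObs = as.integer(doc$n_obs), name = doc$name,
        seed = as.integer(doc$seed), info = list())
  } else stop("unrecognized environment JSON")
}
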