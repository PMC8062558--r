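#' @include infer.R
NULL

# Per-row probability floor separating learned edges from pseudocount-only
# edges: 10 * kappa / (row count mass), computable because the M-step records
# each row's count mass. Unsmoothed models keep every positive edge.
.planningFloor <- function(model, floor = NULL) {
  H <- nStates(model)
  if (!is.null(floor)) return(rep(floor, H))
  kap <- model@metadata$pseudocount
  rc <- model@metadata$rowCounts
  if (is.null(kap) || is.na(kap) || kap == 0 || is.null(rc))
    return(rep(0, H))
  out <- ifelse(rc > 0, 10 * kap / rc, Inf)
  pmin(out, 1)  # a floor above 1 would also kill learned edges of dead rows
}

# adjacency of the planning graph: for each state, the (action, next-state)
# pairs with transition probability strictly above the row floor
.planningAdjacency <- function(model, floor = NULL, blockedEdges = NULL,
                               blockedStates = NULL) {
  H <- nStates(model)
  Na <- model@nActions
  fl <- .planningFloor(model, floor)
  blockedKey <- if (is.null(blockedEdges)) character(0)
    else vapply(blockedEdges, function(e)
      paste(e[1L], e[2L], sep = ":"), character(1))
  dead <- logical(H)
  if (!is.null(blockedStates)) dead[blockedStates] <- TRUE
  adj <- vector("list", H)
  for (i in seq_len(H)) {
    if (dead[i]) { adj[[i]] <- list(act = integer(0), to = integer(0)); next }
    blk <- matrix(model@transitions[i, , ], Na)  # Na x H
    hit <- which(blk > fl[i], arr.ind = TRUE)
    if (nrow(hit)) {
      ord <- order(hit[, 1L], hit[, 2L])  # actions ascending, states ascending
      a <- hit[ord, 1L]; j <- hit[ord, 2L]
      keep <- !dead[j]
      if (length(blockedKey))
        keep <- keep & !(paste(i, a, sep = ":") %in% blockedKey)
      adj[[i]] <- list(act = as.integer(a[keep]), to = as.integer(j[keep]))
    } else adj[[i]] <- list(act = integer(0), to = integer(0))
  }
  adj
}

# breadth-first sweep from the start set; returns predecessors and the first
# goal state reached at the minimal horizon, plus the expansion count
.bfsPlan <- function(adj, startStates, goalStates, maxHorizon) {
  H <- length(adj)
  dist <- rep.int(NA_integer_, H)
  predState <- integer(H)
  predAct <- integer(H)
  frontier <- sort(unique(startStates))
  dist[frontier] <- 0L
  hit <- frontier[frontier %in% goalStates]
  expansions <- 0L
  depth <- 0L
  while (length(hit) == 0L && length(frontier) > 0L && depth < maxHorizon) {
    depth <- depth + 1L
    nxt <- integer(0)
    for (i in frontier) {
      expansions <- expansions + 1L
      e <- adj[[i]]
      for (k in seq_along(e$to)) {
        j <- e$to[k]
        if (is.na(dist[j])) {
          dist[j] <- depth
          predState[j] <- i
          predAct[j] <- e$act[k]
          nxt <- c(nxt, j)
        }
      }
    }
    frontier <- sort(unique(nxt))
    hit <- frontier[frontier %in% goalStates]
  }
  list(goal = if (length(hit)) min(hit) else NA_integer_,
       dist = dist, predState = predState, predAct = predAct,
       expansions = expansions, depthSearched = depth)
}

#' Planning as inference: shortest feasible action sequence to a goal
#'
#' Clamps a start clone (or belief) and a goal — either a specific clone or
#' any clone of a desired observation symbol — and sweeps messages forward
#' through the model to find the minimal horizon at which the goal has
#' positive support; the backward pass then extracts the action sequence
#' (ties broken toward the lowest action id). Support is evaluated on the
#' planning graph, which keeps only transitions strictly above a per-row
#' floor of `10 * kappa / (row count mass)` so pseudocount-only edges never
#' make a goal look feasible.
#'
#' @param model a trained [CSCGModel-class].
#' @param start a clone id, or a belief vector of length H (all states with
#'   positive mass are admissible starts; see [filterPosterior()] for
#'   obtaining one from a recent observation window).
#' @param goal a clone id (`goalType = "clone"`) or an observation symbol
#'   (`goalType = "observation"`).
#' @param goalType `"clone"` or `"observation"`.
#' @param maxHorizon largest horizon searched.
#' @param blockedEdges optional list of `c(state, action)` pairs removed
#'   from the planning graph (used during replanning).
#' @param blockedStates optional state ids removed entirely.
#' @param floor optional explicit probability floor overriding the
#'   pseudocount-derived one.
#' @return a plan: list with `actions`, `clonePath` (length
#'   `horizon + 1`), `expectedObservations` (symbols emitted along the
#'   path), `horizon` and `expansions` (forward-sweep node expansions). A
#'   goal with no support within `maxHorizon` raises a condition of class
#'   `"cscg_infeasible_goal"` carrying the horizon searched.
#' @export
planPath <- function(model, start, goal,
                     goalType = c("clone", "observation"),
                     maxHorizon = 1000L, blockedEdges = NULL,
                     blockedStates = NULL, floor = NULL) {
  goalType <- match.arg(goalType)
  H <- nStates(model)
  startStates <- if (length(start) == H && !is.integer(start) &&
                     length(start) > 1L) {
    which(start > 0)
  } else {
    s <- as.integer(start)
    if (any(is.na(s)) || any(s < 1L) || any(s > H))
      stop("start clone out of range")
    s
  }
  goalStates <- if (goalType == "clone") {
    g <- as.integer(goal)
    if (any(is.na(g)) || any(g < 1L) || any(g > H))
      stop("goal clone out of range")
    g
  } else cloneRange(model, goal)
  adj <- .planningAdjacency(model, floor, blockedEdges, blockedStates)
  bfs <- .bfsPlan(adj, startStates, goalStates, maxHorizon)
  if (is.na(bfs$goal))
    stop(errorCondition(
      sprintf("goal infeasible within horizon %d", maxHorizon),
      horizon = bfs$depthSearched, class = "cscg_infeasible_goal"))
  # backtrack
  path <- bfs$goal
  acts <- integer(0)
  cur <- bfs$goal
  while (bfs$dist[cur] > 0L) {
    acts <- c(bfs$predAct[cur], acts)
    cur <- bfs$predState[cur]
    path <- c(cur, path)
  }
  list(actions = acts, clonePath = path,
       expectedObservations = symbolOf(model, path),
       horizon = length(acts), expansions = bfs$expansions)
}

#' Map environment cells to learned clones
#'
#' Viterbi-decodes a training walk and assigns to every visited cell the
#' clone most frequently decoded there — the bridge between the model's
#' latent space and the generating environment, needed to execute plans.
#'
#' @param model a trained [CSCGModel-class].
#' @param walk result of [randomWalk()] (list with `seq` and `positions`).
#' @return integer vector indexed by cell id (NA for unvisited cells).
#' @export
positionCloneMap <- function(model, walk) {
  dec <- viterbiDecode(model, walk$seq)$path
  pos <- walk$positions
  cells <- sort(unique(pos))
  out <- rep(NA_integer_, max(pos))
  for (cell in cells) {
    cl <- dec[pos == cell]
    tab <- table(cl)
    out[cell] <- as.integer(names(tab)[which.max(tab)])
  }
  out
}

#' Execute a plan in an environment, replanning around failures
#'
#' Runs the planned actions step by step in a grid environment. When the
#' environment rejects an action (the move would leave the grid or enter a
#' wall — e.g. an obstacle the model does not know about), the failed
#' (state, action) edge is removed from the planning graph, the agent
#' re-localizes at its current clone, and a new plan is computed. Terminates
#' at the goal or after `maxSteps` total executed/rejected actions.
#'
#' @param env a [GridEnvironment-class] (possibly with obstacles the model
#'   was not trained on).
#' @param model a trained [CSCGModel-class].
#' @param start starting cell `c(row, col)`.
#' @param goal goal clone id or observation symbol (see `goalType`).
#' @param cloneMap cell-to-clone map from [positionCloneMap()].
#' @param goalType `"clone"` or `"observation"`.
#' @param maxSteps step budget.
#' @param floor optional planning floor override.
#' @return list with `trajectory` (cells visited), `actionsTaken`,
#'   `replans`, `reached` (logical) and `blockedEdges` discovered.
#' @export
executeAndReplan <- function(env, model, start, goal, cloneMap,
                             goalType = c("clone", "observation"),
                             maxSteps = 500L, floor = NULL) {
  goalType <- match.arg(goalType)
  stopifnot(is(env, "GridEnvironment"))
  g <- env@grid
  h <- nrow(g); w <- ncol(g)
  cell <- (start[2L] - 1L) * h + start[1L]
  if (g[cell] == 0L) stop("start cell is a wall")
  goalStates <- if (goalType == "clone") as.integer(goal)
                else cloneRange(model, goal)
  blocked <- list()
  replans <- 0L
  traj <- cell
  acted <- integer(0)
  curClone <- cloneMap[cell]
  if (is.na(curClone)) stop("start cell has no clone assignment")
  plan <- tryCatch(
    planPath(model, curClone, goal, goalType, blockedEdges = blocked,
             floor = floor),
    cscg_infeasible_goal = function(e) NULL)
  steps <- 0L
  while (steps < maxSteps) {
    if (curClone %in% goalStates)
      return(list(trajectory = traj, actionsTaken = acted,
                  replans = replans, reached = TRUE,
                  blockedEdges = blocked))
    if (is.null(plan) || length(plan$actions) == 0L) break
    a <- plan$actions[1L]
    steps <- steps + 1L
    r <- (cell - 1L) %% h + 1L
    c <- (cell - 1L) %/% h + 1L
    r2 <- r + .GRID_MOVES[a, 1L]; c2 <- c + .GRID_MOVES[a, 2L]
    legal <- r2 >= 1L && r2 <= h && c2 >= 1L && c2 <= w && g[r2, c2] != 0L
    if (legal) {
      cell <- (c2 - 1L) * h + r2
      traj <- c(traj, cell)
      acted <- c(acted, a)
      curClone <- plan$clonePath[2L]
      plan$actions <- plan$actions[-1L]
      plan$clonePath <- plan$clonePath[-1L]
    } else {
      # action rejected: drop the edge and replan from the current clone
      blocked[[length(blocked) + 1L]] <- c(curClone, a)
      replans <- replans + 1L
      plan <- tryCatch(
        planPath(model, curClone, goal, goalType, blockedEdges = blocked,
                 floor = floor),
        cscg_infeasible_goal = function(e) NULL)
      if (is.null(plan)) break
    }
  }
  list(trajectory = traj, actionsTaken = acted, replans = replans,
       reached = curClone %in% goalStates, blockedEdges = blocked)
}
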