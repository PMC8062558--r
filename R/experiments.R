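#' @include hierarchy.R envs.R
NULL

#' Aliased-room learning pipeline
#'
#' The canonical spatial-map experiment: generate a rectangular room with
#' randomly placed aliased observation symbols, collect a long random walk
#' of action-observation pairs, train a CSCG with smoothed EM, refine with
#' Viterbi training (zero pseudocount), and count the distinct hidden states
#' used by the Viterbi decode of the training walk. On a `height x width`
#' room the theoretical optimum is one state per location
#' (`height * width` distinct states).
#'
#' @param seed integer seed (drives the room, the walk and EM init).
#' @param height,width room dimensions.
#' @param nObs observation alphabet size (default 18: with 20 clones per
#'   symbol this is the 360-state configuration the experiment is usually
#'   run at; the room stays heavily aliased since 48 locations share 18
#'   symbols).
#' @param steps random-walk length.
#' @param clones clones per symbol.
#' @param kappa EM pseudocount.
#' @param maxIter EM iteration budget.
#' @param tol EM stopping tolerance (0 runs all iterations).
#' @return list with `model`, `env`, `walk`, `decode` and
#'   `distinctStates`.
#' @export
aliasedRoomPipeline <- function(seed = 1L, height = 6L, width = 8L,
                                nObs = 18L, steps = 50000L, clones = 20L,
                                kappa = 2e-3, maxIter = 2000L, tol = 1e-9) {
  env <- makeRoom(height, width, nObs, seed = seed)
  walk <- randomWalk(env, steps, seed = seed + 1L)
  model <- fitCSCG(walk$seq, clonesPerObs = clones, nObs = nObs,
                   nActions = 4L, kappa = kappa, maxIter = maxIter,
                   tol = tol, seed = seed, viterbiIter = 50L)
  dec <- viterbiDecode(model, walk$seq)
  list(model = model, env = env, walk = walk, decode = dec,
       distinctStates = length(unique(dec$path)))
}

#' Overlapping-rooms stitching pipeline
#'
#' Two rooms sharing an identical corner patch (plus a confounder copy of
#' the patch elsewhere in room 1) are experienced in two disjoint random
#' walks; a single CSCG is trained on both sequences simultaneously. A
#' correctly stitched map reuses the same clones for the shared patch in
#' both rooms while keeping the confounder separate.
#'
#' @param seed integer seed.
#' @param steps walk length per room.
#' @param clones clones per symbol.
#' @param kappa EM pseudocount.
#' @param maxIter EM iteration budget.
#' @return list with `model`, `rooms`, `walks`, `maps` (cell-to-clone maps
#'   per room), `overlapClones1`, `overlapClones2` (clone ids at
#'   corresponding overlap-patch positions), `confounderClones`, and
#'   `heldOutAccuracy` (post-burn-in next-symbol accuracy on fresh walks).
#' @export
overlapPipeline <- function(seed = 1L, steps = 10000L, clones = 20L,
                            kappa = 1e-2, maxIter = 200L) {
  rooms <- makeOverlappingRooms(seed)
  w1 <- randomWalk(rooms$room1, steps, seed = seed + 1L)
  w2 <- randomWalk(rooms$room2, steps, seed = seed + 2L)
  # two-phase smoothing schedule: a weak-pseudocount phase learns the
  # structure with little merging pressure, then the stated pseudocount
  # smooths the solution before zero-pseudocount Viterbi refinement
  al <- CloneAllocation(clones, nObs = 15L)
  model <- makeCSCG(al, 4L, seed = seed)
  model <- emFit(model, list(w1$seq, w2$seq), kappa = kappa / 100,
                 maxIter = 300L, tol = 1e-9, seed = seed)
  model <- emFit(model, list(w1$seq, w2$seq), kappa = kappa,
                 maxIter = maxIter, tol = 1e-9, seed = seed)
  model <- viterbiTrain(model, list(w1$seq, w2$seq))
  m1 <- positionCloneMap(model, w1)
  m2 <- positionCloneMap(model, w2)
  cellId <- function(r, c, h) (c - 1L) * h + r
  h <- nrow(rooms$room1@grid)
  ann <- rooms$annotations
  ovCells1 <- as.vector(outer(ann$overlap1$rows, ann$overlap1$cols,
                              cellId, h = h))
  ovCells2 <- as.vector(outer(ann$overlap2$rows, ann$overlap2$cols,
                              cellId, h = h))
  cfCells <- as.vector(outer(ann$confounder$rows, ann$confounder$cols,
                             cellId, h = h))
  hw1 <- randomWalk(rooms$room1, 500L, seed = seed + 11L)
  hw2 <- randomWalk(rooms$room2, 500L, seed = seed + 12L)
  acc <- mean(c(predictionAccuracy(model, hw1$seq, burnIn = 10L),
                predictionAccuracy(model, hw2$seq, burnIn = 10L)))
  list(model = model, rooms = rooms, walks = list(w1, w2),
       maps = list(m1, m2),
       overlapClones1 = m1[ovCells1], overlapClones2 = m2[ovCells2],
       confounderClones = m1[cfCells], heldOutAccuracy = acc)
}

#' Schema-transfer pipeline
#'
#' Trains a CSCG in one room, freezes its transition tensor, and relearns
#' only a dense emission matrix from a random walk in a second room with
#' the same layout but different observations. Once every location of the
#' new room has been visited, next-symbol prediction in the new room is
#' perfect, and the frozen graph supports planning in the new room.
#'
#' @param seed integer seed.
#' @param height,width room dimensions.
#' @param nObs alphabet size (some symbols repeat).
#' @param steps1 training walk length in room 1.
#' @param steps2 emission-learning walk length in room 2.
#' @param clones clones per symbol.
#' @param kappa EM pseudocount for room 1.
#' @return list with `model1` (clone mode, room 1), `model2` (dense mode,
#'   room 2), `room1`, `room2`, `walk1`, `walk2`, `cloneMap` (room-1 cells
#'   to clones), `accuracy2` (post-burn-in accuracy in room 2) and
#'   `allVisited` (whether the room-2 walk covered every cell).
#' @export
schemaTransferPipeline <- function(seed = 1L, height = 6L, width = 8L,
                                   nObs = 20L, steps1 = 10000L,
                                   steps2 = 10000L, clones = 20L,
                                   kappa = 1e-2) {
  room1 <- makeRoom(height, width, nObs, seed = seed)
  room2 <- makeRoom(height, width, nObs, seed = seed + 500L)
  w1 <- randomWalk(room1, steps1, seed = seed + 1L)
  model1 <- fitCSCG(w1$seq, clonesPerObs = clones, nObs = nObs,
                    nActions = 4L, kappa = kappa, maxIter = 100L,
                    tol = 1e-8, seed = seed, viterbiIter = 50L)
  w2 <- randomWalk(room2, steps2, seed = seed + 2L)
  model2 <- learnEmission(model1, w2$seq, maxIter = 100L)
  hw2 <- randomWalk(room2, 500L, seed = seed + 3L)
  acc2 <- predictionAccuracy(model2, hw2$seq, burnIn = 10L)
  list(model1 = model1, model2 = model2, room1 = room1, room2 = room2,
       walk1 = w1, walk2 = w2,
       cloneMap = positionCloneMap(model1, w1),
       accuracy2 = acc2,
       allVisited = length(unique(w2$positions)) == sum(room2@grid != 0L))
}

#' Prototypical-routes pipeline
#'
#' Trains a CSCG on complete trials along two overlapping routes and
#' returns everything needed to examine route-specific (splitter) clones in
#' the shared segment.
#'
#' @param kind route environment kind (see [makeRouteEnvironment()]).
#' @param seed integer seed.
#' @param nPaths number of trials (split over the two routes).
#' @param clones clones per symbol.
#' @param kappa EM pseudocount.
#' @return list with `model`, `env`, `paths` (training trials), and
#'   `routeTrials` (one representative decoded trial per route).
#' @export
routesPipeline <- function(kind = "tmaze_fig8", seed = 1L, nPaths = 40L,
                           clones = 10L, kappa = 1e-3) {
  env <- makeRouteEnvironment(kind, seed)
  paths <- sampleRoutePaths(env, nPaths, seed = seed + 1L)
  model <- fitCSCG(paths, clonesPerObs = clones, nObs = env@nObs,
                   nActions = 1L, kappa = kappa, maxIter = 200L,
                   tol = 1e-10, seed = seed, viterbiIter = 50L,
                   init = "memorize")
  routeOf <- vapply(paths, function(p) attr(p, "route"), integer(1))
  reps <- lapply(seq_along(env@routeStarts), function(r) {
    sq <- paths[[which(routeOf == r)[1L]]]
    list(seq = sq, decode = viterbiDecode(model, sq)$path)
  })
  list(model = model, env = env, paths = paths, routeTrials = reps)
}

#' Lap-track (event-specific representation) pipeline
#'
#' Trains on the four-lap corridor sequence to the hard fixed point, then
#' applies a small inference-time pseudocount so that clones of the same
#' position on other laps stay weakly active (the event-specific-
#' representation signature) while the reward at the end of lap four is
#' still predicted with near certainty.
#'
#' @param seed integer seed.
#' @param clones clones per symbol.
#' @param inferKappa inference-time smoothing pseudocount.
#' @return list with `model` (unsmoothed), `smoothed` (inference model),
#'   `track` (from [makeLapTrack()]), and `rewardProb` (predictive
#'   probability of the reward symbol at the final step of the training
#'   sequence under the smoothed model).
#' @export
lapTrackPipeline <- function(seed = 1L, clones = 20L, inferKappa = 1e-5) {
  track <- makeLapTrack()
  model <- fitCSCG(track$train, clonesPerObs = clones, nObs = 14L,
                   nActions = 1L, kappa = 1e-3, maxIter = 200L,
                   tol = 1e-10, seed = seed, viterbiIter = 50L,
                   init = "memorize")
  sm <- smoothModel(model, inferKappa)
  s <- .seqForModel(sm, track$train)
  pred <- cscg_predict_cpp(sm@transitions, sm@prior,
                           sm@allocation@clonesPerObs, s$obs0, s$act0,
                           sm@nActions)$pred
  rewardProb <- pred[14L, ncol(pred)]
  list(model = model, smoothed = sm, track = track,
       rewardProb = rewardProb)
}

#' Five-environment (remapping / retrieval) pipeline
#'
#' Trains a single CSCG on random walks from five environments sharing one
#' observation alphabet. The fitted model, the training walks, and the
#' per-environment clone assignment support the remapping analyses
#' (environment-identity posteriors, activity overlap across environments)
#' and online error correction.
#'
#' @param kind `"rooms"` or `"mazes"` (see [makeRemappingSet()]).
#' @param seed integer seed.
#' @param steps walk length per environment.
#' @param clones clones per symbol.
#' @param kappa EM pseudocount.
#' @param maxIter EM iteration budget (lower it to obtain a partially
#'   trained model).
#' @return list with `model`, `envs`, `walks`, and `cloneSets` (partition
#'   of used states by environment).
#' @export
fiveEnvPipeline <- function(kind = "rooms", seed = 1L, steps = 10000L,
                            clones = 10L, kappa = 1e-3, maxIter = 500L) {
  envs <- makeRemappingSet(kind, seed)
  walks <- lapply(seq_along(envs), function(i)
    randomWalk(envs[[i]], steps, seed = seed + i))
  seqs <- lapply(walks, `[[`, "seq")
  al <- CloneAllocation(clones, nObs = envs[[1L]]@nObs)
  model <- makeCSCG(al, nActions = 4L, seed = seed, init = "random")
  # two-phase smoothing schedule (see the methods vignette): a weak phase
  # learns structure, then the working pseudocount smooths the model; the
  # smoothed EM model itself is the retrieval model (no hard refinement,
  # so every observation stream keeps positive probability)
  it1 <- max(1L, round(0.6 * maxIter))
  it2 <- max(1L, maxIter - it1)
  model <- emFit(model, seqs, kappa = kappa / 100, maxIter = it1,
                 tol = 1e-9, seed = seed)
  model <- emFit(model, seqs, kappa = kappa, maxIter = it2, tol = 1e-9,
                 seed = seed)
  list(model = model, envs = envs, walks = walks,
       cloneSets = environmentCloneSets(model, seqs))
}

#' Error-correction experiment on a five-environment model
#'
#' Corrupts a fresh test walk (each symbol independently replaced with
#' probability `p` by a uniform draw over the other symbols), then runs
#' online MAP correction and scores how many corrupted symbols were
#' restored and how many clean symbols were falsely altered.
#'
#' @param pipe result of [fiveEnvPipeline()].
#' @param seed integer seed (also selects which environment is walked).
#' @param steps test-walk length.
#' @param p corruption probability.
#' @return list with `nCorrupted`, `nCorrected`, `nFalse` (clean symbols
#'   altered) and the per-step outputs.
#' @export
errorCorrectionRun <- function(pipe, seed = 1L, steps = 250L, p = 0.2) {
  envIdx <- (as.integer(seed) - 1L) %% length(pipe$envs) + 1L
  walk <- randomWalk(pipe$envs[[envIdx]], steps, seed = seed + 100L)
  corr <- corruptSequence(walk$seq, p, seed = seed + 200L)
  res <- correctErrors(pipe$model, corr$seq, noiseRate = p)
  out <- res$corrected@observations
  truth <- walk$seq@observations
  mask <- corr$mask
  list(nCorrupted = sum(mask),
       nCorrected = sum(out[mask] == truth[mask]),
       nFalse = sum(out[!mask] != truth[!mask]),
       corrected = out, truth = truth, mask = mask, envIdx = envIdx)
}

#' Activity overlap across environments
#'
#' Mean pairwise Jaccard overlap of the active-clone sets (activation
#' threshold `threshold`) over fresh test walks, one per environment — the
#' quantitative handle on global vs partial remapping.
#'
#' @param model a [CSCGModel-class].
#' @param envs list of environments.
#' @param seed integer seed for the test walks.
#' @param steps test-walk length per environment.
#' @param epsilon soft-evidence uncertainty (0 = hard evidence).
#' @param threshold activation threshold for the active set.
#' @return list with `meanOverlap`, `activeSets`, and `maxActivation`.
#' @export
remapOverlap <- function(model, envs, seed = 1L, steps = 50L, epsilon = 0,
                         threshold = 0.01) {
  traces <- lapply(seq_along(envs), function(i) {
    w <- randomWalk(envs[[i]], steps, seed = seed + 50L + i)
    ev <- softEvidence(w$seq@observations, nObservations(model), epsilon)
    filterPosterior(model, ev, actions = w$seq@actions)
  })
  sets <- lapply(traces, activeClones, threshold = threshold)
  pairs <- utils::combn(length(envs), 2L)
  jac <- apply(pairs, 2L, function(pr) {
    a <- sets[[pr[1L]]]; b <- sets[[pr[2L]]]
    if (length(union(a, b)) == 0L) return(0)
    length(intersect(a, b)) / length(union(a, b))
  })
  list(meanOverlap = mean(jac), activeSets = sets,
       maxActivation = max(vapply(traces, function(t) max(t@probs),
                                  numeric(1))))
}

#' Modular-graph community recovery pipeline
#'
#' Random walk on the aliased three-cluster graph, CSCG training, community
#' detection on the learned transition graph, and the mapping from clones
#' back to ground-truth nodes.
#'
#' @param seed integer seed.
#' @param steps walk length.
#' @param clones clones per symbol.
#' @param kappa EM pseudocount.
#' @return list with `model`, `env`, `walk`, `graph`, `communities`,
#'   `cloneNode` (most frequent ground-truth node per used clone) and
#'   `cloneCluster` (its ground-truth cluster).
#' @export
modularGraphPipeline <- function(seed = 1L, steps = 50000L, clones = 4L,
                                 kappa = 1e-3, nRestarts = 30L) {
  env <- makeModularGraph(seed)
  walk <- randomWalk(env, steps, seed = seed + 1L)
  model <- fitCSCG(walk$seq, clonesPerObs = clones, nObs = env@nObs,
                   nActions = 1L, kappa = kappa, maxIter = 2000L,
                   tol = 1e-9, seed = seed, nRestarts = nRestarts,
                   viterbiIter = 50L)
  g <- transitionGraph(model)
  cm <- detectCommunities(g, seed = seed)
  dec <- viterbiDecode(model, walk$seq)$path
  used <- as.integer(igraph::V(g)$name)
  cloneNode <- vapply(used, function(cl) {
    tab <- table(walk$positions[dec == cl])
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
  list(model = model, env = env, walk = walk, graph = g, communities = cm,
       cloneNode = cloneNode,
       cloneCluster = env@info$communities[cloneNode])
}

#' Hierarchical-maze pipeline
#'
#' Random walk in the multi-room maze, CSCG training, two-level community
#' detection, and clone-to-room assignments for checking that communities
#' respect room boundaries and that the second level recovers the
#' hyper-rooms.
#'
#' @param seed integer seed.
#' @param steps walk length.
#' @param clones clones per symbol.
#' @param kappa EM pseudocount.
#' @param maxIter EM iteration budget.
#' @param nRestarts EM restarts.
#' @return list with `model`, `env`, `walk`, `hier`
#'   ([HierarchicalMap-class]), `cloneRoom` (room label per used clone; 0
#'   for bridge clones) and `usedClones`.
#' @export
hierMazePipeline <- function(seed = 1L, steps = 120000L, clones = 40L,
                             kappa = 2e-3, maxIter = 200L,
                             nRestarts = 1L) {
  env <- makeHierarchicalMaze(seed)
  walk <- randomWalk(env, steps, seed = seed + 1L)
  model <- fitCSCG(walk$seq, clonesPerObs = clones, nObs = 13L,
                   nActions = 4L, kappa = kappa, maxIter = maxIter,
                   tol = 1e-8, nRestarts = nRestarts, seed = seed,
                   viterbiIter = 50L)
  dec <- viterbiDecode(model, walk$seq)$path
  labels <- env@info$roomLabels
  # the maze walk is reversible, so communities are detected on the
  # symmetrized flow; three rounds give chunks -> rooms -> hyper-rooms
  hier <- buildHierarchy(model, levels = 3L, seed = seed,
                         directed = FALSE)
  used <- as.integer(igraph::V(hier@graph)$name)
  cloneRoom <- vapply(used, function(cl) {
    labs <- labels[walk$positions[dec == cl]]
    tab <- table(labs)
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
  list(model = model, env = env, walk = walk, hier = hier,
       cloneRoom = cloneRoom, usedClones = used)
}

#' Run a named experiment and write a report
#'
#' The experiment harness behind the command-line interface: runs one of
#' the packaged experiments at a desk scale, writes a `metrics.json` report
#' (numbers formatted at 12 significant digits, so identical runs produce
#' byte-identical files) plus trace TSVs, and returns the metrics.
#'
#' @param name one of `"aliased_room"`, `"overlap_stitching"`,
#'   `"schema_transfer"`, `"routes"`, `"lap_track"`, `"remapping"`,
#'   `"error_correction"`, `"hierarchy"`.
#' @param seed integer seed.
#' @param outDir output directory (created if missing).
#' @param overrides named list of parameter overrides for the underlying
#'   pipeline.
#' @return the metrics list, invisibly.
#' @export
runExperiment <- function(name = c("aliased_room", "overlap_stitching",
                                   "schema_transfer", "routes", "lap_track",
                                   "remapping", "error_correction",
                                   "hierarchy"),
                          seed = 1L, outDir = ".", overrides = list()) {
  name <- tryCatch(match.arg(name),
                   error = function(e) stop("unknown experiment name"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  callWith <- function(fn, defaults) {
    args <- utils::modifyList(defaults, overrides)
    do.call(fn, args)
  }
  metrics <- switch(name,
    aliased_room = {
      p <- callWith(aliasedRoomPipeline,
                    list(seed = seed, steps = 10000L, maxIter = 200L,
                         tol = 1e-8))
      saveModel(p$model, file.path(outDir, "model.json"))
      list(distinct_viterbi_states = p$distinctStates,
           optimal_states = nrow(p$env@grid) * ncol(p$env@grid),
           final_loglik = utils::tail(modelMeta(p$model)$loglikTrace, 1L))
    },
    overlap_stitching = {
      p <- callWith(overlapPipeline, list(seed = seed, steps = 5000L))
      list(overlap_clones_match =
             all(p$overlapClones1 == p$overlapClones2),
           confounder_disjoint =
             length(intersect(p$confounderClones, p$overlapClones1)) == 0L,
           held_out_accuracy = p$heldOutAccuracy)
    },
    schema_transfer = {
      p <- callWith(schemaTransferPipeline,
                    list(seed = seed, steps1 = 5000L, steps2 = 5000L))
      list(room2_accuracy = p$accuracy2, all_visited = p$allVisited)
    },
    routes = {
      p <- callWith(routesPipeline, list(seed = seed))
      sm <- smoothPosterior(p$model, p$routeTrials[[1L]]$seq)
      list(n_states = nStates(p$model),
           n_used = length(modelMeta(p$model)$usedStates),
           trial_loglik = sm@logLik)
    },
    lap_track = {
      p <- callWith(lapTrackPipeline, list(seed = seed))
      list(reward_probability = p$rewardProb,
           n_used = length(modelMeta(p$model)$usedStates))
    },
    remapping = {
      p <- callWith(fiveEnvPipeline, list(seed = seed, steps = 5000L))
      ov <- remapOverlap(p$model, p$envs, seed = seed)
      for (i in seq_along(p$envs)) {
        w <- randomWalk(p$envs[[i]], 50L, seed = seed + 50L + i)
        post <- environmentPosterior(p$model, p$cloneSets, w$seq)
        utils::write.table(
          data.frame(step = seq_len(ncol(post)), t(post)),
          file.path(outDir, sprintf("room%d_posterior.tsv", i)),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
      list(mean_overlap = ov$meanOverlap,
           max_activation = ov$maxActivation)
    },
    error_correction = {
      p <- callWith(fiveEnvPipeline, list(seed = seed, steps = 5000L))
      runs <- lapply(1:5, function(s) errorCorrectionRun(p, seed = s))
      list(correction_rate = sum(vapply(runs, `[[`, 0, "nCorrected")) /
             sum(vapply(runs, `[[`, 0, "nCorrupted")),
           false_corrections = sum(vapply(runs, `[[`, 0, "nFalse")))
    },
    hierarchy = {
      p <- callWith(hierMazePipeline,
                    list(seed = seed, steps = 40000L, clones = 20L,
                         maxIter = 100L, nRestarts = 1L))
      writeGraphTSV(p$hier@graph, file.path(outDir, "clone_graph.tsv"))
      list(level1_communities =
             length(unique(p$hier@partitions[[1L]])),
           level2_communities =
             length(unique(p$hier@partitions[[2L]])),
           n_used_clones = length(p$usedClones))
    })
  json <- jsonlite::toJSON(c(list(experiment = name, seed = seed), metrics),
                           auto_unbox = TRUE, digits = I(12), pretty = TRUE)
  writeLines(json, file.path(outDir, "metrics.json"))
  invisible(metrics)
}
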