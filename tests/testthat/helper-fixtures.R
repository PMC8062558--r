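# Trained-model fixtures shared across test files, built once per test run.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# small trained room model for planning / graph tests (fast: ~seconds)
smallRoomFixture <- function() {
  cachedFixture("smallRoom", {
    env <- makeRoom(4, 5, 12, seed = 11)
    walk <- randomWalk(env, 8000, seed = 12)
    model <- suppressWarnings(
      fitCSCG(walk$seq, clonesPerObs = 10L, nObs = 12L, nActions = 4L,
              kappa = 1e-2, maxIter = 600L, tol = 1e-9, seed = 11,
              viterbiIter = 50L))
    list(env = env, walk = walk, model = model,
         cloneMap = positionCloneMap(model, walk))
  })
}

fiveRoomFixture <- function() {
  cachedFixture("fiveRoom",
    suppressWarnings(
    fiveEnvPipeline("rooms", seed = 21, steps = 10000L, clones = 10L,
                    kappa = 1e-3, maxIter = 500L)))
}

fiveRoomPartialFixture <- function() {
  cachedFixture("fiveRoomPartial",
    suppressWarnings(
    fiveEnvPipeline("rooms", seed = 21, steps = 10000L, clones = 10L,
                    kappa = 1e-3, maxIter = 10L)))
}

overlapFixture <- function() {
  cachedFixture("overlap", suppressWarnings(
    overlapPipeline(seed = 31)))
}

schemaFixture <- function() {
  cachedFixture("schema", suppressWarnings(
    schemaTransferPipeline(seed = 41)))
}

lapFixture <- function() {
  cachedFixture("lap", suppressWarnings(
    lapTrackPipeline(seed = 51)))
}

tmazeFixture <- function() {
  cachedFixture("tmaze", suppressWarnings(
    routesPipeline("tmaze_fig8", seed = 61)))
}

stochasticRoutesFixture <- function() {
  cachedFixture("stochRoutes",
    suppressWarnings(
    routesPipeline("stochastic_routes", seed = 71, nPaths = 400L,
                   clones = 12L)))
}

modularFixture <- function() {
  cachedFixture("modular", suppressWarnings(
    modularGraphPipeline(seed = 81, steps = 50000L, clones = 4L,
                         nRestarts = 30L)))
}

hierMazeFixture <- function() {
  cachedFixture("hierMaze",
    suppressWarnings(
    hierMazePipeline(seed = 91, steps = 120000L, clones = 40L,
                     kappa = 2e-3, maxIter = 200L, nRestarts = 1L)))
}
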