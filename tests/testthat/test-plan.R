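test_that("planning handles trivial and deterministic goals", {
  m <- cycleModel(4)
  # start equals goal: horizon 0, empty action list
  p0 <- planPath(m, 1, 1, goalType = "clone")
  expect_equal(p0$horizon, 0)
  expect_length(p0$actions, 0)
  # around the cycle
  p <- planPath(m, 1, 3, goalType = "clone")
  expect_equal(p$horizon, 2)
  expect_equal(p$clonePath, 1:3)
  # observation goal reaches the earliest step any clone of the symbol
  # is reachable
  pObs <- planPath(m, 1, 2, goalType = "observation")
  expect_equal(pObs$horizon, 1)
  # infeasible: cycle cannot run backwards in one step budget 0
  expect_error(planPath(m, 1, 4, goalType = "clone", maxHorizon = 1),
               class = "cscg_infeasible_goal")
})

test_that("plans on a learned room match the grid-graph shortest path", {
  fx <- smallRoomFixture()
  oracle <- gridGraphOracle(fx$env)
  h <- nrow(fx$env@grid)
  cm <- fx$cloneMap
  cells <- which(!is.na(cm))
  withr::with_seed(77, {
    pairs <- replicate(25, sample(cells, 2), simplify = FALSE)
  })
  for (pr in pairs) {
    want <- oracle$dist(pr[1], pr[2])
    pl <- planPath(fx$model, cm[pr[1]], cm[pr[2]], goalType = "clone")
    expect_equal(pl$horizon, want)
    # soundness: consecutive plan steps are legal grid moves
    expect_true(all(vapply(seq_along(pl$actions), function(n) {
      fx$model@transitions[pl$clonePath[n], pl$actions[n],
                           pl$clonePath[n + 1]] > 0
    }, logical(1))))
  }
})

test_that("removing blocked cells reroutes plans to the blocked-graph optimum", {
  fx <- smallRoomFixture()
  cm <- fx$cloneMap
  h <- nrow(fx$env@grid)
  start <- 1L                      # top-left corner cell
  goal <- length(fx$env@grid)      # bottom-right corner cell
  # block a column of interior cells to force a detour
  blocked <- c((2 - 1) * h + 2, (2 - 1) * h + 3)  # cells (2,2), (3,2)
  oracle <- gridGraphOracle(fx$env, blockedCells = blocked)
  want <- oracle$dist(start, goal)
  pl <- planPath(fx$model, cm[start], cm[goal], goalType = "clone",
                 blockedStates = stats::na.omit(cm[blocked]))
  expect_equal(pl$horizon, want)
})

test_that("execution replans around unexpected obstacles", {
  fx <- smallRoomFixture()
  cm <- fx$cloneMap
  env <- fx$env
  h <- nrow(env@grid)

  # obstacle-free execution: the original plan runs verbatim, zero replans
  res <- executeAndReplan(env, fx$model, start = c(1, 1),
                          goal = cm[(5 - 1) * h + 4], cloneMap = cm)
  expect_true(res$reached)
  expect_equal(res$replans, 0)

  # wall inserted after training, placed on the nominal plan so the agent
  # must discover it and reroute
  goalClone <- cm[(5 - 1) * h + 4]
  nominal <- planPath(fx$model, cm[1], goalClone, goalType = "clone")
  midClone <- nominal$clonePath[3]
  midCell <- which(cm == midClone)[1]
  gBlocked <- env@grid
  gBlocked[midCell] <- 0L
  envB <- new("GridEnvironment", grid = gBlocked, nObs = env@nObs,
              name = "blocked", seed = env@seed, info = list())
  resB <- executeAndReplan(envB, fx$model, start = c(1, 1),
                           goal = goalClone, cloneMap = cm)
  expect_true(resB$reached)
  expect_gte(resB$replans, 1)
  expect_true(all(gBlocked[resB$trajectory] != 0))

  # fully walled-off goal: failure result, no infinite loop
  gWall <- env@grid
  gWall[3, ] <- 0L                  # cut the room in two
  envW <- new("GridEnvironment", grid = gWall, nObs = env@nObs,
              name = "walled", seed = env@seed, info = list())
  goalCell <- (1 - 1) * h + 4       # cell (4, 1), below the cut
  resW <- executeAndReplan(envW, fx$model, start = c(1, 1),
                           goal = cm[goalCell], cloneMap = cm,
                           maxSteps = 200)
  expect_false(resW$reached)
})
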