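test_that("rooms have the requested shape, alphabet and determinism", {
  env <- makeRoom(6, 8, 4, seed = 3)
  expect_equal(dim(env@grid), c(6L, 8L))
  expect_setequal(unique(as.vector(env@grid)), 1:4)  # coverage
  expect_identical(makeRoom(6, 8, 4, seed = 3)@grid, env@grid)
  expect_false(identical(makeRoom(6, 8, 4, seed = 4)@grid, env@grid))
  expect_error(makeRoom(2, 2, 5, seed = 1), "symbols")

  u <- makeRoom(6, 8, 5, seed = 2, uniformInterior = TRUE)
  interior <- u@grid[2:5, 2:7]
  expect_true(all(interior == 1L))
  border <- c(u@grid[1, ], u@grid[6, ], u@grid[, 1], u@grid[, 8])
  expect_true(all(border != 1L))
})

test_that("overlapping rooms share one patch and carry one confounder", {
  rr <- makeOverlappingRooms(seed = 9)
  g1 <- rr$room1@grid; g2 <- rr$room2@grid
  expect_equal(dim(g1), c(8L, 6L))
  expect_equal(dim(g2), c(8L, 6L))
  a <- rr$annotations
  patch <- g1[a$overlap1$rows, a$overlap1$cols]
  expect_identical(g2[a$overlap2$rows, a$overlap2$cols], patch)
  expect_identical(g1[a$confounder$rows, a$confounder$cols], patch)
  # confounder and overlap are disjoint, non-adjacent cell sets in room 1
  expect_length(intersect(
    outer(a$overlap1$rows, a$overlap1$cols, paste),
    outer(a$confounder$rows, a$confounder$cols, paste)), 0)

  # exactly two copies of the patch in room 1, exactly one in room 2
  countPatches <- function(g, patch) {
    n <- 0
    for (r in 1:(nrow(g) - 2)) for (c in 1:(ncol(g) - 2))
      if (identical(g[r:(r + 2), c:(c + 2)], patch)) n <- n + 1
    n
  }
  expect_equal(countPatches(g1, patch), 2)
  expect_equal(countPatches(g2, patch), 1)
})

test_that("hierarchical maze tiles rooms with bridges and four quadrants", {
  env <- makeHierarchicalMaze(seed = 5)
  g <- env@grid
  syms <- unique(as.vector(g[g != 0]))
  expect_true(all(syms %in% 1:13))
  labels <- env@info$roomLabels
  expect_equal(sort(unique(as.vector(labels[labels > 0]))), 1:16)
  expect_equal(sort(unique(env@info$quadrant)), 1:4)

  # removing bridge cells disconnects the maze into exactly 16 rooms
  noBridge <- g
  noBridge[noBridge == 13L] <- 0L
  visited <- matrix(FALSE, nrow(g), ncol(g))
  comps <- 0
  for (start in which(noBridge != 0)) {
    if (visited[start]) next
    comps <- comps + 1
    queue <- start
    visited[start] <- TRUE
    h <- nrow(g)
    while (length(queue)) {
      cell <- queue[1]; queue <- queue[-1]
      r <- (cell - 1) %% h + 1; c <- (cell - 1) %/% h + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- r + d[1]; c2 <- c + d[2]
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= ncol(g)) {
          cell2 <- (c2 - 1) * h + r2
          if (noBridge[cell2] != 0 && !visited[cell2]) {
            visited[cell2] <- TRUE
            queue <- c(queue, cell2)
          }
        }
      }
    }
  }
  expect_equal(comps, 16)

  # bridges between quadrants: exactly one per adjacent quadrant pair
  bp <- env@info$bridgedPairs
  quad <- env@info$quadrant
  cross <- vapply(bp, function(p) quad[p[1]] != quad[p[2]], logical(1))
  crossKeys <- vapply(bp[cross], function(p)
    paste(sort(quad[p]), collapse = "-"), character(1))
  expect_false(anyDuplicated(crossKeys) > 0)
})

test_that("the modular graph is three aliased degree-4 clusters", {
  env <- makeModularGraph(seed = 2)
  expect_length(env@obs, 15)
  deg <- vapply(env@successors, length, integer(1))
  expect_true(all(deg == 4))
  expect_equal(env@info$communities, rep(1:3, each = 5))
  expect_lt(length(unique(env@obs)), 15)  # aliased labels
  # symmetric adjacency
  for (i in seq_along(env@successors))
    for (j in env@successors[[i]])
      expect_true(i %in% env@successors[[j]])
})

test_that("the lap track is start + four laps + reward", {
  lt <- makeLapTrack()
  obs <- observations(lt$train)
  expect_length(obs, 50)
  expect_equal(obs[1], 13L)
  expect_equal(obs[50], 14L)
  expect_equal(obs[2:49], rep(1:12, 4))
  expect_equal(sum(obs == 1L), 4)  # four laps

  el <- makeLapTrack(elongation = 2)
  expect_identical(observations(el$train), obs)
  extra <- observations(el$test)
  expect_length(extra, 50 + 4 * 2)
  # the elongated sequence differs only by repeated corridor symbols
  expect_identical(unique(extra), unique(obs))
  expect_equal(sum(extra == 6L), 4 * 3)
})

test_that("route environments expose their overlap segments", {
  tm <- makeRouteEnvironment("tmaze_fig8")
  expect_equal(tm@info$overlapObs, c(1L, 2L, 3L))
  # left and right routes contain the identical stem subsequence
  p <- sampleRoutePaths(tm, 2, seed = 1)
  expect_equal(observations(p[[1]])[1:3], c(1L, 2L, 3L))
  expect_equal(observations(p[[2]])[1:3], c(1L, 2L, 3L))
  expect_false(identical(observations(p[[1]]), observations(p[[2]])))

  sr <- makeRouteEnvironment("stochastic_routes")
  expect_equal(sr@info$overlapObs, c(4L, 5L, 11L, 12L, 13L, 5L, 17L))
  paths <- sampleRoutePaths(sr, 60, seed = 2)
  for (sq in paths) {
    nodes <- attr(sq, "nodes")
    for (n in seq_len(length(nodes) - 1))
      expect_true(nodes[n + 1] %in% sr@successors[[nodes[n]]])
    # overlap segment appears verbatim in every trial
    expect_true(any(vapply(seq_len(length(sq@observations) - 6),
      function(i) all(sq@observations[i:(i + 6)] ==
                      sr@info$overlapObs), logical(1))))
  }
  expect_error(makeRouteEnvironment("nope"), "unknown")
})

test_that("remapping sets share alphabets across five environments", {
  rooms <- makeRemappingSet("rooms", seed = 6)
  expect_length(rooms, 5)
  for (e in rooms) expect_equal(sort(as.vector(e@grid)), 1:25)
  expect_false(identical(rooms[[1]]@grid, rooms[[2]]@grid))

  mazes <- makeRemappingSet("mazes", seed = 6)
  expect_length(mazes, 5)
  for (e in mazes) {
    expect_equal(e@nObs, 6L)
    open <- e@grid[e@grid != 0]
    expect_true(all(open %in% 1:6))
    # closed loop: every open cell has exactly two open neighbours
    g <- e@grid; h <- nrow(g)
    for (cell in which(g != 0)) {
      r <- (cell - 1) %% h + 1; c <- (cell - 1) %/% h + 1
      nb <- 0
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- r + d[1]; c2 <- c + d[2]
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= ncol(g) &&
            g[r2, c2] != 0) nb <- nb + 1
      }
      expect_equal(nb, 2)
    }
  }
})

test_that("random walks respect walls and reproduce by seed", {
  env <- makeRemappingSet("mazes", seed = 1)[[1]]
  w <- randomWalk(env, 500, seed = 4)
  expect_true(all(env@grid[w$positions] != 0))
  expect_identical(randomWalk(env, 500, seed = 4)$seq@observations,
                   w$seq@observations)

  # 1 x 2 room: the two legal moves alternate deterministically
  tiny <- makeRoom(1, 2, 2, seed = 1)
  wt <- randomWalk(tiny, 10, seed = 1)
  expect_true(all(abs(diff(wt$positions)) == 1))
  expect_equal(length(unique(wt$seq@observations[1:2])), 2)

  # walk action distribution matches the uniform-over-legal-moves kernel
  env2 <- makeRoom(4, 4, 3, seed = 8)
  w2 <- randomWalk(env2, 20000, seed = 9)
  h <- 4
  moves <- diff(w2$positions)
  fromCorner <- which(w2$positions[-length(w2$positions)] == 1)
  tab <- table(factor(moves[fromCorner], levels = c(1, h)))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("sequence corruption flips the right number of symbols", {
  sq <- AOSequence(rep(1:5, 200), nObs = 5)
  c0 <- corruptSequence(sq, 0, seed = 1)
  expect_identical(c0$seq@observations, sq@observations)
  expect_false(any(c0$mask))

  c1 <- corruptSequence(sq, 0.2, seed = 2)
  expect_true(all(c1$seq@observations[c1$mask] !=
                  sq@observations[c1$mask]))
  expect_true(all(c1$seq@observations[!c1$mask] ==
                  sq@observations[!c1$mask]))
  n <- length(sq@observations)
  expect_lt(abs(sum(c1$mask) - 0.2 * n), 3 * sqrt(n * 0.2 * 0.8))
  expect_error(corruptSequence(sq, 1), "probability")
})

test_that("environments round-trip through JSON", {
  env <- makeRoom(3, 4, 5, seed = 2)
  f <- withr::local_tempfile(fileext = ".json")
  writeEnvironment(env, f)
  env2 <- readEnvironment(f)
  expect_identical(env2@grid, env@grid)
  expect_equal(env2@nObs, env@nObs)

  rg <- makeRouteEnvironment("odor_sequences")
  writeEnvironment(rg, f)
  rg2 <- readEnvironment(f)
  expect_identical(rg2@obs, rg@obs)
  expect_identical(rg2@successors, rg@successors)
  expect_identical(rg2@routeStarts, rg@routeStarts)
})
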