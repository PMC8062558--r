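test_that("the transition graph of a deterministic cycle is a directed ring", {
  m <- cycleModel(3)
  m@metadata$usedStates <- 1:3
  g <- transitionGraph(m, floor = 0)
  expect_equal(igraph::vcount(g), 3)
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 3)
  expect_setequal(paste(el[, 1], el[, 2]),
                  c("1 2", "2 3", "3 1"))
  expect_equal(igraph::V(g)$symbol, 1:3)
})

test_that("a floored graph of a deterministic world has one edge per bigram", {
  fx <- smallRoomFixture()
  g <- transitionGraph(fx$model)
  dec <- viterbiDecode(fx$model, fx$walk$seq)$path
  bigrams <- unique(paste(dec[-length(dec)], dec[-1]))
  el <- igraph::as_edgelist(g)
  expect_setequal(paste(el[, 1], el[, 2]), bigrams)
})

test_that("community detection separates disconnected components", {
  # two disconnected directed 4-cliques
  g <- igraph::make_empty_graph(8, directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(1:8))
  for (a in 1:4) for (b in 1:4) if (a != b)
    g <- igraph::add_edges(g, c(a, b, a + 4, b + 4), weight = 1)
  cm <- detectCommunities(g, seed = 1)
  expect_equal(cm$nCommunities, 2)
  expect_length(unique(cm$membership[1:4]), 1)
  expect_length(unique(cm$membership[5:8]), 1)
  expect_false(cm$membership[1] == cm$membership[5])
  expect_error(detectCommunities(igraph::make_empty_graph(0)), "empty")
})

test_that("hierarchies collapse communities without losing nodes", {
  fx <- smallRoomFixture()
  hier <- buildHierarchy(fx$model, levels = 2, seed = 1)
  n0 <- igraph::vcount(hier@graph)
  expect_length(hier@partitions[[1]], n0)
  # level l+1 node count equals level l community count
  expect_equal(igraph::vcount(hier@levelGraphs[[1]]),
               length(unique(hier@partitions[[1]])))
  expect_equal(igraph::vcount(hier@levelGraphs[[2]]),
               length(unique(hier@partitions[[2]])))
  # a graph that is one community collapses to single nodes above
  ring <- igraph::make_ring(4, directed = TRUE)
  ring <- igraph::set_vertex_attr(ring, "name", value = as.character(1:4))
  igraph::E(ring)$weight <- 1
  h2 <- buildHierarchy(ring, levels = 2, seed = 1)
  expect_equal(igraph::vcount(h2@levelGraphs[[2]]), 1)
})

test_that("hierarchical plans are valid level-0 walks reaching the goal", {
  fx <- smallRoomFixture()
  hier <- buildHierarchy(fx$model, levels = 2, seed = 1)
  W <- marginalTransitions(fx$model)
  nodes <- as.integer(igraph::V(hier@graph)$name)
  withr::with_seed(5, {
    pairs <- replicate(20, sample(nodes, 2), simplify = FALSE)
  })
  oracle <- gridGraphOracle(fx$env)
  cm <- fx$cloneMap
  cellOf <- function(clone) which(cm == clone)[1]
  pairs <- Filter(function(pr) !is.na(cellOf(pr[1])) && !is.na(cellOf(pr[2])),
                  pairs)
  expect_gt(length(pairs), 10)
  for (pr in pairs) {
    path <- hierarchicalPlan(hier, pr[1], pr[2])
    expect_equal(path[1], pr[1])
    expect_equal(path[length(path)], pr[2])
    if (length(path) > 1)
      for (n in seq_len(length(path) - 1))
        expect_gt(W[path[n], path[n + 1]], 0)
    # refinement within selected communities stays near the flat optimum
    flat <- oracle$dist(cellOf(pr[1]), cellOf(pr[2]))
    expect_lte(length(path) - 1, ceiling(1.5 * flat))
  }
  # start equals goal: single-node path
  expect_equal(hierarchicalPlan(hier, nodes[1], nodes[1]), nodes[1])
})

test_that("surrogate partitions preserve sizes and make plans worse", {
  # a world with clear modular structure: two reversible rings joined by
  # a single bidirectional bridge (as in a physical maze, every move can
  # be undone)
  g <- igraph::make_empty_graph(20, directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(1:20))
  for (i in 1:10) {
    j <- i %% 10 + 1
    g <- igraph::add_edges(g, c(i, j, j, i), weight = 1)
    g <- igraph::add_edges(g, c(10 + i, 10 + j, 10 + j, 10 + i), weight = 1)
  }
  g <- igraph::add_edges(g, c(1, 11, 11, 1), weight = 1)
  hier <- buildHierarchy(g, levels = 1, seed = 1)
  p1 <- hier@partitions[[1]]
  expect_gt(length(unique(p1)), 1)

  sur <- surrogatePartition(p1, seed = 3)
  expect_equal(sort(tabulate(sur)), sort(tabulate(as.integer(p1))))
  expect_false(identical(as.integer(sur), as.integer(p1)))

  hierS <- rebuildHierarchy(hier, sur, seed = 3)
  nodes <- as.integer(igraph::V(g)$name)
  withr::with_seed(8, {
    pairs <- replicate(15, sample(nodes, 2), simplify = FALSE)
  })
  lenTrue <- lenSur <- numeric(0)
  nSurFail <- 0
  for (pr in pairs) {
    lt <- tryCatch(length(hierarchicalPlan(hier, pr[1], pr[2])),
                   cscg_infeasible_goal = function(e) NA_integer_)
    ls <- tryCatch(length(hierarchicalPlan(hierS, pr[1], pr[2])),
                   cscg_infeasible_goal = function(e) NA_integer_)
    expect_false(is.na(lt))  # the true partition always yields a plan
    if (is.na(ls)) nSurFail <- nSurFail + 1
    else { lenTrue <- c(lenTrue, lt); lenSur <- c(lenSur, ls) }
  }
  # scrambled communities are never better: longer plans on average, or
  # outright failures to refine
  expect_gte(length(lenTrue) + nSurFail, 10)
  if (length(lenTrue)) expect_gte(mean(lenSur), mean(lenTrue))
})


test_that("an exactly learned maze yields rooms and four hyper-rooms", {
  env <- makeHierarchicalMaze(seed = 5)
  m <- idealGridModel(env)
  hier <- buildHierarchy(m, levels = 3, seed = 1, directed = FALSE)
  sizes <- vapply(hier@partitions, function(p) length(unique(p)), 1L)
  # chunks -> rooms -> hyper-rooms
  expect_equal(sizes[2], 16)
  expect_equal(sizes[3], 4)
  # no community at any level straddles rooms / quadrants
  cells <- attr(m, "cellOrder")
  roomOf <- env@info$roomLabels[cells]
  m1 <- as.integer(hier@partitions[[1]])
  straddle <- tapply(roomOf[roomOf > 0], m1[roomOf > 0],
                     function(r) length(unique(r)))
  expect_true(all(straddle == 1))
  quad <- env@info$quadrant
  comm1room <- tapply(roomOf[roomOf > 0], m1[roomOf > 0],
                      function(r) unique(r)[1])
  top <- as.integer(hier@partitions[[3]])[
    as.integer(hier@partitions[[2]])[as.integer(names(comm1room))]]
  expect_true(all(tapply(quad[comm1room], top,
                         function(q) length(unique(q))) == 1))

  # hierarchical search expands fewer nodes than flat search
  nodes <- as.integer(igraph::V(hier@graph)$name)
  withr::with_seed(3, prs <- replicate(10, sample(nodes, 2), simplify = FALSE))
  eff <- lapply(prs, function(pr) planningEffort(hier, pr[1], pr[2]))
  expect_true(mean(vapply(eff, `[[`, 0, "hierarchical")) <
              mean(vapply(eff, `[[`, 0, "flat")))
  # refinement within the selected communities stays near the flat
  # optimum on average; individual pairs may detour when the top-level
  # hop-count path commits to a longer corridor
  ratio <- vapply(eff, function(e) e$hierLength / max(e$flatLength, 1),
                  numeric(1))
  expect_lte(mean(ratio), 1.5)
  expect_true(all(ratio <= 2.5))
})
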