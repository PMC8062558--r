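# Independent brute-force oracles: exhaustive enumeration over all clone
# paths (feasible for H <= 8, N <= 8). These never call the package's
# message-passing kernels.

enumPaths <- function(model, obs) {
  al <- allocation(model)
  ranges <- lapply(obs, function(s) cloneRange(al, s))
  N <- length(obs)
  as.matrix(expand.grid(rev(ranges)))[, N:1, drop = FALSE]
}

pathProbs <- function(model, paths, obs, act) {
  T <- transitionTensor(model)
  N <- length(obs)
  apply(paths, 1, function(z) {
    pr <- priorProb(model)[z[1]]
    if (N > 1) for (n in 1:(N - 1)) pr <- pr * T[z[n], act[n], z[n + 1]]
    pr
  })
}

oracleLoglik <- function(model, obs, act) {
  paths <- enumPaths(model, obs)
  log(sum(pathProbs(model, paths, obs, act)))
}

# full posterior statistics: per-step state marginals (H x N), expected
# transition counts (H x Na x H), filtered marginals (H x N)
oraclePosteriors <- function(model, obs, act) {
  paths <- enumPaths(model, obs)
  probs <- pathProbs(model, paths, obs, act)
  Z <- sum(probs)
  H <- nStates(model)
  N <- length(obs)
  gam <- matrix(0, H, N)
  counts <- array(0, dim = dim(transitionTensor(model)))
  for (r in seq_len(nrow(paths))) {
    z <- paths[r, ]
    w <- probs[r] / Z
    for (n in seq_len(N)) gam[z[n], n] <- gam[z[n], n] + w
    if (N > 1) for (n in 1:(N - 1))
      counts[z[n], act[n], z[n + 1]] <- counts[z[n], act[n], z[n + 1]] + w
  }
  # filtered marginals at n: renormalized over prefix probabilities
  filt <- matrix(0, H, N)
  for (n in seq_len(N)) {
    pre <- enumPaths(model, obs[1:n])
    pp <- pathProbs(model, pre, obs[1:n], act[seq_len(max(n - 1, 0))])
    for (r in seq_len(nrow(pre))) filt[pre[r, n], n] <- filt[pre[r, n], n] + pp[r]
    filt[, n] <- filt[, n] / sum(filt[, n])
  }
  list(gamma = gam, counts = counts, filtered = filt, loglik = log(Z))
}

oracleViterbi <- function(model, obs, act) {
  paths <- enumPaths(model, obs)
  probs <- pathProbs(model, paths, obs, act)
  best <- max(probs)
  # lowest-index tie break: first row among maxima in row-major enumeration
  # is not necessarily the lexicographically smallest path, so pick it
  # explicitly
  cand <- paths[probs >= best - 1e-300 & probs == best, , drop = FALSE]
  ord <- do.call(order, as.data.frame(cand))
  list(path = cand[ord[1], ], logprob = log(best))
}

# random small model + sequence for parameterised oracle tests
randomSmallCase <- function(seed, maxE = 3, maxM = 2, maxNa = 2, maxN = 7) {
  withr::with_seed(seed, {
    E <- sample(2:maxE, 1)
    M <- sample(1:maxM, E, replace = TRUE)
    Na <- sample(1:maxNa, 1)
    N <- sample(2:maxN, 1)
    obs <- sample(seq_len(E), N, replace = TRUE)
    act <- sample(seq_len(Na), N - 1, replace = TRUE)
    list(model = makeCSCG(CloneAllocation(M), Na, seed = seed),
         obs = obs, act = act,
         seq = AOSequence(obs, act, nObs = E, nActions = Na))
  })
}

# Dijkstra oracle on the generating grid environment (unit edge weights);
# cells are (row, col); blocked cells may be removed
gridGraphOracle <- function(env, blockedCells = NULL) {
  g <- env@grid
  h <- nrow(g); w <- ncol(g)
  open <- which(g != 0L)
  if (!is.null(blockedCells)) open <- setdiff(open, blockedCells)
  idx <- match(seq_len(h * w), open)
  edges <- c()
  for (cell in open) {
    r <- (cell - 1) %% h + 1; c <- (cell - 1) %/% h + 1
    for (d in list(c(-1, 0), c(0, 1), c(1, 0), c(0, -1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
        cell2 <- (c2 - 1) * h + r2
        if (cell2 %in% open)
          edges <- c(edges, idx[cell], idx[cell2])
      }
    }
  }
  gr <- igraph::make_graph(edges, n = length(open), directed = TRUE)
  list(graph = gr, cells = open,
       dist = function(fromCell, toCell)
         as.numeric(igraph::distances(gr, match(fromCell, open),
                                      match(toCell, open), mode = "out")))
}

# deterministic 2-state (or k-state) cycle model under one action
cycleModel <- function(k = 2, clones = 1) {
  al <- CloneAllocation(rep(clones, k))
  m <- makeCSCG(al, 1L, init = "uniform")
  H <- nStates(m)
  tr <- array(0, dim = c(H, 1, H))
  for (s in 1:k) {
    from <- cloneRange(al, s)[1]
    to <- cloneRange(al, s %% k + 1)[1]
    tr[from, 1, to] <- 1
    for (extra in cloneRange(al, s)[-1]) tr[extra, 1, to] <- 1
  }
  p <- numeric(H)
  p[1] <- 1
  m@transitions <- tr
  m@prior <- p
  m
}


# exactly learned model of a grid environment: one clone per open cell,
# transitions deterministic per legal action, uniform elsewhere-free
idealGridModel <- function(env) {
  g <- env@grid
  h <- nrow(g)
  open <- which(g != 0L)
  sym <- g[open]
  ord <- order(sym)
  rank <- match(seq_along(open), ord)
  al <- CloneAllocation(as.integer(table(factor(sym[ord],
                                                levels = seq_len(env@nObs)))))
  H <- length(open)
  tr <- array(0, dim = c(H, 4, H))
  mv <- matrix(c(-1, 0, 0, 1, 1, 0, 0, -1), 4, 2, byrow = TRUE)
  id <- match(seq_along(g), open)
  for (cell in open) {
    r <- (cell - 1) %% h + 1
    c <- (cell - 1) %/% h + 1
    for (a in 1:4) {
      r2 <- r + mv[a, 1]; c2 <- c + mv[a, 2]
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= ncol(g) && g[r2, c2] != 0)
        tr[rank[id[cell]], a, rank[id[(c2 - 1) * h + r2]]] <- 1
    }
  }
  flat <- matrix(tr, nrow = H)
  tr <- array(flat / rowSums(flat), dim = dim(tr))
  m <- new("CSCGModel", allocation = al, nActions = 4L,
           prior = rep(1 / H, H), transitions = tr,
           emission = matrix(numeric(0), 0, 0), emissionMode = "clone",
           metadata = list(usedStates = seq_len(H)))
  attr(m, "cellOrder") <- open[ord]   # cell id of each state
  m
}
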