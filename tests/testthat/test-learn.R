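test_that("forward pass reproduces hand-computable log-likelihoods", {
  # deterministic 2-state cycle: the observed alternation has probability 1
  m <- cycleModel(2)
  sq <- AOSequence(c(1L, 2L, 1L, 2L), rep(1L, 3), nObs = 2, nActions = 1)
  expect_equal(logLikelihood(m, sq), 0)
  # single observation: loglik = log of prior mass on that symbol's clones
  m2 <- makeCSCG(CloneAllocation(c(2L, 3L)), 1L, seed = 3)
  expect_equal(logLikelihood(m2, AOSequence(2L, nObs = 2)),
               log(sum(priorProb(m2)[cloneRange(m2, 2)])))
  # impossible sequence under an unsmoothed model flags -Inf, no error
  bad <- AOSequence(c(1L, 1L), 1L, nObs = 2, nActions = 1)
  expect_identical(logLikelihood(m, bad), -Inf)
})

test_that("messages, posteriors and decode match exhaustive enumeration", {
  for (seed in 1:40) {
    cs <- randomSmallCase(seed)
    or <- oraclePosteriors(cs$model, cs$obs, cs$act)
    expect_equal(logLikelihood(cs$model, cs$seq), or$loglik,
                 tolerance = 1e-10)
    st <- eStep(cs$model, cs$seq, keepGammas = TRUE)
    expect_equal(st$counts, or$counts, tolerance = 1e-10)
    # per-step smoothed marginals
    gam <- st$gammas[[1]]
    al <- allocation(cs$model)
    for (n in seq_along(cs$obs)) {
      full <- numeric(nStates(cs$model))
      full[cloneRange(al, cs$obs[n])] <- gam[[n]]
      expect_equal(full, or$gamma[, n], tolerance = 1e-10)
    }
    # filtered marginals (full-state trace)
    tr <- filterPosterior(cs$model, cs$seq)
    expect_equal(activationMatrix(tr), or$filtered, tolerance = 1e-10)
    # smoothed trace equals enumeration gammas
    sm <- smoothPosterior(cs$model, cs$seq)
    expect_equal(activationMatrix(sm), or$gamma, tolerance = 1e-10)
    # Viterbi matches brute-force argmax: same maximal probability, and
    # the decoded path itself attains it (ties may differ in path identity)
    vt <- viterbiDecode(cs$model, cs$seq)
    ov <- oracleViterbi(cs$model, cs$obs, cs$act)
    expect_equal(vt$logProb, ov$logprob, tolerance = 1e-10)
    pp <- pathProbs(cs$model, matrix(vt$path, nrow = 1), cs$obs, cs$act)
    expect_equal(log(pp), ov$logprob, tolerance = 1e-10)
  }
})

test_that("e-step statistics are normalized and additive across sequences", {
  cs <- randomSmallCase(99)
  st <- eStep(cs$model, cs$seq, keepGammas = TRUE)
  expect_equal(sum(st$counts), length(cs$obs) - 1)  # each xi(n) sums to 1
  expect_equal(sum(st$gamma1), 1)
  for (g in st$gammas[[1]]) expect_equal(sum(g), 1)
  # two copies of the sequence double the statistics
  st2 <- eStep(cs$model, list(cs$seq, cs$seq))
  expect_equal(st2$counts, 2 * st$counts)
  expect_equal(st2$loglik, 2 * st$loglik)
})

test_that("e-step cost scales with clone blocks, not alphabet size", {
  obs <- rep(c(1L, 2L), 10)
  sqSmall <- AOSequence(obs, nObs = 2)
  sqBig <- AOSequence(obs, nObs = 40)
  mSmall <- makeCSCG(CloneAllocation(5L, nObs = 2), 1L, seed = 1)
  mBig <- makeCSCG(CloneAllocation(5L, nObs = 40), 1L, seed = 1)
  opsSmall <- eStep(mSmall, sqSmall)$blockOps
  opsBig <- eStep(mBig, sqBig)$blockOps
  expect_identical(opsSmall, opsBig)
})

test_that("m-step implements the smoothed count-ratio formula", {
  # counts row {2, 0} with kappa = 1 -> probabilities {3/4, 1/4}
  m <- makeCSCG(CloneAllocation(c(1L, 1L)), 1L, init = "uniform")
  counts <- array(0, dim = c(2, 1, 2))
  counts[1, 1, 1] <- 2
  st <- list(counts = counts, gamma1 = c(1, 0))
  m2 <- mStep(m, st, kappa = 1)
  expect_equal(as.vector(m2@transitions[1, 1, ]), c(3 / 4, 1 / 4))
  # zero counts with kappa > 0 -> uniform rows
  m3 <- mStep(m, list(counts = array(0, dim = c(2, 1, 2)),
                      gamma1 = c(0, 0)), kappa = 0.5)
  expect_equal(as.vector(m3@transitions[1, 1, ]), c(0.5, 0.5))
  # kappa -> infinity approaches uniform monotonically in TV distance
  tv <- vapply(c(0.1, 1, 10, 100), function(k) {
    mk <- mStep(m, st, kappa = k)
    sum(abs(mk@transitions[1, 1, ] - 0.5)) / 2
  }, numeric(1))
  expect_true(all(diff(tv) < 0))
  # all-zero counts with kappa = 0 is degenerate
  expect_error(mStep(m, list(counts = array(0, dim = c(2, 1, 2)),
                             gamma1 = c(0, 0)), kappa = 0), "degenerate")
})

test_that("joint and conditional m-steps agree for a single action", {
  cs <- randomSmallCase(7, maxNa = 1)
  st <- eStep(cs$model, cs$seq)
  mJ <- mStep(cs$model, st, kappa = 0.01, actionNorm = "joint")
  mC <- mStep(cs$model, st, kappa = 0.01, actionNorm = "conditional")
  expect_equal(mJ@transitions, mC@transitions, tolerance = 1e-12)
})

test_that("EM never decreases the penalized objective", {
  for (seed in c(2, 5)) {
    env <- makeRoom(3, 4, 4, seed = seed)
    w <- randomWalk(env, 800, seed = seed + 1)
    for (norm in c("conditional", "joint")) {
      m <- makeCSCG(CloneAllocation(4L, nObs = 4), 4L, seed = seed)
      m <- suppressWarnings(
        emFit(m, w$seq, kappa = 1e-2, maxIter = 40, tol = 0,
              actionNorm = norm))
      pen <- modelMeta(m)$penalizedTrace
      expect_true(all(diff(pen) > -1e-9 * abs(pen[-length(pen)])))
    }
  }
})

test_that("deterministic-cycle statistics are one-hot and hard EM converges", {
  m <- cycleModel(3)
  sq <- AOSequence(rep(1:3, 5), rep(1L, 14), nObs = 3, nActions = 1)
  st <- eStep(m, sq)
  # every xi(n) is one-hot on the realized (i, k, j) triple
  expect_equal(st$counts, round(st$counts), tolerance = 1e-12)
  expect_equal(sum(st$counts), length(observations(sq)) - 1)
  expect_equal(sum(st$counts > 0), 3)  # the three cycle edges only

  # Viterbi training at a hard fixed point leaves the model unchanged
  m1 <- viterbiTrain(m, sq, maxIter = 1)
  expect_equal(m1@transitions, m@transitions, tolerance = 1e-12)

  # 2 clones/symbol on deterministic cycle data: one clone per symbol
  # survives pruning
  m2 <- suppressWarnings(fitCSCG(sq, clonesPerObs = 2L, nObs = 3,
                                 nActions = 1, kappa = 1e-3, maxIter = 50,
                                 seed = 4))
  expect_equal(length(modelMeta(m2)$usedStates), 3)
  pruned <- pruneClones(m2)
  expect_equal(nStates(pruned), 3)
  expect_equal(viterbiDecode(pruned, sq)$logProb,
               viterbiDecode(m2, sq)$logProb, tolerance = 1e-12)
})

test_that("an action-free cloned HMM equals a single-action CSCG", {
  withr::with_seed(17, {
    obs <- sample.int(3, 400, replace = TRUE,
                      prob = c(0.5, 0.3, 0.2))
  })
  sqFree <- AOSequence(obs, nObs = 3)                      # no actions
  sqOne <- AOSequence(obs, rep(1L, 399), nObs = 3, nActions = 1)
  mA <- makeCSCG(CloneAllocation(3L, nObs = 3), 1L, seed = 9)
  mB <- makeCSCG(CloneAllocation(3L, nObs = 3), 1L, seed = 9)
  fitA <- suppressWarnings(emFit(mA, sqFree, kappa = 1e-3, maxIter = 25,
                                 tol = 0))
  fitB <- suppressWarnings(emFit(mB, sqOne, kappa = 1e-3, maxIter = 25,
                                 tol = 0))
  expect_equal(modelMeta(fitA)$loglikTrace, modelMeta(fitB)$loglikTrace)
  expect_identical(fitA@transitions, fitB@transitions)
})

test_that("a known small CSCG is recovered from its own samples", {
  # ground-truth model with strongly structured transitions
  al <- CloneAllocation(c(2L, 2L))
  truth <- makeCSCG(al, 2L, seed = 123)
  tr <- array(0, dim = c(4, 2, 4))
  # hand-built sparse joint conditional with distinct rows
  rows <- list(c(.6, 0, .2, 0, 0, .2, 0, 0), c(0, .5, 0, .3, .2, 0, 0, 0),
               c(.1, 0, 0, .4, 0, 0, .5, 0), c(0, .3, .3, 0, 0, 0, 0, .4))
  for (i in 1:4) tr[i, , ] <- matrix(rows[[i]], 2, 4)
  truth@transitions <- tr
  truth@prior <- c(.4, .1, .3, .2)
  sim <- sampleCSCG(truth, 50000, seed = 77)
  fit <- makeCSCG(al, 2L, seed = 5)
  fit <- suppressWarnings(emFit(fit, sim$seq, kappa = 1e-6, maxIter = 200,
                                tol = 1e-10, actionNorm = "joint"))
  # best clone permutation (per-symbol swaps) in total variation
  perms <- expand.grid(s1 = 0:1, s2 = 0:1)
  tvBest <- Inf
  for (r in seq_len(nrow(perms))) {
    pm <- 1:4
    if (perms$s1[r] == 1) pm[1:2] <- c(2, 1)
    if (perms$s2[r] == 1) pm[3:4] <- c(4, 3)
    tp <- fit@transitions[pm, , pm, drop = FALSE]
    tv <- max(apply(abs(tp - truth@transitions), 1, sum) / 2)
    tvBest <- min(tvBest, tv)
  }
  expect_lt(tvBest, 0.05)
})

test_that("emission-only relearning freezes transitions and learns rooms", {
  fx <- smallRoomFixture()
  env2 <- makeRoom(4, 5, 8, seed = 99)
  w2 <- randomWalk(env2, 4000, seed = 100)
  base <- smoothModel(fx$model, 1e-4)   # schema kept smoothed, as in EM
  m2 <- learnEmission(base, w2$seq, maxIter = 50)
  expect_identical(m2@transitions, base@transitions)  # bitwise frozen
  expect_equal(m2@emissionMode, "dense")
  expect_true(all(abs(rowSums(m2@emission) - 1) < 1e-9))
  tr <- modelMeta(m2)$emissionLoglikTrace
  expect_true(all(diff(tr) > -1e-6 * abs(tr[-length(tr)])))

  # a room with a single symbol: every visited state's emission row
  # converges to one-hot on that symbol
  env1 <- makeRoom(3, 3, 1, seed = 5)
  w1 <- randomWalk(env1, 500, seed = 6)
  m1 <- learnEmission(base, w1$seq, maxIter = 10)
  visited <- which(rowSums(m1@emission > 0.999) > 0)
  expect_gt(length(visited), 0)
  expect_true(all(m1@emission[visited, 1] > 0.999))
})

test_that("online EM matches batch EM on one batch and tracks drift", {
  env <- makeRoom(3, 4, 5, seed = 7)
  w <- randomWalk(env, 1500, seed = 8)
  m <- makeCSCG(CloneAllocation(4L, nObs = 5), 4L, seed = 7)
  # single batch from zero statistics: the (1 - lambda) factor cancels,
  # so the online update equals the batch m-step with kappa = 0
  st <- onlineEMInit(m, memory = 0.5)
  up <- onlineEMUpdate(st, m, w$seq)
  batch <- mStep(m, eStep(m, w$seq), kappa = 0)
  expect_equal(up$model@transitions, batch@transitions, tolerance = 1e-12)

  # memory -> 0+: statistics equal the last batch only
  stA <- onlineEMInit(m, memory = 1e-9)
  upA <- onlineEMUpdate(stA, m, w$seq)
  b2 <- randomWalk(env, 900, seed = 9)
  mSm <- smoothModel(upA$model, 1e-6)   # keep the stream possible
  upB <- onlineEMUpdate(upA$state, mSm, b2$seq)
  lastOnly <- eStep(mSm, b2$seq)$counts
  expect_equal(upB$state$stats / (1 - 1e-9), lastOnly, tolerance = 1e-6)

  expect_error(onlineEMInit(m, memory = 1), "strictly")

  # stream switching from room A to room B: the share of the running
  # statistics on room-B-only symbol bigrams is non-decreasing per batch
  envB <- makeRoom(3, 4, 5, seed = 70)
  symBigrams <- function(e) {
    g <- e@grid
    pr <- rbind(cbind(as.vector(g[-nrow(g), ]), as.vector(g[-1, ])),
                cbind(as.vector(g[-1, ]), as.vector(g[-nrow(g), ])),
                cbind(as.vector(g[, -ncol(g)]), as.vector(g[, -1])),
                cbind(as.vector(g[, -1]), as.vector(g[, -ncol(g)])))
    unique(paste(pr[, 1], pr[, 2]))
  }
  onlyB <- setdiff(symBigrams(envB), symBigrams(env))
  expect_gt(length(onlyB), 0)
  mS <- mStep(m, eStep(m, w$seq), kappa = 1e-3)   # room-A model
  stS <- onlineEMInit(mS, memory = 0.6)
  stS$stats <- eStep(mS, w$seq)$counts            # room-A history
  model <- mS
  sym <- symbolOf(mS)
  fracB <- numeric(0)
  for (b in 1:4) {
    wB <- randomWalk(envB, 600, seed = 20 + b)
    up <- onlineEMUpdate(stS, smoothModel(model, 1e-6), wB$seq)
    stS <- up$state
    model <- up$model
    key <- paste(sym[slice.index(stS$stats, 1)],
                 sym[slice.index(stS$stats, 3)])
    fracB <- c(fracB, sum(stS$stats[key %in% onlyB]) / sum(stS$stats))
  }
  expect_true(all(diff(fracB) > -1e-10))
})
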