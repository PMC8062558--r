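test_that("hard evidence equals one-hot soft evidence", {
  cs <- randomSmallCase(3)
  ev <- softEvidence(cs$obs, nObservations(cs$model), 0)
  a <- filterPosterior(cs$model, cs$seq)
  b <- filterPosterior(cs$model, ev, actions = cs$act)
  expect_identical(activationMatrix(a), activationMatrix(b))
  s1 <- smoothPosterior(cs$model, cs$seq)
  s2 <- smoothPosterior(cs$model, ev, actions = cs$act)
  expect_identical(activationMatrix(s1), activationMatrix(s2))
})

test_that("uniform evidence at a step reduces to the one-step prediction", {
  cs <- randomSmallCase(8)
  E <- nObservations(cs$model)
  N <- length(cs$obs)
  ev <- softEvidence(cs$obs, E, 0)
  ev[, N] <- 1 / E                     # uninformative last step
  tr <- filterPosterior(cs$model, ev, actions = cs$act)
  # prediction: propagate the previous filtered posterior one step
  prev <- activationMatrix(filterPosterior(
    cs$model, softEvidence(cs$obs[-N], E, 0),
    actions = cs$act[-(N - 1)]))[, N - 1]
  Ta <- transitionTensor(cs$model)[, cs$act[N - 1], ]
  pred <- as.vector(t(Ta) %*% prev)
  pred <- pred / sum(pred)
  expect_equal(activationMatrix(tr)[, N], pred, tolerance = 1e-12)
})

test_that("activation traces are proper distributions and smoothing matches filtering at the last step", {
  cs <- randomSmallCase(12)
  f <- filterPosterior(cs$model, cs$seq)
  s <- smoothPosterior(cs$model, cs$seq)
  expect_true(all(abs(colSums(activationMatrix(f)) - 1) < 1e-12))
  expect_true(all(abs(colSums(activationMatrix(s)) - 1) < 1e-12))
  N <- ncol(activationMatrix(f))
  expect_equal(activationMatrix(s)[, N], activationMatrix(f)[, N],
               tolerance = 1e-12)
  expect_error(filterPosterior(cs$model,
               matrix(0, nObservations(cs$model), 2)), "positive")
})

test_that("viterbi decoding follows the unique path of a deterministic cycle", {
  m <- cycleModel(3)
  sq <- AOSequence(rep(1:3, 4), rep(1L, 11), nObs = 3, nActions = 1)
  dec <- viterbiDecode(m, sq)
  expect_equal(dec$path, rep(1:3, 4))
  expect_equal(dec$logProb, 0)
  bad <- AOSequence(c(1L, 1L), 1L, nObs = 3, nActions = 1)
  expect_error(viterbiDecode(m, bad), "no positive-probability")
})

test_that("error correction restores impossible symbols and leaves valid ones", {
  m <- smoothModel(cycleModel(3), 1e-4)
  clean <- rep(1:3, 8)
  noisy <- clean
  noisy[10] <- (clean[10]) %% 3 + 2 - 1  # a cycle-inconsistent symbol
  if (noisy[10] == clean[10]) noisy[10] <- clean[10] %% 3 + 1
  sq <- AOSequence(noisy, rep(1L, length(noisy) - 1), nObs = 3,
                   nActions = 1)
  res <- correctErrors(m, sq, noiseRate = 0.2)
  expect_equal(res$corrected@observations, clean)
  expect_true(res$changed[10])
  expect_equal(sum(res$changed), 1)
  expect_true(all(abs(colSums(res$posterior) - 1) < 1e-9))
  expect_error(correctErrors(m, sq, noiseRate = 1), "noiseRate")
})

test_that("ancestral sampling reproduces the transition law", {
  m <- cycleModel(4)
  s <- sampleCSCG(m, 11, seed = 2)
  expect_equal(s$seq@observations, rep(1:4, 3))

  # empirical (state, action, next-state) frequencies within 3 SE of T
  truth <- makeCSCG(CloneAllocation(c(2L, 1L)), 2L, seed = 31)
  sim <- sampleCSCG(truth, 20000, seed = 32)
  T <- transitionTensor(truth)
  cnt <- array(0, dim = dim(T))
  z <- sim$states; a <- actions(sim$seq)
  for (n in seq_along(a)) cnt[z[n], a[n], z[n + 1]] <- cnt[z[n], a[n], z[n + 1]] + 1
  for (i in seq_len(nStates(truth))) {
    ni <- sum(cnt[i, , ])
    if (ni < 100) next
    p <- as.vector(T[i, , ])
    o <- as.vector(cnt[i, , ])
    # samples never land on zero-probability cells
    expect_true(all(o[p == 0] == 0))
    keep <- p > 0
    gof <- suppressWarnings(stats::chisq.test(o[keep], p = p[keep]))
    expect_gt(gof$p.value, 1e-4)
  }
  expect_error(sampleCSCG(truth, 5, start = 99), "out of range")
})

test_that("replay samples the forward-predicted next observation", {
  m <- cycleModel(3)
  pre <- AOSequence(c(1L, 2L), 1L, nObs = 3, nActions = 1)
  r <- replayObservation(m, pre, seed = 1)
  expect_equal(r$symbol, 3L)
  expect_equal(r$distribution, c(0, 0, 1))

  # stochastic case: empirical distribution over draws matches prediction
  truth <- makeCSCG(CloneAllocation(c(1L, 1L, 1L)), 1L, seed = 3)
  pre2 <- AOSequence(c(1L, 2L), 1L, nObs = 3, nActions = 1)
  dist <- replayObservation(truth, pre2, seed = 1)$distribution
  draws <- vapply(1:3000, function(s)
    replayObservation(truth, pre2, seed = s)$symbol, integer(1))
  phat <- tabulate(draws, 3) / 3000
  se <- sqrt(dist * (1 - dist) / 3000)
  expect_true(all(abs(phat - dist) <= 3 * se + 1e-9))
})

test_that("environment posteriors follow the clone partition", {
  cs <- randomSmallCase(5)
  H <- nStates(cs$model)
  # all states in one environment: posterior constantly 1
  post <- environmentPosterior(cs$model, list(seq_len(H)), cs$seq)
  expect_equal(as.vector(post), rep(1, length(cs$obs)), tolerance = 1e-12)
  # overlapping sets are rejected
  expect_error(environmentPosterior(cs$model, list(1:2, 2:3), cs$seq),
               "disjoint")
})

test_that("two identical environments stay at the prior ratio", {
  # a model made of two copies of the same cycle, prior 0.7/0.3 across them
  al <- CloneAllocation(c(2L, 2L))
  m <- makeCSCG(al, 1L, init = "uniform")
  tr <- array(0, dim = c(4, 1, 4))
  tr[1, 1, 3] <- 1; tr[3, 1, 1] <- 1   # copy A: clones 1,3 of symbols 1,2
  tr[2, 1, 4] <- 1; tr[4, 1, 2] <- 1   # copy B: clones 2,4
  m@transitions <- tr
  m@prior <- c(0.7, 0.3, 0, 0)
  sq <- AOSequence(rep(c(1L, 2L), 6), rep(1L, 11), nObs = 2, nActions = 1)
  post <- environmentPosterior(m, list(c(1L, 3L), c(2L, 4L)), sq)
  expect_equal(post[1, ], rep(0.7, 12), tolerance = 1e-12)
  expect_equal(post[2, ], rep(0.3, 12), tolerance = 1e-12)
})
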