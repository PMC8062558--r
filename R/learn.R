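#' @include model.R
NULL

#' Log-likelihood of a sequence under a CSCG
#'
#' Exact log P(x, a) computed by a scaled forward pass restricted to the
#' clone blocks of the observed symbols (dense-emission models use the full
#' state space). A sequence that is impossible under an unsmoothed model
#' yields `-Inf` rather than an error.
#'
#' @param model a [CSCGModel-class].
#' @param seq an [AOSequence-class] (or integer observation vector).
#' @return scalar log-likelihood.
#' @export
logLikelihood <- function(model, seq) {
  s <- .seqForModel(model, seq)
  if (model@emissionMode == "dense") {
    dense_predict_cpp(model@transitions, model@prior, model@emission,
                      s$obs0, s$act0, model@nActions)$loglik
  } else {
    cscg_forward_cpp(model@transitions, model@prior,
                     model@allocation@clonesPerObs, s$obs0, s$act0,
                     model@nActions, FALSE)$loglik
  }
}

#' Forward-backward message trace
#'
#' Runs the scaled forward and backward recursions over the clone blocks of
#' the observed symbols and returns the per-step messages. Message vectors
#' have length `clonesPerObs[x_n]` (the clone block of that step's symbol);
#' `loglik` equals the sum of the log scaling constants.
#'
#' @param model a [CSCGModel-class] (clone emission mode).
#' @param seq an [AOSequence-class].
#' @return list with `alphas`, `betas` (lists of per-step block vectors),
#'   `scales`, `loglik`, and `impossible` (TRUE when the sequence has zero
#'   probability, in which case `loglik` is `-Inf`).
#' @export
forwardBackward <- function(model, seq) {
  stopifnot(model@emissionMode == "clone")
  s <- .seqForModel(model, seq)
  fw <- cscg_forward_cpp(model@transitions, model@prior,
                         model@allocation@clonesPerObs, s$obs0, s$act0,
                         model@nActions, TRUE)
  if (isTRUE(fw$impossible))
    return(list(alphas = fw$alphas, betas = NULL, scales = fw$scales,
                loglik = -Inf, impossible = TRUE))
  N <- length(s$obs0)
  al <- model@allocation
  betas <- vector("list", N)
  betas[[N]] <- rep(1, al@clonesPerObs[s$obs0[N] + 1L])
  if (N > 1L) for (n in (N - 1L):1L) {
    si <- s$obs0[n] + 1L; sj <- s$obs0[n + 1L] + 1L
    blk <- model@transitions[cloneRange(al, si), s$act0[n] + 1L,
                             cloneRange(al, sj), drop = FALSE]
    blk <- matrix(blk, nrow = al@clonesPerObs[si])
    b <- as.vector(blk %*% betas[[n + 1L]])
    betas[[n]] <- b / sum(b)
  }
  list(alphas = fw$alphas, betas = betas, scales = fw$scales,
       loglik = fw$loglik, impossible = FALSE)
}

#' Expectation step: expected transition counts
#'
#' Computes the posterior transition statistics `sum_n xi_{ikj}(n)` and the
#' step-1 state posterior `gamma(1)` for one or more sequences, treating
#' multiple sequences as independent draws from the same model (statistics
#' are summed). Only the `M_i x M_j` clone blocks of consecutive symbols are
#' touched, so the cost scales with clone counts, not alphabet size;
#' `blockOps` reports the number of block cells visited.
#'
#' @param model a [CSCGModel-class] (clone emission mode).
#' @param seqs an [AOSequence-class] or list of them.
#' @param keepGammas also return the per-step posteriors `gamma(n)` for each
#'   sequence (lists of block vectors).
#' @return list with `counts` (H x Na x H array), `gamma1` (length-H prior
#'   statistics), `loglik`, `blockOps`, and optionally `gammas`.
#' @export
eStep <- function(model, seqs, keepGammas = FALSE) {
  stopifnot(model@emissionMode == "clone")
  seqs <- .asSeqList(seqs)
  H <- nStates(model)
  counts <- array(0, dim = c(H, model@nActions, H))
  gamma1 <- numeric(H)
  loglik <- 0
  ops <- 0
  gammas <- if (keepGammas) vector("list", length(seqs)) else NULL
  for (i in seq_along(seqs)) {
    s <- .seqForModel(model, seqs[[i]])
    es <- cscg_estep_cpp(model@transitions, model@prior,
                         model@allocation@clonesPerObs, s$obs0, s$act0,
                         model@nActions, keepGammas)
    if (isTRUE(es$impossible))
      return(list(counts = counts, gamma1 = gamma1, loglik = -Inf,
                  blockOps = ops, impossible = TRUE))
    counts <- counts + es$counts
    gamma1 <- gamma1 + es$gamma1
    loglik <- loglik + es$loglik
    ops <- ops + es$block_ops
    if (keepGammas) gammas[[i]] <- es$gammas
  }
  out <- list(counts = counts, gamma1 = gamma1, loglik = loglik,
              blockOps = ops, impossible = FALSE)
  if (keepGammas) out$gammas <- gammas
  out
}

#' Maximization step
#'
#' Re-estimates the transition tensor from expected counts, with pseudocount
#' smoothing. Two estimators are available:
#' \describe{
#'   \item{`"conditional"` (default)}{per-action row normalization:
#'     `P(z'|z,a) = (kappa + counts[i,k,j]) / sum_j (kappa + counts[i,k,j])`,
#'     combined with an action factor uniform over the actions observed at
#'     state `i`, so the stored tensor is still a valid joint `P(z',a|z)`.
#'     Inference then carries no information from the action marginal. This
#'     estimator consolidates redundant clones much more reliably (see the
#'     methods vignette) and is the one behind the published spatial-map
#'     results.}
#'   \item{`"joint"`}{joint row normalization
#'     `T[i,k,j] = (kappa + counts[i,k,j]) / sum_{k',j'} (kappa + counts)`,
#'     which additionally learns the action marginal `P(a|z)`.}
#' }
#' The prior is re-estimated from the (equally smoothed) `gamma(1)`
#' statistics. Rows of states with zero count mass and `kappa = 0` keep the
#' current model's row; if every count is zero with `kappa = 0` the
#' statistics are degenerate and an error is raised.
#'
#' @param model the current [CSCGModel-class] (supplies fallback rows).
#' @param stats statistics from [eStep()] (list with `counts`, `gamma1`).
#' @param kappa pseudocount >= 0.
#' @param actionNorm `"conditional"` or `"joint"`.
#' @return the updated model; `modelMeta(model)$rowCounts` records each
#'   state's total count mass (used later to floor pseudocount-only edges
#'   when planning).
#' @export
mStep <- function(model, stats, kappa = 0,
                  actionNorm = c("conditional", "joint")) {
  actionNorm <- match.arg(actionNorm)
  stopifnot(kappa >= 0)
  counts <- stats$counts
  H <- dim(counts)[1L]
  Na <- dim(counts)[2L]
  flat <- matrix(counts, nrow = H)
  rowMass <- rowSums(flat)
  if (kappa == 0 && all(rowMass == 0))
    stop("degenerate statistics: all transition counts are zero with kappa = 0")
  if (actionNorm == "joint") {
    sm <- flat + kappa
    rs <- rowSums(sm)
    zero <- rs == 0
    tr <- matrix(model@transitions, nrow = H)
    tr[!zero, ] <- sm[!zero, , drop = FALSE] / rs[!zero]
    model@transitions <- array(tr, dim = dim(counts))
  } else {
    tr <- model@transitions
    # count mass per (state, action): reshape so (i, k) pairs are rows
    Cik <- matrix(rowSums(matrix(counts, H * Na, H)), H, Na)
    supp <- if (kappa > 0) matrix(TRUE, H, Na) else Cik > 0
    nsupp <- rowSums(supp)
    for (k in seq_len(Na)) {
      num <- counts[, k, , drop = FALSE]
      dim(num) <- c(H, H)
      num <- num + kappa
      den <- Cik[, k] + kappa * H
      w <- ifelse(supp[, k], 1 / pmax(nsupp, 1L), 0)
      ok <- den > 0 & w > 0
      if (any(ok))
        tr[ok, k, ] <- (num[ok, , drop = FALSE] / den[ok]) * w[ok]
      drop0 <- !ok & nsupp > 0        # visited state, never-taken action
      if (any(drop0)) tr[drop0, k, ] <- 0
      # states with nsupp == 0 (never visited, kappa = 0) keep their rows
    }
    model@transitions <- tr
  }
  g <- stats$gamma1 + kappa
  if (sum(g) > 0) model@prior <- g / sum(g)
  model@metadata$pseudocount <- kappa
  model@metadata$actionNorm <- actionNorm
  model@metadata$rowCounts <- rowMass
  model
}

# penalized (Dirichlet-MAP) objective used for monotonicity and restart choice
.penalizedLoglik <- function(model, loglik, kappa) {
  if (kappa == 0 || !is.finite(loglik)) return(loglik)
  loglik + kappa * (sum(log(model@transitions)) + sum(log(model@prior)))
}

#' Batch EM for a CSCG
#'
#' Alternates [eStep()] and [mStep()] on one or more sequences until the
#' relative improvement of the penalized log-likelihood falls below `tol` or
#' `maxIter` is reached. With `nRestarts > 1`, additional models are drawn
#' with seeds derived from `seed` and the restart with the best final
#' penalized log-likelihood is returned. The penalized objective (data
#' log-likelihood plus the Dirichlet log-prior terms `kappa * sum(log T)` and
#' `kappa * sum(log pi)`) is non-decreasing over iterations.
#'
#' @param model starting [CSCGModel-class] (used as restart 1).
#' @param seqs an [AOSequence-class] or list of them.
#' @param kappa pseudocount used in every M-step.
#' @param maxIter maximum EM iterations per restart.
#' @param tol relative penalized-loglik improvement threshold; 0 disables
#'   early stopping.
#' @param nRestarts number of random restarts.
#' @param seed seed for restart initialization.
#' @param verbose print per-iteration log-likelihoods.
#' @return the fitted model; `modelMeta(model)$loglikTrace` holds the data
#'   log-likelihood per iteration and `modelMeta(model)$penalizedTrace` the
#'   penalized objective.
#' @export
emFit <- function(model, seqs, kappa = 0, maxIter = 100L, tol = 1e-6,
                  nRestarts = 1L, seed = 1L,
                  actionNorm = c("conditional", "joint"), verbose = FALSE) {
  actionNorm <- match.arg(actionNorm)
  seqs <- .asSeqList(seqs)
  best <- NULL
  bestScore <- -Inf
  for (r in seq_len(nRestarts)) {
    m <- if (r == 1L) model
         else makeCSCG(model@allocation, model@nActions,
                       seed = as.integer(seed) + r - 1L, init = "random")
    fit <- .emLoop(m, seqs, kappa, maxIter, tol, actionNorm, verbose)
    score <- fit$penalized[length(fit$penalized)]
    if (is.null(best) || score > bestScore) {
      best <- fit$model
      bestScore <- score
    }
  }
  best
}

.emLoop <- function(model, seqs, kappa, maxIter, tol,
                    actionNorm = "conditional", verbose = FALSE) {
  trace <- numeric(0)
  pen <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    st <- eStep(model, seqs)
    if (isTRUE(st$impossible))
      stop("sequence has zero probability under the current model; ",
           "use a positive pseudocount")
    trace <- c(trace, st$loglik)
    pen <- c(pen, .penalizedLoglik(model, st$loglik, kappa))
    if (verbose) message(sprintf("iter %d loglik %.6f", it, st$loglik))
    model <- mStep(model, st, kappa, actionNorm = actionNorm)
    if (it > 1L && tol > 0) {
      prev <- pen[it - 1L]
      if (abs(pen[it] - prev) <= tol * abs(prev)) { converged <- TRUE; break }
    }
  }
  if (!converged && tol > 0 && maxIter > 1L)
    warning("EM stopped at maxIter without reaching tol", call. = FALSE)
  model@metadata$loglikTrace <- trace
  model@metadata$penalizedTrace <- pen
  list(model = model, penalized = pen)
}

#' Viterbi training (hard EM)
#'
#' Iterates: decode the MAP clone path of every sequence, count the realized
#' (state, action, next-state) transitions, and re-normalize with zero
#' pseudocount. Stops when the decoded paths no longer change. States never
#' visited by any decoded path are reported as unused and can be removed
#' with [pruneClones()] without changing the likelihood of decoded paths.
#'
#' @param model an EM-trained [CSCGModel-class] (recommended; any valid
#'   model is accepted).
#' @param seqs an [AOSequence-class] or list of them.
#' @param maxIter maximum hard-EM sweeps.
#' @return the refined model; `modelMeta()` gains `usedStates` (sorted ids
#'   visited by the final decoded paths).
#' @export
viterbiTrain <- function(model, seqs, maxIter = 50L,
                         actionNorm = c("conditional", "joint")) {
  actionNorm <- match.arg(actionNorm)
  seqs <- .asSeqList(seqs)
  H <- nStates(model)
  prevPaths <- NULL
  for (it in seq_len(maxIter)) {
    paths <- lapply(seqs, function(sq) viterbiDecode(model, sq)$path)
    if (!is.null(prevPaths) && identical(paths, prevPaths)) break
    prevPaths <- paths
    counts <- array(0, dim = c(H, model@nActions, H))
    prior1 <- numeric(H)
    for (i in seq_along(seqs)) {
      p <- paths[[i]]
      a <- .seqForModel(model, seqs[[i]])$act0 + 1L
      prior1[p[1L]] <- prior1[p[1L]] + 1
      if (length(p) > 1L) for (n in seq_len(length(p) - 1L))
        counts[p[n], a[n], p[n + 1L]] <- counts[p[n], a[n], p[n + 1L]] + 1
    }
    model <- mStep(model, list(counts = counts, gamma1 = prior1),
                   kappa = 0, actionNorm = actionNorm)
  }
  used <- sort(unique(unlist(prevPaths)))
  model@metadata$usedStates <- used
  # hard counts would make the prior one-hot on the decoded start state;
  # a uniform prior over the used clones keeps the refined model usable
  # for localization from arbitrary starting positions
  p <- numeric(H)
  p[used] <- 1 / length(used)
  model@prior <- p
  model
}

#' Remove unused clones from a model
#'
#' Restricts the model to `used` states, re-indexing clone blocks per symbol.
#' Symbols that lose all their clones keep a single placeholder clone (the
#' alphabet must not shift). Rows are renormalized; for a Viterbi-trained
#' model no probability mass leaves the used set, so decoded-path likelihoods
#' are unchanged.
#'
#' @param model a [CSCGModel-class].
#' @param used integer state ids to keep (default:
#'   `modelMeta(model)$usedStates`).
#' @return the pruned model; `modelMeta()$pruneMap` maps old ids to new ids
#'   (NA for dropped states).
#' @export
pruneClones <- function(model, used = NULL) {
  if (is.null(used)) used <- model@metadata$usedStates
  if (is.null(used)) stop("no used-state set; run viterbiTrain first")
  used <- sort(unique(as.integer(used)))
  sym <- symbolOf(model)
  keep <- logical(nStates(model))
  keep[used] <- TRUE
  # every symbol keeps at least one clone
  for (s in seq_len(nObservations(model))) {
    rng <- cloneRange(model, s)
    if (!any(keep[rng])) keep[rng[1L]] <- TRUE
  }
  newIds <- cumsum(keep)
  newIds[!keep] <- NA_integer_
  m2 <- as.integer(tapply(keep, sym, sum))
  al2 <- CloneAllocation(m2)
  tr <- model@transitions[keep, , keep, drop = FALSE]
  H2 <- sum(keep)
  flat <- matrix(tr, nrow = H2)
  rs <- rowSums(flat)
  flat[rs > 0, ] <- flat[rs > 0, , drop = FALSE] / rs[rs > 0]
  flat[rs == 0, ] <- 1 / ncol(flat)
  p <- model@prior[keep]
  meta <- model@metadata
  meta$pruneMap <- newIds
  meta$usedStates <- NULL
  meta$rowCounts <- meta$rowCounts[keep]
  new("CSCGModel", allocation = al2, nActions = model@nActions,
      prior = p / sum(p),
      transitions = array(flat, dim = c(H2, model@nActions, H2)),
      emission = matrix(numeric(0), 0, 0), emissionMode = "clone",
      metadata = meta)
}

#' Sequence-memorizing initialization
#'
#' Builds a CSCG that memorizes the training sequences: the o-th occurrence
#' of symbol `s` is assigned clone `o mod M_s` of its block (round-robin),
#' the realized (clone, action, next-clone) transitions are counted, and the
#' tensor is estimated from these hard counts with a pseudocount. Warm-
#' starting EM from this model implements the rapid-memorize / gradually-
#' generalize schedule: EM then merges clones whose contexts carry no
#' predictive information while keeping the ones that do. This matters for
#' repeated prototypical-sequence data (routes, laps), where the symmetric
#' random initialization leaves EM on a plateau in which distinct temporal
#' contexts of the same symbol can never differentiate.
#'
#' @param allocation a [CloneAllocation-class] (or clones-per-symbol vector).
#' @param nActions action alphabet size.
#' @param seqs an [AOSequence-class] or list of them.
#' @param kappa pseudocount applied to the memorized counts (> 0 so EM can
#'   later reassign occurrences).
#' @return a [CSCGModel-class].
#' @export
memorizeInit <- function(allocation, nActions, seqs, kappa = 1e-3) {
  if (!is(allocation, "CloneAllocation"))
    allocation <- CloneAllocation(allocation)
  seqs <- .asSeqList(seqs)
  H <- allocation@nStates
  nActions <- as.integer(nActions)
  counts <- array(0, dim = c(H, nActions, H))
  prior1 <- numeric(H)
  occ <- integer(allocation@nObs)
  M <- allocation@clonesPerObs
  off <- allocation@offsets
  for (sq in seqs) {
    x <- sq@observations
    a <- if (length(sq@actions)) sq@actions else rep(1L, length(x) - 1L)
    z <- integer(length(x))
    for (n in seq_along(x)) {
      s <- x[n]
      z[n] <- off[s] + occ[s] %% M[s]
      occ[s] <- occ[s] + 1L
    }
    prior1[z[1L]] <- prior1[z[1L]] + 1
    if (length(x) > 1L) for (n in seq_len(length(x) - 1L))
      counts[z[n], a[n], z[n + 1L]] <- counts[z[n], a[n], z[n + 1L]] + 1
  }
  m <- makeCSCG(allocation, nActions, init = "uniform")
  mStep(m, list(counts = counts, gamma1 = prior1), kappa = kappa)
}

#' Two-phase fitting schedule
#'
#' The standard training pipeline: smoothed batch EM (pseudocount `kappa`)
#' followed by Viterbi-training refinement with zero pseudocount,
#' warm-started from the EM solution. Convenience wrapper used by all the
#' room experiments.
#'
#' @param seqs an [AOSequence-class] or list of them.
#' @param clonesPerObs clones per symbol (scalar or vector).
#' @param nObs observation alphabet size (default: from sequences).
#' @param nActions action alphabet size (default: from sequences).
#' @param kappa pseudocount for the EM phase.
#' @param maxIter,tol,nRestarts,seed passed to [emFit()].
#' @param viterbiIter sweeps for the refinement phase (0 skips it).
#' @param prune remove clones unused by the final decoded paths.
#' @param init `"random"` (EM restarts from random tensors) or
#'   `"memorize"` (warm start from [memorizeInit()]; use for repeated
#'   prototypical-sequence data where random starts cannot differentiate
#'   contexts).
#' @return the fitted [CSCGModel-class].
#' @export
fitCSCG <- function(seqs, clonesPerObs, nObs = NULL, nActions = NULL,
                    kappa = 0.01, maxIter = 100L, tol = 1e-6,
                    nRestarts = 1L, seed = 1L, viterbiIter = 50L,
                    prune = FALSE,
                    actionNorm = c("conditional", "joint"),
                    init = c("random", "memorize")) {
  actionNorm <- match.arg(actionNorm)
  init <- match.arg(init)
  seqs <- .asSeqList(seqs)
  if (is.null(nObs)) nObs <- max(vapply(seqs, function(s) s@nObs, 1L))
  if (is.null(nActions))
    nActions <- max(vapply(seqs, function(s) max(s@nActions, 1L), 1L))
  al <- if (length(clonesPerObs) == 1L) CloneAllocation(clonesPerObs, nObs)
        else CloneAllocation(clonesPerObs)
  m <- if (init == "memorize")
    memorizeInit(al, nActions, seqs, kappa = max(kappa, 1e-6))
  else makeCSCG(al, nActions, seed = seed, init = "random")
  m <- emFit(m, seqs, kappa = kappa, maxIter = maxIter, tol = tol,
             nRestarts = nRestarts, seed = seed, actionNorm = actionNorm)
  if (viterbiIter > 0L) m <- viterbiTrain(m, seqs, maxIter = viterbiIter,
                                          actionNorm = actionNorm)
  if (prune) m <- pruneClones(m)
  m
}

#' Learn a dense emission matrix with transitions fixed (schema transfer)
#'
#' Converts the model to dense emission mode and runs EM over the emission
#' matrix only: the E-step is the standard HMM forward-backward with the
#' (frozen) transition tensor, and the M-step row-normalizes the expected
#' observation counts per state. The transition tensor is bit-identical
#' before and after. This is how a learned room graph is reused as a schema
#' in a new room with different observations.
#'
#' @param model a trained [CSCGModel-class] (its transitions are frozen).
#' @param seqs observation walk(s) in the new environment.
#' @param maxIter,tol EM controls.
#' @param init `"uniform"` (default) or `"random"` emission initialization.
#' @param seed seed for `init = "random"`.
#' @return the model in dense emission mode with the learned emission matrix.
#' @export
learnEmission <- function(model, seqs, maxIter = 100L, tol = 1e-8,
                          init = c("uniform", "random"), seed = 1L) {
  init <- match.arg(init)
  seqs <- .asSeqList(seqs)
  H <- nStates(model)
  E <- nObservations(model)
  em <- if (init == "uniform") matrix(1 / E, H, E)
        else withr::with_seed(as.integer(seed), {
          e <- matrix(1 - stats::runif(H * E), H, E)
          e / rowSums(e)
        })
  trace <- numeric(0)
  for (it in seq_len(maxIter)) {
    counts <- matrix(0, H, E)
    loglik <- 0
    for (sq in seqs) {
      s <- .seqForModel(model, sq)
      es <- dense_estep_cpp(model@transitions, model@prior, em,
                            s$obs0, s$act0, model@nActions)
      if (isTRUE(es$impossible)) stop("zero-probability sequence during ",
                                      "emission learning")
      counts <- counts + es$obs_counts
      loglik <- loglik + es$loglik
    }
    trace <- c(trace, loglik)
    rs <- rowSums(counts)
    em[rs > 0, ] <- counts[rs > 0, , drop = FALSE] / rs[rs > 0]
    if (it > 1L && tol > 0 &&
        abs(trace[it] - trace[it - 1L]) <= tol * abs(trace[it - 1L])) break
  }
  model@emission <- em
  model@emissionMode <- "dense"
  model@metadata$emissionLoglikTrace <- trace
  model
}

#' Initialize online EM state
#'
#' @param model a [CSCGModel-class].
#' @param memory forgetting factor lambda, strictly inside (0, 1); values
#'   near 1 weigh all history, values near 0 track only the last batch.
#' @return an online-EM state list (`stats`, `priorStats`, `memory`,
#'   `batchIndex`).
#' @export
onlineEMInit <- function(model, memory = 0.9) {
  if (!(memory > 0 && memory < 1)) stop("memory must be strictly in (0, 1)")
  H <- nStates(model)
  list(stats = array(0, dim = c(H, model@nActions, H)),
       priorStats = numeric(H), memory = memory, batchIndex = 0L)
}

#' Online / adaptive EM update
#'
#' Processes one batch: the expected counts of the batch (E-step under the
#' current model) are folded into the running statistic
#' `A^(b) = lambda * A^(b-1) + (1 - lambda) * sum_{n in batch} xi(n)`,
#' and the transition tensor is re-estimated by row normalization of
#' `A^(b)`. The exponential window lets the model track environments whose
#' statistics drift over time.
#'
#' @param state state from [onlineEMInit()] or a previous update.
#' @param model the current [CSCGModel-class].
#' @param batch an [AOSequence-class] (non-empty).
#' @return list with the updated `state` and `model`.
#' @export
onlineEMUpdate <- function(state, model, batch) {
  lam <- state$memory
  if (!(lam > 0 && lam < 1)) stop("memory must be strictly in (0, 1)")
  st <- eStep(model, batch)
  if (isTRUE(st$impossible)) stop("zero-probability batch; smooth the model")
  state$stats <- lam * state$stats + (1 - lam) * st$counts
  state$priorStats <- lam * state$priorStats + (1 - lam) * st$gamma1
  state$batchIndex <- state$batchIndex + 1L
  model <- mStep(model, list(counts = state$stats,
                             gamma1 = state$priorStats), kappa = 0)
  list(state = state, model = model)
}

#' Next-symbol prediction accuracy
#'
#' Fraction of steps (after a burn-in needed for the agent to localize)
#' where the symbol with maximal one-step-ahead predictive probability
#' equals the observed symbol.
#'
#' @param model a [CSCGModel-class] (clone or dense emission mode).
#' @param seq held-out [AOSequence-class].
#' @param burnIn number of initial steps excluded.
#' @return accuracy in `[0, 1]`.
#' @export
predictionAccuracy <- function(model, seq, burnIn = 10L) {
  s <- .seqForModel(model, seq)
  pred <- if (model@emissionMode == "dense")
    dense_predict_cpp(model@transitions, model@prior, model@emission,
                      s$obs0, s$act0, model@nActions)$pred
  else
    cscg_predict_cpp(model@transitions, model@prior,
                     model@allocation@clonesPerObs, s$obs0, s$act0,
                     model@nActions)$pred
  n <- length(s$obs0)
  idx <- seq.int(burnIn + 1L, n)
  hits <- vapply(idx, function(i) {
    if (sum(pred[, i]) <= 0) return(FALSE)  # sequence became impossible
    which.max(pred[, i]) == s$obs0[i] + 1L
  }, logical(1))
  mean(hits)
}
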