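#' @include learn.R
NULL

#' Build a soft-evidence matrix
#'
#' Soft evidence expresses uncertain sensation as a per-step likelihood
#' vector over the observation alphabet. This helper mixes the one-hot
#' encoding of an observed stream with a uniform floor:
#' `(1 - epsilon) * onehot + epsilon / E`. `epsilon = 0` recovers hard
#' evidence exactly.
#'
#' @param observations integer symbol ids.
#' @param nObs alphabet size E.
#' @param epsilon uniform uncertainty mass in `[0, 1]`.
#' @return E x N numeric matrix (columns are steps).
#' @export
softEvidence <- function(observations, nObs, epsilon = 0) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  x <- as.integer(observations)
  ev <- matrix(epsilon / nObs, nObs, length(x))
  ev[cbind(x, seq_along(x))] <- ev[cbind(x, seq_along(x))] + (1 - epsilon)
  ev
}

# normalize evidence input: AOSequence/int vector -> one-hot; matrix kept
.asEvidence <- function(model, evidence) {
  E <- nObservations(model)
  if (is(evidence, "AOSequence"))
    return(list(ev = softEvidence(evidence@observations, E, 0),
                actions = if (length(evidence@actions)) evidence@actions
                          else NULL))
  if (is.matrix(evidence)) {
    if (nrow(evidence) != E) stop("evidence matrix must have E rows")
    if (any(evidence < 0)) stop("negative evidence entries")
    if (any(colSums(evidence) <= 0))
      stop("evidence step with no positive entry")
    return(list(ev = evidence, actions = NULL))
  }
  list(ev = softEvidence(as.integer(evidence), E, 0), actions = NULL)
}

# per-action transition matrices (and the action-marginalized matrix)
.transMats <- function(model) {
  H <- nStates(model)
  lapply(seq_len(model@nActions), function(a)
    matrix(model@transitions[, a, ], H, H))
}

# shared forward pass under (soft) evidence; returns filtered posteriors,
# predictive-state matrix and per-symbol posterior (used by correctErrors)
.forwardSoft <- function(model, ev, acts) {
  H <- nStates(model)
  E <- nObservations(model)
  N <- ncol(ev)
  sym <- symbolOf(model)
  Ta <- .transMats(model)
  Tm <- if (is.null(acts)) Reduce(`+`, Ta) else NULL
  filt <- matrix(0, H, N)
  obsPost <- matrix(0, E, N)
  loglik <- 0
  apred <- model@prior
  for (n in seq_len(N)) {
    w <- ev[sym, n] * apred
    sc <- sum(w)
    if (sc <= 0) stop("zero-probability evidence at step ", n,
                      "; use a smoothed model or soft evidence")
    loglik <- loglik + log(sc)
    filt[, n] <- w / sc
    op <- vapply(seq_len(E), function(s)
      sum(apred[sym == s]) * ev[s, n], numeric(1))
    obsPost[, n] <- op / sum(op)
    if (n < N) {
      M <- if (is.null(acts)) Tm else Ta[[acts[n]]]
      apred <- as.vector(crossprod(M, filt[, n]))
    }
  }
  list(filt = filt, obsPost = obsPost, loglik = loglik, Ta = Ta, Tm = Tm)
}

#' Filtered clone activations
#'
#' Exact forward (filtered) posteriors over all H clones, under hard
#' evidence (a sequence) or soft evidence (an E x N likelihood matrix).
#' A hard sequence and its one-hot soft-evidence encoding give identical
#' traces. When no actions are available they are integrated out.
#'
#' @param model a [CSCGModel-class] (clone emission mode).
#' @param evidence an [AOSequence-class], integer vector, or E x N matrix.
#' @param actions optional action ids (length N-1) when `evidence` is a
#'   matrix; `NULL` marginalizes over actions.
#' @return a [CloneActivation-class] with `mode = "filtered"`.
#' @export
filterPosterior <- function(model, evidence, actions = NULL) {
  stopifnot(model@emissionMode == "clone")
  e <- .asEvidence(model, evidence)
  if (is.null(actions)) actions <- e$actions
  if (!is.null(actions) && length(actions) != ncol(e$ev) - 1L)
    stop("actions must have length N - 1")
  fw <- .forwardSoft(model, e$ev, actions)
  new("CloneActivation", probs = fw$filt, mode = "filtered",
      logLik = fw$loglik)
}

#' Smoothed clone activations
#'
#' Forward-backward posteriors `gamma(n)` over all H clones, conditioning on
#' the full evidence stream. At the last step the smoothed and filtered
#' posteriors coincide (the backward message is uninformative there).
#'
#' @inheritParams filterPosterior
#' @return a [CloneActivation-class] with `mode = "smoothed"`.
#' @export
smoothPosterior <- function(model, evidence, actions = NULL) {
  stopifnot(model@emissionMode == "clone")
  e <- .asEvidence(model, evidence)
  if (is.null(actions)) actions <- e$actions
  if (!is.null(actions) && length(actions) != ncol(e$ev) - 1L)
    stop("actions must have length N - 1")
  fw <- .forwardSoft(model, e$ev, actions)
  H <- nStates(model)
  N <- ncol(e$ev)
  sym <- symbolOf(model)
  beta <- rep(1, H)
  out <- matrix(0, H, N)
  g <- fw$filt[, N]
  out[, N] <- g
  if (N > 1L) for (n in (N - 1L):1L) {
    M <- if (is.null(actions)) fw$Tm else fw$Ta[[actions[n]]]
    beta <- as.vector(M %*% (e$ev[sym, n + 1L] * beta))
    beta <- beta / sum(beta)
    g <- fw$filt[, n] * beta
    out[, n] <- g / sum(g)
  }
  new("CloneActivation", probs = out, mode = "smoothed", logLik = fw$loglik)
}

#' @describeIn activationMatrix activation matrix of a trace
#' @export
setMethod("activationMatrix", "CloneActivation", function(x) x@probs)

setMethod("show", "CloneActivation", function(object) {
  cat("CloneActivation (", object@mode, "): ", nrow(object@probs),
      " clones x ", ncol(object@probs), " steps, loglik ",
      format(object@logLik, digits = 8), "\n", sep = "")
})

#' Active-clone set of a trace
#'
#' States whose activation reaches `threshold` at any step (optionally a
#' subset of steps). This is the support notion used by the remapping and
#' splitter-cell analyses.
#'
#' @param trace a [CloneActivation-class].
#' @param threshold activation threshold (default 0.01 posterior mass).
#' @param steps optional step indices to restrict to.
#' @return integer vector of state ids.
#' @export
activeClones <- function(trace, threshold = 0.01, steps = NULL) {
  p <- trace@probs
  if (!is.null(steps)) p <- p[, steps, drop = FALSE]
  which(apply(p, 1L, max) >= threshold)
}

#' Export a clone-activation trace as TSV
#'
#' Long format with columns `step`, `clone_id`, `activation`; entries below
#' `floor` are omitted to keep files small.
#'
#' @param trace a [CloneActivation-class].
#' @param path output path.
#' @param floor smallest activation written (default 1e-6).
#' @return `path`, invisibly.
#' @export
writeActivationTSV <- function(trace, path, floor = 1e-6) {
  p <- trace@probs
  idx <- which(p >= floor, arr.ind = TRUE)
  df <- data.frame(step = idx[, 2L], clone_id = idx[, 1L],
                   activation = p[idx])
  df <- df[order(df$step, df$clone_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' MAP clone path (Viterbi decoding)
#'
#' The most probable hidden clone path given a hard action-observation
#' sequence. Ties are broken toward the lowest state index, so decodes are
#' reproducible.
#'
#' @param model a [CSCGModel-class] (clone emission mode).
#' @param seq an [AOSequence-class].
#' @return list with `path` (integer state ids, `path[n]` is a clone of
#'   `x_n`) and `logProb`. A sequence with no positive-probability path
#'   (possible when the model is unsmoothed) raises an error.
#' @export
viterbiDecode <- function(model, seq) {
  stopifnot(model@emissionMode == "clone")
  s <- .seqForModel(model, seq)
  v <- cscg_viterbi_cpp(model@transitions, model@prior,
                        model@allocation@clonesPerObs, s$obs0, s$act0,
                        model@nActions)
  if (length(v$path) == 0L)
    stop("no positive-probability clone path for this sequence")
  list(path = v$path + 1L, logProb = v$logprob)
}

#' Online MAP error correction of a corrupted symbol stream
#'
#' Models observation noise as soft evidence that assigns `1 - noiseRate` to
#' the received symbol and spreads `noiseRate` uniformly over the other
#' `E - 1` symbols, then runs a forward (online) pass and outputs, at every
#' step, the symbol with maximal posterior probability given the evidence so
#' far. A smoothed variant (`mode = "smoothed"`) that also uses future
#' evidence is provided, but the online forward pass is the default
#' procedure.
#'
#' @param model a [CSCGModel-class] (smoothed, so no stream has probability
#'   zero).
#' @param noisySeq corrupted [AOSequence-class].
#' @param noiseRate assumed corruption probability in `[0, 1)`.
#' @param mode `"online"` (forward only) or `"smoothed"`.
#' @param startUniform start from a uniform state distribution instead of
#'   the model's trained prior (default TRUE: retrieval begins unlocalized,
#'   so early evidence must not be overridden by where training walks
#'   happened to start).
#' @return list with `corrected` (an [AOSequence-class]), `posterior`
#'   (E x N symbol posteriors), and `changed` (logical, positions altered).
#' @export
correctErrors <- function(model, noisySeq, noiseRate,
                          mode = c("online", "smoothed"),
                          startUniform = TRUE) {
  mode <- match.arg(mode)
  if (!(noiseRate >= 0 && noiseRate < 1)) stop("noiseRate must be in [0, 1)")
  stopifnot(is(noisySeq, "AOSequence"))
  if (startUniform) model@prior <- rep(1 / nStates(model), nStates(model))
  E <- nObservations(model)
  x <- noisySeq@observations
  N <- length(x)
  ev <- matrix(noiseRate / (E - 1), E, N)
  ev[cbind(x, seq_len(N))] <- 1 - noiseRate
  acts <- if (length(noisySeq@actions)) noisySeq@actions else NULL
  if (mode == "online") {
    fw <- .forwardSoft(model, ev, acts)
    post <- fw$obsPost
  } else {
    tr <- smoothPosterior(model, ev, acts)
    sym <- symbolOf(model)
    post <- apply(tr@probs, 2L, function(col)
      vapply(seq_len(E), function(s) sum(col[sym == s]), numeric(1)))
    post <- sweep(post, 2L, colSums(post), "/")
  }
  corrected <- apply(post, 2L, which.max)
  AOout <- AOSequence(corrected, actions = acts, nObs = E,
                      nActions = noisySeq@nActions)
  list(corrected = AOout, posterior = post, changed = corrected != x)
}

#' Ancestral sampling from a CSCG (generative replay)
#'
#' Draws `z_1` from the prior (or a given start clone / start distribution),
#' then repeatedly samples `(a_n, z_{n+1}) ~ T[z_n, , ]`. Observations are
#' emitted deterministically by the clone allocation (or sampled from the
#' dense emission matrix).
#'
#' @param model a [CSCGModel-class].
#' @param nSteps number of transitions (the sequence has `nSteps + 1`
#'   observations).
#' @param start `NULL` (sample from the prior), a single clone id, or a
#'   probability vector over the H states.
#' @param seed integer seed.
#' @return list with `seq` (an [AOSequence-class]) and `states` (the sampled
#'   clone path).
#' @export
sampleCSCG <- function(model, nSteps, start = NULL, seed = 1L) {
  stopifnot(nSteps >= 1)
  H <- nStates(model)
  sym <- symbolOf(model)
  withr::with_seed(as.integer(seed), {
    z <- if (is.null(start)) {
      sample.int(H, 1L, prob = model@prior)
    } else if (length(start) == 1L) {
      s0 <- as.integer(start)
      if (is.na(s0) || s0 < 1L || s0 > H) stop("start clone out of range")
      s0
    } else {
      if (length(start) != H) stop("start distribution must have length H")
      sample.int(H, 1L, prob = start)
    }
    states <- integer(nSteps + 1L)
    acts <- integer(nSteps)
    states[1L] <- z
    Na <- model@nActions
    for (n in seq_len(nSteps)) {
      row <- as.vector(model@transitions[z, , ])  # Na*H joint cells
      pick <- sample.int(length(row), 1L, prob = row)
      a <- (pick - 1L) %% Na + 1L
      z <- (pick - 1L) %/% Na + 1L
      acts[n] <- a
      states[n + 1L] <- z
    }
    obs <- if (model@emissionMode == "dense") {
      vapply(states, function(s)
        sample.int(nObservations(model), 1L, prob = model@emission[s, ]),
        integer(1))
    } else sym[states]
    list(seq = AOSequence(obs, actions = acts, nObs = nObservations(model),
                          nActions = Na),
         states = states)
  })
}

#' Sample the next observation during forward message passing (replay)
#'
#' Computes the one-step-ahead predictive distribution over observation
#' symbols given a prefix (normalized messages from hidden states to the
#' observation) and samples from it.
#'
#' @param model a [CSCGModel-class] (clone emission mode).
#' @param prefix an [AOSequence-class] seen so far.
#' @param action optional next action; `NULL` integrates over actions.
#' @param seed integer seed.
#' @return list with `symbol` (the sampled next observation) and
#'   `distribution` (the predictive probabilities it was drawn from).
#' @export
replayObservation <- function(model, prefix, action = NULL, seed = 1L) {
  tr <- filterPosterior(model, prefix)
  alpha <- tr@probs[, ncol(tr@probs)]
  Ta <- .transMats(model)
  M <- if (is.null(action)) Reduce(`+`, Ta) else Ta[[action]]
  apred <- as.vector(crossprod(M, alpha))
  sym <- symbolOf(model)
  E <- nObservations(model)
  p <- vapply(seq_len(E), function(s) sum(apred[sym == s]), numeric(1))
  p <- p / sum(p)
  s <- withr::with_seed(as.integer(seed), sample.int(E, 1L, prob = p))
  list(symbol = s, distribution = p)
}

#' Assign clones to environments from training walks
#'
#' Sums the filtered forward messages over each environment's training walk
#' to obtain a per-environment distribution over hidden states, then assigns
#' every used state to the environment where it accumulates the most mass.
#' The result is a partition of the used states, suitable for
#' [environmentPosterior()].
#'
#' @param model a [CSCGModel-class].
#' @param seqs list of [AOSequence-class], one per environment.
#' @param minMass states whose total mass across all walks is below this are
#'   treated as unused and left unassigned.
#' @return list of integer state-id vectors, one per environment.
#' @export
environmentCloneSets <- function(model, seqs, minMass = 1e-6) {
  seqs <- .asSeqList(seqs)
  W <- vapply(seqs, function(sq) rowSums(filterPosterior(model, sq)@probs),
              numeric(nStates(model)))
  used <- rowSums(W) > minMass
  assign <- apply(W, 1L, which.max)
  lapply(seq_along(seqs), function(e) which(used & assign == e))
}

#' Per-step environment-identity posterior
#'
#' Given a partition of the hidden states into per-environment clone sets,
#' the probability of being in environment `e` at step `n` is the filtered
#' posterior mass on that environment's clones.
#'
#' @param model a [CSCGModel-class].
#' @param cloneSets list of disjoint integer state-id vectors.
#' @param seq test [AOSequence-class] (or soft-evidence matrix).
#' @param actions optional actions when `seq` is a matrix.
#' @return numeric matrix nEnv x N; column sums are <= 1 (mass on
#'   unassigned states is not attributed to any environment).
#' @export
environmentPosterior <- function(model, cloneSets, seq, actions = NULL) {
  all_ids <- unlist(cloneSets)
  if (anyDuplicated(all_ids)) stop("cloneSets must be disjoint")
  tr <- filterPosterior(model, seq, actions)
  out <- vapply(cloneSets, function(ids)
    colSums(tr@probs[ids, , drop = FALSE]), numeric(ncol(tr@probs)))
  t(out)
}
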