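#' @include allocation.R sequence.R
NULL

#' Create a CSCG model
#'
#' Builds a clone-structured cognitive graph with a given clone allocation
#' and action alphabet. `init = "uniform"` sets every row block of the
#' transition tensor uniform; `init = "random"` draws every entry i.i.d.
#' uniform on (0, 1] and normalizes each row block jointly over
#' (action, next state) — strictly positive so EM cannot start on an
#' absorbing zero. The prior is uniform over all H states.
#'
#' @param allocation a [CloneAllocation-class] (or an integer vector of
#'   clones per symbol, passed to [CloneAllocation()]).
#' @param nActions number of actions (>= 1).
#' @param seed integer seed for `init = "random"`; the same seed always
#'   yields the identical model.
#' @param init `"random"` or `"uniform"`.
#' @return a [CSCGModel-class].
#' @examples
#' m <- makeCSCG(CloneAllocation(2L, nObs = 3), nActions = 2, seed = 1)
#' nStates(m)
#' @export
makeCSCG <- function(allocation, nActions = 1L, seed = 1L,
                     init = c("random", "uniform")) {
  if (!is(allocation, "CloneAllocation"))
    allocation <- CloneAllocation(allocation)
  init <- match.arg(init)
  nActions <- as.integer(nActions)
  if (is.na(nActions) || nActions < 1L) stop("nActions must be >= 1")
  H <- allocation@nStates
  trans <- if (init == "uniform") {
    array(1 / (nActions * H), dim = c(H, nActions, H))
  } else {
    tr <- withr::with_seed(as.integer(seed), {
      # runif lives on (0,1); shift ensures strict positivity at the boundary
      array(1 - stats::runif(H * nActions * H), dim = c(H, nActions, H))
    })
    .normalizeRows(tr)
  }
  new("CSCGModel", allocation = allocation, nActions = nActions,
      prior = rep(1 / H, H), transitions = trans,
      emission = matrix(numeric(0), 0, 0), emissionMode = "clone",
      metadata = list(seed = as.integer(seed), init = init,
                      pseudocount = NA_real_, loglikTrace = numeric(0),
                      rowCounts = NULL))
}

# joint (action, next-state) normalization of every row of an H x Na x H array
.normalizeRows <- function(trans) {
  H <- dim(trans)[1L]
  flat <- matrix(trans, nrow = H)
  rs <- rowSums(flat)
  if (any(rs <= 0)) stop("degenerate row: zero total mass")
  array(flat / rs, dim = dim(trans))
}

#' @describeIn nStates state count of a model
#' @export
setMethod("nStates", "CSCGModel", function(x) x@allocation@nStates)

#' @describeIn nObservations alphabet size of a model
#' @export
setMethod("nObservations", "CSCGModel", function(x) x@allocation@nObs)

#' @describeIn nActions action alphabet of a model
#' @export
setMethod("nActions", "CSCGModel", function(x) x@nActions)

#' @describeIn allocation clone allocation of a model
#' @export
setMethod("allocation", "CSCGModel", function(x) x@allocation)

#' @describeIn transitionTensor transition tensor of a model
#' @export
setMethod("transitionTensor", "CSCGModel", function(x) x@transitions)

#' @describeIn priorProb prior of a model
#' @export
setMethod("priorProb", "CSCGModel", function(x) x@prior)

#' @describeIn modelMeta metadata list of a model
#' @export
setMethod("modelMeta", "CSCGModel", function(x) x@metadata)

setMethod("show", "CSCGModel", function(object) {
  cat("CSCGModel:", nStates(object), "states (",
      nObservations(object), "symbols ),", object@nActions, "actions,",
      object@emissionMode, "emissions\n")
  tr <- object@metadata$loglikTrace
  if (length(tr))
    cat("  trained:", length(tr), "EM iterations, final loglik",
        format(tr[length(tr)], digits = 8), "\n")
  kap <- object@metadata$pseudocount
  if (!is.null(kap) && !is.na(kap)) cat("  pseudocount:", kap, "\n")
})

#' Action-marginalized transition matrix
#'
#' Integrating the action out of `P(z', a | z)` recovers the transition
#' matrix of a standard cloned HMM: `P(z' | z) = sum_a T[z, a, z']`.
#'
#' @param model a [CSCGModel-class].
#' @return row-stochastic H x H matrix.
#' @export
marginalTransitions <- function(model) {
  stopifnot(is(model, "CSCGModel"))
  H <- nStates(model)
  out <- matrix(0, H, H)
  for (a in seq_len(model@nActions)) out <- out + model@transitions[, a, ]
  out
}

#' Apply pseudocount smoothing to a trained model
#'
#' Adds a uniform pseudocount to every (action, next-state) cell of each row
#' of the transition tensor and renormalizes, exactly as the M-step with
#' pseudocount would when each row carries unit count mass. Gives every
#' transition nonzero probability so no test sequence has probability zero.
#'
#' @param model a [CSCGModel-class].
#' @param kappa pseudocount (>= 0) on the conditional probability scale.
#' @param smoothPrior also smooth the prior toward uniform (default TRUE).
#' @return the smoothed model.
#' @export
smoothModel <- function(model, kappa, smoothPrior = TRUE) {
  stopifnot(is(model, "CSCGModel"), kappa >= 0)
  if (kappa == 0) return(model)
  tr <- .normalizeRows(model@transitions + kappa)
  model@transitions <- tr
  if (smoothPrior) {
    p <- model@prior + kappa
    model@prior <- p / sum(p)
  }
  model@metadata$inferenceSmoothing <- kappa
  model
}

# Coerce a sequence for the compiled kernels (0-based), validating alphabets.
# A sequence without actions is accepted for a single-action model (all
# actions are then that action).
.seqForModel <- function(model, seq) {
  if (!is(seq, "AOSequence")) seq <- AOSequence(seq)
  x <- seq@observations
  if (seq@nObs > nObservations(model) || max(x) > nObservations(model))
    stop("sequence observations exceed the model alphabet")
  a <- seq@actions
  n <- length(x)
  if (length(a) == 0L) {
    if (model@nActions != 1L)
      stop("sequence has no actions but the model has ", model@nActions,
           " actions; supply actions or marginalize explicitly")
    a <- rep(1L, max(n - 1L, 0L))
  }
  if (length(a) && max(a) > model@nActions)
    stop("sequence actions exceed the model action alphabet")
  list(obs0 = x - 1L, act0 = a - 1L)
}

.asSeqList <- function(seqs) {
  if (is(seqs, "AOSequence")) list(seqs)
  else if (is.list(seqs)) seqs
  else list(AOSequence(seqs))
}

#' Save a model to a JSON archive
#'
#' A single JSON document with members `version`, `clones_per_obs`, `prior`,
#' `transitions` (flattened column-major, dim recorded), optional `emission`,
#' and `meta` (seed, pseudocount, loglik trace). Numerics are written with 17
#' significant digits, which round-trips IEEE doubles exactly.
#'
#' @param model a [CSCGModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [loadModel()]
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "CSCGModel"))
  meta <- model@metadata
  doc <- list(
    version = "1",
    n_obs = nObservations(model),
    n_actions = model@nActions,
    clones_per_obs = model@allocation@clonesPerObs,
    prior = model@prior,
    transitions_dim = dim(model@transitions),
    transitions = as.vector(model@transitions),
    emission_mode = model@emissionMode,
    emission = if (model@emissionMode == "dense") as.vector(model@emission)
               else NULL,
    meta = list(seed = meta$seed,
                pseudocount = meta$pseudocount,
                loglik_trace = meta$loglikTrace,
                row_counts = meta$rowCounts)
  )
  json <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                           null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Load a model from a JSON archive
#'
#' @param path file written by [saveModel()].
#' @return a [CSCGModel-class]; numeric fields equal the saved model bit for
#'   bit, so log-likelihoods computed before and after a round trip agree
#'   exactly.
#' @export
loadModel <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("cannot parse model file: ",
                                           conditionMessage(e)))
  if (is.null(doc$version)) stop("cannot parse model file: missing version")
  if (!identical(as.character(doc$version), "1"))
    stop("unsupported model file version: ", doc$version)
  req <- c("clones_per_obs", "prior", "transitions", "transitions_dim")
  if (!all(req %in% names(doc))) stop("cannot parse model file: missing fields")
  al <- CloneAllocation(as.integer(doc$clones_per_obs))
  dims <- as.integer(doc$transitions_dim)
  tr <- array(as.numeric(doc$transitions), dim = dims)
  mode <- if (is.null(doc$emission_mode)) "clone" else doc$emission_mode
  em <- if (identical(mode, "dense"))
    matrix(as.numeric(doc$emission), nrow = dims[1L])
  else matrix(numeric(0), 0, 0)
  meta <- doc$meta
  new("CSCGModel", allocation = al, nActions = as.integer(doc$n_actions),
      prior = as.numeric(doc$prior), transitions = tr, emission = em,
      emissionMode = mode,
      metadata = list(seed = if (is.null(meta$seed)) NA_integer_
                             else as.integer(meta$seed),
                      pseudocount = if (is.null(meta$pseudocount)) NA_real_
                                    else as.numeric(meta$pseudocount),
                      loglikTrace = as.numeric(meta$loglik_trace),
                      rowCounts = if (is.null(meta$row_counts)) NULL
                                  else as.numeric(meta$row_counts)))
}
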