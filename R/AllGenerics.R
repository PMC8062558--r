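#' @include AllClasses.R
NULL

#' Number of observation symbols
#' @param x a CloneAllocation, AOSequence, CSCGModel or environment object.
#' @return integer alphabet size E.
#' @export
setGeneric("nObservations", function(x) standardGeneric("nObservations"))

#' Number of hidden states
#' @param x a CloneAllocation or CSCGModel.
#' @return integer total state count H.
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' Number of actions
#' @param x a CSCGModel or AOSequence.
#' @return integer action alphabet size.
#' @export
setGeneric("nActions", function(x) standardGeneric("nActions"))

#' Clone allocation of a model
#' @param x a CSCGModel.
#' @return the [CloneAllocation-class].
#' @export
setGeneric("allocation", function(x) standardGeneric("allocation"))

#' Transition tensor accessor
#' @param x a CSCGModel.
#' @return numeric array of dim c(H, nActions, H).
#' @export
setGeneric("transitionTensor", function(x) standardGeneric("transitionTensor"))

#' Prior over hidden states
#' @param x a CSCGModel.
#' @return numeric vector of length H summing to 1.
#' @export
setGeneric("priorProb", function(x) standardGeneric("priorProb"))

#' Model metadata
#' @param x a CSCGModel.
#' @return list of provenance fields (seed, pseudocount, loglik trace, ...).
#' @export
setGeneric("modelMeta", function(x) standardGeneric("modelMeta"))

#' Observations of a sequence
#' @param x an AOSequence.
#' @return integer vector of symbol ids.
#' @export
setGeneric("observations", function(x) standardGeneric("observations"))

#' Actions of a sequence
#' @param x an AOSequence.
#' @return integer vector of action ids (length N-1, possibly 0).
#' @export
setGeneric("actions", function(x) standardGeneric("actions"))

#' Activation matrix of a clone-activation trace
#' @param x a CloneActivation.
#' @return numeric matrix H x N of per-step posteriors.
#' @export
setGeneric("activationMatrix", function(x) standardGeneric("activationMatrix"))
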