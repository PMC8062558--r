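#' @include AllGenerics.R
NULL

#' Construct a clone allocation
#'
#' @param clonesPerObs integer vector; `clonesPerObs[s]` clones are allocated
#'   to observation symbol `s`. A scalar together with `nObs` recycles the
#'   same clone count for every symbol.
#' @param nObs optional alphabet size when `clonesPerObs` is scalar.
#' @return a [CloneAllocation-class].
#' @examples
#' al <- CloneAllocation(c(3L, 2L))
#' nStates(al)       # 5
#' cloneRange(al, 2) # 4:5
#' @export
CloneAllocation <- function(clonesPerObs, nObs = NULL) {
  if (!is.null(nObs) && length(clonesPerObs) == 1L)
    clonesPerObs <- rep(clonesPerObs, nObs)
  m <- as.integer(clonesPerObs)
  if (length(m) < 1L || any(is.na(m)) || any(m < 1L))
    stop("clone counts must be positive integers")
  new("CloneAllocation",
      clonesPerObs = m,
      offsets = as.integer(cumsum(c(1L, m[-length(m)]))),
      nObs = length(m),
      nStates = as.integer(sum(m)))
}

#' Clone indices of an observation symbol
#'
#' Returns the contiguous block of hidden-state indices allocated to a
#' symbol: states `offsets[s] .. offsets[s] + clonesPerObs[s] - 1`.
#'
#' @param allocation a [CloneAllocation-class] (or a CSCGModel).
#' @param symbol observation symbol id in 1..E.
#' @return integer vector of state indices.
#' @export
cloneRange <- function(allocation, symbol) {
  if (is(allocation, "CSCGModel")) allocation <- allocation@allocation
  symbol <- as.integer(symbol)
  if (length(symbol) != 1L || is.na(symbol) || symbol < 1L ||
      symbol > allocation@nObs)
    stop("symbol out of range")
  seq.int(allocation@offsets[symbol],
          length.out = allocation@clonesPerObs[symbol])
}

#' Symbol emitted by each hidden state
#'
#' @param allocation a [CloneAllocation-class] (or a CSCGModel).
#' @param states integer state ids (default: all states).
#' @return integer vector of symbol ids, one per state.
#' @export
symbolOf <- function(allocation, states = NULL) {
  if (is(allocation, "CSCGModel")) allocation <- allocation@allocation
  all_sym <- rep.int(seq_len(allocation@nObs), allocation@clonesPerObs)
  if (is.null(states)) return(all_sym)
  states <- as.integer(states)
  if (any(is.na(states)) || any(states < 1L) || any(states > allocation@nStates))
    stop("state id out of range")
  all_sym[states]
}

#' @describeIn nObservations alphabet size of an allocation
#' @export
setMethod("nObservations", "CloneAllocation", function(x) x@nObs)

#' @describeIn nStates total state count of an allocation
#' @export
setMethod("nStates", "CloneAllocation", function(x) x@nStates)

setMethod("show", "CloneAllocation", function(object) {
  cat("CloneAllocation:", object@nObs, "symbols,", object@nStates,
      "states\n  clones per symbol:",
      if (length(unique(object@clonesPerObs)) == 1L)
        paste0(object@clonesPerObs[1L], " (uniform)")
      else paste(utils::head(object@clonesPerObs, 10L), collapse = " "),
      "\n")
})
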