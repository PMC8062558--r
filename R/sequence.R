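#' @include AllGenerics.R
NULL

#' Construct an action-observation sequence
#'
#' @param observations integer symbol ids in 1..nObs.
#' @param actions integer action ids in 1..nActions, length
#'   `length(observations) - 1`, or `NULL` for an action-free sequence.
#' @param nObs observation alphabet size (default: max observed).
#' @param nActions action alphabet size (default: max action, or 1).
#' @return an [AOSequence-class].
#' @export
AOSequence <- function(observations, actions = NULL, nObs = NULL,
                       nActions = NULL) {
  x <- as.integer(observations)
  a <- if (is.null(actions)) integer(0) else as.integer(actions)
  if (is.null(nObs)) nObs <- max(x)
  if (is.null(nActions)) nActions <- if (length(a)) max(a) else 1L
  new("AOSequence", observations = x, actions = a,
      nObs = as.integer(nObs), nActions = as.integer(nActions))
}

#' @describeIn observations observation stream of a sequence
#' @export
setMethod("observations", "AOSequence", function(x) x@observations)

#' @describeIn actions action stream of a sequence
#' @export
setMethod("actions", "AOSequence", function(x) x@actions)

#' @describeIn nObservations alphabet size of a sequence
#' @export
setMethod("nObservations", "AOSequence", function(x) x@nObs)

#' @describeIn nActions action alphabet of a sequence
#' @export
setMethod("nActions", "AOSequence", function(x) x@nActions)

setMethod("length", "AOSequence", function(x) length(x@observations))

setMethod("show", "AOSequence", function(object) {
  n <- length(object@observations)
  cat("AOSequence: N =", n, "observations over", object@nObs, "symbols,",
      if (length(object@actions)) paste(object@nActions, "actions")
      else "no actions", "\n")
  k <- min(n, 12L)
  cat("  x:", paste(object@observations[seq_len(k)], collapse = " "),
      if (n > k) "...\n" else "\n")
})

#' Write a sequence as TSV
#'
#' Columns `step`, `action`, `observation`; the action cell of the last row
#' is empty (there is no action after the final observation).
#'
#' @param seq an [AOSequence-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAOSequence <- function(seq, path) {
  stopifnot(is(seq, "AOSequence"))
  n <- length(seq@observations)
  act <- if (length(seq@actions)) c(as.character(seq@actions), "")
         else rep("", n)
  df <- data.frame(step = seq_len(n), action = act,
                   observation = seq@observations)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sequence from TSV
#'
#' @param path file written by [writeAOSequence()].
#' @param nObs,nActions optional alphabet sizes (defaults inferred).
#' @return an [AOSequence-class].
#' @export
readAOSequence <- function(path, nObs = NULL, nActions = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character", "integer"))
  if (!all(c("step", "action", "observation") %in% names(df)))
    stop("not a sequence TSV: expected columns step, action, observation")
  a <- df$action
  a <- a[nzchar(a)]
  AOSequence(df$observation,
             actions = if (length(a)) as.integer(a) else NULL,
             nObs = nObs, nActions = nActions)
}
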