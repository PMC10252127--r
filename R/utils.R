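#' @keywords internal
expit <- function(x) 1 / (1 + exp(-x))

#' @keywords internal
logit <- function(p) log(p / (1 - p))

#' Derive independent RNG substream seeds from one master seed
#'
#' A single user-facing seed is expanded deterministically into named
#' substream seeds so that, e.g., redrawing censoring times does not
#' perturb the covariate draws. All derived seeds stay below 2^31.
#'
#' @param seed integer master seed.
#' @param streams character vector of stream names.
#' @return named integer vector of seeds, one per stream.
#' @keywords internal
substream_seeds <- function(seed, streams) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  s <- sample.int(.Machine$integer.max - 1L, length(streams))
  names(s) <- streams
  s
}

# reverse cumulative sum: out[i] = sum(x[i:n])
#' @keywords internal
revcumsum <- function(x) {
  if (is.matrix(x)) {
    apply(x[nrow(x):1, , drop = FALSE], 2L, cumsum)[nrow(x):1, , drop = FALSE]
  } else rev(cumsum(rev(x)))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
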