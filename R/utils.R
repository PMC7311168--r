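#' @keywords internal
"_PACKAGE"

# Canonical condition order used everywhere downstream.
CONDITIONS <- c("CS+", "GS1", "GS2", "GS3", "GS4", "CS-")
PHASES <- c("habituation", "acquisition", "generalization")

#' Derive independent sub-seeds from one master seed
#'
#' A single run seed is expanded into named per-stage seeds so that changing
#' the settings of one stage (e.g. bootstrap repeats) cannot perturb the
#' random stream of another. Sub-seeds are kept below 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param labels Character vector naming the sub-streams.
#' @return Named integer vector of sub-seeds.
#' @export
derive_seeds <- function(seed, labels) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(labels))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, length(labels))
  names(s) <- labels
  s
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
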