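#' Generate a pseudo-randomized experiment schedule
#'
#' Builds the trial sequence of a three-phase differential conditioning
#' experiment: habituation and acquisition present CS+ and CS- (15 trials
#' each by default), the generalization test presents all six faces
#' (CS+, GS1..GS4, CS-) 15 times each, giving 150 trials in total. Within each
#' phase the order is pseudo-randomized so that no more than two trials of the
#' same condition occur in a row (rejection sampling over permutations).
#' Reinforcement (the aversive US at CS+ offset) is assigned to a random
#' subset of CS+ trials per phase: 80% (12/15) during acquisition, 40% (6/15)
#' during generalization, none during habituation. Inter-trial intervals are
#' drawn uniformly from 2000-2500 ms.
#'
#' @param n_per_condition Presentations per condition per phase (default 15).
#' @param phases Character vector of phases to generate.
#' @param reinforcement Named numeric vector of reinforcement fractions for
#'   CS+ per phase.
#' @param iti_range Length-2 numeric, inter-trial interval bounds in ms.
#' @param max_run Maximum allowed run length of one condition (default 2).
#' @param seed Integer seed; the schedule is reproducible given the seed.
#' @param max_attempts Attempt cap for the rejection sampler per phase.
#' @return Object of class `experiment_schedule`: a data frame with columns
#'   `phase`, `trial`, `condition`, `reinforced`, `iti_ms`.
#' @export
#' @examples
#' sched <- make_schedule(seed = 1)
#' table(sched$phase)
make_schedule <- function(n_per_condition = 15,
                          phases = PHASES,
                          reinforcement = c(habituation = 0,
                                            acquisition = 12 / 15,
                                            generalization = 6 / 15),
                          iti_range = c(2000, 2500),
                          max_run = 2,
                          seed = 1L,
                          max_attempts = 10000L) {
  stopifnot(n_per_condition >= 1, all(reinforcement >= 0 & reinforcement <= 1),
            length(iti_range) == 2L, iti_range[1] <= iti_range[2])
  phases <- match.arg(phases, PHASES, several.ok = TRUE)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  out <- list()
  for (ph in phases) {
    conds <- if (ph == "generalization") CONDITIONS else c("CS+", "CS-")
    labels <- rep(conds, each = n_per_condition)
    # a single condition repeated more than max_run times can never satisfy
    # the run-length constraint
    if (length(conds) == 1L && n_per_condition > max_run)
      stop("run-length constraint infeasible: one condition with ",
           n_per_condition, " presentations")
    ord <- sample_no_runs(labels, max_run, max_attempts)
    n <- length(ord)
    reinforced <- rep(FALSE, n)
    frac <- unname(reinforcement[ph])
    if (is.na(frac)) frac <- 0
    csp <- which(ord == "CS+")
    n_reinf <- round(frac * length(csp))
    if (n_reinf > 0)
      reinforced[sample(csp, n_reinf)] <- TRUE
    out[[ph]] <- data.frame(
      phase = ph, trial = seq_len(n), condition = ord,
      reinforced = reinforced,
      iti_ms = stats::runif(n, iti_range[1], iti_range[2]),
      stringsAsFactors = FALSE
    )
  }
  sched <- do.call(rbind, out)
  rownames(sched) <- NULL
  class(sched) <- c("experiment_schedule", "data.frame")
  sched
}

# rejection-sample a permutation with no run longer than max_run
sample_no_runs <- function(labels, max_run, max_attempts) {
  for (i in seq_len(max_attempts)) {
    ord <- sample(labels)
    r <- rle(ord)
    if (max(r$lengths) <= max_run) return(ord)
  }
  stop("could not satisfy the run-length constraint (<= ", max_run,
       " in a row) after ", max_attempts, " attempts")
}

#' Validate the structural invariants of a schedule
#'
#' Checks trial counts per phase and condition, reinforcement counts,
#' the run-length constraint and the ITI bounds. Errors on first violation.
#'
#' @param sched An `experiment_schedule`.
#' @param n_per_condition Expected presentations per condition.
#' @param max_run Maximum allowed run length.
#' @return Invisibly `TRUE`.
#' @export
validate_schedule <- function(sched, n_per_condition = 15, max_run = 2) {
  for (ph in unique(sched$phase)) {
    s <- sched[sched$phase == ph, ]
    conds <- if (ph == "generalization") CONDITIONS else c("CS+", "CS-")
    tab <- table(factor(s$condition, levels = conds))
    if (!all(tab == n_per_condition))
      stop("phase ", ph, ": unbalanced condition counts")
    if (any(s$reinforced & s$condition != "CS+"))
      stop("phase ", ph, ": reinforcement outside CS+")
    if (max(rle(s$condition)$lengths) > max_run)
      stop("phase ", ph, ": run-length constraint violated")
    if (any(s$iti_ms < 2000 | s$iti_ms > 2500))
      stop("phase ", ph, ": ITI out of bounds")
  }
  invisible(TRUE)
}
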