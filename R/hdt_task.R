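#' The Hungry Donkey Task payoff environment
#'
#' The Hungry Donkey Task (HDT) is a child-friendly Iowa Gambling Task in
#' which children open one of four doors per trial to win "apples".  Doors A
#' and B always pay 4 apples but carry large scheduled losses; doors C and D
#' always pay 2 apples with small losses.  Per 10 selections of a door the
#' canonical schedule loses 50 apples on A and B and 10 apples on C and D, so
#' A/B are net-disadvantageous (-10 per block) and C/D net-advantageous
#' (+10 per block).
#'
#' Loss *magnitudes* are fixed by the task (A: 0/8/10/12, B: 0/50,
#' C: 0/1/2/3, D: 0/10).  The position of losses within each 10-selection
#' block is a fixed pseudo-random permutation drawn once from
#' `schedule_seed`, so a schedule object delivers identical outcome
#' sequences across runs.  Outcomes are indexed by the per-door selection
#' count (deck-indexed), not the global trial number.
#'
#' @param schedule_seed integer seed fixing the within-block loss positions.
#'   The default (101) is the package's canonical schedule.
#' @return An object of class `hdt_schedule`: a list with `gains` (named
#'   integer, apples per selection) and `losses` (4 x 10 integer matrix,
#'   rows A-D, one block of loss magnitudes per door).
#' @examples
#' sch <- canonical_schedule()
#' rowSums(sch$losses)  # A,B lose 50 per block; C,D lose 10
#' @export
canonical_schedule <- function(schedule_seed = 101L) {
  base <- list(
    A = c(8L, 10L, 10L, 10L, 12L, 0L, 0L, 0L, 0L, 0L),
    B = c(50L, rep(0L, 9L)),
    C = c(1L, 2L, 2L, 2L, 3L, 0L, 0L, 0L, 0L, 0L),
    D = c(10L, rep(0L, 9L))
  )
  losses <- with_seed(schedule_seed, {
    t(vapply(base, function(x) x[sample.int(10L)], integer(10L)))
  })
  rownames(losses) <- DOORS
  structure(
    list(gains = c(A = 4L, B = 4L, C = 2L, D = 2L),
         losses = losses, schedule_seed = schedule_seed),
    class = "hdt_schedule"
  )
}

#' Scheduled outcome of a door selection
#'
#' Returns the deterministic (gain, loss, net) outcome delivered on the
#' `nth_selection`-th time a door is opened.  The loss is read from position
#' `((nth_selection - 1) mod 10) + 1` of that door's block sequence; the
#' block repeats every 10 selections of the same door.
#'
#' @param schedule an [canonical_schedule()] object.
#' @param door door id, one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param nth_selection positive integer (vectorised): the running count of
#'   selections of this door, including the current one.
#' @return A data.frame with columns `gain`, `loss`, `net` (apples).
#' @export
door_outcome <- function(schedule, door, nth_selection) {
  stopifnot(inherits(schedule, "hdt_schedule"))
  if (any(nth_selection < 1) || any(nth_selection != round(nth_selection))) {
    stop("nth_selection must be a positive integer count")
  }
  i <- door_index(door)
  if (length(i) != 1L) stop("door must be a single id")
  pos <- ((nth_selection - 1L) %% 10L) + 1L
  gain <- rep(unname(schedule$gains[i]), length(pos))
  loss <- unname(schedule$losses[i, pos])
  data.frame(gain = gain, loss = loss, net = gain - loss)
}

#' Expected net yield of a door, per trial
#'
#' Mean of (gain - loss) over one 10-selection block.  Under the canonical
#' schedule this is -1 apple/trial for doors A and B and +1 for C and D,
#' which is what makes A/B "disadvantageous" and C/D "advantageous".
#'
#' @inheritParams door_outcome
#' @return numeric scalar, apples per trial.
#' @export
expected_net_per_trial <- function(schedule, door) {
  stopifnot(inherits(schedule, "hdt_schedule"))
  i <- door_index(door)
  unname(schedule$gains[i] - mean(schedule$losses[i, ]))
}

#' @export
print.hdt_schedule <- function(x, ...) {
  cat("Hungry Donkey Task payoff schedule (seed ", x$schedule_seed, ")\n",
      sep = "")
  for (d in DOORS) {
    cat(sprintf("  door %s: gain %d/trial, block losses [%s]\n",
                d, x$gains[[d]], paste(x$losses[d, ], collapse = " ")))
  }
  invisible(x)
}

#' Read and write trial tables
#'
#' Trial records are plain CSV with columns `subject_id`, `trial`, `door`,
#' `gain`, `loss`, `net`; doors coded as single characters A-D.
#'
#' @param trials a trials data.frame.
#' @param path file path.
#' @return `read_trials` returns the trials data.frame.
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(c("subject_id", "trial", "door", "gain", "loss", "net")
                %in% names(trials)))
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "trial", "door", "gain", "loss", "net")
  if (!all(need %in% names(tr))) {
    stop("trials file must have columns: ", paste(need, collapse = ", "))
  }
  door_index(tr$door)  # validate codes
  if (any(tr$net != tr$gain - tr$loss)) stop("net != gain - loss in file")
  tr
}
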