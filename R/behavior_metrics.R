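#' Behavioural metrics of HDT performance
#'
#' Three classical summaries of Hungry Donkey Task choice behaviour:
#'
#' * **netscore** — advantageous minus disadvantageous selections,
#'   `(C + D) - (A + B)`.
#' * **win-stay** — among trials whose *previous* trial had a net gain
#'   (net >= 0), the proportion where the same door was chosen again.
#' * **lose-shift** — among trials whose previous trial had a net loss
#'   (net < 0), the proportion where a different door was chosen.
#'
#' "Win" is defined on the *net* outcome (net >= 0), matching the gain/loss
#' definition used by the VPP perseveration term, not on the mere absence
#' of points lost.  When a session contains no eligible predecessor trials
#' the proportion is undefined and returned as `NA` (never 0), and `NA`
#' propagates into downstream tables as a missing value.
#'
#' @param trials a trials data.frame for a single subject, ordered (or
#'   orderable) by `trial`.
#' @return `netscore()`: integer; `win_stay()` / `lose_shift()`: proportion
#'   in \[0, 1\] or `NA` when undefined.
#' @examples
#' tr <- data.frame(trial = 1:3, door = c("C", "C", "D"),
#'                  gain = 2, loss = c(0, 0, 10), net = c(2, 2, -8))
#' netscore(tr)   # 3
#' win_stay(tr)   # 0.5
#' @export
netscore <- function(trials) {
  stopifnot(nrow(trials) > 0L)
  idx <- door_index(trials$door)
  sum(idx >= 3L) - sum(idx <= 2L)
}

#' @rdname netscore
#' @export
win_stay <- function(trials) {
  .transition_prop(trials, win = TRUE, stay = TRUE)
}

#' @rdname netscore
#' @export
lose_shift <- function(trials) {
  .transition_prop(trials, win = FALSE, stay = FALSE)
}

.transition_prop <- function(trials, win, stay) {
  if (nrow(trials) < 2L) return(NA_real_)
  trials <- trials[order(trials$trial), , drop = FALSE]
  prev_net <- trials$net[-nrow(trials)]
  prev_door <- trials$door[-nrow(trials)]
  cur_door <- trials$door[-1L]
  eligible <- if (win) prev_net >= 0 else prev_net < 0
  if (!any(eligible)) return(NA_real_)
  same <- cur_door[eligible] == prev_door[eligible]
  if (stay) mean(same) else mean(!same)
}

#' Behavioural-metric table for a cohort
#'
#' @param trials trials data.frame with a `subject_id` column covering one
#'   or more subjects.
#' @return data.frame with columns `subject_id`, `netscore`, `win_stay`,
#'   `lose_shift` (undefined metrics as `NA`).
#' @export
behavior_metrics <- function(trials) {
  ids <- unique(trials$subject_id)
  rows <- lapply(ids, function(id) {
    tr <- trials[trials$subject_id == id, , drop = FALSE]
    data.frame(subject_id = id, netscore = netscore(tr),
               win_stay = win_stay(tr), lose_shift = lose_shift(tr),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
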