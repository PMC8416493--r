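#' Value-Plus-Perseveration model parameters
#'
#' Bundles one subject's eight decision-process parameters.  The VPP model
#' values each door as a weighted average of an expected-value (EV) learner
#' and a perseveration heuristic:
#' \deqn{V_j = w \, EV_j + (1 - w) \, P_j}
#' and chooses through a softmax with sensitivity \eqn{\theta = 3^c - 1}.
#'
#' * `phi` — updating rate of the chosen door's EV, in (0,1); 0 = never
#'   update, 1 = EV jumps to the latest utility.
#' * `alpha` — feedback sensitivity shaping outcome utility, in (0,1).
#' * `lambda` — loss aversion multiplying the utility of net losses, in
#'   (0,5); 1 = gains and losses weighted equally.
#' * `eps_pos`, `eps_neg` — increments to the chosen door's perseveration
#'   strength after a net gain (net >= 0) or net loss (net < 0).
#'   Unbounded reals: fitted cohort values routinely fall far outside
#'   (-1, 1), e.g. median `eps_neg` near -6.5.
#' * `k` — per-trial perseveration decay factor in (0,1); 1 = no decay,
#'   0 = complete decay.
#' * `w` — EV weight in (0,1).
#' * `c` — response consistency in (0,5); 0 = uniform random choice.
#'
#' Boundary values of the bounded parameters are accepted here (useful for
#' limiting-case checks); [to_unconstrained()] and the fitting routines
#' require strictly interior values.
#'
#' @param phi,alpha,lambda,eps_pos,eps_neg,k,w,c numeric scalars.
#' @return A named numeric vector of class `vpp_params`, in the canonical
#'   order `phi, alpha, lambda, eps_pos, eps_neg, k, w, c`.
#' @examples
#' p <- vpp_params(phi = 0.1, alpha = 0.5, lambda = 0.1,
#'                 eps_pos = 1, eps_neg = -6, k = 0.5, w = 0.8, c = 1)
#' @export
vpp_params <- function(phi, alpha, lambda, eps_pos, eps_neg, k, w, c) {
  x <- c(phi = phi, alpha = alpha, lambda = lambda, eps_pos = eps_pos,
         eps_neg = eps_neg, k = k, w = w, c = c)
  if (!all(is.finite(x))) stop("all VPP parameters must be finite")
  chk <- function(v, lo, hi, nm) {
    if (v < lo || v > hi) {
      stop(sprintf("%s = %g outside [%g, %g]", nm, v, lo, hi))
    }
  }
  chk(phi, 0, 1, "phi"); chk(alpha, 0, 1, "alpha")
  chk(lambda, 0, 5, "lambda"); chk(k, 0, 1, "k")
  chk(w, 0, 1, "w"); chk(c, 0, 5, "c")
  structure(x, class = "vpp_params")
}

# bounds of the bounded parameters, canonical order
.vpp_bounds <- list(
  phi = c(0, 1), alpha = c(0, 1), lambda = c(0, 5),
  eps_pos = NULL, eps_neg = NULL,
  k = c(0, 1), w = c(0, 1), c = c(0, 5)
)
.vpp_names <- names(.vpp_bounds)

as_vpp_params <- function(x) {
  if (inherits(x, "vpp_params")) return(x)
  x <- unlist(x)[.vpp_names]
  do.call(vpp_params, as.list(x))
}

#' Outcome utility under prospect-style valuation
#'
#' `u = net^alpha` for net gains (net >= 0) and `u = -lambda * |net|^alpha`
#' for net losses.  Higher `alpha` means stronger sensitivity to outcome
#' magnitude; `lambda` scales losses relative to gains.
#'
#' @param net signed net outcome in apples (vectorised).
#' @param alpha feedback sensitivity.
#' @param lambda loss aversion.
#' @return numeric utility.
#' @export
utility <- function(net, alpha, lambda) {
  ifelse(net >= 0, abs(net)^alpha, -lambda * abs(net)^alpha)
}

#' Delta-rule update of a door's expected value
#'
#' `ev_new = ev_old + phi * (u - ev_old)`.  With `phi = 1` the EV equals the
#' latest utility; with `phi = 0` it is not updated.  Only the chosen
#' door's EV is updated on a trial.
#'
#' @param ev_old previous expected value.
#' @param u the trial's utility.
#' @param phi updating rate.
#' @return updated expected value.
#' @export
ev_update <- function(ev_old, u, phi) {
  ev_old + phi * (u - ev_old)
}

#' Perseveration-strength update
#'
#' All doors' perseveration strengths first decay by the factor `k`
#' (`k = 1` no decay, `k = 0` complete decay); the chosen door is then
#' incremented by `eps_pos` if the net outcome was a gain (net >= 0) or by
#' `eps_neg` if it was a loss (net < 0).
#'
#' @param P numeric vector of 4 per-door perseveration strengths (A-D).
#' @param chosen door id.
#' @param net signed net outcome of the trial.
#' @param eps_pos,eps_neg perseveration increments after gain / loss.
#' @param k decay factor.
#' @return updated length-4 vector.
#' @export
pers_update <- function(P, chosen, net, eps_pos, eps_neg, k) {
  stopifnot(length(P) == 4L)
  j <- door_index(chosen)
  P <- k * P
  P[j] <- P[j] + if (net >= 0) eps_pos else eps_neg
  P
}

#' Overall door values
#'
#' Weighted average of the EV and perseveration terms,
#' `V = w * EV + (1 - w) * P`.
#'
#' @param EV,P numeric vectors of 4 per-door values.
#' @param w expectancy weight in \[0, 1\].
#' @return length-4 numeric vector.
#' @export
overall_value <- function(EV, P, w) {
  stopifnot(length(EV) == 4L, length(P) == 4L)
  w * EV + (1 - w) * P
}

#' Softmax choice probabilities
#'
#' `p_j = exp(theta * V_j) / sum_m exp(theta * V_m)` with sensitivity
#' `theta = 3^c - 1`, computed with a log-sum-exp shift so large values do
#' not overflow.  `c = 0` gives uniform choice over the four doors.
#'
#' @param V length-4 vector of overall door values.
#' @param c response consistency in \[0, 5\].
#' @return length-4 probability vector summing to 1.
#' @export
choice_probs <- function(V, c) {
  stopifnot(length(V) == 4L)
  theta <- 3^c - 1
  z <- theta * V
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Simulate one HDT session from a VPP agent
#'
#' Plays `n_trials` trials: door values are converted to choice
#' probabilities, a door is sampled, the scheduled outcome for that door's
#' current selection count is delivered, and the EV / perseveration states
#' are updated with the observed net outcome.  The summed log-probability of
#' the realised choices is attached as attribute `"log_prob"`, which must
#' equal [sequence_loglik()] on the generated session.
#'
#' @param params a [vpp_params()] object (or coercible named vector).
#' @param schedule an [canonical_schedule()] payoff schedule.
#' @param n_trials number of trials (the study protocol uses 200).
#' @param seed integer seed; the session is reproducible given
#'   (params, schedule, n_trials, seed).
#' @param subject_id identifier stored in the output.
#' @return trials data.frame (`subject_id`, `trial`, `door`, `gain`,
#'   `loss`, `net`) with attribute `log_prob`.
#' @export
simulate_session <- function(params, schedule = canonical_schedule(),
                             n_trials = 200L, seed = 1L,
                             subject_id = "S1") {
  params <- as_vpp_params(params)
  stopifnot(n_trials >= 1L)
  p <- as.list(unclass(params))
  ev <- numeric(4L); pers <- numeric(4L)
  nsel <- integer(4L)
  door <- integer(n_trials); gain <- integer(n_trials)
  loss <- integer(n_trials)
  logp <- 0
  with_seed(seed, {
    for (t in seq_len(n_trials)) {
      pr <- choice_probs(overall_value(ev, pers, p$w), p$c)
      j <- sample.int(4L, 1L, prob = pr)
      logp <- logp + log(pr[j])
      nsel[j] <- nsel[j] + 1L
      pos <- ((nsel[j] - 1L) %% 10L) + 1L
      g <- schedule$gains[[j]]; l <- schedule$losses[j, pos]
      door[t] <- j; gain[t] <- g; loss[t] <- l
      x <- g - l
      u <- utility(x, p$alpha, p$lambda)
      ev[j] <- ev_update(ev[j], u, p$phi)
      pers <- pers * p$k
      pers[j] <- pers[j] + if (x >= 0) p$eps_pos else p$eps_neg
    }
  })
  out <- data.frame(subject_id = subject_id, trial = seq_len(n_trials),
                    door = DOORS[door], gain = gain, loss = loss,
                    net = gain - loss, stringsAsFactors = FALSE)
  attr(out, "log_prob") <- logp
  out
}

#' Log-likelihood of a choice sequence under the VPP model
#'
#' Forward rollout: for each trial the log-probability of the recorded
#' choice given the state before the trial is accumulated, then the state is
#' updated using that trial's recorded net outcome.  EV and perseveration
#' strengths start at 0 for all doors.  The inner loop runs in compiled
#' code.
#'
#' @param params a [vpp_params()] object.
#' @param trials a trials data.frame with `trial`, `door`, `net` columns.
#' @return scalar log-likelihood.
#' @export
sequence_loglik <- function(params, trials) {
  params <- as_vpp_params(params)
  trials <- trials[order(trials$trial), , drop = FALSE]
  ll <- vpp_loglik_cpp(door_index(trials$door), as.numeric(trials$net),
                       params[["phi"]], params[["alpha"]],
                       params[["lambda"]], params[["eps_pos"]],
                       params[["eps_neg"]], params[["k"]],
                       params[["w"]], params[["c"]])
  if (!is.finite(ll)) {
    stop(sprintf(
      "non-finite log-likelihood (%s) for params [%s] on %d trials",
      ll, paste(signif(unclass(params), 4), collapse = ", "), nrow(trials)))
  }
  ll
}

#' Map VPP parameters to and from an unconstrained vector
#'
#' Bounded parameters are mapped by a scaled logit onto the real line
#' (`z = logit((x - lo) / (hi - lo))`); `eps_pos` and `eps_neg` pass through
#' unchanged.  The map is a bijection between the open parameter box and
#' R^8 and round-trips to better than 1e-10; boundary values are rejected.
#' The zero vector maps back to the box midpoints
#' (phi = alpha = k = w = 0.5, lambda = c = 2.5, eps = 0).
#'
#' @param params a [vpp_params()] object with strictly interior bounded
#'   fields.
#' @return `to_unconstrained`: named numeric vector of length 8.
#' @export
to_unconstrained <- function(params) {
  params <- as_vpp_params(params)
  z <- vapply(.vpp_names, function(nm) {
    b <- .vpp_bounds[[nm]]
    x <- params[[nm]]
    if (is.null(b)) return(x)
    if (x <= b[1] || x >= b[2]) {
      stop(sprintf("%s = %g is on/outside its open interval (%g, %g)",
                   nm, x, b[1], b[2]))
    }
    qlogis((x - b[1]) / (b[2] - b[1]))
  }, numeric(1))
  names(z) <- .vpp_names
  z
}

#' @param z unconstrained numeric vector of length 8 (canonical order).
#' @return `from_unconstrained`: a [vpp_params()] object.
#' @rdname to_unconstrained
#' @export
from_unconstrained <- function(z) {
  stopifnot(length(z) == 8L)
  x <- vapply(seq_along(.vpp_names), function(i) {
    b <- .vpp_bounds[[i]]
    if (is.null(b)) z[[i]] else b[1] + (b[2] - b[1]) * plogis(z[[i]])
  }, numeric(1))
  names(x) <- .vpp_names
  do.call(vpp_params, as.list(x))
}

#' Read and write VPP parameter tables
#'
#' One row per subject, columns `subject_id, phi, alpha, lambda, eps_pos,
#' eps_neg, k, w, c`.
#'
#' @param params a parameter data.frame.
#' @param path file path.
#' @export
write_params <- function(params, path) {
  stopifnot(all(c("subject_id", .vpp_names) %in% names(params)))
  write.csv(params, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  p <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", .vpp_names) %in% names(p))) {
    stop("parameter file must have columns: subject_id, ",
         paste(.vpp_names, collapse = ", "))
  }
  p
}
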