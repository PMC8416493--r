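# Independent brute-force oracles used across test files.  These stay
# deliberately naive (explicit loops, no shared code with the package
# internals beyond the public API's data layout).

# win-stay / lose-shift by materialising every (t-1, t) transition pair
oracle_transition_metrics <- function(door, net) {
  stay_w <- tot_w <- shift_l <- tot_l <- 0
  for (t in 2:length(door)) {
    if (net[t - 1] >= 0) {
      tot_w <- tot_w + 1
      if (door[t] == door[t - 1]) stay_w <- stay_w + 1
    } else {
      tot_l <- tot_l + 1
      if (door[t] != door[t - 1]) shift_l <- shift_l + 1
    }
  }
  list(win_stay = if (tot_w == 0) NA_real_ else stay_w / tot_w,
       lose_shift = if (tot_l == 0) NA_real_ else shift_l / tot_l)
}

# Mann-Whitney U by exhaustive pair comparison, ties scoring 1/2
oracle_u <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) {
    u <- u + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  u
}

# Benjamini-Hochberg step-up from the definition:
# adj_i = min over j with p_j >= p_i of (m * p_j / rank_j), capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  r <- rank(p, ties.method = "first")
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- m * p[o] / seq_len(m)
    adj[o[i]] <- min(1, min(cand[i:m]))
  }
  adj
}

# a random trial table (not via simulate_session, so metric tests do not
# depend on the model code)
random_session <- function(n, seed) {
  set.seed(seed)
  door <- sample(c("A", "B", "C", "D"), n, replace = TRUE)
  net <- sample(c(-46L, -8L, -6L, -1L, 0L, 2L, 4L), n, replace = TRUE)
  gain <- pmax(net, 0L)
  data.frame(subject_id = "X", trial = seq_len(n), door = door,
             gain = gain, loss = gain - net, net = net,
             stringsAsFactors = FALSE)
}
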