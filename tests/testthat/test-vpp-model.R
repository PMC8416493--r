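test_that("outcome utility follows the prospect-style valuation", {
  expect_equal(utility(0, 0.37, 4.2), 0)
  expect_equal(utility(4, 1, 99), 4)
  expect_equal(utility(-4, 1, 2), -8)
  expect_equal(utility(9, 0.5, 1), 3)
  expect_equal(utility(-9, 0.5, 2), -6)
})

test_that("EV updating interpolates between no update and full update", {
  expect_equal(ev_update(7, 4, 1), 4)   # full update: EV = utility
  expect_equal(ev_update(7, 4, 0), 7)   # no update
  expect_equal(ev_update(2, 4, 0.5), 3)
})

test_that("perseveration decays all doors then increments the chosen one", {
  expect_equal(pers_update(c(0, 0, 0, 0), "A", 4, 1, -1, k = 1),
               c(1, 0, 0, 0))
  expect_equal(pers_update(c(5, 5, 5, 5), "B", -46, 1, -1, k = 0),
               c(0, -1, 0, 0))
  expect_equal(pers_update(c(2, 0, 0, 0), "A", 4, 1, -1, k = 0.5),
               c(2, 0, 0, 0))
  # net = 0 counts as a gain
  expect_equal(pers_update(c(0, 0, 0, 0), "C", 0, 3, -7, k = 1),
               c(0, 0, 3, 0))
  expect_error(pers_update(c(0, 0, 0, 0), "Z", 0, 1, -1, 1), "unknown door")
})

test_that("overall value mixes EV and perseveration by w", {
  EV <- c(2, -1, 0.5, 0); P <- c(1, 3, -2, 0)
  expect_equal(overall_value(EV, P, 1), EV)
  expect_equal(overall_value(EV, P, 0), P)
  expect_equal(overall_value(EV, P, 0.5)[1], 1.5)
})

test_that("softmax choice rule has sensitivity 3^c - 1", {
  expect_equal(choice_probs(c(9, -4, 0, 2), 0), rep(0.25, 4))
  expect_equal(choice_probs(rep(1.7, 4), 3.1), rep(0.25, 4))
  # theta = 1 at c = log_3(2): p_A = e^1.5 / (e^1.5 + 3)
  pA <- choice_probs(c(1.5, 0, 0, 0), log(2) / log(3))[1]
  expect_equal(pA, exp(1.5) / (exp(1.5) + 3), tolerance = 1e-12)
  expect_equal(round(pA, 3), 0.599)
  # probabilities sum to 1 and are shift-invariant
  set.seed(42)
  for (i in 1:25) {
    V <- rnorm(4, sd = 5); cc <- runif(1, 0, 5)
    p <- choice_probs(V, cc)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(choice_probs(V + rnorm(1), cc), p, tolerance = 1e-10)
  }
})

test_that("session simulation is seeded and uniform when c = 0", {
  p <- vpp_params(0.3, 0.5, 1, 2, -6, 0.5, 0.8, 1)
  s1 <- simulate_session(p, n_trials = 100, seed = 9)
  s2 <- simulate_session(p, n_trials = 100, seed = 9)
  expect_identical(s1, s2)
  expect_false(identical(simulate_session(p, n_trials = 100, seed = 10), s1))
  # random chooser: door frequencies ~ 0.25 over 10,000 trials
  p0 <- vpp_params(0.3, 0.5, 1, 2, -6, 0.5, 0.8, 0)
  s <- simulate_session(p0, n_trials = 10000, seed = 1)
  freq <- table(factor(s$door, c("A", "B", "C", "D"))) / 10000
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("sequence log-likelihood matches hand-rolled forward rollouts", {
  # two-trial oracle: ln 0.25 + ln(e^1.5 / (e^1.5 + 3))
  p <- vpp_params(phi = 0.5, alpha = 1, lambda = 1, eps_pos = 1,
                  eps_neg = -1, k = 1, w = 0.5, c = log(2) / log(3))
  tr <- data.frame(trial = 1:2, door = c("A", "A"), net = c(4, 4))
  expect_equal(sequence_loglik(p, tr),
               log(0.25) + log(exp(1.5) / (exp(1.5) + 3)),
               tolerance = 1e-10)
  # single trial from fresh state: ln 0.25
  expect_equal(sequence_loglik(p, tr[1, ]), log(0.25), tolerance = 1e-12)
  # c = 0 closed form: n * ln(1/4) for any data
  s <- random_session(200, seed = 77)
  p0 <- vpp_params(0.9, 0.1, 4, 10, -10, 0.2, 0.1, 0)
  expect_equal(sequence_loglik(p0, s), 200 * log(0.25), tolerance = 1e-12)
  # unordered input is sorted by trial index
  shuf <- tr[2:1, ]
  expect_equal(sequence_loglik(p, shuf), sequence_loglik(p, tr))
})

test_that("likelihood of a simulated session equals the simulator's own log-probs", {
  set.seed(5)
  for (i in 1:8) {
    p <- vpp_params(runif(1, .05, .95), runif(1, .05, .95), runif(1, .1, 4),
                    rnorm(1, 0, 4), rnorm(1, -6, 2), runif(1, .05, .95),
                    runif(1, .05, .95), runif(1, 0.2, 2))
    s <- simulate_session(p, n_trials = 150, seed = 1000 + i)
    expect_equal(sequence_loglik(p, s), attr(s, "log_prob"),
                 tolerance = 1e-10)
  }
})

test_that("larger gain-perseveration strictly raises the repeat probability", {
  # one rewarded choice of door A, then probability of repeating A
  repeat_prob <- function(eps_pos) {
    P <- pers_update(rep(0, 4), "A", net = 4, eps_pos, -1, k = 1)
    EV <- c(ev_update(0, utility(4, 0.5, 1), 0.3), 0, 0, 0)
    choice_probs(overall_value(EV, P, w = 0.5), c = 1)[1]
  }
  probs <- vapply(c(0.5, 1, 2, 4, 8), repeat_prob, numeric(1))
  expect_true(all(diff(probs) > 0))
})

test_that("unconstrained transform is a bijection of the parameter box", {
  # zero vector maps to the box midpoints
  mid <- from_unconstrained(rep(0, 8))
  expect_equal(unclass(mid),
               c(phi = 0.5, alpha = 0.5, lambda = 2.5, eps_pos = 0,
                 eps_neg = 0, k = 0.5, w = 0.5, c = 2.5))
  expect_equal(unname(to_unconstrained(mid)), rep(0, 8), tolerance = 1e-12)
  # round trips on random interior points
  set.seed(11)
  for (i in 1:20) {
    z <- rnorm(8, 0, 3)
    expect_equal(unname(to_unconstrained(from_unconstrained(z))), z,
                 tolerance = 1e-10)
  }
  # boundaries rejected
  expect_error(to_unconstrained(vpp_params(0, .5, 1, 0, 0, .5, .5, 1)),
               "open interval")
  expect_error(vpp_params(1.2, .5, 1, 0, 0, .5, .5, 1), "outside")
})
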