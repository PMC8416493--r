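# shared fixture: a synthetic cohort on the analysis scale
make_cohort <- function(n = 70, seed = 1) {
  pars <- draw_params(n, seed = seed)
  ph <- simulate_phenotypes(pars, seed = seed + 1)
  merge(pars, ph, by = "subject_id")
}

test_that("model specs enforce recursiveness", {
  expect_error(path_model_spec("intake_eah_kcal", c("eps_pos", "bmi_z")),
               "recursiveness")
  expect_error(path_model_spec("bmi_z", "eps_pos"), "recursiveness")
  expect_error(path_model_spec("intake_eah_kcal", "eps_pos",
                               covariates = "intake_eah_kcal"),
               "cannot predict itself")
  expect_error(path_model_spec("intake_eah_kcal", c("eps_pos", "k"),
                               interactions = list(c("k", "age"))),
               "pair of declared predictors")
})

test_that("preprocessing applies the analysis-scale transforms", {
  d <- make_cohort(50, seed = 2)
  spec <- path_model_spec("intake_standard_kcal",
                          c("lambda", "eps_pos", "k"),
                          interactions = list(c("k", "eps_pos")))
  mm <- preprocess(d, spec)
  # z-scoring: mean 0, SD 1 to machine precision
  for (v in c("lambda", "eps_pos", "k")) {
    expect_lt(abs(mean(mm[[v]])), 1e-12)
    expect_equal(sd(mm[[v]]), 1, tolerance = 1e-12)
  }
  # lambda standardised on the log scale: {e, e^2, e^3} -> z of {1,2,3}
  d2 <- d
  d2$lambda <- rep(exp(1:3), length.out = nrow(d))
  mm2 <- preprocess(d2, spec)
  expect_equal(mm2$lambda,
               as.numeric(scale(rep(1:3, length.out = nrow(d)))),
               tolerance = 1e-12)
  # intake on the kcal/100 scale: 643.9 kcal -> 6.439
  d3 <- d
  d3$intake_standard_kcal[1] <- 643.9
  expect_equal(preprocess(d3, spec)$intake_standard_kcal[1], 6.439)
  # interaction is the product of the standardised components
  expect_equal(mm$k_x_eps_pos, mm$k * mm$eps_pos)
  # listwise deletion with a message; zero variance is an error
  d4 <- d; d4$eps_pos[3] <- NA
  expect_message(mm4 <- preprocess(d4, spec), "listwise deletion")
  expect_equal(nrow(mm4), nrow(d) - 1)
  d5 <- d; d5$k <- 1e-6
  expect_error(preprocess(d5, spec), "zero-variance column: k")
})

test_that("normality screen computes moment skewness and excess kurtosis", {
  # symmetric two-point variable: skew 0, excess kurtosis -2, unflagged
  x <- rep(c(-1, 1), 50)
  ns <- normality_screen(x)
  expect_equal(ns$skewness, 0)
  expect_equal(ns$kurtosis, -2)
  expect_false(ns$flag)
  # large normal sample: unflagged
  set.seed(8)
  expect_false(normality_screen(rnorm(1e5))$flag)
  # heavy right-skewed sample (like raw loss aversion): flagged;
  # log transform removes the flag
  y <- rlnorm(5000, 0, 1.5)
  expect_true(normality_screen(y)$flag)
  expect_false(normality_screen(log(y))$flag)
  expect_error(normality_screen(rep(3, 10)), "constant")
  expect_error(normality_screen(c(1, 2, 3)), "at least 4")
})

test_that("noise-free data reproduce generating coefficients exactly", {
  set.seed(31)
  n <- 80
  d <- data.frame(subject_id = 1:n, eps_pos = rnorm(n, 2, 3),
                  k = runif(n))
  zx <- as.numeric(scale(d$eps_pos)); zk <- as.numeric(scale(d$k))
  d$intake_standard_kcal <- 100 * (6.4 + 0.88 * zx - 0.12 * zk)
  d$bmi_z <- 0.15 * d$intake_standard_kcal / 100 - 0.3
  spec <- path_model_spec("intake_standard_kcal", c("eps_pos", "k"))
  mm <- preprocess(d, spec)
  fit <- fit_path_model(mm, spec)
  co <- fit$coefficients
  g <- function(eq, tm) co$estimate[co$equation == eq & co$term == tm]
  expect_equal(g("intake_standard_kcal", "eps_pos"), 0.88,
               tolerance = 1e-10)
  expect_equal(g("intake_standard_kcal", "k"), -0.12, tolerance = 1e-10)
  expect_equal(g("bmi_z", "intake_standard_kcal"), 0.15, tolerance = 1e-10)
  expect_equal(unname(fit$r2), c(1, 1), tolerance = 1e-10)
})

test_that("the intake -> BMI-z path equals the simple regression", {
  d <- make_cohort(70, seed = 3)
  spec <- path_model_spec("intake_eah_kcal", c("eps_pos", "k", "eps_neg"),
                          interactions = list(c("k", "eps_neg")))
  mm <- preprocess(d, spec)
  fit <- fit_path_model(mm, spec)
  b_path <- fit$coefficients$estimate[
    fit$coefficients$equation == "bmi_z" &
      fit$coefficients$term == "intake_eah_kcal"]
  simple <- coef(lm(bmi_z ~ intake_eah_kcal, data = mm))[[2]]
  expect_equal(b_path, simple, tolerance = 1e-12)
})

test_that("indirect effects are exact coefficient products with Sobel SEs", {
  # printed-coefficient arithmetic through a minimal fit container
  fake <- structure(list(coefficients = data.frame(
    equation = c("intake", "intake", "bmi_z"),
    term = c("eps_pos", "k", "intake"),
    estimate = c(0.88, -0.12, 0.15), se = c(0.20, 0.22, 0.04),
    p = NA, stringsAsFactors = FALSE)), class = "path_fit")
  ie <- indirect_effect(fake, c("eps_pos", "intake"), c("intake", "bmi_z"))
  expect_equal(ie$estimate, 0.132)
  expect_equal(ie$se, sqrt(0.88^2 * 0.04^2 + 0.15^2 * 0.20^2))
  # b = 0: estimate 0, SE = |a| * SE_b
  fake0 <- fake
  fake0$coefficients$estimate[3] <- 0
  ie0 <- indirect_effect(fake0, c("eps_pos", "intake"),
                         c("intake", "bmi_z"))
  expect_equal(ie0$estimate, 0)
  expect_equal(ie0$se, 0.88 * 0.04)
  expect_error(indirect_effect(fake, c("w", "intake"),
                               c("intake", "bmi_z")), "no path")
  # identity on a real fit: estimate == product of the stored coefficients
  d <- make_cohort(70, seed = 4)
  spec <- path_model_spec("intake_standard_kcal", c("eps_pos", "k"))
  fit <- fit_path_model(preprocess(d, spec), spec)
  co <- fit$coefficients
  a <- co$estimate[co$term == "eps_pos"]
  b <- co$estimate[co$equation == "bmi_z" &
                     co$term == "intake_standard_kcal"]
  ie2 <- indirect_effect(fit, c("eps_pos", "intake_standard_kcal"),
                         c("intake_standard_kcal", "bmi_z"))
  expect_identical(ie2$estimate, a * b)
})

test_that("simple slopes probe a fitted moderation", {
  d <- make_cohort(120, seed = 5)
  spec <- path_model_spec("intake_eah_kcal", c("eps_pos", "k", "eps_neg"),
                          interactions = list(c("k", "eps_neg")))
  mm <- preprocess(d, spec)
  fit <- fit_path_model(mm, spec)
  co <- fit$coefficients
  b_f <- co$estimate[co$term == "eps_neg" & co$equation == "intake_eah_kcal"]
  b_i <- co$estimate[co$term == "k_x_eps_neg"]
  probe <- moderation_probe(fit, focal = "eps_neg", moderator = "k",
                            levels = c(-1, 0, 1))
  expect_equal(probe$slope, b_f + b_i * c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(probe$slope[2], b_f)
  expect_true(all(probe$se > 0))
  # printed-coefficient arithmetic: -0.45 + 0.89 * 1 = 0.44
  expect_equal(-0.45 + 0.89 * 1, 0.44)
  # slope sign flips across moderator levels when the interaction
  # dominates an opposite-signed focal effect
  expect_true(sign(-0.45 + 0.89 * -1) != sign(-0.45 + 0.89 * 1))
  expect_error(moderation_probe(fit, "eps_pos", "k"), "no .* interaction")
})

test_that("fit indices approach their ideals when the model is true", {
  d <- make_cohort(10000, seed = 6)
  spec <- path_model_spec("intake_standard_kcal", c("eps_pos", "k"))
  mm <- preprocess(d, spec)
  fit <- suppressWarnings(fit_path_model(mm, spec))
  ix <- fit_indices(fit, mm)
  expect_equal(ix$df, 2)
  expect_lt(ix$rmsea, 0.02)
  expect_gt(ix$cfi, 0.99)
  expect_lt(ix$srmr, 0.02)
  expect_true(ix$cfi >= 0 && ix$cfi <= 1)
  # fully independent data: indices stay defined and bounded
  set.seed(9)
  ind <- data.frame(eps_pos = rnorm(500), k = rnorm(500),
                    intake_standard_kcal = 100 * rnorm(500, 6, 2),
                    bmi_z = rnorm(500))
  mmi <- preprocess(ind, spec)
  fiti <- fit_path_model(mmi, spec)
  ixi <- fit_indices(fiti, mmi)
  expect_true(is.finite(ixi$T) && ixi$cfi >= 0 && ixi$cfi <= 1)
})

test_that("small samples trigger the 10:1 free-parameter warning", {
  d <- make_cohort(40, seed = 7)
  spec <- path_model_spec("intake_eah_kcal", c("eps_pos", "k", "eps_neg"),
                          interactions = list(c("k", "eps_neg")))
  mm <- preprocess(d, spec)
  expect_warning(fit_path_model(mm, spec), "below 10:1")
  # rank deficiency is reported with the offending columns
  d2 <- make_cohort(40, seed = 8)
  d2$k <- d2$eps_pos  # perfectly collinear after standardisation
  spec2 <- path_model_spec("intake_standard_kcal", c("eps_pos", "k"))
  expect_error(suppressWarnings(
    fit_path_model(preprocess(d2, spec2), spec2)), "collinear")
})

test_that("bootstrap intervals are seeded and collapse under zero noise", {
  set.seed(41)
  n <- 60
  d <- data.frame(subject_id = 1:n, eps_pos = rnorm(n), k = runif(n))
  zx <- as.numeric(scale(d$eps_pos)); zk <- as.numeric(scale(d$k))
  d$intake_standard_kcal <- 100 * (6.4 + 0.88 * zx - 0.12 * zk)
  d$bmi_z <- 0.15 * d$intake_standard_kcal / 100
  spec <- path_model_spec("intake_standard_kcal", c("eps_pos", "k"))
  mm <- preprocess(d, spec)
  bt <- suppressWarnings(bootstrap_uncertainty(mm, spec, B = 250, seed = 1))
  expect_lt(max(bt$coef_ci$upper - bt$coef_ci$lower), 1e-8)
  expect_lt(max(bt$indirect_ci$upper - bt$indirect_ci$lower), 1e-8)
  bt2 <- suppressWarnings(bootstrap_uncertainty(mm, spec, B = 250, seed = 1))
  expect_identical(bt$coef_ci, bt2$coef_ci)
  expect_error(bootstrap_uncertainty(mm, spec, B = 50, seed = 1), "B >= 200")
})
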