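#' Specification of a recursive intake -> BMI-z path model
#'
#' Each model is a two-equation recursive system: laboratory intake
#' regressed on a set of (standardised) decision parameters, optional
#' parameter-by-parameter interactions and optional covariates; and BMI-z
#' regressed on intake alone.  Because the system is recursive with
#' uncorrelated errors, equation-wise least squares is the maximum-
#' likelihood estimator.  BMI-z may not appear as a predictor anywhere
#' (recursiveness), and intake is its sole structural predictor.
#'
#' @param intake_var name of the intake column (kcal; scaled to kcal/100 by
#'   [preprocess()]).
#' @param predictors character vector of parameter columns predicting
#'   intake.
#' @param interactions `NULL`, or a list of ordered character pairs, each a
#'   subset of `predictors`; the product of the standardised components is
#'   added as a predictor of intake.
#' @param covariates optional additional intake predictors (kept on their
#'   raw scale, e.g. age in years or pre-meal fullness in mm).
#' @param bmiz_var name of the BMI-z column.
#' @param log_vars columns replaced by their natural log before
#'   standardisation (default the strongly right-skewed loss-aversion
#'   parameter).
#' @return object of class `path_model_spec`.
#' @export
path_model_spec <- function(intake_var, predictors, interactions = NULL,
                            covariates = character(),
                            bmiz_var = "bmi_z", log_vars = "lambda") {
  stopifnot(is.character(intake_var), length(intake_var) == 1L,
            is.character(predictors), length(predictors) >= 1L)
  if (bmiz_var %in% c(predictors, covariates, intake_var)) {
    stop("recursiveness violated: '", bmiz_var,
         "' cannot predict intake or coincide with it; BMI-z is ",
         "endogenous with intake as its sole predictor")
  }
  if (intake_var %in% c(predictors, covariates)) {
    stop("'", intake_var, "' cannot predict itself")
  }
  if (!is.null(interactions)) {
    if (!is.list(interactions)) interactions <- list(interactions)
    for (pr in interactions) {
      if (length(pr) != 2L || !all(pr %in% predictors)) {
        stop("each interaction must be a pair of declared predictors")
      }
    }
  }
  structure(list(intake_var = intake_var, predictors = predictors,
                 interactions = interactions, covariates = covariates,
                 bmiz_var = bmiz_var, log_vars = log_vars),
            class = "path_model_spec")
}

.interaction_name <- function(pr) paste0(pr[1], "_x_", pr[2])

.exog_terms <- function(spec) {
  c(spec$predictors,
    vapply(spec$interactions %||% list(), .interaction_name, character(1)),
    spec$covariates)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the analysis matrix for a path model
#'
#' Applies the analysis-scale transforms: listwise deletion on the used
#' columns, natural-log transform of `log_vars`, z-scoring of every
#' parameter predictor on the analysis sample (mean 0, SD 1), division of
#' intake by 100 (kcal -> kcal/100), and construction of interaction
#' columns as products of the already-standardised components (the product
#' is not re-standardised).  Covariates and BMI-z pass through unchanged.
#'
#' @param data data.frame holding the phenotype and parameter columns.
#' @param spec a [path_model_spec()].
#' @return data.frame with columns: standardised predictors, interaction
#'   columns, covariates, scaled intake and BMI-z.
#' @export
preprocess <- function(data, spec) {
  stopifnot(inherits(spec, "path_model_spec"))
  used <- c(spec$predictors, spec$covariates, spec$intake_var,
            spec$bmiz_var)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  keep <- complete.cases(data[used])
  if (!all(keep)) {
    message("preprocess: listwise deletion removed ", sum(!keep),
            " of ", length(keep), " rows with missing values")
  }
  d <- data[keep, used, drop = FALSE]
  for (v in intersect(spec$log_vars, spec$predictors)) {
    if (any(d[[v]] <= 0)) stop("log transform of '", v,
                               "' requires positive values")
    d[[v]] <- log(d[[v]])
  }
  for (v in c(spec$predictors, spec$intake_var, spec$bmiz_var)) {
    if (sd(d[[v]]) == 0) stop("zero-variance column: ", v)
  }
  for (v in spec$predictors) {
    d[[v]] <- (d[[v]] - mean(d[[v]])) / sd(d[[v]])
  }
  d[[spec$intake_var]] <- d[[spec$intake_var]] / 100
  for (pr in spec$interactions %||% list()) {
    d[[.interaction_name(pr)]] <- d[[pr[1]]] * d[[pr[2]]]
  }
  d[, c(.exog_terms(spec), spec$intake_var, spec$bmiz_var), drop = FALSE]
}

#' Fit a recursive path model by equation-wise least squares
#'
#' Fits `intake ~ predictors (+ interactions + covariates)` and
#' `BMI-z ~ intake` by ordinary least squares, which is the ML estimator
#' for this recursive system with uncorrelated errors.  Reports
#' unstandardised coefficients, conventional standard errors, p-values and
#' R-squared per equation.  Because BMI-z has intake as its only
#' predictor, its path coefficient equals the simple regression of BMI-z
#' on intake.  A warning is issued when the sample-size to free-parameter
#' ratio falls below the conventional 10:1 floor (free parameters counted
#' as structural path coefficients plus the two residual variances).
#'
#' @param mm analysis matrix from [preprocess()].
#' @param spec the [path_model_spec()].
#' @return object of class `path_fit`: list with `coefficients`
#'   (data.frame: equation, term, estimate, se, p), `r2`, `n`, `spec`,
#'   the two `lm` fits, and ML residual variances `psi`.
#' @export
fit_path_model <- function(mm, spec) {
  stopifnot(inherits(spec, "path_model_spec"))
  exog <- .exog_terms(spec)
  n <- nrow(mm)
  if (n <= length(exog) + 2L) {
    stop("need n > number of predictors + 2 (n = ", n, ")")
  }
  f1 <- stats::as.formula(paste0("`", spec$intake_var, "` ~ ",
                                 paste0("`", exog, "`", collapse = " + ")))
  f2 <- stats::as.formula(paste0("`", spec$bmiz_var, "` ~ `",
                                 spec$intake_var, "`"))
  m1 <- lm(f1, data = mm)
  m2 <- lm(f2, data = mm)
  if (anyNA(coef(m1))) {
    bad <- names(coef(m1))[is.na(coef(m1))]
    stop("rank-deficient design; collinear columns: ",
         paste(gsub("`", "", bad), collapse = ", "))
  }
  tidy_eq <- function(m, endo) {
    s <- summary(m)$coefficients
    data.frame(equation = endo,
               term = gsub("`", "", rownames(s)),
               estimate = s[, 1], se = s[, 2], p = s[, 4],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  coefs <- rbind(tidy_eq(m1, spec$intake_var), tidy_eq(m2, spec$bmiz_var))
  r2 <- c(summary(m1)$r.squared, summary(m2)$r.squared)
  names(r2) <- c(spec$intake_var, spec$bmiz_var)
  free <- (length(exog) + 1L) + 2L  # structural paths + residual variances
  if (n / free < 10) {
    warning(sprintf(
      "sample-size to free-parameter ratio %.1f:1 is below 10:1", n / free))
  }
  structure(list(coefficients = coefs, r2 = r2, n = n, spec = spec,
                 lm_intake = m1, lm_bmiz = m2,
                 psi = c(intake = mean(residuals(m1)^2),
                         bmiz = mean(residuals(m2)^2))),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("Recursive path model (n = %d)\n", x$n))
  out <- x$coefficients
  out$estimate <- round(out$estimate, 3)
  out$se <- round(out$se, 3)
  out$p <- signif(out$p, 3)
  print(out, row.names = FALSE)
  cat("R-squared:", paste(sprintf("%s = %.3f", names(x$r2), x$r2),
                          collapse = ", "), "\n")
  invisible(x)
}

.get_coef <- function(fit, edge) {
  co <- fit$coefficients
  hit <- co$equation == edge[2] & co$term == edge[1]
  if (!any(hit)) {
    stop("no path '", edge[1], "' -> '", edge[2], "' in the fitted model")
  }
  co[hit, , drop = FALSE]
}

#' Product-of-coefficients indirect effect
#'
#' The indirect (mediated) effect of a parameter on BMI-z through intake:
#' the product of the a-path (parameter -> intake) and b-path (intake ->
#' BMI-z) coefficients, with the delta-method (Sobel) standard error
#' `sqrt(a^2 SE_b^2 + b^2 SE_a^2)` and a normal-theory p-value.
#'
#' @param fit a [fit_path_model()] result.
#' @param a_path character pair `c(from, to)` for the a-path, e.g.
#'   `c("eps_pos", "intake_standard_kcal")`.
#' @param b_path character pair for the b-path, e.g.
#'   `c("intake_standard_kcal", "bmi_z")`.
#' @return list with `estimate`, `se`, `z`, `p`, and the two path
#'   coefficients `a` and `b`.
#' @export
indirect_effect <- function(fit, a_path, b_path) {
  stopifnot(inherits(fit, "path_fit"))
  arow <- .get_coef(fit, a_path)
  brow <- .get_coef(fit, b_path)
  a <- arow$estimate; b <- brow$estimate
  est <- a * b
  se <- sqrt(a^2 * brow$se^2 + b^2 * arow$se^2)
  z <- if (se > 0) est / se else NA_real_
  list(estimate = est, se = se, z = z,
       p = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)),
       a = a, b = b)
}

#' Simple slopes of a moderated association
#'
#' Probes a fitted interaction: the slope of the focal predictor on intake
#' at chosen moderator values is `B_focal + B_interaction * level`, with
#' delta-method standard errors from the OLS coefficient covariance.
#' Moderator levels are on the moderator's analysis (standardised) scale,
#' so `level = 1` means one SD above the mean.
#'
#' @param fit a [fit_path_model()] result whose spec includes the
#'   focal-by-moderator interaction.
#' @param focal name of the focal predictor.
#' @param moderator name of the moderating predictor.
#' @param levels numeric moderator values (default -1, 0, 1 SD).
#' @return data.frame with `level`, `slope`, `se`, `z`, `p`.
#' @export
moderation_probe <- function(fit, focal, moderator,
                             levels = c(-1, 0, 1)) {
  stopifnot(inherits(fit, "path_fit"))
  inter <- NULL
  for (pr in fit$spec$interactions %||% list()) {
    if (setequal(pr, c(focal, moderator))) inter <- .interaction_name(pr)
  }
  if (is.null(inter)) {
    stop("model has no ", focal, " x ", moderator, " interaction")
  }
  V <- stats::vcov(fit$lm_intake)
  cn <- gsub("`", "", colnames(V))
  i_f <- match(focal, cn); i_i <- match(inter, cn)
  bf <- coef(fit$lm_intake)[[i_f]]; bi <- coef(fit$lm_intake)[[i_i]]
  slope <- bf + bi * levels
  se <- sqrt(V[i_f, i_f] + levels^2 * V[i_i, i_i] +
               2 * levels * V[i_f, i_i])
  z <- slope / se
  data.frame(level = levels, slope = slope, se = se, z = z,
             p = 2 * pnorm(-abs(z)))
}

# Model-implied covariance matrix of (exog, intake, bmiz) given ML
# estimates; exogenous (co)variances are free and set to their sample
# values.
.implied_cov <- function(fit, S) {
  exog <- .exog_terms(fit$spec)
  p <- ncol(S)
  a <- coef(fit$lm_intake)[-1L]
  b <- coef(fit$lm_bmiz)[[2L]]
  Sxx <- S[exog, exog, drop = FALSE]
  sxi <- drop(Sxx %*% a)
  var_i <- drop(crossprod(a, Sxx %*% a)) + fit$psi[["intake"]]
  var_b <- b^2 * var_i + fit$psi[["bmiz"]]
  Sig <- matrix(0, p, p, dimnames = dimnames(S))
  Sig[exog, exog] <- Sxx
  iv <- fit$spec$intake_var; bv <- fit$spec$bmiz_var
  Sig[exog, iv] <- sxi; Sig[iv, exog] <- sxi
  Sig[iv, iv] <- var_i
  Sig[exog, bv] <- b * sxi; Sig[bv, exog] <- b * sxi
  Sig[iv, bv] <- Sig[bv, iv] <- b * var_i
  Sig[bv, bv] <- var_b
  Sig
}

.f_ml <- function(S, Sigma) {
  p <- ncol(S)
  as.numeric(determinant(Sigma, logarithm = TRUE)$modulus -
               determinant(S, logarithm = TRUE)$modulus +
               sum(diag(S %*% solve(Sigma))) - p)
}

#' Covariance-based fit indices for a path model
#'
#' Compares the model-implied covariance matrix of all modelled variables
#' with the sample (ML, denominator n) covariance matrix.  The test
#' statistic is `T = (n - 1) * F_ML`; the degrees of freedom equal the
#' number of omitted direct exogenous -> BMI-z paths.  RMSEA is
#' `sqrt(max(T - df, 0) / (df (n - 1)))`; CFI compares against the
#' independence (diagonal-covariance) baseline; SRMR is the root mean
#' square of the standardised covariance residuals (lower triangle
#' including the diagonal).  Conventional good-fit guides: RMSEA < 0.07,
#' CFI > 0.95, SRMR < 0.08.
#'
#' @param fit a [fit_path_model()] result.
#' @param mm the analysis matrix the model was fitted to.
#' @return list with `T`, `df`, `p_value`, `rmsea`, `cfi`, `srmr`,
#'   `T_baseline`, `df_baseline`.
#' @export
fit_indices <- function(fit, mm) {
  stopifnot(inherits(fit, "path_fit"))
  vars <- c(.exog_terms(fit$spec), fit$spec$intake_var, fit$spec$bmiz_var)
  n <- fit$n
  X <- as.matrix(mm[, vars, drop = FALSE])
  S <- cov(X) * (n - 1) / n
  df <- length(.exog_terms(fit$spec))
  Sig <- .implied_cov(fit, S)
  if (df == 0L) {
    warning("saturated model: indices reported by convention")
    Tstat <- 0
  } else {
    Tstat <- max((n - 1) * .f_ml(S, Sig), 0)
  }
  Sig_b <- diag(diag(S)); dimnames(Sig_b) <- dimnames(S)
  T_b <- (n - 1) * .f_ml(S, Sig_b)
  df_b <- ncol(S) * (ncol(S) - 1) / 2
  rmsea <- if (df > 0) sqrt(max(Tstat - df, 0) / (df * (n - 1))) else 0
  denom <- max(T_b - df_b, Tstat - df, 0)
  cfi <- if (denom == 0) 1 else 1 - max(Tstat - df, 0) / denom
  sdv <- sqrt(diag(S))
  R <- (S - Sig) / tcrossprod(sdv)
  srmr <- sqrt(mean(R[lower.tri(R, diag = TRUE)]^2))
  list(T = Tstat, df = df,
       p_value = if (df > 0) pchisq(Tstat, df, lower.tail = FALSE)
                 else NA_real_,
       rmsea = rmsea, cfi = min(max(cfi, 0), 1), srmr = srmr,
       T_baseline = T_b, df_baseline = df_b)
}

#' Skewness/kurtosis screen for path-analysis variables
#'
#' Moment-based sample skewness and *excess* kurtosis (normal = 0).  A
#' variable is flagged as exceeding acceptable non-normality when
#' |skewness| > 2 or |kurtosis| > 7, the screen used to decide which
#' variables to transform (e.g. log) before path analysis.
#'
#' @param x numeric vector, n >= 4.
#' @return list with `skewness`, `kurtosis` (excess), `flag`.
#' @export
normality_screen <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4L) stop("need at least 4 finite observations")
  m <- mean(x); m2 <- mean((x - m)^2)
  if (m2 == 0) stop("constant column: skewness/kurtosis undefined")
  skew <- mean((x - m)^3) / m2^1.5
  kurt <- mean((x - m)^4) / m2^2 - 3
  list(skewness = skew, kurtosis = kurt,
       flag = abs(skew) > 2 || abs(kurt) > 7)
}

# Fast equation refit on row indices (used by the bootstrap): returns the
# non-intercept coefficients of both equations or NULL if rank deficient.
.refit_coefs <- function(X1, y1, x2, y2, idx) {
  q <- stats::lm.fit(X1[idx, , drop = FALSE], y1[idx])
  if (q$rank < ncol(X1)) return(NULL)
  xi <- x2[idx]
  b <- cov(xi, y2[idx]) / var(xi)
  list(a = q$coefficients[-1L], b = b)
}

#' Bootstrap uncertainty for path coefficients and indirect effects
#'
#' Nonparametric case resampling: subjects are resampled with replacement,
#' both equations are refitted, and 2.5/97.5 percentile intervals are
#' formed for every intake-equation coefficient, the intake -> BMI-z
#' coefficient, and each product-of-coefficients indirect effect.
#' Rank-deficient replicates are dropped and counted.
#'
#' @param mm analysis matrix from [preprocess()].
#' @param spec the [path_model_spec()].
#' @param B number of bootstrap replicates (>= 200).
#' @param seed integer seed (intervals are reproducible).
#' @param conf confidence level.
#' @return list with `coef_ci` (equation, term, estimate, lower, upper),
#'   `indirect_ci` (via each exogenous term), `B`, `n_dropped`, `seed`.
#' @export
bootstrap_uncertainty <- function(mm, spec, B = 1000L, seed = 1L,
                                  conf = 0.95) {
  stopifnot(B >= 200L)
  fit <- fit_path_model(mm, spec)
  exog <- .exog_terms(spec)
  n <- nrow(mm)
  X1 <- cbind(1, as.matrix(mm[, exog, drop = FALSE]))
  y1 <- mm[[spec$intake_var]]
  x2 <- mm[[spec$intake_var]]; y2 <- mm[[spec$bmiz_var]]
  draws <- with_seed(seed, {
    lapply(seq_len(B), function(r) {
      .refit_coefs(X1, y1, x2, y2, sample.int(n, n, replace = TRUE))
    })
  })
  ok <- !vapply(draws, is.null, logical(1))
  A <- do.call(rbind, lapply(draws[ok], function(d) c(d$a, b = d$b)))
  colnames(A) <- c(exog, spec$intake_var)
  alpha <- (1 - conf) / 2
  ci <- apply(A, 2, quantile, probs = c(alpha, 1 - alpha))
  co <- fit$coefficients
  est1 <- co$estimate[co$equation == spec$intake_var &
                        co$term != "(Intercept)"]
  estb <- co$estimate[co$equation == spec$bmiz_var &
                        co$term == spec$intake_var]
  coef_ci <- data.frame(
    equation = c(rep(spec$intake_var, length(exog)), spec$bmiz_var),
    term = c(exog, spec$intake_var),
    estimate = c(est1, estb),
    lower = ci[1, ], upper = ci[2, ], row.names = NULL,
    stringsAsFactors = FALSE)
  ind <- A[, exog, drop = FALSE] * A[, spec$intake_var]
  ici <- apply(ind, 2, quantile, probs = c(alpha, 1 - alpha))
  indirect_ci <- data.frame(
    term = exog, estimate = est1 * estb,
    lower = ici[1, ], upper = ici[2, ], row.names = NULL,
    stringsAsFactors = FALSE)
  list(coef_ci = coef_ci, indirect_ci = indirect_ci, B = B,
       n_dropped = sum(!ok), seed = seed, conf = conf)
}
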