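#' Exclusion filters for phenotype tables
#'
#' Removes subjects per the active criteria and returns an audit log of
#' removals.  Available criteria:
#' * `"noncompliant"` — drop subjects with `compliant == FALSE` (protocol
#'   violations such as not fasting);
#' * `"eah_fullness"` — drop subjects whose pre-EAH fullness was below 75%
#'   of the 150 mm visual-analog scale, i.e. strictly less than 112.5 mm
#'   (a rating of exactly 112.5 mm is retained).
#'
#' @param pheno phenotype data.frame with `compliant` and/or
#'   `fullness_eah_mm` columns as required by the active criteria.
#' @param criteria character vector of active criteria (possibly empty).
#' @return list with `data` (filtered table) and `log` (data.frame:
#'   criterion, n_removed).
#' @export
apply_exclusions <- function(pheno,
                             criteria = c("noncompliant", "eah_fullness")) {
  known <- c("noncompliant", "eah_fullness")
  bad <- setdiff(criteria, known)
  if (length(bad)) stop("unknown criteria: ", paste(bad, collapse = ", "))
  log <- data.frame(criterion = character(0), n_removed = integer(0),
                    stringsAsFactors = FALSE)
  for (cr in criteria) {
    col <- switch(cr, noncompliant = "compliant",
                  eah_fullness = "fullness_eah_mm")
    if (!col %in% names(pheno)) {
      stop("criterion '", cr, "' needs column '", col, "'")
    }
    drop <- switch(cr,
                   noncompliant = !pheno$compliant,
                   eah_fullness = pheno$fullness_eah_mm < 112.5)
    log <- rbind(log, data.frame(criterion = cr, n_removed = sum(drop),
                                 stringsAsFactors = FALSE))
    pheno <- pheno[!drop, , drop = FALSE]
  }
  list(data = pheno, log = log)
}

#' The six final path-model specifications
#'
#' Expected-value (EV) and perseveration models crossed with the three
#' eating paradigms.  EV models predict intake from updating and feedback
#' sensitivity (plus log loss-aversion for the EAH and buffet paradigms);
#' perseveration models predict intake from the gain increment and decay
#' (plus the loss increment for EAH/buffet, and the decay-by-loss
#' interaction for EAH).
#'
#' @param covariates optional named list mapping paradigm
#'   (`standard`/`eah`/`buffet`) to covariate columns added to the intake
#'   equation (used by the covariate sensitivity analysis).
#' @return named list of six [path_model_spec()] objects.
#' @export
default_model_specs <- function(covariates = NULL) {
  cv <- function(paradigm) {
    if (is.null(covariates)) character(0) else
      covariates[[paradigm]] %||% character(0)
  }
  iv <- c(standard = "intake_standard_kcal", eah = "intake_eah_kcal",
          buffet = "intake_buffet_kcal")
  list(
    pers_standard = path_model_spec(iv[["standard"]], c("eps_pos", "k"),
                                    covariates = cv("standard")),
    pers_eah = path_model_spec(iv[["eah"]], c("eps_pos", "k", "eps_neg"),
                               interactions = list(c("k", "eps_neg")),
                               covariates = cv("eah")),
    pers_buffet = path_model_spec(iv[["buffet"]],
                                  c("eps_pos", "k", "eps_neg"),
                                  covariates = cv("buffet")),
    ev_standard = path_model_spec(iv[["standard"]], c("phi", "alpha"),
                                  covariates = cv("standard")),
    ev_eah = path_model_spec(iv[["eah"]], c("phi", "alpha", "lambda"),
                             covariates = cv("eah")),
    ev_buffet = path_model_spec(iv[["buffet"]], c("phi", "alpha", "lambda"),
                                covariates = cv("buffet"))
  )
}

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()].  Unknown fields and
#' unknown model names are rejected.  A single global `seed` controls all
#' randomness: each stage derives a fixed child seed
#' `(seed + stage_index * 104729) mod (2^31 - 1)` so stages are
#' individually reproducible.
#'
#' @param n_subjects cohort size (study cohort: 70).
#' @param n_trials HDT trials per subject (study protocol: 200).
#' @param seed global integer seed.
#' @param fit logical: fit VPP parameters by MAP (`TRUE`) or use the true
#'   generating parameters in downstream analyses (`FALSE`, faster).
#' @param n_starts MAP starts per subject.
#' @param bootstrap_B bootstrap replicates for path-coefficient intervals
#'   (0 disables the bootstrap stage).
#' @param models character vector of model names, a subset of
#'   `names(default_model_specs())`.
#' @param sensitivity logical: also run the covariate-adjusted and
#'   exclusion-filtered variants of each model.
#' @param outdir output directory for CSVs and the summary report, or
#'   `NULL` to skip writing.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 70L, n_trials = 200L, seed = 1L,
                            fit = TRUE, n_starts = 10L, bootstrap_B = 0L,
                            models = names(default_model_specs()),
                            sensitivity = TRUE, outdir = NULL) {
  bad <- setdiff(models, names(default_model_specs()))
  if (length(bad)) {
    stop("unknown model name(s): ", paste(bad, collapse = ", "))
  }
  stopifnot(n_subjects >= 3L, n_trials >= 1L, n_starts >= 1L,
            bootstrap_B == 0L || bootstrap_B >= 200L)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials), seed = as.integer(seed),
                 fit = isTRUE(fit), n_starts = as.integer(n_starts),
                 bootstrap_B = as.integer(bootstrap_B), models = models,
                 sensitivity = isTRUE(sensitivity), outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Fields are validated by [pipeline_config()]; unknown fields are an
#' error.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, cfg)
}

stage_seed <- function(seed, stage) {
  (seed + stage * 104729L) %% 2147483647L
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes, in order: parameter drawing, HDT session simulation, phenotype
#' generation, (optionally) per-subject MAP fitting, behavioural metrics,
#' descriptive statistics (parameter quartiles and the Spearman
#' correlation matrix of decision variables with Benjamini-Hochberg
#' adjusted p-values), and the six path models with fit indices and
#' indirect effects, plus covariate and exclusion sensitivity variants.
#' Any stage failure aborts with the stage name.  All randomness derives
#' from `config$seed`, so two runs with the same config are identical.
#'
#' @param config a [pipeline_config()].
#' @return list with elements `params_true`, `trials`, `pheno`,
#'   `params_fit` (NULL unless fitting), `metrics`, `descriptives`,
#'   `spearman`, `path` (per model: `fit`, `indices`, `indirect`,
#'   optional `bootstrap`, optional `sensitivity`), `exclusions`,
#'   `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  sd0 <- config$seed
  params_true <- run_stage("draw_params",
    draw_params(config$n_subjects, seed = stage_seed(sd0, 1L)))
  trials <- run_stage("simulate_trials",
    simulate_hdt_cohort(params_true, n_trials = config$n_trials,
                        seed = stage_seed(sd0, 2L)))
  pheno <- run_stage("simulate_phenotypes",
    simulate_phenotypes(params_true, seed = stage_seed(sd0, 3L)))
  params_fit <- if (config$fit) {
    run_stage("fit_cohort",
      fit_cohort(trials, n_starts = config$n_starts,
                 seed = stage_seed(sd0, 4L)))
  }
  metrics <- run_stage("behavior_metrics", behavior_metrics(trials))
  analysis_params <- if (config$fit) params_fit else params_true
  dm <- merge(analysis_params[, c("subject_id", .vpp_names)], metrics,
              by = "subject_id")
  desc <- run_stage("descriptives", {
    vars <- c(.vpp_names, "netscore", "win_stay", "lose_shift")
    qs <- t(vapply(vars, function(v) {
      quantile(dm[[v]], c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
    }, numeric(3)))
    data.frame(variable = vars, q25 = qs[, 1], median = qs[, 2],
               q75 = qs[, 3], row.names = NULL, stringsAsFactors = FALSE)
  })
  spearman <- run_stage("spearman", {
    sm <- spearman_matrix(dm, c(.vpp_names, "netscore", "win_stay",
                                "lose_shift"))
    pp <- sm$p[.vpp_names, .vpp_names]
    raw <- pp[upper.tri(pp)]
    adj <- bh_adjust(raw)  # the family of all pairwise parameter tests
    pa <- pp; pa[upper.tri(pa)] <- adj; pa[lower.tri(pa)] <- t(pa)[lower.tri(pa)]
    c(sm, list(p_adj_params = pa))
  })
  analysis <- merge(analysis_params, pheno, by = "subject_id")
  specs <- default_model_specs()[config$models]
  covmap <- list(standard = c("age", "fullness_standard_mm"),
                 eah = c("age", "fullness_eah_mm"),
                 buffet = c("age", "fullness_buffet_mm"))
  specs_cov <- default_model_specs(covariates = covmap)[config$models]
  excl <- run_stage("apply_exclusions", apply_exclusions(pheno))
  analysis_excl <- merge(analysis_params, excl$data, by = "subject_id")
  fit_one <- function(dat, spec) {
    mm <- preprocess(dat, spec)
    fit <- suppressWarnings(fit_path_model(mm, spec))
    ind <- do.call(rbind, lapply(.exog_terms(spec), function(tm) {
      ie <- indirect_effect(fit, c(tm, spec$intake_var),
                            c(spec$intake_var, spec$bmiz_var))
      data.frame(term = tm, estimate = ie$estimate, se = ie$se, p = ie$p,
                 stringsAsFactors = FALSE)
    }))
    out <- list(fit = fit, indices = fit_indices(fit, mm), indirect = ind)
    if (config$bootstrap_B > 0L) {
      out$bootstrap <- bootstrap_uncertainty(
        mm, spec, B = config$bootstrap_B, seed = stage_seed(sd0, 5L))
    }
    out
  }
  path <- run_stage("path_models", {
    lapply(seq_along(specs), function(i) {
      res <- fit_one(analysis, specs[[i]])
      if (config$sensitivity) {
        res$sensitivity <- list(
          covariates = fit_one(analysis, specs_cov[[i]])$fit,
          exclusions = fit_one(analysis_excl, specs[[i]])$fit)
      }
      res
    })
  })
  names(path) <- names(specs)
  out <- list(params_true = params_true, trials = trials, pheno = pheno,
              params_fit = params_fit, metrics = metrics,
              descriptives = desc, spearman = spearman, path = path,
              exclusions = excl$log, config = config)
  if (!is.null(config$outdir)) write_pipeline_outputs(out, config$outdir)
  out
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(outdir, f)
  write_params(res$params_true, fp("params_true.csv"))
  write_trials(res$trials, fp("trials.csv"))
  write.csv(res$pheno, fp("phenotypes.csv"), row.names = FALSE)
  if (!is.null(res$params_fit)) {
    write.csv(res$params_fit, fp("params_fit.csv"), row.names = FALSE)
  }
  write.csv(res$metrics, fp("metrics.csv"), row.names = FALSE)
  write.csv(res$descriptives, fp("descriptives.csv"), row.names = FALSE)
  write.csv(round(res$spearman$rho, 4), fp("spearman_rho.csv"))
  for (nm in names(res$path)) {
    write.csv(res$path[[nm]]$fit$coefficients,
              fp(paste0("path_", nm, "_coefficients.csv")),
              row.names = FALSE)
    write.csv(res$path[[nm]]$indirect,
              fp(paste0("path_", nm, "_indirect.csv")), row.names = FALSE)
  }
  rep <- c(
    sprintf("Pipeline run: %d subjects x %d trials, seed %d",
            res$config$n_subjects, res$config$n_trials, res$config$seed),
    "", "Parameter/metric quartiles:",
    utils::capture.output(print(res$descriptives, row.names = FALSE)),
    "", "Path models:")
  for (nm in names(res$path)) {
    ix <- res$path[[nm]]$indices
    rep <- c(rep, sprintf(
      "  %s: T = %.3f (df %d, p %.3f), RMSEA %.3f, CFI %.3f, SRMR %.3f",
      nm, ix$T, ix$df, ix$p_value, ix$rmsea, ix$cfi, ix$srmr),
      utils::capture.output(print(res$path[[nm]]$fit)))
  }
  writeLines(rep, fp("summary.txt"))
  invisible(outdir)
}
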