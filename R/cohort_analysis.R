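#' Analysis configuration
#'
#' Bundles the declared, deterministic choices of the statistical pipeline:
#' the outcome cutoff, the adjustment covariate set, which continuous
#' variables are compared with a Wilcoxon rank-sum test rather than a t test
#' (a declared list, not a normality autotest), the small-network threshold
#' for the sensitivity analysis, the race stratification variable, the tie
#' weight coding, and the race codebook.
#'
#' @param cutoff Outcome cutoff in hours (> 0); arrival beyond it counts as
#'   delayed. Default 6.
#' @param covariates Adjustment set for the block-wise models. Default: age,
#'   stroke severity (NIHSS), EMS usage, living alone, education, Black
#'   race, median household income.
#' @param wilcoxon_vars Continuous variables compared by Wilcoxon rank-sum
#'   instead of t test (skewed survey summaries: education, income).
#' @param compare_vars Variables for the descriptive group comparison and
#'   their type (`"continuous"`/`"categorical"`).
#' @param small_network_threshold Networks smaller than this are dropped in
#'   the small-network sensitivity analysis. Default 4.
#' @param race_var Binary patient column used for stratified and interaction
#'   race analyses. Default `"race_black"`.
#' @param weights A [tie_weights()] coding.
#' @param race_codebook Race categories for the race diversity index.
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(cutoff = 6,
                            covariates = c("age", "nihss", "ems",
                                           "living_alone", "education_years",
                                           "race_black", "income_k"),
                            wilcoxon_vars = c("education_years", "income_k"),
                            compare_vars = default_compare_vars(),
                            small_network_threshold = 4,
                            race_var = "race_black",
                            weights = tie_weights(),
                            race_codebook = c("white", "black", "other")) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  structure(list(cutoff = cutoff, covariates = covariates,
                 wilcoxon_vars = wilcoxon_vars, compare_vars = compare_vars,
                 small_network_threshold = small_network_threshold,
                 race_var = race_var, weights = weights,
                 race_codebook = race_codebook),
            class = "analysis_config")
}

default_compare_vars <- function() {
  tibble::tibble(
    variable = c("age", "sex", "education_years", "income_k", "married",
                 "living_alone", "nihss", "ems", "race_black", "tpa_given"),
    type = c("continuous", "categorical", "continuous", "continuous",
             "categorical", "categorical", "continuous", "categorical",
             "categorical", "categorical")
  )
}

#' Load an analysis configuration from a JSON file
#'
#' Keys mirror the arguments of [analysis_config()]; absent keys keep their
#' defaults, unknown keys are an error naming the key.
#'
#' @param path JSON file, or `NULL` for the defaults.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path = NULL) {
  if (is.null(path)) return(analysis_config())
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown analysis config key: '", bad[1], "'", call. = FALSE)
  }
  if (!is.null(raw$weights)) {
    raw$weights <- tie_weights(raw$weights$w_strong, raw$weights$w_weak)
  }
  if (!is.null(raw$compare_vars)) {
    raw$compare_vars <- tibble::as_tibble(raw$compare_vars)
  }
  do.call(analysis_config, raw)
}

# Delayed-arrival indicator at a given cutoff. Uses the stored boolean when
# the cutoff matches the recorded one; any other cutoff requires the
# continuous arrival_hours field.
arrival_outcome <- function(patients, cutoff = NULL) {
  if (is.null(cutoff)) return(patients$arrival_hours_gt_cutoff)
  stored <- patients$cutoff
  if (all(stored == cutoff)) return(patients$arrival_hours_gt_cutoff)
  if (anyNA(patients$arrival_hours)) {
    stop("cutoff ", cutoff, " differs from the recorded cutoff and ",
         "arrival_hours is missing; cannot relabel the outcome",
         call. = FALSE)
  }
  patients$arrival_hours > cutoff
}

#' Descriptive comparison of slow vs fast arrivers
#'
#' One row per declared variable. Continuous variables use an unpaired
#' two-sided Welch t test (summary: mean (sd)) unless listed in
#' `config$wilcoxon_vars`, in which case a Wilcoxon rank-sum test is used
#' (summary: median \[q1, q3\]). Categorical variables use a chi-squared
#' test with continuity correction unless any expected cell count is below 5
#' (Cochran's rule), in which case Fisher's exact test is used (summary:
#' n (%)).
#'
#' @param cohort An [ego_cohort()].
#' @param cutoff Outcome cutoff in hours; `NULL` uses the cohort's recorded
#'   cutoff.
#' @param config An [analysis_config()].
#' @return Tibble with columns `variable`, `summary_slow`, `summary_fast`,
#'   `test` (`"t"`, `"wilcoxon"`, `"chi2"`, `"fisher"`), `p_value`.
#' @export
compare_groups <- function(cohort, cutoff = NULL, config = analysis_config()) {
  stopifnot(inherits(cohort, "ego_cohort"))
  pts <- cohort$patients
  slow <- arrival_outcome(pts, cutoff)
  vars <- config$compare_vars
  rows <- lapply(seq_len(nrow(vars)), function(i) {
    v <- vars$variable[i]
    if (!v %in% names(pts)) {
      stop("comparison variable '", v, "' absent from cohort", call. = FALSE)
    }
    x <- pts[[v]]
    if (vars$type[i] == "continuous") {
      compare_continuous(v, x, slow, v %in% config$wilcoxon_vars)
    } else {
      compare_categorical(v, x, slow)
    }
  })
  dplyr::bind_rows(rows)
}

compare_continuous <- function(variable, x, slow, use_wilcoxon) {
  xs <- x[slow & !is.na(x)]
  xf <- x[!slow & !is.na(x)]
  if (use_wilcoxon) {
    p <- suppressWarnings(stats::wilcox.test(xs, xf)$p.value)
    summ <- function(v) {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      sprintf("%.1f [%.1f, %.1f]", q[2], q[1], q[3])
    }
    test <- "wilcoxon"
  } else {
    p <- stats::t.test(xs, xf)$p.value
    summ <- function(v) sprintf("%.1f (%.1f)", mean(v), stats::sd(v))
    test <- "t"
  }
  tibble::tibble(variable = variable, summary_slow = summ(xs),
                 summary_fast = summ(xf), test = test, p_value = p)
}

compare_categorical <- function(variable, x, slow) {
  keep <- !is.na(x)
  tab <- table(factor(x[keep]), factor(slow[keep], levels = c(TRUE, FALSE)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    p <- stats::fisher.test(tab)$p.value
    test <- "fisher"
  } else {
    p <- stats::chisq.test(tab)$p.value
    test <- "chi2"
  }
  summ <- function(is_slow) {
    n <- tab[, as.character(is_slow)]
    # percents reported to the nearest integer
    lvl <- rownames(tab)
    pos <- if (all(lvl %in% c("TRUE", "FALSE"))) "TRUE" else lvl[1]
    sprintf("%d (%d%%)", n[pos], as.integer(round(100 * n[pos] / sum(n))))
  }
  tibble::tibble(variable = variable, summary_slow = summ(TRUE),
                 summary_fast = summ(FALSE),
                 test = test, p_value = p)
}

#' Maximum-likelihood logistic regression with Wald inference
#'
#' Thin wrapper over [stats::glm()] that makes the failure modes of small
#' epidemiological fits explicit: rows with missing values in used columns
#' are dropped (with `n_used` recorded), a constant outcome or constant
#' predictor raises a classed `egodelay_degenerate_fit` condition naming the
#' offending variable, and (quasi-)complete separation raises a classed
#' `egodelay_separation` condition rather than returning silent huge odds
#' ratios. Confidence intervals are Wald: `exp(beta +/- 1.96 se)`.
#'
#' @param data Data frame containing `outcome` and `terms`.
#' @param outcome Name of the binary (logical/0-1) outcome column.
#' @param terms Character vector of predictor column names.
#' @return List with `coefficients` (tibble: term, estimate, se, or,
#'   ci_low, ci_high, p_value), `loglik`, `n_used`.
#' @export
fit_logistic <- function(data, outcome, terms) {
  cols <- c(outcome, terms)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("column '", missing_cols[1], "' absent from data", call. = FALSE)
  }
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  y <- as.numeric(d[[outcome]])
  if (length(unique(y)) < 2L) {
    rlang::abort(paste0("degenerate fit: outcome '", outcome,
                        "' is constant"),
                 class = "egodelay_degenerate_fit", variable = outcome)
  }
  for (v in terms) {
    xv <- d[[v]]
    if (length(unique(as.numeric(xv))) < 2L) {
      rlang::abort(paste0("degenerate fit: predictor '", v, "' is constant"),
                   class = "egodelay_degenerate_fit", variable = v)
    }
  }
  fml <- stats::reformulate(terms, response = outcome)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = d, family = stats::binomial()),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("numerically 0 or 1|did not converge", msg)) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- summary(fit)$coefficients
  # separation shows as exploding coefficients or standard errors
  if (!fit$converged ||
      (separated && (max(abs(cf[, 1])) > 10 || max(cf[, 2]) > 10))) {
    rlang::abort(paste0("separation or non-convergence fitting ",
                        paste(terms, collapse = " + ")),
                 class = "egodelay_separation", variable = terms[length(terms)])
  }
  est <- unname(cf[, 1])
  se <- unname(cf[, 2])
  coefs <- tibble::tibble(
    term = rownames(cf),
    estimate = est,
    se = se,
    or = exp(est),
    ci_low = exp(est - 1.96 * se),
    ci_high = exp(est + 1.96 * se),
    p_value = unname(cf[, 4])
  )
  list(coefficients = coefs, loglik = as.numeric(stats::logLik(fit)),
       n_used = nrow(d))
}

#' Block-wise adjusted model for one network metric
#'
#' Sequential-entry logistic regression: block 1 regresses delayed arrival
#' on the adjustment covariates alone, block 2 adds the single network
#' metric (metrics are modelled one at a time because they are collinear).
#' Both blocks are fitted on the same complete-case rows so their
#' log-likelihoods are comparable; `lr_p` is the 1-df likelihood-ratio p for
#' adding the metric, while the headline `or`/`ci`/`p_value` are Wald.
#'
#' @param cohort An [ego_cohort()].
#' @param metric Name of a network metric column (see [metrics_table()]).
#' @param metrics Optional precomputed metrics table; computed from the
#'   cohort when `NULL`.
#' @param covariates Adjustment covariate names.
#' @param cutoff Outcome cutoff in hours; `NULL` for the recorded one.
#' @param config An [analysis_config()] (used for weights/codebook when
#'   `metrics` is computed here, and for default covariates).
#' @return One-row tibble: `metric`, `or`, `ci_low`, `ci_high`, `p_value`,
#'   `loglik_base`, `loglik_full`, `lr_p`, `n_used`.
#' @export
blockwise_models <- function(cohort, metric, metrics = NULL,
                             covariates = NULL, cutoff = NULL,
                             config = analysis_config()) {
  stopifnot(inherits(cohort, "ego_cohort"))
  if (is.null(covariates)) covariates <- config$covariates
  if (is.null(metrics)) {
    metrics <- metrics_table(cohort, config$weights, config$race_codebook)
  }
  if (!metric %in% names(metrics)) {
    stop("metric column '", metric, "' absent from metrics table",
         call. = FALSE)
  }
  d <- dplyr::left_join(cohort$patients, metrics, by = "patient_id")
  d$.delayed <- as.numeric(arrival_outcome(d, cutoff))
  cols <- c(".delayed", covariates, metric)
  d <- d[stats::complete.cases(d[cols]), cols, drop = FALSE]
  base <- fit_logistic(d, ".delayed", covariates)
  full <- fit_logistic(d, ".delayed", c(covariates, metric))
  row <- full$coefficients[full$coefficients$term == metric, ]
  lr <- 2 * (full$loglik - base$loglik)
  tibble::tibble(
    metric = metric, or = row$or, ci_low = row$ci_low, ci_high = row$ci_high,
    p_value = row$p_value, loglik_base = base$loglik,
    loglik_full = full$loglik,
    lr_p = stats::pchisq(lr, df = 1, lower.tail = FALSE),
    n_used = full$n_used
  )
}

#' Adjusted forest-plot table over all network metrics
#'
#' Runs [blockwise_models()] for each metric in the canonical reporting
#' order (structure first: size, constraint, effective size, mean degree;
#' then composition). Degenerate or separated fits yield a row with missing
#' estimates and a `status` describing the failure instead of aborting the
#' whole table.
#'
#' @inheritParams blockwise_models
#' @param metrics_names Metrics to model; defaults to all ten.
#' @return Tibble of per-metric adjusted results with a `status` column
#'   (`"ok"` or the failure class).
#' @export
forest_table <- function(cohort, metrics = NULL, covariates = NULL,
                         cutoff = NULL, config = analysis_config(),
                         metrics_names = network_metric_names) {
  if (is.null(metrics)) {
    metrics <- metrics_table(cohort, config$weights, config$race_codebook)
  }
  rows <- lapply(metrics_names, function(m) {
    tryCatch(
      dplyr::mutate(
        blockwise_models(cohort, m, metrics, covariates, cutoff, config),
        status = "ok"),
      egodelay_degenerate_fit = function(e) degenerate_row(m, "degenerate"),
      egodelay_separation = function(e) degenerate_row(m, "separation")
    )
  })
  dplyr::bind_rows(rows)
}

degenerate_row <- function(metric, status) {
  tibble::tibble(metric = metric, or = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p_value = NA_real_,
                 loglik_base = NA_real_, loglik_full = NA_real_,
                 lr_p = NA_real_, n_used = NA_integer_, status = status)
}

#' Unadjusted comparison of network metrics between arrival groups
#'
#' Median \[IQR\] per group and a Wilcoxon rank-sum p value for every
#' network metric (exact where ties allow, normal approximation with tie
#' correction otherwise).
#'
#' @inheritParams forest_table
#' @return Tibble: `metric`, `median_slow`, `q1_slow`, `q3_slow`,
#'   `median_fast`, `q1_fast`, `q3_fast`, `p_value`, `n_slow`, `n_fast`.
#' @export
network_comparisons <- function(cohort, metrics = NULL, cutoff = NULL,
                                config = analysis_config(),
                                metrics_names = network_metric_names) {
  if (is.null(metrics)) {
    metrics <- metrics_table(cohort, config$weights, config$race_codebook)
  }
  d <- dplyr::left_join(cohort$patients, metrics, by = "patient_id")
  slow <- arrival_outcome(d, cutoff)
  rows <- lapply(metrics_names, function(m) {
    xs <- d[[m]][slow & !is.na(d[[m]])]
    xf <- d[[m]][!slow & !is.na(d[[m]])]
    q_s <- stats::quantile(xs, c(0.25, 0.5, 0.75), names = FALSE)
    q_f <- stats::quantile(xf, c(0.25, 0.5, 0.75), names = FALSE)
    tibble::tibble(
      metric = m, median_slow = q_s[2], q1_slow = q_s[1], q3_slow = q_s[3],
      median_fast = q_f[2], q1_fast = q_f[1], q3_fast = q_f[3],
      p_value = suppressWarnings(stats::wilcox.test(xs, xf)$p.value),
      n_slow = length(xs), n_fast = length(xf)
    )
  })
  dplyr::bind_rows(rows)
}

#' Sensitivity analyses
#'
#' Re-runs the adjusted per-metric models under four perturbations:
#' (a) a 3-hour outcome cutoff (requires `arrival_hours`); (b) removal of
#' very small networks (fewer members than the configured threshold);
#' (c) stratification by the race variable (which is dropped from the
#' stratified covariate set, being constant within stratum); and (d) an
#' interaction model adding a metric-by-race term, whose OR/CI/p are
#' reported per metric. Strata too small or degenerate to fit yield status
#' rows, not errors.
#'
#' @inheritParams forest_table
#' @param cutoff3 Alternative cutoff in hours for analysis (a). Default 3.
#' @return Named list of tibbles: `main`, `cutoff3`, `min_size`,
#'   `strat_race`, `strat_other`, `interaction`.
#' @export
sensitivity_suite <- function(cohort, config = analysis_config(),
                              metrics = NULL, cutoff3 = 3,
                              metrics_names = network_metric_names) {
  stopifnot(inherits(cohort, "ego_cohort"))
  if (is.null(metrics)) {
    metrics <- metrics_table(cohort, config$weights, config$race_codebook)
  }
  covs <- config$covariates
  race <- config$race_var

  main <- forest_table(cohort, metrics, covs, config$cutoff, config,
                       metrics_names)

  alt <- forest_table(cohort, metrics, covs, cutoff3, config, metrics_names)

  keep <- metrics$patient_id[!is.na(metrics$size) &
                               metrics$size >= config$small_network_threshold]
  big <- subset_cohort(cohort, keep)
  min_size <- forest_table(big, metrics[metrics$patient_id %in% keep, ],
                           covs, config$cutoff, config, metrics_names)

  strat_covs <- setdiff(covs, race)
  strat <- function(flag) {
    ids <- cohort$patients$patient_id[!is.na(cohort$patients[[race]]) &
                                        cohort$patients[[race]] == flag]
    sub <- subset_cohort(cohort, ids)
    forest_table(sub, metrics[metrics$patient_id %in% ids, ], strat_covs,
                 config$cutoff, config, metrics_names)
  }

  inter <- dplyr::bind_rows(lapply(metrics_names, function(m) {
    tryCatch(interaction_model(cohort, m, metrics, covs, race,
                               config$cutoff),
             egodelay_degenerate_fit = function(e) degenerate_row(m, "degenerate"),
             egodelay_separation = function(e) degenerate_row(m, "separation"))
  }))

  list(main = main, cutoff3 = alt, min_size = min_size,
       strat_race = strat(TRUE), strat_other = strat(FALSE),
       interaction = inter)
}

interaction_model <- function(cohort, metric, metrics, covariates, race_var,
                              cutoff) {
  d <- dplyr::left_join(cohort$patients, metrics, by = "patient_id")
  d$.delayed <- as.numeric(arrival_outcome(d, cutoff))
  d$.interaction <- d[[metric]] * as.numeric(d[[race_var]])
  cols <- c(".delayed", covariates, metric, ".interaction")
  d <- d[stats::complete.cases(d[cols]), cols, drop = FALSE]
  base <- fit_logistic(d, ".delayed", c(covariates, metric))
  full <- fit_logistic(d, ".delayed", c(covariates, metric, ".interaction"))
  row <- full$coefficients[full$coefficients$term == ".interaction", ]
  lr <- 2 * (full$loglik - base$loglik)
  tibble::tibble(
    metric = metric, or = row$or, ci_low = row$ci_low, ci_high = row$ci_high,
    p_value = row$p_value, loglik_base = base$loglik,
    loglik_full = full$loglik,
    lr_p = stats::pchisq(lr, df = 1, lower.tail = FALSE),
    n_used = full$n_used, status = "ok"
  )
}

#' Restrict a cohort to a subset of patients
#'
#' @param cohort An [ego_cohort()].
#' @param patient_ids Ids to keep.
#' @return The restricted `ego_cohort`.
#' @export
subset_cohort <- function(cohort, patient_ids) {
  stopifnot(inherits(cohort, "ego_cohort"))
  keep <- cohort$patients$patient_id %in% patient_ids
  ego_cohort(cohort$patients[keep, , drop = FALSE],
             cohort$networks[cohort$patients$patient_id[keep]])
}

#' First-contact tie strength by arrival group
#'
#' For the interview subgroup: the share of patients in each arrival group
#' whose first contact (or person present) at symptom onset was a strongly
#' tied person, reported as a percent rounded to the nearest integer.
#'
#' @param first_contact Data frame with columns `group` and
#'   `first_contact_strong` (logical/0-1).
#' @return Tibble: `group`, `n`, `n_strong`, `pct_strong` (integer percent,
#'   `NA` for an empty group).
#' @export
qualitative_tabulation <- function(first_contact) {
  stopifnot(all(c("group", "first_contact_strong") %in% names(first_contact)))
  d <- tibble::as_tibble(first_contact)
  d$first_contact_strong <- as.logical(d$first_contact_strong)
  groups <- if (is.factor(d$group)) levels(d$group) else
    sort(unique(as.character(d$group)))
  dplyr::bind_rows(lapply(groups, function(g) {
    x <- d$first_contact_strong[as.character(d$group) == g]
    tibble::tibble(
      group = g, n = length(x), n_strong = sum(x, na.rm = TRUE),
      pct_strong = if (length(x)) as.integer(round(100 * sum(x, na.rm = TRUE) /
                                                     length(x))) else
        NA_integer_
    )
  }))
}
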