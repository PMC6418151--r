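# cohort with prescribed group sizes and per-patient covariates, networks
# kept minimal where the test only exercises the patient-level statistics
make_stat_cohort <- function(patients) {
  nets <- lapply(patients$patient_id,
                 function(pid) make_star(2, patient_id = pid))
  ego_cohort(patients, nets)
}

test_that("compare_groups applies the declared test-selection rules", {
  set.seed(1)
  n <- 80
  pts <- data.frame(
    patient_id = sprintf("p%03d", 1:n),
    arrival_hours_gt_cutoff = rep(c(1, 0), each = n / 2),
    cutoff = 6,
    age = rnorm(n, 60, 10),
    education_years = sample(10:18, n, replace = TRUE),
    income_k = rlnorm(n, log(45), 0.4),
    race_black = rbinom(n, 1, 0.3),
    ems = rbinom(n, 1, 0.6),
    # rare category to trip Cochran's rule
    tpa_given = c(rep(0, n / 2), rbinom(n / 2, 1, 0.08))
  )
  co <- make_stat_cohort(pts)
  cfg <- analysis_config(compare_vars = tibble::tibble(
    variable = c("age", "education_years", "income_k", "race_black", "ems",
                 "tpa_given"),
    type = c("continuous", "continuous", "continuous", "categorical",
             "categorical", "categorical")))
  out <- compare_groups(co, config = cfg)
  expect_equal(out$test[out$variable == "age"], "t")
  expect_equal(out$test[out$variable == "education_years"], "wilcoxon")
  expect_equal(out$test[out$variable == "income_k"], "wilcoxon")
  expect_equal(out$test[out$variable == "tpa_given"], "fisher")
  expect_true(all(out$test[out$variable %in% c("race_black", "ems")] ==
                    "chi2"))
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))
  # absent variable errors by name
  bad <- analysis_config(compare_vars = tibble::tibble(
    variable = "charlson", type = "continuous"))
  expect_error(compare_groups(co, config = bad), "charlson")
})

test_that("the selected tests reproduce stats:: results on a known table", {
  # race-style 2x2: expected counts all >= 5 so the rule picks chi-squared
  pts <- data.frame(
    patient_id = sprintf("p%03d", 1:175),
    arrival_hours_gt_cutoff = rep(c(1, 0), c(67, 108)),
    cutoff = 6,
    race_black = c(rep(c(1, 0), c(28, 39)), rep(c(1, 0), c(27, 81)))
  )
  co <- make_stat_cohort(pts)
  cfg <- analysis_config(compare_vars = tibble::tibble(
    variable = "race_black", type = "categorical"))
  out <- compare_groups(co, config = cfg)
  expect_equal(out$test, "chi2")
  expect_equal(out$p_value,
               chisq.test(matrix(c(28, 39, 27, 81), 2))$p.value)
  expect_equal(out$summary_slow, "28 (42%)")
  expect_equal(out$summary_fast, "27 (25%)")
})

test_that("Fisher's exact p equals the hypergeometric enumeration oracle on small tables", {
  # identical balanced distributions -> p = 1
  expect_equal(fisher.test(matrix(c(5, 5, 5, 5), 2))$p.value, 1)
  for (r1 in 1:8) {
    for (r2 in 1:8) {
      for (a in 0:r1) {
        for (c_ in 0:r2) {
          tab <- matrix(c(a, r1 - a, c_, r2 - c_), 2)
          if (any(colSums(tab) == 0)) next
          expect_equal(fisher.test(tab)$p.value, oracle_fisher_p(tab),
                       tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("chi-squared matches the textbook formula on a hand-computed table", {
  tab <- matrix(c(30, 20, 10, 40), 2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((abs(tab - expected) - 0.5)^2 / expected)  # Yates correction
  expect_equal(chisq.test(tab)$p.value,
               pchisq(x2, df = 1, lower.tail = FALSE))
})

test_that("fit_logistic recovers the cross-product odds ratio of a 2x2 design", {
  # saturated logistic on a binary predictor: OR = ad/bc exactly
  d <- data.frame(
    y = rep(c(1, 0, 1, 0), c(20, 30, 10, 40)),
    x = rep(c(1, 1, 0, 0), c(20, 30, 10, 40))
  )
  fit <- fit_logistic(d, "y", "x")
  expect_equal(fit$coefficients$or[fit$coefficients$term == "x"],
               (20 * 40) / (30 * 10), tolerance = 1e-6)
  expect_equal(fit$n_used, 100)
  # CI is Wald
  row <- fit$coefficients[fit$coefficients$term == "x", ]
  expect_equal(row$ci_low, exp(row$estimate - 1.96 * row$se))
  expect_equal(row$ci_high, exp(row$estimate + 1.96 * row$se))
})

test_that("fit_logistic is unbiased under the null at large n", {
  set.seed(402)
  hits <- 0
  for (rep in 1:20) {
    n <- 10000
    d <- data.frame(y = rbinom(n, 1, 0.4), x = rnorm(n))
    fit <- fit_logistic(d, "y", "x")
    row <- fit$coefficients[fit$coefficients$term == "x", ]
    expect_lt(abs(row$or - 1), 0.2)
    if (abs(row$estimate) < 3 * row$se) hits <- hits + 1
  }
  expect_gte(hits, 19)  # |beta| < 3 se in >= 99% of null replicates
})

test_that("degenerate and separated fits raise classed signals, not huge ORs", {
  d <- data.frame(y = rep(1, 30), x = rnorm(30))
  expect_error(fit_logistic(d, "y", "x"), class = "egodelay_degenerate_fit")
  d2 <- data.frame(y = rbinom(30, 1, 0.5), x = rep(2, 30))
  expect_error(fit_logistic(d2, "y", "x"), class = "egodelay_degenerate_fit")
  # perfect separation
  d3 <- data.frame(y = rep(c(0, 1), each = 25),
                   x = c(rnorm(25, -5), rnorm(25, 5)))
  expect_error(fit_logistic(d3, "y", "x"), class = "egodelay_separation")
})

test_that("blockwise models nest properly and flag degenerate metrics", {
  co <- generate_cohort(paperlike_config(), seed = 21)
  m <- metrics_table(co)
  for (metric in c("size", "constraint_x100", "pct_kin")) {
    res <- blockwise_models(co, metric, metrics = m)
    expect_gte(res$loglik_full, res$loglik_base)  # nested models
    expect_lte(res$ci_low, res$or)
    expect_lte(res$or, res$ci_high)
    expect_gt(res$or, 0)
    expect_lte(res$n_used, length(co))
  }
  m$flat <- 1
  expect_error(blockwise_models(co, "flat", metrics = m),
               class = "egodelay_degenerate_fit")
  expect_error(blockwise_models(co, "nonexistent", metrics = m),
               "nonexistent")
})

test_that("blockwise parameter recovery: a positive constraint effect is detected at n = 1000", {
  co <- generate_logistic_cohort(1000, "constraint_x100", or = 1.04,
                                 seed = 314)
  res <- blockwise_models(co, "constraint_x100")
  expect_gt(res$or, 1)
  expect_gt(res$ci_low, 1)  # CI excludes 1 at this n and effect size
  expect_lt(res$p_value, 0.05)
})

test_that("forest_table keeps the canonical row order and survives failures", {
  co <- generate_cohort(paperlike_config(), seed = 33)
  m <- metrics_table(co)
  m$pct_stroke <- 0  # constant metric: degenerate, must not abort the table
  f <- forest_table(co, metrics = m)
  expect_equal(f$metric,
               c("size", "constraint_x100", "effective_size", "mean_degree",
                 "pct_kin", "sd_age", "iqv_sex", "iqv_race",
                 "pct_nonexercisers", "pct_stroke"))
  expect_equal(f$status[f$metric == "pct_stroke"], "degenerate")
  expect_true(all(f$status[f$metric %in% c("size", "constraint_x100")] ==
                    "ok"))
})

test_that("sensitivity: unchanged without small networks; cutoff relabels exactly; strata and interaction are reported", {
  cfg <- paperlike_config()
  co <- generate_cohort(cfg, seed = 55)
  m <- metrics_table(co)
  acfg <- analysis_config()

  res <- sensitivity_suite(co, acfg, metrics = m)
  expect_named(res, c("main", "cutoff3", "min_size", "strat_race",
                      "strat_other", "interaction"))

  # (b) no networks below the threshold -> identical to the main analysis
  big_ids <- m$patient_id[m$size >= acfg$small_network_threshold]
  big <- subset_cohort(co, big_ids)
  res_big <- sensitivity_suite(big, acfg,
                               metrics = m[m$patient_id %in% big_ids, ])
  expect_equal(res_big$min_size, res_big$main)

  # (a) the 3 h cutoff relabels outcomes exactly as arrival_hours dictates
  relabeled <- arrival_outcome(co$patients, 3)
  expect_equal(relabeled, co$patients$arrival_hours > 3)
  expect_gte(sum(relabeled), sum(co$patients$arrival_hours_gt_cutoff))

  # (c)/(d) strata and interaction rows exist for every metric
  expect_equal(nrow(res$strat_race), 10)
  expect_equal(nrow(res$strat_other), 10)
  expect_equal(nrow(res$interaction), 10)
  ok <- res$interaction$status == "ok"
  expect_true(any(ok))
  expect_true(all(res$interaction$loglik_full[ok] >=
                    res$interaction$loglik_base[ok]))
})

test_that("interaction CI covers 1 under a no-interaction data-generating model", {
  # identical metric effect in both race strata by construction
  # 100 replicates: at ~95% true coverage a >= 90% bound needs this many
  # draws to keep the Monte Carlo false-failure rate near 1%
  cover <- 0
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    co <- generate_logistic_cohort(2000, "size", or = 0.9,
                                   seed = 7000 + r)
    res <- interaction_model(co, "size", compute_metric(co, "size"),
                             analysis_config()$covariates, "race_black",
                             NULL)
    if (res$ci_low <= 1 && res$ci_high >= 1) cover <- cover + 1
  }
  expect_gte(cover / n_rep, 0.9)
})

test_that("qualitative tabulation reproduces integer percents per group", {
  d <- data.frame(
    group = rep(c("slow", "fast"), c(12, 15)),
    first_contact_strong = c(rep(c(TRUE, FALSE), c(9, 3)),
                             rep(c(TRUE, FALSE), c(7, 8)))
  )
  out <- qualitative_tabulation(d)
  expect_equal(out$pct_strong[out$group == "slow"], 75L)
  expect_equal(out$pct_strong[out$group == "fast"], 47L)
  none <- qualitative_tabulation(
    data.frame(group = "slow", first_contact_strong = rep(FALSE, 5)))
  expect_equal(none$pct_strong, 0L)
})

test_that("network_comparisons summarises per-group medians with Wilcoxon p", {
  co <- generate_cohort(paperlike_config(), seed = 88)
  t2 <- network_comparisons(co)
  expect_equal(nrow(t2), 10)
  expect_true(all(t2$q1_slow <= t2$median_slow &
                    t2$median_slow <= t2$q3_slow, na.rm = TRUE))
  expect_true(all(t2$p_value >= 0 & t2$p_value <= 1, na.rm = TRUE))
  expect_equal(t2$n_slow[t2$metric == "size"], 67)
})
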