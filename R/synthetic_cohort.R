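#' Per-group generative parameters for the synthetic cohort
#'
#' One arrival group's distributional parameters, covering both the ego
#' network (size, connectivity, tie strength, alter attributes) and the
#' patient covariates. Network sizes are drawn from a discretised log-normal
#' (median and log-scale dispersion), alter–alter ties are independent
#' Bernoulli draws at the given density, and alter ages are drawn around the
#' ego's age with the given spread.
#'
#' @param size_median Median network size (>= 1).
#' @param size_dispersion Log-scale SD of the size distribution.
#' @param density Probability of each alter–alter tie.
#' @param strong_frac Probability that any tie (ego–alter or alter–alter) is
#'   strong rather than weak.
#' @param kin_frac Probability an alter is kin.
#' @param age_spread SD (years) of alter ages around the ego's age.
#' @param nonexerciser_frac Probability an alter does not exercise.
#' @param sex_female Probability an alter is female.
#' @param race_homogeneity Probability an alter shares the ego's race;
#'   otherwise the race is uniform over the codebook.
#' @param stroke_frac Probability an alter ever had a stroke.
#' @param age_mean,age_sd Patient age distribution (years).
#' @param nihss_mean Mean of the (Poisson) NIHSS severity draw.
#' @param nihss_max Upper truncation of NIHSS (<= 42).
#' @param ems_frac,living_alone_frac,married_frac,black_frac,tpa_frac
#'   Patient-level Bernoulli fractions.
#' @param pt_sex_female Probability the patient is female.
#' @param education_median,education_spread Education years (normal,
#'   rounded).
#' @param income_median,income_dispersion Median household income in $1000
#'   (log-normal).
#' @return A named list of class `group_params`.
#' @export
group_params <- function(size_median = 8, size_dispersion = 0.45,
                         density = 0.6, strong_frac = 0.65, kin_frac = 0.57,
                         age_spread = 13.5, nonexerciser_frac = 0.44,
                         sex_female = 0.65, race_homogeneity = 0.95,
                         stroke_frac = 0.15,
                         age_mean = 61.7, age_sd = 15.6, nihss_mean = 3,
                         nihss_max = 13, ems_frac = 0.69,
                         living_alone_frac = 0.25, married_frac = 0.48,
                         black_frac = 0.25, tpa_frac = 0.5,
                         pt_sex_female = 0.54, education_median = 14,
                         education_spread = 2.2, income_median = 48.9,
                         income_dispersion = 0.39) {
  p <- as.list(environment())
  probs <- c("density", "strong_frac", "kin_frac", "nonexerciser_frac",
             "sex_female", "race_homogeneity", "stroke_frac", "ems_frac",
             "living_alone_frac", "married_frac", "black_frac", "tpa_frac",
             "pt_sex_female")
  for (nm in probs) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("group parameter '", nm, "' must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  if (p$size_median < 1) stop("size_median must be >= 1", call. = FALSE)
  if (p$nihss_max > 42) stop("nihss_max must be <= 42", call. = FALSE)
  structure(p, class = "group_params")
}

#' Simulation configuration for a two-group synthetic cohort
#'
#' @param n_slow,n_fast Group sizes (defaults 67 delayed / 108 early
#'   arrivers).
#' @param slow,fast [group_params()] for each arrival group.
#' @param cutoff Outcome cutoff in hours defining the groups (default 6).
#' @param missing_rate Probability that each optional alter attribute is
#'   recorded as missing (default 0: complete surveys).
#' @param race_codebook Race categories used for alter races.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(n_slow = 67, n_fast = 108,
                       slow = group_params(), fast = group_params(),
                       cutoff = 6, missing_rate = 0,
                       race_codebook = c("white", "black", "other")) {
  stopifnot(n_slow >= 0, n_fast >= 0, cutoff > 0,
            inherits(slow, "group_params"), inherits(fast, "group_params"))
  if (missing_rate < 0 || missing_rate > 1) {
    stop("missing_rate must be a probability in [0, 1]", call. = FALSE)
  }
  structure(list(n_slow = as.integer(n_slow), n_fast = as.integer(n_fast),
                 slow = slow, fast = fast, cutoff = cutoff,
                 missing_rate = missing_rate, race_codebook = race_codebook),
            class = "sim_config")
}

#' Null configuration: no group differences
#'
#' Both arrival groups share every generative parameter, so any detected
#' group contrast is a false positive; used for type-I-error calibration.
#'
#' @param n_slow,n_fast Group sizes.
#' @param params The shared [group_params()].
#' @return A `sim_config`.
#' @export
null_config <- function(n_slow = 67, n_fast = 108,
                        params = group_params()) {
  sim_config(n_slow, n_fast, slow = params, fast = params)
}

#' Study-calibrated configuration
#'
#' Group-conditional defaults chosen so that generated cohorts reproduce the
#' direction and approximate magnitude of the reported group contrasts:
#' delayed arrivers get smaller (median 5 vs 8), denser, more strongly tied
#' networks with more kin, a narrower alter age spread and more
#' nonexercisers, plus the corresponding covariate contrasts (more Black
#' patients, lower income, less EMS use, no thrombolysis). The numeric
#' values are documented calibration constants, fixed here and never fitted
#' at run time.
#'
#' @return A `sim_config` with 67 slow and 108 fast arrivers.
#' @export
paperlike_config <- function() {
  slow <- group_params(
    size_median = 5, size_dispersion = 0.51, density = 0.92,
    strong_frac = 0.80, kin_frac = 0.62, age_spread = 12.0,
    nonexerciser_frac = 0.62, sex_female = 0.65, race_homogeneity = 0.95,
    stroke_frac = 0.15,
    age_mean = 61.0, age_sd = 15.9, nihss_mean = 3, nihss_max = 12,
    ems_frac = 0.55, living_alone_frac = 0.33, married_frac = 0.36,
    black_frac = 0.42, tpa_frac = 0, pt_sex_female = 0.48,
    education_median = 14, education_spread = 2.2,
    income_median = 39.0, income_dispersion = 0.39
  )
  fast <- group_params(
    size_median = 8, size_dispersion = 0.45, density = 0.72,
    strong_frac = 0.60, kin_frac = 0.57, age_spread = 13.5,
    nonexerciser_frac = 0.44, sex_female = 0.65, race_homogeneity = 0.95,
    stroke_frac = 0.15,
    age_mean = 61.7, age_sd = 15.6, nihss_mean = 3, nihss_max = 13,
    ems_frac = 0.69, living_alone_frac = 0.25, married_frac = 0.48,
    black_frac = 0.25, tpa_frac = 0.5, pt_sex_female = 0.54,
    education_median = 14, education_spread = 2.2,
    income_median = 48.9, income_dispersion = 0.39
  )
  sim_config(67, 108, slow = slow, fast = fast)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

rbern <- function(n, prob) stats::runif(n) < prob

# trusted fast path: slices of generator-built canonical tables, so the
# constructor checks of ego_network() are skipped
new_ego_network <- function(patient_id, alters, ties) {
  structure(list(patient_id = patient_id, alters = alters, ties = ties),
            class = "ego_network")
}

empty_ties <- tibble::tibble(alter_a = character(), alter_b = character(),
                             strength = character())

# vectorised draw of one arrival group's patients (covariates only)
draw_patients <- function(ids, slow, p, cutoff) {
  k <- length(ids)
  arrival <- if (slow) {
    cutoff + stats::rexp(k, rate = 1 / 6)
  } else {
    cutoff * stats::rbeta(k, 1, 1.5)
  }
  tibble::tibble(
    patient_id = ids,
    arrival_hours = arrival,
    arrival_hours_gt_cutoff = slow,
    cutoff = cutoff,
    age = round(clamp(stats::rnorm(k, p$age_mean, p$age_sd), 21, 95)),
    nihss = pmin(stats::rpois(k, p$nihss_mean), p$nihss_max),
    ems = rbern(k, p$ems_frac),
    living_alone = rbern(k, p$living_alone_frac),
    education_years = round(clamp(stats::rnorm(k, p$education_median,
                                               p$education_spread), 8, 20)),
    race_black = rbern(k, p$black_frac),
    income_k = round(stats::rlnorm(k, log(p$income_median),
                                   p$income_dispersion), 1),
    married = rbern(k, p$married_frac),
    sex = ifelse(rbern(k, p$pt_sex_female), "female", "male"),
    tpa_given = if (slow) rep(FALSE, k) else rbern(k, p$tpa_frac)
  )
}

# vectorised draw of one group's networks: all alters, then all candidate
# alter-alter ties, drawn as flat vectors and sliced per patient
draw_networks <- function(ids, p, ego_age, ego_black, codebook,
                          missing_rate) {
  k <- length(ids)
  sizes <- pmax(1L, as.integer(round(stats::rlnorm(k, log(p$size_median),
                                                   p$size_dispersion))))
  total <- sum(sizes)
  who <- rep.int(seq_len(k), sizes)
  ego_race <- ifelse(ego_black, "black", "white")[who]
  alters <- tibble::tibble(
    alter_id = unlist(lapply(sizes, function(n) sprintf("a%02d",
                                                        seq_len(n))),
                      use.names = FALSE),
    is_kin = rbern(total, p$kin_frac),
    age = round(clamp(stats::rnorm(total, ego_age[who], p$age_spread),
                      18, 95)),
    sex = ifelse(rbern(total, p$sex_female), "female", "male"),
    race = ifelse(rbern(total, p$race_homogeneity), ego_race,
                  sample(codebook, total, replace = TRUE)),
    exerciser = !rbern(total, p$nonexerciser_frac),
    had_stroke = rbern(total, p$stroke_frac),
    tie_to_ego = ifelse(rbern(total, p$strong_frac), "strong", "weak")
  )
  if (missing_rate > 0) {
    for (col in c("is_kin", "age", "sex", "race", "exerciser",
                  "had_stroke")) {
      alters[[col]][rbern(total, missing_rate)] <- NA
    }
  }
  npairs <- choose(sizes, 2)
  pair_who <- rep.int(seq_len(k), npairs)
  pairs <- lapply(sizes, function(n) {
    if (n >= 2L) utils::combn(sprintf("a%02d", seq_len(n)), 2L) else
      matrix(character(), nrow = 2)
  })
  pair_a <- unlist(lapply(pairs, function(m) m[1L, ]), use.names = FALSE)
  pair_b <- unlist(lapply(pairs, function(m) m[2L, ]), use.names = FALSE)
  present <- rbern(sum(npairs), p$density)
  all_ties <- tibble::tibble(
    alter_a = pair_a[present],
    alter_b = pair_b[present],
    strength = ifelse(rbern(sum(npairs), p$strong_frac),
                      "strong", "weak")[present]
  )
  alter_split <- split(seq_len(total), who)
  tie_split <- split(seq_len(nrow(all_ties)), pair_who[present])
  lapply(seq_len(k), function(i) {
    idx <- tie_split[[as.character(i)]]
    ties <- if (is.null(idx)) empty_ties else slice_tbl(all_ties, idx)
    new_ego_network(ids[i], slice_tbl(alters, alter_split[[i]]), ties)
  })
}

# minimal-overhead row slice of a tibble with known-valid indices
slice_tbl <- function(df, idx) {
  tibble::new_tibble(lapply(unclass(df), `[`, idx), nrow = length(idx))
}

draw_group <- function(ids, slow, p, cutoff, codebook, missing_rate) {
  patients <- draw_patients(ids, slow, p, cutoff)
  networks <- draw_networks(ids, p, patients$age, patients$race_black,
                            codebook, missing_rate)
  list(patients = patients, networks = networks)
}

#' Generate a synthetic two-group cohort
#'
#' Outcome-first simulation: the arrival group is drawn first (group sizes
#' exact) and drives both the network and the covariate distributions, with
#' a continuous `arrival_hours` drawn consistently with the group label so
#' that alternative cutoffs can relabel the outcome. Deterministic given
#' `seed` and `config`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return An [ego_cohort()] of `n_slow + n_fast` patients (slow first).
#' @export
generate_cohort <- function(config = paperlike_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("p%04d", seq_len(config$n_slow + config$n_fast))
  g_slow <- draw_group(ids[seq_len(config$n_slow)], TRUE, config$slow,
                       config$cutoff, config$race_codebook,
                       config$missing_rate)
  g_fast <- draw_group(ids[seq_len(config$n_fast) + config$n_slow], FALSE,
                       config$fast, config$cutoff, config$race_codebook,
                       config$missing_rate)
  ego_cohort(dplyr::bind_rows(g_slow$patients, g_fast$patients),
             c(g_slow$networks, g_fast$networks))
}

#' Compute a single network metric across a cohort
#'
#' Fast path used by the simulation-calibration suites: computes just one
#' of the ten network metrics instead of the full [metrics_table()].
#'
#' @param cohort An [ego_cohort()].
#' @param metric One of the metric names of [metrics_table()].
#' @param weights A [tie_weights()] coding (structural metrics only).
#' @param race_codebook Race codebook (race diversity only).
#' @return Tibble with `patient_id` and the metric column.
#' @export
compute_metric <- function(cohort, metric, weights = tie_weights(),
                           race_codebook = c("white", "black", "other")) {
  stopifnot(inherits(cohort, "ego_cohort"))
  f <- switch(metric,
    size = function(net) network_size(net),
    constraint_x100 = function(net) burt_constraint(net, weights),
    effective_size = function(net) effective_size(net, weights),
    mean_degree = function(net) mean_degree(net),
    pct_kin = pct_kin,
    sd_age = sd_age,
    iqv_sex = function(net) {
      if (any(!is.na(net$alters$sex))) iqv(net, "sex") else NA_real_
    },
    iqv_race = function(net) {
      if (any(!is.na(net$alters$race))) {
        iqv(net, "race", race_codebook = race_codebook)
      } else NA_real_
    },
    pct_nonexercisers = function(net) pct_binary(net, "nonexerciser"),
    pct_stroke = function(net) pct_binary(net, "had_stroke"),
    stop("unknown metric '", metric, "'", call. = FALSE)
  )
  out <- tibble::tibble(
    patient_id = cohort$patients$patient_id,
    value = vapply(cohort$networks, function(net) as.numeric(f(net)),
                   numeric(1), USE.NAMES = FALSE)
  )
  names(out)[2] <- metric
  out
}

#' Generate a cohort with a known true adjusted odds ratio
#'
#' Outcome-second simulation for calibration studies: networks and
#' covariates are drawn from a single shared [group_params()] (no built-in
#' group contrast), one network metric is computed, and the delayed-arrival
#' outcome is then drawn from a logistic model
#' `logit P(delayed) = a0 + log(or) * metric + sum log(covariate_ors) * x`.
#' The conditional (covariate-adjusted) odds ratio of the metric is
#' therefore exactly `or`, which is what the block-wise model estimates.
#' The intercept is solved numerically on the drawn sample so the expected
#' delayed fraction equals `target_prevalence`.
#'
#' @param n Number of patients.
#' @param metric Network metric column name (see [metrics_table()]).
#' @param or True conditional odds ratio per unit of the metric.
#' @param params Shared [group_params()].
#' @param covariate_ors Named per-unit odds ratios of the patient covariates
#'   entering the true model.
#' @param target_prevalence Expected fraction delayed (default 67/175).
#' @param seed Integer seed, or `NULL`.
#' @param cutoff Outcome cutoff in hours.
#' @param weights [tie_weights()] used to compute structural metrics.
#' @return An [ego_cohort()]; the realised linear predictor's metric
#'   coefficient is `log(or)` by construction.
#' @export
generate_logistic_cohort <- function(n, metric, or,
                                     params = group_params(),
                                     covariate_ors = c(age = 1.01,
                                                       nihss = 1.00,
                                                       ems = 0.70,
                                                       living_alone = 1.30,
                                                       education_years = 0.95,
                                                       race_black = 2.00,
                                                       income_k = 0.99),
                                     target_prevalence = 67 / 175,
                                     seed = NULL, cutoff = 6,
                                     weights = tie_weights()) {
  stopifnot(or > 0, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("p%04d", seq_len(n))
  g <- draw_group(ids, FALSE, params, cutoff, c("white", "black", "other"),
                  0)
  patients <- g$patients
  networks <- g$networks
  cohort0 <- ego_cohort(patients, networks)
  x <- compute_metric(cohort0, metric, weights)[[metric]]
  if (anyNA(x)) stop("metric '", metric, "' missing in generated cohort",
                     call. = FALSE)
  offset <- log(or) * x
  for (v in names(covariate_ors)) {
    offset <- offset + log(covariate_ors[[v]]) * as.numeric(patients[[v]])
  }
  a0 <- stats::uniroot(
    function(a) mean(stats::plogis(a + offset)) - target_prevalence,
    interval = c(-50, 50)
  )$root
  slow <- rbern(n, stats::plogis(a0 + offset))
  patients$arrival_hours_gt_cutoff <- slow
  # redraw arrival times consistently with the assigned outcome
  patients$arrival_hours <- ifelse(
    slow, cutoff + stats::rexp(n, rate = 1 / 6),
    cutoff * stats::rbeta(n, 1, 1.5))
  patients$tpa_given <- patients$tpa_given & !slow
  ego_cohort(patients, networks)
}
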