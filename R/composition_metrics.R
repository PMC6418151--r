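#' Percentage of kin among network members
#'
#' Share of alters who are family, among alters with known kin status
#' (pairwise deletion of missing attributes; no imputation).
#'
#' @param network An [ego_network()].
#' @return Percent in `[0, 100]`, or `NA_real_` when no alter has a known
#'   kin status.
#' @export
pct_kin <- function(network) {
  stopifnot(inherits(network, "ego_network"))
  pct_of(network$alters$is_kin)
}

pct_of <- function(x) {
  known <- !is.na(x)
  if (!any(known)) return(NA_real_)
  100 * sum(x[known]) / sum(known)
}

#' Standard deviation of network members' ages
#'
#' Sample standard deviation (n − 1 denominator) over alters with known age;
#' reflects the range of ages of the people around the patient.
#'
#' @inheritParams pct_kin
#' @return SD in years, or `NA_real_` with fewer than two known ages.
#' @export
sd_age <- function(network) {
  stopifnot(inherits(network, "ego_network"))
  ages <- network$alters$age[!is.na(network$alters$age)]
  if (length(ages) < 2L) return(NA_real_)
  stats::sd(ages)
}

#' Index of qualitative variation for a categorical alter attribute
#'
#' Normalised categorical diversity, `IQV = (1 - sum p_i^2) / (1 - 1/k)`
#' over the shares `p_i` of each category among alters with a known value:
#' 0 when all members fall in one category, 1 at the uniform mix over the
#' `k` reference categories.
#'
#' @inheritParams pct_kin
#' @param attribute `"sex"` or `"race"`.
#' @param k Number of reference categories (>= 2). Defaults to 2 for sex and
#'   to the size of the race codebook for race; using the codebook size
#'   rather than the number of observed categories anchors a homogeneous
#'   network at 0 regardless of codebook.
#' @param race_codebook Character vector of race categories; only its length
#'   is used (default `c("white", "black", "other")`).
#' @return IQV in `[0, 1]`, or `NA_real_` when no alter has a known value.
#' @export
iqv <- function(network, attribute = c("sex", "race"), k = NULL,
                race_codebook = c("white", "black", "other")) {
  stopifnot(inherits(network, "ego_network"))
  attribute <- match.arg(attribute)
  if (is.null(k)) {
    k <- if (attribute == "sex") 2L else length(race_codebook)
  }
  stopifnot(k >= 2L)
  x <- network$alters[[attribute]]
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  p <- as.vector(table(x)) / length(x)
  (1 - sum(p^2)) / (1 - 1 / k)
}

#' Percentage of network members with a binary health attribute
#'
#' Share of alters who do not exercise, or who ever had a stroke, among
#' alters with a known status.
#'
#' @inheritParams pct_kin
#' @param attribute `"nonexerciser"` (the complement of the `exerciser`
#'   flag) or `"had_stroke"`.
#' @return Percent in `[0, 100]`, or `NA_real_` when no status is known.
#' @export
pct_binary <- function(network, attribute = c("nonexerciser", "had_stroke")) {
  stopifnot(inherits(network, "ego_network"))
  attribute <- match.arg(attribute)
  x <- if (attribute == "nonexerciser") {
    !network$alters$exerciser
  } else {
    network$alters$had_stroke
  }
  pct_of(x)
}

#' Per-patient table of network composition metrics
#'
#' @param cohort An [ego_cohort()].
#' @param race_codebook Passed to [iqv()] for the race diversity index.
#' @return Tibble with columns `patient_id`, `pct_kin`, `sd_age`, `iqv_sex`,
#'   `iqv_race`, `pct_nonexercisers`, `pct_stroke`.
#' @export
composition_table <- function(cohort,
                              race_codebook = c("white", "black", "other")) {
  stopifnot(inherits(cohort, "ego_cohort"))
  nets <- cohort$networks
  col <- function(f) vapply(nets, f, numeric(1), USE.NAMES = FALSE)
  tibble::tibble(
    patient_id = as.character(cohort$patients$patient_id),
    pct_kin = col(pct_kin),
    sd_age = col(sd_age),
    iqv_sex = col(function(net) {
      if (any(!is.na(net$alters$sex))) iqv(net, "sex") else NA_real_
    }),
    iqv_race = col(function(net) {
      if (any(!is.na(net$alters$race))) {
        iqv(net, "race", race_codebook = race_codebook)
      } else NA_real_
    }),
    pct_nonexercisers = col(function(net) pct_binary(net, "nonexerciser")),
    pct_stroke = col(function(net) pct_binary(net, "had_stroke"))
  )
}

#' Merged structural + composition metrics per patient
#'
#' Convenience wrapper joining [structural_table()] and
#' [composition_table()] on `patient_id`, in the canonical reporting order
#' of the network metrics.
#'
#' @inheritParams structural_table
#' @inheritParams composition_table
#' @return Tibble with one row per patient and all ten metric columns.
#' @export
metrics_table <- function(cohort, weights = tie_weights(),
                          race_codebook = c("white", "black", "other")) {
  dplyr::left_join(structural_table(cohort, weights),
                   composition_table(cohort, race_codebook),
                   by = "patient_id")
}

# canonical reporting order: structure first, then composition
network_metric_names <- c("size", "constraint_x100", "effective_size",
                          "mean_degree", "pct_kin", "sd_age", "iqv_sex",
                          "iqv_race", "pct_nonexercisers", "pct_stroke")
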