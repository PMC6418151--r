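#' Weighted adjacency matrix of an ego network
#'
#' Builds the symmetric tie-weight matrix over the ego plus all alters, with
#' the ego in the first row/column. Ego–alter entries take the weight of the
#' reported `tie_to_ego`; alter–alter entries take the weight of the listed
#' tie and 0 where no tie was reported; the diagonal is 0.
#'
#' @param network An [ego_network()].
#' @param weights A [tie_weights()] coding.
#' @return A `(size + 1) x (size + 1)` numeric matrix with dimnames
#'   `c("ego", alter ids)`.
#' @export
weighted_adjacency <- function(network, weights = tie_weights()) {
  stopifnot(inherits(network, "ego_network"), inherits(weights, "tie_weights"))
  ids <- network$alters$alter_id
  n <- length(ids)
  w <- function(s) ifelse(s == "strong", weights$w_strong, weights$w_weak)
  z <- matrix(0, n + 1L, n + 1L, dimnames = list(c("ego", ids), c("ego", ids)))
  if (n > 0L) {
    z[1L, -1L] <- z[-1L, 1L] <- w(network$alters$tie_to_ego)
  }
  if (nrow(network$ties)) {
    ia <- match(network$ties$alter_a, ids) + 1L
    ib <- match(network$ties$alter_b, ids) + 1L
    z[cbind(ia, ib)] <- z[cbind(ib, ia)] <- w(network$ties$strength)
  }
  z
}

# Tie-proportion matrix P with p_ij = (z_ij + z_ji) / sum_k (z_ik + z_ki).
# Rows with no ties stay all-zero (isolated nodes cannot occur for the ego
# or, by construction, for any alter — all alters are tied to the ego).
proportion_matrix <- function(z) {
  s <- z + t(z)
  rs <- rowSums(s)
  rs[rs == 0] <- 1
  s / rs
}

# internal cores working on a prebuilt weight matrix, so one adjacency
# build serves both structural-hole metrics
constraint_from_z <- function(z) {
  P <- proportion_matrix(z)
  p <- P[1L, -1L]
  Pa <- P[-1L, -1L, drop = FALSE]
  indirect <- as.vector(p %*% Pa)
  100 * sum((p + indirect)^2)
}

effective_from_z <- function(z) {
  n <- nrow(z) - 1L
  P <- proportion_matrix(z)
  p <- P[1L, -1L]
  za <- z[-1L, -1L, drop = FALSE]
  mx <- apply(za, 1L, max)
  mx[mx == 0] <- 1
  redundancy <- as.vector((za / mx) %*% p)
  n - sum(redundancy)
}

#' Burt constraint of the patient's network, scaled to 0–100
#'
#' Constraint measures how concentrated the ego's ties are within a single
#' interconnected cluster: it increases with density, strong ties and
#' hierarchy, and decreases with size. For each alter j the dyadic
#' constraint is `c_j = (p_j + sum_q p_q p_qj)^2` where `p_j` is the
#' proportion of the ego's total tie weight spent on j and the sum runs over
#' the other alters q; total constraint is `C = sum_j c_j`, reported here as
#' `100 * C` to match the 0–100 reporting scale (an isolated dyad scores
#' 100, a size-n star scores 100/n, an equal-weight clique of size n scores
#' `100 * (2n - 1)^2 / n^3`).
#'
#' @inheritParams weighted_adjacency
#' @return `100 * C` for the ego, or `NA_real_` for an empty network (the
#'   metric is undefined, not an error).
#' @export
burt_constraint <- function(network, weights = tie_weights()) {
  if (network_size(network) == 0L) return(NA_real_)
  constraint_from_z(weighted_adjacency(network, weights))
}

#' Effective size of the patient's network
#'
#' The number of nonredundant contacts: network size discounted for
#' redundancy among alters, `E = sum_j (1 - sum_q p_q m_jq)` where
#' `m_jq = z_jq / max_k z_jk` is alter j's tie to q scaled by j's strongest
#' alter–alter tie (the ego is excluded from both the q sum and the max).
#' Equals the size when no alters know each other and 1 for an equal-weight
#' clique; on a single-weight network it reduces to `n - 2t/n` with `t` the
#' number of alter–alter ties.
#'
#' @inheritParams weighted_adjacency
#' @return Effective size in `[1, size]`, or `NA_real_` for an empty network.
#' @export
effective_size <- function(network, weights = tie_weights()) {
  if (network_size(network) == 0L) return(NA_real_)
  effective_from_z(weighted_adjacency(network, weights))
}

#' Mean degree of network members
#'
#' Average, over alters, of the number of alter–alter ties incident to each
#' alter. The patient is excluded both as a node and from the edge set, so a
#' pure star network scores 0. Set `include_ego_tie = TRUE` to count each
#' alter's tie to the ego as well (+1 per alter), for comparability studies.
#'
#' @inheritParams weighted_adjacency
#' @param include_ego_tie Count the ego tie in each alter's degree?
#'   Default `FALSE`.
#' @return Mean degree, or `NA_real_` for an empty network.
#' @export
mean_degree <- function(network, include_ego_tie = FALSE) {
  n <- network_size(network)
  if (n == 0L) return(NA_real_)
  2 * nrow(network$ties) / n + if (include_ego_tie) 1 else 0
}

#' Per-patient table of network structure metrics
#'
#' @param cohort An [ego_cohort()].
#' @inheritParams weighted_adjacency
#' @param include_ego_tie Passed to [mean_degree()].
#' @return Tibble with columns `patient_id`, `size`, `constraint_x100`,
#'   `effective_size`, `mean_degree`; metrics of empty networks are `NA`.
#' @export
structural_table <- function(cohort, weights = tie_weights(),
                             include_ego_tie = FALSE) {
  stopifnot(inherits(cohort, "ego_cohort"))
  nets <- cohort$networks
  per_net <- vapply(nets, function(net) {
    if (network_size(net) == 0L) return(c(NA_real_, NA_real_))
    z <- weighted_adjacency(net, weights)
    c(constraint_from_z(z), effective_from_z(z))
  }, numeric(2), USE.NAMES = FALSE)
  tibble::tibble(
    patient_id = as.character(cohort$patients$patient_id),
    size = vapply(nets, network_size, integer(1), USE.NAMES = FALSE),
    constraint_x100 = per_net[1, ],
    effective_size = per_net[2, ],
    mean_degree = vapply(nets, mean_degree, numeric(1),
                         include_ego_tie = include_ego_tie,
                         USE.NAMES = FALSE)
  )
}
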