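# Canonical hand-built networks and a tiny cohort, constructed in code.

make_clique <- function(n, strength = "strong", tie_to_ego = "strong",
                        patient_id = paste0("clique", n)) {
  ids <- sprintf("a%d", seq_len(n))
  ties <- NULL
  if (n >= 2) {
    p <- t(utils::combn(ids, 2))
    ties <- data.frame(alter_a = p[, 1], alter_b = p[, 2],
                       strength = strength)
  }
  ego_network(patient_id,
              data.frame(alter_id = ids, tie_to_ego = tie_to_ego), ties)
}

make_star <- function(n, tie_to_ego = "strong",
                      patient_id = paste0("star", n)) {
  ego_network(patient_id,
              data.frame(alter_id = sprintf("a%d", seq_len(n)),
                         tie_to_ego = tie_to_ego))
}

# Two-patient toy cohort with full attributes, used for reader round-trips.
make_toy_cohort <- function() {
  patients <- data.frame(
    patient_id = c("p1", "p2"),
    arrival_hours = c(9.5, 2.25),
    arrival_hours_gt_cutoff = c(1, 0),
    cutoff = 6,
    age = c(70, 55), nihss = c(3, 1), ems = c(1, 0),
    living_alone = c(0, 1), education_years = c(12, 16),
    race_black = c(1, 0), income_k = c(39.1, 52.4), married = c(1, 0),
    sex = c("female", "male"), tpa_given = c(0, 1)
  )
  net1 <- ego_network("p1", data.frame(
    alter_id = c("alice", "bob", "cara"),
    is_kin = c(TRUE, TRUE, FALSE),
    age = c(68, 45, NA),
    sex = c("female", "male", "female"),
    race = c("black", "black", NA),
    exerciser = c(FALSE, NA, TRUE),
    had_stroke = c(FALSE, FALSE, NA),
    tie_to_ego = c("strong", "strong", "weak")
  ), data.frame(alter_a = "alice", alter_b = "bob", strength = "strong"))
  net2 <- ego_network("p2", data.frame(
    alter_id = c("dan", "eva"),
    is_kin = c(FALSE, FALSE),
    age = c(30, 60),
    sex = c("male", "female"),
    race = c("white", "white"),
    exerciser = c(TRUE, TRUE),
    had_stroke = c(FALSE, FALSE),
    tie_to_ego = c("weak", "weak")
  ))
  ego_cohort(patients, list(net1, net2))
}
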