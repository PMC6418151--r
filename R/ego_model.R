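#' Construct a single patient's ego network
#'
#' An ego network is the survey-derived personal network of one patient (the
#' "ego"): the people they named (alters), attributes of each alter, and the
#' ties the patient reported among alters. The ego is implicit — by
#' construction of the name generator every alter is tied to the ego, with a
#' reported strength of `"strong"` or `"weak"` — and is excluded from the
#' network size.
#'
#' @param patient_id Single string identifying the patient.
#' @param alters Data frame with one row per alter. Required columns:
#'   `alter_id` (unique within the network) and `tie_to_ego`
#'   (`"strong"`/`"weak"`; `NA` is coerced to `"strong"`, the default for
#'   core name-generator contacts). Optional attribute columns, `NA` where
#'   unknown: `is_kin`, `age`, `sex` (`"female"`/`"male"`), `race`,
#'   `exerciser`, `had_stroke`.
#' @param ties Data frame of alter–alter ties with columns `alter_a`,
#'   `alter_b`, `strength` (`"strong"`/`"weak"`). Undirected: each unordered
#'   pair appears at most once; self-ties are invalid.
#'
#' @return An object of class `ego_network`: a list with elements
#'   `patient_id`, `alters` (tibble), `ties` (tibble).
#' @export
#' @examples
#' net <- ego_network(
#'   "p1",
#'   alters = data.frame(alter_id = c("a", "b", "c"),
#'                       tie_to_ego = c("strong", "strong", "weak"),
#'                       is_kin = c(TRUE, FALSE, NA)),
#'   ties = data.frame(alter_a = "a", alter_b = "b", strength = "weak")
#' )
#' network_size(net)
ego_network <- function(patient_id, alters, ties = NULL) {
  if (length(patient_id) != 1L || is.na(patient_id) || !nzchar(patient_id)) {
    stop("`patient_id` must be a single non-empty string", call. = FALSE)
  }
  patient_id <- as.character(patient_id)
  alters <- as_alter_table(alters, patient_id)
  ties <- as_tie_table(ties, alters$alter_id, patient_id)
  structure(
    list(patient_id = patient_id, alters = alters, ties = ties),
    class = "ego_network"
  )
}

alter_attr_cols <- c("is_kin", "age", "sex", "race", "exerciser", "had_stroke")

as_alter_table <- function(alters, patient_id) {
  if (is.null(alters)) {
    alters <- data.frame(alter_id = character(), tie_to_ego = character())
  }
  alters <- tibble::as_tibble(alters)
  if (!"alter_id" %in% names(alters)) {
    stop("alter table for patient '", patient_id, "' lacks an alter_id column",
         call. = FALSE)
  }
  alters$alter_id <- as.character(alters$alter_id)
  if (anyNA(alters$alter_id) || anyDuplicated(alters$alter_id)) {
    stop("alter_id must be unique and non-missing within patient '",
         patient_id, "'", call. = FALSE)
  }
  if (!"tie_to_ego" %in% names(alters)) alters$tie_to_ego <- NA_character_
  # unrated ego ties default to strong: name-generator alters are core contacts
  alters$tie_to_ego <- ifelse(is.na(alters$tie_to_ego), "strong",
                              as.character(alters$tie_to_ego))
  bad <- !alters$tie_to_ego %in% c("strong", "weak")
  if (any(bad)) {
    stop("invalid tie_to_ego '", alters$tie_to_ego[which(bad)[1]],
         "' for patient '", patient_id, "' (must be strong/weak)",
         call. = FALSE)
  }
  for (col in alter_attr_cols) {
    if (!col %in% names(alters)) {
      alters[[col]] <- if (col == "age") NA_real_ else
        if (col %in% c("sex", "race")) NA_character_ else NA
    }
  }
  for (col in c("is_kin", "exerciser", "had_stroke")) {
    alters[[col]] <- as_optional_logical(alters[[col]], col, patient_id)
  }
  alters$age <- as.numeric(alters$age)
  alters$sex <- check_levels(as.character(alters$sex), c("female", "male"),
                             "sex", patient_id)
  alters$race <- as.character(alters$race)
  alters[, c("alter_id", "is_kin", "age", "sex", "race", "exerciser",
             "had_stroke", "tie_to_ego")]
}

as_tie_table <- function(ties, alter_ids, patient_id) {
  if (is.null(ties) || nrow(ties) == 0L) {
    return(tibble::tibble(alter_a = character(), alter_b = character(),
                          strength = character()))
  }
  ties <- tibble::as_tibble(ties)
  need <- c("alter_a", "alter_b", "strength")
  if (!all(need %in% names(ties))) {
    stop("tie table for patient '", patient_id,
         "' must have columns alter_a, alter_b, strength", call. = FALSE)
  }
  ties$alter_a <- as.character(ties$alter_a)
  ties$alter_b <- as.character(ties$alter_b)
  ties$strength <- check_levels(as.character(ties$strength),
                                c("strong", "weak"), "strength", patient_id)
  if (anyNA(ties$strength)) {
    stop("missing tie strength for patient '", patient_id, "'", call. = FALSE)
  }
  unknown <- setdiff(c(ties$alter_a, ties$alter_b), alter_ids)
  if (length(unknown)) {
    stop("tie for patient '", patient_id, "' references unknown alter id '",
         unknown[1], "'", call. = FALSE)
  }
  if (any(ties$alter_a == ties$alter_b)) {
    stop("self-tie for patient '", patient_id, "'", call. = FALSE)
  }
  key <- paste(pmin(ties$alter_a, ties$alter_b),
               pmax(ties$alter_a, ties$alter_b))
  if (anyDuplicated(key)) {
    stop("duplicate unordered tie pair for patient '", patient_id, "'",
         call. = FALSE)
  }
  # canonical orientation: alter_a < alter_b, sorted — order-independent storage
  a <- pmin(ties$alter_a, ties$alter_b)
  b <- pmax(ties$alter_a, ties$alter_b)
  ord <- order(a, b)
  tibble::tibble(alter_a = a[ord], alter_b = b[ord],
                 strength = ties$strength[ord])
}

as_optional_logical <- function(x, col, patient_id) {
  if (is.logical(x)) return(x)
  x <- suppressWarnings(as.numeric(x))
  if (any(!is.na(x) & !x %in% c(0, 1))) {
    stop("column ", col, " for patient '", patient_id,
         "' must be 0/1 or missing", call. = FALSE)
  }
  as.logical(x)
}

check_levels <- function(x, levels, col, patient_id) {
  bad <- !is.na(x) & !x %in% levels
  if (any(bad)) {
    stop("invalid ", col, " value '", x[which(bad)[1]], "' for patient '",
         patient_id, "' (allowed: ", paste(levels, collapse = ", "), ")",
         call. = FALSE)
  }
  x
}

#' @export
print.ego_network <- function(x, ...) {
  cat("<ego_network> patient", x$patient_id, "—", nrow(x$alters),
      "alters,", nrow(x$ties), "alter-alter ties\n")
  invisible(x)
}

#' Number of alters in an ego network
#'
#' Network size is the number of named individuals in the personal network,
#' excluding the patient.
#'
#' @param network An [ego_network()].
#' @return Integer count of alters.
#' @export
network_size <- function(network) {
  stopifnot(inherits(network, "ego_network"))
  nrow(network$alters)
}

#' Strong/weak tie weight coding
#'
#' Numeric weights used when building the weighted adjacency matrix for the
#' structural-hole measures. Only the ratio matters (all structural metrics
#' are invariant to uniform rescaling); the conventional 2:1 strong/weak
#' coding is the default.
#'
#' @param w_strong Weight of a strong tie (default 1).
#' @param w_weak Weight of a weak tie (default 0.5). Must satisfy
#'   `w_strong >= w_weak > 0`.
#' @return A `tie_weights` object.
#' @export
tie_weights <- function(w_strong = 1, w_weak = 0.5) {
  stopifnot(is.numeric(w_strong), is.numeric(w_weak),
            length(w_strong) == 1L, length(w_weak) == 1L)
  if (!(w_strong >= w_weak && w_weak > 0)) {
    stop("tie weights must satisfy w_strong >= w_weak > 0", call. = FALSE)
  }
  structure(list(w_strong = as.numeric(w_strong), w_weak = as.numeric(w_weak)),
            class = "tie_weights")
}

patient_cols <- c("patient_id", "arrival_hours", "arrival_hours_gt_cutoff",
                  "cutoff", "age", "nihss", "ems", "living_alone",
                  "education_years", "race_black", "income_k", "married",
                  "sex", "tpa_given")

#' Assemble a paired patient/network cohort
#'
#' @param patients Data frame of per-patient clinical and demographic
#'   covariates, one row per patient. Required: `patient_id`,
#'   `arrival_hours_gt_cutoff` (1 = delayed beyond the cutoff), `cutoff`
#'   (hours, > 0). Recognised covariates: `age`, `nihss` (0–42), `ems`,
#'   `living_alone`, `education_years`, `race_black`, `income_k`, `married`,
#'   `sex`, `tpa_given`, and optionally `arrival_hours` (continuous
#'   onset-to-arrival time, needed to re-derive the outcome at a different
#'   cutoff).
#' @param networks List of [ego_network()] objects, one per patient row
#'   (matched by `patient_id`).
#' @return An `ego_cohort`: list with tibble `patients` and named list
#'   `networks`.
#' @export
ego_cohort <- function(patients, networks) {
  patients <- tibble::as_tibble(patients)
  if (!all(c("patient_id", "arrival_hours_gt_cutoff", "cutoff") %in%
           names(patients))) {
    stop("patients table needs patient_id, arrival_hours_gt_cutoff, cutoff",
         call. = FALSE)
  }
  patients$patient_id <- as.character(patients$patient_id)
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id in patients table", call. = FALSE)
  }
  if (!"arrival_hours" %in% names(patients)) {
    patients$arrival_hours <- NA_real_
  }
  for (col in setdiff(patient_cols,
                      c("patient_id", "sex", names(patients)))) {
    patients[[col]] <- NA_real_
  }
  if (!"sex" %in% names(patients)) patients$sex <- NA_character_
  patients$sex <- check_levels(as.character(patients$sex),
                               c("female", "male"), "sex", "<cohort>")
  for (col in c("arrival_hours_gt_cutoff", "ems", "living_alone",
                "race_black", "married", "tpa_given")) {
    patients[[col]] <- as_optional_logical(patients[[col]], col, "<cohort>")
  }
  for (col in c("arrival_hours", "cutoff", "age", "nihss", "education_years",
                "income_k")) {
    patients[[col]] <- as.numeric(patients[[col]])
  }
  if (any(is.na(patients$cutoff)) || any(patients$cutoff <= 0)) {
    stop("cutoff must be present and > 0 for every patient", call. = FALSE)
  }
  bad_nihss <- !is.na(patients$nihss) &
    (patients$nihss < 0 | patients$nihss > 42)
  if (any(bad_nihss)) {
    stop("nihss outside [0, 42] for patient '",
         patients$patient_id[which(bad_nihss)[1]], "'", call. = FALSE)
  }
  if (anyNA(patients$arrival_hours_gt_cutoff)) {
    stop("arrival_hours_gt_cutoff must be 0/1 for every patient",
         call. = FALSE)
  }
  patients <- patients[, patient_cols]

  stopifnot(is.list(networks))
  ids <- vapply(networks, function(n) {
    stopifnot(inherits(n, "ego_network"))
    n$patient_id
  }, character(1))
  names(networks) <- ids
  missing_net <- setdiff(patients$patient_id, ids)
  if (length(missing_net)) {
    stop("no network for patient '", missing_net[1], "'", call. = FALSE)
  }
  extra <- setdiff(ids, patients$patient_id)
  if (length(extra)) {
    stop("network patient '", extra[1], "' absent from patient table",
         call. = FALSE)
  }
  networks <- networks[patients$patient_id]
  structure(list(patients = patients, networks = networks),
            class = "ego_cohort")
}

#' @export
print.ego_cohort <- function(x, ...) {
  n_slow <- sum(x$patients$arrival_hours_gt_cutoff)
  cat("<ego_cohort>", nrow(x$patients), "patients (", n_slow, "slow /",
      nrow(x$patients) - n_slow, "fast at cutoff",
      unique(x$patients$cutoff)[1], "h )\n")
  invisible(x)
}

#' @export
length.ego_cohort <- function(x) nrow(x$patients)

#' Read a cohort from the three-file CSV interchange format
#'
#' The canonical flat encoding of a surveyed cohort: a patient covariate
#' table, an alter roster, and an alter–alter tie list. Booleans are coded
#' 0/1 and missing values are empty fields. Every alter and tie row must
#' reference a patient present in the patient table; ties must reference
#' known alter ids.
#'
#' @param patients_csv,alters_csv,ties_csv Paths to the three CSV files
#'   (schemas: see [write_cohort()]).
#' @return An [ego_cohort()].
#' @export
read_cohort <- function(patients_csv, alters_csv, ties_csv) {
  for (f in c(patients_csv, alters_csv, ties_csv)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  patients <- readr::read_csv(patients_csv, show_col_types = FALSE,
                              progress = FALSE,
                              col_types = readr::cols(
                                patient_id = "c", sex = "c",
                                .default = readr::col_double()))
  alters <- readr::read_csv(alters_csv, show_col_types = FALSE,
                            progress = FALSE,
                            col_types = readr::cols(
                              patient_id = "c", alter_id = "c", sex = "c",
                              race = "c", tie_to_ego = "c"))
  ties <- readr::read_csv(ties_csv, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            patient_id = "c", alter_a = "c", alter_b = "c",
                            strength = "c"))
  if (nrow(alters) && !"patient_id" %in% names(alters)) {
    stop(alters_csv, ": missing patient_id column", call. = FALSE)
  }
  ids <- as.character(patients$patient_id)
  for (tab in list(list(alters, alters_csv), list(ties, ties_csv))) {
    if (nrow(tab[[1]])) {
      orphan <- setdiff(unique(tab[[1]]$patient_id), ids)
      if (length(orphan)) {
        stop(tab[[2]], ": patient '", orphan[1],
             "' absent from patient table", call. = FALSE)
      }
    }
  }
  networks <- lapply(ids, function(pid) {
    a <- alters[alters$patient_id == pid, , drop = FALSE]
    t <- ties[ties$patient_id == pid, , drop = FALSE]
    ego_network(pid, a[setdiff(names(a), "patient_id")],
                t[setdiff(names(t), "patient_id")])
  })
  ego_cohort(patients, networks)
}

#' Write a cohort to the three-file CSV interchange format
#'
#' Emits `patients.csv`, `alters.csv` and `ties.csv` under `out_dir` in the
#' exact schema [read_cohort()] consumes, with deterministic column and row
#' order, booleans as 0/1 and missing values as empty fields, so that
#' `read_cohort(write_cohort(x))` reproduces `x` exactly.
#'
#' @param cohort An [ego_cohort()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the named character vector of the three file paths.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "ego_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)

  bool01 <- function(df) {
    df[] <- lapply(df, function(x) if (is.logical(x)) as.integer(x) else x)
    df
  }
  paths <- c(patients = file.path(out_dir, "patients.csv"),
             alters = file.path(out_dir, "alters.csv"),
             ties = file.path(out_dir, "ties.csv"))
  readr::write_csv(bool01(cohort$patients), paths["patients"], na = "",
                   progress = FALSE)
  alters <- dplyr::bind_rows(lapply(cohort$networks, function(n) {
    if (nrow(n$alters) == 0L) return(NULL)
    tibble::tibble(patient_id = n$patient_id, n$alters)
  }))
  if (is.null(alters) || nrow(alters) == 0L) {
    alters <- tibble::tibble(patient_id = character(),
                             alter_id = character(), is_kin = logical(),
                             age = numeric(), sex = character(),
                             race = character(), exerciser = logical(),
                             had_stroke = logical(), tie_to_ego = character())
  }
  readr::write_csv(bool01(alters), paths["alters"], na = "", progress = FALSE)
  ties <- dplyr::bind_rows(lapply(cohort$networks, function(n) {
    if (nrow(n$ties) == 0L) return(NULL)
    tibble::tibble(patient_id = n$patient_id, n$ties)
  }))
  if (is.null(ties) || nrow(ties) == 0L) {
    ties <- tibble::tibble(patient_id = character(), alter_a = character(),
                           alter_b = character(), strength = character())
  }
  readr::write_csv(ties, paths["ties"], na = "", progress = FALSE)
  invisible(paths)
}

#' Read one ego network from GraphML
#'
#' Expects a node attribute `role` taking the value `"ego"` on exactly one
#' node and `"alter"` elsewhere, and an edge attribute `strength`
#' (`"strong"`/`"weak"`) on every edge. Ego-incident edges become the
#' alters' `tie_to_ego`; remaining edges become alter–alter ties. Optional
#' alter attributes (`is_kin`, `age`, `sex`, `race`, `exerciser`,
#' `had_stroke`) are read when present, with empty strings and NaN mapped
#' back to missing.
#'
#' @param path GraphML file.
#' @param patient_id Patient id for the resulting network; defaults to the
#'   graph attribute `patient_id`, falling back to the file name.
#' @return An [ego_network()].
#' @export
read_graphml <- function(path, patient_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  g <- igraph::read_graph(path, format = "graphml")
  vat <- igraph::vertex_attr_names(g)
  if (!"role" %in% vat) {
    stop(path, ": no 'role' node attribute designating the ego",
         call. = FALSE)
  }
  role <- igraph::V(g)$role
  if (sum(role == "ego") != 1L) {
    stop(path, ": exactly one node must have role = 'ego'", call. = FALSE)
  }
  if (!"strength" %in% igraph::edge_attr_names(g)) {
    stop(path, ": edges lack a 'strength' attribute", call. = FALSE)
  }
  if (is.null(patient_id)) {
    patient_id <- if ("patient_id" %in% igraph::graph_attr_names(g)) {
      igraph::graph_attr(g, "patient_id")
    } else {
      sub("\\.graphml$", "", basename(path))
    }
  }
  vname <- if ("name" %in% vat) igraph::V(g)$name else
    as.character(seq_len(igraph::vcount(g)))
  ego_idx <- which(role == "ego")
  el <- igraph::as_edgelist(g, names = FALSE)
  strength <- igraph::E(g)$strength
  if (anyNA(strength) || !all(strength %in% c("strong", "weak"))) {
    stop(path, ": edge strength must be 'strong' or 'weak'", call. = FALSE)
  }
  ego_edge <- el[, 1] == ego_idx | el[, 2] == ego_idx

  opt <- function(attr, blank) {
    if (!attr %in% vat) return(rep(blank, igraph::vcount(g)))
    x <- igraph::vertex_attr(g, attr)
    if (is.character(x)) x[!nzchar(x)] <- NA
    if (is.numeric(x)) x[is.nan(x)] <- NA
    x
  }
  alters <- tibble::tibble(
    alter_id = vname,
    is_kin = as_optional_logical(opt("is_kin", NA_real_), "is_kin",
                                 patient_id),
    age = as.numeric(opt("age", NA_real_)),
    sex = as.character(opt("sex", NA_character_)),
    race = as.character(opt("race", NA_character_)),
    exerciser = as_optional_logical(opt("exerciser", NA_real_), "exerciser",
                                    patient_id),
    had_stroke = as_optional_logical(opt("had_stroke", NA_real_),
                                     "had_stroke", patient_id),
    tie_to_ego = NA_character_
  )
  for (e in which(ego_edge)) {
    other <- setdiff(el[e, ], ego_idx)
    alters$tie_to_ego[other] <- strength[e]
  }
  alters <- alters[-ego_idx, , drop = FALSE]
  ties <- tibble::tibble(
    alter_a = vname[el[!ego_edge, 1]],
    alter_b = vname[el[!ego_edge, 2]],
    strength = strength[!ego_edge]
  )
  ego_network(patient_id, alters, ties)
}

#' Write one ego network to GraphML
#'
#' Inverse of [read_graphml()]: the ego appears as a node with
#' `role = "ego"` and id `"ego"`, alters carry their attributes (missing
#' encoded as empty string / NaN), and every edge carries `strength`.
#'
#' @param network An [ego_network()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(network, path) {
  stopifnot(inherits(network, "ego_network"))
  a <- network$alters
  n <- nrow(a)
  blank_chr <- function(x) ifelse(is.na(x), "", as.character(x))
  verts <- data.frame(
    name = c("ego", a$alter_id),
    role = c("ego", rep("alter", n)),
    is_kin = c(NaN, as.numeric(a$is_kin)),
    age = c(NaN, a$age),
    sex = blank_chr(c(NA, a$sex)),
    race = blank_chr(c(NA, a$race)),
    exerciser = c(NaN, as.numeric(a$exerciser)),
    had_stroke = c(NaN, as.numeric(a$had_stroke)),
    stringsAsFactors = FALSE
  )
  edges <- rbind(
    data.frame(from = rep("ego", n), to = a$alter_id,
               strength = a$tie_to_ego, stringsAsFactors = FALSE),
    data.frame(from = network$ties$alter_a, to = network$ties$alter_b,
               strength = network$ties$strength, stringsAsFactors = FALSE)
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  g <- igraph::set_graph_attr(g, "patient_id", network$patient_id)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
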