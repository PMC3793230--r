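#' Synthetic enzyme databases and annotation records with known ground truth
#'
#' Every pipeline stage is testable without downloading any real database
#' release: these generators emit enzyme.dat-style databases with name
#' collisions planted at controlled EC divergence depths, and annotation
#' record sets with planted misassignments, each alongside its exact ground
#' truth. Background names are drawn from an indexed "<substrate> <...>ase"
#' grammar so accidental collisions are impossible by construction.
#'
#' @name synthetic-data
NULL

NAME_SUFFIXES <- c("dehydrogenase", "synthase", "kinase", "reductase",
                   "transferase", "isomerase", "mutase", "carboxylase")

# n unique ECs, components sampled within the real EC grammar
# (class 1-7, subclass/sub-subclass 1-99, serial 1-99), excluding `avoid`.
random_ecs <- function(n, avoid = character()) {
  out <- character(0)
  while (length(out) < n) {
    cand <- sprintf("%d.%d.%d.%d", sample(1:7, n, TRUE), sample(1:99, n, TRUE),
                    sample(1:99, n, TRUE), sample(1:99, n, TRUE))
    out <- setdiff(unique(c(out, setdiff(cand, avoid))), avoid)
  }
  out[seq_len(n)]
}

# a pair of complete ECs whose first difference is exactly at `depth`
ec_pair_at_depth <- function(depth, avoid = character()) {
  stopifnot(depth %in% 1:4)
  repeat {
    base <- c(sample(1:7, 1L), sample(1:99, 1L), sample(1:99, 1L), sample(1:99, 1L))
    a <- base
    b <- base
    pool <- if (depth == 1L) 1:7 else 1:99
    b[depth] <- sample(setdiff(pool, base[depth]), 1L)
    if (depth < 4L) {
      # later components drawn independently; the first difference stays at `depth`
      for (j in (depth + 1L):4L) {
        pool_j <- if (j == 1L) 1:7 else 1:99
        b[j] <- sample(pool_j, 1L)
      }
    }
    pa <- paste(a, collapse = ".")
    pb <- paste(b, collapse = ".")
    if (!pa %in% avoid && !pb %in% avoid && pa != pb) {
      return(c(pa, pb))
    }
  }
}

#' Plan a synthetic enzyme database with planted name collisions
#'
#' @param n_background number of background entries, each with a unique name.
#' @param k_depth named or positional counts of planted collisions per
#'   divergence depth, e.g. `c(2, 0, 1, 3)` plants two depth-1, one depth-3
#'   and three depth-4 collisions.
#' @param n_decoys number of transferred/deleted decoy entries (administrative
#'   records that must never surface in scan output).
#' @param seed RNG seed; every generator output is reproducible from it.
#' @return a `plant_plan` list.
#' @export
plant_plan <- function(n_background = 50, k_depth = c(0, 0, 0, 0),
                       n_decoys = 3, seed = 1) {
  stopifnot(length(k_depth) == 4L, all(k_depth >= 0), n_background >= 0,
            n_decoys >= 0)
  structure(list(n_background = as.integer(n_background),
                 k_depth = as.integer(k_depth),
                 n_decoys = as.integer(n_decoys),
                 seed = as.integer(seed)),
            class = "plant_plan")
}

#' Generate an enzyme database with planted ambiguities and its ground truth
#'
#' Background entries carry unique names; each planted collision reuses one
#' name across two entries whose EC numbers diverge at exactly the requested
#' depth, with the shared name appearing in randomly chosen roles (accepted
#' or alternative on either side — the historical ureidoglycolate collision
#' was an accepted/alternative cross). Transferred and deleted decoys carry
#' an alternative name reusing an indexed name, so any incorrect inclusion
#' of administrative entries would surface as a spurious collision.
#'
#' @param plan a [plant_plan()].
#' @return list with `db` (an `enzyme_db`) and `truth`, a tibble with one
#'   row per planted collision (`name`, `ecs` list, `divergence_depth`,
#'   `severity_class`) sorted like [find_ambiguous_names()] output.
#' @export
generate_enzyme_dat <- function(plan) {
  stopifnot(inherits(plan, "plant_plan"))
  set.seed(plan$seed)
  k <- plan$k_depth
  n_planted_entries <- 2L * sum(k)

  # --- EC ids -------------------------------------------------------------
  planted_pairs <- list()
  used <- character()
  for (depth in 1:4) {
    for (j in seq_len(k[depth])) {
      pr <- ec_pair_at_depth(depth, avoid = used)
      used <- c(used, pr)
      planted_pairs[[length(planted_pairs) + 1L]] <- list(depth = depth, ecs = pr)
    }
  }
  bg_ecs <- random_ecs(plan$n_background, avoid = used)
  used <- c(used, bg_ecs)
  decoy_ecs <- random_ecs(plan$n_decoys, avoid = used)
  target_ecs <- random_ecs(max(plan$n_decoys, 1L), avoid = c(used, decoy_ecs))

  # --- names --------------------------------------------------------------
  bg_names <- sprintf("substrate%04d %s", seq_len(plan$n_background),
                      sample(NAME_SUFFIXES, plan$n_background, TRUE))
  planted_names <- sprintf("shared metabolite%03d %s", seq_len(sum(k)),
                           sample(NAME_SUFFIXES, sum(k), TRUE))
  host_names <- sprintf("host%04d %s", seq_len(2L * sum(k)),
                        sample(NAME_SUFFIXES, max(2L * sum(k), 1L), TRUE)[seq_len(2L * sum(k))])

  entry <- function(id, de, an = character(), status = "active",
                    targets = character()) {
    tibble::tibble(id = id, accepted_name = de, alt_names = list(an),
                   reaction = sprintf("%s + H2O = products", de),
                   cofactors = NA_character_, comments = list(character()),
                   status = status, transfer_targets = list(targets),
                   extra = list(character()))
  }

  rows <- list()
  for (i in seq_len(plan$n_background)) {
    rows[[length(rows) + 1L]] <- entry(bg_ecs[i], bg_names[i])
  }
  truth <- list()
  for (j in seq_along(planted_pairs)) {
    pp <- planted_pairs[[j]]
    nm <- planted_names[j]
    # role pattern of the shared name on the two entries
    roles <- sample(c("de_an", "an_an", "de_de"), 1L)
    h1 <- host_names[2L * j - 1L]
    h2 <- host_names[2L * j]
    if (roles == "de_an") {
      rows[[length(rows) + 1L]] <- entry(pp$ecs[1L], nm)
      rows[[length(rows) + 1L]] <- entry(pp$ecs[2L], h2, an = nm)
    } else if (roles == "an_an") {
      rows[[length(rows) + 1L]] <- entry(pp$ecs[1L], h1, an = nm)
      rows[[length(rows) + 1L]] <- entry(pp$ecs[2L], h2, an = nm)
    } else {
      rows[[length(rows) + 1L]] <- entry(pp$ecs[1L], nm)
      rows[[length(rows) + 1L]] <- entry(pp$ecs[2L], nm)
    }
    truth[[j]] <- tibble::tibble(
      name = nm, ecs = list(sort(pp$ecs)),
      divergence_depth = as.integer(pp$depth),
      severity_class = severity_from_depth(pp$depth)
    )
  }
  # decoys: administrative records whose AN reuses an indexed name
  reusable <- c(bg_names, planted_names)
  for (d in seq_len(plan$n_decoys)) {
    an <- if (length(reusable)) sample(reusable, 1L) else character()
    if (d %% 3L == 0L) {
      rows[[length(rows) + 1L]] <- entry(decoy_ecs[d], "Deleted entry", an = an,
                                         status = "deleted")
    } else {
      tgt <- target_ecs[d]
      rows[[length(rows) + 1L]] <- entry(
        decoy_ecs[d], sprintf("Transferred entry: %s", tgt), an = an,
        status = "transferred", targets = tgt)
    }
  }

  db <- dplyr::bind_rows(rows)
  db <- db[sample(nrow(db)), ]  # input order carries no information
  db <- new_enzyme_db(db)

  truth_tbl <- if (length(truth)) dplyr::bind_rows(truth) else tibble::tibble(
    name = character(), ecs = list(), divergence_depth = integer(),
    severity_class = character())
  truth_tbl <- truth_tbl[order(truth_tbl$divergence_depth, truth_tbl$name), ]
  list(db = db, truth = truth_tbl)
}

#' Plan a synthetic annotation record set
#'
#' @param n_records total number of records.
#' @param frac_conflict fraction of records with a planted name/EC conflict
#'   (EC swapped for an unrelated entry's EC).
#' @param frac_interpolation fraction of records with the interpolation-risk
#'   pattern (an ambiguous name carrying one of its candidate ECs, mimicking
#'   the historical DAL3 record).
#' @param seed RNG seed.
#' @return a `misannotation_plan` list.
#' @export
misannotation_plan <- function(n_records = 100, frac_conflict = 0,
                               frac_interpolation = 0, seed = 1) {
  stopifnot(frac_conflict >= 0, frac_interpolation >= 0,
            frac_conflict + frac_interpolation <= 1, n_records >= 0)
  structure(list(n_records = as.integer(n_records),
                 frac_conflict = frac_conflict,
                 frac_interpolation = frac_interpolation,
                 seed = as.integer(seed)),
            class = "misannotation_plan")
}

#' Generate annotation records with planted misassignments
#'
#' Clean records copy a (name, EC) pair from an active entry whose names are
#' unambiguous in `db`. Conflict records keep such a name but swap the EC
#' for a different entry's EC. Interpolation-risk records use an ambiguous
#' name (divergence depth <= 3) with one of its candidate ECs.
#'
#' @param db an `enzyme_db` with enough active entries for the plan.
#' @param plan a [misannotation_plan()].
#' @return list with `records` (tibble: `record_id`, `protein_name`,
#'   `assigned_ec`, `source_db`, `release_tag`) and `truth` (tibble:
#'   `record_id`, `truth_kind` in clean/name_ec_conflict/interpolation_risk).
#' @export
generate_annotation_records <- function(db, plan) {
  stopifnot(inherits(plan, "misannotation_plan"))
  set.seed(plan$seed + 1L)
  index <- build_name_index(db)
  amb <- find_ambiguous_names(index)
  amb_deep <- amb[amb$divergence_depth <= 3L, ]
  amb_names <- amb$name

  # pool of unambiguous (raw name, ec) pairs from active entries
  active <- db[db$status == "active", ]
  pool_name <- c(active$accepted_name, unlist(active$alt_names))
  pool_ec <- c(active$id, rep(active$id, lengths(active$alt_names)))
  ok <- !normalize_name(pool_name) %in% amb_names
  pool_name <- pool_name[ok]
  pool_ec <- pool_ec[ok]

  n_int <- round(plan$n_records * plan$frac_interpolation)
  n_con <- round(plan$n_records * plan$frac_conflict)
  n_clean <- plan$n_records - n_int - n_con
  if (n_int > 0 && nrow(amb_deep) == 0L) {
    stop("plan infeasible: no ambiguous names with divergence depth <= 3 in the database")
  }
  if ((n_clean > 0 || n_con > 0) && length(pool_name) == 0L) {
    stop("plan infeasible: no unambiguous names in the database")
  }
  all_ecs <- unique(active$id)
  if (n_con > 0 && length(all_ecs) < 2L) {
    stop("plan infeasible: conflicts need at least two distinct ECs")
  }

  mk <- function(kind, n) {
    if (n == 0L) return(NULL)
    if (kind == "clean") {
      i <- sample(length(pool_name), n, replace = TRUE)
      tibble::tibble(protein_name = pool_name[i], assigned_ec = pool_ec[i],
                     truth_kind = "clean")
    } else if (kind == "name_ec_conflict") {
      i <- sample(length(pool_name), n, replace = TRUE)
      wrong <- vapply(pool_ec[i], function(ec) sample(setdiff(all_ecs, ec), 1L),
                      character(1L))
      tibble::tibble(protein_name = pool_name[i], assigned_ec = unname(wrong),
                     truth_kind = "name_ec_conflict")
    } else {
      i <- sample(nrow(amb_deep), n, replace = TRUE)
      tibble::tibble(
        protein_name = amb_deep$name[i],
        assigned_ec = vapply(amb_deep$ecs[i], function(e) sample(e, 1L), character(1L)),
        truth_kind = "interpolation_risk")
    }
  }
  recs <- dplyr::bind_rows(mk("clean", n_clean), mk("name_ec_conflict", n_con),
                           mk("interpolation_risk", n_int))
  if (is.null(recs) || nrow(recs) == 0L) {
    recs <- tibble::tibble(protein_name = character(), assigned_ec = character(),
                           truth_kind = character())
  }
  recs <- recs[sample(nrow(recs)), ]
  recs$record_id <- sprintf("rec%04d", seq_len(nrow(recs)))
  recs$source_db <- "synthetic"
  recs$release_tag <- NA_character_
  list(
    records = recs[, c("record_id", "protein_name", "assigned_ec",
                       "source_db", "release_tag")],
    truth = recs[, c("record_id", "truth_kind")]
  )
}

#' The two-entry recommended-nomenclature fixture
#'
#' The packaged worked example: EC 3.5.3.19 (accepted name "Ureidoglycolate
#' hydrolase", other name "Ureidoglycolate amidohydrolase", reaction
#' Ureidoglycolate + H2O = 2 NH3 + CO2 + glyoxylate) and EC 4.3.2.3
#' (accepted name "Ureidoglycolate lyase", other names "Ureidoglycolatase",
#' "Ureidoglycolase", "Ureidoglycolate hydrolase", reaction Ureidoglycolate
#' = urea + glyoxylate). The name "ureidoglycolate hydrolase" is shared
#' across the two entries — a class-level (depth 1) ambiguity whose use is
#' deprecated.
#'
#' @return an `enzyme_db` with the two entries.
#' @export
ureidoglycolate_fixture <- function() {
  new_enzyme_db(tibble::tibble(
    id = c("3.5.3.19", "4.3.2.3"),
    accepted_name = c("Ureidoglycolate hydrolase", "Ureidoglycolate lyase"),
    alt_names = list(
      "Ureidoglycolate amidohydrolase",
      c("Ureidoglycolatase", "Ureidoglycolase", "Ureidoglycolate hydrolase")
    ),
    reaction = c("Ureidoglycolate + H(2)O = 2 NH(3) + CO(2) + glyoxylate",
                 "Ureidoglycolate = urea + glyoxylate"),
    cofactors = NA_character_,
    comments = list(character(), character()),
    status = "active",
    transfer_targets = list(character(), character()),
    extra = list(character(), character())
  ))
}
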