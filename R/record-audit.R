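#' Audit protein annotation records against a reference name index
#'
#' An annotation record pairs a protein name with an assigned EC number. The
#' auditor flags the patterns behind historical misassignments such as the
#' yeast DAL3 / E. coli AllA case, where proteins named "ureidoglycolate
#' hydrolase" were filed under the ammonia-releasing EC 3.5.3.19 although the
#' name also — and originally — denoted the urea-releasing lyase EC 4.3.2.3.
#'
#' Finding kinds:
#' \describe{
#'   \item{ambiguous_name_usage}{the record's name maps to two or more
#'     distinct EC numbers in the reference index.}
#'   \item{name_ec_conflict}{the name is indexed, an EC is assigned, and the
#'     assigned EC matches none of the indexed candidates (partial numbers
#'     such as `3.5.3.-` match by component prefix and count as consistent).}
#'   \item{interpolation_risk}{the name is ambiguous, the assigned EC matches
#'     one candidate, and another candidate diverges from it at depth <= 3 —
#'     the record may have inherited the wrong branch of the nomenclature,
#'     the interpolation pattern of curation errors.}
#' }
#'
#' @name record-audit
NULL

empty_findings <- function() {
  tibble::tibble(
    record_id = character(), finding_kind = character(),
    candidate_ecs = list(), divergence_depth = integer(),
    explanation = character()
  )
}

#' Audit annotation records
#'
#' @param records tibble/data.frame with columns `record_id` (unique),
#'   `protein_name`, `assigned_ec` (EC string, possibly partial; `NA` or `""`
#'   for absent), and optionally `source_db`, `release_tag`.
#' @param index a `name_index` built with [build_name_index()] from the
#'   reference database.
#' @return tibble of findings, one row per (record, finding kind):
#'   `record_id`, `finding_kind`, `candidate_ecs` (list), `divergence_depth`
#'   (minimum pairwise depth of the candidate set, `NA` when fewer than two
#'   candidates), `explanation`. Records whose names are not indexed yield no
#'   finding; records with an unparseable assigned EC are skipped with a
#'   message.
#' @export
audit_records <- function(records, index) {
  needed <- c("record_id", "protein_name", "assigned_ec")
  if (!all(needed %in% names(records))) {
    stop("annotation records are missing columns: ",
         paste(setdiff(needed, names(records)), collapse = ", "))
  }
  if (anyDuplicated(records$record_id)) {
    stop("record_id values must be unique")
  }

  found <- list()
  add <- function(row) found[[length(found) + 1L]] <<- row
  for (i in seq_len(nrow(records))) {
    rid <- records$record_id[i]
    nm <- normalize_name(records$protein_name[i])
    assigned <- records$assigned_ec[i]
    has_ec <- !is.na(assigned) && nzchar(trimws(assigned))
    if (has_ec && !ec_is_valid(assigned)) {
      message(sprintf("record '%s': unparseable assigned EC '%s'; record skipped",
                      rid, assigned))
      next
    }
    hits <- index[index$name == nm, ]
    candidates <- sort(unique(hits$ec))
    if (length(candidates) == 0L) next

    depth <- NA_integer_
    if (length(candidates) >= 2L) {
      pairs <- utils::combn(candidates, 2L)
      depth <- as.integer(min(ec_divergence_depth(pairs[1L, ], pairs[2L, ])))
      add(tibble::tibble(
        record_id = rid, finding_kind = "ambiguous_name_usage",
        candidate_ecs = list(candidates), divergence_depth = depth,
        explanation = sprintf(
          "name '%s' maps to %d EC numbers (%s), diverging at depth %d",
          nm, length(candidates), paste(candidates, collapse = ", "), depth)
      ))
    }
    if (has_ec) {
      matched <- candidates[ec_matches(assigned, candidates)]
      if (length(matched) == 0L) {
        add(tibble::tibble(
          record_id = rid, finding_kind = "name_ec_conflict",
          candidate_ecs = list(candidates), divergence_depth = depth,
          explanation = sprintf(
            "assigned EC %s matches none of the ECs indexed for name '%s' (%s)",
            assigned, nm, paste(candidates, collapse = ", "))
        ))
      } else if (length(candidates) >= 2L) {
        others <- setdiff(candidates, matched)
        if (length(others) &&
            any(ec_divergence_depth(rep(matched[1L], length(others)), others) <= 3L)) {
          add(tibble::tibble(
            record_id = rid, finding_kind = "interpolation_risk",
            candidate_ecs = list(candidates), divergence_depth = depth,
            explanation = sprintf(
              "assigned EC %s is one of several activities named '%s'; a candidate differing within the first three EC components exists",
              assigned, nm)
          ))
        }
      }
    }
  }
  if (length(found) == 0L) return(empty_findings())
  dplyr::bind_rows(found)
}

#' Read annotation records from a TSV file
#'
#' Expects a header with at least `record_id`, `protein_name`, `assigned_ec`;
#' `source_db` and `release_tag` are carried through when present.
#'
#' @param path TSV file path.
#' @return tibble of annotation records.
#' @export
read_annotation_records <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = character())
  needed <- c("record_id", "protein_name", "assigned_ec")
  if (!all(needed %in% names(df))) {
    stop("annotation TSV is missing columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  }
  df$assigned_ec[df$assigned_ec == ""] <- NA_character_
  tibble::as_tibble(df)
}

#' Write audit findings as TSV
#'
#' @param findings output of [audit_records()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_findings <- function(findings, path) {
  flat <- data.frame(
    record_id = findings$record_id,
    finding_kind = findings$finding_kind,
    candidate_ecs = vapply(findings$candidate_ecs, paste, character(1L),
                           collapse = ";"),
    divergence_depth = findings$divergence_depth,
    explanation = findings$explanation,
    stringsAsFactors = FALSE
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
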