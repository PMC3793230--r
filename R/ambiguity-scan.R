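#' Scan an enzyme database for names shared by several EC numbers
#'
#' The same enzyme name attached to more than one EC number is an occasion
#' for misclassification: a curator reading "ureidoglycolate hydrolase" may
#' pick the ammonia-releasing EC 3.5.3.19 when the urea-releasing EC 4.3.2.3
#' was meant. This module indexes every accepted and alternative name of the
#' active entries of an `enzyme_db`, reports each name carried by two or more
#' distinct EC numbers, and classifies the collision by the depth at which
#' the EC numbers diverge (depth 1 = top-level class differs, the most severe
#' case).
#'
#' @name ambiguity-scan
NULL

#' Build the name -> EC index of an enzyme database
#'
#' Indexes the accepted (`DE`) and alternative (`AN`) names of every *active*
#' entry; transferred and deleted entries contribute nothing (their
#' description text is administrative). Duplicate (name, EC, role) triples
#' are collapsed.
#'
#' @param db an `enzyme_db`.
#' @param normalize logical; pass names through [normalize_name()] (default).
#'   `FALSE` indexes raw names verbatim, for sensitivity analysis of the
#'   normalization rule.
#' @return a `name_index`: tibble with columns `name`, `ec`, `name_role`
#'   (`"accepted"` or `"alternative"`).
#' @export
build_name_index <- function(db, normalize = TRUE) {
  validate_enzyme_db(db)
  active <- db[db$status == "active", ]
  key <- if (normalize) normalize_name else identity
  n_alt <- lengths(active$alt_names)
  idx <- tibble::tibble(
    name = c(if (nrow(active)) key(active$accepted_name) else character(),
             if (sum(n_alt)) key(unlist(active$alt_names)) else character()),
    ec = c(active$id, rep(active$id, n_alt)),
    name_role = c(rep("accepted", nrow(active)), rep("alternative", sum(n_alt)))
  )
  idx <- unique(idx)
  idx <- idx[order(idx$name, idx$ec, idx$name_role), ]
  attr(idx, "normalized") <- normalize
  class(idx) <- c("name_index", class(idx))
  idx
}

#' Find names assigned to more than one EC number
#'
#' One record per indexed name carried by at least two distinct EC numbers.
#' The divergence depth of a record is the minimum pairwise
#' [ec_divergence_depth()] over its EC set — the most severe collision
#' governs. Severity classes: `class_level` (depth 1), `subclass_level`
#' (depth 2 or 3), `serial_only` (depth 4). Output is sorted by (depth,
#' name), so reports are deterministic regardless of input order.
#'
#' @param index a `name_index` from [build_name_index()].
#' @return tibble with columns `name`, `ecs` (list of sorted EC strings),
#'   `assignments` (list of tibbles with `ec`, `name_role`),
#'   `n_ecs`, `divergence_depth`, `severity_class`.
#' @export
find_ambiguous_names <- function(index) {
  groups <- split(seq_len(nrow(index)), index$name)
  keep <- vapply(groups, function(ii) length(unique(index$ec[ii])) >= 2L, logical(1L))
  groups <- groups[keep]
  ec_sets <- lapply(groups, function(ii) sort(unique(index$ec[ii])))
  depths <- vapply(ec_sets, function(ecs) {
    pairs <- utils::combn(ecs, 2L)
    as.integer(min(ec_divergence_depth(pairs[1L, ], pairs[2L, ])))
  }, integer(1L))
  out <- tibble::tibble(
    name = names(groups),
    ecs = unname(ec_sets),
    assignments = unname(lapply(groups, function(ii) {
      tibble::tibble(ec = index$ec[ii], name_role = index$name_role[ii])
    })),
    n_ecs = unname(lengths(ec_sets)),
    divergence_depth = unname(depths),
    severity_class = severity_from_depth(unname(depths))
  )
  out[order(out$divergence_depth, out$name), ]
}

#' Summary count table of an ambiguity scan
#'
#' Per-depth counts plus the two cumulative readings of interest: names whose
#' EC numbers differ somewhere in the first three components (depth <= 3) and
#' names whose EC numbers differ in the first component (depth == 1), so both
#' the nested and the disjoint reading of per-depth counts are recoverable.
#'
#' @param records output of [find_ambiguous_names()].
#' @return named list: `total`, `by_depth` (named counts for depths 1-4),
#'   `depth_le_3`, `depth_1`.
#' @export
summarize_scan <- function(records) {
  by_depth <- vapply(1:4, function(d) sum(records$divergence_depth == d), integer(1L))
  names(by_depth) <- as.character(1:4)
  list(
    total = nrow(records),
    by_depth = by_depth,
    depth_le_3 = sum(by_depth[1:3]),
    depth_1 = by_depth[["1"]]
  )
}

#' Write an ambiguity scan report as TSV
#'
#' One row per ambiguous name: the canonical name, the EC numbers with their
#' name roles joined by semicolons, the divergence depth and the severity
#' class.
#'
#' @param records output of [find_ambiguous_names()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_scan_report <- function(records, path) {
  flat <- data.frame(
    name = records$name,
    ec_assignments = vapply(records$assignments, function(a) {
      paste(sprintf("%s(%s)", a$ec, a$name_role), collapse = ";")
    }, character(1L)),
    divergence_depth = records$divergence_depth,
    severity_class = records$severity_class,
    stringsAsFactors = FALSE
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
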