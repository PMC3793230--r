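#' Read and write ENZYME flat files
#'
#' The ExPASy ENZYME database distributes `enzyme.dat`, a line-coded flat
#' file: each record is a block of two-letter-coded lines (`ID`, `DE`, `AN`,
#' `CA`, `CF`, `CC`, `DR`, ...) terminated by `//`. `DE` and `CA` text may
#' continue over several lines; every `AN` line carries one alternative name.
#' Entries whose description starts with "Transferred entry:" or equals
#' "Deleted entry" are administrative placeholders for renumbered or removed
#' EC classes.
#'
#' @name enzyme-dat
NULL

KNOWN_CODES <- c("ID", "DE", "AN", "CA", "CF", "CC")
PRESERVED_CODES <- c("DR", "PR")  # preserved verbatim, no message

strip_period <- function(x) sub("\\.$", "", x)

new_enzyme_db <- function(entries, release_tag = NULL) {
  db <- tibble::as_tibble(entries)
  validate_enzyme_db(db)
  attr(db, "release_tag") <- release_tag
  class(db) <- c("enzyme_db", class(db))
  db
}

validate_enzyme_db <- function(db) {
  needed <- c("id", "accepted_name", "alt_names", "reaction", "cofactors",
              "comments", "status", "transfer_targets", "extra")
  if (!all(needed %in% names(db))) {
    stop("enzyme database is missing columns: ",
         paste(setdiff(needed, names(db)), collapse = ", "))
  }
  if (anyDuplicated(db$id)) {
    stop("duplicate entry id: ",
         paste(unique(db$id[duplicated(db$id)]), collapse = ", "))
  }
  if (nrow(db) > 0L && !all(ec_is_complete(db$id))) {
    stop("entry ids must be complete EC numbers: ",
         paste(db$id[!ec_is_complete(db$id)], collapse = ", "))
  }
  if (!all(db$status %in% c("active", "transferred", "deleted"))) {
    stop("status must be one of active/transferred/deleted")
  }
  has_targets <- lengths(db$transfer_targets) > 0L
  if (any(has_targets != (db$status == "transferred"))) {
    stop("transfer_targets must be non-empty exactly for transferred entries")
  }
  invisible(db)
}

#' @export
print.enzyme_db <- function(x, ...) {
  cat(sprintf("<enzyme_db> %d entries (%d active, %d transferred, %d deleted)\n",
              nrow(x), sum(x$status == "active"),
              sum(x$status == "transferred"), sum(x$status == "deleted")))
  if (!is.null(attr(x, "release_tag"))) {
    cat("release:", attr(x, "release_tag"), "\n")
  }
  NextMethod()
}

#' Parse text in the enzyme.dat dialect
#'
#' @param text character: either a single string (possibly containing
#'   newlines) or a vector of lines.
#' @param release_tag optional label recorded on the returned database.
#' @return an `enzyme_db`: a tibble with one row per record and columns
#'   `id`, `accepted_name`, `alt_names` (list), `reaction`, `cofactors`,
#'   `comments` (list), `status`, `transfer_targets` (list), `extra` (list of
#'   verbatim preserved lines).
#' @details Multi-line `DE`/`CA` text is concatenated with a single space and
#'   the single terminal period is stripped from stored names and reactions.
#'   Unknown line codes are preserved verbatim in `extra` and reported with a
#'   message, never an error. A malformed `ID` line, a duplicate id, or a
#'   record left unterminated at end of input is an error.
#' @examples
#' db <- parse_enzyme_dat(c("ID   4.3.2.3", "DE   Ureidoglycolate lyase.", "//"))
#' db$accepted_name
#' @export
parse_enzyme_dat <- function(text, release_tag = NULL) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(text)
  }

  entries <- list()
  cur <- NULL
  cur_start <- NA_integer_
  seen_ids <- character()
  terminators <- 0L

  finish <- function(cur) {
    de <- strip_period(paste(cur$de, collapse = " "))
    status <- "active"
    targets <- character()
    if (grepl("^Transferred entry:", de)) {
      status <- "transferred"
      targets <- regmatches(de, gregexpr("[0-9]+\\.[0-9]+\\.[0-9]+\\.n?[0-9]+", de))[[1L]]
    } else if (identical(de, "Deleted entry")) {
      status <- "deleted"
    }
    list(
      id = cur$id,
      accepted_name = de,
      alt_names = list(strip_period(cur$an)),
      reaction = if (length(cur$ca)) strip_period(paste(cur$ca, collapse = " ")) else NA_character_,
      cofactors = if (length(cur$cf)) strip_period(paste(cur$cf, collapse = " ")) else NA_character_,
      comments = list(cur$cc),
      status = status,
      transfer_targets = list(targets),
      extra = list(cur$extra)
    )
  }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (identical(trimws(line), "")) next
    if (startsWith(line, "//")) {
      if (!is.null(cur)) {
        entries[[length(entries) + 1L]] <- finish(cur)
        cur <- NULL
      }
      terminators <- terminators + 1L
      next
    }
    code <- substr(line, 1L, 2L)
    content <- trimws(substr(line, 3L, nchar(line)))
    if (code == "ID") {
      if (!is.null(cur)) {
        stop(sprintf("line %d: new ID before record '%s' was terminated", i, cur$id))
      }
      if (!ec_is_complete(content)) {
        stop(sprintf("line %d: malformed ID line (not a complete EC number): '%s'",
                     i, content))
      }
      if (content %in% seen_ids) {
        stop(sprintf("line %d: duplicate ID '%s'", i, content))
      }
      seen_ids <- c(seen_ids, content)
      cur <- list(id = content, de = character(), an = character(),
                  ca = character(), cf = character(), cc = character(),
                  extra = character())
      cur_start <- i
      next
    }
    if (is.null(cur)) next  # header/preamble outside any record
    switch(code,
      DE = { cur$de <- c(cur$de, content) },
      AN = { cur$an <- c(cur$an, content) },
      CA = { cur$ca <- c(cur$ca, content) },
      CF = { cur$cf <- c(cur$cf, content) },
      CC = { cur$cc <- c(cur$cc, content) },
      {
        if (!code %in% PRESERVED_CODES) {
          message(sprintf("line %d: unknown line code '%s' preserved but ignored", i, code))
        }
        cur$extra <- c(cur$extra, line)
      }
    )
  }
  if (!is.null(cur)) {
    stop(sprintf("unexpected end of input: record '%s' has no '//' terminator", cur$id))
  }

  if (length(entries) == 0L) {
    db <- tibble::tibble(
      id = character(), accepted_name = character(),
      alt_names = list(), reaction = character(), cofactors = character(),
      comments = list(), status = character(), transfer_targets = list(),
      extra = list()
    )
  } else {
    db <- tibble::tibble(
      id = vapply(entries, `[[`, character(1L), "id"),
      accepted_name = vapply(entries, `[[`, character(1L), "accepted_name"),
      alt_names = lapply(entries, function(e) e$alt_names[[1L]]),
      reaction = vapply(entries, `[[`, character(1L), "reaction"),
      cofactors = vapply(entries, `[[`, character(1L), "cofactors"),
      comments = lapply(entries, function(e) e$comments[[1L]]),
      status = vapply(entries, `[[`, character(1L), "status"),
      transfer_targets = lapply(entries, function(e) e$transfer_targets[[1L]]),
      extra = lapply(entries, function(e) e$extra[[1L]])
    )
  }
  db <- new_enzyme_db(db, release_tag = release_tag)
  attr(db, "n_terminators") <- terminators
  db
}

#' Read an enzyme.dat file from disk
#'
#' @param path file path.
#' @inheritParams parse_enzyme_dat
#' @return an `enzyme_db`; see [parse_enzyme_dat()].
#' @export
read_enzyme_dat <- function(path, release_tag = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  # Latin-1 fallback for bytes that are not valid UTF-8
  bad <- !validUTF8(lines)
  if (any(bad)) lines[bad] <- iconv(lines[bad], from = "latin1", to = "UTF-8")
  parse_enzyme_dat(lines, release_tag = release_tag)
}

#' Serialize an enzyme database to the enzyme.dat dialect
#'
#' `parse_enzyme_dat(serialize_enzyme_dat(db))` reproduces `db` exactly
#' (whitespace-normalized). Names, reactions and cofactors regain their
#' terminal period; preserved `extra` lines are emitted verbatim before the
#' record terminator.
#'
#' @param db an `enzyme_db`.
#' @return character vector of lines.
#' @export
serialize_enzyme_dat <- function(db) {
  validate_enzyme_db(db)
  out <- character()
  for (i in seq_len(nrow(db))) {
    rec <- c(
      paste0("ID   ", db$id[i]),
      paste0("DE   ", db$accepted_name[i], "."),
      if (length(db$alt_names[[i]])) paste0("AN   ", db$alt_names[[i]], "."),
      if (!is.na(db$reaction[i])) paste0("CA   ", db$reaction[i], "."),
      if (!is.na(db$cofactors[i])) paste0("CF   ", db$cofactors[i], "."),
      if (length(db$comments[[i]])) paste0("CC   ", db$comments[[i]]),
      db$extra[[i]],
      "//"
    )
    out <- c(out, rec)
  }
  out
}

#' Write an enzyme database to disk in the enzyme.dat dialect
#'
#' @inheritParams serialize_enzyme_dat
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_enzyme_dat <- function(db, path) {
  writeLines(serialize_enzyme_dat(db), path)
  invisible(path)
}

#' Canonical comparison form of an enzyme name
#'
#' Lowercases, trims leading/trailing whitespace, collapses internal
#' whitespace runs to a single space, and strips exactly one terminal period.
#' Nothing else: parentheses are kept and spelling variants
#' ("ureidoglycollate") remain distinct. Idempotent.
#'
#' @param raw character vector of names; empty or whitespace-only elements
#'   are an error.
#' @return character vector of canonical names.
#' @examples
#' normalize_name("Ureidoglycolate hydrolase.")  # "ureidoglycolate hydrolase"
#' @export
normalize_name <- function(raw) {
  if (length(raw) == 0L) return(character())
  if (any(is.na(raw) | trimws(raw) == "")) {
    stop("cannot normalize an empty or whitespace-only name")
  }
  s <- tolower(trimws(raw))
  s <- gsub("[[:space:]]+", " ", s)
  sub("\\.$", "", s)
}
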