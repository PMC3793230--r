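# Independent oracles, deliberately written with different code paths from
# the implementation they check.

# Character-walk name normalization: no regex, single pass.
walk_normalize <- function(s) {
  chars <- strsplit(tolower(s), "")[[1]]
  out <- character(0)
  ws <- c(" ", "\t", "\n", "\r")
  pending_space <- FALSE
  for (ch in chars) {
    if (ch %in% ws) {
      if (length(out)) pending_space <- TRUE
    } else {
      if (pending_space) { out <- c(out, " "); pending_space <- FALSE }
      out <- c(out, ch)
    }
  }
  if (length(out) && out[length(out)] == ".") out <- out[-length(out)]
  paste(out, collapse = "")
}

# Quadratic brute-force ambiguity scan over all (entry, name) occurrences of
# the active entries of a database. Normalization re-implemented inline.
brute_force_ambiguities <- function(db) {
  act <- db[db$status == "active", ]
  nm <- character(0); ec <- character(0)
  for (i in seq_len(nrow(act))) {
    for (raw in c(act$accepted_name[i], act$alt_names[[i]])) {
      s <- tolower(raw)
      s <- gsub("[ \t]+", " ", s)
      s <- sub("^ ", "", s); s <- sub(" $", "", s)
      if (substring(s, nchar(s)) == ".") s <- substring(s, 1, nchar(s) - 1)
      nm <- c(nm, s); ec <- c(ec, act$id[i])
    }
  }
  res <- list()
  for (u in sort(unique(nm))) {
    ecs <- sort(unique(ec[nm == u]))
    if (length(ecs) < 2) next
    depth <- 4L
    for (a in seq_along(ecs)) {
      for (b in seq_along(ecs)) {
        if (b <= a) next
        ca <- strsplit(ecs[a], ".", fixed = TRUE)[[1]]
        cb <- strsplit(ecs[b], ".", fixed = TRUE)[[1]]
        for (j in 1:4) {
          if (ca[j] != cb[j]) { depth <- min(depth, j); break }
        }
      }
    }
    res[[length(res) + 1]] <- list(name = u, ecs = ecs, depth = depth)
  }
  res
}

# Compare scan output with the brute-force oracle (names, EC sets, depths).
expect_scan_matches_oracle <- function(db) {
  got <- find_ambiguous_names(build_name_index(db))
  want <- brute_force_ambiguities(db)
  expect_equal(nrow(got), length(want))
  got <- got[order(got$name), ]
  want <- want[order(vapply(want, `[[`, character(1), "name"))]
  for (i in seq_along(want)) {
    expect_identical(got$name[i], want[[i]]$name)
    expect_identical(got$ecs[[i]], want[[i]]$ecs)
    expect_identical(got$divergence_depth[i], want[[i]]$depth)
  }
  invisible(got)
}

# Structured-content equality of two enzyme databases (attributes ignored).
expect_db_equal <- function(a, b) {
  cols <- c("id", "accepted_name", "alt_names", "reaction", "cofactors",
            "comments", "status", "transfer_targets", "extra")
  for (col in cols) {
    expect_identical(unname(a[[col]]), unname(b[[col]]))
  }
  invisible(TRUE)
}
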