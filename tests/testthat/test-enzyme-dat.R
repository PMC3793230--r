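test_that("a minimal record parses into the expected entry", {
  db <- parse_enzyme_dat(c(
    "ID   4.3.2.3",
    "DE   Ureidoglycolate lyase.",
    "AN   Ureidoglycolatase.",
    "//"
  ))
  expect_equal(nrow(db), 1L)
  expect_identical(db$id, "4.3.2.3")
  expect_identical(db$accepted_name, "Ureidoglycolate lyase")
  expect_identical(db$alt_names[[1]], "Ureidoglycolatase")
  expect_identical(db$status, "active")
})

test_that("an empty stream yields an empty database", {
  db <- parse_enzyme_dat(character())
  expect_equal(nrow(db), 0L)
  expect_identical(serialize_enzyme_dat(db), character())
})

test_that("multi-line DE and CA are concatenated with one space", {
  db <- parse_enzyme_dat(c(
    "ID   1.1.1.1",
    "DE   Alcohol",
    "DE   dehydrogenase.",
    "CA   A primary alcohol + NAD(+) =",
    "CA   an aldehyde + NADH.",
    "//"
  ))
  expect_identical(db$accepted_name, "Alcohol dehydrogenase")
  expect_identical(db$reaction, "A primary alcohol + NAD(+) = an aldehyde + NADH")
})

test_that("transferred and deleted entries get status and targets", {
  db <- parse_enzyme_dat(c(
    "ID   1.1.1.5",
    "DE   Transferred entry: 1.1.1.303 and 1.1.1.304.",
    "//",
    "ID   1.1.1.74",
    "DE   Deleted entry.",
    "//"
  ))
  expect_identical(db$status, c("transferred", "deleted"))
  expect_identical(db$transfer_targets[[1]], c("1.1.1.303", "1.1.1.304"))
  expect_identical(db$transfer_targets[[2]], character())
})

test_that("parse errors carry line numbers and name the offending record", {
  expect_error(parse_enzyme_dat(c("ID   not.an.ec", "//")), "line 1.*malformed ID")
  expect_error(
    parse_enzyme_dat(c("ID   1.1.1.1", "//", "ID   1.1.1.1", "//")),
    "line 3.*duplicate ID '1\\.1\\.1\\.1'")
  expect_error(parse_enzyme_dat(c("ID   1.1.1.1", "DE   X.")),
               "'1\\.1\\.1\\.1'.*no '//' terminator")
})

test_that("unknown line codes are preserved and reported, never fatal", {
  expect_message(
    db <- parse_enzyme_dat(c("ID   1.1.1.1", "DE   X.", "ZZ   mystery", "//")),
    "unknown line code 'ZZ'")
  expect_identical(db$extra[[1]], "ZZ   mystery")
  # DR cross-references are preserved silently
  expect_silent(
    db2 <- parse_enzyme_dat(c("ID   1.1.1.2", "DE   Y.",
                              "DR   P07327, ADH1A_HUMAN;", "//")))
  expect_identical(db2$extra[[1]], "DR   P07327, ADH1A_HUMAN;")
  rt <- parse_enzyme_dat(serialize_enzyme_dat(db2))
  expect_db_equal(db2, rt)
})

test_that("entry count equals the number of record terminators", {
  gen <- generate_enzyme_dat(plant_plan(n_background = 30, k_depth = c(1, 1, 1, 1),
                                        seed = 11))
  txt <- serialize_enzyme_dat(gen$db)
  db <- parse_enzyme_dat(txt)
  expect_equal(nrow(db), sum(txt == "//"))
  expect_equal(nrow(db), attr(db, "n_terminators"))
})

test_that("serialize keeps AN order and emits one AN line per name", {
  db <- parse_enzyme_dat(c("ID   1.1.1.1", "DE   X.", "AN   First name.",
                           "AN   Second name.", "//"))
  txt <- serialize_enzyme_dat(db)
  an <- grep("^AN", txt, value = TRUE)
  expect_identical(an, c("AN   First name.", "AN   Second name."))
})

test_that("parse-serialize round trip is the identity on generated databases", {
  for (seed in c(3, 7)) {
    gen <- generate_enzyme_dat(plant_plan(n_background = 40,
                                          k_depth = c(2, 1, 1, 2), seed = seed))
    rt <- parse_enzyme_dat(serialize_enzyme_dat(gen$db))
    expect_db_equal(gen$db, rt)
  }
})

test_that("file round trip through disk preserves content", {
  gen <- generate_enzyme_dat(plant_plan(n_background = 15, k_depth = c(1, 0, 0, 1),
                                        seed = 5))
  path <- withr::local_tempfile(fileext = ".dat")
  write_enzyme_dat(gen$db, path)
  expect_db_equal(gen$db, read_enzyme_dat(path))
})

test_that("normalize_name applies exactly the documented canonicalization", {
  expect_identical(normalize_name("Ureidoglycolate hydrolase."),
                   "ureidoglycolate hydrolase")
  expect_identical(normalize_name("x"), "x")
  expect_identical(normalize_name("  A  B. "), walk_normalize("  A  B. "))
  # exactly one terminal period is stripped
  expect_identical(normalize_name("a b.."), "a b.")
  # spelling variants are NOT unified
  expect_false(normalize_name("ureidoglycollate lyase") ==
                 normalize_name("ureidoglycolate lyase"))
  expect_error(normalize_name("   "), "empty")
  expect_error(normalize_name(""), "empty")
})

test_that("normalize_name is idempotent and matches the character-walk oracle", {
  set.seed(9)
  pieces <- c("Alpha", "BETA.", "gamma", " ", "\t", "  ", "delta.")
  for (i in 1:40) {
    raw <- paste(sample(pieces, sample(2:5, 1), replace = TRUE), collapse = "")
    if (trimws(raw) == "") next
    once <- normalize_name(raw)
    expect_identical(normalize_name(once), once)
    expect_identical(once, walk_normalize(raw))
  }
})
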