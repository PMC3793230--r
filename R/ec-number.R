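#' Enzyme Commission (EC) number utilities
#'
#' EC numbers are four-component identifiers of the form
#' `class.subclass.sub-subclass.serial` (e.g. `"3.5.3.19"`). The serial may be
#' a preliminary token such as `"n1"`. Partial numbers (e.g. `"3.5.3.-"`) are
#' legal in annotation records but never as database entry ids.
#'
#' @name ec-numbers
NULL

# Split EC strings into a 4-column character matrix ("-" kept verbatim).
# Returns NA rows for strings that do not have exactly four dot-separated
# fields.
ec_split <- function(x) {
  parts <- strsplit(as.character(x), ".", fixed = TRUE)
  out <- matrix(NA_character_, nrow = length(x), ncol = 4L)
  ok <- lengths(parts) == 4L
  if (any(ok)) out[ok, ] <- t(vapply(parts[ok], identity, character(4L)))
  out
}

ec_component_ok <- function(comp, first = FALSE, serial = FALSE, allow_partial = TRUE) {
  ok <- !is.na(comp)
  num <- grepl("^[0-9]+$", comp) & comp != "0"
  if (first) num <- num & suppressWarnings(as.integer(comp)) <= 7L
  if (serial) num <- num | grepl("^n[0-9]+$", comp)
  dash <- allow_partial & comp == "-"
  ok & (num | dash)
}

#' Validate EC number strings
#'
#' @param x character vector of EC numbers.
#' @param allow_partial logical; accept trailing `"-"` components
#'   (`"3.5.3.-"`). Partial numbers must have the dashes as a suffix: once a
#'   component is `"-"`, all later components must be too.
#' @return logical vector.
#' @examples
#' ec_is_valid(c("3.5.3.19", "4.3.2.3", "3.5.3.-", "8.1.1.1"))
#' @export
ec_is_valid <- function(x, allow_partial = TRUE) {
  m <- ec_split(x)
  ok <- ec_component_ok(m[, 1L], first = TRUE, allow_partial = FALSE) &
    ec_component_ok(m[, 2L], allow_partial = allow_partial) &
    ec_component_ok(m[, 3L], allow_partial = allow_partial) &
    ec_component_ok(m[, 4L], serial = TRUE, allow_partial = allow_partial)
  if (allow_partial) {
    # dashes must be a suffix: no numeric component after a "-"
    dash <- !is.na(m) & m == "-"
    suffix_ok <- !(( dash[, 2L] & !(dash[, 3L] & dash[, 4L])) |
                   ( dash[, 3L] & !dash[, 4L]))
    ok <- ok & suffix_ok
  }
  ok & !is.na(ok)
}

#' @rdname ec_is_valid
#' @export
ec_is_complete <- function(x) {
  ec_is_valid(x, allow_partial = FALSE)
}

#' Depth at which two complete EC numbers diverge
#'
#' Returns the 1-based index of the first component where `a` and `b` differ:
#' depth 1 means the top-level class differs (substantially different
#' activities, e.g. hydrolase vs lyase), depth 4 means only the serial number
#' differs (essentially the same enzyme). Vectorized over pairs.
#'
#' @param a,b character vectors of complete EC numbers; recycled to a common
#'   length. `a[i] == b[i]` is an error (the depth is undefined), as are
#'   partial or invalid numbers.
#' @return integer vector in 1:4.
#' @examples
#' ec_divergence_depth("3.5.3.19", "4.3.2.3")   # 1
#' ec_divergence_depth("3.5.3.19", "3.5.1.5")   # 3
#' @export
ec_divergence_depth <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  if (!all(ec_is_complete(a)) || !all(ec_is_complete(b))) {
    stop("divergence depth requires complete EC numbers (no partial components)")
  }
  if (any(a == b)) {
    stop("divergence depth is undefined for identical EC numbers: ",
         paste(unique(a[a == b]), collapse = ", "))
  }
  ma <- ec_split(a)
  mb <- ec_split(b)
  diff1 <- ma != mb
  apply(diff1, 1L, function(d) which(d)[1L])
}

#' Match an (optionally partial) assigned EC against candidate ECs
#'
#' A partial number such as `"3.5.3.-"` matches any candidate sharing its
#' non-dash prefix components; complete numbers match by equality.
#'
#' @param assigned single EC string, possibly partial.
#' @param candidates character vector of complete EC numbers.
#' @return logical vector along `candidates`.
#' @export
ec_matches <- function(assigned, candidates) {
  stopifnot(length(assigned) == 1L)
  if (!ec_is_valid(assigned)) stop("invalid EC number: ", assigned)
  ma <- ec_split(assigned)[1L, ]
  mc <- ec_split(candidates)
  keep <- ma != "-"
  apply(mc, 1L, function(row) all(row[keep] == ma[keep]))
}

severity_from_depth <- function(depth) {
  out <- rep(NA_character_, length(depth))
  out[depth == 4L] <- "serial_only"
  out[depth %in% c(2L, 3L)] <- "subclass_level"
  out[depth == 1L] <- "class_level"
  out
}
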