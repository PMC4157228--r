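#' Parse and normalize Enzyme Commission (EC) numbers
#'
#' An EC number has four dot-separated fields, `class.subclass.subsubclass.serial`,
#' e.g. `1.1.1.1` (alcohol dehydrogenase). Trailing fields may be unspecified;
#' the canonical rendering writes those as `-`, so `1.14.13` normalizes to
#' `1.14.13.-`. Wildcards are suffix-only: a numeric field may never follow a
#' `-`. An optional `EC ` or `ec:` prefix is stripped. The first field is the
#' enzyme class, 1-7 in the current nomenclature; class 9 is additionally
#' accepted as a reserved range for synthetic identifiers (see
#' [fixture_spec()]).
#'
#' Matching throughout the package is exact on the canonical string: a partial
#' EC (`1.1.1.-`) never matches a complete one (`1.1.1.1`), since hierarchical
#' expansion would silently inflate overlap counts.
#'
#' @param x Character vector of raw EC tokens.
#' @return `ec_parse()`: character vector of canonical EC strings.
#'   `ec_is_valid()`: logical vector.
#' @examples
#' ec_parse(c("1.1.1.1", "ec:2.7.11.1", "1.14.13"))
#' ec_is_valid(c("1.1.1.1", "1.-.2.3"))
#' @export
ec_parse <- function(x) {
  vapply(x, ec_parse_one, character(1), USE.NAMES = FALSE)
}

#' @rdname ec_parse
#' @export
ec_is_valid <- function(x) {
  vapply(x, function(tok) {
    !is.na(tryCatch(ec_parse_one(tok), keggcomp_parse_error = function(e) NA_character_))
  }, logical(1), USE.NAMES = FALSE)
}

ec_parse_one <- function(raw) {
  if (length(raw) != 1L || is.na(raw)) {
    abort_parse("EC token must be a single non-missing string")
  }
  tok <- stringr::str_trim(raw)
  if (!nzchar(tok)) {
    abort_parse("empty EC token")
  }
  tok <- stringr::str_remove(tok, stringr::regex("^ec[: ]\\s*", ignore_case = TRUE))
  fields <- stringr::str_split_1(tok, stringr::fixed("."))
  if (length(fields) < 1L || length(fields) > 4L || any(!nzchar(fields))) {
    abort_parse(sprintf("malformed EC number '%s': expected 1-4 dot-separated fields", raw))
  }
  fields <- c(fields, rep("-", 4L - length(fields)))
  is_wild <- fields == "-"
  is_num <- stringr::str_detect(fields, "^[0-9]+$")
  if (any(!is_wild & !is_num)) {
    bad <- fields[!is_wild & !is_num][1]
    abort_parse(sprintf("malformed EC number '%s': field '%s' is neither numeric nor '-'", raw, bad))
  }
  if (any(is_num & cumsum(is_wild) > 0L)) {
    abort_parse(sprintf("malformed EC number '%s': numeric field after a wildcard", raw))
  }
  if (is_wild[1]) {
    abort_parse(sprintf("malformed EC number '%s': class field may not be a wildcard", raw))
  }
  cls <- as.integer(fields[1])
  if (!(cls %in% c(1:7, 9L))) {
    abort_parse(sprintf(
      "malformed EC number '%s': class %d outside 1-7 (or reserved synthetic class 9)", raw, cls
    ))
  }
  # drop leading zeros in numeric fields so equality is on value, not spelling
  fields[is_num] <- as.character(as.integer(fields[is_num]))
  paste(fields, collapse = ".")
}
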