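#' Construct a query set of EC numbers
#'
#' Normally produced by [read_query()] or [generate_query()]; the constructor
#' is exported so programmatic queries can enter the pipeline directly.
#' Duplicates collapse to one member; canonical order is first-seen.
#'
#' @param ecs Character vector of EC tokens (parsed via [ec_parse()]).
#' @param n_input_lines Number of input lines the set was read from.
#' @param n_rejected Number of unparseable lines skipped.
#' @param source Free-text origin (file name or generator tag).
#' @return An object of class `query_set` with fields `ecs` (deduplicated,
#'   first-seen order), `n_input_lines`, `n_rejected`, `source`.
#' @export
query_set <- function(ecs, n_input_lines = length(ecs), n_rejected = 0L,
                      source = "<memory>") {
  ecs <- unique(ec_parse(as.character(ecs)))
  structure(
    list(
      ecs = ecs,
      n_input_lines = as.integer(n_input_lines),
      n_rejected = as.integer(n_rejected),
      source = source
    ),
    class = "query_set"
  )
}

#' @export
print.query_set <- function(x, ...) {
  cat(sprintf("<query_set> %d distinct ECs from %d lines (%d rejected) [%s]\n",
    length(x$ecs), x$n_input_lines, x$n_rejected, x$source))
  invisible(x)
}

#' Read a query list of EC numbers from a text file
#'
#' One EC per line; if a line has several whitespace- or tab-separated
#' columns, the first column is taken. Blank lines and lines starting with
#' `#` are ignored. Unparseable tokens are counted, reported as a warning
#' with their line numbers, and skipped; a file yielding zero valid ECs is
#' an error.
#'
#' @param file Path to the query file.
#' @return A [query_set()].
#' @export
read_query <- function(file) {
  if (!file.exists(file)) {
    abort_data(sprintf("query file not found: %s", file))
  }
  lines <- readLines(file, encoding = "UTF-8")
  content <- which(nzchar(stringr::str_trim(lines)) & !stringr::str_starts(lines, "#"))
  tokens <- stringr::str_split_i(stringr::str_trim(lines[content]), "[\t ]+", 1L)
  ok <- ec_is_valid(tokens)
  if (any(!ok)) {
    rlang::warn(sprintf("skipped %d unparseable query line(s): %s",
      sum(!ok), paste(content[!ok], collapse = ", ")))
  }
  if (!any(ok)) {
    abort_data(sprintf("query file %s contains no valid EC numbers (%d lines rejected)",
      file, length(tokens)))
  }
  query_set(ec_parse(tokens[ok]),
    n_input_lines = length(content),
    n_rejected = sum(!ok),
    source = basename(file)
  )
}

pathway_universal_ecs <- function(defs, pathway_id) {
  defs$ec_links$ec[defs$ec_links$pathway_id == pathway_id]
}

#' Partition the enzymes of one pathway into shared and unique sets
#'
#' For pathway `p`: `shared` is the intersection of the query with the
#' reference organism's annotated ECs in `p`; `unique_ref` the reference ECs
#' absent from the query; `unique_query` the query ECs that belong to the
#' pathway's universal EC set but are not annotated in the reference. Mapping
#' the query through the universal set (rather than the reference's own) is
#' what lets query enzymes absent from the reference still count as
#' in-pathway. The three sets are pairwise disjoint.
#'
#' @param query A [query_set()].
#' @param ref An [organism_annotation()].
#' @param defs The [definitions_set()] supplying universal pathway EC sets.
#' @param pathway_id Pathway identifier.
#' @return A list of class `pathway_partition` with sorted character vectors
#'   `shared`, `unique_query`, `unique_ref` and the `pathway_id`.
#' @export
partition_pathway <- function(query, ref, defs, pathway_id) {
  if (!pathway_id %in% defs$pathways$pathway_id) {
    abort_data(sprintf("unknown pathway id '%s'", pathway_id))
  }
  universal <- pathway_universal_ecs(defs, pathway_id)
  ref_ecs <- ref$pathway_ecs[[pathway_id]] %||% character(0)
  structure(
    list(
      pathway_id = pathway_id,
      shared = sort_c(intersect(query$ecs, ref_ecs)),
      unique_query = sort_c(setdiff(intersect(query$ecs, universal), ref_ecs)),
      unique_ref = sort_c(setdiff(ref_ecs, query$ecs))
    ),
    class = "pathway_partition"
  )
}

#' Compare the non-mapped enzyme complements
#'
#' An EC is non-mapped when it belongs to no pathway's universal EC set.
#' The query's non-mapped ECs are split into those also annotated in the
#' reference organism (`shared`), those absent from it (`unique_query`),
#' and the reference's own non-mapped ECs missing from the query
#' (`unique_ref`).
#'
#' @inheritParams partition_pathway
#' @return A list of class `nonmapped_partition` with sorted character
#'   vectors `shared`, `unique_query`, `unique_ref`.
#' @export
partition_nonmapped <- function(query, ref, defs) {
  mapped_universe <- unique(defs$ec_links$ec)
  q_nm <- setdiff(query$ecs, mapped_universe)
  r_nm <- setdiff(ref$all_ecs, mapped_universe)
  structure(
    list(
      shared = sort_c(intersect(q_nm, r_nm)),
      unique_query = sort_c(setdiff(q_nm, r_nm)),
      unique_ref = sort_c(setdiff(r_nm, q_nm))
    ),
    class = "nonmapped_partition"
  )
}
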