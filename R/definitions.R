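#' Definitions sets: organisms, pathways, EC links, organism annotations
#'
#' A definitions set is the local cache all other functionality consumes. It
#' holds four components mirroring the flat-file dialect of the definitions
#' directory (see [load_definitions()]):
#'
#' * `organisms`: tibble with `code` (KEGG-style lowercase mnemonic, e.g.
#'   `spo`), `name`, `taxonomy`;
#' * `pathways`: tibble with `pathway_id` (5-digit text, e.g. `00250`),
#'   `name`, `category`;
#' * `ec_links`: tibble with `ec`, `pathway_id` — the universal many-to-many
#'   EC-to-pathway map;
#' * `annotations`: named list of organism annotations (see
#'   [organism_annotation()]).
#'
#' All components are canonically ordered (sorted by identifier) so that two
#' sets with the same content compare equal and serialize byte-identically.
#'
#' @param organisms,pathways,ec_links Data frames as described above.
#' @param annotations Named list of `organism_annotation` objects.
#' @param version_stamp Free-text provenance stamp (fetch date or fixture seed).
#' @return An object of class `kegg_definitions`.
#' @seealso [load_definitions()], [save_definitions()], [query_reference()]
#' @export
definitions_set <- function(organisms = NULL, pathways = NULL, ec_links = NULL,
                            annotations = list(), version_stamp = "unversioned") {
  empty_chr <- character(0)
  organisms <- as_tibble(organisms %||%
    tibble(code = empty_chr, name = empty_chr, taxonomy = empty_chr))
  pathways <- as_tibble(pathways %||%
    tibble(pathway_id = empty_chr, name = empty_chr, category = empty_chr))
  ec_links <- as_tibble(ec_links %||% tibble(ec = empty_chr, pathway_id = empty_chr))

  organisms <- arrange(organisms[c("code", "name", "taxonomy")], .data$code)
  pathways <- arrange(pathways[c("pathway_id", "name", "category")], .data$pathway_id)
  ec_links <- arrange(distinct(ec_links[c("ec", "pathway_id")]), .data$ec, .data$pathway_id)
  annotations <- annotations[sort_c(names(annotations) %||% character(0))]

  defs <- structure(
    list(
      organisms = organisms,
      pathways = pathways,
      ec_links = ec_links,
      annotations = annotations,
      version_stamp = as.character(version_stamp)
    ),
    class = "kegg_definitions"
  )
  validate_definitions(defs)
  defs
}

#' Per-organism annotation
#'
#' Holds what the definitions know about one reference organism: its genome
#' gene total (the enrichment background), gene counts and annotated EC sets
#' per pathway, and the global EC list including enzymes mapped to no pathway.
#' Gene and EC counts are deliberately distinct: one gene may carry several
#' ECs and one EC may be carried by several genes, so the per-pathway gene
#' count is not derivable from the EC set.
#'
#' @param code Organism code.
#' @param total_genes Count of all genes in the genome.
#' @param pathway_genes Named integer vector, pathway id -> gene count.
#' @param pathway_ecs Named list, pathway id -> character vector of canonical ECs.
#' @param all_ecs Character vector: every EC annotated anywhere in the organism.
#' @return An object of class `organism_annotation`.
#' @export
organism_annotation <- function(code, total_genes, pathway_genes = integer(0),
                                pathway_ecs = list(), all_ecs = character(0)) {
  pathway_genes <- pathway_genes[sort_c(names(pathway_genes) %||% character(0))]
  pathway_ecs <- pathway_ecs[sort_c(names(pathway_ecs) %||% character(0))]
  pathway_ecs <- lapply(pathway_ecs, function(e) sort_c(unique(e)))
  if (!length(pathway_genes)) pathway_genes <- stats::setNames(integer(0), character(0))
  if (!length(pathway_ecs)) pathway_ecs <- stats::setNames(list(), character(0))
  structure(
    list(
      code = as.character(code),
      total_genes = as.integer(total_genes),
      pathway_genes = stats::setNames(as.integer(pathway_genes), names(pathway_genes)),
      pathway_ecs = pathway_ecs,
      all_ecs = sort_c(unique(as.character(all_ecs)))
    ),
    class = "organism_annotation"
  )
}

validate_definitions <- function(defs) {
  org <- defs$organisms
  if (anyDuplicated(org$code)) {
    abort_data(sprintf("duplicated organism code(s): %s",
      paste(unique(org$code[duplicated(org$code)]), collapse = ", ")))
  }
  bad_code <- org$code[!stringr::str_detect(org$code, "^[a-z]{2,5}$")]
  if (length(bad_code)) {
    abort_data(sprintf("invalid organism code(s): %s (expected 2-5 lowercase letters)",
      paste(bad_code, collapse = ", ")))
  }
  pw <- defs$pathways
  if (anyDuplicated(pw$pathway_id)) {
    abort_data(sprintf("duplicated pathway id(s): %s",
      paste(unique(pw$pathway_id[duplicated(pw$pathway_id)]), collapse = ", ")))
  }
  bad_pid <- pw$pathway_id[!stringr::str_detect(pw$pathway_id, "^[0-9]{5}$")]
  if (length(bad_pid)) {
    abort_data(sprintf("invalid pathway id(s): %s (expected 5 digits)",
      paste(bad_pid, collapse = ", ")))
  }
  dangling <- setdiff(defs$ec_links$pathway_id, pw$pathway_id)
  if (length(dangling)) {
    abort_data(sprintf("EC links reference unknown pathway id(s): %s",
      paste(sort_c(dangling), collapse = ", ")))
  }
  ann_codes <- names(defs$annotations)
  orphan_ann <- setdiff(ann_codes, org$code)
  if (length(orphan_ann)) {
    abort_data(sprintf("annotations for organism(s) absent from the organism table: %s",
      paste(orphan_ann, collapse = ", ")))
  }
  for (ann in defs$annotations) {
    validate_annotation(ann, pw$pathway_id)
  }
  invisible(defs)
}

validate_annotation <- function(ann, known_pathways) {
  pids <- union(names(ann$pathway_genes), names(ann$pathway_ecs))
  dangling <- setdiff(pids, known_pathways)
  if (length(dangling)) {
    abort_data(sprintf("annotation for '%s' references unknown pathway id(s): %s",
      ann$code, paste(sort_c(dangling), collapse = ", ")))
  }
  stray <- setdiff(unlist(ann$pathway_ecs, use.names = FALSE), ann$all_ecs)
  if (length(stray)) {
    abort_data(sprintf("annotation for '%s': pathway EC(s) missing from the global EC list: %s",
      ann$code, paste(sort_c(stray), collapse = ", ")))
  }
  n_ecs <- lengths(ann$pathway_ecs)
  has_ecs <- names(n_ecs)[n_ecs > 0L]
  uncounted <- has_ecs[!(has_ecs %in% names(ann$pathway_genes)) |
    ann$pathway_genes[has_ecs] < 1L]
  uncounted <- uncounted[!is.na(uncounted)]
  if (length(uncounted)) {
    abort_data(sprintf("annotation for '%s': pathway(s) with ECs but no positive gene count: %s",
      ann$code, paste(uncounted, collapse = ", ")))
  }
  if (length(ann$pathway_genes) && ann$total_genes < max(ann$pathway_genes)) {
    abort_data(sprintf("annotation for '%s': total_genes (%d) below a pathway gene count (%d)",
      ann$code, ann$total_genes, max(ann$pathway_genes)))
  }
  invisible(ann)
}

definitions_files <- function() {
  c(organisms = "kegg_org.txt", pathways = "kegg_pathways.txt", ec_links = "kegg_ec.txt")
}

# -- flat-file reading ---------------------------------------------------

read_def_file <- function(path, n_fields, what) {
  if (!file.exists(path)) {
    abort_data(sprintf("definitions file missing: %s", basename(path)))
  }
  lines <- readLines(path, encoding = "UTF-8")
  keep <- which(nzchar(stringr::str_trim(lines)) & !stringr::str_starts(lines, "#"))
  rows <- stringr::str_split(lines[keep], stringr::fixed("\t"))
  bad <- which(lengths(rows) < n_fields)
  if (length(bad)) {
    abort_data(sprintf("%s line %d: expected at least %d tab-separated fields",
      basename(path), keep[bad[1]], n_fields))
  }
  list(rows = rows, line_no = keep, lines = lines)
}

#' Load a definitions directory
#'
#' Reads the four-file tab-delimited definitions dialect:
#'
#' * `kegg_org.txt` — `code<TAB>name<TAB>taxonomy`;
#' * `kegg_pathways.txt` — `pathway_id<TAB>name<TAB>category`;
#' * `kegg_ec.txt` — `ec<TAB>pathway_id`, one link per line;
#' * `org_<code>.txt` per annotated organism — records tagged in column 1:
#'   `TOTAL<TAB>total_genes`, `PGENES<TAB>pathway_id<TAB>count`,
#'   `PEC<TAB>pathway_id<TAB>ec`, `EC<TAB>ec`.
#'
#' Lines starting with `#` are comments; a `# version:` comment in
#' `kegg_org.txt` carries the version stamp. Malformed input (missing file,
#' duplicate identifiers, dangling pathway references) raises a typed error
#' naming the file and line; nothing is silently repaired. Line order in the
#' files does not affect the resulting set.
#'
#' @param directory Path to the definitions directory.
#' @return A [definitions_set()].
#' @export
load_definitions <- function(directory) {
  if (!dir.exists(directory)) {
    abort_data(sprintf("definitions directory not found: %s", directory))
  }
  fo <- read_def_file(file.path(directory, "kegg_org.txt"), 2L, "organisms")
  version <- stringr::str_match(fo$lines, "^#\\s*version:\\s*(.+)$")[, 2]
  version <- version[!is.na(version)][1]
  orgs <- tibble(
    code = vapply(fo$rows, `[[`, "", 1L),
    name = vapply(fo$rows, `[[`, "", 2L),
    taxonomy = vapply(fo$rows, function(r) if (length(r) >= 3L) r[[3L]] else "", "")
  )
  dup <- which(duplicated(orgs$code))
  if (length(dup)) {
    abort_data(sprintf("kegg_org.txt line %d: duplicated organism code '%s'",
      fo$line_no[dup[1]], orgs$code[dup[1]]))
  }

  fp <- read_def_file(file.path(directory, "kegg_pathways.txt"), 2L, "pathways")
  pws <- tibble(
    pathway_id = vapply(fp$rows, `[[`, "", 1L),
    name = vapply(fp$rows, `[[`, "", 2L),
    category = vapply(fp$rows, function(r) if (length(r) >= 3L) r[[3L]] else "Uncategorized", "")
  )
  dup <- which(duplicated(pws$pathway_id))
  if (length(dup)) {
    abort_data(sprintf("kegg_pathways.txt line %d: duplicated pathway id '%s'",
      fp$line_no[dup[1]], pws$pathway_id[dup[1]]))
  }

  fe <- read_def_file(file.path(directory, "kegg_ec.txt"), 2L, "ec links")
  links <- tibble(
    ec = ec_parse(vapply(fe$rows, `[[`, "", 1L)),
    pathway_id = vapply(fe$rows, `[[`, "", 2L)
  )
  dangle <- which(!(links$pathway_id %in% pws$pathway_id))
  if (length(dangle)) {
    abort_data(sprintf("kegg_ec.txt line %d: unknown pathway id '%s'",
      fe$line_no[dangle[1]], links$pathway_id[dangle[1]]))
  }

  annotations <- list()
  for (code in orgs$code) {
    org_path <- file.path(directory, sprintf("org_%s.txt", code))
    if (file.exists(org_path)) {
      annotations[[code]] <- read_org_file(org_path, code)
    }
  }

  definitions_set(orgs, pws, links, annotations,
    version_stamp = version %||% "unversioned")
}

read_org_file <- function(path, code) {
  f <- read_def_file(path, 2L, "organism annotation")
  total <- NA_integer_
  pgenes <- integer(0)
  pecs <- list()
  ecs <- character(0)
  for (i in seq_along(f$rows)) {
    r <- f$rows[[i]]
    tag <- r[[1L]]
    if (tag == "TOTAL") {
      total <- as.integer(r[[2L]])
    } else if (tag == "PGENES") {
      if (length(r) < 3L) {
        abort_data(sprintf("%s line %d: PGENES needs pathway id and count", basename(path), f$line_no[i]))
      }
      pgenes[[r[[2L]]]] <- as.integer(r[[3L]])
    } else if (tag == "PEC") {
      if (length(r) < 3L) {
        abort_data(sprintf("%s line %d: PEC needs pathway id and EC", basename(path), f$line_no[i]))
      }
      pecs[[r[[2L]]]] <- c(pecs[[r[[2L]]]], ec_parse(r[[3L]]))
    } else if (tag == "EC") {
      ecs <- c(ecs, ec_parse(r[[2L]]))
    } else {
      abort_data(sprintf("%s line %d: unknown record tag '%s'", basename(path), f$line_no[i], tag))
    }
  }
  if (is.na(total)) {
    abort_data(sprintf("%s: missing TOTAL record", basename(path)))
  }
  organism_annotation(code, total, pgenes, pecs, ecs)
}

#' Save a definitions set as a definitions directory
#'
#' Writes the canonical flat-file dialect read by [load_definitions()]:
#' records sorted by identifier, tab-separated fields, LF line endings, so
#' diffs and checksums are stable across platforms and
#' `load_definitions(save_definitions(d))` reproduces `d` exactly.
#'
#' @param defs A [definitions_set()].
#' @param directory Target directory (created if absent).
#' @return `defs`, invisibly.
#' @export
save_definitions <- function(defs, directory) {
  stopifnot(inherits(defs, "kegg_definitions"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  write_lf <- function(lines, file) {
    con <- file(file.path(directory, file), open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  }
  o <- defs$organisms
  write_lf(c(
    sprintf("# version: %s", defs$version_stamp),
    "# code\tname\ttaxonomy",
    sprintf("%s\t%s\t%s", o$code, o$name, o$taxonomy)
  ), "kegg_org.txt")
  p <- defs$pathways
  write_lf(c("# pathway_id\tname\tcategory",
    sprintf("%s\t%s\t%s", p$pathway_id, p$name, p$category)), "kegg_pathways.txt")
  l <- defs$ec_links
  write_lf(c("# ec\tpathway_id", sprintf("%s\t%s", l$ec, l$pathway_id)), "kegg_ec.txt")
  for (ann in defs$annotations) {
    write_org_file(ann, directory)
  }
  invisible(defs)
}

write_org_file <- function(ann, directory) {
  lines <- c(
    "# record\tfields...",
    sprintf("TOTAL\t%d", ann$total_genes),
    sprintf("PGENES\t%s\t%d", names(ann$pathway_genes), ann$pathway_genes),
    unlist(lapply(names(ann$pathway_ecs), function(pid) {
      sprintf("PEC\t%s\t%s", pid, ann$pathway_ecs[[pid]])
    })),
    sprintf("EC\t%s", ann$all_ecs)
  )
  con <- file(file.path(directory, sprintf("org_%s.txt", ann$code)), open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(ann)
}

#' Look up the annotation of a reference organism
#'
#' @param defs A [definitions_set()].
#' @param code Organism code (lowercase, case-sensitive, KEGG convention).
#' @return The [organism_annotation()] for `code`.
#' @export
query_reference <- function(defs, code) {
  stopifnot(inherits(defs, "kegg_definitions"))
  ann <- defs$annotations[[code]]
  if (is.null(ann)) {
    abort_data(sprintf(
      "unknown reference organism code '%s'; available codes are listed in kegg_org.txt (%s)",
      code, paste(sort_c(names(defs$annotations)), collapse = ", ")
    ))
  }
  ann
}

#' @export
print.kegg_definitions <- function(x, ...) {
  cat(sprintf(
    "<kegg_definitions> %d organisms, %d pathways, %d EC links, %d annotations (version: %s)\n",
    nrow(x$organisms), nrow(x$pathways), nrow(x$ec_links),
    length(x$annotations), x$version_stamp
  ))
  invisible(x)
}
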