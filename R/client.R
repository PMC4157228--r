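# Client for a KEGG-style REST service. Endpoints are plain-text GET:
#   <base>/list/organism, <base>/list/pathway, <base>/link/ec/pathway,
#   <base>/list/<code>, <base>/link/ec/<code>, <base>/link/pathway/<code>
# The base URL is configurable so tests run against a file:// directory tree;
# nothing downstream of a populated definitions directory touches the network.

the_client <- new.env(parent = emptyenv())
the_client$last_request <- -Inf

#' Describe a KEGG-style REST endpoint
#'
#' @param base_url Service root, e.g. `"https://rest.kegg.jp"`; a `file://`
#'   URL pointing at a directory tree works for offline mocks.
#' @param operation `"list"` or `"link"`.
#' @param arguments Character vector of path tokens appended to the
#'   operation, e.g. `"pathway"` or `c("ec", "pathway")`.
#' @return An object of class `kegg_endpoint`; `render_url()` gives the full
#'   URL (`base/operation/arg1/...`).
#' @export
kegg_endpoint <- function(base_url, operation = c("list", "link"), arguments) {
  operation <- match.arg(operation)
  structure(
    list(
      base_url = sub("/+$", "", base_url),
      operation = operation,
      arguments = as.character(arguments)
    ),
    class = "kegg_endpoint"
  )
}

#' @rdname kegg_endpoint
#' @param endpoint A `kegg_endpoint`.
#' @export
render_url <- function(endpoint) {
  paste(c(endpoint$base_url, endpoint$operation, endpoint$arguments), collapse = "/")
}

# Namespace prefixes the client understands; stripping is explicit and
# versioned because KEGG has changed prefixes over time. An unrecognized
# "ns:token" field is an error, never silently kept.
kegg_prefixes <- function() c("path", "ec", "rn", "ko", "cpd", "md")

strip_kegg_prefix <- function(field, extra = character(0)) {
  m <- stringr::str_match(field, "^([A-Za-z0-9]+):(\\S+)$")
  hit <- !is.na(m[, 1])
  if (any(hit)) {
    known <- m[hit, 2] %in% c(kegg_prefixes(), extra)
    if (any(!known)) {
      abort_data(sprintf("unknown KEGG namespace prefix '%s:' in field '%s'",
        m[hit, 2][!known][1], field[hit][!known][1]))
    }
    field[hit] <- m[hit, 3]
  }
  # pathway identifiers carry a second, colon-less "map" prefix
  field <- stringr::str_replace(field, "^map(?=[0-9]{5}$)", "")
  field
}

#' Fetch one endpoint as tab-split records
#'
#' Issues a single GET, honouring a minimum inter-request delay (KEGG asks
#' that its API not be used for bulk downloads; requests are sequential and
#' spaced by `delay` seconds). Each non-empty response line becomes one
#' character-vector record, split on tabs, with known namespace prefixes
#' stripped. Transport failures raise a network error carrying the URL; an
#' empty body raises a distinct empty-response error, since KEGG answers
#' empty for unknown arguments.
#'
#' @param endpoint A [kegg_endpoint()].
#' @param timeout Connection timeout, seconds.
#' @param delay Minimum spacing between consecutive requests, seconds.
#' @param extra_prefixes Additional namespace prefixes (e.g. an organism
#'   code for gene identifiers) accepted during stripping.
#' @return List of character-vector records.
#' @export
fetch_table <- function(endpoint, timeout = 30,
                        delay = getOption("keggcomp.request_delay", 0.35),
                        extra_prefixes = character(0)) {
  wait <- the_client$last_request + delay - as.numeric(Sys.time())
  if (is.finite(wait) && wait > 0) Sys.sleep(wait)
  the_client$last_request <- as.numeric(Sys.time())

  u <- render_url(endpoint)
  withr::local_options(timeout = timeout)
  lines <- tryCatch(
    suppressWarnings(readLines(url(u), encoding = "UTF-8")),
    error = function(e) {
      abort_network(sprintf("request failed for %s: %s", u, conditionMessage(e)), url = u)
    }
  )
  lines <- lines[nzchar(stringr::str_trim(lines))]
  if (!length(lines)) {
    abort_empty_response(sprintf("empty response from %s (unknown argument?)", u), url = u)
  }
  lapply(stringr::str_split(lines, stringr::fixed("\t")), strip_kegg_prefix,
    extra = extra_prefixes)
}

# Some services prepend a T-number column to list/organism records.
drop_tnumber <- function(rec) {
  if (stringr::str_detect(rec[[1L]], "^T[0-9]+$")) rec[-1L] else rec
}

# link endpoints are orientation-agnostic here: the field parsing as an EC
# number is the EC, the other field the partner identifier.
orient_ec_link <- function(rec) {
  if (ec_is_valid(rec[[1L]])) c(rec[[1L]], rec[[2L]]) else c(rec[[2L]], rec[[1L]])
}

#' Refresh the core definitions files from the service
#'
#' Fetches the organism list, pathway list and universal EC-to-pathway links,
#' then replaces `kegg_org.txt`, `kegg_pathways.txt` and `kegg_ec.txt`
#' atomically (all files are staged and renamed only after every fetch has
#' succeeded), so a failed update never corrupts an existing definitions
#' directory. Per-organism annotation files already in the directory are kept.
#' The version stamp records the fetch time.
#'
#' @param base_url Service root.
#' @param directory Definitions directory to (re)populate.
#' @param delay Inter-request delay, seconds.
#' @return The loaded [definitions_set()], invisibly.
#' @export
update_definitions <- function(base_url, directory,
                               delay = getOption("keggcomp.request_delay", 0.35)) {
  orgs_rec <- lapply(
    fetch_table(kegg_endpoint(base_url, "list", "organism"), delay = delay),
    drop_tnumber
  )
  pw_rec <- fetch_table(kegg_endpoint(base_url, "list", "pathway"), delay = delay)
  link_rec <- lapply(
    fetch_table(kegg_endpoint(base_url, "link", c("ec", "pathway")), delay = delay),
    orient_ec_link
  )

  orgs <- tibble(
    code = vapply(orgs_rec, `[[`, "", 1L),
    name = vapply(orgs_rec, function(r) if (length(r) >= 2L) r[[2L]] else "", ""),
    taxonomy = vapply(orgs_rec, function(r) if (length(r) >= 3L) r[[3L]] else "", "")
  )
  pws <- tibble(
    pathway_id = vapply(pw_rec, `[[`, "", 1L),
    name = vapply(pw_rec, function(r) if (length(r) >= 2L) r[[2L]] else "", ""),
    category = vapply(pw_rec, function(r) if (length(r) >= 3L) r[[3L]] else "Uncategorized", "")
  )
  links <- tibble(
    ec = ec_parse(vapply(link_rec, `[[`, "", 1L)),
    pathway_id = vapply(link_rec, `[[`, "", 2L)
  )
  stamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  defs <- definitions_set(orgs, pws, links, annotations = list(), version_stamp = stamp)

  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  staging <- file.path(directory, sprintf(".staging_%d", Sys.getpid()))
  dir.create(staging, showWarnings = FALSE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  save_definitions(defs, staging)
  for (f in definitions_files()) {
    if (!file.rename(file.path(staging, f), file.path(directory, f))) {
      abort_data(sprintf("failed to move %s into %s", f, directory))
    }
  }
  invisible(load_definitions(directory))
}

#' Fetch and cache one organism's annotation
#'
#' Resolves the organism's gene list, gene-to-EC links and gene-to-pathway
#' links into an [organism_annotation()]: the genome gene total is the count
#' of distinct gene records; per-pathway gene counts are distinct genes
#' linked to the pathway; per-pathway EC sets are the ECs carried by those
#' genes; the global EC list covers every linked EC, mapped or not. A gene
#' carrying two ECs contributes both while counting once. The exact
#' endpoints KEGG uses for these joins are not fixed by the service contract;
#' this resolution (list/<code> + link/ec/<code> + link/pathway/<code>) is
#' this package's declared reconstruction.
#'
#' @param base_url Service root.
#' @param code Organism code.
#' @param directory If non-`NULL`, the annotation is cached there as
#'   `org_<code>.txt`.
#' @param delay Inter-request delay, seconds.
#' @return An [organism_annotation()].
#' @export
fetch_organism_annotation <- function(base_url, code, directory = NULL,
                                      delay = getOption("keggcomp.request_delay", 0.35)) {
  genes_rec <- fetch_table(kegg_endpoint(base_url, "list", code),
    delay = delay, extra_prefixes = code)
  gene_ids <- unique(vapply(genes_rec, `[[`, "", 1L))

  ec_rec <- tryCatch(
    fetch_table(kegg_endpoint(base_url, "link", c("ec", code)),
      delay = delay, extra_prefixes = code),
    keggcomp_empty_response = function(e) list()
  )
  gene_ec <- if (length(ec_rec)) {
    oriented <- lapply(ec_rec, function(r) {
      if (ec_is_valid(r[[2L]])) c(r[[1L]], r[[2L]]) else c(r[[2L]], r[[1L]])
    })
    tibble(
      gene = vapply(oriented, `[[`, "", 1L),
      ec = ec_parse(vapply(oriented, `[[`, "", 2L))
    )
  } else {
    tibble(gene = character(0), ec = character(0))
  }

  pw_rec <- tryCatch(
    fetch_table(kegg_endpoint(base_url, "link", c("pathway", code)),
      delay = delay, extra_prefixes = code),
    keggcomp_empty_response = function(e) list()
  )
  gene_pw <- if (length(pw_rec)) {
    tibble(
      gene = vapply(pw_rec, `[[`, "", 1L),
      pathway_id = stringr::str_remove(vapply(pw_rec, `[[`, "", 2L),
        stringr::regex(sprintf("^%s(?=[0-9]{5}$)", code)))
    )
  } else {
    tibble(gene = character(0), pathway_id = character(0))
  }

  pw_genes <- gene_pw |>
    distinct(.data$pathway_id, .data$gene) |>
    dplyr::count(.data$pathway_id, name = "genes")
  pw_ecs <- gene_pw |>
    dplyr::inner_join(gene_ec, by = "gene", relationship = "many-to-many") |>
    distinct(.data$pathway_id, .data$ec)

  ann <- organism_annotation(
    code = code,
    total_genes = length(gene_ids),
    pathway_genes = stats::setNames(pw_genes$genes, pw_genes$pathway_id),
    pathway_ecs = split(pw_ecs$ec, pw_ecs$pathway_id),
    all_ecs = unique(gene_ec$ec)
  )
  if (!is.null(directory)) {
    dir.create(directory, showWarnings = FALSE, recursive = TRUE)
    write_org_file(ann, directory)
  }
  ann
}
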