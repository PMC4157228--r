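report_columns <- function() {
  c(
    "pathway_id", "name", "category", "n_all_genes", "n_ref_genes",
    "n_ref_ecs", "n_query_ecs", "n_shared", "n_unique_ref", "n_unique_query",
    "shared_list", "unique_ref_list", "unique_query_list", "p", "p_adj", "url"
  )
}

#' Reporting filter: keep pathways carrying at least one enzyme
#'
#' A pathway appears in the report only when the query or the reference
#' organism contributes at least one enzyme to it, i.e. the union of the
#' shared and unique sets is non-empty.
#'
#' @param pathway_ids Character vector of candidate pathway ids.
#' @param partitions List of [partition_pathway()] results, parallel to
#'   `pathway_ids`.
#' @return The subset of `pathway_ids` passing the filter.
#' @export
filter_pathways <- function(pathway_ids, partitions) {
  keep <- vapply(partitions, function(pt) {
    length(pt$shared) + length(pt$unique_query) + length(pt$unique_ref) > 0L
  }, logical(1))
  pathway_ids[keep]
}

join_ecs <- function(ecs) {
  if (!length(ecs)) "-" else paste(ecs, collapse = ";")
}

split_ecs <- function(s) {
  if (identical(s, "-") || !nzchar(s)) character(0) else stringr::str_split_1(s, stringr::fixed(";"))
}

#' Build a color-coded KEGG pathway-map URL
#'
#' Produces a `show_pathway` URL against the EC-namespace reference map,
#' highlighting every enzyme of the partition: shared enzymes yellow,
#' enzymes unique to the query red, enzymes unique to the reference organism
#' green. Enzyme/color pairs are joined with `/` and the pair separator tab
#' is percent-encoded as `%09`; classes appear in the order shared,
#' unique-to-query, unique-to-reference, each sorted, so each EC occurs
#' exactly once.
#'
#' @param pathway_id Pathway identifier.
#' @param partition A [partition_pathway()] result.
#' @param base Web base URL of the KEGG site.
#' @return The URL string.
#' @export
build_map_url <- function(pathway_id, partition, base = "https://www.kegg.jp") {
  stem <- sprintf("%s/kegg-bin/show_pathway?ec%s", sub("/+$", "", base), pathway_id)
  segs <- c(
    sprintf("%s%%09yellow", partition$shared),
    sprintf("%s%%09red", partition$unique_query),
    sprintf("%s%%09green", partition$unique_ref)
  )
  if (!length(segs)) stem else paste(c(stem, segs), collapse = "/")
}

#' Compare a query enzyme set against a reference organism
#'
#' Runs the full comparison: maps the query onto every pathway, partitions
#' shared/unique enzymes, tests each reported pathway for enrichment or
#' depletion with the two-tailed Fisher exact test against the reference
#' genome background, adjusts p-values across the reported rows, builds
#' color-coded map URLs, and assembles the non-mapped enzyme comparison.
#'
#' @param defs A [definitions_set()].
#' @param ref_code Reference organism code (must have an annotation in
#'   `defs`).
#' @param query A [query_set()].
#' @param correction Multiple-testing correction across reported pathways.
#' @param background First-row total of the contingency table: all distinct
#'   query ECs, or only those mapping to at least one pathway.
#' @param sort Row order: ascending `pathway_id` (the default) or ascending
#'   adjusted p-value.
#' @param kegg_base Web base for map URLs.
#' @return An object of class `pathway_comparison`: a list with `rows` (one
#'   tibble row per reported pathway, 16 columns), `nonmapped`
#'   ([partition_nonmapped()]), `reference_code`, `query_source`,
#'   `definitions_version`, `correction`, `background`. Use [tidy()] for the
#'   row tibble, [glance()] for a one-row summary, [render_report()] for the
#'   tab-delimited text form.
#' @examples
#' spec <- fixture_spec(seed = 1, n_pathways = 6, n_organisms = 2)
#' defs <- generate_definitions(spec)
#' qry <- generate_query(spec, defs, "syna")$query
#' cmp <- compare_pathways(defs, "syna", qry)
#' tidy(cmp)
#' @export
compare_pathways <- function(defs, ref_code, query,
                             correction = c("bh", "bonferroni", "none"),
                             background = c("all-query", "mapped-query"),
                             sort = c("id", "padj"),
                             kegg_base = "https://www.kegg.jp") {
  correction <- match.arg(correction)
  background <- match.arg(background)
  sort <- match.arg(sort)
  stopifnot(inherits(query, "query_set"))
  ref <- query_reference(defs, ref_code)

  pids <- sort_c(defs$pathways$pathway_id)
  partitions <- lapply(pids, function(pid) partition_pathway(query, ref, defs, pid))
  names(partitions) <- pids
  reported <- filter_pathways(pids, partitions)
  mapped_query_size <- length(intersect(query$ecs, unique(defs$ec_links$ec)))

  rows <- purrr::map_dfr(reported, function(pid) {
    pt <- partitions[[pid]]
    tab <- build_table(pt, query, ref, pid,
      background = background, mapped_query_size = mapped_query_size)
    meta <- defs$pathways[defs$pathways$pathway_id == pid, ]
    ref_ecs <- ref$pathway_ecs[[pid]] %||% character(0)
    tibble(
      pathway_id = pid,
      name = meta$name,
      category = meta$category,
      n_all_genes = length(pathway_universal_ecs(defs, pid)),
      n_ref_genes = as.integer(tab[["c"]]),
      n_ref_ecs = length(ref_ecs),
      n_query_ecs = as.integer(tab[["a"]]),
      n_shared = length(pt$shared),
      n_unique_ref = length(pt$unique_ref),
      n_unique_query = length(pt$unique_query),
      shared_list = join_ecs(pt$shared),
      unique_ref_list = join_ecs(pt$unique_ref),
      unique_query_list = join_ecs(pt$unique_query),
      p = fisher_two_tailed(tab[["a"]], tab[["b"]], tab[["c"]], tab[["d"]]),
      p_adj = NA_real_,
      url = build_map_url(pid, pt, base = kegg_base)
    )
  })
  if (!nrow(rows)) {
    rows <- empty_report_rows()
  } else {
    rows$p_adj <- adjust_pvalues(rows$p, correction)
    if (sort == "padj") {
      rows <- arrange(rows, .data$p_adj, .data$pathway_id)
    }
  }

  structure(
    list(
      reference_code = ref_code,
      query_source = query$source,
      rows = rows,
      nonmapped = partition_nonmapped(query, ref, defs),
      definitions_version = defs$version_stamp,
      correction = correction,
      background = background
    ),
    class = "pathway_comparison"
  )
}

empty_report_rows <- function() {
  tibble(
    pathway_id = character(0), name = character(0), category = character(0),
    n_all_genes = integer(0), n_ref_genes = integer(0), n_ref_ecs = integer(0),
    n_query_ecs = integer(0), n_shared = integer(0), n_unique_ref = integer(0),
    n_unique_query = integer(0), shared_list = character(0),
    unique_ref_list = character(0), unique_query_list = character(0),
    p = numeric(0), p_adj = numeric(0), url = character(0)
  )
}

format_p <- function(p) {
  ifelse(p < 1e-4, sprintf("%.5e", p), sprintf("%.6g", p))
}

#' Render or re-read the tab-delimited comparison report
#'
#' `render_report()` writes the pipeline-friendly text form: one `#`-prefixed
#' metadata line, one `#`-prefixed header naming the 16 columns, one
#' tab-separated row per reported pathway (EC lists `;`-joined, `-` for an
#' empty list, probabilities with 6 significant digits and scientific
#' notation below 1e-4), then three labeled `NONMAPPED` rows for the shared /
#' unique-to-reference / unique-to-query non-mapped enzymes. Rendering is
#' deterministic: the same comparison always yields byte-identical output.
#' `parse_report()` inverts it.
#'
#' @param report A [compare_pathways()] result.
#' @param file Connection or file name; `""` writes to standard output.
#' @return `render_report()`: the lines, invisibly. `parse_report()`: a
#'   `pathway_comparison` object.
#' @export
render_report <- function(report, file = "") {
  stopifnot(inherits(report, "pathway_comparison"))
  if (identical(file, "")) file <- stdout()
  r <- report$rows
  meta <- sprintf(
    "# keggcomp comparison\treference=%s\tquery=%s\tdefinitions=%s\tcorrection=%s\tbackground=%s",
    report$reference_code, report$query_source, report$definitions_version,
    report$correction, report$background
  )
  header <- paste0("#", paste(report_columns(), collapse = "\t"))
  data_rows <- if (nrow(r)) {
    paste(
      r$pathway_id, r$name, r$category, r$n_all_genes, r$n_ref_genes,
      r$n_ref_ecs, r$n_query_ecs, r$n_shared, r$n_unique_ref, r$n_unique_query,
      r$shared_list, r$unique_ref_list, r$unique_query_list,
      format_p(r$p), format_p(r$p_adj), r$url,
      sep = "\t"
    )
  } else {
    character(0)
  }
  nm <- report$nonmapped
  nm_rows <- c(
    sprintf("NONMAPPED\tshared\t%d\t%s", length(nm$shared), join_ecs(nm$shared)),
    sprintf("NONMAPPED\tunique_ref\t%d\t%s", length(nm$unique_ref), join_ecs(nm$unique_ref)),
    sprintf("NONMAPPED\tunique_query\t%d\t%s", length(nm$unique_query), join_ecs(nm$unique_query))
  )
  lines <- c(meta, header, data_rows, nm_rows)
  writeLines(lines, con = file)
  invisible(lines)
}

#' @rdname render_report
#' @param lines Character vector of report lines, or a file path to read.
#' @export
parse_report <- function(lines) {
  if (length(lines) == 1L && file.exists(lines)) {
    lines <- readLines(lines, encoding = "UTF-8")
  }
  meta_line <- lines[stringr::str_starts(lines, "# keggcomp comparison")][1]
  if (is.na(meta_line)) {
    abort_data("not a keggcomp report: missing metadata line")
  }
  meta_kv <- stringr::str_split_1(meta_line, stringr::fixed("\t"))[-1]
  meta <- stringr::str_match(meta_kv, "^([a-z]+)=(.*)$")
  meta_map <- stats::setNames(meta[, 3], meta[, 2])

  body <- lines[!stringr::str_starts(lines, "#")]
  is_nm <- stringr::str_starts(body, "NONMAPPED\t")
  fields <- stringr::str_split(body[!is_nm], stringr::fixed("\t"))
  bad <- which(lengths(fields) != 16L)
  if (length(bad)) {
    abort_data(sprintf("report row %d has %d fields, expected 16", bad[1], lengths(fields)[bad[1]]))
  }
  col <- function(i) vapply(fields, `[[`, "", i)
  rows <- tibble(
    pathway_id = col(1), name = col(2), category = col(3),
    n_all_genes = as.integer(col(4)), n_ref_genes = as.integer(col(5)),
    n_ref_ecs = as.integer(col(6)), n_query_ecs = as.integer(col(7)),
    n_shared = as.integer(col(8)), n_unique_ref = as.integer(col(9)),
    n_unique_query = as.integer(col(10)),
    shared_list = col(11), unique_ref_list = col(12), unique_query_list = col(13),
    p = as.numeric(col(14)), p_adj = as.numeric(col(15)), url = col(16)
  )
  if (!length(fields)) rows <- rows[0, ]

  nm_fields <- stringr::str_split(body[is_nm], stringr::fixed("\t"))
  nm <- list(shared = character(0), unique_ref = character(0), unique_query = character(0))
  for (f in nm_fields) nm[[f[[2L]]]] <- split_ecs(f[[4L]])
  structure(
    list(
      reference_code = unname(meta_map[["reference"]]),
      query_source = unname(meta_map[["query"]]),
      rows = rows,
      nonmapped = structure(nm[c("shared", "unique_query", "unique_ref")],
        class = "nonmapped_partition"),
      definitions_version = unname(meta_map[["definitions"]]),
      correction = unname(meta_map[["correction"]]),
      background = unname(meta_map[["background"]])
    ),
    class = "pathway_comparison"
  )
}

#' @export
print.pathway_comparison <- function(x, ...) {
  cat(sprintf(
    "<pathway_comparison> query '%s' vs reference '%s': %d reported pathway(s)\n",
    x$query_source, x$reference_code, nrow(x$rows)
  ))
  if (nrow(x$rows)) {
    print(select(x$rows, "pathway_id", "name", "n_shared", "n_unique_ref",
      "n_unique_query", "p", "p_adj"), ...)
  }
  nm <- x$nonmapped
  cat(sprintf("non-mapped enzymes: %d shared, %d unique to reference, %d unique to query\n",
    length(nm$shared), length(nm$unique_ref), length(nm$unique_query)))
  invisible(x)
}

#' Tidiers for pathway comparisons
#'
#' `tidy()` returns the per-pathway report rows as a tibble; `glance()`
#' returns a one-row summary (pathway counts, enzyme totals, smallest
#' adjusted p-value).
#'
#' @param x A [compare_pathways()] result.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pathway_comparison
#' @export
tidy.pathway_comparison <- function(x, ...) {
  x$rows
}

#' @rdname tidy.pathway_comparison
#' @method glance pathway_comparison
#' @export
glance.pathway_comparison <- function(x, ...) {
  nm <- x$nonmapped
  tibble(
    reference_code = x$reference_code,
    n_pathways_reported = nrow(x$rows),
    n_significant = sum(x$rows$p_adj < 0.05),
    n_shared_mapped = sum(x$rows$n_shared),
    n_unique_query_mapped = sum(x$rows$n_unique_query),
    n_unique_ref_mapped = sum(x$rows$n_unique_ref),
    n_nonmapped_shared = length(nm$shared),
    n_nonmapped_unique_query = length(nm$unique_query),
    n_nonmapped_unique_ref = length(nm$unique_ref),
    min_p_adj = if (nrow(x$rows)) min(x$rows$p_adj) else NA_real_
  )
}

#' Plot a pathway comparison
#'
#' Bar chart of adjusted significance (-log10 adjusted p) per reported
#' pathway, colored by pathway category, with the conventional 0.05
#' threshold marked.
#'
#' @param object A [compare_pathways()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pathway_comparison
#' @export
autoplot.pathway_comparison <- function(object, ...) {
  d <- mutate(object$rows, neglog = -log10(pmax(.data$p_adj, 1e-300)))
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$pathway_id, -.data$neglog),
    y = .data$neglog, fill = .data$category
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(
      x = "pathway", y = expression(-log[10] ~ "adjusted p"),
      title = sprintf("Pathway representation vs %s", object$reference_code)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @rdname tidy.pathway_comparison
#' @export
plot_comparison <- function(x, ...) {
  autoplot(x, ...)
}
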