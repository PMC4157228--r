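#' Specification for synthetic KEGG-like definitions
#'
#' Describes a synthetic definitions set with controlled overlap and
#' enrichment structure, so every part of the package runs and can be
#' exercised fully offline. Synthetic ECs are drawn from the reserved class
#' 9 (`9.x.y.z`), which no real enzyme uses, so fixture identifiers can
#' never be mistaken for genuine EC numbers. The seed fully determines the
#' generated set (Mersenne-Twister, scoped so the caller's RNG state is
#' untouched).
#'
#' The defaults emulate a compact microbial-scale annotation: 50 pathways of
#' 6-14 enzymes with overlapping membership, three annotated organisms each
#' carrying about 85% of each pathway's enzymes, 10-19 genes per enzyme, and
#' a 20% non-enzymatic remainder on top of the enzyme gene total — roughly
#' 5,000 genes per genome — plus 40 orphan enzymes that belong to no
#' pathway.
#'
#' @param seed Integer seed; fully determines the output.
#' @param n_pathways Number of pathways.
#' @param ecs_per_pathway Length-2 integer range of enzymes per pathway.
#' @param n_organisms Number of annotated organisms (codes `syna`, `synb`, ...).
#' @param annotation_prob Probability an organism carries a given pathway
#'   enzyme (and a given orphan enzyme).
#' @param genes_per_ec Length-2 integer range of genes carrying one enzyme.
#' @param n_orphan_ecs Enzymes belonging to no pathway.
#' @param enriched_pathways List of `c(pathway_index, inclusion_prob)` pairs:
#'   query inclusion probability override for those pathways' enzymes.
#' @param baseline_query_prob Query inclusion probability everywhere else.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         n_pathways = 50L,
                         ecs_per_pathway = c(6L, 14L),
                         n_organisms = 3L,
                         annotation_prob = 0.85,
                         genes_per_ec = c(10L, 19L),
                         n_orphan_ecs = 40L,
                         enriched_pathways = list(),
                         baseline_query_prob = 0.3) {
  spec <- structure(
    list(
      seed = as.integer(seed),
      n_pathways = as.integer(n_pathways),
      ecs_per_pathway = as.integer(ecs_per_pathway),
      n_organisms = as.integer(n_organisms),
      annotation_prob = annotation_prob,
      genes_per_ec = as.integer(genes_per_ec),
      n_orphan_ecs = as.integer(n_orphan_ecs),
      enriched_pathways = enriched_pathways,
      baseline_query_prob = baseline_query_prob
    ),
    class = "fixture_spec"
  )
  probs <- c(spec$annotation_prob, spec$baseline_query_prob,
    vapply(spec$enriched_pathways, `[[`, numeric(1), 2L))
  if (any(probs < 0 | probs > 1)) {
    abort_usage("fixture probabilities must lie in [0, 1]")
  }
  if (spec$n_pathways < 1L || spec$n_organisms < 1L || spec$n_orphan_ecs < 0L ||
    any(spec$ecs_per_pathway < 1L) || any(spec$genes_per_ec < 1L) ||
    spec$ecs_per_pathway[1] > spec$ecs_per_pathway[2] ||
    spec$genes_per_ec[1] > spec$genes_per_ec[2]) {
    abort_usage("infeasible fixture spec: counts must be positive ordered ranges")
  }
  idx <- vapply(spec$enriched_pathways, `[[`, numeric(1), 1L)
  if (length(idx) && (any(idx < 1) || any(idx > spec$n_pathways))) {
    abort_usage("enriched pathway index outside 1..n_pathways")
  }
  spec
}

fixture_categories <- function() {
  c(
    "Carbohydrate metabolism", "Amino acid metabolism", "Lipid metabolism",
    "Energy metabolism", "Nucleotide metabolism"
  )
}

# Synthetic canonical ECs "9.s.x.y": pathway pool uses subclass 1..20,
# orphans 21..40, so the two can never collide.
synth_ecs <- function(n, subclass_range) {
  pool_size <- diff(subclass_range + c(0L, 1L)) * 30L * 30L
  stopifnot(n <= pool_size)
  idx <- sample.int(pool_size, n) - 1L
  s <- subclass_range[1] + idx %/% 900L
  x <- (idx %% 900L) %/% 30L + 1L
  y <- idx %% 30L + 1L
  sprintf("9.%d.%d.%d", s, x, y)
}

#' Generate a synthetic definitions set
#'
#' Deterministic given `spec$seed`. Pathway enzyme sets are drawn from a
#' shared pool (about 60% of the total slot count), so neighbouring pathways
#' overlap as KEGG pathways do. Each organism annotates each pathway enzyme
#' independently with `annotation_prob`; per-enzyme gene counts are drawn
#' uniformly from `genes_per_ec`; a pathway's gene count is the sum over its
#' annotated enzymes; the genome total adds a 20% non-enzymatic margin on
#' top of the organism's summed enzyme genes.
#'
#' @param spec A [fixture_spec()].
#' @return A [definitions_set()] with one annotation per organism.
#' @export
generate_definitions <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, generate_definitions_impl(spec), .rng_kind = "Mersenne-Twister")
}

# sample() interprets a length-1 numeric as 1:n; draw by index to avoid that
resample <- function(x, n, replace = TRUE) {
  x[sample.int(length(x), n, replace = replace)]
}

generate_definitions_impl <- function(spec) {
  sizes <- resample(seq(spec$ecs_per_pathway[1], spec$ecs_per_pathway[2]),
    spec$n_pathways)
  pool <- synth_ecs(max(10L, ceiling(sum(sizes) * 0.6)), c(1L, 20L))
  orphans <- if (spec$n_orphan_ecs > 0L) synth_ecs(spec$n_orphan_ecs, c(21L, 40L)) else character(0)

  pids <- sprintf("9%04d", seq_len(spec$n_pathways))
  universal <- lapply(sizes, function(k) resample(pool, min(k, length(pool)), replace = FALSE))
  names(universal) <- pids

  pws <- tibble(
    pathway_id = pids,
    name = sprintf("Synthetic pathway %03d", seq_len(spec$n_pathways)),
    category = rep_len(fixture_categories(), spec$n_pathways)
  )
  links <- tibble(
    ec = unlist(universal, use.names = FALSE),
    pathway_id = rep(pids, lengths(universal))
  )
  codes <- paste0("syn", letters[seq_len(spec$n_organisms)])
  orgs <- tibble(
    code = codes,
    name = sprintf("Synthetica organism %s", toupper(substr(codes, 4, 4))),
    taxonomy = "Synthetica; fixtures"
  )

  annotations <- lapply(codes, function(code) {
    pecs <- lapply(universal, function(ecs) ecs[runif(length(ecs)) < spec$annotation_prob])
    pecs <- pecs[lengths(pecs) > 0L]
    org_orphans <- orphans[runif(length(orphans)) < spec$annotation_prob]
    all_ecs <- unique(c(unlist(pecs, use.names = FALSE), org_orphans))
    genes_per <- stats::setNames(
      resample(seq(spec$genes_per_ec[1], spec$genes_per_ec[2]), length(all_ecs)),
      all_ecs
    )
    pgenes <- vapply(pecs, function(ecs) sum(genes_per[ecs]), integer(1))
    total <- as.integer(ceiling(1.2 * sum(genes_per)))
    organism_annotation(code, max(total, 1L), pgenes, pecs, all_ecs)
  })
  names(annotations) <- codes

  definitions_set(orgs, pws, links, annotations,
    version_stamp = sprintf("fixture-seed-%d", spec$seed))
}

#' Generate a synthetic query with known enrichment truth
#'
#' Draws each universal pathway enzyme into the query with
#' `baseline_query_prob`, overridden by the inclusion probability of any
#' enriched pathway containing it (the maximum applies when pathways
#' overlap); orphan enzymes of the reference organism enter with the
#' baseline probability. Truth labels for the enriched pathways accompany
#' the query so power and calibration studies are self-contained.
#'
#' @param spec A [fixture_spec()] (supplies the inclusion probabilities).
#' @param defs The [generate_definitions()] output to draw from.
#' @param reference_code Organism whose orphan enzymes seed the non-mapped
#'   part of the query.
#' @param seed Seed for the query draw; defaults to `spec$seed + 1` so the
#'   query is reproducible yet not locked to the definitions draw. Vary it
#'   to obtain replicate queries over fixed definitions.
#' @return A list with `query` (a [query_set()]) and `truth` (tibble:
#'   `pathway_id`, `inclusion_prob`, `enriched`).
#' @export
generate_query <- function(spec, defs, reference_code, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(defs, "kegg_definitions"))
  ref <- query_reference(defs, reference_code)
  withr::with_seed(as.integer(seed), {
    pids <- defs$pathways$pathway_id
    incl <- stats::setNames(rep(spec$baseline_query_prob, length(pids)), pids)
    for (e in spec$enriched_pathways) {
      incl[pids[e[[1L]]]] <- e[[2L]]
    }
    # per-EC inclusion probability: max over pathways containing the EC
    ec_prob <- defs$ec_links |>
      mutate(prob = unname(incl[.data$pathway_id])) |>
      group_by(.data$ec) |>
      summarise(prob = max(.data$prob), .groups = "drop")
    drawn <- ec_prob$ec[runif(nrow(ec_prob)) < ec_prob$prob]
    orphan_universe <- setdiff(ref$all_ecs, unique(defs$ec_links$ec))
    drawn_orphans <- orphan_universe[runif(length(orphan_universe)) < spec$baseline_query_prob]
    truth <- tibble(
      pathway_id = pids,
      inclusion_prob = unname(incl),
      enriched = unname(incl) != spec$baseline_query_prob
    )
    list(
      query = query_set(sort_c(c(drawn, drawn_orphans)),
        source = sprintf("fixture-query-seed-%d", as.integer(seed))),
      truth = truth
    )
  }, .rng_kind = "Mersenne-Twister")
}

#' Write a query set as a plain-text query file
#'
#' One canonical EC per line, suitable for [read_query()] and the command
#' line interface.
#'
#' @param query A [query_set()].
#' @param file Target path.
#' @return `file`, invisibly.
#' @export
write_query <- function(query, file) {
  stopifnot(inherits(query, "query_set"))
  con <- base::file(file, open = "wb")
  on.exit(close(con))
  writeLines(query$ecs, con, sep = "\n", useBytes = TRUE)
  invisible(file)
}
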