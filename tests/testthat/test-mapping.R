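test_that("query files are read first-column, deduplicated, comments skipped", {
  f <- withr::local_tempfile(lines = c(
    "# a comment",
    "1.1.1.1",
    "2.7.11.1",
    "1.1.1.1",
    "",
    "4.2.1.11\tENO1\tscore=3",
    "3.5.1.5 extra column"
  ))
  q <- read_query(f)
  expect_identical(q$ecs, c("1.1.1.1", "2.7.11.1", "4.2.1.11", "3.5.1.5"))
  expect_identical(q$n_input_lines, 5L)
  expect_identical(q$n_rejected, 0L)
})

test_that("unparseable query lines are skipped with a warning, not fatal", {
  f <- withr::local_tempfile(lines = c("1.1.1.1", "not-an-ec", "2.2.2.2"))
  expect_warning(q <- read_query(f), "line")
  expect_identical(q$ecs, c("1.1.1.1", "2.2.2.2"))
  expect_identical(q$n_rejected, 1L)

  g <- withr::local_tempfile(lines = c("frog", "toad"))
  expect_error(
    suppressWarnings(read_query(g)),
    "no valid EC",
    class = "keggcomp_data_error"
  )
  expect_error(read_query(tempfile()), class = "keggcomp_data_error")
})

test_that("pathway partitions follow the universal-set mapping rule", {
  # universal {e1,e2,e3}, reference has {e1,e2}, query {e2,e3}
  defs <- definitions_set(
    organisms = tibble::tibble(code = "abc", name = "x", taxonomy = ""),
    pathways = tibble::tibble(pathway_id = "00100", name = "p", category = "c"),
    ec_links = tibble::tibble(ec = c("9.1.1.1", "9.1.1.2", "9.1.1.3"), pathway_id = "00100"),
    annotations = list(abc = organism_annotation(
      "abc", 50L, c("00100" = 4L),
      list("00100" = c("9.1.1.1", "9.1.1.2")), c("9.1.1.1", "9.1.1.2")
    ))
  )
  q <- query_set(c("9.1.1.2", "9.1.1.3"))
  pt <- partition_pathway(q, query_reference(defs, "abc"), defs, "00100")
  expect_identical(pt$shared, "9.1.1.2")
  expect_identical(pt$unique_ref, "9.1.1.1")
  expect_identical(pt$unique_query, "9.1.1.3")
  expect_error(partition_pathway(q, query_reference(defs, "abc"), defs, "99999"),
    class = "keggcomp_data_error")
})

test_that("identity query yields empty unique sets; counts balance as in-pathway totals", {
  defs <- tiny_defs()
  ref <- query_reference(defs, "spo")
  q <- query_set(ref$pathway_ecs[["00010"]])
  pt <- partition_pathway(q, ref, defs, "00010")
  expect_identical(pt$shared, sort(ref$pathway_ecs[["00010"]], method = "radix"))
  expect_length(pt$unique_query, 0)
  expect_length(pt$unique_ref, 0)

  # the in-pathway query count always decomposes as shared + unique-to-query
  q2 <- query_set(c("1.1.1.1", "4.1.2.13", "1.2.3.4", "3.5.1.5"))
  pt2 <- partition_pathway(q2, ref, defs, "00010")
  in_pathway <- intersect(q2$ecs, defs$ec_links$ec[defs$ec_links$pathway_id == "00010"])
  expect_identical(
    length(pt2$shared) + length(pt2$unique_query),
    length(in_pathway)
  )
  expect_identical(pt2$unique_query, "4.1.2.13")
})

test_that("non-mapped comparison covers exactly the pathway-free ECs", {
  defs <- tiny_defs()
  ref <- query_reference(defs, "spo")
  # 3.5.1.5 is annotated in spo but belongs to no pathway; 9.9.9.9 is query-only
  q <- query_set(c("1.1.1.1", "3.5.1.5", "9.9.9.9"))
  nm <- partition_nonmapped(q, ref, defs)
  expect_identical(nm$shared, "3.5.1.5")
  expect_identical(nm$unique_query, "9.9.9.9")
  expect_length(nm$unique_ref, 0)
  # a mapped EC never appears in the non-mapped sets
  expect_false("1.1.1.1" %in% unlist(nm))
  # every query EC lands in a pathway in-set or the non-mapped sets
  mapped <- unique(defs$ec_links$ec)
  for (e in q$ecs) {
    expect_true(e %in% mapped || e %in% c(nm$shared, nm$unique_query))
  }
})

test_that("partition symmetry: swapping query and reference swaps the unique sets", {
  for (seed in 1:10) {
    spec <- fixture_spec(seed = seed, n_pathways = 5, n_organisms = 1,
      ecs_per_pathway = c(3L, 8L))
    defs <- generate_definitions(spec)
    ref <- query_reference(defs, "syna")
    q <- generate_query(spec, defs, "syna")$query
    for (pid in defs$pathways$pathway_id) {
      universal <- defs$ec_links$ec[defs$ec_links$pathway_id == pid]
      pt <- partition_pathway(q, ref, defs, pid)
      # swapped roles: reference annotated with the query's in-pathway ECs,
      # query made of the reference's in-pathway ECs
      ref2 <- organism_annotation(
        "syna", ref$total_genes,
        c(stats::setNames(max(1L, length(intersect(q$ecs, universal))), pid)),
        stats::setNames(list(intersect(q$ecs, universal)), pid),
        intersect(q$ecs, universal)
      )
      ref_ecs <- ref$pathway_ecs[[pid]]
      if (is.null(ref_ecs) || !length(ref_ecs)) next
      q2 <- query_set(ref_ecs)
      pt2 <- partition_pathway(q2, ref2, defs, pid)
      expect_identical(pt2$shared, pt$shared)
      expect_identical(pt2$unique_query, pt$unique_ref)
      expect_identical(pt2$unique_ref, pt$unique_query)
    }
  }
})

test_that("adding a query EC never decreases a shared count (monotonicity)", {
  spec <- fixture_spec(seed = 3, n_pathways = 6, n_organisms = 1,
    ecs_per_pathway = c(3L, 8L))
  defs <- generate_definitions(spec)
  ref <- query_reference(defs, "syna")
  q <- generate_query(spec, defs, "syna")$query
  extra <- setdiff(ref$all_ecs, q$ecs)
  if (length(extra)) {
    q2 <- query_set(c(q$ecs, extra[1]))
    for (pid in defs$pathways$pathway_id) {
      expect_gte(
        length(partition_pathway(q2, ref, defs, pid)$shared),
        length(partition_pathway(q, ref, defs, pid)$shared)
      )
    }
  }
})
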