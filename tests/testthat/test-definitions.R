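test_that("a hand-built one-record set round-trips field by field", {
  defs <- definitions_set(
    organisms = tibble::tibble(code = "abc", name = "One organism", taxonomy = "Lineage"),
    pathways = tibble::tibble(pathway_id = "00010", name = "Glycolysis", category = "Carbohydrate metabolism"),
    ec_links = tibble::tibble(ec = "1.1.1.1", pathway_id = "00010"),
    annotations = list(abc = organism_annotation(
      "abc", 10L, c("00010" = 2L), list("00010" = "1.1.1.1"), "1.1.1.1"
    )),
    version_stamp = "hand-1"
  )
  dir <- withr::local_tempdir()
  save_definitions(defs, dir)
  expect_setequal(
    list.files(dir),
    c("kegg_org.txt", "kegg_pathways.txt", "kegg_ec.txt", "org_abc.txt")
  )
  back <- load_definitions(dir)
  expect_identical(back$organisms, defs$organisms)
  expect_identical(back$pathways, defs$pathways)
  expect_identical(back$ec_links, defs$ec_links)
  expect_identical(back$version_stamp, "hand-1")
  ann <- back$annotations$abc
  expect_identical(ann$total_genes, 10L)
  expect_identical(ann$pathway_genes, c("00010" = 2L))
  expect_identical(ann$pathway_ecs, list("00010" = "1.1.1.1"))
  expect_identical(ann$all_ecs, "1.1.1.1")
})

test_that("an empty set serializes to header-only files and reloads empty", {
  dir <- withr::local_tempdir()
  save_definitions(definitions_set(), dir)
  back <- load_definitions(dir)
  expect_identical(nrow(back$organisms), 0L)
  expect_identical(nrow(back$pathways), 0L)
  expect_identical(nrow(back$ec_links), 0L)
  expect_length(back$annotations, 0)
})

test_that("serialization is canonical: sorted, tab-separated, LF, byte-stable", {
  defs <- tiny_defs()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  save_definitions(defs, d1)
  # same content presented in a different input order must serialize identically
  shuffled <- definitions_set(
    defs$organisms[2:1, ], defs$pathways[c(3, 1, 2), ],
    defs$ec_links[sample.int(nrow(defs$ec_links)), ],
    defs$annotations[c("spo", "eco")], defs$version_stamp
  )
  save_definitions(shuffled, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e5),
      readBin(file.path(d2, f), "raw", 1e5), info = f)
  }
  raw <- readBin(file.path(d1, "kegg_ec.txt"), "raw", 1e5)
  expect_false(any(raw == charToRaw("\r")))
})

test_that("save -> load is the identity on random generated sets", {
  for (seed in 1:25) {
    spec <- fixture_spec(
      seed = seed, n_pathways = sample(2:6, 1), n_organisms = sample(1:3, 1),
      ecs_per_pathway = c(2L, 6L), n_orphan_ecs = sample(0:5, 1)
    )
    defs <- generate_definitions(spec)
    dir <- withr::local_tempdir()
    save_definitions(defs, dir)
    expect_equal(load_definitions(dir), defs)
  }
})

test_that("malformed directories are rejected with file and line diagnostics", {
  dir <- withr::local_tempdir()
  save_definitions(tiny_defs(), dir)

  unlink(file.path(dir, "kegg_org.txt"))
  err <- tryCatch(load_definitions(dir), error = identity)
  expect_s3_class(err, "keggcomp_data_error")
  expect_match(conditionMessage(err), "kegg_org.txt")

  dir2 <- withr::local_tempdir()
  save_definitions(tiny_defs(), dir2)
  pw <- file.path(dir2, "kegg_pathways.txt")
  writeLines(c(readLines(pw), "00010\tDuplicate glycolysis\tX"), pw)
  err <- tryCatch(load_definitions(dir2), error = identity)
  expect_s3_class(err, "keggcomp_data_error")
  expect_match(conditionMessage(err), "line 5")
  expect_match(conditionMessage(err), "00010")

  dir3 <- withr::local_tempdir()
  save_definitions(tiny_defs(), dir3)
  ecf <- file.path(dir3, "kegg_ec.txt")
  writeLines(c(readLines(ecf), "5.5.5.5\t99999"), ecf)
  err <- tryCatch(load_definitions(dir3), error = identity)
  expect_s3_class(err, "keggcomp_data_error")
  expect_match(conditionMessage(err), "99999")
})

test_that("rejections are typed errors, never silent repair", {
  expect_error(
    definitions_set(pathways = tibble::tibble(
      pathway_id = c("00010", "00010"), name = c("a", "b"), category = c("c", "c")
    )),
    class = "keggcomp_data_error"
  )
  expect_error(
    definitions_set(ec_links = tibble::tibble(ec = "1.1.1.1", pathway_id = "00010")),
    class = "keggcomp_data_error"
  )
  expect_error(
    definitions_set(
      organisms = tibble::tibble(code = "ABC", name = "x", taxonomy = "")
    ),
    class = "keggcomp_data_error"
  )
  # annotation invariants: pathway ECs outside the global list; bad totals
  expect_error(
    definitions_set(
      organisms = tibble::tibble(code = "abc", name = "x", taxonomy = ""),
      pathways = tibble::tibble(pathway_id = "00010", name = "p", category = "c"),
      annotations = list(abc = organism_annotation(
        "abc", 5L, c("00010" = 1L), list("00010" = "1.1.1.1"), character(0)
      ))
    ),
    class = "keggcomp_data_error"
  )
  expect_error(
    definitions_set(
      organisms = tibble::tibble(code = "abc", name = "x", taxonomy = ""),
      pathways = tibble::tibble(pathway_id = "00010", name = "p", category = "c"),
      annotations = list(abc = organism_annotation(
        "abc", 1L, c("00010" = 5L), list("00010" = "1.1.1.1"), "1.1.1.1"
      ))
    ),
    class = "keggcomp_data_error"
  )
})

test_that("reference lookup is exact and case-sensitive", {
  defs <- tiny_defs()
  expect_identical(query_reference(defs, "spo")$total_genes, 120L)
  err <- tryCatch(query_reference(defs, "zzz"), error = identity)
  expect_s3_class(err, "keggcomp_data_error")
  expect_match(conditionMessage(err), "kegg_org.txt")
  expect_error(query_reference(defs, "SPO"), class = "keggcomp_data_error")
})
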