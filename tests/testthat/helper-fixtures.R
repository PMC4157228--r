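# Small hand-built fixtures shared across tests.

local_fast_client <- function(env = parent.frame()) {
  withr::local_options(keggcomp.request_delay = 0, .local_envir = env)
}

# A tiny definitions set built field by field: two organisms, three pathways,
# overlapping universal EC sets, one orphan EC annotated in 'spo' only.
tiny_defs <- function() {
  links <- tibble::tribble(
    ~ec, ~pathway_id,
    "1.1.1.1", "00010",
    "2.7.1.1", "00010",
    "4.1.2.13", "00010",
    "1.1.1.1", "00020",
    "1.2.3.4", "00020",
    "6.3.1.2", "00250",
    "2.6.1.1", "00250"
  )
  spo <- organism_annotation(
    "spo",
    total_genes = 120L,
    pathway_genes = c("00010" = 9L, "00250" = 4L),
    pathway_ecs = list(
      "00010" = c("1.1.1.1", "2.7.1.1"),
      "00250" = c("6.3.1.2", "2.6.1.1")
    ),
    all_ecs = c("1.1.1.1", "2.7.1.1", "6.3.1.2", "2.6.1.1", "3.5.1.5")
  )
  eco <- organism_annotation(
    "eco",
    total_genes = 80L,
    pathway_genes = c("00020" = 3L),
    pathway_ecs = list("00020" = c("1.2.3.4")),
    all_ecs = c("1.2.3.4")
  )
  definitions_set(
    organisms = tibble::tribble(
      ~code, ~name, ~taxonomy,
      "spo", "Synthetic fission yeast", "Fungi; synthetic",
      "eco", "Synthetic bacterium", "Bacteria; synthetic"
    ),
    pathways = tibble::tribble(
      ~pathway_id, ~name, ~category,
      "00010", "Glycolysis", "Carbohydrate metabolism",
      "00020", "Citrate cycle", "Carbohydrate metabolism",
      "00250", "Alanine, aspartate and glutamate metabolism", "Amino acid metabolism"
    ),
    ec_links = links,
    annotations = list(spo = spo, eco = eco),
    version_stamp = "tiny-1"
  )
}

# Mock KEGG-style REST service as a directory tree served over file://.
# Content is consistent: 2 organisms, 3 pathways, 5 universal links, and a
# resolvable per-organism annotation for 'spo' (6 genes; one gene with two
# ECs, one EC on two genes).
write_mock_kegg <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  w <- function(rel, lines) {
    path <- file.path(dir, rel)
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    writeLines(lines, path)
  }
  w("list/organism", c(
    "T00001\tspo\tSynthetic fission yeast\tFungi; synthetic",
    "T00002\teco\tSynthetic bacterium\tBacteria; synthetic"
  ))
  w("list/pathway", c(
    "path:map00010\tGlycolysis\tCarbohydrate metabolism",
    "path:map00020\tCitrate cycle\tCarbohydrate metabolism",
    "path:map00250\tAlanine, aspartate and glutamate metabolism\tAmino acid metabolism"
  ))
  w("link/ec/pathway", c(
    "ec:1.1.1.1\tpath:map00010",
    "ec:2.7.1.1\tpath:map00010",
    "ec:4.1.2.13\tpath:map00010",
    "ec:1.2.3.4\tpath:map00020",
    "ec:6.3.1.2\tpath:map00250"
  ))
  w("list/spo", c(
    "spo:g1\tgene 1", "spo:g2\tgene 2", "spo:g3\tgene 3",
    "spo:g4\tgene 4", "spo:g5\tgene 5", "spo:g6\tgene 6"
  ))
  w("link/ec/spo", c(
    "spo:g1\tec:1.1.1.1",
    "spo:g2\tec:2.7.1.1",
    "spo:g2\tec:1.2.3.4", # one gene carrying two ECs
    "spo:g3\tec:1.1.1.1" # one EC carried by two genes
  ))
  # unknown organism: the service answers with an empty body
  w("list/zzz", character(0))
  w("link/pathway/spo", c(
    "spo:g1\tpath:spo00010",
    "spo:g2\tpath:spo00010",
    "spo:g3\tpath:spo00010",
    "spo:g2\tpath:spo00020"
  ))
  paste0("file://", normalizePath(dir))
}

# Run the CLI in-process, separating the stdout payload from stderr messages.
run_cli <- function(args) {
  out <- character(0)
  msgs <- character(0)
  status <- withCallingHandlers(
    {
      out <- capture.output(st <- keggcomp_cli(args))
      st
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  list(status = status, stdout = out, stderr = msgs)
}

expect_valid_defs <- function(defs) {
  expect_s3_class(defs, "kegg_definitions")
  expect_true(all(defs$ec_links$pathway_id %in% defs$pathways$pathway_id))
  expect_true(all(names(defs$annotations) %in% defs$organisms$code))
  for (ann in defs$annotations) {
    expect_true(all(unlist(ann$pathway_ecs) %in% ann$all_ecs))
    if (length(ann$pathway_genes)) {
      expect_gte(ann$total_genes, max(ann$pathway_genes))
    }
  }
  invisible(defs)
}
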