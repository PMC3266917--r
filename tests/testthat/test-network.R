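empty_hits <- function() {
  data.frame(rank = integer(), probability = numeric(),
             partner_id = character(), entry_name = character())
}

test_that("a query with no hits and no known partners is a single node", {
  db <- protein_db(data.frame(id = "Q1", entry_name = "", sequence = "MKVLA"))
  g <- build_network("Q1", empty_hits(), db)
  expect_identical(g$nodes$id, "Q1")
  expect_identical(g$nodes$role, "query")
  expect_identical(nrow(g$edges), 0L)
})

test_that("one hit with two known partners expands to the documented graph", {
  recs <- data.frame(id = c("Q1", "H1", "K1", "K2"), entry_name = "",
                     sequence = "MKVLA")
  ann <- data.frame(protein_id = recs$id,
                    `function` = "", disease = "", tissue_specificity = "",
                    subcellular_location = "",
                    known_partners = I(list(character(), c("K1", "K2"),
                                            "H1", "H1")),
                    check.names = FALSE)
  db <- protein_db(recs, ann)
  hits <- data.frame(rank = 1L, probability = 0.9, partner_id = "H1",
                     entry_name = "")
  g <- build_network("Q1", hits, db)
  expect_identical(nrow(g$nodes), 4L)
  expect_setequal(g$nodes$role[g$nodes$id %in% c("K1", "K2")],
                  "known_neighbor")
  expect_identical(sum(g$edges$provenance == "predicted"), 1L)
  expect_gte(sum(g$edges$provenance == "known"), 2L)
  # predicted edges carry the probability, known edges weight 1
  expect_identical(g$edges$weight[g$edges$provenance == "predicted"], 0.9)
  expect_true(all(g$edges$weight[g$edges$provenance == "known"] == 1))
})

test_that("edges equal the union oracle on the fixture database", {
  hits <- single_query(seq_of(carrier_a_id), small_db, small_model,
                       query_id = carrier_a_id)
  g <- build_network(carrier_a_id, hits, small_db)
  # oracle: predicted edge set union known edge set among included nodes
  pred <- paste(pmin(carrier_a_id, hits$partner_id),
                pmax(carrier_a_id, hits$partner_id))
  included <- g$nodes$id
  known <- character()
  for (i in seq_len(nrow(small_ann))) {
    a <- small_ann$protein_id[i]
    if (!a %in% included) next
    for (b in intersect(small_ann$known_partners[[i]], included)) {
      known <- c(known, paste(min(a, b), max(a, b)))
    }
  }
  want <- union(pred, unique(known))
  got <- paste(g$edges$source, g$edges$target)
  expect_setequal(got, want)
  expect_false(anyDuplicated(got) > 0)
  # no self loops; weights legal per provenance
  expect_true(all(g$edges$source != g$edges$target))
  pw <- g$edges$weight[grepl("predicted", g$edges$provenance)]
  expect_true(all(pw > 0.5 & pw <= 1))
  expect_true(all(g$edges$weight[g$edges$provenance == "known"] == 1))
})

test_that("node and edge sets are invariant to hit order", {
  hits <- single_query(seq_of(carrier_a_id), small_db, small_model,
                       query_id = carrier_a_id)
  if (nrow(hits) >= 2) {
    g1 <- build_network(carrier_a_id, hits, small_db)
    g2 <- build_network(carrier_a_id, hits[rev(seq_len(nrow(hits))), ],
                        small_db)
    expect_identical(g1$nodes, g2$nodes)
    expect_identical(g1$edges, g2$edges)
  }
})

test_that("a pair both predicted and known merges provenance once", {
  recs <- data.frame(id = c("Q1", "H1"), entry_name = "", sequence = "MKVLA")
  ann <- data.frame(protein_id = recs$id,
                    `function` = "", disease = "", tissue_specificity = "",
                    subcellular_location = "",
                    known_partners = I(list("H1", "Q1")),
                    check.names = FALSE)
  db <- protein_db(recs, ann)
  hits <- data.frame(rank = 1L, probability = 0.77, partner_id = "H1",
                     entry_name = "")
  g <- build_network("Q1", hits, db)
  expect_identical(nrow(g$edges), 1L)
  expect_identical(g$edges$provenance, "known+predicted")
  expect_identical(g$edges$weight, 0.77)
})

test_that("TSV and GraphML exports round-trip losslessly", {
  hits <- single_query(seq_of(carrier_a_id), small_db, small_model,
                       query_id = carrier_a_id)
  g <- build_network(carrier_a_id, hits, small_db)
  ef <- withr::local_tempfile(fileext = ".tsv")
  nf <- withr::local_tempfile(fileext = ".tsv")
  export_graph(g, ef, format = "tsv", nodes_path = nf)
  back <- import_graph(ef, format = "tsv", nodes_path = nf)
  expect_identical(back$nodes, g$nodes)
  expect_identical(back$edges, g$edges)

  gf <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, gf, format = "graphml")
  back2 <- import_graph(gf, format = "graphml")
  expect_identical(back2$nodes, g$nodes)
  expect_identical(back2$edges[, c("source", "target", "provenance")],
                   g$edges[, c("source", "target", "provenance")])
  expect_equal(back2$edges$weight, g$edges$weight, tolerance = 1e-12)
})

test_that("an empty graph exports a header-only edge table", {
  db <- protein_db(data.frame(id = "Q1", entry_name = "", sequence = "MKVLA"))
  g <- build_network("Q1", empty_hits(), db)
  ef <- withr::local_tempfile(fileext = ".tsv")
  export_graph(g, ef, format = "tsv")
  lines <- readLines(ef)
  expect_identical(lines, "source\ttarget\tprovenance\tweight")
  expect_error(export_graph(g, ef, format = "dot"), "arg")
})
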