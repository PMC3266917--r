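write_lines <- function(lines, path) writeLines(lines, path)

test_that("read_fasta concatenates wrapped lines and parses headers", {
  f <- withr::local_tempfile(fileext = ".fasta")
  write_lines(c(">P1", "MKV", "LA"), f)
  rec <- read_fasta(f)
  expect_identical(rec$id, "P1")
  expect_identical(rec$sequence, "MKVLA")

  write_lines(c(">sp|P63208|SKP1_HUMAN some description", "MPSIKLQSSDGE"), f)
  rec <- read_fasta(f)
  expect_identical(rec$id, "P63208")
  expect_identical(rec$entry_name, "SKP1_HUMAN")

  # empty file gives an empty record table
  write_lines(character(), f)
  expect_identical(nrow(read_fasta(f)), 0L)
})

test_that("read_fasta rejects malformed records with informative errors", {
  f <- withr::local_tempfile(fileext = ".fasta")
  write_lines(c(">P1", "MKV*LA"), f)
  expect_error(read_fasta(f), "P1.*\\*")
  write_lines(c(">P1", "MKVLA", ">P2", ">P3", "MMM"), f)
  expect_error(read_fasta(f), "P2")
  expect_error(read_fasta(file.path(tempdir(), "no-such-file.fasta")),
               "not found")
})

test_that("FASTA round-trip preserves ids, entry names and sequences", {
  recs <- data.frame(id = c("P1", "P2", "P3"),
                     entry_name = c("AAA_TEST", "", "CCC_TEST"),
                     sequence = c("MKVLA", random_sequence_fixed(150),
                                  "CCCKKKWWW"),
                     stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_identical(back$id, recs$id)
  expect_identical(back$entry_name, recs$entry_name)
  expect_identical(back$sequence, recs$sequence)
  # 150-residue sequence wraps into 3 lines of at most 60
  lines <- readLines(f)
  body <- lines[(which(lines == ">P2") + 1):(which(startsWith(lines, ">sp|P3")) - 1)]
  expect_length(body, 3L)
  expect_true(all(nchar(body) <= 60L))
})

test_that("annotation loading parses cells and enforces the schema", {
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste("protein_id", "function", "disease", "tissue_specificity",
               "subcellular_location", "known_partners", sep = "\t")
  writeLines(c(hdr, "P1\t\t\tLiver\t\tP2;P3", "P2\t\t\t\t\t"), f)
  ann <- load_annotations(f)
  expect_identical(ann$tissue_specificity[1], "Liver")
  expect_setequal(ann$known_partners[[1]], c("P2", "P3"))
  expect_identical(ann$known_partners[[2]], character())

  writeLines(c(paste(hdr, "extra", sep = "\t"),
               "P1\t\t\t\t\t\tx"), f)
  expect_error(load_annotations(f), "unknown: extra")
  writeLines(c(hdr, "P1\t\t\tLiver\t\t", "P1\t\t\tBrain\t\t"), f)
  expect_error(load_annotations(f), "duplicate")
})

test_that("protein_db enforces invariants and symmetrizes known partners", {
  recs <- data.frame(id = c("P1", "P2", "P3"), entry_name = "",
                     sequence = c("MKVLA", "CCCCC", "WWWWW"))
  ann <- data.frame(protein_id = c("P1", "P2", "P3"),
                    `function` = "", disease = "", tissue_specificity = "",
                    subcellular_location = "",
                    known_partners = I(list("P2", character(), character())),
                    check.names = FALSE)
  expect_message(db <- protein_db(recs, ann), "symmetrized")
  a2 <- db$annotations$known_partners[[
    match("P2", db$annotations$protein_id)]]
  expect_true("P1" %in% a2)
  # symmetric input stays silent
  expect_silent(protein_db(recs, db$annotations))
  # duplicate ids and dangling annotations are rejected
  expect_error(protein_db(recs[c(1, 1, 2), ]), "duplicate")
  bad <- ann; bad$protein_id[3] <- "P9"
  expect_error(protein_db(recs, bad), "P9")
})

test_that("tissue filter is a case-insensitive order-preserving idempotent subset", {
  hits <- single_query(seq_of(carrier_a_id), small_db, small_model,
                       query_id = carrier_a_id)
  tissues <- vapply(hits$partner_id, function(id) {
    small_ann$tissue_specificity[match(id, small_ann$protein_id)]
  }, "")
  filtered <- tissue_match(hits, small_db, "liver")
  # brute-force filter over the fixture annotations
  expect_identical(filtered$partner_id,
                   hits$partner_id[grepl("liver", tissues,
                                         ignore.case = TRUE)])
  expect_false(is.unsorted(match(filtered$partner_id, hits$partner_id)))
  expect_identical(tissue_match(filtered, small_db, "liver"), filtered)
  # no match gives an empty table, not an error
  expect_identical(nrow(tissue_match(hits, small_db, "xyzzy")), 0L)
  expect_error(tissue_match(hits, small_db, ""), "nzchar")
})

test_that("known-interaction filter equals the set-intersection oracle", {
  hits <- single_query(seq_of(carrier_a_id), small_db, small_model,
                       query_id = carrier_a_id)
  entry <- small_db$records$entry_name[
    match(carrier_a_id, small_db$records$id)]
  known <- small_db$annotations$known_partners[[
    match(carrier_a_id, small_db$annotations$protein_id)]]
  filtered <- known_interaction_match(entry, hits, small_db)
  expect_setequal(filtered$partner_id, intersect(hits$partner_id, known))
  expect_false(is.unsorted(match(filtered$partner_id, hits$partner_id)))
  expect_identical(known_interaction_match(entry, filtered, small_db),
                   filtered)
  expect_error(known_interaction_match("NOPE_HUMAN", hits, small_db),
               "does not resolve")
})

test_that("pair tables reject conflicting duplicate labels", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id_a\tid_b\tlabel",
               "P1\tP2\tinteract",
               "P2\tP1\tnon-interact"), f)
  expect_error(load_ppi_pairs(f), "conflicting")
})
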