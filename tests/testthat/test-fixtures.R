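test_that("generators are pure functions of the spec and seed", {
  spec <- fixture_spec(n_proteins = 30, n_pairs = 60, seed = 9)
  p1 <- generate_proteome(spec)
  p2 <- generate_proteome(spec)
  expect_identical(p1, p2)
  expect_identical(generate_interactome(p1, spec),
                   generate_interactome(p2, spec))
  expect_identical(generate_annotations(p1, spec),
                   generate_annotations(p2, spec))
  # a different seed changes the proteome
  spec2 <- fixture_spec(n_proteins = 30, n_pairs = 60, seed = 10)
  expect_false(identical(p1, generate_proteome(spec2)))
})

test_that("proteome respects the spec: ids, lengths, planted motifs", {
  spec <- fixture_spec(n_proteins = 40, n_pairs = 80,
                       length_range = c(50, 90), seed = 12)
  prot <- generate_proteome(spec)
  expect_identical(nrow(prot), 40L)
  expect_false(anyDuplicated(prot$id) > 0)
  expect_true(all(grepl("^SYN[0-9]{4}$", prot$id)))
  lens <- nchar(prot$sequence)
  expect_true(all(lens >= 50 & lens <= 90))
  motifs <- c(pair1A = spec$motif_pairs[[1]][1],
              pair1B = spec$motif_pairs[[1]][2])
  for (i in which(nzchar(prot$motif))) {
    expect_true(grepl(motifs[[prot$motif[i]]], prot$sequence[i],
                      fixed = TRUE))
  }
})

test_that("noise-free labels follow the complementary-motif rule exactly", {
  spec <- fixture_spec(n_proteins = 40, n_pairs = 80, noise_rate = 0,
                       seed = 13)
  prot <- generate_proteome(spec)
  pairs <- generate_interactome(prot, spec)
  expect_identical(pairs$label, pairs$label_true)
  tag <- stats::setNames(prot$motif, prot$id)
  comp <- triadppi:::is_complementary(tag[pairs$id_a], tag[pairs$id_b])
  expect_identical(unname(comp), pairs$label == "interact")
})

test_that("class balance matches the requested positive fraction", {
  spec <- fixture_spec(n_proteins = 40, n_pairs = 81,
                       positive_fraction = 0.4, seed = 14)
  pairs <- generate_interactome(generate_proteome(spec), spec)
  n_pos <- sum(pairs$label_true == "interact")
  expect_lte(abs(n_pos - 0.4 * 81), 1)
  expect_identical(nrow(pairs), 81L)
})

test_that("label noise flips at the requested binomial rate", {
  spec <- fixture_spec(n_proteins = 120, n_pairs = 2000, noise_rate = 0.1,
                       seed = 15)
  pairs <- generate_interactome(generate_proteome(spec), spec)
  flips <- sum(pairs$label != pairs$label_true)
  bounds <- qbinom(c(0.025, 0.975), 2000, 0.1)
  expect_gte(flips, bounds[1])
  expect_lte(flips, bounds[2])
})

test_that("annotations are symmetric, in-vocabulary and positive-backed", {
  spec <- fixture_spec(n_proteins = 40, n_pairs = 80, seed = 16)
  prot <- generate_proteome(spec)
  pairs <- generate_interactome(prot, spec)
  ann <- generate_annotations(prot, spec, pairs)
  partners <- stats::setNames(ann$known_partners, ann$protein_id)
  for (a in names(partners)) {
    for (b in partners[[a]]) expect_true(a %in% partners[[b]])
  }
  expect_true(all(ann$tissue_specificity %in%
                    c("Liver", "Brain", "Kidney", "Heart", "Lung",
                      "Ubiquitous")))
  # every known edge is a true positive pair
  true_pos <- paste(pmin(pairs$id_a, pairs$id_b),
                    pmax(pairs$id_a, pairs$id_b))[
    pairs$label_true == "interact"]
  for (a in names(partners)) {
    for (b in partners[[a]]) {
      expect_true(paste(min(a, b), max(a, b)) %in% true_pos)
    }
  }
})

test_that("impossible specs are rejected", {
  expect_error(fixture_spec(noise_rate = 0.6), "noise_rate")
  expect_error(fixture_spec(length_range = c(5, 50)), "length_range")
  expect_error(fixture_spec(motif_pairs = list(c("CK", "WWW"))), "nchar")
  expect_error(fixture_spec(motif_pairs = list(c("CKZKC", "WWWHH"))),
               "standard residues")
  # more positives requested than complementary pairs exist
  spec <- fixture_spec(n_proteins = 6, n_pairs = 100, carrier_fraction = 0.5,
                       seed = 17)
  expect_error(generate_interactome(generate_proteome(spec), spec),
               "positive pairs")
})

test_that("fixture files round-trip through the package loaders", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(n_proteins = 25, n_pairs = 50, seed = 18)
  paths <- write_fixture_files(spec, dir)
  prot <- generate_proteome(spec)
  back <- read_fasta(paths$fasta)
  expect_identical(back$id, prot$id)
  expect_identical(back$sequence, prot$sequence)
  pairs <- load_ppi_pairs(paths$pairs)
  expect_identical(pairs[, c("id_a", "id_b", "label")],
                   generate_interactome(prot, spec)[, c("id_a", "id_b",
                                                        "label")])
  ann <- load_annotations(paths$annotations)
  want <- generate_annotations(prot, spec, generate_interactome(prot, spec))
  expect_identical(ann$protein_id, want$protein_id)
  expect_identical(lapply(ann$known_partners, sort),
                   lapply(want$known_partners, sort))
  # the written fixture assembles into a valid database
  expect_silent(protein_db(back, ann))
})
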