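# Shared small fixtures, built once per suite run. Sizes are kept small so
# the whole suite stays fast; the acceptance tests use the full-size
# default fixture.

# 60-protein fixture with annotations and a trained model, for the search,
# network and filter tests.
small_spec <- fixture_spec(n_proteins = 60L, n_pairs = 160L,
                           noise_rate = 0.05, seed = 7L)
small_proteome <- generate_proteome(small_spec)
small_pairs <- generate_interactome(small_proteome, small_spec)
small_ann <- generate_annotations(small_proteome, small_spec, small_pairs)
small_db <- protein_db(small_proteome[, c("id", "entry_name", "sequence")],
                       small_ann, species = "synthetic")
small_model <- train_svm(small_pairs, small_db, seed = 11L)

# sequence lookup shorthand
seq_of <- function(id, db = small_db) db$records$sequence[db$records$id == id]

# Sub-databases for the oracle comparisons (20 proteins for single query,
# 15 for indirect paths), annotation-free.
db20 <- protein_db(small_proteome[1:20, c("id", "entry_name", "sequence")])
db15 <- protein_db(small_proteome[21:35, c("id", "entry_name", "sequence")])

# Representative carrier / background sequences from the small proteome.
carrier_a_id <- small_proteome$id[small_proteome$motif == "pair1A"][1]
carrier_b_id <- small_proteome$id[small_proteome$motif == "pair1B"][1]
background_id <- small_proteome$id[small_proteome$motif == ""][1]
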