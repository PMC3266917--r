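# Synthetic proteome / interactome / annotation generator with a planted,
# learnable sequence signal. Interaction follows a complementary-motif
# rule: a pair is a true positive exactly when one protein carries motif A
# and the other carries motif B of the same motif pair. Triad features can
# represent motif content, so the planted signal is learnable by the
# implemented featurization and classifier tests are meaningful.

STANDARD_RESIDUES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

TISSUE_VOCABULARY <- c("Liver", "Brain", "Kidney", "Heart", "Lung",
                       "Ubiquitous")

# Approximate natural amino-acid background frequencies (vertebrate
# proteome averages), used by the "natural" background mode.
NATURAL_FREQUENCIES <- c(
  A = 0.074, C = 0.025, D = 0.054, E = 0.068, F = 0.047, G = 0.074,
  H = 0.026, I = 0.068, K = 0.058, L = 0.099, M = 0.025, N = 0.045,
  P = 0.039, Q = 0.034, R = 0.042, S = 0.057, T = 0.051, V = 0.073,
  W = 0.013, Y = 0.032)

#' Specification of a synthetic benchmark
#'
#' Defines the study conditions for the synthetic proteome and interactome:
#' proteome size, sequence length range, the complementary motif pair(s)
#' planted into carrier sequences, the number of labeled pairs and their
#' class balance, and the label-noise rate.
#'
#' @param n_proteins Number of proteins in the proteome.
#' @param length_range Integer (min, max) of sequence lengths; min >= 9.
#' @param motif_pairs List of character pairs \code{c(motifA, motifB)};
#'   each motif is a residue string of length >= 3.
#' @param carrier_fraction Fraction of proteins that receive a motif
#'   (split evenly between the A and B motif of each pair).
#' @param positive_fraction Fraction of labeled pairs that are positives.
#' @param n_pairs Total number of labeled pairs to emit.
#' @param noise_rate Independent label-flip probability in [0, 0.5).
#' @param background \code{"uniform"} residue composition or
#'   \code{"natural"} frequencies.
#' @param seed Integer seed; every generator is a pure function of
#'   (spec, seed).
#' @return An object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(n_proteins = 200L,
                         length_range = c(60L, 150L),
                         motif_pairs = list(c("CKCCKKCKCKCC",
                                              "WHWWHHWHWHWW")),
                         carrier_fraction = 0.8,
                         positive_fraction = 0.5,
                         n_pairs = 800L,
                         noise_rate = 0.05,
                         background = c("uniform", "natural"),
                         seed = 20120126L) {
  background <- match.arg(background)
  stopifnot(n_proteins >= 2L,
            length(length_range) == 2L, length_range[1] >= 9L,
            length_range[1] <= length_range[2],
            length(motif_pairs) >= 1L,
            positive_fraction > 0, positive_fraction < 1,
            n_pairs >= 2L,
            noise_rate >= 0, noise_rate < 0.5,
            carrier_fraction > 0, carrier_fraction <= 1)
  for (mp in motif_pairs) {
    stopifnot(length(mp) == 2L, all(nchar(mp) >= 3L))
    if (max(nchar(mp)) > length_range[1] - 2L) {
      stop("motifs must fit inside the shortest sequence with flanks")
    }
    if (!all(strsplit(paste(mp, collapse = ""), "")[[1]] %in%
               STANDARD_RESIDUES)) {
      stop("motifs must use the 20 standard residues")
    }
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 motif_pairs = motif_pairs,
                 carrier_fraction = carrier_fraction,
                 positive_fraction = positive_fraction,
                 n_pairs = as.integer(n_pairs),
                 noise_rate = noise_rate,
                 background = background,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic proteome
#'
#' Sequences are drawn i.i.d. over the 20 standard residues (uniform or
#' natural composition) at lengths uniform in the spec's range. A fraction
#' of proteins become motif carriers: the motif replaces a stretch at a
#' random interior position, keeping the length. Deterministic given the
#' spec's seed.
#'
#' @param spec A \code{\link{fixture_spec}}.
#' @return Data frame with columns \code{id} ("SYN0001", ...),
#'   \code{entry_name}, \code{sequence}, plus a \code{motif} attribute
#'   column recording which motif (if any) each protein carries.
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    n <- spec$n_proteins
    probs <- switch(spec$background,
                    uniform = rep(1 / 20, 20),
                    natural = unname(NATURAL_FREQUENCIES[STANDARD_RESIDUES]))
    lens <- sample(spec$length_range[1]:spec$length_range[2], n,
                   replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(STANDARD_RESIDUES, L, replace = TRUE, prob = probs),
            collapse = "")
    }, "")

    motif_tag <- rep("", n)
    n_carriers <- round(n * spec$carrier_fraction)
    carriers <- sample(n, n_carriers)
    # deal carriers round-robin over the motifs of all pairs (A then B)
    motifs <- unlist(lapply(seq_along(spec$motif_pairs), function(i) {
      stats::setNames(spec$motif_pairs[[i]],
                      paste0("pair", i, c("A", "B")))
    }))
    assignment <- rep_len(seq_along(motifs), n_carriers)
    for (j in seq_along(carriers)) {
      i <- carriers[j]
      motif <- motifs[assignment[j]]
      mlen <- nchar(motif)
      pos <- sample(2:(lens[i] - mlen), 1L)  # interior splice
      substr(seqs[i], pos, pos + mlen - 1L) <- motif
      motif_tag[i] <- names(motifs)[assignment[j]]
    }
    data.frame(id = sprintf("SYN%04d", seq_len(n)),
               entry_name = sprintf("SYN%04d_SYNTH", seq_len(n)),
               sequence = seqs, motif = motif_tag,
               stringsAsFactors = FALSE)
  })
}

# TRUE complementary-motif relation between two motif tags.
is_complementary <- function(tag_a, tag_b) {
  nzchar(tag_a) & nzchar(tag_b) &
    substr(tag_a, 1, nchar(tag_a) - 1L) ==
      substr(tag_b, 1, nchar(tag_b) - 1L) &
    substr(tag_a, nchar(tag_a), nchar(tag_a)) !=
      substr(tag_b, nchar(tag_b), nchar(tag_b))
}

#' Generate a labeled synthetic interactome
#'
#' True positives are the complementary-motif pairs (one protein carries
#' motif A, the other motif B of the same pair); negatives are sampled from
#' all other pairs. The requested number of pairs is drawn at the spec's
#' class balance, then labels are flipped independently at the spec's
#' noise rate. Deterministic given the spec's seed.
#'
#' @param proteome Data frame from \code{\link{generate_proteome}}.
#' @param spec The \code{\link{fixture_spec}} used to generate it.
#' @return Labeled pair data frame with columns \code{id_a}, \code{id_b},
#'   \code{label}, plus \code{label_true} (the pre-noise label, for
#'   diagnostics).
#' @export
generate_interactome <- function(proteome, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed + 1L, {
    n <- nrow(proteome)
    idx <- utils::combn(n, 2L)
    comp <- is_complementary(proteome$motif[idx[1, ]],
                             proteome$motif[idx[2, ]])
    pos_pool <- which(comp)
    neg_pool <- which(!comp)
    n_pos <- round(spec$n_pairs * spec$positive_fraction)
    n_neg <- spec$n_pairs - n_pos
    if (length(pos_pool) < n_pos) {
      stop("spec cannot supply ", n_pos, " positive pairs (only ",
           length(pos_pool), " complementary-motif pairs exist)")
    }
    if (length(neg_pool) < n_neg) stop("not enough negative pairs")
    take_pos <- sample(pos_pool, n_pos)
    take_neg <- sample(neg_pool, n_neg)
    take <- c(take_pos, take_neg)
    label_true <- rep(c("interact", "non-interact"), c(n_pos, n_neg))
    # randomize within-pair order so the classifier cannot key on position
    swap <- sample(c(TRUE, FALSE), length(take), replace = TRUE)
    a <- ifelse(swap, idx[2, take], idx[1, take])
    b <- ifelse(swap, idx[1, take], idx[2, take])
    flip <- stats::runif(length(take)) < spec$noise_rate
    label <- ifelse(flip,
                    ifelse(label_true == "interact", "non-interact",
                           "interact"),
                    label_true)
    out <- data.frame(id_a = proteome$id[a], id_b = proteome$id[b],
                      label = label, label_true = label_true,
                      stringsAsFactors = FALSE)
    # shuffle row order; validity is order-independent
    out <- out[sample(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Generate synthetic annotations
#'
#' Tissue labels are drawn from a small vocabulary; known partners are a
#' random symmetric subset of the true positive (pre-noise) pairs.
#' Deterministic given the spec's seed.
#'
#' @param proteome Data frame from \code{\link{generate_proteome}}.
#' @param spec The \code{\link{fixture_spec}}.
#' @param interactome Optional labeled pairs from
#'   \code{\link{generate_interactome}}; when given, known partners are
#'   sampled from its true positives, otherwise from all complementary
#'   pairs.
#' @param known_fraction Fraction of true positive pairs promoted to known
#'   interactions.
#' @return Annotation data frame with the standard six columns
#'   (\code{known_partners} is a list column).
#' @export
generate_annotations <- function(proteome, spec, interactome = NULL,
                                 known_fraction = 0.3) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed + 2L, {
    n <- nrow(proteome)
    tissue <- sample(TISSUE_VOCABULARY, n, replace = TRUE)
    if (is.null(interactome)) {
      idx <- utils::combn(n, 2L)
      comp <- is_complementary(proteome$motif[idx[1, ]],
                               proteome$motif[idx[2, ]])
      pos_a <- proteome$id[idx[1, comp]]
      pos_b <- proteome$id[idx[2, comp]]
    } else {
      pos <- interactome$label_true == "interact"
      pos_a <- interactome$id_a[pos]
      pos_b <- interactome$id_b[pos]
    }
    n_known <- round(length(pos_a) * known_fraction)
    take <- if (length(pos_a) > 0L) sample(length(pos_a), n_known) else integer()
    partners <- stats::setNames(vector("list", n), proteome$id)
    partners[] <- list(character())
    for (i in take) {
      partners[[pos_a[i]]] <- union(partners[[pos_a[i]]], pos_b[i])
      partners[[pos_b[i]]] <- union(partners[[pos_b[i]]], pos_a[i])
    }
    data.frame(protein_id = proteome$id,
               `function` = ifelse(nzchar(proteome$motif),
                                   paste0("synthetic binder (",
                                          proteome$motif, ")"),
                                   "synthetic background protein"),
               disease = "",
               tissue_specificity = tissue,
               subcellular_location = sample(c("Cytoplasm", "Nucleus",
                                               "Membrane"), n,
                                             replace = TRUE),
               known_partners = I(unname(partners)),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
}

#' Write a complete synthetic benchmark to disk
#'
#' Emits \code{db.fasta}, \code{pairs.tsv} and \code{annotations.tsv} into
#' a directory, in the formats the loaders of this package read back.
#'
#' @param spec A \code{\link{fixture_spec}}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the list of written paths.
#' @export
write_fixture_files <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  proteome <- generate_proteome(spec)
  pairs <- generate_interactome(proteome, spec)
  ann <- generate_annotations(proteome, spec, pairs)
  fasta <- file.path(dir, "db.fasta")
  pairs_path <- file.path(dir, "pairs.tsv")
  ann_path <- file.path(dir, "annotations.tsv")
  write_fasta(proteome, fasta)
  utils::write.table(pairs[, c("id_a", "id_b", "label")], pairs_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ann_out <- ann
  ann_out$known_partners <- vapply(ann$known_partners, paste,
                                   "", collapse = ";")
  utils::write.table(ann_out, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta = fasta, pairs = pairs_path,
                 annotations = ann_path))
}
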