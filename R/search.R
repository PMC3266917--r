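# Query modes: Single Query screens one sequence against a whole database
# and ranks candidate partners with probability > 0.5 in descending order;
# Multiple Query scores one candidate pair directly and can search for
# chains through one or two intermediate proteins.

POSITIVE_THRESHOLD <- 0.5  # strict: a hit must exceed 50%

# Symmetrized probabilities of the query sequence against every database
# protein, computed in one SVM predict call per ordering.
score_against_db <- function(query_sequence, db, model, map) {
  check_fingerprint(model, map)
  if (nrow(db$records) == 0L) stop("database is empty")
  vq <- triad_vector(query_sequence, map)$values
  V <- do.call(rbind, lapply(db$records$sequence,
                             function(s) triad_vector(s, map)$values))
  Q <- matrix(vq, nrow = nrow(V), ncol = 343L, byrow = TRUE)
  lab <- c(paste0("A.", triad_labels()), paste0("B.", triad_labels()))
  X_qd <- cbind(Q, V); colnames(X_qd) <- lab
  X_dq <- cbind(V, Q); colnames(X_dq) <- lab
  p <- (predict_prob_matrix(model, X_qd) + predict_prob_matrix(model, X_dq)) / 2
  stats::setNames(p, db$records$id)
}

# Threshold, sort and rank a named probability vector. Ties in probability
# are broken by accession so output is independent of storage order.
rank_hits <- function(probabilities, db, exclude_ids = character()) {
  probabilities <- probabilities[!names(probabilities) %in% exclude_ids]
  keep <- probabilities > POSITIVE_THRESHOLD
  p <- probabilities[keep]
  ids <- names(p)
  o <- order(-p, ids)
  entry <- db$records$entry_name[match(ids[o], db$records$id)]
  data.frame(rank = seq_along(o), probability = unname(p[o]),
             partner_id = ids[o], entry_name = entry,
             stringsAsFactors = FALSE)
}

#' Screen a query sequence for partners in a protein database
#'
#' Computes the symmetrized interaction probability of the query against
#' every database protein and returns the candidates with probability
#' strictly above 50%, ranked in descending order. Probability ties are
#' broken by accession so the ranking does not depend on database storage
#' order.
#'
#' @param query_sequence Amino-acid sequence of the query protein.
#' @param db A \code{\link{protein_db}}.
#' @param model A trained \code{ppi_model}.
#' @param query_id Optional accession of the query; if the query itself is
#'   stored in the database, its self-match is excluded.
#' @param map Residue class map (must match the model's).
#' @return Data frame of class \code{partner_hits} with columns
#'   \code{rank}, \code{probability}, \code{partner_id}, \code{entry_name}.
#' @export
single_query <- function(query_sequence, db, model, query_id = NULL,
                         map = residue_class_map()) {
  p <- score_against_db(query_sequence, db, model, map)
  hits <- rank_hits(p, db, exclude_ids = query_id %||% character())
  class(hits) <- c("partner_hits", class(hits))
  hits
}

#' Direct interaction probability of two query sequences
#'
#' The symmetrized posterior probability that the two proteins interact;
#' the pair is classified as interacting when the probability exceeds 0.5.
#'
#' @inheritParams predict_probability
#' @return Probability in [0, 1].
#' @export
direct_interaction <- function(seqA, seqB, model, map = residue_class_map()) {
  predict_probability(model, seqA, seqB, symmetrize = TRUE, map = map)
}

#' Indirect interaction paths through one or two intermediate proteins
#'
#' Searches the database for chains query A - C - query B (one
#' intermediate) and A - C - D - B (two intermediates, C and D distinct)
#' in which every edge's predicted probability exceeds 0.5. Each path is
#' scored by the product of its edge probabilities; paths are returned in
#' descending score order, shorter paths before longer ones at equal score.
#' Optionally known interactions among database proteins are merged in as
#' edges of probability 1.
#'
#' @param seqA,seqB Query sequences.
#' @param db A \code{\link{protein_db}} providing candidate intermediates.
#' @param model A trained \code{ppi_model}.
#' @param max_intermediates 1 or 2.
#' @param exclude_ids Accessions never used as intermediates (e.g. the
#'   queries themselves if they are stored in \code{db}).
#' @param use_known_edges If \code{TRUE}, known partner edges among
#'   database proteins are added with probability 1.0.
#' @param map Residue class map.
#' @return Data frame of class \code{interaction_paths} with columns
#'   \code{via1}, \code{via2} (\code{NA} for one-intermediate paths),
#'   \code{p1}, \code{p2}, \code{p3} and \code{path_score}.
#' @export
indirect_interaction <- function(seqA, seqB, db, model,
                                 max_intermediates = 2L,
                                 exclude_ids = character(),
                                 use_known_edges = FALSE,
                                 map = residue_class_map()) {
  if (!max_intermediates %in% c(1L, 2L)) {
    stop("max_intermediates must be 1 or 2")
  }
  if (nrow(db$records) == 0L) stop("database is empty")

  pA <- score_against_db(seqA, db, model, map)
  pB <- score_against_db(seqB, db, model, map)
  ids <- setdiff(db$records$id, exclude_ids)
  pA <- pA[ids]; pB <- pB[ids]

  paths <- data.frame(via1 = character(), via2 = character(),
                      p1 = numeric(), p2 = numeric(), p3 = numeric(),
                      path_score = numeric(), stringsAsFactors = FALSE)

  candA <- ids[pA[ids] > POSITIVE_THRESHOLD]  # first hop from A
  candB <- ids[pB[ids] > POSITIVE_THRESHOLD]  # last hop to B

  # one intermediate: A - C - B
  one <- intersect(candA, candB)
  if (length(one) > 0L) {
    paths <- rbind(paths, data.frame(
      via1 = one, via2 = NA_character_,
      p1 = unname(pA[one]), p2 = unname(pB[one]), p3 = NA_real_,
      path_score = unname(pA[one] * pB[one]), stringsAsFactors = FALSE))
  }

  if (max_intermediates == 2L && length(candA) > 0L && length(candB) > 0L) {
    P_mid <- db_pair_probabilities(db, model, candA, candB, map,
                                   use_known_edges)
    for (cc in candA) {
      for (dd in candB) {
        if (cc == dd) next
        pm <- P_mid[cc, dd]
        if (pm > POSITIVE_THRESHOLD) {
          paths <- rbind(paths, data.frame(
            via1 = cc, via2 = dd,
            p1 = unname(pA[cc]), p2 = pm, p3 = unname(pB[dd]),
            path_score = unname(pA[cc]) * pm * unname(pB[dd]),
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  n_int <- ifelse(is.na(paths$via2), 1L, 2L)
  o <- order(-paths$path_score, n_int, paths$via1, paths$via2,
             na.last = FALSE)
  paths <- paths[o, , drop = FALSE]
  rownames(paths) <- NULL
  class(paths) <- c("interaction_paths", class(paths))
  paths
}

# Symmetrized probability matrix among database proteins (rows, cols),
# optionally overridden to 1 where a known partner edge exists.
db_pair_probabilities <- function(db, model, rows, cols, map,
                                  use_known_edges = FALSE) {
  all_ids <- union(rows, cols)
  seqs <- db_sequences(db, all_ids)
  V <- do.call(rbind, lapply(seqs, function(s) triad_vector(s, map)$values))
  rownames(V) <- all_ids
  grid <- expand.grid(a = rows, b = cols, stringsAsFactors = FALSE)
  lab <- c(paste0("A.", triad_labels()), paste0("B.", triad_labels()))
  X_ab <- cbind(V[grid$a, , drop = FALSE], V[grid$b, , drop = FALSE])
  X_ba <- cbind(V[grid$b, , drop = FALSE], V[grid$a, , drop = FALSE])
  colnames(X_ab) <- lab; colnames(X_ba) <- lab
  p <- (predict_prob_matrix(model, X_ab) + predict_prob_matrix(model, X_ba)) / 2
  P <- matrix(p, nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  if (use_known_edges && !is.null(db$annotations)) {
    for (a in rows) {
      ann <- db_annotation(db, a)
      if (!is.null(ann)) {
        hit <- intersect(ann$known_partners[[1]], cols)
        P[a, hit] <- 1.0
      }
    }
  }
  P
}

#' Write a partner hit table to TSV
#'
#' Columns \code{rank}, \code{probability} (4 decimals), \code{partner_id},
#' \code{entry_name}.
#'
#' @param hits Partner hit table from \code{\link{single_query}}.
#' @param path Output path.
#' @export
write_hits <- function(hits, path) {
  out <- data.frame(rank = hits$rank,
                    probability = sprintf("%.4f", hits$probability),
                    partner_id = hits$partner_id,
                    entry_name = hits$entry_name,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
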