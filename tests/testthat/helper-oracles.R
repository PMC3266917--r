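# Independent brute-force oracles used across test files. These never call
# the implementation paths they check.

# Triad counting by explicit window enumeration with per-residue lookup.
oracle_triad_counts <- function(sequence, map = residue_class_map()) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  counts <- integer(343L)
  if (length(chars) < 3L) return(counts)
  for (i in seq_len(length(chars) - 2L)) {
    cls <- sapply(chars[i:(i + 2L)], function(a) {
      if (a %in% names(map)) unname(map[a]) else NA_integer_
    })
    if (anyNA(cls)) next
    idx <- (cls[1] - 1L) * 49L + (cls[2] - 1L) * 7L + cls[3]
    counts[idx] <- counts[idx] + 1L
  }
  counts
}

# Negative log-likelihood of the sigmoid calibration model with Platt's
# regularized targets; the quantity fit_platt minimizes.
oracle_platt_nll <- function(A, B, f, y) {
  n_pos <- sum(y); n_neg <- length(y) - n_pos
  t <- ifelse(y, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  x <- A * f + B
  sum(ifelse(x >= 0, t * x + log1p(exp(-x)), (t - 1) * x + log1p(exp(x))))
}

# Two-stage grid-search minimizer of the calibration objective: a coarse
# grid over a wide (A, B) box, repeatedly refined around the best cell.
oracle_platt_grid <- function(f, y, A_range = c(-20, 5), B_range = c(-8, 8),
                              steps = 41L, refinements = 8L) {
  best <- c(A = NA, B = NA, nll = Inf)
  for (r in seq_len(refinements)) {
    As <- seq(A_range[1], A_range[2], length.out = steps)
    Bs <- seq(B_range[1], B_range[2], length.out = steps)
    for (A in As) for (B in Bs) {
      v <- oracle_platt_nll(A, B, f, y)
      if (v < best["nll"]) best <- c(A = A, B = B, nll = v)
    }
    dA <- diff(A_range) / (steps - 1)
    dB <- diff(B_range) / (steps - 1)
    A_range <- best["A"] + c(-dA, dA)
    B_range <- best["B"] + c(-dB, dB)
  }
  best
}

# Brute-force oracle for single query: score every database protein one at
# a time through the public pair predictor, filter, sort.
oracle_single_query <- function(query_seq, db, model, query_id = NULL) {
  p <- vapply(seq_len(nrow(db$records)), function(i) {
    predict_probability(model, query_seq, db$records$sequence[i])
  }, numeric(1))
  names(p) <- db$records$id
  if (!is.null(query_id)) p <- p[names(p) != query_id]
  p <- p[p > 0.5]
  o <- order(-p, names(p))
  data.frame(rank = seq_along(o), probability = unname(p[o]),
             partner_id = names(p)[o], stringsAsFactors = FALSE)
}

# Exhaustive path enumeration over all ordered intermediate choices, using
# only the public pair predictor.
oracle_paths <- function(seqA, seqB, db, model, max_intermediates) {
  ids <- db$records$id
  p_of <- function(s1, s2) predict_probability(model, s1, s2)
  sq <- function(id) db$records$sequence[db$records$id == id]
  out <- list()
  for (cc in ids) {
    p1 <- p_of(seqA, sq(cc)); p2 <- p_of(sq(cc), seqB)
    if (p1 > 0.5 && p2 > 0.5) {
      out[[length(out) + 1]] <- data.frame(
        via1 = cc, via2 = NA_character_, path_score = p1 * p2)
    }
  }
  if (max_intermediates == 2) {
    for (cc in ids) for (dd in ids) {
      if (cc == dd) next
      p1 <- p_of(seqA, sq(cc)); pm <- p_of(sq(cc), sq(dd))
      p3 <- p_of(sq(dd), seqB)
      if (p1 > 0.5 && pm > 0.5 && p3 > 0.5) {
        out[[length(out) + 1]] <- data.frame(
          via1 = cc, via2 = dd, path_score = p1 * pm * p3)
      }
    }
  }
  do.call(rbind, out)
}

# Deterministic sequence of a given length (cycled standard alphabet).
random_sequence_fixed <- function(len) {
  paste(rep_len(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len),
        collapse = "")
}

# Random amino-acid sequence over the 20 standard residues.
random_sequence <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                     "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
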