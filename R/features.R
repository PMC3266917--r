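# Conjoint-triad featurization: 20 amino acids reduced to 7 physicochemical
# classes (grouped by dipole and side-chain volume), then 7^3 = 343 triad
# counts over all length-3 windows of a sequence.

# Ambiguity codes tolerated in input sequences but carrying no class.
AMBIGUITY_CODES <- c("B", "J", "O", "U", "X", "Z")

#' Residue-to-class mapping for conjoint-triad features
#'
#' Loads the 7-class reduction of the 20 standard amino acids used by the
#' conjoint-triad descriptor. The default table groups residues by dipole
#' and side-chain volume: \{A,G,V\}, \{I,L,F,P\}, \{Y,M,T,S\}, \{H,N,Q,W\},
#' \{R,K\}, \{D,E\}, \{C\}. The table ships as a plain TSV
#' (\code{extdata/residue_classes.tsv}) so alternative groupings can be
#' supplied.
#'
#' @param path Path to a two-column TSV (\code{residue}, \code{class}).
#'   Defaults to the table installed with the package.
#' @return A named integer vector of class \code{residue_class_map}: names
#'   are the 20 residue letters, values class indices in 1..7.
#' @export
#' @examples
#' map <- residue_class_map()
#' map["C"]  # cysteine sits alone in class 7
residue_class_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "residue_classes.tsv", package = "triadppi")
  }
  if (!file.exists(path)) stop("residue class table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (!identical(sort(names(tab)), c("class", "residue"))) {
    stop("residue class table must have columns 'residue' and 'class'")
  }
  map <- as.integer(tab$class)
  names(map) <- toupper(tab$residue)
  if (anyDuplicated(names(map))) stop("duplicate residue in class table")
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(std %in% names(map))) {
    stop("class table must map all 20 standard residues; missing: ",
         paste(setdiff(std, names(map)), collapse = ","))
  }
  if (!setequal(unique(map), 1:7)) stop("class table must use exactly classes 1..7")
  structure(map, class = "residue_class_map")
}

#' Map a single residue letter to its conjoint-triad class
#'
#' @param aa A single amino-acid letter.
#' @param map A \code{\link{residue_class_map}}.
#' @param ambiguity How to treat tolerated ambiguity codes (B, J, O, U, X, Z):
#'   \code{"skip"} returns \code{NA_integer_} (the residue carries no class),
#'   \code{"strict"} raises an error.
#' @return Integer class index in 1..7, or \code{NA_integer_} for a skipped
#'   ambiguity code.
#' @export
classify_residue <- function(aa, map = residue_class_map(),
                             ambiguity = c("skip", "strict")) {
  ambiguity <- match.arg(ambiguity)
  aa <- toupper(aa)
  if (length(aa) != 1L || nchar(aa) != 1L) stop("'aa' must be one letter")
  if (aa %in% names(map)) return(unname(map[aa]))
  if (aa %in% AMBIGUITY_CODES) {
    if (ambiguity == "strict") stop("ambiguous residue '", aa, "' rejected in strict mode")
    return(NA_integer_)
  }
  stop("residue '", aa, "' is not in the accepted alphabet")
}

# Map a character vector of residues to class indices (NA for ambiguity
# codes under "skip"); errors on letters outside the tolerated alphabet.
residue_classes_of <- function(chars, map, ambiguity = "skip") {
  cls <- unname(map[chars])
  unknown <- is.na(cls) & !(chars %in% AMBIGUITY_CODES)
  if (any(unknown)) {
    stop("sequence contains residue(s) outside the accepted alphabet: ",
         paste(unique(chars[unknown]), collapse = ","))
  }
  if (ambiguity == "strict" && anyNA(cls)) {
    stop("ambiguous residue '", chars[which(is.na(cls))[1]],
         "' rejected in strict mode")
  }
  cls
}

#' Conjoint-triad descriptor of one protein sequence
#'
#' Slides a window of three consecutive residues along the sequence, maps
#' each residue to its class, and counts every class triple, giving a
#' 343-dimensional raw count vector. Counts are normalized min-max over the
#' 343 components, d = (f - min f) / max f, which removes the dependence on
#' sequence length. Windows containing an ambiguity code are skipped under
#' the default policy.
#'
#' @param sequence Amino-acid string (uppercased internally).
#' @param map A \code{\link{residue_class_map}}.
#' @param ambiguity \code{"skip"} (windows with ambiguous residues are not
#'   counted) or \code{"strict"} (such sequences are rejected).
#' @return An object of class \code{triad_vector}: a list with
#'   \code{values} (343 normalized components in [0, 1]),
#'   \code{raw_counts} (343 nonnegative integers) and
#'   \code{source_length} (residue count of the input).
#' @export
#' @examples
#' tv <- triad_vector("MKVLAAGVC")
#' sum(tv$raw_counts)  # number of windows = length - 2
triad_vector <- function(sequence, map = residue_class_map(),
                         ambiguity = c("skip", "strict")) {
  ambiguity <- match.arg(ambiguity)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  chars <- chars[chars != " "]
  cls <- residue_classes_of(chars, map, ambiguity)
  n <- length(cls)
  if (sum(!is.na(cls)) < 3L) stop("sequence too short for triad encoding")
  raw <- integer(343L)
  if (n >= 3L) {
    c1 <- cls[1:(n - 2L)]
    c2 <- cls[2:(n - 1L)]
    c3 <- cls[3:n]
    idx <- (c1 - 1L) * 49L + (c2 - 1L) * 7L + c3
    raw <- tabulate(idx[!is.na(idx)], nbins = 343L)
  }
  names(raw) <- triad_labels()
  vals <- if (max(raw) > 0L) (raw - min(raw)) / max(raw) else as.numeric(raw)
  structure(list(values = vals, raw_counts = raw, source_length = n),
            class = "triad_vector")
}

# "c1.c2.c3" labels in the index order used by triad_vector().
triad_labels <- function() {
  g <- expand.grid(c3 = 1:7, c2 = 1:7, c1 = 1:7)
  paste(g$c1, g$c2, g$c3, sep = ".")
}

#' @export
print.triad_vector <- function(x, ...) {
  nz <- sum(x$raw_counts > 0L)
  cat("conjoint-triad vector: 343 components,", nz, "nonzero,",
      "source length", x$source_length, "\n")
  invisible(x)
}

#' Compose the descriptor of an ordered protein pair
#'
#' Concatenates the two 343-dimensional triad vectors into a single
#' 686-dimensional pair descriptor \code{[vA || vB]}. Order invariance is
#' obtained downstream, at prediction time, by averaging the scores of the
#' two orderings (see \code{\link{predict_probability}}).
#'
#' @param vA,vB \code{triad_vector} objects (or bare numeric vectors of
#'   length 343).
#' @return Numeric vector of length 686 of class \code{pair_vector}.
#' @export
pair_vector <- function(vA, vB) {
  a <- if (inherits(vA, "triad_vector")) vA$values else vA
  b <- if (inherits(vB, "triad_vector")) vB$values else vB
  if (length(a) != 343L || length(b) != 343L) {
    stop("pair_vector requires two 343-dimensional triad vectors")
  }
  out <- c(a, b)
  names(out) <- c(paste0("A.", triad_labels()), paste0("B.", triad_labels()))
  class(out) <- "pair_vector"
  out
}

# Feature matrix for a set of ordered id pairs, caching one triad vector
# per distinct protein.
pair_feature_matrix <- function(ids_a, ids_b, db, map = residue_class_map(),
                                ambiguity = "skip") {
  stopifnot(length(ids_a) == length(ids_b))
  ids <- unique(c(ids_a, ids_b))
  seqs <- db_sequences(db, ids)
  tv <- lapply(seqs, function(s) triad_vector(s, map, ambiguity)$values)
  V <- do.call(rbind, tv)
  rownames(V) <- ids
  X <- cbind(V[ids_a, , drop = FALSE], V[ids_b, , drop = FALSE])
  colnames(X) <- c(paste0("A.", triad_labels()), paste0("B.", triad_labels()))
  rownames(X) <- NULL
  X
}

# Canonical fingerprint of a residue-class map, stored in trained models so
# a model refuses to score features produced under a different table.
map_fingerprint <- function(map) {
  o <- order(names(map))
  paste(names(map)[o], unclass(map)[o], sep = "=", collapse = ";")
}
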