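# File-backed protein store: FASTA sequences plus a TSV annotation table
# (function, disease, tissue specificity, subcellular location, known
# partners), with the post-hoc hit filters built on top of it.

TOLERATED_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                        c("B", "J", "O", "U", "X", "Z"))

ANNOTATION_COLUMNS <- c("protein_id", "function", "disease",
                        "tissue_specificity", "subcellular_location",
                        "known_partners")

#' Read protein records from a FASTA file
#'
#' Headers are parsed for an identifier: the first whitespace-delimited
#' token. If that token follows the UniProt dialect \code{db|ACC|ENTRY_NAME}
#' both the accession and the entry name are captured; otherwise the whole
#' token is the id and the entry name is empty. Wrapped sequence lines are
#' concatenated and uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns \code{id}, \code{entry_name},
#'   \code{sequence} (possibly zero rows for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("failed to parse FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    return(data.frame(id = character(), entry_name = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  headers <- names(set)
  token <- sub("\\s.*$", "", headers)
  entry <- character(length(token))
  uni <- grepl("^[^|]+\\|[^|]+\\|[^|]+$", token)
  id <- token
  id[uni] <- vapply(strsplit(token[uni], "|", fixed = TRUE), `[`, "", 2L)
  entry[uni] <- vapply(strsplit(token[uni], "|", fixed = TRUE), `[`, "", 3L)
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L) {
      stop("record '", id[i], "' has a header but no sequence")
    }
    bad <- setdiff(strsplit(seqs[i], "")[[1]], TOLERATED_ALPHABET)
    if (length(bad) > 0L) {
      stop("record '", id[i], "' contains character(s) outside the ",
           "accepted amino-acid alphabet: ", paste(bad, collapse = ","))
    }
  }
  data.frame(id = id, entry_name = entry, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein records to a FASTA file
#'
#' Sequence lines are wrapped at 60 columns. When a record carries an entry
#' name the header is written in the UniProt dialect
#' \code{sp|id|entry_name} so that \code{\link{read_fasta}} round-trips both
#' fields.
#'
#' @param records Data frame with columns \code{id}, \code{sequence} and
#'   optionally \code{entry_name}.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(records$sequence)
  entry <- if ("entry_name" %in% names(records)) records$entry_name else ""
  has_entry <- !is.na(entry) & nzchar(entry)
  names(set) <- ifelse(has_entry,
                       paste0("sp|", records$id, "|", entry),
                       records$id)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(NULL)
}

#' Load per-protein annotation records from a TSV file
#'
#' The table must carry exactly the columns \code{protein_id},
#' \code{function}, \code{disease}, \code{tissue_specificity},
#' \code{subcellular_location} and \code{known_partners}
#' (semicolon-separated accessions). Empty cells become empty strings /
#' empty partner sets.
#'
#' @param path Path to the annotation TSV.
#' @return A data frame with the five text columns plus a list column
#'   \code{known_partners} of character vectors.
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  if (!setequal(names(tab), ANNOTATION_COLUMNS)) {
    extra <- setdiff(names(tab), ANNOTATION_COLUMNS)
    missing <- setdiff(ANNOTATION_COLUMNS, names(tab))
    stop("annotation table columns do not match the expected schema",
         if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ",")),
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ",")))
  }
  tab <- tab[, ANNOTATION_COLUMNS]
  if (any(!nzchar(tab$protein_id))) stop("annotation row with empty protein_id")
  if (anyDuplicated(tab$protein_id)) {
    stop("duplicate protein_id in annotation table: ",
         paste(unique(tab$protein_id[duplicated(tab$protein_id)]), collapse = ","))
  }
  tab$known_partners <- lapply(tab$known_partners, function(x) {
    p <- strsplit(x, ";", fixed = TRUE)[[1]]
    p[nzchar(p)]
  })
  tab
}

#' Assemble a searchable protein database
#'
#' Bundles sequence records and annotations, enforcing id uniqueness and
#' referential integrity, and symmetrizes the known-partner relation
#' (physical interaction is undirected): if B lists A, A is made to list B.
#' Any symmetrization performed is reported with a message.
#'
#' @param records Data frame from \code{\link{read_fasta}} or
#'   \code{\link{generate_proteome}}.
#' @param annotations Optional data frame from
#'   \code{\link{load_annotations}} or \code{\link{generate_annotations}}.
#' @param species Free-text species label.
#' @return An object of class \code{protein_db}.
#' @export
protein_db <- function(records, annotations = NULL, species = "unspecified") {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  if (anyDuplicated(records$id)) {
    stop("duplicate protein id(s): ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ","))
  }
  if (any(!nzchar(records$sequence))) stop("empty sequence in records")
  if (!"entry_name" %in% names(records)) records$entry_name <- ""
  if (!is.null(annotations)) {
    unresolved <- setdiff(annotations$protein_id, records$id)
    if (length(unresolved) > 0L) {
      stop("annotation refers to unknown protein id(s): ",
           paste(unresolved, collapse = ","))
    }
    annotations <- symmetrize_partners(annotations, records$id)
  }
  structure(list(records = records, annotations = annotations,
                 species = species),
            class = "protein_db")
}

# Make the known-partner relation symmetric; report how many edges were
# added. Partner ids outside the database are dropped with a message.
symmetrize_partners <- function(annotations, valid_ids) {
  part <- annotations$known_partners
  names(part) <- annotations$protein_id
  outside <- setdiff(unique(unlist(part)), valid_ids)
  if (length(outside) > 0L) {
    message("dropping known partner id(s) not present in the database: ",
            paste(outside, collapse = ","))
    part <- lapply(part, setdiff, y = outside)
  }
  added <- 0L
  for (a in names(part)) {
    for (b in part[[a]]) {
      if (!b %in% names(part)) {
        # partner has a sequence record but no annotation row: create one
        annotations <- rbind(annotations,
          data.frame(protein_id = b, `function` = "", disease = "",
                     tissue_specificity = "", subcellular_location = "",
                     known_partners = I(list(character())),
                     check.names = FALSE))
        part[[b]] <- character()
      }
      if (!a %in% part[[b]]) {
        part[[b]] <- c(part[[b]], a)
        added <- added + 1L
      }
    }
  }
  if (added > 0L) {
    message("symmetrized known-partner relation: added ", added,
            " reciprocal edge(s)")
  }
  annotations$known_partners <- unname(part[annotations$protein_id])
  annotations
}

#' @export
print.protein_db <- function(x, ...) {
  cat("protein database (", x$species, "): ", nrow(x$records),
      " sequences, ",
      if (is.null(x$annotations)) 0L else nrow(x$annotations),
      " annotated\n", sep = "")
  invisible(x)
}

# ---- lookups -------------------------------------------------------------

db_sequences <- function(db, ids) {
  i <- match(ids, db$records$id)
  if (anyNA(i)) {
    stop("unknown protein id(s): ", paste(ids[is.na(i)], collapse = ","))
  }
  stats::setNames(db$records$sequence[i], ids)
}

db_annotation <- function(db, id) {
  if (is.null(db$annotations)) return(NULL)
  i <- match(id, db$annotations$protein_id)
  if (is.na(i)) return(NULL)
  db$annotations[i, ]
}

# Resolve a UniProt-style entry name to the record's accession.
resolve_entry_name <- function(db, entry_name) {
  i <- match(entry_name, db$records$entry_name)
  if (is.na(i) || !nzchar(entry_name)) {
    stop("entry name '", entry_name, "' does not resolve to any protein")
  }
  db$records$id[i]
}

# ---- post-hoc hit filters ------------------------------------------------

#' Filter partner hits by tissue-specificity keyword
#'
#' Keeps the hits whose partner's tissue-specificity annotation contains the
#' keyword (case-insensitive substring match). Ranking order is preserved;
#' the filter is idempotent.
#'
#' @param hits Partner hit table from \code{\link{single_query}}.
#' @param db A \code{\link{protein_db}} with annotations.
#' @param keyword Non-empty search keyword.
#' @return The matching subset of \code{hits}, in the original order.
#' @export
tissue_match <- function(hits, db, keyword) {
  stopifnot(is.character(keyword), length(keyword) == 1L, nzchar(keyword))
  if (nrow(hits) == 0L) return(hits)
  if (is.null(db$annotations)) return(hits[0L, ])
  tissue <- vapply(hits$partner_id, function(id) {
    a <- db_annotation(db, id)
    if (is.null(a)) "" else a$tissue_specificity
  }, "")
  hits[grepl(keyword, tissue, ignore.case = TRUE, fixed = FALSE), ,
       drop = FALSE]
}

#' Restrict partner hits to experimentally known partners of the query
#'
#' Given the query's UniProt-style entry name, keeps only the hits that are
#' members of the query's known-partner set. Order is preserved.
#'
#' @param query_entry_name Entry name of the query protein (must resolve in
#'   \code{db}).
#' @param hits Partner hit table from \code{\link{single_query}}.
#' @param db A \code{\link{protein_db}} with annotations.
#' @return The subset of \code{hits} that are known partners of the query.
#' @export
known_interaction_match <- function(query_entry_name, hits, db) {
  qid <- resolve_entry_name(db, query_entry_name)
  ann <- db_annotation(db, qid)
  known <- if (is.null(ann)) character() else ann$known_partners[[1]]
  hits[hits$partner_id %in% known, , drop = FALSE]
}

#' Load labeled interaction pairs from a TSV file
#'
#' Expects columns \code{id_a}, \code{id_b}, \code{label} with labels
#' \code{"interact"} / \code{"non-interact"}.
#'
#' @param path Path to the pair TSV.
#' @return A labeled pair data frame suitable for \code{\link{train_svm}}.
#' @export
load_ppi_pairs <- function(path) {
  if (!file.exists(path)) stop("pair file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (!all(c("id_a", "id_b", "label") %in% names(tab))) {
    stop("pair table must have columns id_a, id_b, label")
  }
  validate_pairs(tab[, c("id_a", "id_b", "label")])
}

# Shared validation for labeled pair tables: legal labels and no unordered
# pair carrying both labels.
validate_pairs <- function(pairs) {
  if (!all(pairs$label %in% c("interact", "non-interact"))) {
    stop("labels must be 'interact' or 'non-interact'")
  }
  key <- ifelse(pairs$id_a < pairs$id_b,
                paste(pairs$id_a, pairs$id_b),
                paste(pairs$id_b, pairs$id_a))
  lab_by_key <- split(pairs$label, key)
  conflict <- names(lab_by_key)[vapply(lab_by_key,
                                       function(l) length(unique(l)) > 1L,
                                       logical(1))]
  if (length(conflict) > 0L) {
    stop("conflicting labels for unordered pair(s): ",
         paste(conflict, collapse = "; "))
  }
  pairs
}
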