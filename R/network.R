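# Partner network construction: predicted positive edges around the query
# merged with known interactions among the involved proteins, expanded by
# a configurable ring of known neighbors.

#' Build the partner network around a query protein
#'
#' Nodes are the query, its predicted partners, and (up to \code{depth}
#' expansion rings) the known partners of any included node. Edges are the
#' predicted query-partner edges, weighted by probability, plus every known
#' interaction among included nodes, weighted 1.0. The graph is simple and
#' undirected; when a pair is both predicted and known its provenance is
#' recorded once as \code{"known+predicted"} with the predicted weight
#' retained.
#'
#' @param query_id Accession of the query protein.
#' @param hits Partner hit table from \code{\link{single_query}}.
#' @param db A \code{\link{protein_db}} (annotations supply known edges).
#' @param depth Number of known-neighbor expansion rings (0, 1 or 2).
#' @return An object of class \code{interaction_graph}: list with a
#'   \code{nodes} data frame (\code{id}, \code{role}) and an \code{edges}
#'   data frame (\code{source}, \code{target}, \code{provenance},
#'   \code{weight}), both in deterministic order.
#' @export
build_network <- function(query_id, hits, db, depth = 1L) {
  stopifnot(depth %in% 0:2)
  if (!query_id %in% db$records$id && !is.null(db$annotations)) {
    stop("query id '", query_id, "' is not in the database")
  }
  partner_ids <- hits$partner_id
  node_role <- stats::setNames(rep("predicted_partner", length(partner_ids)),
                               partner_ids)
  node_role[query_id] <- "query"

  # expand by rings of known neighbors
  frontier <- names(node_role)
  for (ring in seq_len(depth)) {
    neighbors <- character()
    for (id in frontier) {
      ann <- db_annotation(db, id)
      if (!is.null(ann)) neighbors <- c(neighbors, ann$known_partners[[1]])
    }
    new_ids <- setdiff(unique(neighbors), names(node_role))
    if (length(new_ids) == 0L) break
    node_role[new_ids] <- "known_neighbor"
    frontier <- new_ids
  }

  included <- names(node_role)

  # predicted query-hit edges
  edges <- data.frame(source = character(), target = character(),
                      provenance = character(), weight = numeric(),
                      stringsAsFactors = FALSE)
  if (length(partner_ids) > 0L) {
    edges <- data.frame(
      source = pmin(query_id, partner_ids),
      target = pmax(query_id, partner_ids),
      provenance = "predicted",
      weight = hits$probability,
      stringsAsFactors = FALSE)
    edges <- edges[edges$source != edges$target, , drop = FALSE]
  }

  # known edges among included nodes
  if (!is.null(db$annotations)) {
    for (a in included) {
      ann <- db_annotation(db, a)
      if (is.null(ann)) next
      for (b in intersect(ann$known_partners[[1]], included)) {
        if (a < b) {
          edges <- rbind(edges, data.frame(
            source = a, target = b, provenance = "known", weight = 1.0,
            stringsAsFactors = FALSE))
        }
      }
    }
  }

  # collapse duplicates: a pair both predicted and known keeps the
  # predicted weight under the merged provenance tag
  key <- paste(edges$source, edges$target)
  if (anyDuplicated(key)) {
    keep <- !logical(nrow(edges))
    for (k in unique(key[duplicated(key)])) {
      rows <- which(key == k)
      prov <- sort(unique(edges$provenance[rows]))
      w <- if ("predicted" %in% prov) {
        edges$weight[rows[edges$provenance[rows] == "predicted"][1]]
      } else edges$weight[rows[1]]
      edges$provenance[rows[1]] <- paste(prov, collapse = "+")
      edges$weight[rows[1]] <- w
      keep[rows[-1]] <- FALSE
    }
    edges <- edges[keep, , drop = FALSE]
  }

  nodes <- data.frame(id = names(node_role), role = unname(node_role),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("partner network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges (",
      sum(grepl("predicted", x$edges$provenance)), "predicted /",
      sum(grepl("known", x$edges$provenance)), "known )\n")
  invisible(x)
}

#' Export / import a partner network
#'
#' \code{"tsv"} writes the edge list (\code{source}, \code{target},
#' \code{provenance}, \code{weight}) with full double precision, plus a
#' companion node table (\code{id}, \code{role}) when \code{nodes_path} is
#' given; \code{"graphml"} writes a single GraphML file carrying both node
#' roles and edge attributes. Both formats round-trip through
#' \code{import_graph}.
#'
#' @param g An \code{interaction_graph}.
#' @param path Output path (edge list for TSV, the GraphML file otherwise).
#' @param format \code{"tsv"} or \code{"graphml"}.
#' @param nodes_path Optional node-table path (TSV format only).
#' @export
export_graph <- function(g, path, format = c("tsv", "graphml"),
                         nodes_path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(g, "interaction_graph"))
  if (format == "tsv") {
    edges <- g$edges
    edges$weight <- sprintf("%.17g", edges$weight)
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(nodes_path)) {
      utils::write.table(g$nodes, nodes_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  } else {
    ig <- igraph::graph_from_data_frame(
      g$edges, directed = FALSE,
      vertices = g$nodes)
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_graph
#' @param path Path of the exported graph to read back.
#' @return \code{import_graph} returns an \code{interaction_graph}. A TSV
#'   import without a node table reconstructs the node set from the edge
#'   endpoints with role \code{"unknown"}.
#' @export
import_graph <- function(path, format = c("tsv", "graphml"),
                         nodes_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("graph file not found: ", path)
  if (format == "tsv") {
    edges <- utils::read.delim(path, header = TRUE,
                               colClasses = c("character", "character",
                                              "character", "character"))
    edges$weight <- as.numeric(edges$weight)
    if (!is.null(nodes_path)) {
      nodes <- utils::read.delim(nodes_path, header = TRUE,
                                 colClasses = "character")
    } else {
      ids <- sort(unique(c(edges$source, edges$target)))
      nodes <- data.frame(id = ids, role = "unknown",
                          stringsAsFactors = FALSE)
    }
  } else {
    ig <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(id = igraph::V(ig)$name,
                        role = igraph::V(ig)$role,
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(ig)
    edges <- data.frame(source = pmin(el[, 1], el[, 2]),
                        target = pmax(el[, 1], el[, 2]),
                        provenance = igraph::E(ig)$provenance,
                        weight = igraph::E(ig)$weight,
                        stringsAsFactors = FALSE)
  }
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "interaction_graph")
}
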