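#' Construct a co-occurrence network object
#'
#' A simple undirected graph over taxa, with signed Spearman-correlation
#' weighted edges. Isolated nodes (taxa passing the abundance filter but
#' with no strong association) are retained in the node set.
#'
#' @param taxa character vector of node (taxon) ids.
#' @param edges data frame with columns `from`, `to`, `rho`, `p`; one row
#'   per unordered node pair. Self-loops and duplicate pairs are rejected.
#' @param stratum optional label of the vegetation x fraction stratum.
#' @param community optional community type label (e.g. "bacteria").
#' @return object of class `cooccurrence_network` with an added `sign`
#'   column on the edges.
#' @export
cooccurrence_network <- function(taxa, edges = NULL, stratum = NA_character_,
                                 community = NA_character_) {
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) stop("cooccurrence_network: duplicated taxon id(s)")
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        rho = numeric(), p = numeric(),
                        sign = integer(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    need <- c("from", "to", "rho", "p")
    if (!all(need %in% names(edges))) {
      stop("cooccurrence_network: edges need columns ",
           paste(need, collapse = ", "))
    }
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    if (any(edges$from == edges$to)) {
      stop("cooccurrence_network: self-loops are not allowed")
    }
    unknown <- setdiff(c(edges$from, edges$to), taxa)
    if (length(unknown)) {
      stop("cooccurrence_network: edge endpoint(s) not in node set: ",
           paste(unique(unknown), collapse = ", "))
    }
    key <- apply(cbind(pmin(edges$from, edges$to),
                       pmax(edges$from, edges$to)), 1, paste, collapse = "\r")
    if (anyDuplicated(key)) {
      stop("cooccurrence_network: parallel edges are not allowed")
    }
    edges$sign <- ifelse(edges$rho >= 0, 1L, -1L)
    rownames(edges) <- NULL
  }
  structure(
    list(taxa = taxa, edges = edges, stratum = stratum, community = community),
    class = "cooccurrence_network"
  )
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("<cooccurrence_network> %s%s: %d nodes, %d edges (%d negative)\n",
              ifelse(is.na(x$community), "", paste0(x$community, " ")),
              ifelse(is.na(x$stratum), "network", x$stratum),
              length(x$taxa), nrow(x$edges), sum(x$edges$sign < 0)))
  invisible(x)
}

#' Convert a co-occurrence network to an igraph graph
#'
#' @param x a [cooccurrence_network()].
#' @return an undirected [igraph::graph] with `rho`, `p` and `sign` edge
#'   attributes and the full node set including isolates.
#' @export
as_igraph <- function(x) {
  stopifnot(inherits(x, "cooccurrence_network"))
  igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                vertices = data.frame(name = x$taxa))
}

#' Write a co-occurrence network to disk
#'
#' The `edge_list` format is a tab-separated table with columns `source`,
#' `target`, `rho`, `p`, `sign` (header always written, so an empty network
#' yields a header-only file). The `graphml` format additionally preserves
#' isolated nodes.
#'
#' @param x a [cooccurrence_network()].
#' @param path output file path.
#' @param format `"edge_list"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(x, path, format = c("edge_list", "graphml")) {
  stopifnot(inherits(x, "cooccurrence_network"))
  format <- match.arg(format)
  if (format == "edge_list") {
    df <- data.frame(source = x$edges$from, target = x$edges$to,
                     rho = x$edges$rho, p = x$edges$p, sign = x$edges$sign,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
  } else {
    igraph::write_graph(as_igraph(x), path, format = "graphml")
  }
  invisible(path)
}

#' Read a co-occurrence network from disk
#'
#' @param path file written by [write_network()].
#' @param format `"edge_list"` or `"graphml"`.
#' @param taxa optional node set for `edge_list` input (the edge-list format
#'   does not store isolated nodes); defaults to the nodes appearing in
#'   edges.
#' @return a [cooccurrence_network()].
#' @export
read_network <- function(path, format = c("edge_list", "graphml"),
                         taxa = NULL) {
  format <- match.arg(format)
  if (format == "edge_list") {
    df <- .read_tsv_strict(path)
    need <- c("source", "target", "rho", "p")
    if (!all(need %in% names(df))) {
      stop("read_network: edge list needs columns ", paste(need, collapse = ", "))
    }
    if (is.null(taxa)) taxa <- unique(c(df$source, df$target))
    cooccurrence_network(
      taxa,
      if (nrow(df)) data.frame(from = df$source, to = df$target,
                               rho = df$rho, p = df$p,
                               stringsAsFactors = FALSE) else NULL)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    ed <- igraph::as_data_frame(g, what = "edges")
    cooccurrence_network(
      igraph::V(g)$name,
      if (nrow(ed)) data.frame(from = ed$from, to = ed$to,
                               rho = ed$rho, p = ed$p,
                               stringsAsFactors = FALSE) else NULL)
  }
}
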