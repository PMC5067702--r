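#' Construct a typed protein-interaction network
#'
#' Undirected graph over gene symbols with two edge types:
#' \code{interaction} edges carry a confidence in [0, 1];
#' \code{association} edges link an ncRNA to its putative target and
#' carry no confidence. Self-loops and duplicate (u, v) pairs of the
#' same type are rejected.
#'
#' @param nodes character vector of node symbols (may include isolated
#'   nodes absent from the edge list).
#' @param edges data.frame with columns \code{u}, \code{v},
#'   \code{confidence}, \code{type}.
#' @return object of class \code{ppi_network}.
#' @export
ppi_network <- function(nodes = character(),
                        edges = data.frame(u = character(), v = character(),
                                           confidence = numeric(),
                                           type = character(),
                                           stringsAsFactors = FALSE)) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("u", "v", "confidence", "type") %in% names(edges)))
  if (any(edges$u == edges$v)) stop("self-loops are not allowed")
  if (!all(edges$type %in% c("interaction", "association"))) {
    stop("edge type must be 'interaction' or 'association'")
  }
  inter <- edges$type == "interaction"
  if (any(is.na(edges$confidence[inter]))) {
    stop("interaction edges must carry a confidence")
  }
  if (any(edges$confidence[inter] < 0 | edges$confidence[inter] > 1)) {
    stop("confidence must lie in [0, 1]")
  }
  key <- paste(pmin(edges$u, edges$v), pmax(edges$u, edges$v), edges$type,
               sep = "\r")
  if (anyDuplicated(key)) stop("duplicate edge of the same type")
  nodes <- sort(unique(c(nodes, edges$u, edges$v)))
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network:", length(x$nodes), "nodes,",
      sum(x$edges$type == "interaction"), "interaction /",
      sum(x$edges$type == "association"), "association edges\n")
  invisible(x)
}

#' Read a STRING-style edge table
#'
#' Expects a tab-separated file with columns \code{protein1},
#' \code{protein2}, \code{combined_score} (header optional; the first
#' three columns are used). Scores on the STRING 0-999 integer scale are
#' divided by 1000; a table whose maximum score is <= 1 is taken to be
#' already on the [0, 1] scale. Node symbols are upper-cased. Duplicate
#' pairs are collapsed to a single edge keeping the maximum confidence,
#' with a warning.
#'
#' @param path file path.
#' @return \code{\link{ppi_network}} of interaction edges.
#' @export
read_edge_table <- function(path) {
  if (!file.exists(path)) stop("edge table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(ppi_network())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (grepl("protein1", lines[1], ignore.case = TRUE)) {
    fields <- fields[-1]
    offset <- 1L
  } else offset <- 0L
  if (length(fields) == 0) return(ppi_network())
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- which(nf < 3)[1]
    stop("malformed edge-table line ", bad + offset,
         ": expected >= 3 tab-separated columns, got ", nf[bad])
  }
  u <- toupper(vapply(fields, `[`, character(1), 1))
  v <- toupper(vapply(fields, `[`, character(1), 2))
  sc <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3)))
  if (any(is.na(sc))) {
    bad <- which(is.na(sc))[1]
    stop("malformed edge-table line ", bad + offset, ": non-numeric score")
  }
  if (max(sc) > 1) sc <- sc / 1000
  if (any(sc < 0 | sc > 1)) stop("combined scores outside the 0-999 range")
  if (any(u == v)) {
    bad <- which(u == v)[1]
    stop("malformed edge-table line ", bad + offset, ": self-loop")
  }
  key <- paste(pmin(u, v), pmax(u, v), sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate pair(s) collapsed, ",
            "maximum confidence kept")
    sc <- stats::ave(sc, key, FUN = max)
    keep <- !duplicated(key)
    u <- u[keep]; v <- v[keep]; sc <- sc[keep]
  }
  ppi_network(edges = data.frame(u = u, v = v, confidence = sc,
                                 type = "interaction",
                                 stringsAsFactors = FALSE))
}

#' Filter interaction edges by confidence
#'
#' Interaction edges with confidence >= \code{min_conf} (inclusive) are
#' kept; association edges are exempt from the filter; nodes are
#' retained even when isolated.
#'
#' @param net \code{\link{ppi_network}}.
#' @param min_conf confidence threshold in [0, 1].
#' @return filtered \code{ppi_network}.
#' @export
filter_confidence <- function(net, min_conf) {
  stopifnot(inherits(net, "ppi_network"))
  if (min_conf < 0 || min_conf > 1) stop("min_conf must lie in [0, 1]")
  e <- net$edges
  keep <- e$type == "association" |
    (!is.na(e$confidence) & e$confidence >= min_conf)
  ppi_network(nodes = net$nodes, edges = e[keep, , drop = FALSE])
}

#' Induce the target-driven subnetwork
#'
#' Restricts the interaction network to the given target genes and
#' superimposes the ncRNA-target links as association-type edges.
#' Targets absent from the edge table still appear as nodes (degree 0 or
#' association-only), as do the ncRNAs themselves.
#'
#' @param net \code{\link{ppi_network}} (interaction edges).
#' @param targets character vector of target gene symbols.
#' @param assoc optional association data.frame with columns \code{ncrna}
#'   and \code{target}; pairs whose target is in \code{targets} are added
#'   as association edges.
#' @return induced \code{ppi_network}.
#' @export
induce_target_network <- function(net, targets, assoc = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  targets <- toupper(targets)
  e <- net$edges
  keep <- e$type == "interaction" & e$u %in% targets & e$v %in% targets
  edges <- e[keep, , drop = FALSE]
  nodes <- targets
  if (!is.null(assoc) && nrow(assoc) > 0) {
    an <- toupper(assoc$ncrna); at <- toupper(assoc$target)
    sel <- at %in% targets
    if (any(sel)) {
      add <- data.frame(u = an[sel], v = at[sel], confidence = NA_real_,
                        type = "association", stringsAsFactors = FALSE)
      key <- paste(pmin(add$u, add$v), pmax(add$u, add$v), sep = "\r")
      add <- add[!duplicated(key), , drop = FALSE]
      edges <- rbind(edges, add)
      nodes <- c(nodes, add$u)
    }
  }
  ppi_network(nodes = nodes, edges = edges)
}

as_igraph_interaction <- function(net, include_association = FALSE) {
  e <- net$edges
  if (!include_association) e <- e[e$type == "interaction", , drop = FALSE]
  igraph::graph_from_data_frame(
    e[, c("u", "v")], directed = FALSE,
    vertices = data.frame(name = net$nodes))
}

#' Connected components and shortest paths over interaction edges
#'
#' Components are computed over interaction edges only (association
#' edges represent a different relation and are excluded from
#' connectivity by default). When two endpoints are supplied, the
#' shortest path (fewest edges, ties broken by lexicographic node
#' sequence) is returned; endpoints in different components give a
#' "no path" result (\code{NULL} path), not an error.
#'
#' @param net \code{\link{ppi_network}}.
#' @param endpoints optional character vector of two node symbols.
#' @param include_association if TRUE, association edges also contribute
#'   to connectivity.
#' @return list with \code{components} (list of sorted node vectors,
#'   largest first) and \code{path} (character vector or NULL).
#' @export
components_and_paths <- function(net, endpoints = NULL,
                                 include_association = FALSE) {
  stopifnot(inherits(net, "ppi_network"))
  g <- as_igraph_interaction(net, include_association)
  memb <- igraph::components(g)$membership
  comps <- lapply(split(names(memb), memb), function(x) sort(unname(x)))
  names(comps) <- NULL
  comps <- comps[order(-lengths(comps),
                       vapply(comps, `[`, character(1), 1))]
  path <- NULL
  if (!is.null(endpoints)) {
    endpoints <- toupper(endpoints)
    if (length(endpoints) != 2) stop("endpoints must name exactly two nodes")
    absent <- setdiff(endpoints, net$nodes)
    if (length(absent) > 0) {
      stop("endpoint(s) not in network: ", paste(absent, collapse = ", "))
    }
    if (memb[endpoints[1]] == memb[endpoints[2]]) {
      sp <- igraph::all_shortest_paths(g, from = endpoints[1],
                                       to = endpoints[2])$vpaths
      seqs <- lapply(sp, function(p) igraph::V(g)$name[as.integer(p)])
      ord <- order(vapply(seqs, paste, character(1), collapse = "\r"))
      path <- seqs[[ord[1]]]
    }
  }
  list(components = comps, path = path)
}

#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then member genes.
#'
#' @param path file path.
#' @return named list of character vectors (the description is kept in
#'   the \code{"descriptions"} attribute).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- which(nf < 3)[1]
    stop("malformed GMT line ", bad, ": expected >= 3 columns")
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[`, character(1), 2), names(sets))
  sets
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set (intersected with the background), the upper-tail
#' hypergeometric probability P(X >= overlap) of drawing at least the
#' observed overlap when sampling |query| genes without replacement from
#' the background is computed, followed by Benjamini-Hochberg adjustment
#' across sets. Rows are sorted by q then p.
#'
#' @param query character vector of genes (must be a subset of
#'   \code{background}).
#' @param gene_sets named list of character vectors.
#' @param background character vector defining the gene universe
#'   (non-empty).
#' @return data.frame with columns \code{set}, \code{overlap},
#'   \code{set_size}, \code{query_size}, \code{background_size},
#'   \code{p}, \code{q}.
#' @export
overrepresentation <- function(query, gene_sets, background) {
  background <- unique(background)
  if (length(background) == 0) stop("background must be non-empty")
  query <- unique(query)
  outside <- setdiff(query, background)
  if (length(outside) > 0) {
    stop("query gene(s) absent from background: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  N <- length(background); n <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), background)
    m <- length(s)
    k <- length(intersect(s, query))
    p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = m, query_size = n,
               background_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(), overlap = integer(),
                      set_size = integer(), query_size = integer(),
                      background_size = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  }
  out$q <- bh_adjust(out$p)
  out <- out[order(out$q, out$p, out$set), ]
  rownames(out) <- NULL
  out
}
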