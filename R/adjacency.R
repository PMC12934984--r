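# County adjacency graph backing the ICAR prior.

#' Construct an adjacency graph
#'
#' An undirected simple graph over county identifiers. Edges are stored as
#' unordered pairs; duplicates and reversed duplicates are collapsed.
#' Self-loops are rejected (an ICAR neighbor structure has none).
#'
#' @param nodes character vector of county identifiers.
#' @param edges two-column matrix or data.frame of county pairs (character).
#' @return an `adjacency_graph` with elements `nodes` and `edges`
#'   (two-column character matrix, lexicographically ordered pairs).
#' @export
adjacency_graph <- function(nodes, edges) {
  nodes <- sort(unique(as.character(nodes)))
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("edges must have two columns", call. = FALSE)
  mode(edges) <- "character"
  if (nrow(edges) > 0) {
    loops <- edges[, 1] == edges[, 2]
    if (any(loops)) {
      stop("self-loop edge not allowed: (", edges[which(loops)[1], 1], ", ",
           edges[which(loops)[1], 2], ")", call. = FALSE)
    }
    unknown <- setdiff(c(edges), nodes)
    if (length(unknown) > 0) nodes <- sort(unique(c(nodes, unknown)))
    a <- pmin(edges[, 1], edges[, 2])
    b <- pmax(edges[, 1], edges[, 2])
    keep <- !duplicated(paste(a, b, sep = "\r"))
    edges <- cbind(a[keep], b[keep])
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  } else {
    edges <- matrix(character(0), ncol = 2)
  }
  colnames(edges) <- c("county_a", "county_b")
  structure(list(nodes = nodes, edges = edges), class = "adjacency_graph")
}

#' Load a county adjacency graph
#'
#' Accepts either a two-column CSV edge list (`county_a`, `county_b`) or a
#' JSON object mapping each county to its neighbor list. Reversed and
#' duplicated edges are deduplicated; a self-loop is fatal.
#'
#' @param path path to the edge-list CSV or neighbor-map JSON.
#' @param nodes optional county universe (e.g. `panel_counties(panel)`);
#'   isolated counties absent from the edge list are then retained as nodes.
#' @return an `adjacency_graph`.
#' @export
load_adjacency <- function(path, nodes = NULL) {
  if (!file.exists(path)) stop("adjacency file not found: ", path,
                               call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    nb <- jsonlite::read_json(path, simplifyVector = TRUE)
    edges <- do.call(rbind, lapply(names(nb), function(a) {
      if (length(nb[[a]]) == 0) return(NULL)
      cbind(a, as.character(unlist(nb[[a]])))
    }))
    if (is.null(edges)) edges <- matrix(character(0), ncol = 2)
    all_nodes <- union(names(nb), if (is.null(nodes)) character(0) else nodes)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("county_a", "county_b") %in% names(df))) {
      stop("edge list must have columns county_a, county_b", call. = FALSE)
    }
    edges <- cbind(as.character(df$county_a), as.character(df$county_b))
    all_nodes <- union(c(edges), if (is.null(nodes)) character(0) else nodes)
  }
  adjacency_graph(all_nodes, edges)
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("adjacency_graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges,", n_components(x), "component(s)\n")
  invisible(x)
}

#' Graph accessors
#' @param graph an `adjacency_graph`
#' @return `graph_nodes`: node ids; `graph_edges`: 2-column character matrix;
#'   `n_components`: number of connected components; `graph_components`:
#'   integer component label per node (named).
#' @export
graph_nodes <- function(graph) graph$nodes

#' @rdname graph_nodes
#' @export
graph_edges <- function(graph) graph$edges

.as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    as.data.frame(graph$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = graph$nodes, stringsAsFactors = FALSE))
}

#' @rdname graph_nodes
#' @export
graph_components <- function(graph) {
  comp <- igraph::components(.as_igraph(graph))
  memb <- comp$membership
  memb[graph$nodes]
}

#' @rdname graph_nodes
#' @export
n_components <- function(graph) {
  max(graph_components(graph))
}

#' Edge indices relative to the sorted node vector
#' @keywords internal
.edge_index <- function(graph) {
  cbind(match(graph$edges[, 1], graph$nodes),
        match(graph$edges[, 2], graph$nodes))
}

#' Graph Laplacian Q = D - W of the adjacency structure
#' @param graph an `adjacency_graph`
#' @return dense symmetric matrix, rows/cols ordered as `graph_nodes(graph)`.
#' @export
graph_laplacian <- function(graph) {
  n <- length(graph$nodes)
  Q <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  ei <- .edge_index(graph)
  for (k in seq_len(nrow(ei))) {
    i <- ei[k, 1]; j <- ei[k, 2]
    Q[i, j] <- Q[i, j] - 1
    Q[j, i] <- Q[j, i] - 1
    Q[i, i] <- Q[i, i] + 1
    Q[j, j] <- Q[j, j] + 1
  }
  Q
}

# Orthonormal basis of the ICAR support: eigenvectors of the Laplacian with
# nonzero eigenvalue (one zero per connected component). phi = V %*% u has
# sum zero within every component for any u.
.icar_basis <- function(graph) {
  Q <- graph_laplacian(graph)
  eg <- eigen(Q, symmetric = TRUE)
  keep <- eg$values > 1e-8
  list(V = eg$vectors[, keep, drop = FALSE],
       lambda = eg$values[keep],
       rank = sum(keep),
       Q = Q)
}

# hard sum-to-zero centering within each connected component
.center_phi <- function(phi, graph) {
  comp <- graph_components(graph)
  for (k in unique(comp)) {
    idx <- which(comp == k)
    phi[idx] <- phi[idx] - mean(phi[idx])
  }
  phi
}
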