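#' Construct an undirected simple network
#'
#' The basic substrate for all detection and benchmark machinery: a set of
#' opaque node labels plus an undirected, loop-free, deduplicated edge set.
#' Node labels are kept verbatim; all internal ordering uses a stable
#' byte-wise (C locale) sort so that results are reproducible across
#' platforms and locales.
#'
#' @param edges two-column character matrix (or data.frame) of edges, one
#'   edge per row.  Duplicate rows and reversed duplicates collapse to a
#'   single undirected edge.
#' @param nodes optional character vector of node labels; labels appearing
#'   in `edges` are added automatically, so this is only needed for
#'   isolated nodes.
#' @return an object of class `rwa_network` with elements `nodes` (sorted
#'   character vector) and `adj` (named list; `adj[[v]]` is the sorted
#'   character vector of neighbors of `v`).
#' @export
#' @examples
#' net <- network(rbind(c("a", "b"), c("b", "c")))
#' net_degree(net)
network <- function(edges = NULL, nodes = NULL) {
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    if (length(edges) == 0L) {
      edges <- matrix(character(), ncol = 2L)
    }
    if (ncol(edges) != 2L) stop("edges must have two columns")
    storage.mode(edges) <- "character"
    if (any(edges[, 1L] == edges[, 2L])) {
      bad <- edges[edges[, 1L] == edges[, 2L], 1L][1L]
      stop("self-loop at node '", bad, "' is not allowed")
    }
  } else {
    edges <- matrix(character(), ncol = 2L)
  }
  nodes <- sort(unique(c(as.character(nodes), as.vector(edges))),
                method = "radix")
  # canonicalize each edge as (min, max) and dedup
  if (nrow(edges) > 0L) {
    a <- pmin(edges[, 1L], edges[, 2L])
    b <- pmax(edges[, 1L], edges[, 2L])
    key <- !duplicated(paste(a, b, sep = "\r"))
    a <- a[key]; b <- b[key]
  } else {
    a <- b <- character()
  }
  adj <- rep(list(character()), length(nodes))
  names(adj) <- nodes
  if (length(a) > 0L) {
    half <- split(c(b, a), c(a, b))
    adj[names(half)] <- lapply(half, sort, method = "radix")
  }
  structure(list(nodes = nodes, adj = adj),
            class = "rwa_network")
}

#' @export
print.rwa_network <- function(x, ...) {
  cat("rwa_network:", length(x$nodes), "nodes,",
      sum(lengths(x$adj)) / 2L, "edges\n")
  invisible(x)
}

#' Node degrees
#' @param net an `rwa_network`
#' @return named integer vector of degrees
#' @export
net_degree <- function(net) {
  lengths(net$adj)
}

#' Neighbors of a node
#' @param net an `rwa_network`
#' @param v node label
#' @return character vector of neighbor labels (sorted)
#' @export
net_neighbors <- function(net, v) {
  if (!v %in% net$nodes) stop("unknown node '", v, "'")
  net$adj[[v]]
}

#' Edge list of a network
#' @param net an `rwa_network`
#' @return two-column character matrix, one undirected edge per row
#' @export
net_edges <- function(net) {
  out <- lapply(net$nodes, function(v) {
    nb <- net$adj[[v]]
    nb <- nb[nb > v]
    if (length(nb)) cbind(v, nb) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- matrix(character(), ncol = 2L)
  dimnames(out) <- NULL
  out
}

n_edges <- function(net) sum(lengths(net$adj)) / 2L

#' Connected components
#' @param net an `rwa_network`
#' @return list of character vectors, each the node set of one component,
#'   ordered by their smallest label
#' @keywords internal
net_components <- function(net) {
  seen <- stats::setNames(rep(FALSE, length(net$nodes)), net$nodes)
  comps <- list()
  for (v in net$nodes) {
    if (seen[[v]]) next
    stack <- v
    comp <- character()
    while (length(stack)) {
      x <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (seen[[x]]) next
      seen[[x]] <- TRUE
      comp <- c(comp, x)
      stack <- c(stack, net$adj[[x]][!seen[net$adj[[x]]]])
    }
    comps[[length(comps) + 1L]] <- sort(comp, method = "radix")
  }
  comps
}

#' Read a network from disk
#'
#' Edge lists are one edge per line, two whitespace-separated labels;
#' blank lines and lines starting with `#` are ignored; repeated or
#' reversed edge lines collapse to one undirected edge.  GML files are
#' parsed with igraph and node `label`/`name`/`id` attributes are kept
#' verbatim.  Self-loops are rejected in either dialect.
#'
#' @param path file path
#' @param format `"edgelist"` or `"gml"`
#' @return an [network()] object
#' @export
read_network <- function(path, format = c("edgelist", "gml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edgelist") {
    lines <- readLines(path, warn = FALSE)
    keep <- which(!grepl("^\\s*(#|$)", lines))
    toks <- strsplit(trimws(lines[keep]), "\\s+")
    nbad <- lengths(toks) != 2L
    if (any(nbad)) {
      stop("malformed edge list line ", keep[which(nbad)[1L]],
           " in '", path, "': expected two whitespace-separated labels")
    }
    edges <- do.call(rbind, toks)
    if (is.null(edges)) edges <- matrix(character(), ncol = 2L)
    network(edges)
  } else {
    g <- igraph::read_graph(path, format = "gml")
    va <- igraph::vertex_attr_names(g)
    lab <- if ("label" %in% va) {
      igraph::vertex_attr(g, "label")
    } else if ("name" %in% va) {
      igraph::vertex_attr(g, "name")
    } else if ("id" %in% va) {
      igraph::vertex_attr(g, "id")
    } else {
      seq_len(igraph::vcount(g))
    }
    lab <- as.character(lab)
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- cbind(lab[el[, 1L]], lab[el[, 2L]])
    network(edges, nodes = lab)
  }
}

#' Write a network to disk
#'
#' @param net an `rwa_network`
#' @param path file path
#' @param format `"edgelist"` or `"gml"`
#' @return `path`, invisibly
#' @export
write_network <- function(net, path, format = c("edgelist", "gml")) {
  format <- match.arg(format)
  el <- net_edges(net)
  if (format == "edgelist") {
    writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), path)
  } else {
    idx <- stats::setNames(seq_along(net$nodes) - 1L, net$nodes)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("graph [", con)
    writeLines("  directed 0", con)
    for (v in net$nodes) {
      writeLines(sprintf('  node [ id %d label "%s" ]', idx[[v]], v), con)
    }
    if (nrow(el)) {
      writeLines(sprintf("  edge [ source %d target %d ]",
                         idx[el[, 1L]], idx[el[, 2L]]), con)
    }
    writeLines("]", con)
  }
  invisible(path)
}

#' Similarity configuration
#'
#' Chooses the structural node-similarity that drives the random walk.
#' Both variants score a node pair by agreement of their closed
#' neighborhoods (the node itself plus its neighbors), so adjacent nodes
#' always have positive similarity:
#' \describe{
#'   \item{`closed_jaccard` (default)}{`|G[u] n G[v]| / |G[u] u G[v]|`}
#'   \item{`closed_cosine`}{`|G[u] n G[v]| / sqrt(|G[u]| |G[v]|)`}
#' }
#' where `G[x]` is the closed neighborhood of `x`.
#'
#' @param variant `"closed_jaccard"` or `"closed_cosine"`
#' @return object of class `rwa_similarity_config`
#' @export
similarity_config <- function(variant = c("closed_jaccard", "closed_cosine")) {
  variant <- match.arg(variant)
  structure(list(variant = variant), class = "rwa_similarity_config")
}

#' Structural similarity between two nodes
#'
#' Symmetric, 1 for `u == v`, in `[0, 1]`, and positive for adjacent
#' nodes (closed neighborhoods always share both endpoints of an edge).
#'
#' @param net an `rwa_network`
#' @param u,v node labels
#' @param cfg a [similarity_config()]
#' @return similarity in `[0, 1]`
#' @export
#' @examples
#' path3 <- network(rbind(c("a", "b"), c("b", "c")))
#' structural_similarity(path3, "a", "c")  # 1/3
structural_similarity <- function(net, u, v, cfg = similarity_config()) {
  for (x in c(u, v)) {
    if (!x %in% net$nodes) stop("unknown node '", x, "'")
  }
  gu <- c(u, net$adj[[u]])
  gv <- c(v, net$adj[[v]])
  inter <- length(intersect(gu, gv))
  if (cfg$variant == "closed_jaccard") {
    inter / length(union(gu, gv))
  } else {
    inter / sqrt(length(gu) * length(gv))
  }
}

# Full pairwise similarity matrix over net$nodes (dense, labels as
# dimnames).  Uses B = A + I so that |G[u] n G[v]| = (B %*% B)[u, v];
# cached by callers that repeatedly slice it.
similarity_matrix <- function(net, cfg = similarity_config()) {
  n <- length(net$nodes)
  B <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  for (i in seq_len(n)) {
    B[i, net$adj[[i]]] <- 1
  }
  diag(B) <- 1
  inter <- B %*% B
  sz <- rowSums(B)
  if (cfg$variant == "closed_jaccard") {
    uni <- outer(sz, sz, "+") - inter
    S <- inter / uni
  } else {
    S <- inter / sqrt(outer(sz, sz))
  }
  S
}

# Normalize rows of a non-negative matrix with zero diagonal into a
# row-stochastic transition matrix; all-zero rows fall back to the
# uniform distribution over the other indices.
normalize_walk_rows <- function(S) {
  m <- nrow(S)
  diag(S) <- 0
  rs <- rowSums(S)
  dead <- rs <= 0
  if (any(dead)) {
    S[dead, ] <- 1 / (m - 1)
    S[cbind(which(dead), which(dead))] <- 0
    rs[dead] <- 1
  }
  S / rs
}

#' Random-walk transition matrix over an ordered node set
#'
#' Entry `(i, j)`, `i != j`, is the structural similarity of the pair
#' normalized by the row's off-diagonal similarity mass; the diagonal is
#' zero and every row sums to one.  A node with zero similarity to every
#' other listed node gets a uniform row over the remaining indices so the
#' matrix stays stochastic.
#'
#' @param net an `rwa_network`
#' @param ordered_nodes character vector (length >= 2) of node labels
#'   fixing the matrix index order
#' @param cfg a [similarity_config()]
#' @return `m x m` row-stochastic matrix with `dimnames = ordered_nodes`
#' @export
walk_matrix <- function(net, ordered_nodes, cfg = similarity_config()) {
  ordered_nodes <- as.character(ordered_nodes)
  if (length(ordered_nodes) < 2L) {
    stop("walk matrix needs at least two nodes (no off-diagonal mass)")
  }
  if (!all(ordered_nodes %in% net$nodes)) {
    stop("unknown node '",
         ordered_nodes[!ordered_nodes %in% net$nodes][1L], "'")
  }
  S <- similarity_matrix(net, cfg)[ordered_nodes, ordered_nodes]
  normalize_walk_rows(S)
}
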