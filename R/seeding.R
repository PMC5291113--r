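#' Seed-community parameters
#'
#' `Z` is the target seed size; dense subgraphs with fewer than three
#' nodes carry no community signal, so `Z >= 3`, and sensitivity analysis
#' favors the default `Z = 3` (a complete triple around a hub).
#'
#' @param Z integer seed size, `>= 3`
#' @param hub_rule hub definition handed to
#'   [local_maximal_degree_nodes()]; the pipeline default is
#'   `"neighborhood_mean"`, which keeps hubs dispersed across
#'   communities on graphs with broad degree distributions
#' @return object of class `rwa_seed_params`
#' @export
seed_params <- function(Z = 3L, hub_rule = "neighborhood_mean") {
  Z <- as.integer(Z)
  if (is.na(Z) || Z < 3L) stop("Z must be an integer >= 3")
  hub_rule <- match.arg(hub_rule, c("neighborhood_mean", "strict_max"))
  structure(list(Z = Z, hub_rule = hub_rule), class = "rwa_seed_params")
}

#' Local maximal degree nodes
#'
#' Local hubs around which seed communities are grown.  Two readings of
#' "a node with more edges than its neighbors" are provided:
#' \describe{
#'   \item{`strict_max` (default)}{degree at least the degree of *each*
#'     neighbor (ties admit the node).}
#'   \item{`neighborhood_mean`}{degree at least the *mean* degree of the
#'     neighbors.  On graphs with broad degree distributions the strict
#'     rule leaves most communities without any hub, because a single
#'     higher-degree node in an adjacent community disqualifies every
#'     local candidate; the mean rule keeps one or more hubs inside
#'     essentially every community, which is what the detection pipeline
#'     needs (it is the pipeline default via [seed_params()]).}
#' }
#' Both rules agree on paradigmatic cases (star center, middle of a
#' path, all corners of a triangle).  Isolated nodes are excluded.
#'
#' @param net an `rwa_network`
#' @param rule `"strict_max"` or `"neighborhood_mean"`
#' @return sorted character vector of hub labels
#' @export
#' @examples
#' star <- network(cbind("c", c("l1", "l2", "l3", "l4")))
#' local_maximal_degree_nodes(star)  # "c"
local_maximal_degree_nodes <- function(net,
                                       rule = c("strict_max",
                                                "neighborhood_mean")) {
  rule <- match.arg(rule)
  if (length(net$nodes) == 0L) stop("empty network")
  deg <- net_degree(net)
  hubs <- vapply(net$nodes, function(v) {
    dv <- deg[[v]]
    if (dv == 0L) return(FALSE)
    if (rule == "strict_max") {
      all(deg[net$adj[[v]]] <= dv)
    } else {
      dv >= mean(deg[net$adj[[v]]])
    }
  }, logical(1))
  net$nodes[hubs]
}

# Greedily grow a connected dense set from a triple up to size Z by
# repeatedly adding the common neighbor of the current members that
# maximizes the number of edges into the set (ties lexicographic).
grow_seed <- function(net, members, Z) {
  while (length(members) < Z) {
    cand <- Reduce(intersect, net$adj[members])
    cand <- setdiff(cand, members)
    if (length(cand) == 0L) break
    gain <- vapply(cand, function(x) {
      sum(net$adj[[x]] %in% members)
    }, numeric(1))
    best <- sort(cand[gain == max(gain)], method = "radix")[1L]
    members <- c(members, best)
  }
  sort(members, method = "radix")
}

#' Detect seed communities
#'
#' For every local maximal degree hub `n1`, its highest-degree
#' triangle-forming neighbor(s) `n2` (neighbors sharing at least one
#' common neighbor with the hub; a pure bridge endpoint never
#' qualifies), and every common neighbor `n3` of the pair, the triple
#' `{n1, n2, n3}` is a candidate
#' seed (grown greedily to `Z` members when `Z > 3`).  Duplicate node
#' sets are emitted once and seeds wholly contained in another seed are
#' dropped.  A connected component that yields no triangle seed falls
#' back to its highest-degree node plus its top `Z - 1` neighbors, so
#' every component can be seeded.
#'
#' @param net an `rwa_network`
#' @param params a [seed_params()]
#' @return list of seeds, each a list with `members` (sorted character
#'   vector) and `anchor` (the hub it grew from)
#' @export
detect_seed_communities <- function(net, params = seed_params()) {
  if (length(net$nodes) == 0L) stop("empty network")
  Z <- params$Z
  deg <- net_degree(net)
  hubs <- local_maximal_degree_nodes(net, params$hub_rule)
  seeds <- list()
  keys <- character()
  add_seed <- function(members, anchor) {
    key <- paste(members, collapse = "\r")
    if (!key %in% keys) {
      keys <<- c(keys, key)
      seeds[[length(seeds) + 1L]] <<- list(members = members, anchor = anchor)
    }
  }
  for (n1 in hubs) {
    nb <- net$adj[[n1]]
    if (length(nb) == 0L) next
    # partner n2: among neighbors of n1 that share at least one common
    # neighbor with it (i.e. close a triangle; a pure bridge endpoint
    # never qualifies), the one(s) of maximal degree
    has_cn <- nb[vapply(nb, function(v) {
      any(net$adj[[v]] %in% nb)
    }, logical(1))]
    if (length(has_cn) == 0L) next
    top <- has_cn[deg[has_cn] == max(deg[has_cn])]
    for (n2 in top) {
      common <- intersect(net$adj[[n1]], net$adj[[n2]])
      for (n3 in common) {
        add_seed(grow_seed(net, c(n1, n2, n3), Z), n1)
      }
    }
  }
  # drop seeds fully contained in a strictly larger seed (only possible
  # when grown seeds differ in size; identical sets are already deduped)
  sz <- vapply(seeds, function(s) length(s$members), integer(1))
  if (length(seeds) > 1L && length(unique(sz)) > 1L) {
    ord <- order(-sz)
    keep <- rep(TRUE, length(seeds))
    for (pos in seq_along(ord)) {
      i <- ord[pos]
      if (!keep[i]) next
      for (j in ord[seq_len(pos - 1L)]) {
        if (keep[j] && sz[j] > sz[i] &&
            all(seeds[[i]]$members %in% seeds[[j]]$members)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    seeds <- seeds[keep]
  }
  # fallback for components without any seed
  for (comp in net_components(net)) {
    covered <- any(vapply(seeds, function(s) {
      any(s$members %in% comp)
    }, logical(1)))
    if (covered || length(comp) == 0L) next
    hub <- comp[order(-deg[comp], comp, method = "radix")][1L]
    nb <- net$adj[[hub]]
    nb <- nb[order(-deg[nb], nb, method = "radix")]
    members <- sort(c(hub, utils::head(nb, Z - 1L)), method = "radix")
    add_seed(members, hub)
  }
  if (length(seeds) == 0L) stop("no seed community could be detected")
  # deterministic output order: by members lexicographically
  ord <- order(vapply(seeds, function(s) paste(s$members, collapse = "\r"),
                      character(1)), method = "radix")
  seeds[ord]
}

#' Consolidate seed triples into dispersed anchor seeds
#'
#' The raw triple enumeration yields several heavily overlapping triples
#' per hub (one per common neighbor).  Consolidation first unions all
#' triples sharing an anchor into one dense blob per hub, then walks the
#' anchors in decreasing degree order (ties by label) and admits a blob
#' only when it is node-disjoint from every blob admitted so far.  A
#' suppressed blob's region is already represented, so this yields at
#' most one seed per dense region -- at most one per hub, dispersed
#' across the network -- while disjoint regions (in particular different
#' planted communities) always keep their own seed.
#'
#' @param net an `rwa_network`
#' @param seeds list of seeds from [detect_seed_communities()]
#' @return a [community_set()] of disjoint seed communities
#' @export
consolidate_seeds <- function(net, seeds) {
  anchors <- vapply(seeds, `[[`, character(1), "anchor")
  blobs <- lapply(split(seeds, anchors), function(group) {
    sort(unique(unlist(lapply(group, `[[`, "members"))), method = "radix")
  })
  deg <- net_degree(net)
  anc <- names(blobs)
  anc <- anc[order(-deg[anc], anc, method = "radix")]
  admitted <- list()
  claimed <- character()
  for (a in anc) {
    if (!any(blobs[[a]] %in% claimed)) {
      admitted[[length(admitted) + 1L]] <- blobs[[a]]
      claimed <- c(claimed, blobs[[a]])
    }
  }
  community_set(admitted)
}
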