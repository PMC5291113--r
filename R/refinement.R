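#' Merge parameters
#'
#' @param xi overlap-coefficient threshold in `(0, 1]`; default 0.5, i.e.
#'   two communities merge when most members of the smaller one already
#'   sit in the larger one.
#' @return object of class `rwa_merge_params`
#' @export
merge_params <- function(xi = 0.5) {
  if (!(xi > 0 && xi <= 1)) stop("xi must be in (0, 1]")
  structure(list(xi = xi), class = "rwa_merge_params")
}

#' Tightness between a node and a community
#'
#' The fraction of community members adjacent to `u`:
#' `num1 / num2` with `num1` the number of members connected to `u` and
#' `num2` the community size.
#'
#' @param net an `rwa_network`
#' @param u node label, not a member of `community`
#' @param community character vector of member labels (non-empty)
#' @return number in `[0, 1]`
#' @export
tightness <- function(net, u, community) {
  community <- as.character(community)
  if (length(community) == 0L) stop("empty community")
  if (u %in% community) stop("node '", u, "' is a member of the community")
  sum(net$adj[[u]] %in% community) / length(community)
}

#' Attach unassigned nodes to their tightest community
#'
#' Every node absent from all communities is added to the community with
#' the largest tightness, processed in increasing degree order (lowest
#' label first on degree ties; community ties go to the lowest index).  A
#' node with zero tightness to every community (no edge into any of them)
#' becomes its own singleton community.
#'
#' @param net an `rwa_network`
#' @param cs a [community_set()]
#' @return a [community_set()]
#' @export
assign_leftovers <- function(net, cs) {
  cs <- as_community_set(cs)
  left <- setdiff(net$nodes, community_members(cs))
  if (length(left) == 0L) return(cs)
  deg <- net_degree(net)
  left <- left[order(deg[left], left, method = "radix")]
  comms <- unclass(cs)
  for (u in left) {
    tt <- vapply(comms, function(comm) {
      sum(net$adj[[u]] %in% comm) / length(comm)
    }, numeric(1))
    if (max(tt) > 0) {
      k <- which.max(tt)
      comms[[k]] <- sort(c(comms[[k]], u), method = "radix")
    } else {
      comms[[length(comms) + 1L]] <- u
    }
  }
  community_set(comms)
}

overlap_coefficient <- function(a, b) {
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Merge heavily overlapping communities
#'
#' While any pair has overlap coefficient
#' `|Ci n Cj| / min(|Ci|, |Cj|) >= xi`, the pair with the largest
#' coefficient (ties: lowest indices) is replaced by its union.  The
#' community count strictly decreases at each merge, so the loop
#' terminates; at the fixpoint the operation is idempotent.
#'
#' @param cs a [community_set()]
#' @param mp a [merge_params()]
#' @return a [community_set()]
#' @export
merge_communities <- function(cs, mp = merge_params()) {
  comms <- unclass(as_community_set(cs))
  if (length(comms) < 2L) return(community_set(comms))
  nodes <- sort(unique(unlist(comms, use.names = FALSE)), method = "radix")
  # incidence matrix: X[k, v] = 1 iff node v in community k
  X <- matrix(0, length(comms), length(nodes),
              dimnames = list(NULL, nodes))
  for (k in seq_along(comms)) X[k, comms[[k]]] <- 1
  alive <- rep(TRUE, nrow(X))
  inter <- tcrossprod(X)
  sz <- rowSums(X)
  ratio <- inter / outer(sz, sz, pmin)
  diag(ratio) <- 0
  repeat {
    if (max(ratio[alive, alive]) < mp$xi) break
    # pair with the largest overlap coefficient, ties by lowest indices
    idx <- which(ratio == max(ratio[alive, alive]), arr.ind = TRUE)
    idx <- idx[alive[idx[, 1L]] & alive[idx[, 2L]], , drop = FALSE]
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    X[i, ] <- pmax(X[i, ], X[j, ])
    alive[j] <- FALSE
    sz[i] <- sum(X[i, ])
    new_inter <- as.numeric(X %*% X[i, ])
    inter[i, ] <- new_inter
    inter[, i] <- new_inter
    ratio[i, ] <- inter[i, ] / pmin(sz[i], sz)
    ratio[, i] <- ratio[i, ]
    diag(ratio) <- 0
    ratio[!alive, ] <- 0
    ratio[, !alive] <- 0
    if (sum(alive) < 2L) break
  }
  out <- lapply(which(alive), function(k) nodes[X[k, ] > 0])
  community_set(out)
}

#' Resolve overlaps into a total disjoint partition
#'
#' Each node still present in two or more communities is kept in the one
#' to which it is tightest (computed against the community without the
#' node itself; ties go to the lowest index).  Community indices are
#' renumbered contiguously from 1, dropping any community emptied by the
#' resolution.
#'
#' @param net an `rwa_network`
#' @param cs a [community_set()] whose union covers all nodes of `net`
#' @return named integer vector mapping every node label to a community
#'   index in `1..q`
#' @export
finalize_partition <- function(net, cs) {
  cs <- as_community_set(cs)
  members <- community_members(cs)
  if (!setequal(members, net$nodes)) {
    stop("internal error: community set does not cover the network")
  }
  q <- length(cs)
  count <- integer(length(net$nodes))
  names(count) <- net$nodes
  for (comm in cs) count[comm] <- count[comm] + 1L
  assign <- stats::setNames(rep(NA_integer_, length(net$nodes)), net$nodes)
  for (k in seq_len(q)) {
    one <- cs[[k]][count[cs[[k]]] == 1L]
    assign[one] <- k
  }
  for (u in names(assign)[is.na(assign)]) {
    holds <- which(vapply(cs, function(comm) u %in% comm, logical(1)))
    tt <- vapply(holds, function(k) {
      rest <- setdiff(cs[[k]], u)
      if (length(rest) == 0L) 0 else sum(net$adj[[u]] %in% rest) / length(rest)
    }, numeric(1))
    assign[u] <- holds[which.max(tt)]
  }
  # contiguous indices in order of first appearance by community index
  used <- sort(unique(assign))
  stats::setNames(match(assign, used), names(assign))
}

#' Detect communities with the full seed-expansion pipeline
#'
#' Runs, in order: seed detection around local maximal degree hubs;
#' consolidation of overlapping seed triples into one dispersed seed per
#' dense region ([consolidate_seeds()]; disable with
#' `consolidate = FALSE` to expand the raw triples); greedy random-walk
#' expansion; tightness-based assignment of leftover nodes;
#' overlap-driven merging; and final overlap resolution into a disjoint
#' total partition.  Fully deterministic given its inputs.
#'
#' @param net an `rwa_network`
#' @param sp a [seed_params()]
#' @param wp a [walk_params()]
#' @param mp a [merge_params()]
#' @param cfg a [similarity_config()]
#' @param consolidate consolidate seed triples with
#'   [consolidate_seeds()] before expansion; default `TRUE`
#' @param merge_before_leftovers run the merge step before leftover
#'   assignment instead of after; default `FALSE`
#' @return named integer vector (node label -> community index, 1-based
#'   contiguous)
#' @export
#' @examples
#' cl <- function(p, n) t(utils::combn(paste0(p, seq_len(n)), 2))
#' net <- network(rbind(cl("a", 4), cl("b", 4), c("a1", "b1")))
#' table(run_rwa(net))  # two communities of 4
run_rwa <- function(net,
                    sp = seed_params(),
                    wp = walk_params(),
                    mp = merge_params(),
                    cfg = similarity_config(),
                    consolidate = TRUE,
                    merge_before_leftovers = FALSE) {
  if (length(net$nodes) == 0L) stop("empty network")
  if (length(net$nodes) == 1L) {
    return(stats::setNames(1L, net$nodes))
  }
  seeds <- detect_seed_communities(net, sp)
  seed_cs <- if (isTRUE(consolidate)) {
    consolidate_seeds(net, seeds)
  } else {
    community_set(lapply(seeds, `[[`, "members"))
  }
  cs <- expand_communities(net, seed_cs, wp, cfg)
  if (isTRUE(merge_before_leftovers)) {
    cs <- merge_communities(cs, mp)
    cs <- assign_leftovers(net, cs)
  } else {
    cs <- assign_leftovers(net, cs)
    cs <- merge_communities(cs, mp)
  }
  finalize_partition(net, cs)
}

#' Read a membership file
#'
#' One `label<TAB>community_id` pair per line (any whitespace accepted);
#' `#` comments and blank lines are ignored.
#'
#' @param path file path
#' @return named integer vector (node label -> contiguous community index)
#' @export
read_membership <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  nbad <- lengths(toks) != 2L
  if (any(nbad)) {
    stop("malformed membership line ", keep[which(nbad)[1L]], " in '",
         path, "'")
  }
  lab <- vapply(toks, `[[`, character(1), 1L)
  com <- vapply(toks, `[[`, character(1), 2L)
  if (anyDuplicated(lab)) stop("duplicate node label in '", path, "'")
  as_partition(stats::setNames(com, lab))
}

#' Write a membership file
#' @param partition named vector (node label -> community id)
#' @param path file path
#' @return `path`, invisibly
#' @export
write_membership <- function(partition, path) {
  lab <- sort(names(partition), method = "radix")
  writeLines(paste(lab, partition[lab], sep = "\t"), path)
  invisible(path)
}

#' Canonicalize a partition
#'
#' Renumbers community identifiers to contiguous integers `1..q` (in
#' order of the sorted original identifiers) and returns a named integer
#' vector.
#'
#' @param x named vector mapping node labels to community identifiers
#' @return named integer vector
#' @export
as_partition <- function(x) {
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("partition must be a named vector (node label -> community id)")
  }
  ids <- as.character(x)
  used <- sort(unique(ids), method = "radix")
  stats::setNames(match(ids, used), names(x))
}

partition_groups <- function(partition) {
  split(names(partition), partition)
}
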