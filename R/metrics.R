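confusion_matrix <- function(reference, found) {
  nodes <- names(reference)
  if (is.null(nodes) || !setequal(nodes, names(found))) {
    stop("partitions must cover the same node set")
  }
  table(factor(reference[nodes]), factor(found[nodes]))
}

#' Normalized mutual information between two partitions
#'
#' Confusion-matrix NMI: with `X[i, j]` the number of nodes of reference
#' community `i` placed in found community `j`,
#' `NMI = -2 sum X_ij log(X_ij N / (X_i. X_.j)) /
#'        (sum X_i. log(X_i. / N) + sum X_.j log(X_.j / N))`.
#' Symmetric and invariant to community relabeling; 1 exactly when the
#' partitions coincide up to relabeling, 0 when one carries no
#' information about the other (e.g. the all-in-one partition against
#' any multi-community reference).
#'
#' @param reference,found named vectors (node label -> community id)
#'   over the same node set
#' @return number in `[0, 1]`
#' @export
#' @examples
#' p <- c(a = 1, b = 1, c = 2, d = 2)
#' nmi(p, p)                      # 1
#' nmi(p, c(a = 1, b = 1, c = 1, d = 1))  # 0
nmi <- function(reference, found) {
  X <- confusion_matrix(reference, found)
  N <- sum(X)
  ri <- rowSums(X)
  cj <- colSums(X)
  hr <- -sum(ifelse(ri > 0, ri * log(ri / N), 0))
  hf <- -sum(ifelse(cj > 0, cj * log(cj / N), 0))
  if (hr + hf == 0) {
    # both partitions are single communities: identical by construction
    return(1)
  }
  E <- outer(ri, cj) / N
  mi <- sum(ifelse(X > 0, X * log(X / E), 0))
  val <- 2 * mi / (hr + hf)
  min(max(val, 0), 1)
}

#' Best-match precision / recall / F1 report
#'
#' Each reference community is matched to the found community maximizing
#' `F1 = 2 p r / (p + r)` with precision `p = |overlap| / |found|` and
#' recall `r = |overlap| / |reference|`; `overall_f1` is the unweighted
#' mean over reference communities.
#'
#' @param reference,found named vectors over the same node set
#' @return list with `per_community` (data.frame: community, size,
#'   precision, recall, f1) and `overall_f1`
#' @export
f1_report <- function(reference, found) {
  X <- confusion_matrix(reference, found)
  if (nrow(X) == 0L || ncol(X) == 0L) stop("empty partition")
  ri <- rowSums(X)
  cj <- colSums(X)
  per <- lapply(seq_len(nrow(X)), function(i) {
    p <- X[i, ] / cj
    r <- X[i, ] / ri[i]
    f1 <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
    j <- which.max(f1)
    data.frame(community = rownames(X)[i], size = as.integer(ri[i]),
               precision = p[[j]], recall = r[[j]], f1 = f1[[j]])
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  list(per_community = per, overall_f1 = mean(per$f1))
}

#' Classify communities as strong, weak or neither
#'
#' Default mode `per_rest_community`: a community is *strong* when every
#' member has strictly more neighbors inside it than inside any single
#' other community, and *weak* when its internal degree sum (twice its
#' internal edge count) strictly exceeds its edge count to each other
#' community.  Mode `inside_vs_outside` is the classical variant that
#' pools all external edges: strong means every member has more internal
#' than external neighbors, weak means the internal degree sum exceeds
#' the total external edge count; there strong implies weak.  A strong
#' community is labeled `"strong"` even if it also meets the weak
#' condition.
#'
#' @param net an `rwa_network`
#' @param partition named vector covering `net`
#' @param mode `"per_rest_community"` (default) or `"inside_vs_outside"`
#' @return character vector of labels (`"strong"`, `"weak"`,
#'   `"neither"`), one per community, named by community id
#' @export
classify_communities <- function(net, partition,
                                 mode = c("per_rest_community",
                                          "inside_vs_outside")) {
  mode <- match.arg(mode)
  if (!setequal(names(partition), net$nodes)) {
    stop("partition must cover the network's node set")
  }
  groups <- partition_groups(partition)
  ids <- names(groups)
  labels <- stats::setNames(character(length(ids)), ids)
  for (g in ids) {
    mem <- groups[[g]]
    # per-member neighbor counts into each community
    counts <- lapply(mem, function(v) {
      nb <- net$adj[[v]]
      tab <- table(factor(as.character(partition[nb]), levels = ids))
      as.numeric(tab)
    })
    cnt <- do.call(rbind, counts)          # |mem| x |ids|
    colnames(cnt) <- ids
    own <- cnt[, g]
    others <- setdiff(ids, g)
    if (mode == "per_rest_community") {
      strong <- all(vapply(others, function(h) all(own > cnt[, h]),
                           logical(1))) || length(others) == 0L
      weak <- all(vapply(others, function(h) sum(own) > sum(cnt[, h]),
                         logical(1))) || length(others) == 0L
    } else {
      ext <- rowSums(cnt[, others, drop = FALSE])
      strong <- all(own > ext)
      weak <- sum(own) > sum(ext)
    }
    labels[[g]] <- if (strong) "strong" else if (weak) "weak" else "neither"
  }
  labels
}

#' Full comparison report between a reference and a found partition
#'
#' @param reference,found named vectors over the same node set
#' @param net optional `rwa_network`; when given, strong/weak labels of
#'   the found communities are included
#' @param mode classification mode, see [classify_communities()]
#' @return list with `nmi`, `per_community`, `overall_f1` and (when `net`
#'   is given) `labels`
#' @export
metrics_report <- function(reference, found, net = NULL,
                           mode = "per_rest_community") {
  rep <- f1_report(reference, found)
  out <- list(nmi = nmi(reference, found),
              per_community = rep$per_community,
              overall_f1 = rep$overall_f1)
  if (!is.null(net)) {
    out$labels <- classify_communities(net, found, mode)
  }
  out
}
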