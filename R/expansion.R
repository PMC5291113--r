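#' Random-walk parameters
#'
#' @param alpha teleport (restart) probability per step, in `(0, 1]`;
#'   default 0.15, the customary restart rate for personalized walks.
#' @param tol convergence threshold on the L1 change between successive
#'   probability vectors; default `1e-10`.
#' @param max_iter iteration cap; default 1000 (ample for the graph sizes
#'   this method targets, since the map contracts at rate `1 - alpha`).
#' @return object of class `rwa_walk_params`
#' @export
walk_params <- function(alpha = 0.15, tol = 1e-10, max_iter = 1000L) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  if (!(tol > 0)) stop("tol must be positive")
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) stop("max_iter must be >= 1")
  structure(list(alpha = alpha, tol = tol, max_iter = max_iter),
            class = "rwa_walk_params")
}

#' Ordered collection of communities
#'
#' @param communities list of non-empty character vectors of node labels;
#'   communities may overlap during expansion but the final pipeline
#'   output is always a disjoint cover.
#' @return object of class `rwa_community_set` (a list of sorted label
#'   vectors)
#' @export
community_set <- function(communities) {
  if (length(communities) < 1L) stop("need at least one community")
  communities <- lapply(communities, function(v) {
    v <- sort(unique(as.character(v)), method = "radix")
    if (length(v) == 0L) stop("empty community")
    v
  })
  structure(communities, class = "rwa_community_set")
}

#' @export
print.rwa_community_set <- function(x, ...) {
  cat("rwa_community_set:", length(x), "communities, sizes",
      paste(lengths(x), collapse = " "), "\n")
  invisible(x)
}

as_community_set <- function(x) {
  if (inherits(x, "rwa_community_set")) x else community_set(x)
}

community_members <- function(cs) {
  sort(unique(unlist(cs, use.names = FALSE)), method = "radix")
}

#' Stationary distribution of a personalized random walk
#'
#' Iterates `s <- (1 - alpha) * t(M) %*% s + alpha * d` from `s0` until
#' the L1 change drops below `params$tol`.  The fixed point is the
#' stationary distribution `pi = (1 - alpha) t(M) pi + alpha d`; because
#' the update contracts at rate `1 - alpha`, the returned vector
#' satisfies the fixed-point residual bound at the same tolerance.
#'
#' @param M `m x m` row-stochastic transition matrix
#' @param d restart distribution (length `m`, sums to 1)
#' @param s0 initial distribution (length `m`, sums to 1); the limit does
#'   not depend on it, only the iteration path does
#' @param params a [walk_params()]
#' @return stationary probability vector of length `m`
#' @export
stationary_distribution <- function(M, d, s0 = d, params = walk_params()) {
  m <- nrow(M)
  if (ncol(M) != m || length(d) != m || length(s0) != m) {
    stop("dimension mismatch between M, d and s0")
  }
  for (nm in c("d", "s0")) {
    v <- get(nm)
    if (any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      stop(nm, " must be a probability vector summing to 1")
    }
  }
  alpha <- params$alpha
  Mt <- t(M)
  s <- as.numeric(s0)
  d <- as.numeric(d)
  for (iter in seq_len(params$max_iter)) {
    s_new <- (1 - alpha) * as.numeric(Mt %*% s) + alpha * d
    res <- sum(abs(s_new - s))
    s <- s_new
    if (res <= params$tol) {
      return(s)
    }
  }
  stop("random walk did not converge within ", params$max_iter,
       " iterations (last L1 residual ", format(res), ")")
}

# Exact fixed point pi = alpha * (I - (1 - alpha) t(M))^{-1} d, solved
# for all restart vectors at once (columns of D).  Numerically identical
# to the converged iteration (unique fixed point of a contraction); used
# on the expansion hot path where the same M serves q restart vectors.
stationary_solve <- function(M, D, alpha) {
  m <- nrow(M)
  A <- diag(m) - (1 - alpha) * t(M)
  PI <- alpha * solve(A, D)
  # clamp tiny negative round-off and renormalize columns
  PI[PI < 0] <- 0
  sweep(PI, 2L, colSums(PI), "/")
}

#' Average stationary mass per community
#'
#' Entry `j` is the average of `pi` over the members of community `j`:
#' the conditional probability that the walker, restarted under a given
#' community hypothesis, teleports into `Y_j` per member.
#'
#' @param pi stationary probability vector over `V`
#' @param cs a [community_set()]
#' @param V ordered node labels matching `pi`
#' @return numeric vector of length `length(cs)`
#' @export
conditional_community_probability <- function(pi, cs, V) {
  cs <- as_community_set(cs)
  idx <- stats::setNames(seq_along(V), V)
  vapply(cs, function(comm) {
    if (length(comm) == 0L) stop("empty community")
    if (!all(comm %in% V)) stop("community member missing from V")
    mean(pi[idx[comm]])
  }, numeric(1))
}

#' Membership prior of an unassigned node
#'
#' `PP(k)` is proportional to the average structural similarity between
#' `u` and the members of community `k`, normalized to sum to one.  When
#' `u` has zero similarity to every community the prior falls back to
#' uniform.
#'
#' @param net an `rwa_network`
#' @param u node label, not currently a member of any community
#' @param cs a [community_set()]
#' @param cfg a [similarity_config()]
#' @return probability vector of length `length(cs)`
#' @export
membership_prior <- function(net, u, cs, cfg = similarity_config()) {
  cs <- as_community_set(cs)
  raw <- vapply(cs, function(comm) {
    if (length(comm) == 0L) stop("empty community")
    mean(vapply(comm, function(v) {
      structural_similarity(net, u, v, cfg)
    }, numeric(1)))
  }, numeric(1))
  normalize_prior(raw)
}

normalize_prior <- function(raw) {
  if (sum(raw) <= 0) {
    rep(1 / length(raw), length(raw))
  } else {
    raw / sum(raw)
  }
}

# Conditional probability matrix PC (q x q) for the current community
# set: row k holds the per-community averages of the stationary
# distribution of the walk restarted uniformly on community k.  Depends
# only on (V, M, cs), not on the candidate node, so the expansion loop
# computes it once per assignment.  Rows are normalized to sum to one.
community_conditionals <- function(S, cs, V, alpha) {
  m <- length(V)
  q <- length(cs)
  M <- normalize_walk_rows(S[V, V, drop = FALSE])
  D <- matrix(0, m, q)
  idx <- stats::setNames(seq_along(V), V)
  for (k in seq_len(q)) {
    D[idx[cs[[k]]], k] <- 1 / length(cs[[k]])
  }
  PI <- stationary_solve(M, D, alpha)
  PC <- matrix(0, q, q)
  for (j in seq_len(q)) {
    PC[, j] <- colMeans(PI[idx[cs[[j]]], , drop = FALSE])
  }
  PC / rowSums(PC)
}

#' Probability of a node belonging to each community
#'
#' Runs one personalized random walk per community hypothesis: under
#' hypothesis `k` the walker restarts uniformly on the members of
#' community `k` and starts from the similarity profile of `u` over the
#' pooled member set `V`; the stationary distribution is averaged per
#' community into the conditional matrix `PC` (rows normalized).  The
#' similarity-based membership prior `PP` then combines the hypotheses by
#' total probability: `pu(j) = sum_k PC(k, j) * PP(k)`.
#'
#' @param net an `rwa_network`
#' @param u an unassigned node label
#' @param cs a [community_set()]
#' @param wp a [walk_params()]
#' @param cfg a [similarity_config()]
#' @return list with `PC` (`q x q`, rows sum to 1), `PP` (length `q`,
#'   sums to 1) and `pu` (length `q`, sums to 1)
#' @export
belonging_probabilities <- function(net, u, cs,
                                    wp = walk_params(),
                                    cfg = similarity_config()) {
  cs <- as_community_set(cs)
  if (any(vapply(cs, function(comm) u %in% comm, logical(1)))) {
    stop("node '", u, "' is already a community member")
  }
  V <- community_members(cs)
  if (length(V) < 2L) stop("need at least two pooled community members")
  q <- length(cs)
  M <- walk_matrix(net, V, cfg)
  s0 <- normalize_prior(vapply(V, function(v) {
    structural_similarity(net, u, v, cfg)
  }, numeric(1)))
  idx <- stats::setNames(seq_along(V), V)
  PC <- matrix(0, q, q)
  for (k in seq_len(q)) {
    d <- numeric(length(V))
    d[idx[cs[[k]]]] <- 1 / length(cs[[k]])
    pi_k <- stationary_distribution(M, d, s0, wp)
    PC[k, ] <- conditional_community_probability(pi_k, cs, V)
  }
  PC <- PC / rowSums(PC)
  PP <- membership_prior(net, u, cs, cfg)
  pu <- as.numeric(crossprod(PC, PP))
  list(PC = PC, PP = PP, pu = pu / sum(pu))
}

#' Grow communities by greedy random-walk expansion
#'
#' Starting from the seed communities, repeatedly scores every
#' unassigned node adjacent to at least one community by its belonging
#' probabilities and commits the single globally best (node, community)
#' pair, until no adjacent unassigned node remains.  Ties on the
#' probability are broken by larger tightness, then by node label, then
#' by lower community index.  Nodes never adjacent to any community are
#' left for the refinement stage.
#'
#' @param net an `rwa_network`
#' @param seeds list of seeds from [detect_seed_communities()], or any
#'   list of node-label vectors
#' @param wp a [walk_params()]
#' @param cfg a [similarity_config()]
#' @return a [community_set()]
#' @export
expand_communities <- function(net, seeds,
                               wp = walk_params(),
                               cfg = similarity_config()) {
  if (length(seeds) < 1L) stop("need at least one seed")
  comms <- lapply(seeds, function(s) {
    if (is.list(s)) s$members else as.character(s)
  })
  cs <- community_set(comms)
  S <- similarity_matrix(net, cfg)
  repeat {
    assigned <- community_members(cs)
    frontier <- setdiff(net$nodes, assigned)
    frontier <- frontier[vapply(frontier, function(u) {
      any(net$adj[[u]] %in% assigned)
    }, logical(1))]
    if (length(frontier) == 0L) break
    V <- assigned
    q <- length(cs)
    if (length(V) >= 2L) {
      PC <- community_conditionals(S, cs, V, wp$alpha)
    } else {
      PC <- matrix(1, 1L, 1L)
    }
    best <- NULL
    for (u in sort(frontier, method = "radix")) {
      raw <- vapply(seq_len(q), function(k) mean(S[u, cs[[k]]]), numeric(1))
      PP <- normalize_prior(raw)
      pu <- as.numeric(crossprod(PC, PP))
      pu <- pu / sum(pu)
      k <- which.max(pu)
      cand <- list(u = u, k = k, p = pu[k])
      if (is.null(best) || cand$p > best$p + 1e-12) {
        best <- cand
        best$tight <- NA_real_
      } else if (abs(cand$p - best$p) <= 1e-12) {
        # tie: larger tightness, then node label, then community index
        if (is.na(best$tight)) {
          best$tight <- tightness(net, best$u, cs[[best$k]])
        }
        ct <- tightness(net, u, cs[[k]])
        if (ct > best$tight ||
            (ct == best$tight && (u < best$u ||
                                  (u == best$u && k < best$k)))) {
          best <- cand
          best$tight <- ct
        }
      }
    }
    cs[[best$k]] <- sort(c(cs[[best$k]], best$u), method = "radix")
  }
  cs
}
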