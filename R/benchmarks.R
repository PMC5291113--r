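# Run expr with a private RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards.
with_rng <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Specification of an equal-group planted-partition (GN) benchmark
#'
#' The classic four-group benchmark: 128 nodes split randomly into four
#' equal communities of 32, edges placed so the expected degree is 16.
#' `p_in` is the expected fraction of a node's edges that stay inside its
#' own community (`semantics = "fraction"`, the default): the
#' within-community pair probability is `avg_degree * p_in / 31` and the
#' between-community pair probability is `avg_degree * (1 - p_in) / 96`,
#' so the expected degree is `avg_degree` for every `p_in`.  The literal
#' reading of `p_in` as the raw within-pair probability is available via
#' `semantics = "probability"` (there the average degree is only 16 when
#' `p_in` is near 0.52).
#'
#' @param p_in number in `[0, 1]`
#' @param rng_seed integer seed; same spec + same seed reproduce the
#'   identical network
#' @param n_nodes,n_communities,avg_degree benchmark shape (defaults 128,
#'   4, 16; `n_nodes` must divide evenly into equal groups)
#' @param semantics `"fraction"` (default) or `"probability"`
#' @return object of class `rwa_gn_spec`
#' @export
gn_spec <- function(p_in, rng_seed = 1L, n_nodes = 128L,
                    n_communities = 4L, avg_degree = 16,
                    semantics = c("fraction", "probability")) {
  semantics <- match.arg(semantics)
  if (!(p_in >= 0 && p_in <= 1)) stop("p_in must be in [0, 1]")
  n_nodes <- as.integer(n_nodes)
  n_communities <- as.integer(n_communities)
  if (n_nodes %% n_communities != 0L) {
    stop("n_nodes must be a multiple of n_communities")
  }
  structure(list(p_in = p_in, rng_seed = as.integer(rng_seed),
                 n_nodes = n_nodes, n_communities = n_communities,
                 avg_degree = avg_degree, semantics = semantics),
            class = "rwa_gn_spec")
}

#' Generate a GN benchmark network with its planted partition
#'
#' @param spec a [gn_spec()]
#' @return list with `network` (an `rwa_network`) and `partition` (named
#'   integer vector, the planted ground truth)
#' @export
#' @examples
#' gn <- generate_gn(gn_spec(p_in = 0.9, rng_seed = 1))
#' table(gn$partition)
generate_gn <- function(spec) {
  stopifnot(inherits(spec, "rwa_gn_spec"))
  n <- spec$n_nodes
  q <- spec$n_communities
  gsz <- n %/% q
  if (spec$semantics == "fraction") {
    p_within <- spec$avg_degree * spec$p_in / (gsz - 1L)
    p_between <- spec$avg_degree * (1 - spec$p_in) / (n - gsz)
  } else {
    p_within <- spec$p_in
    p_between <- (spec$avg_degree - (gsz - 1L) * spec$p_in) / (n - gsz)
    p_between <- max(p_between, 0)
  }
  if (p_within > 1 || p_between > 1) {
    stop("infeasible spec: pair probability exceeds 1")
  }
  labels <- sprintf("n%03d", seq_len(n))
  with_rng(spec$rng_seed, {
    group <- stats::setNames(rep(seq_len(q), each = gsz)[sample.int(n)],
                             labels)
    pairs <- t(utils::combn(n, 2L))
    same <- group[pairs[, 1L]] == group[pairs[, 2L]]
    p <- ifelse(same, p_within, p_between)
    keep <- stats::runif(nrow(pairs)) < p
    edges <- cbind(labels[pairs[keep, 1L]], labels[pairs[keep, 2L]])
    list(network = network(edges, nodes = labels),
         partition = as_partition(group))
  })
}

#' Specification of an LFR benchmark network
#'
#' Planted-partition networks with power-law degree and community-size
#' distributions.  Each node spends a fraction `1 - mu` of its edges
#' inside its own community and `mu` outside (the mixing parameter).
#'
#' @param N node count
#' @param d target average degree
#' @param Maxd maximum degree (hard truncation)
#' @param Minc,Maxc community size bounds
#' @param mu mixing parameter in `[0, 1]`
#' @param degree_exponent power-law exponent of the degree distribution
#'   (default 2)
#' @param size_exponent power-law exponent of the community-size
#'   distribution (default 1)
#' @param rng_seed integer seed
#' @return object of class `rwa_lfr_spec`
#' @export
lfr_spec <- function(N, d, Maxd, Minc, Maxc, mu,
                     degree_exponent = 2, size_exponent = 1,
                     rng_seed = 1L) {
  if (!(Minc <= Maxc && Maxc <= N)) stop("need Minc <= Maxc <= N")
  if (!(mu >= 0 && mu <= 1)) stop("mu must be in [0, 1]")
  if (!(d <= Maxd)) stop("need d <= Maxd")
  structure(list(N = as.integer(N), d = d, Maxd = as.integer(Maxd),
                 Minc = as.integer(Minc), Maxc = as.integer(Maxc),
                 mu = mu, degree_exponent = degree_exponent,
                 size_exponent = size_exponent,
                 rng_seed = as.integer(rng_seed)),
            class = "rwa_lfr_spec")
}

# Mean of a continuous power law with density ~ x^-tau on [a, b].
powerlaw_mean <- function(a, b, tau) {
  if (abs(tau - 2) < 1e-12) {
    log(b / a) / (1 / a - 1 / b)
  } else if (abs(tau - 1) < 1e-12) {
    (b - a) / log(b / a)
  } else {
    c1 <- (b^(1 - tau) - a^(1 - tau)) / (1 - tau)
    c2 <- (b^(2 - tau) - a^(2 - tau)) / (2 - tau)
    c2 / c1
  }
}

# Inverse-CDF sample from a continuous power law on [a, b], exponent tau.
rpowerlaw <- function(n, a, b, tau) {
  u <- stats::runif(n)
  if (abs(tau - 1) < 1e-12) {
    a * (b / a)^u
  } else {
    (a^(1 - tau) - u * (a^(1 - tau) - b^(1 - tau)))^(1 / (1 - tau))
  }
}

# Draw a degree sequence with power-law tail, max Maxd, mean ~ d.  A
# node whose internal share round((1 - mu) * k) cannot fit inside even
# the largest admissible community (Maxc - 1 partners) is infeasible
# under the planted-partition model, so -- like the reference
# implementation, which rejects such draws -- the support is truncated
# to the feasible range before calibrating the mean.
lfr_degrees <- function(N, d, Maxd, tau, mu, Maxc) {
  kcap <- floor((Maxc - 0.5) / max(1 - mu, 1e-12))
  b <- max(min(Maxd, kcap), ceiling(d))
  f <- function(a) powerlaw_mean(a, b, tau) - d
  if (f(1) > 0) {
    a <- 1
  } else {
    a <- stats::uniroot(f, c(1, b - 1e-6))$root
  }
  k <- round(rpowerlaw(N, a, b, tau))
  pmin(pmax(k, 1L), b)
}

# Community sizes: power-law draws in [Minc, Maxc] adjusted to tile N.
lfr_sizes <- function(N, Minc, Maxc, tau, max_retry = 200L) {
  support <- seq.int(Minc, Maxc)
  w <- support^(-tau)
  for (r in seq_len(max_retry)) {
    sizes <- integer()
    while (sum(sizes) < N) {
      sizes <- c(sizes, sample(support, 1L, prob = w))
    }
    excess <- sum(sizes) - N
    # shave the excess off communities that stay >= Minc
    i <- 1L
    while (excess > 0L && i <= length(sizes)) {
      cut <- min(excess, sizes[i] - Minc)
      sizes[i] <- sizes[i] - cut
      excess <- excess - cut
      i <- i + 1L
    }
    if (excess == 0L) return(sizes)
  }
  stop("could not tile ", N, " nodes into community sizes in [",
       Minc, ", ", Maxc, "]")
}

# Pair up stubs into simple edges avoiding forbidden pairs; repeatedly
# reshuffles the leftover stubs.  Returns a 2-column index matrix.
match_stubs <- function(stubs, is_forbidden, existing_keys = character(),
                        rounds = 60L) {
  edges <- matrix(integer(), ncol = 2L)
  keys <- existing_keys
  for (r in seq_len(rounds)) {
    if (length(stubs) < 2L) break
    stubs <- sample(stubs)
    if (length(stubs) %% 2L == 1L) {
      drop <- length(stubs)
      odd <- stubs[drop]
      stubs <- stubs[-drop]
    } else {
      odd <- integer()
    }
    a <- stubs[seq(1L, length(stubs), by = 2L)]
    b <- stubs[seq(2L, length(stubs), by = 2L)]
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- paste(lo, hi, sep = "_")
    ok <- lo != hi & !key %in% keys & !duplicated(key) & !is_forbidden(lo, hi)
    edges <- rbind(edges, cbind(lo[ok], hi[ok]))
    keys <- c(keys, key[ok])
    stubs <- c(a[!ok], b[!ok], odd)
  }
  edges
}

#' Generate an LFR benchmark network with its planted partition
#'
#' Degrees are drawn from a truncated power law calibrated to the target
#' mean `d`; community sizes from a truncated power law tiled to `N`;
#' each node splits its degree into `round((1 - mu) * k)` internal and
#' the remaining external stubs, which are wired by stub matching with
#' rejection of loops, duplicates and (for external stubs) same-community
#' pairs.  Stub matching can leave a small number of stubs unplaced, so
#' realized degrees are bounded above by the drawn sequence (never above
#' `Maxd`) and the realized mixing is close to `mu`.
#'
#' @param spec an [lfr_spec()]
#' @return list with `network` and `partition` (planted ground truth)
#' @export
generate_lfr <- function(spec) {
  stopifnot(inherits(spec, "rwa_lfr_spec"))
  with_rng(spec$rng_seed, {
    N <- spec$N
    deg <- lfr_degrees(N, spec$d, spec$Maxd, spec$degree_exponent,
                       spec$mu, spec$Maxc)
    sizes <- lfr_sizes(N, spec$Minc, spec$Maxc, spec$size_exponent)
    q <- length(sizes)
    kint <- pmin(round((1 - spec$mu) * deg), deg)
    # assign nodes to communities: largest internal degree first, into a
    # random community with spare capacity whose size can host it
    comm <- integer(N)
    cap <- sizes
    for (i in order(-kint, sample.int(N))) {
      ok <- which(cap > 0L & sizes - 1L >= kint[i])
      if (length(ok) == 0L) {
        ok <- which(cap > 0L)
        kint[i] <- max(sizes[ok]) - 1L  # clamp to the largest host
        ok <- ok[sizes[ok] - 1L >= kint[i]]
      }
      pick <- if (length(ok) == 1L) ok else sample(ok, 1L, prob = cap[ok])
      comm[i] <- pick
      cap[pick] <- cap[pick] - 1L
    }
    # internal wiring per community
    edges <- matrix(integer(), ncol = 2L)
    keys <- character()
    for (k in seq_len(q)) {
      mem <- which(comm == k)
      stubs <- rep(mem, kint[mem])
      e <- match_stubs(stubs, function(lo, hi) rep(FALSE, length(lo)),
                       existing_keys = keys)
      edges <- rbind(edges, e)
      keys <- c(keys, paste(e[, 1L], e[, 2L], sep = "_"))
    }
    # external wiring across communities
    kext <- deg - kint
    stubs <- rep(seq_len(N), kext)
    e <- match_stubs(stubs, function(lo, hi) comm[lo] == comm[hi],
                     existing_keys = keys)
    edges <- rbind(edges, e)
    labels <- sprintf("n%04d", seq_len(N))
    net <- network(cbind(labels[edges[, 1L]], labels[edges[, 2L]]),
                   nodes = labels)
    list(network = net,
         partition = as_partition(stats::setNames(comm, labels)))
  })
}

#' Empirical mixing fraction of a network under a partition
#'
#' Average over nodes of the share of a node's edges that leave its own
#' community; the quantity the LFR mixing parameter `mu` controls.
#'
#' @param net an `rwa_network`
#' @param partition named vector (node -> community)
#' @return number in `[0, 1]`
#' @export
mixing_fraction <- function(net, partition) {
  fr <- vapply(net$nodes, function(v) {
    nb <- net$adj[[v]]
    if (length(nb) == 0L) return(NA_real_)
    mean(partition[nb] != partition[[v]])
  }, numeric(1))
  mean(fr, na.rm = TRUE)
}
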