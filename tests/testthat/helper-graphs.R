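# Graph builders used across the suite.  All fixtures are constructed in
# code; nothing is read from disk except the bundled karate files.

clique_edges <- function(prefix, n) {
  t(utils::combn(paste0(prefix, seq_len(n)), 2L))
}

make_clique <- function(prefix, n) network(clique_edges(prefix, n))

# two cliques of size n joined by a single bridge edge
make_two_cliques <- function(n = 4L) {
  network(rbind(clique_edges("a", n), clique_edges("b", n), c("a1", "b1")))
}

make_triangle <- function(labels = c("a", "b", "c")) {
  network(t(utils::combn(labels, 2L)))
}

make_path <- function(labels) {
  network(cbind(labels[-length(labels)], labels[-1L]))
}

make_star <- function(center = "c", n_leaves = 4L) {
  network(cbind(center, paste0("l", seq_len(n_leaves))))
}

# Erdos-Renyi-ish random simple graph on n labeled nodes (no isolation
# guarantee); deterministic given seed.
random_graph <- function(n, p = 0.4, seed = 1L) {
  labels <- sprintf("v%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2L))
  keep <- withr::with_seed(seed, stats::runif(nrow(pairs)) < p)
  network(cbind(labels[pairs[keep, 1L]], labels[pairs[keep, 2L]]),
          nodes = labels)
}

# random row-stochastic matrix and restart/initial vectors
random_walk_instance <- function(m, seed = 1L) {
  withr::with_seed(seed, {
    M <- matrix(stats::runif(m * m), m, m)
    diag(M) <- 0
    M <- M / rowSums(M)
    d <- stats::runif(m); d <- d / sum(d)
    s0 <- stats::runif(m); s0 <- s0 / sum(s0)
    list(M = M, d = d, s0 = s0)
  })
}

# dense linear-solve oracle for the stationary distribution
solve_stationary_oracle <- function(M, d, alpha) {
  m <- nrow(M)
  pi <- solve(diag(m) - (1 - alpha) * t(M), alpha * d)
  as.numeric(pi)
}

karate_path <- function(file) {
  system.file("extdata", file, package = "rwacd", mustWork = TRUE)
}
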