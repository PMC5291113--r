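test_that("stationary distribution matches closed forms", {
  tri <- make_triangle()
  M <- walk_matrix(tri, c("a", "b", "c"))
  u <- rep(1 / 3, 3)
  expect_equal(stationary_distribution(M, u, u), u, tolerance = 1e-9)
  # alpha = 1: jump-only walk, pi = d regardless of M
  d <- c(0.5, 0.3, 0.2)
  expect_equal(stationary_distribution(M, d, u, walk_params(alpha = 1)), d,
               tolerance = 1e-12)
})

test_that("stationary distribution agrees with the linear-solve oracle", {
  for (m in c(3L, 5L, 12L, 20L)) {
    for (seed in 1:3) {
      inst <- random_walk_instance(m, seed = seed * 100L + m)
      wp <- walk_params()
      pi_iter <- stationary_distribution(inst$M, inst$d, inst$s0, wp)
      pi_solve <- solve_stationary_oracle(inst$M, inst$d, wp$alpha)
      expect_equal(pi_iter, pi_solve, tolerance = 1e-8)
      expect_true(all(pi_iter >= 0))
      expect_equal(sum(pi_iter), 1, tolerance = 1e-9)
      # the internal batch solver takes the same fixed point
      expect_equal(as.numeric(rwacd:::stationary_solve(
        inst$M, matrix(inst$d), wp$alpha)), pi_solve, tolerance = 1e-10)
    }
  }
})

test_that("stationary distribution validates input and reports non-convergence", {
  inst <- random_walk_instance(4L)
  expect_error(stationary_distribution(inst$M, c(2, -1, 0, 0), inst$s0),
               "probability vector")
  expect_error(stationary_distribution(inst$M, inst$d[-1L], inst$s0[-1L]),
               "dimension")
  expect_error(
    stationary_distribution(inst$M, inst$d, inst$s0,
                            walk_params(tol = 1e-14, max_iter = 2L)),
    "did not converge")
})

test_that("conditional community probability averages pi per community", {
  V <- c("a", "b", "c", "d")
  cs <- community_set(list(c("a", "b"), c("c", "d")))
  expect_equal(conditional_community_probability(rep(0.25, 4), cs, V),
               c(0.25, 0.25))
  one <- community_set(list(V))
  expect_equal(conditional_community_probability(rep(0.25, 4), one, V), 0.25)
  # pi concentrated on Y_1
  expect_equal(conditional_community_probability(c(.5, .5, 0, 0), cs, V),
               c(0.5, 0))
  expect_error(conditional_community_probability(rep(1 / 3, 3), cs,
                                                 c("a", "b", "c")),
               "missing from V")
})

test_that("membership prior is the normalized mean similarity", {
  # u - a, communities {a} and {b} with b two hops away: raw similarities
  # 2/3 and 1/3 by hand enumeration of closed neighborhoods
  p3 <- make_path(c("u", "a", "b"))
  expect_equal(membership_prior(p3, "u", list("a", "b")), c(2 / 3, 1 / 3))
  # mirror-image communities
  net <- make_two_cliques(3L)
  netm <- network(rbind(net_edges(net), c("a1", "m"), c("b1", "m")))
  pp <- membership_prior(netm, "m", list(paste0("a", 1:3), paste0("b", 1:3)))
  expect_equal(pp, c(0.5, 0.5))
  # zero similarity everywhere -> uniform
  far <- network(rbind(c("u", "v"), clique_edges("a", 3), clique_edges("b", 3)))
  expect_equal(membership_prior(far, "u",
                                list(paste0("a", 1:3), paste0("b", 1:3))),
               c(0.5, 0.5))
})

test_that("belonging probabilities form a probability table", {
  net <- make_two_cliques(4L)
  # q = 1: normalization forces pu = 1
  bp1 <- belonging_probabilities(net, "a4", list(c("a1", "a2", "a3")))
  expect_equal(bp1$pu, 1)
  # symmetric bridge midpoint between mirror triangles
  sym <- network(rbind(clique_edges("a", 3), clique_edges("b", 3),
                       c("a1", "m"), c("b1", "m")))
  bp <- belonging_probabilities(sym, "m",
                                list(paste0("a", 1:3), paste0("b", 1:3)))
  expect_equal(bp$pu, c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(rowSums(bp$PC), c(1, 1), tolerance = 1e-9)
  expect_equal(sum(bp$PP), 1, tolerance = 1e-12)
  # member of clique A, temporarily unassigned: A wins
  bpa <- belonging_probabilities(net, "a4",
                                 list(c("a1", "a2", "a3"),
                                      c("b1", "b2", "b3")))
  expect_equal(which.max(bpa$pu), 1L)
  expect_equal(sum(bpa$pu), 1, tolerance = 1e-12)
  expect_error(belonging_probabilities(net, "a1", list(c("a1", "a2", "a3"))),
               "already a community member")
})

test_that("pu is permutation-equivariant in the community order", {
  net <- make_two_cliques(4L)
  cs <- list(c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  pu <- belonging_probabilities(net, "a4", cs)$pu
  pu_rev <- belonging_probabilities(net, "a4", rev(cs))$pu
  expect_equal(pu, rev(pu_rev), tolerance = 1e-12)
})

test_that("expansion grows cliques exactly and deterministically", {
  net <- make_two_cliques(4L)
  seeds <- list(c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  cs <- expand_communities(net, seeds)
  expect_identical(unclass(cs)[[1L]], paste0("a", 1:4))
  expect_identical(unclass(cs)[[2L]], paste0("b", 1:4))
  expect_identical(unclass(expand_communities(net, seeds)), unclass(cs))
  # already fully covered: no-op
  full <- list(paste0("a", 1:4), paste0("b", 1:4))
  expect_identical(unclass(expand_communities(net, full)),
                   unclass(community_set(full)))
})

test_that("expansion is monotone and assigns one node per iteration", {
  net <- random_graph(10L, p = 0.5, seed = 7L)
  seeds <- consolidate_seeds(net, detect_seed_communities(net))
  cs <- expand_communities(net, seeds)
  expect_true(all(lengths(cs) >= lengths(seeds)[seq_along(cs)]))
  assigned <- rwacd:::community_members(cs)
  # every node adjacent to the assigned set must itself be assigned
  frontier <- setdiff(net$nodes, assigned)
  expect_false(any(vapply(frontier, function(u) {
    any(net$adj[[u]] %in% assigned)
  }, logical(1))))
})
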