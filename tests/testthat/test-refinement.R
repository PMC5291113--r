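test_that("tightness is the adjacent fraction of the community", {
  net <- make_clique("a", 5)
  netp <- network(rbind(net_edges(net), c("a1", "u"), c("a2", "u")))
  expect_equal(tightness(netp, "u", c("a1", "a2", "a3", "a4")), 0.5)
  expect_equal(tightness(netp, "u", c("a1", "a2")), 1)
  expect_equal(tightness(netp, "u", c("a3", "a4")), 0)
  expect_error(tightness(netp, "u", character()), "empty community")
  expect_error(tightness(netp, "a1", c("a1", "a2")), "member")
  # monotone in added edges from u into the community
  netq <- network(rbind(net_edges(netp), c("a3", "u")))
  expect_gt(tightness(netq, "u", c("a1", "a2", "a3", "a4")),
            tightness(netp, "u", c("a1", "a2", "a3", "a4")))
})

test_that("leftover nodes join their tightest community", {
  net <- network(rbind(clique_edges("a", 4), c("a1", "p")))  # pendant
  cs <- assign_leftovers(net, community_set(list(paste0("a", 1:4))))
  expect_true("p" %in% cs[[1L]])
  # no leftovers: identity
  cs2 <- community_set(list(paste0("a", 1:4), "p"))
  expect_identical(unclass(assign_leftovers(net, cs2)), unclass(cs2))
  # tie goes to the lowest community index
  tie <- network(rbind(c("x1", "u"), c("y1", "u"), c("x1", "x2"),
                       c("y1", "y2")))
  cs3 <- assign_leftovers(tie, community_set(list(c("x1", "x2"),
                                                  c("y1", "y2"))))
  expect_true("u" %in% cs3[[1L]])
  expect_false("u" %in% cs3[[2L]])
  # unreachable nodes seed their own community (z1 first, z2 joins it)
  iso <- network(rbind(clique_edges("a", 3), c("z1", "z2")))
  cs4 <- assign_leftovers(iso, community_set(list(paste0("a", 1:3))))
  expect_equal(length(cs4), 2L)
  expect_setequal(cs4[[2L]], c("z1", "z2"))
})

test_that("merging follows the overlap coefficient with threshold xi", {
  same <- community_set(list(c("a", "b", "c"), c("a", "b", "c")))
  expect_length(merge_communities(same), 1L)
  disjoint <- community_set(list(c("a", "b"), c("c", "d")))
  expect_identical(unclass(merge_communities(disjoint)), unclass(disjoint))
  # |Ci| = 4, |Cj| = 6, overlap 2: ratio exactly 0.5 -> merged
  cs <- community_set(list(c("a", "b", "c", "d"),
                           c("c", "d", "e", "f", "g", "h")))
  merged <- merge_communities(cs)
  expect_length(merged, 1L)
  expect_identical(merged[[1L]], letters[1:8])
  # under a stricter threshold the same pair stays apart
  expect_length(merge_communities(cs, merge_params(xi = 0.6)), 2L)
  # idempotent at the fixpoint, never increases the count
  again <- merge_communities(merged)
  expect_identical(unclass(again), unclass(merged))
})

test_that("finalize resolves overlaps by tightness into a contiguous cover", {
  net <- make_two_cliques(4L)
  cs <- community_set(list(paste0("a", 1:4), paste0("b", 1:4)))
  part <- finalize_partition(net, cs)
  expect_setequal(names(part), net$nodes)
  expect_identical(sort(unique(part)), 1:2)
  # a1 shared between both communities: tighter to its own clique
  shared <- community_set(list(c(paste0("b", 1:4), "a1"), paste0("a", 1:4)))
  part2 <- finalize_partition(net, shared)
  expect_equal(part2[["a1"]], part2[["a2"]])
  expect_error(finalize_partition(net, community_set(list(paste0("a", 1:4)))),
               "does not cover")
})

test_that("the full pipeline partitions clique pairs exactly", {
  for (n in c(4L, 5L)) {
    net <- make_two_cliques(n)
    part <- run_rwa(net)
    expect_identical(max(part), 2L)
    expect_true(all(part[paste0("a", 1:n)] == part[["a1"]]))
    expect_true(all(part[paste0("b", 1:n)] == part[["b1"]]))
    expect_false(part[["a1"]] == part[["b1"]])
  }
})

test_that("run_rwa always yields a total disjoint cover", {
  for (seed in 1:4) {
    net <- random_graph(14L, p = 0.3, seed = seed)
    part <- run_rwa(net)
    expect_setequal(names(part), net$nodes)
    expect_identical(sort(unique(part)), seq_len(max(part)))
    expect_false(anyNA(part))
  }
})

test_that("run_rwa is invariant under node relabeling", {
  net <- random_graph(12L, p = 0.4, seed = 3L)
  part <- run_rwa(net)
  # bijective relabeling that reverses sort order
  relab <- stats::setNames(sprintf("w%02d", rev(seq_along(net$nodes))),
                           net$nodes)
  el <- net_edges(net)
  net2 <- network(cbind(relab[el[, 1L]], relab[el[, 2L]]),
                  nodes = unname(relab))
  part2 <- run_rwa(net2)
  expect_equal(nmi(stats::setNames(part2[relab[names(part)]], names(part)),
                   part), 1)
})

test_that("membership files round-trip", {
  part <- c(a = 2L, b = 2L, c = 1L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_membership(part, f)
  back <- read_membership(f)
  expect_identical(back, as_partition(part)[sort(names(part))])
  writeLines(c("a 1", "a 2"), f)
  expect_error(read_membership(f), "duplicate")
})
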