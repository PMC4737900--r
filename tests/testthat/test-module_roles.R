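test_that("the modularity formula evaluates hand-checked partitions", {
  net <- two_cliques_bridge()
  one <- stats::setNames(rep(1, 6), igraph::V(net)$name)
  expect_equal(modularity_score(net, one), 0)
  split <- stats::setNames(c(1, 1, 1, 2, 2, 2),
                           c("a1", "a2", "a3", "b1", "b2", "b3"))
  expect_equal(modularity_score(net, split), 5 / 14, tolerance = 1e-12)
  tri <- make_net(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  singletons <- stats::setNames(1:3, c("a", "b", "c"))
  expect_equal(modularity_score(tri, singletons), -1 / 3, tolerance = 1e-12)
  expect_error(modularity_score(net, split[-1]), "missing")
})

test_that("the modularity formula agrees with the igraph implementation", {
  set.seed(43)
  for (i in 1:10) {
    g <- random_net(25, 0.2, seed = 43 + i)
    memb <- sample(1:4, igraph::vcount(g), replace = TRUE)
    names(memb) <- igraph::V(g)$name
    expect_equal(modularity_score(g, memb),
                 igraph::modularity(g, memb),
                 tolerance = 1e-12)
  }
})

test_that("greedy module detection recovers clique pairs exactly", {
  net <- two_cliques_bridge()
  part <- detect_modules(net)
  expect_equal(part$n_modules, 2)
  expect_equal(part$modularity, 5 / 14, tolerance = 1e-12)
  expect_equal(part$modularity, exhaustive_max_modularity(net),
               tolerance = 1e-12)
  # members split by clique
  expect_length(unique(part$membership[c("a1", "a2", "a3")]), 1)
  expect_length(unique(part$membership[c("b1", "b2", "b3")]), 1)
  # complete graph: no community structure
  k5 <- make_net(t(combn(paste0("k", 1:5), 2)))
  p5 <- detect_modules(k5)
  expect_equal(p5$n_modules, 1)
  expect_equal(p5$modularity, 0)
})

test_that("greedy modularity is near the exhaustive optimum on small graphs", {
  fixtures <- list(
    two_cliques_bridge(),
    make_net(rbind(c("a", "b"), c("b", "c"), c("c", "d"),
                   c("d", "e"), c("e", "f"))),              # path
    make_net(cbind("h", paste0("l", 1:6))),                 # star
    random_net(8, 0.4, seed = 51),
    random_net(8, 0.6, seed = 52),
    random_net(7, 0.5, seed = 53))
  for (net in fixtures) {
    greedy <- detect_modules(net)$modularity
    best <- exhaustive_max_modularity(net)
    expect_lte(best - greedy, 0.05)
  }
})

test_that("planted partitions are recovered with high adjusted Rand index", {
  pl <- planted_net(blocks = 4, size = 15, p_in = 0.9, p_out = 0.05,
                    seed = 61)
  part <- detect_modules(pl$net)
  ari <- adjusted_rand_index(part$membership[names(pl$labels)], pl$labels)
  expect_gte(ari, 0.9)
  # own ARI agrees with the independent mclust implementation
  expect_equal(ari,
               mclust::adjustedRandIndex(
                 part$membership[names(pl$labels)], pl$labels),
               tolerance = 1e-12)
  # leading-eigenvector alternative also finds the blocks
  part2 <- detect_modules(pl$net, method = "leading_eigen")
  expect_gte(adjusted_rand_index(part2$membership[names(pl$labels)],
                                 pl$labels), 0.9)
})

test_that("module ids are stable: size-ranked, then smallest member", {
  net <- two_cliques_bridge()
  part <- detect_modules(net)
  # equal sizes: module containing 'a1' (lexicographically first) is 1
  expect_equal(unname(part$membership["a1"]), 1)
  expect_equal(unname(part$membership["b1"]), 2)
  expect_identical(detect_modules(net)$membership, part$membership)
})

test_that("within-module degree z-scores use the population deviation", {
  star <- make_net(cbind("hub", paste0("l", 1:4)))
  one <- stats::setNames(rep(1, 5), igraph::V(star)$name)
  z <- within_module_z(star, one)
  expect_equal(unname(z["hub"]), 2, tolerance = 1e-12)  # (4-1.6)/1.2
  expect_equal(sum(z), 0, tolerance = 1e-9)
  # equal within-degrees: sigma = 0 rule gives Z = 0
  tri <- make_net(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  z2 <- within_module_z(tri, stats::setNames(rep(1, 3), c("a", "b", "c")))
  expect_equal(unname(z2), rep(0, 3))
  # Z sums to ~0 within every module of a random graph
  g <- random_net(40, 0.2, seed = 71)
  part <- detect_modules(g)
  z3 <- within_module_z(g, part)
  for (m in unique(part$membership))
    expect_lt(abs(sum(z3[names(part$membership)[part$membership == m]])),
              1e-9)
})

test_that("participation coefficients follow the link-share formula", {
  # center with 2 links into module A and 1 into module B: P = 4/9
  net <- make_net(rbind(c("x", "a1"), c("x", "a2"), c("x", "b1"),
                        c("a1", "a2")))
  memb <- stats::setNames(c(1, 1, 1, 2), c("x", "a1", "a2", "b1"))
  p <- participation_p(net, memb)
  expect_equal(unname(p["x"]), 4 / 9, tolerance = 1e-12)
  expect_equal(unname(p["a1"]), 0)  # all links inside own module
  # 4 links split evenly over 2 modules: P = 0.5
  net2 <- make_net(rbind(c("x", "a1"), c("x", "a2"),
                         c("x", "b1"), c("x", "b2")))
  memb2 <- stats::setNames(c(1, 1, 1, 2, 2),
                           c("x", "a1", "a2", "b1", "b2"))
  expect_equal(unname(participation_p(net2, memb2)["x"]), 0.5,
               tolerance = 1e-12)
  # P bounded by 1 - 1/N_M on random graphs
  g <- random_net(40, 0.2, seed = 81)
  part <- detect_modules(g)
  pp <- participation_p(g, part)
  expect_true(all(pp >= 0 - 1e-12))
  expect_true(all(pp <= 1 - 1 / part$n_modules + 1e-12))
})

test_that("role classification follows the Z/P boundaries", {
  z <- c(6.336, 1.250, 2.828, 2.5, 2.6, 0)
  p <- c(0.000, 0.747, 0.328, 0.62, 0.63, 0.1)
  roles <- classify_roles(z, p)
  expect_equal(roles$role,
               c("module_hub", "connector", "module_hub",
                 "peripheral",       # both exactly on the boundary
                 "network_hub", "peripheral"))
  s <- attr(roles, "summary")
  expect_equal(sum(s$count), 6)
  expect_equal(sum(s$fraction), 1)
})

test_that("the node role table combines degree, module, Z, P, and class", {
  pl <- planted_net(blocks = 3, size = 10, p_in = 0.9, p_out = 0.05,
                    seed = 91)
  part <- detect_modules(pl$net)
  tab <- node_role_table(pl$net, part)
  expect_setequal(tab$node, igraph::V(pl$net)$name)
  expect_identical(tab$degree,
                   as.integer(igraph::degree(pl$net)[tab$node]))
  expect_true(all(tab$role %in% c("peripheral", "connector",
                                  "module_hub", "network_hub")))
  expect_equal(unname(part$membership[tab$node]), tab$module)
})
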