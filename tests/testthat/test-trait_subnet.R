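std_traits <- function(vals, sample_ids) {
  standardize_traits(trait_table(vals, sample_ids = sample_ids))
}

test_that("gene significance is the squared profile-trait correlation", {
  sams <- paste0("s", 1:10)
  tvals <- cbind(oil = c(5, 3, 8, 1, 9, 2, 7, 4, 6, 10))
  traits <- std_traits(tvals, sams)
  # a gene tracking the trait exactly: GS = 1
  gvals <- rbind(track = tvals[, 1],
                 ortho = c(1, -1, 1, -1, 1, -1, 1, -1, 1, -1) +
                   mean(tvals[, 1]) * 0)
  # make 'ortho' exactly uncorrelated with the trait by regression residual
  res <- stats::resid(stats::lm(rnorm(10) ~ traits$values[, 1]))
  gvals["ortho", ] <- res - min(res) + 1
  tbl <- abundance_table(gvals, gene_ids = rownames(gvals),
                         sample_ids = sams, log_transformed = TRUE)
  gs <- gene_significance(tbl, traits)
  expect_equal(unname(gs["track", "oil"]), 1, tolerance = 1e-12)
  expect_equal(unname(gs["ortho", "oil"]), 0, tolerance = 1e-12)
  expect_error(gene_significance(tbl, trait_table(tvals, sample_ids = sams)),
               "standardize")
})

test_that("gene significance equals the squared similarity-module r", {
  set.seed(12)
  sams <- paste0("s", 1:10)
  gvals <- matrix(rnorm(50), 5, 10,
                  dimnames = list(paste0("g", 1:5), sams))
  tvals <- cbind(tr = rnorm(10))
  traits <- std_traits(tvals, sams)
  tbl <- abundance_table(gvals, gene_ids = rownames(gvals),
                         sample_ids = sams, log_transformed = TRUE)
  gs <- gene_significance(tbl, traits)
  # oracle: run the trait through the similarity module as a profile
  for (g in rownames(gvals)) {
    both <- abundance_table(rbind(gene = gvals[g, ],
                                  trait = traits$values[, 1]),
                            gene_ids = c("gene", "trait"),
                            sample_ids = sams, log_transformed = TRUE)
    expect_equal(unname(gs[g, "tr"]),
                 unname(pearson_similarity(both)$S["gene", "trait"]^2),
                 tolerance = 1e-12)
  }
})

test_that("gene-significance vs connectivity correlation behaves at the poles", {
  g <- random_net(200, 0.08, seed = 14)
  k <- igraph::degree(g)
  gs <- cbind(linear = k / max(k))
  rownames(gs) <- names(k)
  out <- gs_connectivity_correlation(gs, g)
  expect_equal(out$r, 1, tolerance = 1e-12)
  const <- cbind(flat = rep(0.5, length(k)))
  rownames(const) <- names(k)
  expect_true(is.na(gs_connectivity_correlation(const, g)$r))
  # permuted gene significance: mostly non-significant
  set.seed(15)
  null_p <- replicate(50, {
    gsp <- cbind(perm = sample(gs[, 1]))
    rownames(gsp) <- names(k)
    gs_connectivity_correlation(gsp, g)$p
  })
  expect_gte(mean(null_p > 0.05), 0.9)
})

test_that("degree-trait correlations detect a planted negative dependence", {
  n <- 30
  sams <- paste0("s", 1:10)
  ids <- sprintf("g%02d", 1:n)
  # threshold graph: i ~ j iff i + j <= n + 1 gives degrees decreasing in i
  edges <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (i + j <= n + 1) edges <- rbind(edges, c(ids[i], ids[j]))
  net <- make_net(edges, nodes = ids)
  deg <- igraph::degree(net)
  expect_true(all(diff(deg[ids]) <= 0))
  # gene i most abundant in sample ceiling(i/3); trait rises with sample
  tvals <- cbind(oil = 1:10)
  traits <- std_traits(tvals, sams)
  gvals <- matrix(1, n, 10, dimnames = list(ids, sams))
  for (i in 1:n) gvals[i, ceiling(i / 3)] <- 100
  tbl <- abundance_table(gvals, gene_ids = ids, sample_ids = sams)
  out <- degree_trait_correlations(net, tbl, traits)
  expect_lt(out$r[out$trait == "oil"], 0)
  expect_lt(out$p[out$trait == "oil"], 0.01)
  expect_equal(out$stars[out$trait == "oil"], "**")
  # shuffled abundance rows: mostly non-significant
  set.seed(16)
  null_r <- replicate(50, {
    tbl_p <- abundance_table(gvals[sample(n), , drop = FALSE],
                             gene_ids = ids, sample_ids = sams)
    degree_trait_correlations(net, tbl_p, traits)$r
  })
  expect_gte(mean(abs(null_r) < 0.4), 0.9)
  # constant degrees: correlation undefined
  ring <- make_net(cbind(ids, ids[c(2:n, 1)]))
  out_ring <- degree_trait_correlations(ring, tbl, traits)
  expect_true(is.na(out_ring$r))
  expect_error(degree_trait_correlations(net, tbl,
                                         std_traits(cbind(pH = rnorm(10)),
                                                    paste0("x", 1:10))),
               "3 network genes|shared", perl = TRUE)
})

test_that("subnetwork extraction reports signs, rankings, and guards", {
  # alk-style star: hub with 31 all-negative links plus background genes
  hub <- "83025976"
  partners <- sprintf("p%02d", 1:31)
  others <- c("o1", "o2")
  edges <- rbind(cbind(hub, partners), c("o1", "o2"))
  gene_names <- stats::setNames(c("alkB", rep(c("alkK", "alkH", "alkJ"),
                                              length.out = 31),
                                  "nifH", "nifH"),
                                c(hub, partners, others))
  net <- make_net(edges, gene_names = gene_names,
                  signs = c(rep(-1L, 31), 1L))
  rep_alk <- extract_subnetwork(net, degradation_gene_sets()$alk)
  expect_equal(nrow(rep_alk$nodes), 32)
  expect_equal(rep_alk$negative_fraction, 1)
  expect_equal(rep_alk$positive_fraction, 0)
  expect_equal(rep_alk$nodes$node[1], hub)
  expect_equal(rep_alk$nodes$degree[1], 31)
  expect_warning(rep_none <- extract_subnetwork(net, "phnX"), "no network")
  expect_equal(nrow(rep_none$nodes), 0)
  expect_error(extract_subnetwork(net, character()), "nonempty")
})

test_that("signed fractions always sum to one", {
  set.seed(18)
  for (i in 1:5) {
    g <- random_net(20, 0.3, seed = 100 + i)
    igraph::E(g)$sign <- sample(c(-1L, 1L), igraph::ecount(g),
                                replace = TRUE)
    igraph::V(g)$gene_name <- sample(c("alkB", "alkK", "nahA"),
                                     igraph::vcount(g), replace = TRUE)
    rep_i <- extract_subnetwork(g, c("alkB", "alkK"))
    if (nrow(rep_i$edges))
      expect_equal(rep_i$negative_fraction + rep_i$positive_fraction, 1)
  }
})

test_that("keystone ranking is a degree sort with stable ties", {
  star <- make_net(cbind("hub", paste0("l", 1:5)))
  expect_equal(keystone_rank(star, 1)$node, "hub")
  all_ranked <- keystone_rank(star, 99)
  expect_equal(nrow(all_ranked), 6)
  expect_equal(all_ranked$node[1], "hub")
  expect_equal(all_ranked$node[-1], sort(paste0("l", 1:5)))  # tie-break by id
  g <- random_net(40, 0.2, seed = 200)
  ks <- keystone_rank(g, 10)
  deg <- igraph::degree(g)
  ord <- order(-deg, names(deg))[1:10]
  expect_identical(ks$node, names(deg)[ord])
  expect_identical(ks$degree, as.integer(deg[ord]))
})
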