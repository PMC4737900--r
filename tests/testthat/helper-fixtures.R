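# Shared builders for graph and similarity fixtures. All stochastic
# fixtures take explicit seeds.

# similarity_matrix from a raw symmetric |r| matrix (diag forced to 1)
make_sim <- function(S, sign = NULL, gene_ids = NULL, annotations = NULL) {
  n <- nrow(S)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(n))
  if (is.null(sign)) sign <- matrix(1, n, n)
  diag(S) <- 1
  diag(sign) <- 1
  dimnames(S) <- dimnames(sign) <- list(gene_ids, gene_ids)
  structure(list(S = S, sign = sign,
                 n_pairs = matrix(10, n, n,
                                  dimnames = list(gene_ids, gene_ids)),
                 gene_ids = gene_ids, annotations = annotations,
                 condition = "fixture"),
            class = "similarity_matrix")
}

# econetwork from an explicit edge list (optionally signed/weighted)
make_net <- function(edges, nodes = NULL, weights = NULL, signs = NULL,
                     gene_names = NULL) {
  g <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
  if (!is.null(nodes)) g <- g + setdiff(nodes, igraph::V(g)$name)
  igraph::E(g)$weight <- if (is.null(weights)) 1 else weights
  igraph::E(g)$sign <- if (is.null(signs)) 1L else signs
  if (!is.null(gene_names))
    igraph::V(g)$gene_name <- gene_names[igraph::V(g)$name]
  g$s_t <- 0.9
  g$condition <- "fixture"
  class(g) <- c("econetwork", class(g))
  g
}

# two 3-cliques joined by one bridge edge; natural split has M = 5/14
two_cliques_bridge <- function() {
  make_net(rbind(c("a1", "a2"), c("a1", "a3"), c("a2", "a3"),
                 c("b1", "b2"), c("b1", "b3"), c("b2", "b3"),
                 c("a1", "b1")))
}

# every set partition of n items as a list of integer label vectors
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_lab) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(next_lab)) {
      recurse(c(labels, lab), max(next_lab, lab + 1L))
    }
  }
  recurse(integer(), 1L)
  out
}

# exhaustive maximum modularity over all partitions (graphs of <= 8 nodes)
exhaustive_max_modularity <- function(net) {
  g <- fmenet:::as_igraph(net)
  n <- igraph::vcount(g)
  stopifnot(n <= 8)
  parts <- all_partitions(n)
  best <- -Inf
  for (p in parts) {
    m <- modularity_score(g, stats::setNames(p, igraph::V(g)$name))
    if (m > best) best <- m
  }
  best
}

# seeded Erdos-Renyi econetwork
random_net <- function(n, p, seed) {
  g <- fmenet:::with_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
  igraph::E(g)$weight <- 1
  igraph::E(g)$sign <- 1L
  class(g) <- c("econetwork", class(g))
  g
}

# planted-partition econetwork with known block labels
planted_net <- function(blocks = 4, size = 15, p_in = 0.9, p_out = 0.05,
                        seed = 1) {
  fmenet:::with_seed(seed, {
    n <- blocks * size
    lab <- rep(seq_len(blocks), each = size)
    g <- igraph::sample_sbm(n,
                            pref.matrix = matrix(p_out, blocks, blocks) +
                              diag(rep(p_in - p_out, blocks)),
                            block.sizes = rep(size, blocks))
    igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
    keep <- igraph::degree(g) > 0
    lab <- lab[keep]
    g <- igraph::delete_vertices(g, !keep)
    igraph::E(g)$weight <- 1
    igraph::E(g)$sign <- 1L
    class(g) <- c("econetwork", class(g))
    list(net = g, labels = stats::setNames(lab, igraph::V(g)$name))
  })
}

# tab-delimited abundance file on disk; returns the path
write_abundance_fixture <- function(lines, dir = tempdir()) {
  path <- tempfile("abund", tmpdir = dir, fileext = ".tsv")
  writeLines(lines, path)
  path
}
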