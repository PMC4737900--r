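#' Construct the co-occurrence network at a similarity threshold
#'
#' Every gene pair with |r| >= `s_t` becomes an undirected edge, weighted by
#' the similarity (the connection strength) and signed by the sign of the
#' underlying correlation. Genes left without any edge are dropped; the
#' number of remaining nodes is the network size.
#'
#' @param sim a [pearson_similarity()] result.
#' @param s_t similarity threshold in (0, 1), normally from
#'   [select_threshold()].
#' @return an object of class `econetwork`: an [igraph::graph] with vertex
#'   attributes `name` (gene id) plus any annotations, edge attributes
#'   `weight` (similarity) and `sign`, and graph attributes `s_t`,
#'   `condition`.
#' @export
build_network <- function(sim, s_t) {
  stopifnot(inherits(sim, "similarity_matrix"), s_t > 0, s_t < 1)
  A <- sim$S
  diag(A) <- 0
  A[A < s_t] <- 0
  keep <- which(rowSums(A) > 0)
  if (!length(keep)) stop("no edges at threshold ", s_t, "; empty network")
  A <- A[keep, keep, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  sg <- sim$sign[keep, keep, drop = FALSE]
  igraph::E(g)$sign <- sg[cbind(el[, 1], el[, 2])]
  if (!is.null(sim$annotations)) {
    ann <- sim$annotations[keep, , drop = FALSE]
    for (col in colnames(ann))
      g <- igraph::set_vertex_attr(g, col, value = as.character(ann[[col]]))
  }
  g$s_t <- s_t
  g$condition <- if (is.null(sim$condition)) NA_character_ else
    paste(sim$condition, collapse = "+")
  class(g) <- c("econetwork", class(g))
  g
}

as_igraph <- function(net) {
  stopifnot(inherits(net, "igraph"))
  net
}

#' Average connectivity
#'
#' The mean node degree, `2L / n` for `L` links over `n` nodes.
#'
#' @param net an `econetwork` (or any igraph graph).
#' @return a single number.
#' @export
average_connectivity <- function(net) {
  g <- as_igraph(net)
  2 * igraph::ecount(g) / igraph::vcount(g)
}

#' Average clustering coefficient
#'
#' Mean over nodes of the local clustering coefficient (triangles through
#' the node over wedges centred on it); nodes of degree < 2 contribute 0 by
#' default.
#'
#' @param net an `econetwork`.
#' @param include_low_degree count degree-0/1 nodes as 0 in the mean
#'   (default TRUE) or exclude them.
#' @return a single number in `[0, 1]`.
#' @export
clustering_coefficient <- function(net, include_low_degree = TRUE) {
  g <- as_igraph(net)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  if (!include_low_degree) cc <- cc[igraph::degree(g) >= 2]
  if (!length(cc)) return(NA_real_)
  mean(cc)
}

#' Average geodesic path length
#'
#' Mean unweighted shortest-path distance over all connected node pairs;
#' pairs in different components are excluded from the mean.
#'
#' @param net an `econetwork`.
#' @return a single number, >= 1 whenever the network has an edge.
#' @export
average_path_length <- function(net) {
  g <- as_igraph(net)
  igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
}

#' Power-law fit to the degree distribution
#'
#' Correlation of `log10(count of nodes with degree k)` against `log10(k)`
#' over degrees with nonzero counts — the conventional "r of scale free"
#' diagnostic; strongly negative r indicates an approximately power-law
#' (scale-free) degree distribution.
#'
#' @param net an `econetwork`.
#' @return a list with `r` and `p` (both `NA` when fewer than 3 distinct
#'   positive degrees are present).
#' @export
scale_free_fit <- function(net) {
  g <- as_igraph(net)
  k <- igraph::degree(g)
  tab <- table(k[k > 0])
  if (length(tab) < 3L) return(list(r = NA_real_, p = NA_real_))
  x <- log10(as.numeric(names(tab)))
  y <- log10(as.numeric(tab))
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Topology index suite of a network
#'
#' Computes the standard index set used to characterize molecular
#' ecological networks: size, links, average connectivity, average geodesic
#' distance, average clustering coefficient, and the scale-free fit.
#'
#' @param net an `econetwork`.
#' @return a one-row data.frame with columns `n`, `L`, `avgK`, `GD`,
#'   `avgCC`, `scale_free_r`, `scale_free_p`.
#' @export
topology_indices <- function(net) {
  g <- as_igraph(net)
  sf <- scale_free_fit(g)
  data.frame(n = igraph::vcount(g), L = igraph::ecount(g),
             avgK = average_connectivity(g), GD = average_path_length(g),
             avgCC = clustering_coefficient(g),
             scale_free_r = sf$r, scale_free_p = sf$p)
}

#' Export an edge list with weights and signs
#'
#' @param net an `econetwork`.
#' @param path optional output path for a tab-delimited file; when `NULL`
#'   the edge list data.frame is returned instead.
#' @return the edge-list data.frame (invisibly when written to file).
#' @export
export_edgelist <- function(net, path = NULL) {
  g <- as_igraph(net)
  el <- igraph::as_edgelist(g)
  sgn <- igraph::E(g)$sign
  if (is.null(sgn)) sgn <- rep(NA_integer_, nrow(el))
  df <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                   weight = igraph::E(g)$weight, sign = sgn,
                   stringsAsFactors = FALSE)
  if (is.null(path)) return(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Export a network to GraphML
#'
#' @param net an `econetwork`.
#' @param path output path.
#' @export
export_graphml <- function(net, path) {
  g <- as_igraph(net)
  class(g) <- "igraph"
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a network to Cytoscape SIF format
#'
#' One line per edge: `source <relation> target`, with relation `pp` for
#' positive and `np` for negative edges.
#'
#' @param net an `econetwork`.
#' @param path output path.
#' @export
export_sif <- function(net, path) {
  df <- export_edgelist(net)
  rel <- ifelse(!is.na(df$sign) & df$sign < 0, "np", "pp")
  writeLines(paste(df$gene_a, rel, df$gene_b), path)
  invisible(path)
}
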