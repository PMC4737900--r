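#' Gene significance with respect to environmental traits
#'
#' For every (gene, trait) pair, the squared Pearson correlation between
#' the gene's abundance profile and the standardized trait over the shared
#' samples — how much of the gene's abundance variation a geochemical trait
#' explains. The unsquared |r| variant is available for sensitivity checks.
#'
#' @param tbl an [abundance_table()] (normally log-transformed).
#' @param traits a standardized [trait_table()].
#' @param squared use r^2 (default) or |r|.
#' @return a genes-by-traits numeric matrix in `[0, 1]`; `NA` for genes
#'   with constant profiles.
#' @export
gene_significance <- function(tbl, traits, squared = TRUE) {
  stopifnot(inherits(tbl, "abundance_table"), inherits(traits, "trait_table"))
  if (!traits$standardized)
    stop("standardize traits first (standardize_traits)")
  shared <- intersect(tbl$sample_ids, traits$sample_ids)
  if (length(shared) < 3L) stop("need at least 3 shared samples")
  vals <- tbl$values[, shared, drop = FALSE]
  vals[!tbl$detected[, shared, drop = FALSE]] <- NA_real_
  tv <- traits$values[shared, , drop = FALSE]
  r <- suppressWarnings(stats::cor(t(vals), tv,
                                   use = "pairwise.complete.obs"))
  gs <- if (squared) r^2 else abs(r)
  dimnames(gs) <- list(tbl$gene_ids, traits$trait_names)
  gs
}

#' Correlate gene significance with node connectivity
#'
#' For each trait, the Pearson correlation (and p-value) between gene
#' significance and node degree over the genes present in the network:
#' does a trait preferentially explain the abundance of highly connected
#' genes?
#'
#' @param gs a [gene_significance()] matrix.
#' @param net an `econetwork`.
#' @return a data.frame with columns `trait`, `r`, `p`, `n_genes` (`NA`
#'   r/p when gene significance has no variance).
#' @export
gs_connectivity_correlation <- function(gs, net) {
  g <- as_igraph(net)
  shared <- intersect(rownames(gs), igraph::V(g)$name)
  if (length(shared) < 3L)
    stop("fewer than 3 genes shared between network and gene significance")
  k <- igraph::degree(g)[shared]
  out <- lapply(colnames(gs), function(tr) {
    x <- gs[shared, tr]
    ok <- is.finite(x)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(k[ok]) == 0)
      return(data.frame(trait = tr, r = NA_real_, p = NA_real_,
                        n_genes = sum(ok)))
    ct <- stats::cor.test(x[ok], k[ok])
    data.frame(trait = tr, r = unname(ct$estimate), p = ct$p.value,
               n_genes = sum(ok))
  })
  do.call(rbind, out)
}

#' Correlate node degrees with environmental factors
#'
#' Pairs each gene's network degree with a per-gene exposure to each trait
#' and reports the Pearson correlation with significance stars. Degree is a
#' per-gene quantity while traits are per-sample, so an exposure construction
#' is needed: the default (`method = "abundance_weighted"`) takes each
#' gene's abundance-weighted mean of the per-sample trait values, i.e. the
#' trait level of the samples where the gene is most abundant. The
#' alternative (`method = "gs"`) correlates degree directly with gene
#' significance.
#'
#' @param net an `econetwork`.
#' @param tbl the [abundance_table()] the network was built from.
#' @param traits a standardized [trait_table()].
#' @param method `"abundance_weighted"` (default) or `"gs"`.
#' @return a data.frame with columns `trait`, `r`, `p`, `stars`
#'   (`**` p < 0.01, `*` p < 0.05), `n_genes`.
#' @export
degree_trait_correlations <- function(net, tbl, traits,
                                      method = c("abundance_weighted",
                                                 "gs")) {
  method <- match.arg(method)
  g <- as_igraph(net)
  stopifnot(inherits(traits, "trait_table"))
  shared_s <- intersect(tbl$sample_ids, traits$sample_ids)
  if (length(shared_s) < 3L)
    stop("fewer than 3 shared samples between abundance and trait tables")
  genes <- intersect(igraph::V(g)$name, tbl$gene_ids)
  if (length(genes) < 3L) stop("fewer than 3 network genes in the table")
  k <- igraph::degree(g)[genes]
  exposure <- switch(method,
    abundance_weighted = {
      w <- tbl$values[genes, shared_s, drop = FALSE]
      w[!tbl$detected[genes, shared_s, drop = FALSE]] <- 0
      if (tbl$log_transformed) w <- 10^w  # weights on the intensity scale
      sw <- rowSums(w)
      (w %*% traits$values[shared_s, , drop = FALSE]) / pmax(sw, .Machine$double.eps)
    },
    gs = gene_significance(tbl, traits)[genes, , drop = FALSE])
  out <- lapply(traits$trait_names, function(tr) {
    if (!tr %in% colnames(exposure)) stop("missing trait column: ", tr)
    x <- exposure[, tr]
    ok <- is.finite(x)
    if (stats::sd(k[ok]) == 0 || sum(ok) < 3L || stats::sd(x[ok]) == 0)
      return(data.frame(trait = tr, r = NA_real_, p = NA_real_,
                        stars = "", n_genes = sum(ok)))
    ct <- stats::cor.test(k[ok], x[ok])
    data.frame(trait = tr, r = unname(ct$estimate), p = ct$p.value,
               stars = if (ct$p.value < 0.01) "**"
                       else if (ct$p.value < 0.05) "*" else "",
               n_genes = sum(ok))
  })
  do.call(rbind, out)
}

#' Bundled functional-category gene sets
#'
#' Gene-name sets for the two focal hydrocarbon-degradation categories:
#' `alk` (alkane degradation: alkane monooxygenase, aldehyde dehydrogenase,
#' alcohol dehydrogenase, acyl-CoA synthetase) and `pah` (polycyclic
#' aromatic hydrocarbon degradation).
#'
#' @return a named list of character vectors of gene names.
#' @export
degradation_gene_sets <- function() {
  list(alk = c("alkB", "alkH", "alkJ", "alkK"),
       pah = c("bphA", "bphB", "bphC", "bphD", "nahA", "nahB", "nahF",
               "phdA", "phdCI", "phdG", "phdJ", "phdK", "aorL", "nidA",
               "oxoH"))
}

#' Extract a functional-category subnetwork
#'
#' Induced subgraph on the nodes whose `gene_name` annotation matches the
#' given list, with per-edge signs, the negative-edge fraction, a degree
#' ranking (keystone candidates), and each node's local clustering
#' coefficient (the "strength degree" of a hub).
#'
#' @param net an `econetwork` whose vertices carry a `gene_name` attribute.
#' @param gene_names nonempty character vector of gene names, e.g. an
#'   element of [degradation_gene_sets()].
#' @return an object of class `subnetwork_report`: `graph` (the induced
#'   `econetwork`), `nodes` (data.frame: node, gene_name, degree,
#'   local_cc, rank), `edges` (edge list with signs), `negative_fraction`,
#'   `positive_fraction`.
#' @export
extract_subnetwork <- function(net, gene_names) {
  g <- as_igraph(net)
  if (!length(gene_names)) stop("gene_names must be nonempty")
  gn <- igraph::vertex_attr(g, "gene_name")
  if (is.null(gn)) stop("network has no gene_name vertex annotation")
  keep <- which(gn %in% gene_names)
  if (!length(keep)) {
    warning("no network genes match the requested gene names")
    return(structure(list(graph = NULL,
                          nodes = data.frame(node = character(),
                                             gene_name = character(),
                                             degree = integer(),
                                             local_cc = numeric(),
                                             rank = integer()),
                          edges = data.frame(), negative_fraction = NA_real_,
                          positive_fraction = NA_real_),
                     class = "subnetwork_report"))
  }
  sub <- igraph::induced_subgraph(g, keep)
  class(sub) <- class(net)
  edges <- export_edgelist(sub)
  neg <- if (nrow(edges)) mean(edges$sign < 0) else NA_real_
  k <- igraph::degree(sub)
  cc <- igraph::transitivity(sub, type = "local", isolates = "zero")
  nodes <- data.frame(node = igraph::V(sub)$name,
                      gene_name = igraph::vertex_attr(sub, "gene_name"),
                      degree = as.integer(k), local_cc = cc,
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(-nodes$degree, nodes$node), ]
  nodes$rank <- seq_len(nrow(nodes))
  rownames(nodes) <- NULL
  structure(list(graph = sub, nodes = nodes, edges = edges,
                 negative_fraction = neg,
                 positive_fraction = if (is.na(neg)) NA_real_ else 1 - neg),
            class = "subnetwork_report")
}

#' @export
print.subnetwork_report <- function(x, ...) {
  cat(sprintf("subnetwork_report: %d nodes, %d edges (%.1f%% negative)\n",
              nrow(x$nodes), nrow(x$edges), 100 * x$negative_fraction))
  invisible(x)
}

#' Rank keystone genes by connectivity
#'
#' The top-`k` nodes by degree (ties broken by gene id), optionally merged
#' with topological role labels so module hubs and connectors are flagged:
#' the operational definition of candidate keystone genes.
#'
#' @param net an `econetwork` (a full network or a subnetwork).
#' @param k number of genes to return; default 6. Values beyond the node
#'   count return all nodes, ranked.
#' @param roles optional [node_role_table()] output to merge role labels.
#' @return a data.frame with columns `rank`, `node`, `degree`, plus
#'   `gene_name` and `role` where available.
#' @export
keystone_rank <- function(net, k = 6L, roles = NULL) {
  stopifnot(k >= 1L)
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  ord <- order(-deg, names(deg))
  ord <- ord[seq_len(min(k, length(ord)))]
  df <- data.frame(rank = seq_along(ord), node = names(deg)[ord],
                   degree = as.integer(deg[ord]), stringsAsFactors = FALSE)
  gn <- igraph::vertex_attr(g, "gene_name")
  if (!is.null(gn)) df$gene_name <- gn[ord]
  if (!is.null(roles))
    df$role <- roles$role[match(df$node, roles$node)]
  df
}
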