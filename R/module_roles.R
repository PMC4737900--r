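#' Modularity of a partition
#'
#' Evaluates `M = sum_s [ l_s / L - (d_s / 2L)^2 ]` over modules `s`, where
#' `l_s` is the number of links with both ends in module `s` (each counted
#' once), `d_s` the sum of degrees of the module's nodes, and `L` the total
#' number of links. Modularity compares the within-module link fraction to
#' its expectation under random linkage with the same degrees.
#'
#' @param net an `econetwork` (or igraph graph) with at least one edge.
#' @param membership module assignment: a vector of module ids named by (or
#'   ordered as) the network's nodes, or a `module_partition`.
#' @return the modularity, a number in `[-1, 1]`.
#' @export
modularity_score <- function(net, membership) {
  g <- as_igraph(net)
  L <- igraph::ecount(g)
  if (L < 1) stop("modularity requires at least one link")
  memb <- align_membership(g, membership)
  el <- igraph::as_edgelist(g, names = FALSE)
  within <- memb[el[, 1]] == memb[el[, 2]]
  mod_of_edge <- ifelse(within, memb[el[, 1]], NA)
  l_s <- table(factor(mod_of_edge, levels = sort(unique(memb))))
  d_s <- tapply(igraph::degree(g), memb, sum)
  d_s <- d_s[as.character(sort(unique(memb)))]
  sum(as.numeric(l_s) / L - (as.numeric(d_s) / (2 * L))^2)
}

align_membership <- function(g, membership) {
  if (inherits(membership, "module_partition"))
    membership <- membership$membership
  nodes <- igraph::V(g)$name
  if (!is.null(names(membership))) {
    missing <- setdiff(nodes, names(membership))
    if (length(missing))
      stop("nodes missing from partition: ",
           paste(utils::head(missing, 5), collapse = ", "))
    membership <- membership[nodes]
  } else if (length(membership) != igraph::vcount(g)) {
    stop("membership length does not match node count")
  }
  as.integer(factor(membership))
}

#' Detect modules by greedy modularity maximization
#'
#' Agglomerative merging from singleton modules: at each step the merge
#' with the largest modularity gain is performed, the whole merge tree is
#' scanned, and the level with the maximum modularity score separates the
#' graph into modules. Module ids in the result are relabelled 1, 2, ... by
#' decreasing size, ties broken by the lexicographically smallest member
#' gene id, so runs are reproducible.
#'
#' @param net an `econetwork` with at least one edge.
#' @param method `"fast_greedy"` (default, the greedy merge-tree procedure)
#'   or `"leading_eigen"` (spectral alternative).
#' @return an object of class `module_partition`: `membership` (named
#'   integer vector), `n_modules`, `modularity` (evaluated with
#'   [modularity_score()]), and for the greedy method `merges` and
#'   `modularity_trace` (modularity at every level of the merge tree).
#' @export
detect_modules <- function(net, method = c("fast_greedy", "leading_eigen")) {
  g <- as_igraph(net)
  method <- match.arg(method)
  if (igraph::ecount(g) < 1) stop("module detection requires edges")
  cl <- switch(method,
               fast_greedy = igraph::cluster_fast_greedy(g, weights = NULL),
               leading_eigen = igraph::cluster_leading_eigen(g,
                                                             weights = NULL))
  memb <- if (method == "fast_greedy") {
    # cut the merge tree at the level with maximum modularity ourselves:
    # the stored membership can sit one level off after floating-point ties
    igraph::cut_at(cl, steps = which.max(cl$modularity) - 1L)
  } else {
    igraph::membership(cl)
  }
  memb <- relabel_modules(g, as.integer(memb))
  part <- structure(list(membership = memb,
                         n_modules = length(unique(memb)),
                         modularity = NA_real_,
                         method = method,
                         merges = if (method == "fast_greedy") cl$merges,
                         modularity_trace = if (method == "fast_greedy")
                           cl$modularity),
                    class = "module_partition")
  part$modularity <- modularity_score(g, part)
  part
}

relabel_modules <- function(g, memb) {
  nodes <- igraph::V(g)$name
  sizes <- table(memb)
  first_member <- tapply(nodes, memb, function(x) min(sort(x)))
  ord <- order(-as.numeric(sizes), first_member[names(sizes)])
  new_id <- stats::setNames(seq_along(ord), names(sizes)[ord])
  stats::setNames(as.integer(new_id[as.character(memb)]), nodes)
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules, modularity M = %.4f (%s)\n",
              x$n_modules, x$modularity, x$method))
  invisible(x)
}

#' Within-module degree z-score
#'
#' For node `i` in module `s`, `Z_i = (kappa_i - mean kappa) / sd kappa`,
#' where `kappa_i` is the number of links of `i` to other nodes of `s` and
#' mean/sd are taken over the nodes of `s` (population standard deviation;
#' `Z_i = 0` when the module's within-degrees are all equal). High `Z_i`
#' marks nodes that are hubs within their own module.
#'
#' @param net an `econetwork`.
#' @param part a [detect_modules()] partition (or membership vector).
#' @return named numeric vector of `Z_i` per node.
#' @export
within_module_z <- function(net, part) {
  g <- as_igraph(net)
  memb <- align_membership(g, part)
  kappa <- within_degrees(g, memb)
  z <- numeric(length(kappa))
  for (m in unique(memb)) {
    idx <- which(memb == m)
    k <- kappa[idx]
    mu <- mean(k)
    sigma <- sqrt(mean((k - mu)^2))
    z[idx] <- if (sigma > 0) (k - mu) / sigma else 0
  }
  stats::setNames(z, igraph::V(g)$name)
}

within_degrees <- function(g, memb) {
  el <- igraph::as_edgelist(g, names = FALSE)
  within <- memb[el[, 1]] == memb[el[, 2]]
  k <- numeric(igraph::vcount(g))
  ends <- c(el[within, 1], el[within, 2])
  if (length(ends)) {
    tab <- table(ends)
    k[as.integer(names(tab))] <- as.numeric(tab)
  }
  k
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_s (kappa_is / kappa_i)^2`, where `kappa_is` is the number
#' of links of node `i` into module `s` and `kappa_i` its total degree.
#' `P_i = 0` when all links stay inside the node's own module; values near
#' `1 - 1/N_M` mean links spread evenly over the modules.
#'
#' @param net an `econetwork`.
#' @param part a [detect_modules()] partition (or membership vector).
#' @return named numeric vector of `P_i` per node.
#' @export
participation_p <- function(net, part) {
  g <- as_igraph(net)
  memb <- align_membership(g, part)
  el <- igraph::as_edgelist(g, names = FALSE)
  n <- igraph::vcount(g)
  n_mod <- max(memb)
  kis <- matrix(0, n, n_mod)
  for (r in seq_len(nrow(el))) {
    a <- el[r, 1]; b <- el[r, 2]
    kis[a, memb[b]] <- kis[a, memb[b]] + 1
    kis[b, memb[a]] <- kis[b, memb[a]] + 1
  }
  k <- rowSums(kis)
  p <- 1 - rowSums((kis / pmax(k, 1))^2)
  p[k == 0] <- NA_real_  # cannot occur in a built network; guard anyway
  stats::setNames(p, igraph::V(g)$name)
}

#' Classify topological node roles from Z and P
#'
#' The Z-P parameter plane is partitioned into four regions: peripheral
#' nodes (`Z <= z_threshold`, `P <= p_threshold`), connectors
#' (`Z <= z_threshold`, `P > p_threshold`), module hubs
#' (`Z > z_threshold`, `P <= p_threshold`), and network hubs (both above).
#' The conventional boundaries are `Z = 2.5` and `P = 0.62`.
#'
#' @param z named vector of within-module degree z-scores.
#' @param p named vector of participation coefficients, aligned with `z`.
#' @param z_threshold,p_threshold role boundaries; defaults 2.5 and 0.62.
#' @return an object of class `node_roles`: a data.frame with columns
#'   `node`, `Z`, `P`, `role` plus a `summary` attribute of per-role counts
#'   and fractions.
#' @export
classify_roles <- function(z, p, z_threshold = 2.5, p_threshold = 0.62) {
  if (length(z) != length(p)) stop("Z and P must be aligned")
  if (!is.null(names(z)) && !is.null(names(p))) p <- p[names(z)]
  role <- ifelse(z > z_threshold,
                 ifelse(p > p_threshold, "network_hub", "module_hub"),
                 ifelse(p > p_threshold, "connector", "peripheral"))
  df <- data.frame(node = if (is.null(names(z))) seq_along(z) else names(z),
                   Z = as.numeric(z), P = as.numeric(p), role = role,
                   stringsAsFactors = FALSE, row.names = NULL)
  lv <- c("peripheral", "connector", "module_hub", "network_hub")
  counts <- table(factor(role, levels = lv))
  summary <- data.frame(role = lv, count = as.integer(counts),
                        fraction = as.numeric(counts) / length(role))
  attr(df, "summary") <- summary
  class(df) <- c("node_roles", class(df))
  df
}

#' @export
print.node_roles <- function(x, ...) {
  s <- attr(x, "summary")
  cat("node_roles:", nrow(x), "nodes\n")
  print.data.frame(s, row.names = FALSE)
  invisible(x)
}

#' Node role table for a network partition
#'
#' Convenience wrapper computing degree, module, `Z_i`, `P_i`, and the role
#' class for every node, merged with any gene annotations.
#'
#' @param net an `econetwork`.
#' @param part a [detect_modules()] partition.
#' @param z_threshold,p_threshold role boundaries; see [classify_roles()].
#' @return a data.frame with columns `node`, `module`, `degree`, `Z`, `P`,
#'   `role` and any vertex annotation columns.
#' @export
node_role_table <- function(net, part, z_threshold = 2.5,
                            p_threshold = 0.62) {
  g <- as_igraph(net)
  z <- within_module_z(g, part)
  p <- participation_p(g, part)
  roles <- classify_roles(z, p, z_threshold, p_threshold)
  memb <- align_membership(g, part)
  df <- data.frame(node = igraph::V(g)$name, module = memb,
                   degree = as.integer(igraph::degree(g)),
                   Z = as.numeric(z), P = as.numeric(p),
                   role = roles$role, stringsAsFactors = FALSE)
  for (a in setdiff(igraph::vertex_attr_names(g), "name"))
    df[[a]] <- igraph::vertex_attr(g, a)
  df
}
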