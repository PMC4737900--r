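#' Published network index table (regression fixture)
#'
#' Topology index values reported for a two-condition soil study
#' (uncontaminated vs. long-term oil-contaminated, 10 replicate samples
#' each, functional-gene microarray): original gene counts, the
#' RMT-selected similarity thresholds, network size and links, the
#' scale-free fit, average connectivity, geodesic distance, clustering
#' coefficient, modularity with module counts, and the corresponding
#' rewired-null-ensemble means and standard deviations. Bundled as a
#' plain-text fixture for arithmetic consistency checks (e.g. avgK = 2L/n,
#' percent reductions between conditions); the underlying intensity data
#' are not publicly deposited, so these printed values are the only
#' recoverable surface.
#'
#' @return a data.frame, one row per condition.
#' @export
reference_network_indices <- function() {
  utils::read.delim(system.file("extdata", "reference_network_indices.tsv",
                                package = "fmenet"),
                    stringsAsFactors = FALSE)
}

#' Published node-role table (regression fixture)
#'
#' The module-hub and connector genes reported for the same two-condition
#' soil study: gene ids with within-module connectivity `Z_i`,
#' participation coefficient `P_i`, gene names, and the reported role
#' class. Used as a regression fixture for [classify_roles()]. One
#' reported connector row carries a printed `P_i` of 0.617, below the
#' role boundary `P = 0.62` that the same study states; under the stated
#' rule that row classifies as peripheral.
#'
#' @return a data.frame, one row per reported hub/connector gene.
#' @export
reference_node_roles <- function() {
  utils::read.delim(system.file("extdata", "reference_node_roles.tsv",
                                package = "fmenet"),
                    colClasses = c(gene_id = "character"),
                    stringsAsFactors = FALSE)
}
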