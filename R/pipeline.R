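#' Run the full network pipeline on one condition
#'
#' Orchestrates the stages end-to-end for a single condition's abundance
#' table: prevalence filtering, log transformation, duplicate-profile
#' collapse, similarity matrix, RMT threshold selection, network
#' construction, module detection, node-role classification, the
#' degree-preserving null ensemble, and (when traits are given) gene
#' significance and degree-trait correlations. All randomness derives from
#' `seed`, so a rerun reproduces the bundle exactly.
#'
#' @param tbl an [abundance_table()] of raw intensities for one condition.
#' @param traits optional [trait_table()] (standardized internally).
#' @param min_fraction prevalence filter fraction, default 0.5.
#' @param missing_policy,small_constant see [log_transform()].
#' @param scan_min,scan_max,step,alpha,min_eigs see [select_threshold()].
#' @param s_t optional fixed threshold, skipping the scan.
#' @param R null-ensemble replicates, default 100.
#' @param swaps_per_link see [rewire_network()].
#' @param seed master integer seed.
#' @param out_dir optional directory; when given, all stage exports (TSV
#'   edge list, GraphML, SIF, scan trace, role table, summary row, JSON
#'   provenance) are written there.
#' @return a `condition_bundle` list: `table` (preprocessed), `sim`,
#'   `dedup_mapping`, `scan`, `s_t`, `network`, `partition`, `roles`,
#'   `ensemble`, `indices`, `summary` (one Table-style row: n_original,
#'   s_t, n, L, scale_free_r, avgK, GD, avgCC, M, n_modules and null-model
#'   means/sds), and `trait_results` when traits were supplied.
#' @export
run_condition <- function(tbl, traits = NULL, min_fraction = 0.5,
                          missing_policy = "fill_small",
                          small_constant = 0.5,
                          scan_min = 0.30, scan_max = 0.99, step = 0.01,
                          alpha = 0.01, min_eigs = 100L, s_t = NULL,
                          R = 100L, swaps_per_link = 100L, seed = 1L,
                          out_dir = NULL) {
  stopifnot(inherits(tbl, "abundance_table"))
  n_original <- length(tbl$gene_ids)
  filtered <- prevalence_filter(tbl, min_fraction)
  logged <- log_transform(filtered, missing_policy, small_constant)
  sim <- pearson_similarity(logged)
  dd <- deduplicate_profiles(sim)
  scan <- NULL
  if (is.null(s_t)) {
    scan <- select_threshold(dd$sim, scan_min = scan_min,
                             scan_max = scan_max, step = step,
                             alpha = alpha, min_eigs = min_eigs)
    s_t <- scan$s_t
  }
  net <- build_network(dd$sim, s_t)
  part <- detect_modules(net)
  roles <- node_role_table(net, part)
  ens <- build_ensemble(net, R = R, seed = seed,
                        swaps_per_link = swaps_per_link)
  idx <- topology_indices(net)
  summary <- data.frame(
    condition = net$condition, n_original = n_original, s_t = s_t,
    n = idx$n, L = idx$L, scale_free_r = idx$scale_free_r,
    avgK = idx$avgK, GD = idx$GD, avgCC = idx$avgCC,
    M = part$modularity, n_modules = part$n_modules,
    rand_GD_mean = ens$summary$mean[ens$summary$index == "GD"],
    rand_GD_sd = ens$summary$sd[ens$summary$index == "GD"],
    rand_avgCC_mean = ens$summary$mean[ens$summary$index == "avgCC"],
    rand_avgCC_sd = ens$summary$sd[ens$summary$index == "avgCC"],
    rand_M_mean = ens$summary$mean[ens$summary$index == "M"],
    rand_M_sd = ens$summary$sd[ens$summary$index == "M"])
  trait_results <- NULL
  if (!is.null(traits)) {
    std <- if (traits$standardized) traits else standardize_traits(traits)
    gs <- gene_significance(logged, std)
    trait_results <- list(
      gene_significance = gs,
      gs_connectivity = gs_connectivity_correlation(gs, net),
      degree_trait = degree_trait_correlations(net, logged, std))
  }
  bundle <- list(table = logged, sim = sim, dedup_mapping = dd$mapping,
                 scan = scan, s_t = s_t, network = net, partition = part,
                 roles = roles, ensemble = ens, indices = idx,
                 summary = summary, trait_results = trait_results,
                 seed = seed)
  class(bundle) <- "condition_bundle"
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.condition_bundle <- function(x, ...) {
  cat("condition_bundle\n")
  print.data.frame(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  export_edgelist(bundle$network, p("edges.tsv"))
  export_graphml(bundle$network, p("network.graphml"))
  export_sif(bundle$network, p("network.sif"))
  if (!is.null(bundle$scan)) write_scan_trace(bundle$scan, p("scan.tsv"))
  utils::write.table(bundle$roles, p("roles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$summary, p("summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$ensemble$replicates, p("null_replicates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- list(seed = bundle$seed, s_t = bundle$s_t,
               n_genes = length(bundle$table$gene_ids),
               n_samples = length(bundle$table$sample_ids),
               R = bundle$ensemble$R,
               swaps_per_link = bundle$ensemble$swaps_per_link)
  jsonlite::write_json(prov, p("provenance.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' Compare two condition bundles
#'
#' Emits the null-ensemble comparison report for the two conditions plus
#' percent changes (condition a -> condition b) of average connectivity,
#' module count, and modularity.
#'
#' @param bundle_a,bundle_b [run_condition()] results.
#' @param labels length-2 condition labels.
#' @return a list with `report` (a [compare_networks()] data.frame) and
#'   `percent_change` (data.frame with index, value_a, value_b, change_pct).
#' @export
compare_conditions <- function(bundle_a, bundle_b,
                               labels = c("a", "b")) {
  stopifnot(inherits(bundle_a, "condition_bundle"),
            inherits(bundle_b, "condition_bundle"))
  report <- compare_networks(bundle_a$ensemble, bundle_b$ensemble, labels)
  pick <- function(b, what) switch(what,
                                   avgK = b$summary$avgK,
                                   n_modules = b$summary$n_modules,
                                   M = b$summary$M)
  pc <- do.call(rbind, lapply(c("avgK", "n_modules", "M"), function(w) {
    va <- pick(bundle_a, w); vb <- pick(bundle_b, w)
    data.frame(index = w, value_a = va, value_b = vb,
               change_pct = percent_change(va, vb))
  }))
  list(report = report, percent_change = pc)
}
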