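#' Degree-preserving rewiring of a network
#'
#' Randomizes link positions by repeated double-edge swaps while keeping
#' the node set, the number of links, and every node's degree unchanged
#' (the Maslov-Sneppen null model). Swaps that would create self-loops or
#' parallel edges are rejected.
#'
#' @param net an `econetwork` (or igraph graph) with at least 2 links.
#' @param swaps_per_link attempted swaps per link; default 100, well past
#'   mixing for networks of this scale.
#' @param seed optional integer seed for reproducibility.
#' @return a rewired graph with the same class and graph attributes; edge
#'   weights and signs are dropped (link positions are random, so weights
#'   carry no meaning in the null model).
#' @export
rewire_network <- function(net, swaps_per_link = 100L, seed = NULL) {
  g <- as_igraph(net)
  L <- igraph::ecount(g)
  if (L < 2L) {
    warning("graph admits no degree-preserving swap; returning a copy")
    return(net)
  }
  run <- function() igraph::rewire(g, igraph::keeping_degseq(
    loops = FALSE, niter = swaps_per_link * L))
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  out$s_t <- g$s_t
  out$condition <- g$condition
  class(out) <- class(net)
  out
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Build a null ensemble of rewired networks
#'
#' Generates `R` degree-preserving rewired replicates of the network (each
#' from its own seed-derived stream), computes the full topology index
#' suite plus modularity for every replicate, and summarizes each index by
#' its ensemble mean and standard deviation. These null distributions are
#' what empirical index values are judged against: a single network per
#' condition has no replicate-based error, so the rewired ensemble supplies
#' the spread.
#'
#' @param net an `econetwork`.
#' @param R number of replicates, default 100.
#' @param seed master integer seed; per-replicate seeds are derived from it.
#' @param swaps_per_link passed to [rewire_network()].
#' @return an object of class `null_ensemble`: `replicates` (data.frame of
#'   per-replicate indices), `summary` (per-index mean/sd), `empirical`
#'   (the source network's indices), `R`, `seed`, `swaps_per_link`.
#' @export
build_ensemble <- function(net, R = 100L, seed = 1L, swaps_per_link = 100L) {
  stopifnot(R >= 2L)
  g <- as_igraph(net)
  emp <- network_index_row(g)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, R))
  reps <- vector("list", R)
  for (i in seq_len(R)) {
    rg <- rewire_network(g, swaps_per_link = swaps_per_link, seed = seeds[i])
    stopifnot(identical(sort(igraph::degree(rg)), sort(igraph::degree(g))))
    reps[[i]] <- network_index_row(rg)
  }
  reps <- do.call(rbind, reps)
  reps$replicate <- seq_len(R)
  idx_cols <- setdiff(colnames(reps), "replicate")
  summary <- data.frame(index = idx_cols,
                        mean = vapply(reps[idx_cols], mean, 0,
                                      USE.NAMES = FALSE),
                        sd = vapply(reps[idx_cols], stats::sd, 0,
                                    USE.NAMES = FALSE))
  structure(list(replicates = reps, summary = summary, empirical = emp,
                 R = R, seed = seed, swaps_per_link = swaps_per_link),
            class = "null_ensemble")
}

network_index_row <- function(g) {
  ti <- topology_indices(g)
  part <- detect_modules(g)
  ti$M <- part$modularity
  ti$n_modules <- part$n_modules
  ti$scale_free_p <- NULL
  ti
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null_ensemble: R = %d rewired replicates (seed %d)\n",
              x$R, x$seed))
  s <- x$summary
  s$empirical <- as.numeric(x$empirical[1, s$index])
  print.data.frame(s, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare two networks through their null ensembles
#'
#' For each topology index, a two-sample Welch t-test contrasts the two
#' null-ensemble distributions (n = R per side, using the ensemble standard
#' deviations), and each condition's empirical value is additionally scored
#' against its own ensemble as a z-score. When both ensemble standard
#' deviations are zero the comparison is degenerate: t = 0 and p = 1 when
#' the means agree, p = 0 otherwise.
#'
#' @param ens_a,ens_b [build_ensemble()] results for the two conditions,
#'   built with the same `R` and index suite.
#' @param labels length-2 character vector of condition labels.
#' @return an object of class `comparison_report`: a data.frame with per
#'   index the empirical values, ensemble means/sds, Welch `t`, `df`, `p`,
#'   and empirical-vs-own-ensemble z-scores.
#' @export
compare_networks <- function(ens_a, ens_b, labels = c("a", "b")) {
  stopifnot(inherits(ens_a, "null_ensemble"), inherits(ens_b, "null_ensemble"))
  if (ens_a$R != ens_b$R)
    stop("ensembles must use the same replicate count R")
  if (!identical(ens_a$summary$index, ens_b$summary$index))
    stop("ensembles carry different index suites")
  R <- ens_a$R
  out <- lapply(seq_len(nrow(ens_a$summary)), function(i) {
    idx <- ens_a$summary$index[i]
    m1 <- ens_a$summary$mean[i]; s1 <- ens_a$summary$sd[i]
    m2 <- ens_b$summary$mean[i]; s2 <- ens_b$summary$sd[i]
    tt <- welch_t(m1, s1, m2, s2, R)
    e1 <- as.numeric(ens_a$empirical[1, idx])
    e2 <- as.numeric(ens_b$empirical[1, idx])
    data.frame(index = idx,
               empirical_a = e1, empirical_b = e2,
               null_mean_a = m1, null_sd_a = s1,
               null_mean_b = m2, null_sd_b = s2,
               t = tt$t, df = tt$df, p = tt$p,
               z_a = if (s1 > 0) (e1 - m1) / s1 else NA_real_,
               z_b = if (s2 > 0) (e2 - m2) / s2 else NA_real_,
               significant = !is.na(tt$p) & tt$p < 0.05)
  })
  out <- do.call(rbind, out)
  attr(out, "labels") <- labels
  class(out) <- c("comparison_report", class(out))
  out
}

welch_t <- function(m1, s1, m2, s2, R) {
  if (s1 == 0 && s2 == 0) {
    if (isTRUE(all.equal(m1, m2))) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = Inf * sign(m1 - m2), df = NA_real_, p = 0))
  }
  se2 <- s1^2 / R + s2^2 / R
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1^2 / R)^2 / (R - 1) + (s2^2 / R)^2 / (R - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Percent change between two values
#'
#' `100 * (before - after) / before`: positive values are reductions.
#'
#' @param before,after numeric; `before` must be nonzero.
#' @return percent change.
#' @export
percent_change <- function(before, after) {
  if (any(before == 0)) stop("percent change undefined for before = 0")
  100 * (before - after) / before
}
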