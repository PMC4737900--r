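#' Build the absolute Pearson similarity matrix
#'
#' Pairwise Pearson correlations between gene abundance profiles across
#' samples; the similarity used for network construction is the absolute
#' value |r|, with the sign of r retained separately so that edges can later
#' be labelled positive (co-occurrence) or negative (exclusion).
#'
#' With a complete matrix (the `fill_small` policy of [log_transform()]) all
#' samples enter every pair. Under `leave_missing`, each pair uses its
#' pairwise-complete samples, and pairs with fewer than `min_overlap` shared
#' samples are set to similarity 0 (sign 0): too few points to estimate r.
#'
#' @param tbl an [abundance_table()], normally log-transformed.
#' @param min_overlap minimum shared detected samples per pair; default 5,
#'   half of a ten-replicate design.
#' @return an object of class `similarity_matrix` with elements `S`
#'   (symmetric |r|, unit diagonal), `sign` (sign of r), `n_pairs` (samples
#'   used per entry), `gene_ids`, and carried-through `annotations`,
#'   `condition`.
#' @export
pearson_similarity <- function(tbl, min_overlap = 5L) {
  stopifnot(inherits(tbl, "abundance_table"))
  n_s <- length(tbl$sample_ids)
  if (n_s < 3L) stop("need at least 3 samples to estimate correlations")
  vals <- tbl$values
  vals[!tbl$detected] <- NA_real_
  complete <- all(tbl$detected)
  if (complete) {
    sds <- apply(vals, 1L, stats::sd)
    if (all(sds == 0)) stop("all gene profiles are constant")
    r <- suppressWarnings(stats::cor(t(vals)))
    n_pairs <- matrix(n_s, nrow(vals), nrow(vals))
  } else {
    r <- suppressWarnings(stats::cor(t(vals), use = "pairwise.complete.obs"))
    det <- tbl$detected * 1
    n_pairs <- det %*% t(det)
  }
  r[!is.finite(r)] <- 0          # zero-variance genes: isolated, not errors
  if (!complete) r[n_pairs < min_overlap] <- 0  # complete data use full n
  r <- (r + t(r)) / 2            # enforce exact symmetry
  r <- pmin(pmax(r, -1), 1)
  S <- abs(r)
  sg <- sign(r)
  diag(S) <- 1
  diag(sg) <- 1
  dimnames(S) <- dimnames(sg) <- dimnames(n_pairs) <-
    list(tbl$gene_ids, tbl$gene_ids)
  structure(list(S = S, sign = sg, n_pairs = n_pairs,
                 gene_ids = tbl$gene_ids, annotations = tbl$annotations,
                 condition = unique(tbl$condition)),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  off <- x$S[upper.tri(x$S)]
  cat(sprintf("similarity_matrix: %d genes; |r| quartiles %.3f / %.3f / %.3f\n",
              length(x$gene_ids),
              stats::quantile(off, 0.25), stats::median(off),
              stats::quantile(off, 0.75)))
  invisible(x)
}

#' Collapse perfectly duplicated correlation profiles
#'
#' Genes whose profiles are identical (or affinely related) have identical
#' rows in the similarity matrix; such exactly degenerate rows contribute
#' spurious zero eigenvalue spacings and distort the spacing distribution.
#' This collapses each group of genes with pairwise |r| >= 1 - tol to one
#' representative (the first by input order) and returns the mapping so that
#' network membership can later be re-expanded.
#'
#' @param sim a [pearson_similarity()] result.
#' @param tol tolerance on 1 - |r|; default 0, meaning exact ties up to
#'   floating-point roundoff (even byte-identical profiles correlate at
#'   1 minus a few ulps through the BLAS path).
#' @return a list with `sim` (the reduced `similarity_matrix`) and `mapping`
#'   (named character vector gene id -> representative id).
#' @export
deduplicate_profiles <- function(sim, tol = 0) {
  stopifnot(inherits(sim, "similarity_matrix"), tol >= 0)
  n <- length(sim$gene_ids)
  rep_of <- seq_len(n)
  for (j in seq_len(n)) {
    if (rep_of[j] != j) next
    if (j == n) break
    dup <- which(sim$S[j, ] >= 1 - tol - 64 * .Machine$double.eps)
    dup <- dup[dup > j & rep_of[dup] == dup]
    rep_of[dup] <- j
  }
  mapping <- stats::setNames(sim$gene_ids[rep_of], sim$gene_ids)
  keep <- which(rep_of == seq_len(n))
  out <- sim
  out$S <- sim$S[keep, keep, drop = FALSE]
  out$sign <- sim$sign[keep, keep, drop = FALSE]
  out$n_pairs <- sim$n_pairs[keep, keep, drop = FALSE]
  out$gene_ids <- sim$gene_ids[keep]
  if (!is.null(sim$annotations))
    out$annotations <- sim$annotations[keep, , drop = FALSE]
  list(sim = out, mapping = mapping)
}

#' Export a similarity matrix to tab-delimited text
#'
#' Writes the |r| matrix and, optionally, the sign matrix with gene ids as
#' row and column labels.
#'
#' @param sim a `similarity_matrix`.
#' @param path output path for the |r| matrix.
#' @param sign_path optional output path for the sign matrix.
#' @export
write_similarity <- function(sim, path, sign_path = NULL) {
  utils::write.table(sim$S, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  if (!is.null(sign_path))
    utils::write.table(sim$sign, sign_path, sep = "\t", quote = FALSE,
                       col.names = NA)
  invisible(path)
}
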