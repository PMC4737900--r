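#' Construct an abundance table
#'
#' An abundance table holds a gene-by-sample matrix of nonnegative
#' hybridization intensities (or other abundance measurements) together with
#' per-gene annotations, per-sample condition labels, and a detection mask.
#' Zero or missing intensities mean "not detected": they carry no abundance
#' information and are excluded from downstream correlations unless filled.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are taken as gene and sample identifiers if `gene_ids` /
#'   `sample_ids` are not given.
#' @param gene_ids character vector of unique gene (probe) identifiers.
#' @param sample_ids character vector of unique sample identifiers.
#' @param annotations optional data.frame of per-gene annotation columns
#'   (e.g. `gene_name`, `category`, `subcategory`, `organism`), one row per
#'   gene.
#' @param condition optional condition label, either a single string applied
#'   to all samples or one string per sample.
#' @param detected optional logical matrix marking detected entries; by
#'   default entries that are `NA` or 0 are undetected.
#' @param log_transformed logical; whether `values` are already on a log
#'   scale (set by [log_transform()]).
#' @return an object of class `abundance_table`.
#' @seealso [read_abundance()], [prevalence_filter()], [log_transform()]
#' @export
abundance_table <- function(values, gene_ids = rownames(values),
                            sample_ids = colnames(values),
                            annotations = NULL, condition = NULL,
                            detected = NULL, log_transformed = FALSE) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene_ids and sample_ids are required (or give a named matrix)")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) != nrow(values)")
  if (length(sample_ids) != ncol(values))
    stop("length(sample_ids) != ncol(values)")
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  storage.mode(values) <- "double"
  if (is.null(detected)) {
    detected <- !is.na(values) & values != 0
  } else {
    detected <- as.matrix(detected)
    stopifnot(identical(dim(detected), dim(values)))
  }
  bad <- detected & (!is.finite(values) | (!log_transformed & values < 0))
  if (any(bad))
    stop("detected values must be finite", if (!log_transformed) " and >= 0")
  values[!detected] <- NA_real_
  dimnames(values) <- dimnames(detected) <- list(gene_ids, sample_ids)
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
    if (nrow(annotations) != length(gene_ids))
      stop("annotations must have one row per gene")
    rownames(annotations) <- gene_ids
  }
  if (!is.null(condition)) {
    condition <- as.character(condition)
    if (length(condition) == 1L) condition <- rep(condition, length(sample_ids))
    if (length(condition) != length(sample_ids))
      stop("condition must be length 1 or one per sample")
    names(condition) <- sample_ids
  }
  structure(list(values = values, detected = detected,
                 gene_ids = gene_ids, sample_ids = sample_ids,
                 annotations = annotations, condition = condition,
                 log_transformed = log_transformed),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d genes x %d samples (%.1f%% detected%s)\n",
              length(x$gene_ids), length(x$sample_ids),
              100 * mean(x$detected),
              if (x$log_transformed) ", log scale" else ""))
  if (!is.null(x$condition))
    cat("conditions:", paste(unique(x$condition), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Read a tab-delimited gene-by-sample abundance table
#'
#' The expected layout is the common functional-microarray export: first
#' column gene (probe) id, then any declared annotation columns, then one
#' column per sample holding hybridization intensities. Blank cells and
#' zeros are treated as "not detected".
#'
#' @param path path to a UTF-8, tab-delimited text file.
#' @param annotation_cols character vector naming header columns to treat as
#'   per-gene annotations rather than samples. Defaults to the conventional
#'   annotation headers when present.
#' @param condition optional condition label for all samples in the file.
#' @return an [abundance_table()].
#' @export
read_abundance <- function(path,
                           annotation_cols = c("gene_name", "category",
                                               "subcategory", "organism"),
                           condition = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"), fileEncoding = "UTF-8")
  if (ncol(raw) < 2L) stop("need at least a gene id column and one sample")
  header <- colnames(raw)
  dup_h <- unique(header[duplicated(header)])
  if (length(dup_h))
    stop("duplicated column names in header: ", paste(dup_h, collapse = ", "))
  gene_ids <- raw[[1L]]
  ann_cols <- intersect(annotation_cols, header[-1L])
  sample_cols <- setdiff(header[-1L], ann_cols)
  if (!length(sample_cols)) stop("no sample columns found")
  vals <- as.matrix(raw[sample_cols])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  bad <- which(!is.na(vals) & is.na(num), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric intensity at row %d (gene %s), column '%s': '%s'",
                 bad[1, 1], gene_ids[bad[1, 1]],
                 sample_cols[bad[1, 2]], vals[bad[1, , drop = FALSE]]))
  ann <- if (length(ann_cols)) raw[ann_cols] else NULL
  num[is.na(num)] <- 0
  abundance_table(num, gene_ids = gene_ids, sample_ids = sample_cols,
                  annotations = ann, condition = condition)
}

#' Write an abundance table to tab-delimited text
#'
#' Inverse of [read_abundance()]: undetected entries are written as blanks.
#'
#' @param tbl an [abundance_table()].
#' @param path output file path.
#' @export
write_abundance <- function(tbl, path) {
  vals <- tbl$values
  out <- matrix(format(vals, trim = TRUE, digits = 17), nrow = nrow(vals))
  out[!tbl$detected] <- ""
  df <- data.frame(gene_id = tbl$gene_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(tbl$annotations)) df <- cbind(df, tbl$annotations)
  colnames_out <- c(colnames(df), tbl$sample_ids)
  df <- cbind(df, as.data.frame(out, stringsAsFactors = FALSE))
  colnames(df) <- colnames_out
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Filter genes by detection prevalence
#'
#' Keeps genes detected in at least `ceiling(min_fraction * n_samples)`
#' samples. Majority presence (`min_fraction = 0.5`) is the convention for
#' co-occurrence network construction from replicated designs: correlations
#' estimated from fewer shared detections are dominated by the detection
#' floor.
#'
#' @param tbl an [abundance_table()].
#' @param min_fraction required detected fraction, in (0, 1].
#' @return the filtered [abundance_table()], gene order preserved.
#' @export
prevalence_filter <- function(tbl, min_fraction = 0.5) {
  stopifnot(inherits(tbl, "abundance_table"),
            is.numeric(min_fraction), length(min_fraction) == 1L,
            min_fraction > 0, min_fraction <= 1)
  need <- ceiling(min_fraction * length(tbl$sample_ids))
  keep <- rowSums(tbl$detected) >= need
  if (!any(keep))
    stop("prevalence filter removed all genes; lower min_fraction")
  subset_genes(tbl, which(keep))
}

subset_genes <- function(tbl, idx) {
  abundance_table(ifelse(tbl$detected[idx, , drop = FALSE],
                         tbl$values[idx, , drop = FALSE], 0),
                  gene_ids = tbl$gene_ids[idx],
                  sample_ids = tbl$sample_ids,
                  annotations = if (!is.null(tbl$annotations))
                    tbl$annotations[idx, , drop = FALSE],
                  condition = tbl$condition,
                  detected = tbl$detected[idx, , drop = FALSE],
                  log_transformed = tbl$log_transformed)
}

#' Log10-transform intensities
#'
#' Intensities are log10-transformed before correlation, the standard
#' variance-stabilizing step for hybridization data. Undetected entries are
#' either filled with a small pseudo-intensity (`fill_small`: `small_constant`
#' times the smallest detected intensity in the table, then marked detected,
#' yielding a complete matrix for the eigen-analysis) or left missing
#' (`leave_missing`: downstream correlations then use pairwise-complete
#' samples).
#'
#' The default `small_constant = 0.5` places fills just below the
#' detection floor. With few samples this matters: a fill orders of
#' magnitude below the data is a high-leverage outlier that can dominate
#' a 10-sample Pearson correlation, and entries sharing a fill pattern
#' acquire spurious similarity.
#'
#' @param tbl an [abundance_table()] on the raw intensity scale.
#' @param missing_policy `"fill_small"` (default) or `"leave_missing"`.
#' @param small_constant multiplier for the fill value, default 0.5.
#' @return a log10-scale [abundance_table()].
#' @export
log_transform <- function(tbl,
                          missing_policy = c("fill_small", "leave_missing"),
                          small_constant = 0.5) {
  stopifnot(inherits(tbl, "abundance_table"))
  missing_policy <- match.arg(missing_policy)
  if (tbl$log_transformed) stop("table is already log-transformed")
  vals <- tbl$values
  det <- tbl$detected
  if (any(det & vals <= 0, na.rm = TRUE))
    stop("detected intensities must be > 0 for the log transform")
  if (missing_policy == "fill_small") {
    fill <- small_constant * min(vals[det])
    vals[!det] <- fill
    det[] <- TRUE
  }
  out <- log10(vals)
  out[!det] <- 0  # placeholder; masked by detected=FALSE
  abundance_table(out, gene_ids = tbl$gene_ids, sample_ids = tbl$sample_ids,
                  annotations = tbl$annotations, condition = tbl$condition,
                  detected = det, log_transformed = TRUE)
}

#' Construct a sample-by-trait table
#'
#' @param values numeric matrix or data.frame, samples in rows, traits in
#'   columns (e.g. oil concentration, texture, TOC, TN, pH, water, salt).
#' @param sample_ids character vector of unique sample ids.
#' @param standardized logical; whether traits are already z-scores.
#' @return an object of class `trait_table`.
#' @export
trait_table <- function(values, sample_ids = rownames(values),
                        standardized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) stop("sample_ids required")
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(values))
    stop("one row per sample required")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (is.null(colnames(values))) stop("trait columns must be named")
  rownames(values) <- sample_ids
  structure(list(values = values, sample_ids = sample_ids,
                 trait_names = colnames(values), standardized = standardized),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("trait_table: %d samples x %d traits%s\n",
              nrow(x$values), ncol(x$values),
              if (x$standardized) " (standardized)" else ""))
  invisible(x)
}

#' Read a tab-delimited sample-by-trait table
#'
#' First column sample id, remaining columns numeric traits.
#'
#' @param path path to a tab-delimited text file.
#' @return a [trait_table()].
#' @export
read_traits <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, fileEncoding = "UTF-8")
  vals <- as.matrix(raw[-1L])
  if (!is.numeric(vals)) stop("trait columns must be numeric")
  trait_table(vals, sample_ids = as.character(raw[[1L]]))
}

#' Standardize traits to z-scores
#'
#' Environmental variables come in incommensurate units, so each trait is
#' centred and scaled to unit variance over its non-missing samples before
#' any statistical use.
#'
#' @param tr a [trait_table()].
#' @return a standardized [trait_table()].
#' @export
standardize_traits <- function(tr) {
  stopifnot(inherits(tr, "trait_table"))
  vals <- tr$values
  for (j in seq_len(ncol(vals))) {
    x <- vals[, j]
    ok <- !is.na(x)
    if (sum(ok) < 2L || stats::sd(x[ok]) == 0)
      stop("trait '", tr$trait_names[j],
           "' is constant or has < 2 values; cannot standardize")
    vals[ok, j] <- (x[ok] - mean(x[ok])) / stats::sd(x[ok])
  }
  trait_table(vals, sample_ids = tr$sample_ids, standardized = TRUE)
}
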