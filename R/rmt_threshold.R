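#' Eigenvalues of the thresholded similarity matrix
#'
#' Applies a candidate threshold `t` to the similarity matrix: entries with
#' |r| >= t are kept, all others set to 0, the diagonal stays 1, and genes
#' left with no surviving off-diagonal entry are removed. Returns the
#' ascending eigenvalues of the resulting symmetric matrix — the raw
#' material of the nearest-neighbor spacing analysis.
#'
#' @param sim a [pearson_similarity()] result.
#' @param t threshold in (0, 1).
#' @param min_eigs minimum retained nodes for the threshold to be judged
#'   usable; default 100.
#' @return a list with `eigenvalues` (ascending), `n_nodes`, and `usable`
#'   (FALSE when fewer than `min_eigs` nodes survive, in which case
#'   `eigenvalues` is `NULL`).
#' @export
thresholded_spectrum <- function(sim, t, min_eigs = 100L) {
  stopifnot(inherits(sim, "similarity_matrix"), t > 0, t < 1)
  A <- sim$S
  A[A < t] <- 0
  diag(A) <- 1
  keep <- which(rowSums(A > 0) > 1L)  # diagonal plus >= 1 neighbor
  if (length(keep) < min_eigs)
    return(list(eigenvalues = NULL, n_nodes = length(keep), usable = FALSE))
  ev <- eigen(A[keep, keep], symmetric = TRUE, only.values = TRUE)$values
  list(eigenvalues = sort(ev), n_nodes = length(keep), usable = TRUE)
}

#' Unfold an eigenvalue spectrum
#'
#' Spacing statistics are comparable across systems only after "unfolding":
#' mapping eigenvalues through a smooth estimate of the cumulative spectral
#' density so that the mean local spacing is 1 everywhere. The smooth
#' estimate is a cubic smoothing spline fit to the empirical cumulative
#' count (a low-order polynomial is available as an alternative); the
#' nearest-neighbor spacings are the first differences of the mapped
#' eigenvalues, renormalized to sample mean exactly 1.
#'
#' @param eigs numeric vector of eigenvalues (any order; duplicates allowed
#'   and produce zero spacings).
#' @param method `"spline"` (default) or `"poly"`.
#' @param df effective degrees of freedom of the spline (or polynomial
#'   degree + 1). The default (`NULL`) adapts to the spectrum size as
#'   `n/10`, bounded to `[5, 40]`: enough flexibility to track the secular
#'   density (which for thresholded similarity matrices is a mixture over
#'   many components) while leaving local level fluctuations in the
#'   spacings.
#' @return numeric vector of unfolded spacings, mean 1.
#' @export
unfold_spectrum <- function(eigs, method = c("spline", "poly"), df = NULL) {
  method <- match.arg(method)
  eigs <- sort(as.numeric(eigs))
  n <- length(eigs)
  if (n < 3L) stop("need at least 3 eigenvalues to unfold")
  if (diff(range(eigs)) == 0) stop("degenerate spectrum: all eigenvalues equal")
  cum <- seq_len(n)
  if (is.null(df)) df <- max(5, min(40, n %/% 10))
  df <- min(df, max(2, length(unique(eigs)) - 1))
  if (method == "spline") {
    fit <- stats::smooth.spline(eigs, cum, df = df)
    unfolded <- stats::predict(fit, eigs)$y
  } else {
    fit <- stats::lm(cum ~ stats::poly(eigs, degree = max(1, df - 1)))
    unfolded <- stats::fitted(fit)
  }
  s <- diff(unfolded)
  s[s < 0] <- 0  # non-monotone wiggles of the smooth map are ties
  m <- mean(s)
  if (m <= 0) stop("degenerate spectrum: no positive spacings")
  s / m
}

#' Chi-square goodness of fit of spacings to Poisson or GOE statistics
#'
#' Bins the unfolded spacings in fixed-width bins on `[0, s_max]` plus an
#' open tail bin, and compares the observed counts to the model density:
#' Poisson statistics `P(s) = exp(-s)` (system-specific, non-random
#' structure) or the Gaussian-orthogonal-ensemble Wigner surmise
#' `P(s) = (pi s / 2) exp(-pi s^2 / 4)` (random-matrix behaviour). Adjacent
#' bins are merged from the right until every expected count reaches
#' `min_expected`; degrees of freedom are the used bins minus one.
#'
#' @param spacings unfolded spacings from [unfold_spectrum()].
#' @param model `"poisson"` or `"goe"`.
#' @param bin_width histogram bin width, default 0.1.
#' @param s_max upper edge of the fixed-width bins, default 3.
#' @param min_expected minimum expected count per (merged) bin, default 1.
#' @return a list with `statistic`, `df`, `p_value`, `n`, `model`, and the
#'   merged-bin table (`breaks`, `observed`, `expected`).
#' @export
nnsd_gof <- function(spacings, model = c("poisson", "goe"),
                     bin_width = 0.1, s_max = 3, min_expected = 1) {
  model <- match.arg(model)
  s <- as.numeric(spacings)
  n <- length(s)
  if (n < 30L) stop("need at least 30 spacings for the goodness-of-fit test")
  breaks <- c(seq(0, s_max, by = bin_width), Inf)
  obs <- as.vector(table(cut(s, breaks, right = FALSE,
                             include.lowest = TRUE)))
  cdf <- switch(model,
                poisson = function(x) 1 - exp(-pmin(x, 700)),
                goe = function(x) 1 - exp(-pi * x^2 / 4))
  p_bin <- diff(cdf(breaks))
  exp_ct <- n * p_bin
  # merge right-to-left until every expected count is adequate
  o <- obs; e <- exp_ct; b <- breaks
  i <- length(o)
  while (i >= 1L) {
    if (e[i] < min_expected && length(o) > 1L) {
      j <- if (i == 1L) 2L else i - 1L
      e[j] <- e[j] + e[i]; o[j] <- o[j] + o[i]
      o <- o[-i]; e <- e[-i]; b <- b[-i]
      i <- min(i, length(o))
    } else i <- i - 1L
  }
  stat <- sum((o - e)^2 / e)
  df <- length(o) - 1L
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p, n = n, model = model,
       breaks = b, observed = o, expected = e)
}

#' Select the similarity threshold by the GOE-to-Poisson transition
#'
#' Scans candidate thresholds in ascending order. At each threshold the
#' similarity matrix is cut, the distinct eigenvalues of the thresholded
#' matrix are unfolded, and the nearest-neighbor spacing distribution is
#' tested against Poisson statistics. Below the transition the spectrum
#' follows GOE (random) statistics and Poisson is rejected; the selected
#' threshold `s_t` is the smallest scanned value at which the Poisson fit
#' is accepted (p > `alpha`) and stays accepted for `persistence`
#' consecutive usable thresholds — the transition point of the spacing
#' distribution from GOE to Poisson. (Far past the transition the network
#' shatters into micro-components whose structured multiplicities leave
#' the Poisson regime again; persistence over a window, rather than over
#' the entire remaining scan, keeps the end-of-scan artifact from masking
#' a clear transition.)
#'
#' Exactly degenerate eigenvalues (equal to within `degeneracy_tol`) are
#' collapsed before unfolding: multiplicities arise combinatorially from
#' isomorphic fragments of the thresholded matrix and would flood the
#' zero-spacing bin with ties that carry no information about level
#' repulsion.
#'
#' @param sim a [pearson_similarity()] result (run
#'   [deduplicate_profiles()] first if exact duplicate profiles may exist).
#' @param scan_min,scan_max,step scan grid over (0, 1); defaults 0.30, 0.99,
#'   0.01.
#' @param alpha acceptance level for the Poisson fit, default 0.01: with
#'   several hundred pooled spacings the chi-square test is sensitive
#'   enough that a minority substructure deviating mildly from Poisson
#'   would otherwise mask an unambiguous transition.
#' @param min_eigs minimum distinct eigenvalues for a threshold to be
#'   judged, default 100.
#' @param persistence consecutive usable thresholds over which the Poisson
#'   fit must hold, default 2.
#' @param degeneracy_tol rounding tolerance for collapsing degenerate
#'   eigenvalues, default 1e-8.
#' @param unfold_df,unfold_method passed to [unfold_spectrum()].
#' @return an object of class `threshold_scan`: `s_t` plus a `trace`
#'   data.frame (threshold, n_nodes, n_eigs, chi2_poisson, chi2_goe,
#'   p_poisson, p_goe, usable, accepted).
#' @export
select_threshold <- function(sim, scan_min = 0.30, scan_max = 0.99,
                             step = 0.01, alpha = 0.01, min_eigs = 100L,
                             persistence = 2L, degeneracy_tol = 1e-8,
                             unfold_df = NULL, unfold_method = "spline") {
  stopifnot(scan_min > 0, scan_max < 1, scan_min < scan_max, step > 0,
            persistence >= 1L)
  ts <- seq(scan_min, scan_max, by = step)
  trace <- data.frame(threshold = ts, n_nodes = NA_integer_,
                      n_eigs = NA_integer_,
                      chi2_poisson = NA_real_, chi2_goe = NA_real_,
                      p_poisson = NA_real_, p_goe = NA_real_,
                      usable = FALSE, accepted = FALSE)
  prev_nodes <- Inf
  for (k in seq_along(ts)) {
    sp <- thresholded_spectrum(sim, ts[k], min_eigs = min_eigs)
    trace$n_nodes[k] <- sp$n_nodes
    if (sp$n_nodes > prev_nodes)
      stop("internal error: retained-node count increased with threshold")
    prev_nodes <- sp$n_nodes
    if (!sp$usable) next
    ev <- sp$eigenvalues
    ev <- ev[c(TRUE, diff(ev) > degeneracy_tol)]
    trace$n_eigs[k] <- length(ev)
    if (length(ev) < min_eigs) next
    s <- tryCatch(unfold_spectrum(ev, method = unfold_method,
                                  df = unfold_df),
                  error = function(e) NULL)
    if (is.null(s) || length(s) < 30L) next
    gp <- nnsd_gof(s, "poisson")
    gg <- nnsd_gof(s, "goe")
    trace$usable[k] <- TRUE
    trace$chi2_poisson[k] <- gp$statistic
    trace$chi2_goe[k] <- gg$statistic
    trace$p_poisson[k] <- gp$p_value
    trace$p_goe[k] <- gg$p_value
    trace$accepted[k] <- gp$p_value > alpha
  }
  usable <- which(trace$usable)
  s_t <- NA_real_
  for (k in usable) {
    window <- usable[usable >= k][seq_len(min(persistence,
                                              sum(usable >= k)))]
    if (length(window) && all(trace$accepted[window])) {
      s_t <- ts[k]
      break
    }
  }
  if (is.na(s_t))
    stop("no GOE-to-Poisson transition found in [", scan_min, ", ", scan_max,
         "]; widen the scan range or provide more genes")
  structure(list(s_t = s_t, trace = trace, alpha = alpha,
                 min_eigs = min_eigs, persistence = persistence),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("threshold_scan: s_t = %.2f (%d of %d thresholds usable)\n",
              x$s_t, sum(x$trace$usable), nrow(x$trace)))
  invisible(x)
}

#' Write the threshold scan trace to tab-delimited text
#'
#' @param scan a [select_threshold()] result.
#' @param path output path.
#' @export
write_scan_trace <- function(scan, path) {
  utils::write.table(scan$trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
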