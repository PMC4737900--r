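#' Configuration for the synthetic abundance generator
#'
#' The generator emulates a replicated functional-microarray design: a few
#' thousand gene probes measured over ~10 replicate samples per condition,
#' with groups of genes co-varying in blocks (shared latent factors), a
#' mixture of positive and negative associations, a detection floor that
#' censors the weakest intensities, and environmental traits driven by the
#' same latent factors as chosen gene blocks.
#'
#' Defaults describe the study conditions the package is validated under:
#' 1000 genes x 10 samples, 5 planted blocks (one of 200 genes, four of
#' 100) at within-block correlation 0.95 (the regime implied by
#' similarity thresholds near 0.95), 30% of loadings negative, a
#' detection floor censoring the lowest 5% of intensities, and traits
#' 1-3 driven by blocks 1-3 at correlation 0.8. The genes outside the
#' blocks and the hub cluster form a diffuse background web (random unit
#' loadings on a few shared factors) whose pairwise correlations spread
#' continuously below `bg_cor` — the community-wide covariation that
#' keeps the bulk spectrum in the random (GOE) regime until high
#' thresholds, as in real arrays. The planted hub is the center of its
#' own star-like cluster: a private profile onto which `hub_satellites`
#' genes load so that satellite-satellite correlations equal
#' `hub_satellite_cor` while hub-satellite correlations equal its square
#' root. The hub's cluster is larger than the largest block and the hub
#' reaches it at a systematically higher correlation than any
#' peer-to-peer pair, which is what a connectivity keystone looks like
#' in these networks.
#'
#' @param n_genes total number of genes.
#' @param n_samples number of samples.
#' @param n_blocks number of correlated blocks.
#' @param block_sizes integer vector of block sizes; must sum to at most
#'   `n_genes` (remaining genes host the hub cluster and the background
#'   web).
#' @param within_cor target within-block correlation magnitude in (0, 1):
#'   the squared latent-factor loading; scalar or one value per block.
#' @param neg_fraction fraction of genes given negative loadings.
#' @param detection_quantile fraction of the lowest intensities masked as
#'   undetected.
#' @param bg_cor squared loading of each unstructured background gene on
#'   its random direction in the background-factor space; controls how
#'   strong the diffuse community-wide covariation is (pairwise background
#'   correlations spread over `[0, bg_cor]`).
#' @param bg_factors dimension of the shared background-factor space.
#' @param hub_satellites number of unstructured-pool genes re-assigned as
#'   satellites of the hub (its planted links); 0 disables the hub.
#' @param hub_satellite_cor target satellite-satellite correlation; each
#'   satellite loads on the hub's profile with the square root of this as
#'   loading.
#' @param trait_blocks integer vector saying which block drives each trait.
#' @param trait_effect correlation of each driven trait with its block
#'   factor.
#' @param n_noise_traits additional traits that are pure noise.
#' @param intensity_log_mean,intensity_log_sd location/scale of the
#'   log10-intensity values (arbitrary hybridization units).
#' @param seed integer seed; the configuration plus seed fully determines
#'   the output.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 1000L, n_samples = 10L,
                             n_blocks = 5L,
                             block_sizes = c(200L, rep(100L, n_blocks - 1L)),
                             within_cor = 0.95,
                             neg_fraction = 0.3,
                             detection_quantile = 0.05,
                             bg_cor = 0.8, bg_factors = 3L,
                             hub_satellites = 250L, hub_satellite_cor = 0.92,
                             trait_blocks = seq_len(min(3L, n_blocks)),
                             trait_effect = 0.8,
                             n_noise_traits = 2L,
                             intensity_log_mean = 3, intensity_log_sd = 0.5,
                             seed = 1L) {
  if (length(block_sizes) != n_blocks)
    stop("block_sizes must have n_blocks entries")
  if (sum(block_sizes) > n_genes)
    stop("block sizes exceed n_genes")
  n_free <- n_genes - sum(block_sizes)
  if (hub_satellites > 0L && hub_satellites + 1L > n_free)
    stop("hub plus satellites exceed the unstructured gene pool (",
         n_free, ")")
  if (!length(within_cor) %in% c(1L, n_blocks))
    stop("within_cor must be scalar or one value per block")
  within_cor <- rep_len(within_cor, n_blocks)
  stopifnot(all(within_cor > 0), all(within_cor <= 1),
            neg_fraction >= 0, neg_fraction <= 1,
            detection_quantile >= 0, detection_quantile < 1,
            all(trait_blocks >= 1), all(trait_blocks <= n_blocks))
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 n_blocks = as.integer(n_blocks),
                 block_sizes = as.integer(block_sizes),
                 within_cor = within_cor, neg_fraction = neg_fraction,
                 detection_quantile = detection_quantile,
                 bg_cor = bg_cor, bg_factors = as.integer(bg_factors),
                 hub_satellites = as.integer(hub_satellites),
                 hub_satellite_cor = hub_satellite_cor,
                 trait_blocks = as.integer(trait_blocks),
                 trait_effect = trait_effect,
                 n_noise_traits = as.integer(n_noise_traits),
                 intensity_log_mean = intensity_log_mean,
                 intensity_log_sd = intensity_log_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic abundance table, trait table, and ground truth
#'
#' Per block, one standard-normal latent factor value per sample; each
#' gene's log-intensity is `loading x factor + noise` with loading sign
#' drawn from the negative fraction, scaled and shifted to hybridization
#' like positive intensities via `10^(mean + sd * z)`. The hub cluster
#' (a star of satellites on the hub's private profile) and the diffuse
#' background web occupy the genes outside the blocks; see
#' [synthetic_config()]. The lowest `detection_quantile` fraction of
#' intensities is masked undetected (a detection floor, not random
#' dropout). Traits are linear in their driving block factor plus noise.
#'
#' @param cfg a [synthetic_config()].
#' @return a list with `abundance` (an [abundance_table()]), `traits` (a
#'   [trait_table()]), and `truth` (block label per gene, 0 = outside the
#'   blocks; hub gene id; satellite ids; trait driver map; the latent
#'   factor matrix; loadings).
#' @export
generate_synthetic <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    n_g <- cfg$n_genes; n_s <- cfg$n_samples
    gene_ids <- sprintf("g%04d", seq_len(n_g))
    sample_ids <- sprintf("s%02d", seq_len(n_s))
    block <- rep(0L, n_g)
    block[seq_len(sum(cfg$block_sizes))] <-
      rep(seq_len(cfg$n_blocks), cfg$block_sizes)
    factors <- matrix(stats::rnorm(cfg$n_blocks * n_s), cfg$n_blocks, n_s)
    a <- sqrt(cfg$within_cor)  # per-block loadings
    sgn <- ifelse(stats::runif(n_g) < cfg$neg_fraction, -1, 1)
    z <- matrix(stats::rnorm(n_g * n_s), n_g, n_s)  # idiosyncratic noise
    lat <- matrix(0, n_g, n_s)
    loading <- numeric(n_g)
    for (i in seq_len(n_g)) {
      if (block[i] > 0L) {
        ab <- a[block[i]]
        loading[i] <- sgn[i] * ab
        lat[i, ] <- loading[i] * factors[block[i], ] +
          sqrt(1 - ab^2) * z[i, ]
      } else {
        lat[i, ] <- z[i, ]
      }
    }
    hub_id <- NA_character_
    satellite_ids <- character()
    if (cfg$hub_satellites > 0L) {
      free <- which(block == 0L)
      hub <- free[1L]
      hub_id <- gene_ids[hub]
      sat <- free[1L + seq_len(cfg$hub_satellites)]
      satellite_ids <- gene_ids[sat]
      as <- sqrt(cfg$hub_satellite_cor)
      hub_std <- (lat[hub, ] - mean(lat[hub, ])) / stats::sd(lat[hub, ])
      lat[hub, ] <- hub_std  # centered scale keeps the hub clear of the
                             # detection floor that its satellites avoid
      for (i in sat) {
        loading[i] <- as
        lat[i, ] <- as * hub_std + sqrt(1 - as^2) * z[i, ]
      }
    }
    # remaining unstructured genes: diffuse background covariation via
    # random directions in a small shared factor space, so pairwise
    # background correlations form a continuum instead of a point mass
    bg <- setdiff(which(block == 0L),
                  match(c(hub_id, satellite_ids), gene_ids))
    if (length(bg) && cfg$bg_cor > 0) {
      f_bg <- matrix(stats::rnorm(cfg$bg_factors * n_s), cfg$bg_factors,
                     n_s)
      ab <- sqrt(cfg$bg_cor)
      for (i in bg) {
        w <- stats::rnorm(cfg$bg_factors)
        w <- w / sqrt(sum(w^2))
        lat[i, ] <- ab * drop(w %*% f_bg) + sqrt(1 - cfg$bg_cor) * z[i, ]
      }
    }
    intensities <- 10^(cfg$intensity_log_mean + cfg$intensity_log_sd * lat)
    detected <- matrix(TRUE, n_g, n_s)
    if (cfg$detection_quantile > 0) {
      floor_val <- stats::quantile(intensities, cfg$detection_quantile)
      detected <- intensities > floor_val
    }
    vals <- ifelse(detected, intensities, 0)
    tbl <- abundance_table(vals, gene_ids = gene_ids,
                           sample_ids = sample_ids,
                           annotations = data.frame(
                             gene_name = paste0("fam", pmax(block, 0)),
                             category = ifelse(block > 0,
                                               paste0("block", block),
                                               "noise"),
                             stringsAsFactors = FALSE),
                           condition = "synthetic")
    n_traits <- length(cfg$trait_blocks) + cfg$n_noise_traits
    tv <- matrix(stats::rnorm(n_s * n_traits), n_s, n_traits)
    for (j in seq_along(cfg$trait_blocks)) {
      b <- cfg$trait_blocks[j]
      tv[, j] <- cfg$trait_effect * factors[b, ] +
        sqrt(1 - cfg$trait_effect^2) * tv[, j]
    }
    colnames(tv) <- c(paste0("trait_block", cfg$trait_blocks),
                      if (cfg$n_noise_traits > 0)
                        paste0("trait_noise", seq_len(cfg$n_noise_traits)))
    traits <- trait_table(tv, sample_ids = sample_ids)
    truth <- list(block = stats::setNames(block, gene_ids), hub = hub_id,
                  satellites = satellite_ids,
                  trait_drivers = stats::setNames(cfg$trait_blocks,
                                                  colnames(tv)[seq_along(cfg$trait_blocks)]),
                  factors = factors, loading = stats::setNames(loading,
                                                               gene_ids))
    list(abundance = tbl, traits = traits, truth = truth)
  })
}

#' Eigenvalues of a sampled GOE matrix
#'
#' Draws a symmetric matrix with independent Gaussian entries (off-diagonal
#' variance half the diagonal variance) and returns its eigenvalues — the
#' reference random-matrix spectrum whose nearest-neighbor spacings follow
#' the Wigner surmise.
#'
#' @param n matrix dimension, at least 50.
#' @param seed integer seed.
#' @return ascending numeric vector of `n` eigenvalues.
#' @export
generate_goe_spectrum <- function(n, seed = 1L) {
  stopifnot(n >= 50L)
  with_seed(seed, {
    m <- matrix(stats::rnorm(n * n, sd = sqrt(0.5)), n, n)
    s <- m + t(m)           # off-diag var 1, diag var 2
    sort(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
  })
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b vectors of cluster labels over the same items.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_idx - expected)
}
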