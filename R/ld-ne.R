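#' Burrows composite squared correlation between two loci
#'
#' Composite linkage-disequilibrium measure for unphased diploid data: the
#' squared Pearson correlation of genotype dosages (the Burrows composite
#' Delta normalized by the allele-frequency variances). For loci sampled
#' independently in `S` diploids its expectation is approximately `1/S`,
#' which is the sampling term the LD-Ne estimator subtracts.
#'
#' @param g_a,g_b integer genotype vectors (0/1/2, `NA` missing) over the
#'   same samples.
#' @return squared composite correlation, or `NA` if either locus is
#'   monomorphic among the jointly genotyped samples.
#' @export
composite_r2 <- function(g_a, g_b) {
  ok <- !is.na(g_a) & !is.na(g_b)
  if (sum(ok) < 2) return(NA_real_)
  a <- g_a[ok]; b <- g_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  cor(a, b)^2
}

#' LD-based effective population size from mean adjusted r-squared
#'
#' Random-mating drift relation: `Ne = 1 / (3 * (r2 - 1/S))` where `r2` is
#' the mean composite r-squared over (unlinked) locus pairs and `1/S` the
#' sample-size expectation. A non-positive denominator (no drift signal at
#' this sample size) yields `Inf`, the estimator's conventional report,
#' not an error. `correction = "waples"` uses the empirical small-sample
#' expectation `E[r2] = 1/S + 3.19/S^2` instead of `1/S`.
#'
#' @param mean_r2 mean composite r-squared across locus pairs.
#' @param S diploid sample size (>= 2).
#' @param correction `"none"` (default; subtracts `1/S`), `"pearson"`
#'   (subtracts `1/(S-1)`, the finite-sample expectation of a squared
#'   product-moment correlation between independent loci — empirically
#'   near-unbiased for the dosage r2 used here), or `"waples"`.
#' @return effective population size (positive real or `Inf`).
#' @export
ld_ne <- function(mean_r2, S, correction = c("none", "pearson",
                                             "waples")) {
  correction <- match.arg(correction)
  if (S < 2) stop("S must be at least 2")
  expected <- switch(correction, none = 1 / S,
                     pearson = 1 / (S - 1),
                     waples = 1 / S + 3.19 / S^2)
  denom <- 3 * (mean_r2 - expected)
  ifelse(denom <= 0, Inf, 1 / denom)
}

## Mean composite r2 over locus pairs on different chromosomes (default)
## using the full dosage correlation matrix; pairs beyond `max_pairs` are
## subsampled deterministically under the caller's RNG stream.
mean_r2_unlinked <- function(gm, maf_cutoff = 0.05, max_pairs = 50000,
                             cross_chrom_only = TRUE) {
  g <- gm$geno
  n <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * pmax(n, 1))
  maf <- pmin(p, 1 - p)
  keep <- n >= 2 & maf >= maf_cutoff & maf > 0
  if (sum(keep) < 2) return(c(mean_r2 = NA_real_, n_pairs = 0))
  g <- g[, keep, drop = FALSE]
  chrom <- gm$sites$chrom[keep]
  cc <- if (anyNA(g)) suppressWarnings(cor(g, use = "pairwise.complete.obs"))
        else suppressWarnings(cor(g))
  r2 <- cc^2
  use <- upper.tri(r2)
  if (cross_chrom_only)
    use <- use & outer(chrom, chrom, `!=`)
  vals <- r2[use]
  vals <- vals[!is.na(vals)]
  if (length(vals) > max_pairs)  # deterministic, evenly spaced thinning
    vals <- vals[round(seq(1, length(vals), length.out = max_pairs))]
  c(mean_r2 = mean(vals), n_pairs = length(vals))
}

#' Resampled LD-Ne estimates for one population and period
#'
#' Draws `n` individuals without replacement `reps` times from the given
#' population/period, LD-thins each draw, filters on minor allele
#' frequency, averages composite r-squared over locus pairs on different
#' chromosomes, and converts to Ne. Deterministic under `seed` (each
#' replicate consumes a derived seed, so replicates are independently
#' reproducible).
#'
#' @param gm a [genotype_matrix].
#' @param meta data.frame with `sample_id`, `population`, `period`.
#' @param population,period labels selecting the sample set.
#' @param n diploid sample size per replicate.
#' @param reps number of replicates (default 100).
#' @param seed integer seed (optional).
#' @param maf_cutoff minor-allele-frequency cutoff (default 0.05).
#' @param thin_bp LD-thinning stride passed to [thin_one_per_window()];
#'   `NULL` disables thinning.
#' @param max_pairs cap on locus pairs per replicate (default 50000).
#' @param correction passed to [ld_ne()].
#' @return data.frame: `population`, `period`, `replicate`, `S`,
#'   `n_pairs`, `mean_r2`, `ne`, `maf_cutoff`.
#' @export
resample_ne <- function(gm, meta, population, period, n, reps = 100,
                        seed = NULL, maf_cutoff = 0.05, thin_bp = 10000,
                        max_pairs = 50000, correction = "pearson") {
  ids <- meta$sample_id[meta$population == population &
                          meta$period == period]
  ids <- intersect(ids, gm$sample_ids)
  if (length(ids) < n)
    stop("period has ", length(ids), " samples, fewer than n = ", n)
  rows <- lapply(seq_len(reps), function(r) {
    rs <- if (is.null(seed)) NULL else
      derive_seed(seed, paste0(population, period, r))
    with_seed(rs, {
      draw <- sample(ids, n)
      sub <- subset_gm(gm, samples = draw)
      if (!is.null(thin_bp)) sub <- thin_one_per_window(sub, thin_bp)
      mr <- mean_r2_unlinked(sub, maf_cutoff = maf_cutoff,
                             max_pairs = max_pairs)
      data.frame(population = population, period = period, replicate = r,
                 S = n, n_pairs = as.integer(mr["n_pairs"]),
                 mean_r2 = unname(mr["mean_r2"]),
                 ne = ld_ne(unname(mr["mean_r2"]), n,
                            correction = correction),
                 maf_cutoff = maf_cutoff, stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}
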