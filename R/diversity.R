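#' Windowed nucleotide diversity (pi)
#'
#' Per-site pairwise diversity from diploid genotype codes: with `n` the
#' number of non-missing alleles at the site and `a` the alternate-allele
#' count, `site_pi = 2*a*(n-a) / (n*(n-1))`, i.e. the proportion of
#' differing allele pairs among the `n` sampled chromosomes. Sites are
#' summed in non-overlapping windows and divided by the window width so the
#' result is a per-bp diversity. Invariant (and missing-heavy, `n < 2`)
#' sites contribute zero and are counted in `n_flagged`.
#'
#' The final window of a chromosome is reported with its true span (from
#' the contig length when known, otherwise the last site position) and
#' flagged `partial`; its `pi` still uses the nominal width's worth of
#' sequence actually spanned.
#'
#' @param gm a [genotype_matrix].
#' @param window_bp window width in bp (default 50 kb).
#' @return data.frame with columns `chrom`, `start`, `end` (half-open bp),
#'   `pi`, `n_variant_sites`, `n_flagged`, `partial`.
#' @export
windowed_pi <- function(gm, window_bp = 50000) {
  stopifnot(window_bp > 0)
  if (nrow(gm$sites) == 0) stop("empty genotype matrix")
  g <- gm$geno
  n <- 2L * colSums(!is.na(g))
  a <- colSums(g, na.rm = TRUE)
  ok <- n >= 2L
  site_pi <- numeric(length(n))
  site_pi[ok] <- 2 * a[ok] * (n[ok] - a[ok]) / (n[ok] * (n[ok] - 1))
  win <- (gm$sites$pos - 1L) %/% as.integer(window_bp)
  key <- paste(gm$sites$chrom, win, sep = "\r")
  agg_pi <- rowsum(site_pi, key, reorder = FALSE)
  agg_var <- rowsum(as.numeric(site_pi > 0), key, reorder = FALSE)
  agg_flag <- rowsum(as.numeric(!ok), key, reorder = FALSE)
  parts <- strsplit(rownames(agg_pi), "\r", fixed = TRUE)
  chrom <- vapply(parts, `[`, "", 1)
  w <- as.integer(vapply(parts, `[`, "", 2))
  start <- w * as.integer(window_bp)
  end_nominal <- start + as.integer(window_bp)
  chrom_span <- if (!is.null(gm$contigs)) gm$contigs[chrom] else
    tapply(gm$sites$pos, gm$sites$chrom, max)[chrom]
  end <- pmin(end_nominal, as.numeric(chrom_span))
  end[is.na(end)] <- end_nominal[is.na(end)]
  out <- data.frame(chrom = chrom, start = start, end = end,
                    pi = as.numeric(agg_pi) / window_bp,
                    n_variant_sites = as.integer(agg_var),
                    n_flagged = as.integer(agg_flag),
                    partial = end < end_nominal,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Mean per-sample nucleotide diversity of a sample subset
#'
#' Convenience wrapper: genome-wide pi for the given samples, i.e. the
#' window-width-weighted mean of [windowed_pi()] over all windows. Used by
#' the temporal resampling layer, where pi is recomputed per resampled
#' individual set.
#'
#' @param gm a [genotype_matrix].
#' @param samples sample ids to include.
#' @param window_bp window width passed to [windowed_pi()].
#' @return single numeric pi value.
#' @export
pi_of_samples <- function(gm, samples, window_bp = 50000) {
  ws <- windowed_pi(subset_gm(gm, samples = samples), window_bp = window_bp)
  sum(ws$pi * window_bp) / sum(pmax(ws$end - ws$start, 1))
}
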