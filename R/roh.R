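#' Detect runs of homozygosity for one sample
#'
#' Sliding-window ROH scan in the PLINK style. Windows of `window_snp`
#' consecutive SNPs are scored homozygous-compatible when they contain at
#' most `window_het` heterozygous and at most `window_missing` missing
#' calls. Each SNP's hit fraction is the proportion of
#' homozygous-compatible windows among the windows covering it; SNPs with
#' hit fraction at least `window_threshold` become candidates. Maximal
#' candidate runs are split at inter-SNP gaps larger than `max_gap_bp`,
#' trimmed to their outermost homozygous SNPs, and kept when they span at
#' least `min_len_bp` and contain at least `min_snps` SNPs.
#'
#' Only `window_snp = 20` and `window_het = 1` are fixed by the analysis
#' design; the remaining thresholds default to PLINK 1.9 conventions and
#' should be scaled for small test genomes.
#'
#' @param gm a [genotype_matrix].
#' @param sample sample id.
#' @param window_snp SNPs per sliding window (default 20).
#' @param window_het maximum heterozygous calls per window (default 1).
#' @param window_missing maximum missing calls per window (default 5).
#' @param window_threshold minimum hit fraction for a SNP (default 0.05).
#' @param min_len_bp minimum segment span in bp (default 100 kb, the
#'   reporting threshold for F_ROH).
#' @param min_snps minimum SNPs per segment (default 100).
#' @param max_gap_bp maximum gap between consecutive SNPs in a segment
#'   (default 1 Mb).
#' @return data.frame of segments: `sample_id`, `chrom`, `start`, `end`
#'   (bp positions of the outermost SNPs), `n_snps`, `length`,
#'   `length_class` in `{"100kb-1Mb", ">1Mb", "sub-100kb"}`. Segments below
#'   `min_len_bp` are not returned.
#' @export
detect_roh <- function(gm, sample, window_snp = 20, window_het = 1,
                       window_missing = 5, window_threshold = 0.05,
                       min_len_bp = 1e5, min_snps = 100,
                       max_gap_bp = 1e6) {
  stopifnot(window_snp > 0, min_len_bp > 0, min_snps > 0)
  idx <- match(sample, gm$sample_ids)
  if (is.na(idx)) stop("unknown sample id: ", sample)
  g_all <- gm$geno[idx, ]
  if (all(is.na(g_all))) {
    warning("sample ", sample, " has no genotype calls; no ROH reported")
    return(empty_roh())
  }
  out <- lapply(unique(gm$sites$chrom), function(ch) {
    on_ch <- gm$sites$chrom == ch
    roh_one_chrom(g_all[on_ch], gm$sites$pos[on_ch], ch, sample,
                  window_snp, window_het, window_missing, window_threshold,
                  min_len_bp, min_snps, max_gap_bp)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) empty_roh() else out
}

empty_roh <- function() {
  data.frame(sample_id = character(), chrom = character(),
             start = integer(), end = integer(), n_snps = integer(),
             length = integer(), length_class = character(),
             stringsAsFactors = FALSE)
}

roh_one_chrom <- function(g, pos, chrom, sample, ws, max_het, max_miss,
                          thr, min_len, min_snps, max_gap) {
  n <- length(g)
  if (n < min_snps) return(NULL)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  if (n >= ws) {
    ch <- c(0, cumsum(het)); cm <- c(0, cumsum(mis))
    i <- seq_len(n - ws + 1L)
    win_ok <- (ch[i + ws] - ch[i]) <= max_het &
      (cm[i + ws] - cm[i]) <= max_miss
    ## hit fraction per SNP: windows i..i+ws-1 cover SNP j when
    ## j-ws+1 <= i <= j; bounded at the chromosome ends
    cok <- c(0, cumsum(win_ok))
    j <- seq_len(n)
    lo <- pmax(j - ws + 1L, 1L); hi <- pmin(j, n - ws + 1L)
    n_cover <- hi - lo + 1L
    n_hit <- cok[hi + 1L] - cok[lo]
    cand <- n_cover > 0L & (n_hit / pmax(n_cover, 1L)) >= thr
  } else cand <- rep(FALSE, n)
  if (!any(cand)) return(NULL)
  ## split candidate runs at large physical gaps
  r <- rle(cand)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  segs <- list()
  for (k in which(r$values)) {
    a <- starts[k]; b <- ends[k]
    cut <- which(diff(pos[a:b]) > max_gap)
    bounds <- c(a - 1L, a - 1L + cut, b)
    for (p in seq_len(length(bounds) - 1L))
      segs[[length(segs) + 1L]] <- c(bounds[p] + 1L, bounds[p + 1L])
  }
  rows <- lapply(segs, function(ab) {
    a <- ab[1]; b <- ab[2]
    ## trim to outermost homozygous SNPs
    hom <- which(!mis[a:b] & g[a:b] != 1L)
    if (!length(hom)) return(NULL)
    a2 <- a + hom[1] - 1L; b2 <- a + hom[length(hom)] - 1L
    len <- pos[b2] - pos[a2]
    nsnp <- b2 - a2 + 1L
    if (len < min_len || nsnp < min_snps) return(NULL)
    data.frame(sample_id = sample, chrom = chrom,
               start = pos[a2], end = pos[b2], n_snps = nsnp,
               length = len, length_class = roh_class(len),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) NULL else do.call(rbind, rows)
}

roh_class <- function(len) {
  ifelse(len > 1e6, ">1Mb", ifelse(len > 1e5, "100kb-1Mb", "sub-100kb"))
}

#' Genomic inbreeding coefficient from ROH segments
#'
#' F_ROH(>100kb) is the summed length of ROH segments longer than 100 kb
#' divided by the genome length; it decomposes exactly into the 100 kb-1 Mb
#' and >1 Mb classes. Segments of 100 kb or shorter are excluded from all
#' reported coefficients.
#'
#' @param segments data.frame as returned by [detect_roh()] (one sample).
#' @param genome_length_bp total genome length in bp.
#' @return data.frame (one row) with `sample_id`, `froh_gt100kb`,
#'   `froh_100kb_1mb`, `froh_gt1mb`.
#' @export
compute_froh <- function(segments, genome_length_bp) {
  stopifnot(genome_length_bp > 0)
  if (nrow(segments) && any(segments$length <= 0))
    stop("invariant violation: non-positive ROH segment length")
  sample_id <- if (nrow(segments)) segments$sample_id[1] else NA_character_
  mid <- segments$length > 1e5 & segments$length <= 1e6
  big <- segments$length > 1e6
  f_mid <- sum(segments$length[mid]) / genome_length_bp
  f_big <- sum(segments$length[big]) / genome_length_bp
  data.frame(sample_id = sample_id,
             froh_gt100kb = f_mid + f_big,
             froh_100kb_1mb = f_mid, froh_gt1mb = f_big,
             stringsAsFactors = FALSE)
}

#' F_ROH for every sample of a genotype matrix
#'
#' @param gm a [genotype_matrix].
#' @param genome_length_bp genome length; defaults to the sum of contig
#'   lengths from the VCF header.
#' @param ... ROH detection parameters passed to [detect_roh()].
#' @return data.frame, one row per sample.
#' @export
froh_all_samples <- function(gm, genome_length_bp = sum(gm$contigs), ...) {
  out <- lapply(gm$sample_ids, function(s) {
    f <- compute_froh(detect_roh(gm, s, ...), genome_length_bp)
    f$sample_id <- s
    f
  })
  do.call(rbind, out)
}
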