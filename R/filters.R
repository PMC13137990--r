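#' Default hard-filter rules for SNP site quality
#'
#' The GATK-style fail conditions used to hard-filter raw SNPs: a site
#' failing ANY rule is removed. Each rule is a (annotation, comparator,
#' threshold) triple where the comparator expresses the FAIL condition,
#' e.g. `QD < 2` removes sites with QD below 2. Rules for caller-specific
#' tags (SB, MQ0, MQ0F) are inactive whenever the tag is absent, as are all
#' rules on records lacking the annotation.
#'
#' @return data.frame with columns `annotation`, `comparator`, `threshold`.
#' @export
default_hard_filters <- function() {
  data.frame(
    annotation = c("QUAL", "QD", "MQ", "FS", "SOR", "MQRankSum",
                   "ReadPosRankSum", "DP", "SB", "MQ0", "MQ0F"),
    comparator = c("<", "<", "<", ">", ">", "<", "<", "<", ">=", ">=", ">="),
    threshold  = c(30, 2, 40, 60, 3, -12.5, -8, 3, -1, 4, 0.1),
    stringsAsFactors = FALSE)
}

#' Apply hard site filters to a genotype matrix
#'
#' Removes every site for which at least one fail condition holds. A rule
#' whose annotation is missing (column absent, or `NA` at that site) is
#' skipped for that record; skips are counted. Comparisons are strict or
#' non-strict exactly as written in the rule table, so e.g. `QD = 2.0`
#' survives the fail condition `QD < 2.0`.
#'
#' @param gm a [genotype_matrix] whose site table carries the annotations
#'   (lower-case column names; `qual` from the QUAL column).
#' @param rules data.frame as from [default_hard_filters()].
#' @return filtered [genotype_matrix] with attribute `filter_report`: a
#'   data.frame of per-rule fail and skip counts.
#' @export
apply_hard_filters <- function(gm, rules = default_hard_filters()) {
  need <- c("annotation", "comparator", "threshold")
  if (!is.data.frame(rules) || !all(need %in% names(rules)))
    stop("rules must be a data.frame with annotation, comparator, threshold")
  if (!all(rules$comparator %in% c("<", ">", "<=", ">=")))
    stop("malformed rule: comparator must be one of <, >, <=, >=")
  if (any(is.na(rules$threshold)) || !is.numeric(rules$threshold))
    stop("malformed rule: threshold must be numeric")
  n <- nrow(gm$sites)
  fail_any <- rep(FALSE, n)
  report <- data.frame(annotation = rules$annotation,
                       comparator = rules$comparator,
                       threshold = rules$threshold,
                       n_fail = 0L, n_skipped = 0L)
  for (i in seq_len(nrow(rules))) {
    col <- tolower(rules$annotation[i])
    val <- gm$sites[[col]]
    if (is.null(val)) { report$n_skipped[i] <- n; next }
    fails <- switch(rules$comparator[i],
                    "<"  = val <  rules$threshold[i],
                    ">"  = val >  rules$threshold[i],
                    "<=" = val <= rules$threshold[i],
                    ">=" = val >= rules$threshold[i])
    report$n_skipped[i] <- sum(is.na(fails))
    fails[is.na(fails)] <- FALSE
    report$n_fail[i] <- sum(fails)
    fail_any <- fail_any | fails
  }
  out <- subset_gm(gm, sites = !fail_any)
  attr(out, "filter_report") <- report
  out
}

#' Filter sites by missingness and depth percentiles
#'
#' First drops sites whose fraction of missing genotype calls is strictly
#' greater than `max_missing` (a site missing in exactly 20% of samples is
#' kept under the default). Depth percentiles are then computed empirically
#' across the sites that survived the missingness filter, and sites whose
#' total depth falls outside `[lo, hi]` (inclusive) are removed.
#'
#' @param gm a [genotype_matrix]; per-site depth is taken from the `dp`
#'   site column.
#' @param max_missing maximum tolerated missing fraction (default 0.20).
#' @param depth_lo_pct,depth_hi_pct percentile bounds of the empirical
#'   site-depth distribution (defaults 2.5 and 97.5).
#' @return filtered [genotype_matrix].
#' @export
filter_missingness_depth <- function(gm, max_missing = 0.20,
                                     depth_lo_pct = 2.5,
                                     depth_hi_pct = 97.5) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  miss <- colMeans(is.na(gm$geno))
  keep <- miss <= max_missing
  if (!any(keep)) stop_empty("all sites removed by missingness filter")
  gm <- subset_gm(gm, sites = keep)
  dp <- gm$sites$dp
  if (!is.null(dp) && !all(is.na(dp))) {
    qs <- quantile(dp, probs = c(depth_lo_pct, depth_hi_pct) / 100,
                   na.rm = TRUE, names = FALSE, type = 7)
    keep <- !is.na(dp) & dp >= qs[1] & dp <= qs[2]
    if (!any(keep)) stop_empty("all sites removed by depth filter")
    gm <- subset_gm(gm, sites = keep)
  }
  gm
}

#' Thin to at most one site per genomic window
#'
#' Partitions each chromosome into non-overlapping `stride_bp` bins
#' (`[k*stride + 1, (k+1)*stride]` in 1-based coordinates) and keeps the
#' first site of each bin. Deterministic and idempotent for
#' `stride_bp` fixed.
#'
#' @param gm a [genotype_matrix].
#' @param stride_bp bin width in bp (default 10 kb).
#' @return thinned [genotype_matrix].
#' @export
thin_one_per_window <- function(gm, stride_bp = 10000) {
  stopifnot(stride_bp > 0)
  if (nrow(gm$sites) == 0) return(gm)
  bin <- (gm$sites$pos - 1L) %/% as.integer(stride_bp)
  key <- paste(gm$sites$chrom, bin)
  keep <- !duplicated(key)  # sites are sorted, so first = lowest position
  subset_gm(gm, sites = keep)
}
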