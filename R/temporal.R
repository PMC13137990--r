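#' Resample a per-individual metric and summarize
#'
#' Draws `n` individuals without replacement `reps` times and records the
#' per-draw statistic (median by default). The summary is the median of
#' the replicate values plus a 2.5/25/75/97.5 percentile box. Instead of a
#' value vector, `values` may be a function of a character vector of ids
#' (e.g. a subset-level statistic such as pi), in which case `ids` must
#' name the available individuals.
#'
#' @param values named numeric vector (per-individual metric) or
#'   `function(ids) -> numeric(1)`.
#' @param n individuals per draw.
#' @param reps number of draws (default 100).
#' @param seed integer seed (optional).
#' @param ids candidate ids when `values` is a function.
#' @param stat per-draw statistic applied to value draws (default
#'   [median]); ignored when `values` is a function.
#' @return list with `replicates` (numeric vector, length `reps`) and
#'   `summary` (median, q2.5, q25, q75, q97.5).
#' @export
resample_metric <- function(values, n, reps = 100, seed = NULL,
                            ids = NULL, stat = median) {
  is_fun <- is.function(values)
  pool <- if (is_fun) ids else names(values) %||% seq_along(values)
  if (is.null(pool)) stop("values must be named or ids supplied")
  pool <- sort(pool)  # draws depend on ids, not on input order
  if (length(pool) < n)
    stop("only ", length(pool), " individuals available, n = ", n)
  reps_v <- vapply(seq_len(reps), function(r) {
    rs <- if (is.null(seed)) NULL else derive_seed(seed, paste0("rep", r))
    with_seed(rs, {
      draw <- sample(pool, n)
      if (is_fun) values(draw) else stat(unname(values[draw]))
    })
  }, 0)
  qs <- quantile(reps_v, c(0.025, 0.25, 0.75, 0.975), names = FALSE)
  list(replicates = reps_v,
       summary = c(median = median(reps_v), q2.5 = qs[1], q25 = qs[2],
                   q75 = qs[3], q97.5 = qs[4]))
}

#' Wilcoxon rank-sum test (Mann-Whitney U)
#'
#' Two-sided test of location shift. For combined sample sizes of at most
#' `exact_max` (default 12) the p-value is exact by enumeration of all
#' group assignments of the pooled values (valid under ties); otherwise
#' the tie-corrected normal approximation with continuity correction is
#' used. The exact two-sided p is `min(1, 2*min(P(U <= u), P(U >= u)))`.
#'
#' @param x,y numeric samples.
#' @param exact_max largest `length(x) + length(y)` for the exact branch.
#' @return list with `U` (statistic for `x`), `p_value`, `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 12) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  m <- length(x); n <- length(y); N <- m + n
  pooled <- c(x, y)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  if (N <= exact_max) {
    combs <- combn(N, m)
    us <- apply(combs, 2, function(ix) sum(rk[ix]) - m * (m + 1) / 2)
    p <- min(1, 2 * min(mean(us <= U), mean(us >= U)))
    return(list(U = U, p_value = p, method = "exact"))
  }
  mu <- m * n / 2
  tie <- table(pooled)
  sigma2 <- m * n / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p_value = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Proportional change between two period values
#'
#' `(after - before) / before`, the reporting convention for temporal
#' genetic change; multiply by 100 for percent. `before = 0` yields `NA`
#' with a warning rather than an error.
#'
#' @param before,after numeric scalars.
#' @return signed fraction.
#' @export
proportional_change <- function(before, after) {
  if (is.na(before) || before == 0) {
    warning("proportional change undefined for before = 0")
    return(NA_real_)
  }
  (after - before) / before
}

significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                              ifelse(p < 0.01, "**",
                                     ifelse(p < 0.05, "*", ""))))
}

#' Temporal erosion report across sampling periods
#'
#' For every population and metric: equal-n resampled period summaries
#' (median and percentile box) and pairwise period comparisons —
#' proportional change of the resampled medians, rank-sum test and
#' significance stars — for period I (oldest vs middle), period II
#' (middle vs newest) and overall (oldest vs newest). By default the test
#' compares the 100 replicate values of the two periods, which mirrors the
#' figure-style significance but pseudo-replicates the individuals and
#' therefore overstates evidence; `test_on = "individuals"` tests the raw
#' per-individual values instead. An optional Benjamini-Hochberg column is
#' appended across all comparisons.
#'
#' @param metrics data.frame with `sample_id`, `metric`, `value`.
#' @param meta data.frame with `sample_id`, `population`, `period`.
#' @param n individuals resampled per draw; either a single number or a
#'   named vector per population.
#' @param periods period labels oldest to newest (default the three-period
#'   design `pre-1979`, `1980-1999`, `post-2000`).
#' @param reps resampling replicates (default 100).
#' @param seed integer seed (optional).
#' @param test_on `"replicates"` (default) or `"individuals"`.
#' @return object of class `erosion_report`: list of `summary` and
#'   `comparisons` data.frames.
#' @export
build_report <- function(metrics, meta, n, periods = c("pre-1979",
                                                       "1980-1999",
                                                       "post-2000"),
                         reps = 100, seed = NULL,
                         test_on = c("replicates", "individuals")) {
  test_on <- match.arg(test_on)
  stopifnot(all(c("sample_id", "metric", "value") %in% names(metrics)),
            all(c("sample_id", "population", "period") %in% names(meta)))
  pops <- unique(meta$population)
  summary_rows <- list(); comp_rows <- list()
  for (pop in pops) {
    n_pop <- if (length(n) > 1) n[[pop]] else n
    for (met in unique(metrics$metric)) {
      reps_by_period <- list(); vals_by_period <- list()
      for (per in periods) {
        ids <- meta$sample_id[meta$population == pop & meta$period == per]
        rows <- metrics$metric == met & metrics$sample_id %in% ids
        v <- setNames(metrics$value[rows], metrics$sample_id[rows])
        if (!length(v) || length(v) < n_pop) {
          warning(sprintf("population %s, metric %s: period %s has %d < %d individuals; omitted",
                          pop, met, per, length(v), n_pop))
          next
        }
        rs <- resample_metric(v, n = n_pop, reps = reps,
                              seed = if (is.null(seed)) NULL else
                                derive_seed(seed, paste(pop, met, per)))
        reps_by_period[[per]] <- rs$replicates
        vals_by_period[[per]] <- v
        summary_rows[[length(summary_rows) + 1]] <-
          data.frame(population = pop, metric = met, period = per,
                     n = n_pop, t(rs$summary), stringsAsFactors = FALSE)
      }
      have <- names(reps_by_period)
      pairs <- list(c(1, 2), c(2, 3), c(1, 3))
      labels <- c("period I", "period II", "overall")
      for (k in seq_along(pairs)) {
        pa <- periods[pairs[[k]][1]]; pb <- periods[pairs[[k]][2]]
        if (!(pa %in% have) || !(pb %in% have)) next
        before <- median(reps_by_period[[pa]])
        after <- median(reps_by_period[[pb]])
        tst <- if (test_on == "replicates")
          rank_sum_test(reps_by_period[[pa]], reps_by_period[[pb]])
        else rank_sum_test(unname(vals_by_period[[pa]]),
                           unname(vals_by_period[[pb]]))
        pc <- if (before != 0) (after - before) / before else NA_real_
        comp_rows[[length(comp_rows) + 1]] <-
          data.frame(population = pop, metric = met, comparison = labels[k],
                     before_period = pa, after_period = pb,
                     before = before, after = after,
                     prop_change = pc, prop_change_pct = 100 * pc,
                     U = tst$U, p_value = tst$p_value,
                     stars = significance_stars(tst$p_value),
                     stringsAsFactors = FALSE)
      }
    }
  }
  comparisons <- if (length(comp_rows)) do.call(rbind, comp_rows) else
    data.frame()
  if (nrow(comparisons))
    comparisons$p_bh <- p.adjust(comparisons$p_value, method = "BH")
  structure(list(summary = do.call(rbind, summary_rows),
                 comparisons = comparisons,
                 test_on = test_on),
            class = "erosion_report")
}

#' @export
print.erosion_report <- function(x, ...) {
  cat("<erosion_report> (tests on", x$test_on, "values)\n\nPeriod summaries:\n")
  print(x$summary, row.names = FALSE, digits = 4)
  cat("\nComparisons:\n")
  if (nrow(x$comparisons)) {
    show <- x$comparisons[, c("population", "metric", "comparison",
                              "prop_change_pct", "p_value", "stars")]
    print(show, row.names = FALSE, digits = 4)
  } else cat("  (none)\n")
  invisible(x)
}
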