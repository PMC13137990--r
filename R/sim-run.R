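#' Burn in an ancestral population
#'
#' Runs the yearly non-Wright-Fisher cycle at the (rescaled) ancestral
#' carrying capacity for the (rescaled) number of burn-in generations,
#' periodically dropping fixed mutations, and records a diversity
#' trajectory. The returned population carries segregating neutral and
#' deleterious variation and is the starting point for
#' [run_scenarios()].
#'
#' @param cfg a [sim_config()] (see [desk_sim_config()] for the
#'   desk-scale profile).
#' @param seed integer seed (optional).
#' @param record_every record census/fitness/heterozygosity every this
#'   many generations (default 25).
#' @param mutation_cap abort when the registry exceeds this many
#'   mutations (runaway-memory guard; default 5e6).
#' @return an `nwf_population` with attribute `trajectory` (data.frame:
#'   `gen`, `N`, `mean_fitness`, `syn_het`) where `syn_het` is the mean
#'   per-coding-bp synonymous heterozygosity.
#' @export
burn_in <- function(cfg, seed = NULL, record_every = 25,
                    mutation_cap = 5e6) {
  with_seed(seed, {
    genome <- build_genome(cfg$chrom_lengths, cfg$n_genes, cfg$gene_len)
    pop <- init_population(cfg$K_scaled, genome, cfg)
    traj <- list()
    for (g in seq_len(cfg$gens_scaled)) {
      pop <- tick(pop, cfg$K_scaled)
      if (pop$extinct) break
      if (g %% 20L == 0L) pop <- purge_fixed(pop)
      if (pop$mut$n > mutation_cap)
        stop("mutation registry exceeded cap (", mutation_cap,
             "); increase rescaling or reduce genome size")
      if (g %% record_every == 0L || g == cfg$gens_scaled)
        traj[[length(traj) + 1L]] <-
          data.frame(gen = g, N = length(pop$age),
                     mean_fitness = mean(pop$w),
                     syn_het = synonymous_heterozygosity(pop))
    }
    attr(pop, "trajectory") <- do.call(rbind, traj)
    pop
  })
}

## Mean per-site heterozygosity at synonymous (neutral) mutations,
## per coding bp.
synonymous_heterozygosity <- function(pop) {
  N <- length(pop$age)
  if (N == 0L) return(NA_real_)
  reg <- pop$mut
  het_count <- 0L
  for (i in seq_len(N)) {
    ids <- c(pop$h1[[i]], pop$h2[[i]])
    dup <- duplicated(ids)
    het <- ids[!(ids %in% ids[dup])]
    het_count <- het_count + sum(!reg$nonsyn[het])
  }
  het_count / N / pop$genome$coding_len
}

#' Run carrying-capacity scenarios from a burned-in population
#'
#' For each carrying capacity, runs `reps` independent replicates of the
#' yearly cycle from the same starting population (fresh RNG streams
#' derived from `seed`), recording yearly census, mean fitness and
#' homozygous-load proportion, the extinction year of each replicate, the
#' extinction probability (extinct replicates / total) and the mean
#' extinction time with its standard error.
#'
#' @param pop a burned-in `nwf_population`.
#' @param K_list carrying capacities (e.g. the declining series
#'   `c(50, 40, 30, 20, 10)` or increasing series `c(100, 150, 200,
#'   250)`).
#' @param years projection horizon in years (default 1000).
#' @param reps replicates per K (default 100).
#' @param seed integer seed (optional).
#' @param record_every trajectory recording interval in years (default
#'   10; extinction detection is still yearly).
#' @return object of class `scenario_result`: list with `aggregate`
#'   (data.frame per K: `K`, `n_reps`, `n_extinct`,
#'   `extinction_probability`, `mean_extinction_year`, `se_extinction_year`),
#'   `extinction_years` (list per K), `trajectories` (data.frame: `K`,
#'   `replicate`, `year`, `N`, `mean_fitness`, `load_proportion`).
#' @export
run_scenarios <- function(pop, K_list, years = 1000, reps = 100,
                          seed = NULL, record_every = 10) {
  agg <- list(); ext_years <- list(); traj <- list()
  for (K in K_list) {
    ext <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      rs <- if (is.null(seed)) NULL else
        derive_seed(seed, paste0("K", K, "rep", r))
      p <- clone_population(pop)
      with_seed(rs, {
        for (y in seq_len(years)) {
          p <- tick(p, K)
          if (y %% 20L == 0L) p <- purge_fixed(p)
          if (p$extinct) { ext[r] <- y; break }
          if (y %% record_every == 0L) {
            sm <- population_summaries(p)
            traj[[length(traj) + 1L]] <-
              data.frame(K = K, replicate = r, year = y, N = sm$n,
                         mean_fitness = sm$mean_fitness,
                         load_proportion = sm$load_proportion)
          }
        }
      })
      if (!is.na(ext[r]))
        traj[[length(traj) + 1L]] <-
          data.frame(K = K, replicate = r, year = ext[r], N = 0,
                     mean_fitness = NA_real_, load_proportion = NA_real_)
    }
    n_ext <- sum(!is.na(ext))
    agg[[length(agg) + 1L]] <-
      data.frame(K = K, n_reps = reps, n_extinct = n_ext,
                 extinction_probability = n_ext / reps,
                 mean_extinction_year = if (n_ext) mean(ext, na.rm = TRUE)
                 else NA_real_,
                 se_extinction_year = if (n_ext > 1)
                   stats::sd(ext, na.rm = TRUE) / sqrt(n_ext) else NA_real_)
    ext_years[[as.character(K)]] <- ext
  }
  structure(list(aggregate = do.call(rbind, agg),
                 extinction_years = ext_years,
                 trajectories = do.call(rbind, traj)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>\n")
  print(x$aggregate, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Temporal (variance) effective size of a running population
#'
#' Advances the population `gens` further years at carrying capacity `K`,
#' snapshotting synonymous-mutation frequencies every `step` years, and
#' estimates the per-year variance effective size from the standardized
#' frequency change over each increment:
#' `F = E[(p1 - p0)^2 / (pbar*(1-pbar))] ~ step / (2*Ne)`, averaged over
#' increments (short increments keep the diffusion linear, avoiding the
#' saturation bias of one long window). Also returns the per-capita
#' yearly birth rate and mean parent age observed in the window, which
#' convert per-generation rates to per-year rates in diffusion
#' comparisons.
#'
#' @param pop an `nwf_population` (not modified; a copy is advanced).
#' @param K carrying capacity during the measurement window.
#' @param gens length of the window in years (default 100).
#' @param step years per frequency increment (default 10).
#' @param freq_band loci with increment-start frequency inside this band
#'   enter that increment's F (default `c(0.1, 0.9)`).
#' @param seed integer seed (optional).
#' @return list with `ne_year`, `generation_time`, `birth_rate`,
#'   `newborn_fraction` (mean fraction of the census aged 1, i.e. the
#'   survival-adjusted probability that a lineage's chromosome was
#'   created by gametogenesis this year — the per-year conversion factor
#'   for per-gamete mutation rates), `n_increments`, and the advanced
#'   `population`.
#' @export
measure_temporal_ne <- function(pop, K, gens = 100, step = 10,
                                freq_band = c(0.1, 0.9), seed = NULL) {
  with_seed(seed, {
    reg <- pop$mut
    syn_ids <- function(p) {
      ids <- unique(c(unlist(p$h1), unlist(p$h2)))
      ids[!reg$nonsyn[ids]]
    }
    births0 <- pop$births_total; page0 <- pop$parent_age_sum
    census_sum <- 0; n_years <- 0L
    newborn_frac <- numeric(0)
    f_by_inc <- numeric(0)
    ids <- syn_ids(pop); p_prev <- mutation_frequencies(pop, ids)
    for (g in seq_len(gens)) {
      pop <- tick(pop, K)
      if (pop$extinct) break
      n_years <- n_years + 1L
      census_sum <- census_sum + length(pop$age)
      newborn_frac <- c(newborn_frac, mean(pop$age == 1L))
      if (g %% step == 0L) {
        p_now <- mutation_frequencies(pop, ids)
        use <- p_prev >= freq_band[1] & p_prev <= freq_band[2]
        if (sum(use) >= 5) {
          pbar <- (p_prev[use] + p_now[use]) / 2
          ok <- pbar > 0 & pbar < 1
          f_by_inc <- c(f_by_inc,
                        mean((p_now[use][ok] - p_prev[use][ok])^2 /
                               (pbar[ok] * (1 - pbar[ok]))))
        }
        ids <- syn_ids(pop)
        p_prev <- mutation_frequencies(pop, ids)
      }
    }
    births <- pop$births_total - births0
    Fbar <- mean(f_by_inc)
    list(ne_year = if (length(f_by_inc) && Fbar > 0) step / (2 * Fbar)
         else Inf,
         generation_time = (pop$parent_age_sum - page0) / (2 * births),
         birth_rate = births / census_sum,
         newborn_fraction = mean(newborn_frac),
         n_increments = length(f_by_inc), population = pop)
  })
}
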