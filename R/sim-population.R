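#' Forward-simulation configuration
#'
#' Parameters of the non-Wright-Fisher model and its population-genetic
#' rescaling. With rescaling factor `lambda`, carrying capacities and
#' generation counts divide by `lambda` while the mutation rate,
#' inter-gene recombination rate and selection coefficients multiply by
#' `lambda` (scaled `s` capped at -1), preserving the products that govern
#' diversity and load. `lambda = 1` is the full-scale configuration
#' (ancestral K 10,000 for 100,000 burn-in generations, 20,000 genes);
#' `lambda = 100` is the desk-scale profile used throughout the tests.
#'
#' @param ancestral_K ancestral carrying capacity before rescaling
#'   (default 10000).
#' @param burnin_gens burn-in generations before rescaling (default
#'   100000).
#' @param mu per-site per-generation mutation rate (default 1.47e-8).
#' @param recomb inter-gene recombination probability per gene boundary
#'   (default 1e-3).
#' @param dfe a [dfe_config()].
#' @param lambda rescaling factor (>= 1, default 1).
#' @param fecundity probability a female aged >= 1 produces her single
#'   yearly offspring (default 0.9).
#' @param max_age maximum age in years (default 12).
#' @param n_genes,gene_len,chrom_lengths genome architecture passed to
#'   [build_genome()].
#' @param selection logical; `FALSE` disables fitness effects on survival
#'   (neutral control).
#' @return list of class `sim_config` (includes the scaled rates
#'   `K_scaled`, `gens_scaled`, `mu_scaled`, `recomb_scaled`).
#' @export
sim_config <- function(ancestral_K = 10000, burnin_gens = 100000,
                       mu = 1.47e-8, recomb = 1e-3, dfe = dfe_config(),
                       lambda = 1, fecundity = 0.9, max_age = 12,
                       n_genes = 20000, gene_len = 1500,
                       chrom_lengths = NULL, selection = TRUE) {
  stopifnot(lambda >= 1, mu * lambda < 1)
  cfg <- list(ancestral_K = ancestral_K, burnin_gens = burnin_gens,
              mu = mu, recomb = recomb, dfe = dfe, lambda = lambda,
              fecundity = fecundity, max_age = max_age,
              n_genes = n_genes, gene_len = gene_len,
              chrom_lengths = chrom_lengths, selection = selection,
              K_scaled = max(2, round(ancestral_K / lambda)),
              gens_scaled = max(1, round(burnin_gens / lambda)),
              mu_scaled = mu * lambda,
              recomb_scaled = min(0.5, recomb * lambda))
  class(cfg) <- "sim_config"
  cfg
}

#' Desk-scale configuration (rescaling factor 100)
#'
#' The scaled-down study profile: ancestral K 100 for 1000 generations,
#' 1000 genes of 1500 bp, mu and s multiplied by 100.
#'
#' @param ... overrides passed to [sim_config()].
#' @export
desk_sim_config <- function(...) {
  sim_config(lambda = 100, n_genes = 1000, ...)
}

## Mutation registry: append-only parallel vectors indexed by mutation id.
new_mut_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$n <- 0L
  reg$s <- numeric(0)        # scaled selection coefficient (<= 0)
  reg$h <- numeric(0)
  reg$nonsyn <- logical(0)
  reg$gene <- integer(0)
  reg$pos <- integer(0)      # bp position within the genome
  reg$class <- character(0)  # strength class on the UNSCALED s
  reg
}

## Register k new mutations at uniform coding positions; returns their ids.
register_mutations <- function(reg, k, cfg, genome) {
  if (k == 0L) return(integer(0))
  d <- draw_mutation(k, cfg$dfe)
  gene <- sample.int(genome$n_genes, k, replace = TRUE)
  off <- sample.int(genome$gene_len, k, replace = TRUE)
  ids <- reg$n + seq_len(k)
  reg$n <- reg$n + k
  reg$s <- c(reg$s, pmax(-1, d$s * cfg$lambda))
  reg$h <- c(reg$h, d$h)
  reg$nonsyn <- c(reg$nonsyn, d$type == "nonsynonymous")
  reg$gene <- c(reg$gene, gene)
  reg$pos <- c(reg$pos, genome$genes$start[gene] + off - 1L)
  reg$class <- c(reg$class, d$strength_class)
  ids
}

#' Initialize a mutation-free age-structured population
#'
#' @param n number of individuals.
#' @param genome a [build_genome()] map.
#' @param cfg a [sim_config()].
#' @return object of class `nwf_population`.
#' @export
init_population <- function(n, genome, cfg) {
  structure(list(age = rep(1L, n),
                 sex = rep_len(c(0L, 1L), n),   # 0 female, 1 male
                 h1 = rep(list(integer(0)), n),
                 h2 = rep(list(integer(0)), n),
                 w = rep(1, n), fixed_logw = 0,
                 mut = new_mut_registry(), genome = genome, cfg = cfg,
                 gen = 0L, births_total = 0L, parent_age_sum = 0,
                 extinct = FALSE),
            class = "nwf_population")
}

#' @export
print.nwf_population <- function(x, ...) {
  cat(sprintf("<nwf_population> N = %d, generation %d, mean fitness %.4f%s\n",
              length(x$age), x$gen, if (length(x$w)) mean(x$w) else NA,
              if (x$extinct) " [EXTINCT]" else ""))
  invisible(x)
}

## Deep copy (the mutation registry is an environment).
clone_population <- function(pop) {
  reg <- new_mut_registry()
  for (f in ls(pop$mut)) assign(f, get(f, pop$mut), reg)
  pop$mut <- reg
  pop
}

#' Multiplicative fitness of one individual
#'
#' `w = prod_hom (1 + s) * prod_het (1 + h*s)`, floored at zero; mutations
#' present on both haplotypes count once as homozygous. Synonymous
#' (neutral) mutations contribute nothing.
#'
#' @param h1,h2 integer vectors of mutation ids (the two haplotypes).
#' @param reg mutation registry (from a population's `$mut`).
#' @param fixed_logw log-fitness contribution of fixed deleterious
#'   mutations carried by every individual (default 0).
#' @return fitness in `[0, 1]`.
#' @export
individual_fitness <- function(h1, h2, reg, fixed_logw = 0) {
  ids <- c(h1, h2)
  if (length(ids)) {
    if (any(ids > reg$n)) stop("unresolvable mutation id")
    dup <- duplicated(ids)
    hom <- ids[dup]
    het <- ids[!(ids %in% hom)]
    s_hom <- reg$s[hom]; s_het <- reg$s[het]
    sel_hom <- s_hom < 0; sel_het <- s_het < 0
    lw <- sum(log1p(s_hom[sel_hom])) +
      sum(log1p(reg$h[het][sel_het] * s_het[sel_het]))
  } else lw <- 0
  max(0, exp(fixed_logw + lw))
}

## One recombinant gamete plus new mutations; returns list(ids, new_ids).
make_gamete <- function(h1, h2, pop) {
  genome <- pop$genome; cfg <- pop$cfg; reg <- pop$mut
  ng <- genome$n_genes
  p_switch <- rep(cfg$recomb_scaled, ng)
  p_switch[!duplicated(genome$genes$chrom)] <- 0.5  # free assortment
  assign <- cumsum(rbinom(ng, 1L, p_switch)) %% 2L
  ids <- c(h1[assign[reg$gene[h1]] == 0L], h2[assign[reg$gene[h2]] == 1L])
  n_new <- rpois(1L, cfg$mu_scaled * genome$coding_len)
  new_ids <- register_mutations(reg, n_new, cfg, genome)
  list(ids = c(ids, new_ids), new_ids = new_ids)
}

#' Advance the population one year
#'
#' The yearly non-Wright-Fisher cycle: (1) every female aged >= 1 produces
#' at most one offspring (Bernoulli with the configured fecundity) with a
#' random male aged >= 1; offspring haplotypes recombine at gene
#' boundaries and receive Poisson new mutations; (2) viability selection:
#' each individual (newborns included) survives with probability
#' `min(1, w * K / N)` where `N` is the post-reproduction census, with
#' certain death beyond the maximum age; (3) survivors age one year. An
#' empty population is an absorbing extinct state.
#'
#' @param pop an `nwf_population`.
#' @param K carrying capacity for this year.
#' @param audit logical; when `TRUE` the result carries an `audit`
#'   attribute recording, per newborn, the parent haplotypes and new
#'   mutation ids (for Mendelian bookkeeping checks).
#' @return the advanced `nwf_population`.
#' @export
tick <- function(pop, K, audit = FALSE) {
  stopifnot(K > 0)
  pop$gen <- pop$gen + 1L
  n0 <- length(pop$age)
  if (n0 == 0L) { pop$extinct <- TRUE; return(pop) }
  females <- which(pop$sex == 0L & pop$age >= 1L)
  males <- which(pop$sex == 1L & pop$age >= 1L)
  audit_log <- list()
  if (length(females) && length(males)) {
    breeding <- females[runif(length(females)) < pop$cfg$fecundity]
    if (length(breeding)) {
      dads <- males[sample.int(length(males), length(breeding),
                               replace = TRUE)]
      for (j in seq_along(breeding)) {
        mo <- breeding[j]; fa <- dads[j]
        g1 <- make_gamete(pop$h1[[mo]], pop$h2[[mo]], pop)
        g2 <- make_gamete(pop$h1[[fa]], pop$h2[[fa]], pop)
        k <- length(pop$age) + 1L
        pop$age[k] <- 0L
        pop$sex[k] <- rbinom(1L, 1L, 0.5)
        pop$h1[[k]] <- g1$ids
        pop$h2[[k]] <- g2$ids
        pop$w[k] <- individual_fitness(g1$ids, g2$ids, pop$mut,
                                       pop$fixed_logw)
        if (audit)
          audit_log[[length(audit_log) + 1L]] <-
            list(mother = mo, father = fa,
                 new_ids = c(g1$new_ids, g2$new_ids))
      }
      pop$births_total <- pop$births_total + length(breeding)
      pop$parent_age_sum <- pop$parent_age_sum +
        sum(pop$age[breeding]) + sum(pop$age[dads])
    }
  }
  N <- length(pop$age)
  p <- if (pop$cfg$selection) pmin(1, pop$w * K / N)
       else rep(min(1, K / N), N)
  p[pop$age + 1L > pop$cfg$max_age] <- 0
  keep <- runif(N) < p
  pop$age <- pop$age[keep] + 1L
  pop$sex <- pop$sex[keep]
  pop$h1 <- pop$h1[keep]
  pop$h2 <- pop$h2[keep]
  pop$w <- pop$w[keep]
  if (!length(pop$age)) pop$extinct <- TRUE
  if (audit) attr(pop, "audit") <- audit_log
  pop
}

## Drop mutations fixed in every haplotype (their fitness effect moves to
## fixed_logw, so absolute fitness is unchanged) ; lost ids vanish with
## their carriers. Keeps haplotype vectors short on long runs.
purge_fixed <- function(pop) {
  N <- length(pop$age)
  if (N == 0L) return(pop)
  reg <- pop$mut
  ids <- as.integer(c(unlist(pop$h1), unlist(pop$h2)))
  if (!length(ids)) return(pop)
  cnt <- tabulate(ids, nbins = reg$n)
  fixed <- which(cnt == 2L * N)
  if (!length(fixed)) return(pop)
  mask <- rep(FALSE, reg$n); mask[fixed] <- TRUE
  strip <- function(h) h[!mask[h]]
  pop$h1 <- lapply(pop$h1, strip)
  pop$h2 <- lapply(pop$h2, strip)
  pop$fixed_logw <- pop$fixed_logw + sum(log1p(reg$s[fixed]))
  pop
}

#' Population-level fitness and load summaries
#'
#' Returns the mean multiplicative fitness, the pooled homozygous-load
#' proportion (homozygous deleterious genotypes over homozygous plus
#' heterozygous deleterious genotypes, across all individuals), and
#' segregating deleterious mutation counts per strength class.
#'
#' @param pop an `nwf_population`.
#' @return list with `mean_fitness`, `load_proportion`, `strength_counts`,
#'   `n`.
#' @export
population_summaries <- function(pop) {
  N <- length(pop$age)
  if (N == 0L) stop("empty population")
  reg <- pop$mut
  hom_tot <- 0L; het_tot <- 0L
  seg_ids <- integer(0)
  for (i in seq_len(N)) {
    ids <- c(pop$h1[[i]], pop$h2[[i]])
    dup <- duplicated(ids)
    hom <- ids[dup]
    het <- ids[!(ids %in% hom)]
    hom_tot <- hom_tot + sum(reg$s[hom] < 0)
    het_tot <- het_tot + sum(reg$s[het] < 0)
  }
  all_ids <- unique(c(unlist(pop$h1), unlist(pop$h2)))
  del <- all_ids[reg$s[all_ids] < 0]
  counts <- table(factor(reg$class[del],
                         levels = c("strong", "moderate", "weak",
                                    "neutral")))
  list(mean_fitness = mean(pop$w),
       load_proportion = if (hom_tot + het_tot > 0)
         hom_tot / (hom_tot + het_tot) else 0,
       strength_counts = counts, n = N)
}

#' Population frequencies of given mutation ids
#'
#' @param pop an `nwf_population`.
#' @param ids integer mutation ids.
#' @return numeric vector of frequencies in `[0, 1]`.
#' @export
mutation_frequencies <- function(pop, ids) {
  N <- length(pop$age)
  if (N == 0L || !length(ids)) return(rep(0, length(ids)))
  all_ids <- as.integer(c(unlist(pop$h1), unlist(pop$h2)))
  if (!length(all_ids)) return(rep(0, length(ids)))
  cnt <- tabulate(all_ids, nbins = pop$mut$n)
  cnt[ids] / (2 * N)
}
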