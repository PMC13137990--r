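#' Cohort generator configuration
#'
#' Describes a two-population (or single-population), three-period
#' synthetic study: per-epoch effective sizes, epoch lengths, samples
#' drawn at the end of each epoch, and per-epoch selfing rates. Sites are
#' unlinked biallelic SNPs laid out across chromosomes at a fixed spacing;
#' a configured fraction carry deleterious (nonsynonymous) effects drawn
#' from the DFE, a further fraction are synonymous, and the rest are
#' noncoding-neutral. Site INFO annotations (QUAL, QD, MQ, FS, SOR, DP)
#' are synthesized from declared distributions, with a configurable
#' fraction of deliberately low-quality sites so the hard filters have
#' something to remove.
#'
#' @param populations named list; each element a list with `ne` (three
#'   epoch effective sizes, oldest first), `epoch_gens` (three epoch
#'   lengths in generations), `samples` (individuals sampled per period)
#'   and optionally `selfing` (per-epoch selfing probability, default 0).
#' @param n_sites total SNP count.
#' @param n_chrom chromosomes the sites are spread over.
#' @param site_spacing_bp spacing between consecutive sites (default
#'   12000, i.e. at most one site per 10-kb thinning bin).
#' @param frac_lof,frac_missense,frac_synonymous fractions of sites whose
#'   derived allele is loss-of-function, deleterious missense, or
#'   synonymous; the remainder is noncoding-neutral. LOF and missense
#'   sites are deleterious with DFE-drawn `s`, `h`.
#' @param dfe a [dfe_config()] for deleterious site effects.
#' @param init_freq_range range of initial derived-allele frequencies.
#' @param low_quality_fraction fraction of sites given failing INFO values.
#' @param periods period labels, oldest first.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(populations = list(
                            SW = list(ne = c(1000, 450, 330),
                                      epoch_gens = c(40, 30, 30),
                                      samples = c(10, 7, 16),
                                      selfing = c(0, 0, 0))),
                          n_sites = 1000, n_chrom = 10,
                          site_spacing_bp = 12000,
                          frac_lof = 0.03, frac_missense = 0.07,
                          frac_synonymous = 0.2, dfe = dfe_config(),
                          init_freq_range = c(0.05, 0.95),
                          low_quality_fraction = 0,
                          periods = c("pre-1979", "1980-1999",
                                      "post-2000")) {
  stopifnot(length(periods) == 3,
            frac_lof + frac_missense + frac_synonymous <= 1)
  for (p in populations) {
    stopifnot(length(p$ne) == 3, all(p$ne > 0),
              length(p$epoch_gens) == 3, length(p$samples) == 3)
    if (any(p$samples > 2 * p$ne))
      stop("sample request exceeds 2*Ne for an epoch")
  }
  structure(list(populations = populations, n_sites = n_sites,
                 n_chrom = n_chrom, site_spacing_bp = site_spacing_bp,
                 frac_lof = frac_lof, frac_missense = frac_missense,
                 frac_synonymous = frac_synonymous, dfe = dfe,
                 init_freq_range = init_freq_range,
                 low_quality_fraction = low_quality_fraction,
                 periods = periods),
            class = "cohort_config")
}

## Wright-Fisher diploid step with viability-weighted parent sampling and
## optional selfing; unlinked sites, fully vectorized.
wf_generation <- function(G, n_next, logw_hom, logw_het, del_idx, selfing) {
  N <- nrow(G); L <- ncol(G)
  w <- rep(1, N)
  if (length(del_idx)) {
    Gd <- G[, del_idx, drop = FALSE]
    w <- exp((Gd == 2L) %*% logw_hom + (Gd == 1L) %*% logw_het)[, 1]
  }
  p1 <- sample.int(N, n_next, replace = TRUE, prob = w)
  p2 <- sample.int(N, n_next, replace = TRUE, prob = w)
  selfed <- runif(n_next) < selfing
  p2[selfed] <- p1[selfed]
  gam <- function(par) {
    gp <- G[par, , drop = FALSE]
    (gp == 2L) + (gp == 1L) * (runif(n_next * L) < 0.5)
  }
  list(G = gam(p1) + gam(p2), p1 = p1, p2 = p2, selfed = selfed)
}

#' Generate a synthetic temporal cohort
#'
#' Discrete-generation diploid Wright-Fisher simulation through three
#' epochs of declining (or arbitrary) effective size, with viability
#' selection on deleterious sites and optional selfing, sampling
#' individuals at the end of each epoch as the three period cohorts. All
#' populations share ancestral site frequencies, then drift
#' independently. Returns the genotypes as a [genotype_matrix] with
#' synthesized INFO annotations, a sample metadata table, and a truth
#' record (per-site class, ancestral allele and effects; per-individual
#' selfing-derived inbreeding F). Deterministic: the same seed reproduces
#' the output byte-for-byte.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @param dir optional directory; when given, writes `cohort.vcf.gz`,
#'   `metadata.tsv` and `truth.json` and returns their paths too.
#' @return list with `gm`, `meta` (`sample_id`, `population`, `period`,
#'   `collection_year`), `truth`, and (with `dir`) `paths`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1,
                            dir = NULL) {
  with_seed(seed, {
    L <- config$n_sites
    per_chrom <- ceiling(L / config$n_chrom)
    chrom <- paste0("chr", rep(seq_len(config$n_chrom),
                               each = per_chrom))[seq_len(L)]
    pos <- (sequence(rle(chrom)$lengths) - 1L) *
      config$site_spacing_bp + 1L
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, L, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    ## site classes and effects (shared by all populations)
    n_lof <- round(config$frac_lof * L)
    n_mis <- round(config$frac_missense * L)
    n_syn <- round(config$frac_synonymous * L)
    class <- sample(rep(c("LOF", "missense", "synonymous", "neutral"),
                        c(n_lof, n_mis, n_syn, L - n_lof - n_mis - n_syn)))
    s <- numeric(L); h <- rep(0.25, L)
    del <- class %in% c("LOF", "missense")
    if (any(del)) {
      d <- draw_mutation(sum(del), config$dfe)
      ## force deleterious effects regardless of the type draw
      s_d <- ifelse(d$s < 0, d$s,
                    -rgamma(sum(del), config$dfe$shape,
                            scale = config$dfe$mean_s / config$dfe$shape))
      s[del] <- s_d
      h[del] <- ifelse(s_d < config$dfe$h_threshold, config$dfe$h_strong,
                       config$dfe$h_weak)
    }
    p0 <- runif(L, config$init_freq_range[1], config$init_freq_range[2])
    del_idx <- which(del)
    logw_hom <- matrix(log1p(pmax(-1 + 1e-12, s[del_idx])), ncol = 1)
    logw_het <- matrix(log1p(h[del_idx] * pmax(-1, s[del_idx])), ncol = 1)

    geno_rows <- list(); meta_rows <- list(); froh_truth <- list()
    year_ranges <- list(c(1950, 1978), c(1980, 1999), c(2000, 2020))
    for (pn in names(config$populations)) {
      pc <- config$populations[[pn]]
      selfing <- pc$selfing %||% c(0, 0, 0)
      N0 <- pc$ne[1]
      G <- matrix(rbinom(N0 * L, 2L, rep(p0, each = N0)), N0, L)
      Fped <- rep(0, N0)
      for (ep in 1:3) {
        for (g in seq_len(pc$epoch_gens[ep])) {
          st <- wf_generation(G, pc$ne[ep], logw_hom, logw_het, del_idx,
                              selfing[ep])
          Fped <- ifelse(st$selfed, 0.5 * (1 + Fped[st$p1]), 0)
          G <- st$G
        }
        take <- sample.int(nrow(G), pc$samples[ep])
        ids <- sprintf("%s_%s_%02d", pn, c("pre", "mid", "post")[ep],
                       seq_along(take))
        geno_rows[[length(geno_rows) + 1L]] <- G[take, , drop = FALSE]
        yr <- year_ranges[[ep]]
        meta_rows[[length(meta_rows) + 1L]] <-
          data.frame(sample_id = ids, population = pn,
                     period = config$periods[ep],
                     collection_year = sample(seq(yr[1], yr[2]),
                                              length(take),
                                              replace = TRUE),
                     stringsAsFactors = FALSE)
        froh_truth[[length(froh_truth) + 1L]] <-
          setNames(Fped[take], ids)
      }
    }
    geno <- do.call(rbind, geno_rows)
    meta <- do.call(rbind, meta_rows)
    rownames(meta) <- NULL
    n_samp <- nrow(geno)

    ## synthesized INFO annotations
    lowq <- runif(L) < config$low_quality_fraction
    sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                        qual = round(ifelse(lowq, runif(L, 5, 29),
                                            rnorm(L, 80, 15)), 1),
                        dp = rpois(L, 18 * n_samp),
                        qd = round(ifelse(lowq, runif(L, 0.2, 1.9),
                                          pmax(2.5, rnorm(L, 16, 4))), 2),
                        mq = round(pmax(41, rnorm(L, 57, 3)), 2),
                        fs = round(pmin(55, stats::rexp(L, 1 / 4)), 2),
                        sor = round(pmin(2.9, abs(rnorm(L, 1.2, 0.5))), 2),
                        stringsAsFactors = FALSE)
    contigs <- setNames(rep(per_chrom * config$site_spacing_bp + 1000,
                            config$n_chrom),
                        paste0("chr", seq_len(config$n_chrom)))
    gm <- genotype_matrix(geno, sites, meta$sample_id, contigs = contigs)
    truth <- list(seed = seed,
                  site = data.frame(chrom = chrom, pos = pos,
                                    class = class, s = s, h = h,
                                    ancestral = "ref",
                                    init_freq = p0,
                                    stringsAsFactors = FALSE),
                  froh = unlist(froh_truth),
                  ne = lapply(config$populations, `[[`, "ne"))
    out <- list(gm = gm, meta = meta, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      paths <- c(vcf = file.path(dir, "cohort.vcf.gz"),
                 meta = file.path(dir, "metadata.tsv"),
                 truth = file.path(dir, "truth.json"))
      write_genotypes(gm, paths["vcf"])
      write.table(meta, paths["meta"], sep = "\t", quote = FALSE,
                  row.names = FALSE)
      jsonlite::write_json(list(seed = seed, froh = as.list(truth$froh),
                                ne = truth$ne,
                                site = truth$site),
                           paths["truth"], auto_unbox = TRUE, digits = NA)
      out$paths <- paths
    }
    out
  })
}

#' Generate outgroup genotypes for polarization
#'
#' The outgroup lineage split before the first epoch: it is homozygous for
#' the true ancestral (REF) allele at most sites, flipping to homozygous
#' derived at a per-site probability proportional to the divergence time.
#' With `divergence_generations = 0` the outgroup is an exact copy of a
#' random ingroup individual (degenerate control).
#'
#' @param cohort output of [generate_cohort()].
#' @param divergence_generations lineage split depth.
#' @param n_outgroup outgroup individuals (default 1).
#' @param flip_rate per-generation per-site substitution probability
#'   scale (default 1e-5).
#' @param seed integer seed.
#' @return a [genotype_matrix] of outgroup sample(s) over the same sites.
#' @export
generate_outgroup <- function(cohort, divergence_generations,
                              n_outgroup = 1, flip_rate = 1e-5,
                              seed = 1) {
  stopifnot(divergence_generations >= 0)
  with_seed(seed, {
    L <- nrow(cohort$gm$sites)
    if (divergence_generations == 0) {
      i <- sample(length(cohort$gm$sample_ids), 1)
      g <- matrix(cohort$gm$geno[rep(i, n_outgroup), ], n_outgroup, L)
    } else {
      p_flip <- min(0.45, divergence_generations * flip_rate)
      flips <- matrix(runif(n_outgroup * L) < p_flip, n_outgroup, L)
      g <- matrix(0L, n_outgroup, L)
      g[flips] <- 2L
    }
    genotype_matrix(g, cohort$gm$sites[, c("chrom", "pos", "ref", "alt")],
                    sprintf("outgroup_%02d", seq_len(n_outgroup)),
                    contigs = cohort$gm$contigs)
  })
}

#' Generate toy gene models (FASTA reference + GFF3 CDS intervals)
#'
#' Builds `n_genes` random valid coding sequences (ATG start, no internal
#' stop, terminal stop), placed with spacers on one synthetic chromosome;
#' strands alternate and every third gene is split into two exons by a
#' GT..AG intron so splice regions exist. Output is directly consumable
#' by [annotate_consequence()].
#'
#' @param n_genes number of genes.
#' @param gene_len CDS length in bp, divisible by 3 (default 1500).
#' @param intron_len intron length for two-exon genes (default 120).
#' @param seed integer seed.
#' @param dir optional directory; when given writes `genes.fa` and
#'   `genes.gff3`.
#' @return list with `reference` (named character), `cds_model`
#'   (data.frame), `cds_seqs` (named character, coding orientation) and
#'   (with `dir`) `paths`.
#' @export
generate_gene_models <- function(n_genes = 20, gene_len = 1500,
                                 intron_len = 120, seed = 1, dir = NULL) {
  stopifnot(gene_len %% 3 == 0, gene_len >= 9)
  with_seed(seed, {
    code <- Biostrings::GENETIC_CODE
    sense <- names(code)[code != "*"]
    stops <- c("TAA", "TAG", "TGA")
    chrom <- "G1"
    seq_parts <- character(0)
    cursor <- 0L
    rows <- list(); cds_seqs <- character(0)
    spacer_len <- 150L
    for (i in seq_len(n_genes)) {
      n_cod <- gene_len / 3
      cds <- paste0("ATG",
                    paste(sample(setdiff(sense, "ATG"), n_cod - 2,
                                 replace = TRUE), collapse = ""),
                    sample(stops, 1))
      gid <- sprintf("gene%03d", i)
      strand <- if (i %% 2 == 0) "-" else "+"
      two_exon <- i %% 3 == 0
      spacer <- paste(sample(c("A", "C", "G", "T"), spacer_len,
                             replace = TRUE), collapse = "")
      seq_parts <- c(seq_parts, spacer)
      cursor <- cursor + spacer_len
      if (two_exon) {
        cut <- 3 * sample(seq(2, n_cod - 2), 1)  # codon boundary
        ex1 <- substr(cds, 1, cut)
        ex2 <- substr(cds, cut + 1, gene_len)
        intron <- paste0("GT",
                         paste(sample(c("A", "C", "T"), intron_len - 4,
                                      replace = TRUE), collapse = ""),
                         "AG")
        genomic <- paste0(ex1, intron, ex2)
        ## on the minus strand the whole gene is reverse-complemented, so
        ## the low-coordinate exon is the (reversed) LAST coding exon
        lo <- if (strand == "-") nchar(ex2) else nchar(ex1)
        iv <- data.frame(gene_id = gid, chrom = chrom,
                         start = cursor + c(1, lo + intron_len + 1),
                         end = cursor + c(lo, nchar(genomic)),
                         strand = strand)
      } else {
        genomic <- cds
        iv <- data.frame(gene_id = gid, chrom = chrom,
                         start = cursor + 1, end = cursor + gene_len,
                         strand = strand)
      }
      if (strand == "-")
        genomic <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(genomic)))
      seq_parts <- c(seq_parts, genomic)
      cursor <- cursor + nchar(genomic)
      rows[[i]] <- iv
      cds_seqs[gid] <- cds
    }
    reference <- setNames(paste(seq_parts, collapse = ""), chrom)
    cds_model <- do.call(rbind, rows)
    validate_cds_model(cds_model)
    out <- list(reference = reference, cds_model = cds_model,
                cds_seqs = cds_seqs)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      fa <- file.path(dir, "genes.fa")
      gff <- file.path(dir, "genes.gff3")
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(reference), fa)
      lines <- c("##gff-version 3",
                 sprintf("%s\terosionscope\tCDS\t%d\t%d\t.\t%s\t0\tID=cds_%s;Parent=%s",
                         cds_model$chrom, cds_model$start, cds_model$end,
                         cds_model$strand, cds_model$gene_id,
                         cds_model$gene_id))
      writeLines(lines, gff)
      out$paths <- c(fasta = fa, gff = gff)
    }
    out
  })
}

#' Add post-mortem deamination-style genotype damage
#'
#' Mimics C-to-T (and G-to-A) miscalls in degraded historical samples: at
#' sites whose alleles are a C/T (G/A) pair, each C (G) allele call flips
#' to the damaged base with the given probability, moving genotypes
#' toward the T (A) allele. Rates of 0 are the identity; plausible rates
#' for museum material are below a few percent.
#'
#' @param gm a [genotype_matrix].
#' @param ct_rate,ga_rate per-allele flip probabilities in `[0, 0.05]`.
#' @param seed integer seed.
#' @param samples sample ids to damage (default all).
#' @return list with `gm` (damaged) and `truth` (data.frame of flipped
#'   calls: `sample_id`, `chrom`, `pos`, `n_flipped`).
#' @export
add_postmortem_damage <- function(gm, ct_rate, ga_rate = ct_rate,
                                  seed = 1, samples = gm$sample_ids) {
  stopifnot(ct_rate >= 0, ct_rate <= 0.05, ga_rate >= 0, ga_rate <= 0.05)
  with_seed(seed, {
    ref <- gm$sites$ref; alt <- gm$sites$alt
    dmg_dir <- integer(nrow(gm$sites))  # +1: flips raise g, -1: lower g
    rate <- numeric(nrow(gm$sites))
    ct_up <- ref == "C" & alt == "T"; ct_dn <- ref == "T" & alt == "C"
    ga_up <- ref == "G" & alt == "A"; ga_dn <- ref == "A" & alt == "G"
    dmg_dir[ct_up] <- 1L; dmg_dir[ct_dn] <- -1L
    dmg_dir[ga_up] <- 1L; dmg_dir[ga_dn] <- -1L
    rate[ct_up | ct_dn] <- ct_rate
    rate[ga_up | ga_dn] <- ga_rate
    rows <- match(samples, gm$sample_ids)
    truth <- list()
    for (i in rows) {
      g <- gm$geno[i, ]
      elig <- dmg_dir != 0L & !is.na(g)
      src <- ifelse(dmg_dir == 1L, 2L - g, g)  # undamaged-base alleles
      n_flip <- integer(length(g))
      idx <- which(elig & src > 0L)
      if (length(idx))
        n_flip[idx] <- rbinom(length(idx), src[idx], rate[idx])
      g2 <- g + dmg_dir * n_flip
      gm$geno[i, ] <- pmin(2L, pmax(0L, g2))
      flipped <- which(n_flip > 0L)
      if (length(flipped))
        truth[[length(truth) + 1L]] <-
          data.frame(sample_id = gm$sample_ids[i],
                     chrom = gm$sites$chrom[flipped],
                     pos = gm$sites$pos[flipped],
                     n_flipped = n_flip[flipped],
                     stringsAsFactors = FALSE)
    }
    list(gm = gm,
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), n_flipped = integer()))
  })
}
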