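test_that("polarization follows the strict majority-plus-outgroup rule", {
  ## 10 ingroup diploids, 1 outgroup
  g_in <- matrix(0L, 10, 3)
  g_in[7:10, 1] <- 1L          # 6/10 hom-ref -> ancestral ref
  g_in[6:10, 2] <- 2L          # exactly 5/10 hom-ref -> unpolarized
  g_in[, 3] <- 2L              # all hom-alt -> ancestral alt
  gm_in <- make_gm(g_in, pos = c(100, 200, 300))
  gm_out <- make_gm(matrix(c(0L, 0L, 2L), 1, 3), pos = c(100, 200, 300))
  pol <- polarize(gm_in, gm_out)
  expect_equal(pol$ancestral, c("ref", "unpolarized", "alt"))
  expect_equal(pol$derived, c("G", NA, "A"))
  ## heterozygous outgroup blocks polarization
  gm_out2 <- make_gm(matrix(c(1L, 0L, 2L), 1, 3), pos = c(100, 200, 300))
  expect_equal(polarize(gm_in, gm_out2)$ancestral[1], "unpolarized")
  ## site absent from outgroup -> unpolarized, not an error
  gm_out3 <- make_gm(matrix(0L, 1, 1), pos = 100)
  pol3 <- polarize(gm_in, gm_out3)
  expect_equal(pol3$ancestral, c("ref", "unpolarized", "unpolarized"))
  ## omitting the outgroup entirely is an explicit error
  expect_error(polarize(gm_in, NULL), "outgroup genotypes are required")
})

test_that("Grantham lookups match the published distances", {
  expect_equal(grantham_score("L", "I"), 5L)
  expect_equal(grantham_score("C", "W"), 215L)
  expect_equal(grantham_score("Ser", "Phe"), 155L)
  expect_equal(grantham_score("A", "A"), 0L)
  ## symmetry over random pairs
  set.seed(2)
  aas <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")
  a1 <- sample(aas, 30, TRUE); a2 <- sample(aas, 30, TRUE)
  expect_equal(grantham_score(a1, a2), grantham_score(a2, a1))
  expect_error(grantham_score("X", "A"), "non-standard")
  expect_error(grantham_score("*", "A"), "non-standard")
  expect_match(grantham_checksum(), "^[0-9a-f]{32}$")
})

test_that("consequence classification handles the canonical codon cases", {
  ## single-exon plus-strand gene: ATG | GAA | CTT | TCT | ... | TAA
  cds <- paste0("ATG", "GAA", "CTT", "TCT", "TGC", "TAA")
  ref <- setNames(paste0(strrep("T", 10), cds, strrep("T", 10)), "c1")
  model <- data.frame(gene_id = "g1", chrom = "c1", start = 11,
                      end = 10 + nchar(cds), strand = "+")
  ann <- annotate_consequence(
    data.frame(chrom = "c1",
               pos = c(14, 19, 21, 11, 26, 9),
               ref = c("G", "T", "C", "A", "T", "T"),
               alt = c("T", "C", "T", "G", "G", "A")),
    model, ref)
  ## GAA -> TAA stop gained; CTT -> CTC synonymous; TCT -> TTT missense
  expect_equal(ann$consequence,
               c("stop_gained", "synonymous", "missense", "start_lost",
                 "stop_lost", "noncoding"))
  expect_equal(ann$grantham[3], 155L)
  expect_equal(ann$aa_ref[3], "S")
  expect_equal(ann$aa_alt[3], "F")
})

test_that("minus-strand and splice-region variants classify correctly", {
  gmod <- generate_gene_models(n_genes = 9, gene_len = 300, seed = 5)
  cm <- gmod$cds_model
  minus <- unique(cm$gene_id[cm$strand == "-"])[1]
  iv <- cm[cm$gene_id == minus, ]
  ## genomic base at the last position of a minus-strand gene = first CDS base
  pos <- max(iv$end)
  base <- substr(gmod$reference, pos, pos)
  expect_equal(unname(erosionscope:::complement_base(base)),
               unname(substr(gmod$cds_seqs[minus], 1, 1)))
  ## intronic position 1 bp after a donor exon end -> splice_site
  two_exon <- names(which(table(cm$gene_id) == 2))[1]
  iv2 <- cm[cm$gene_id == two_exon, ]
  iv2 <- iv2[order(iv2$start), ]
  splice_pos <- iv2$end[1] + 1
  b <- substr(gmod$reference, splice_pos, splice_pos)
  ann <- annotate_consequence(
    data.frame(chrom = "G1", pos = splice_pos, ref = b,
               alt = setdiff(c("A", "C", "G", "T"), b)[1]),
    cm, gmod$reference)
  expect_equal(ann$consequence, "splice_site")
  ## CDS not divisible by 3 is rejected
  bad <- cm; bad$end[1] <- bad$end[1] + 1
  expect_error(annotate_consequence(data.frame(chrom = "G1", pos = 1,
                                               ref = "A", alt = "C"),
                                    bad, gmod$reference),
               "divisible by 3")
})

test_that("classification boundaries: LOF set, GS > 150 strict", {
  expect_equal(classify_site("stop_gained"), "LOF")
  expect_equal(classify_site("splice_site"), "LOF")
  expect_equal(classify_site("missense", 155L), "deleterious_missense")
  expect_equal(classify_site("missense", 150L), "tolerated")
  expect_equal(classify_site("synonymous"), "synonymous")
  expect_equal(classify_site("noncoding"), "excluded")
})

test_that("individual load ratio counts derived alleles, including hom-ref at alt-ancestral sites", {
  ## 5 deleterious sites; sample genotypes: 3 hom-derived + 2 het -> 0.6
  g <- matrix(c(2L, 2L, 1L, 1L, 0L), 1, 5)
  gm <- make_gm(g, pos = (1:5) * 100)
  ann <- data.frame(chrom = "chr1", pos = (1:5) * 100,
                    ancestral = c("ref", "ref", "ref", "ref", "alt"),
                    derived = c("G", "G", "G", "G", "A"),
                    category = "LOF")
  out <- individual_load(gm, ann, "s1", "LOF")
  ## sites 1,2 hom-alt-derived; site 5 hom-REF where ref is derived
  expect_equal(out$n_hom_derived, 3L)
  expect_equal(out$n_het, 2L)
  expect_equal(out$load_ratio, 0.6)
  ## all het -> ratio 0
  ann2 <- transform(ann, ancestral = "ref")
  g2 <- matrix(1L, 1, 5)
  gm2 <- make_gm(g2, pos = (1:5) * 100)
  expect_equal(individual_load(gm2, ann2, "s1", "LOF")$load_ratio, 0)
  ## no qualifying sites -> undefined and flagged
  ann3 <- transform(ann, category = "synonymous")
  out3 <- individual_load(gm, ann3, "s1", "LOF")
  expect_true(is.na(out3$load_ratio))
  expect_false(out3$defined)
  ## unpolarized sites drop out of the denominator
  ann4 <- ann; ann4$ancestral[1:2] <- "unpolarized"
  out4 <- individual_load(gm, ann4, "s1", "LOF")
  expect_equal(out4$n_hom_derived + out4$n_het, 3L)
})

test_that("load ratio is invariant under site permutation", {
  set.seed(9)
  g <- matrix(sample(0:2, 40, TRUE), 1, 40)
  ann <- data.frame(chrom = "chr1", pos = (1:40) * 50,
                    ancestral = sample(c("ref", "alt"), 40, TRUE),
                    derived = "G", category = "deleterious_missense")
  gm <- make_gm(g, pos = (1:40) * 50)
  base <- individual_load(gm, ann, "s1", "deleterious_missense")
  for (i in 1:3) {
    perm <- sample(40)
    gm_p <- make_gm(g[, perm, drop = FALSE], pos = ((1:40) * 50)[perm])
    out <- individual_load(gm_p, ann[perm, ], "s1",
                           "deleterious_missense")
    expect_equal(out$load_ratio, base$load_ratio)
    expect_true(out$load_ratio >= 0 && out$load_ratio <= 1)
  }
})

test_that("median load ratio rises with the generator's selfing rate", {
  ## seed-averaged directional check across a selfing gradient
  rates <- c(0, 0.45, 0.9)
  meds <- sapply(1:6, function(sd) {
    vapply(seq_along(rates), function(k) {
      cc <- cohort_config(populations = list(
        P = list(ne = c(60, 60, 60), epoch_gens = c(4, 4, 10),
                 samples = c(2, 2, 10), selfing = c(0, 0, rates[k]))),
        n_sites = 500, n_chrom = 4, frac_lof = 0.1, frac_missense = 0.15)
      co <- generate_cohort(cc, seed = 900 + 31 * sd)
      post <- co$meta$sample_id[co$meta$period == "post-2000"]
      tr <- co$truth$site
      ann <- data.frame(chrom = tr$chrom, pos = tr$pos,
                        ancestral = "ref", derived = co$gm$sites$alt,
                        category = c(LOF = "LOF",
                                     missense = "deleterious_missense",
                                     synonymous = "synonymous",
                                     neutral = "excluded")[tr$class])
      lr <- vapply(post, function(s)
        individual_load(co$gm, ann, s,
                        "deleterious_missense")$load_ratio, 0)
      median(lr, na.rm = TRUE)
    }, 0)
  })
  avg <- rowMeans(meds)
  expect_true(avg[1] < avg[2] && avg[2] < avg[3])
})
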