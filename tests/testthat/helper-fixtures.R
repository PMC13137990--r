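## Shared fixtures and independent oracles for the test suite.

## Write a small VCF text file and return its path.
write_toy_vcf <- function(records, samples = c("s1", "s2"),
                          contigs = c(chr1 = 1e6),
                          info_fields = c("DP", "QD", "MQ")) {
  path <- tempfile(fileext = ".vcf")
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                      as.integer(contigs)),
              sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"x\">",
                      info_fields),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", samples),
                    collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gts, qual = 50,
                       info = "DP=20;QD=10;MQ=50") {
  paste(c(chrom, pos, ".", ref, alt, qual, "PASS", info, "GT", gts),
        collapse = "\t")
}

## Quick in-memory genotype matrix.
make_gm <- function(geno, pos, chrom = "chr1", ref = "A", alt = "G",
                    samples = paste0("s", seq_len(nrow(geno))), ...) {
  genotype_matrix(geno,
                  data.frame(chrom = chrom, pos = pos,
                             ref = rep_len(ref, length(pos)),
                             alt = rep_len(alt, length(pos)),
                             stringsAsFactors = FALSE),
                  samples, ...)
}

## O(n^2) pairwise-difference oracle for nucleotide diversity: mean
## proportion of differing allele pairs per site, summed over sites.
pi_pairwise_oracle <- function(geno) {
  total <- 0
  for (j in seq_len(ncol(geno))) {
    g <- geno[, j]
    alleles <- unlist(lapply(g[!is.na(g)], function(x)
      switch(x + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))))
    n <- length(alleles)
    if (n < 2) next
    diff <- 0
    for (a in seq_len(n - 1))
      for (b in seq((a + 1), n))
        diff <- diff + (alleles[a] != alleles[b])
    total <- total + diff / choose(n, 2)
  }
  total
}

## Brute-force enumeration oracle for the two-sided rank-sum p-value.
ranksum_oracle <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  rk <- rank(pooled)
  U_obs <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(length(pooled), m)
  us <- apply(combs, 2, function(ix) sum(rk[ix]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(us <= U_obs), mean(us >= U_obs)))
}

## Full-translation oracle: classify a coding SNP by translating the
## whole CDS before and after the substitution.
translate_oracle <- function(cds_before, cds_after) {
  code <- Biostrings::GENETIC_CODE
  tr <- function(s) {
    n <- nchar(s) %/% 3
    vapply(seq_len(n), function(i)
      code[[substr(s, 3 * i - 2, 3 * i)]], "")
  }
  a <- tr(cds_before); b <- tr(cds_after)
  d <- which(a != b)
  if (substr(cds_after, 1, 3) != "ATG") return("start_lost")
  if (!length(d)) return("synonymous")
  if (a[d] == "*") return("stop_lost")
  if (b[d] == "*") return("stop_gained")
  "missense"
}

## A small registry for fitness identity checks.
toy_registry <- function(s, h, nonsyn = rep(TRUE, length(s))) {
  reg <- new.env(parent = emptyenv())
  reg$n <- length(s); reg$s <- s; reg$h <- h; reg$nonsyn <- nonsyn
  reg$gene <- rep(1L, length(s)); reg$pos <- seq_along(s)
  reg$class <- rep("strong", length(s))
  reg
}
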