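#' Build the simulated genome architecture
#'
#' Distributes `n_genes` genes of `gene_len` bp over the chromosomes in
#' proportion to chromosome length using largest-remainder apportionment,
#' then places each chromosome's genes end-to-end separated by uniform
#' spacers. Recombination acts only between adjacent genes on the same
#' chromosome; chromosomes assort freely.
#'
#' @param chrom_lengths numeric vector of chromosome lengths in bp
#'   (default: 19 equal chromosomes sized to fit the gene complement).
#' @param n_genes total number of genes.
#' @param gene_len gene length in bp (default 1500).
#' @return object of class `genome_map`: list with `chrom` (data.frame
#'   `length`, `n_genes`), `genes` (data.frame `chrom`, `start`, `end`),
#'   `n_genes`, `gene_len`, `coding_len`.
#' @export
build_genome <- function(chrom_lengths = NULL, n_genes = 20000,
                         gene_len = 1500) {
  stopifnot(n_genes >= 1, gene_len >= 3)
  if (is.null(chrom_lengths))
    chrom_lengths <- rep(ceiling(n_genes / 19) * gene_len * 2, 19)
  share <- n_genes * chrom_lengths / sum(chrom_lengths)
  counts <- floor(share)
  rem <- n_genes - sum(counts)
  if (rem > 0) {
    extra <- order(share - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  if (any(counts * gene_len > chrom_lengths))
    stop("chromosome too short for its gene allocation")
  genes <- do.call(rbind, lapply(seq_along(chrom_lengths), function(c) {
    k <- counts[c]
    if (k == 0) return(NULL)
    spacer <- floor((chrom_lengths[c] - k * gene_len) / (k + 1))
    start <- spacer + (seq_len(k) - 1) * (gene_len + spacer) + 1
    data.frame(chrom = c, start = start, end = start + gene_len - 1)
  }))
  structure(list(chrom = data.frame(length = chrom_lengths,
                                    n_genes = counts),
                 genes = genes, n_genes = n_genes, gene_len = gene_len,
                 coding_len = n_genes * gene_len),
            class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("<genome_map> %d genes x %d bp on %d chromosomes (%.3g bp coding)\n",
              x$n_genes, x$gene_len, nrow(x$chrom), x$coding_len))
  invisible(x)
}
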