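#' Polarize alleles into ancestral and derived states
#'
#' A site's ancestral allele is the allele X for which (i) strictly more
#' than 50% of the genotyped ingroup individuals are homozygous X, and
#' (ii) every genotyped outgroup individual is homozygous X. Sites failing
#' either condition, absent from the outgroup, or without genotyped
#' outgroup individuals are reported `unpolarized` (they are excluded from
#' load statistics downstream, not an error). The derived allele is the
#' other allele.
#'
#' @param gm_ingroup a [genotype_matrix] of the focal species.
#' @param gm_outgroup a [genotype_matrix] of outgroup individual(s);
#'   matched to the ingroup by (chrom, pos); alleles must agree.
#' @return data.frame with `chrom`, `pos`, `ancestral` in
#'   `{"ref", "alt", "unpolarized"}` and `derived` (allele character or
#'   `NA`), one row per ingroup site.
#' @export
polarize <- function(gm_ingroup, gm_outgroup) {
  if (is.null(gm_outgroup))
    stop("outgroup genotypes are required for polarization; ",
         "supply an outgroup genotype_matrix")
  si <- gm_ingroup$sites; so <- gm_outgroup$sites
  key_i <- paste(si$chrom, si$pos)
  key_o <- paste(so$chrom, so$pos)
  m <- match(key_i, key_o)
  gi <- gm_ingroup$geno
  n_geno <- colSums(!is.na(gi))
  f_homref <- colSums(gi == 0L, na.rm = TRUE) / pmax(n_geno, 1L)
  f_homalt <- colSums(gi == 2L, na.rm = TRUE) / pmax(n_geno, 1L)
  anc <- rep("unpolarized", nrow(si))
  has_og <- !is.na(m)
  if (any(has_og)) {
    go <- gm_outgroup$geno[, m[has_og], drop = FALSE]
    n_og <- colSums(!is.na(go))
    og_all_ref <- n_og > 0 & colSums(go == 0L, na.rm = TRUE) == n_og
    og_all_alt <- n_og > 0 & colSums(go == 2L, na.rm = TRUE) == n_og
    ## allele identity check when the outgroup carries allele columns
    same <- so$ref[m[has_og]] == si$ref[has_og] &
      so$alt[m[has_og]] == si$alt[has_og]
    og_all_ref <- og_all_ref & same
    og_all_alt <- og_all_alt & same
    idx <- which(has_og)
    anc[idx[f_homref[idx] > 0.5 & og_all_ref]] <- "ref"
    anc[idx[f_homalt[idx] > 0.5 & og_all_alt]] <- "alt"
  }
  derived <- ifelse(anc == "ref", si$alt,
                    ifelse(anc == "alt", si$ref, NA_character_))
  data.frame(chrom = si$chrom, pos = si$pos, ancestral = anc,
             derived = derived, stringsAsFactors = FALSE)
}
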