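#' Build a per-site load annotation table
#'
#' Combines polarization with consequence annotation in the
#' ancestral-to-derived direction: where the derived allele is ALT the
#' usual REF->ALT consequence applies; where the derived allele is REF the
#' substitution is evaluated ALT->REF (the ALT allele is the ancestral
#' codon state). Unpolarized sites carry category `excluded`.
#'
#' @param gm a [genotype_matrix] (ingroup).
#' @param polarization output of [polarize()] for the same sites.
#' @param cds_model,reference_seq gene models and sequence as in
#'   [annotate_consequence()].
#' @return data.frame with `chrom`, `pos`, `ancestral`, `derived`,
#'   `consequence`, `grantham`, `category`.
#' @export
annotate_sites <- function(gm, polarization, cds_model, reference_seq) {
  si <- gm$sites
  stopifnot(nrow(si) == nrow(polarization))
  swap <- polarization$ancestral == "alt"
  ## For ALT-ancestral sites the reference sequence carries the DERIVED
  ## base, so the REF->ALT annotation is mirrored: codon-level classes are
  ## direction-symmetric (synonymous/missense, same Grantham distance)
  ## except stop gain/loss, which swap roles.
  ann_fwd <- annotate_consequence(
    data.frame(chrom = si$chrom, pos = si$pos, ref = si$ref, alt = si$alt,
               stringsAsFactors = FALSE), cds_model, reference_seq)
  cons <- ann_fwd$consequence
  cons[swap & ann_fwd$consequence == "stop_gained"] <- "stop_lost"
  cons[swap & ann_fwd$consequence == "stop_lost"] <- "stop_gained"
  category <- classify_site(cons, ann_fwd$grantham)
  category[polarization$ancestral == "unpolarized"] <- "excluded"
  data.frame(chrom = si$chrom, pos = si$pos,
             ancestral = polarization$ancestral,
             derived = polarization$derived,
             consequence = cons, grantham = ann_fwd$grantham,
             category = category, stringsAsFactors = FALSE)
}

#' Realized genetic-load ratio of one individual
#'
#' Counts genotypes carrying the DERIVED allele at polarized sites of the
#' requested category and returns `load_ratio = n_hom_derived /
#' (n_hom_derived + n_het)`. Counting is polarization-driven: at sites
#' where the REF allele is derived, homozygous-reference genotypes count
#' as homozygous derived. Sites that are unpolarized, of another category,
#' or ungenotyped in this sample are excluded from the denominator. When
#' no qualifying site exists the ratio is `NA` with `defined = FALSE`.
#'
#' @param gm a [genotype_matrix].
#' @param annotations site table from [annotate_sites()].
#' @param sample sample id.
#' @param category one of `"LOF"`, `"deleterious_missense"`,
#'   `"synonymous"`.
#' @return one-row data.frame: `sample_id`, `category`, `n_hom_derived`,
#'   `n_het`, `load_ratio`, `defined`.
#' @export
individual_load <- function(gm, annotations, sample,
                            category = c("LOF", "deleterious_missense",
                                         "synonymous")) {
  category <- match.arg(category)
  idx <- match(sample, gm$sample_ids)
  if (is.na(idx)) stop("unknown sample id: ", sample)
  ## align annotations to sites by coordinate, not row order
  m <- match(paste(gm$sites$chrom, gm$sites$pos),
             paste(annotations$chrom, annotations$pos))
  if (anyNA(m)) stop("annotations missing for some sites")
  annotations <- annotations[m, , drop = FALSE]
  use <- annotations$category == category &
    annotations$ancestral != "unpolarized"
  g <- gm$geno[idx, use]
  anc <- annotations$ancestral[use]
  ok <- !is.na(g)
  hom_der <- sum(ok & ((anc == "ref" & g == 2L) | (anc == "alt" & g == 0L)))
  het <- sum(ok & g == 1L)
  denom <- hom_der + het
  data.frame(sample_id = sample, category = category,
             n_hom_derived = hom_der, n_het = het,
             load_ratio = if (denom > 0) hom_der / denom else NA_real_,
             defined = denom > 0, stringsAsFactors = FALSE)
}

#' Load ratios for all samples and categories
#'
#' @param gm a [genotype_matrix].
#' @param annotations site table from [annotate_sites()].
#' @param categories categories to compute (default all three).
#' @return data.frame, one row per sample x category.
#' @export
cohort_load <- function(gm, annotations,
                        categories = c("LOF", "deleterious_missense",
                                       "synonymous")) {
  out <- lapply(categories, function(cat)
    do.call(rbind, lapply(gm$sample_ids, function(s)
      individual_load(gm, annotations, s, cat))))
  do.call(rbind, out)
}
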