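#' Read gene models (CDS intervals) from a GFF3 file
#'
#' Loads `CDS` features from the 9 standard GFF3 columns into the flat
#' interval table consumed by [annotate_consequence()]. The gene id is
#' taken from the `Parent` attribute (falling back to `ID`).
#'
#' @param path GFF3 file.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end` (1-based,
#'   inclusive), `strand`.
#' @export
read_gene_models <- function(path) {
  g <- read.delim(path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE,
                  col.names = c("chrom", "source", "type", "start", "end",
                                "score", "strand", "phase", "attr"))
  g <- g[g$type == "CDS", , drop = FALSE]
  get_tag <- function(attr, tag) {
    m <- regmatches(attr, regexec(paste0("(^|;)", tag, "=([^;]+)"), attr))
    vapply(m, function(x) if (length(x) == 3) x[3] else NA_character_, "")
  }
  gene_id <- get_tag(g$attr, "Parent")
  gene_id[is.na(gene_id)] <- get_tag(g$attr[is.na(gene_id)], "ID")
  data.frame(gene_id = gene_id, chrom = g$chrom, start = g$start,
             end = g$end, strand = g$strand, stringsAsFactors = FALSE)
}

validate_cds_model <- function(cds_model) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  stopifnot(all(need %in% names(cds_model)))
  len <- tapply(cds_model$end - cds_model$start + 1, cds_model$gene_id, sum)
  bad <- names(len)[len %% 3 != 0]
  if (length(bad))
    stop("CDS length not divisible by 3 for gene(s): ",
         paste(bad, collapse = ", "))
  invisible(cds_model)
}

as_ref_seqs <- function(reference_seq) {
  if (inherits(reference_seq, "DNAStringSet")) return(reference_seq)
  Biostrings::DNAStringSet(unlist(reference_seq))
}

## CDS nucleotide sequence of one gene, 5'->3' in coding orientation.
gene_cds_seq <- function(iv, refs) {
  iv <- iv[order(iv$start), , drop = FALSE]
  chrseq <- refs[[iv$chrom[1]]]
  parts <- lapply(seq_len(nrow(iv)), function(k)
    Biostrings::subseq(chrseq, iv$start[k], iv$end[k]))
  s <- do.call(Biostrings::xscat, parts)
  if (iv$strand[1] == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

complement_base <- function(b) chartr("ACGT", "TGCA", b)

#' Annotate coding consequences of SNPs
#'
#' Minimal SnpEff-style classifier for single-nucleotide variants against a
#' CDS model: the affected codon is translated before and after the change
#' and classified as `synonymous`, `missense`, `stop_gained`, `stop_lost`
#' or `start_lost`; intronic positions within 2 bp of an exon boundary are
#' `splice_site`; everything else is `noncoding`. Minus-strand genes are
#' handled by complementing alleles into coding orientation. Missense
#' calls also carry the Grantham distance of the substitution.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`
#'   (single bases; `ref` must match the reference sequence).
#' @param cds_model CDS interval table as from [read_gene_models()].
#' @param reference_seq named character vector or `DNAStringSet` of
#'   chromosome sequences.
#' @return `variants` with added columns `consequence`, `gene_id`,
#'   `aa_ref`, `aa_alt`, `grantham` (`NA` unless missense).
#' @export
annotate_consequence <- function(variants, cds_model, reference_seq) {
  validate_cds_model(cds_model)
  refs <- as_ref_seqs(reference_seq)
  code <- Biostrings::GENETIC_CODE
  genes <- split(cds_model, cds_model$gene_id)
  cds_seq <- lapply(genes, gene_cds_seq, refs = refs)

  n <- nrow(variants)
  consequence <- rep("noncoding", n)
  gene_hit <- rep(NA_character_, n)
  aa_ref <- aa_alt <- rep(NA_character_, n)
  gs <- rep(NA_integer_, n)

  for (i in seq_len(n)) {
    chrom <- variants$chrom[i]; pos <- variants$pos[i]
    hit <- NULL
    for (gid in names(genes)) {
      iv <- genes[[gid]]
      if (iv$chrom[1] != chrom) next
      if (any(pos >= iv$start & pos <= iv$end)) { hit <- gid; break }
      ## splice region: within 2 bp of an internal exon boundary
      if (nrow(iv) > 1) {
        iv_o <- iv[order(iv$start), ]
        donors <- iv_o$end[-nrow(iv_o)]
        accept <- iv_o$start[-1]
        if (any((pos > donors & pos <= donors + 2) |
                (pos < accept & pos >= accept - 2))) {
          consequence[i] <- "splice_site"; gene_hit[i] <- gid
          hit <- NA; break
        }
      }
    }
    if (is.null(hit) || is.na(hit)) next
    iv <- genes[[hit]][order(genes[[hit]]$start), , drop = FALSE]
    strand <- iv$strand[1]
    lens <- iv$end - iv$start + 1
    k <- which(pos >= iv$start & pos <= iv$end)[1]
    plus_pos <- sum(lens[seq_len(k - 1)]) + (pos - iv$start[k] + 1)
    cdspos <- if (strand == "+") plus_pos else sum(lens) - plus_pos + 1
    seq <- cds_seq[[hit]]
    ref_b <- variants$ref[i]; alt_b <- variants$alt[i]
    if (strand == "-") { ref_b <- complement_base(ref_b)
                         alt_b <- complement_base(alt_b) }
    if (substr(seq, cdspos, cdspos) != ref_b) {
      warning("reference mismatch at ", chrom, ":", pos, "; skipped")
      next
    }
    ci <- (cdspos - 1) %/% 3
    cod_ref <- substr(seq, ci * 3 + 1, ci * 3 + 3)
    off <- (cdspos - 1) %% 3 + 1
    cod_alt <- cod_ref
    substr(cod_alt, off, off) <- alt_b
    a_ref <- code[[cod_ref]]; a_alt <- code[[cod_alt]]
    gene_hit[i] <- hit; aa_ref[i] <- a_ref; aa_alt[i] <- a_alt
    consequence[i] <-
      if (ci == 0 && cod_alt != "ATG") "start_lost"
      else if (a_ref == "*" && a_alt != "*") "stop_lost"
      else if (a_ref != "*" && a_alt == "*") "stop_gained"
      else if (a_ref == a_alt) "synonymous"
      else "missense"
    if (consequence[i] == "missense")
      gs[i] <- grantham_score(a_ref, a_alt)
  }
  variants$consequence <- consequence
  variants$gene_id <- gene_hit
  variants$aa_ref <- aa_ref
  variants$aa_alt <- aa_alt
  variants$grantham <- gs
  variants
}

#' Classify an annotated site into a load category
#'
#' Loss-of-function (LOF) = premature stop, lost stop or start, or splice
#' disruption; missense with Grantham score strictly greater than 150 =
#' `deleterious_missense` (a score of exactly 150 is `tolerated`);
#' synonymous variants form their own load category; everything else is
#' `tolerated` (coding) or `excluded` (noncoding / unscored).
#'
#' @param consequence character vector of consequence labels.
#' @param grantham integer Grantham scores (`NA` unless missense).
#' @return character vector of categories in `{"LOF",
#'   "deleterious_missense", "synonymous", "tolerated", "excluded"}`.
#' @export
classify_site <- function(consequence, grantham = NA_integer_) {
  lof <- c("stop_gained", "stop_lost", "start_lost", "splice_site")
  out <- rep("excluded", length(consequence))
  out[consequence %in% lof] <- "LOF"
  mis <- consequence == "missense"
  out[mis & !is.na(grantham) & grantham > 150] <- "deleterious_missense"
  out[mis & !is.na(grantham) & grantham <= 150] <- "tolerated"
  out[consequence == "synonymous"] <- "synonymous"
  out
}
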