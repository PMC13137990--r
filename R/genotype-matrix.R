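#' Genotype matrix: samples x biallelic SNPs
#'
#' The central empirical container: an integer matrix of diploid genotype
#' codes (0 hom-ref, 1 het, 2 hom-alt, `NA` missing) with per-site
#' coordinates, alleles and numeric INFO annotations. All sites are
#' biallelic SNPs; positions are 1-based and strictly increasing within a
#' chromosome (internal window arithmetic is half-open `[start, end)`).
#'
#' @param geno integer matrix, samples in rows, sites in columns; values in
#'   `{0, 1, 2, NA}`.
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `qual`, `dp` plus further numeric annotation columns.
#' @param sample_ids character vector, one per row of `geno`.
#' @param contigs optional named numeric vector of contig lengths (bp).
#' @param n_excluded number of non-biallelic / non-SNP records dropped on
#'   ingestion.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sites, sample_ids, contigs = NULL,
                            n_excluded = 0L) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (length(sample_ids) < 1) stop("at least one sample required")
  if (nrow(geno) != length(sample_ids))
    stop("geno rows must match sample_ids")
  if (ncol(geno) != nrow(sites)) stop("geno columns must match sites rows")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype codes must be 0, 1, 2 or NA")
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (nrow(sites)) {
    ord <- order(sites$chrom, sites$pos)
    sites <- sites[ord, , drop = FALSE]
    geno <- geno[, ord, drop = FALSE]
    dup <- stats::ave(sites$pos, sites$chrom,
                      FUN = function(p) c(1L, diff(p)))
    if (any(dup <= 0L))
      stop("positions must be strictly increasing within a chromosome")
  }
  rownames(sites) <- NULL
  rownames(geno) <- sample_ids
  structure(list(geno = geno, sites = sites,
                 sample_ids = as.character(sample_ids),
                 contigs = contigs, n_excluded = as.integer(n_excluded)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d sites on %d chromosome(s)\n",
              length(x$sample_ids), nrow(x$sites),
              length(unique(x$sites$chrom))))
  if (x$n_excluded > 0)
    cat(sprintf("  %d non-biallelic/non-SNP records excluded at read\n",
                x$n_excluded))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by samples and/or sites
#'
#' @param gm a [genotype_matrix].
#' @param samples character vector of sample ids or integer indices.
#' @param sites integer or logical index over site columns.
#' @return a [genotype_matrix].
#' @export
subset_gm <- function(gm, samples = NULL, sites = NULL) {
  geno <- gm$geno; sdf <- gm$sites; ids <- gm$sample_ids
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, ids) else samples
    if (anyNA(idx)) stop("unknown sample id: ",
                         paste(samples[is.na(idx)], collapse = ", "))
    geno <- geno[idx, , drop = FALSE]; ids <- ids[idx]
  }
  if (!is.null(sites)) {
    geno <- geno[, sites, drop = FALSE]
    sdf <- sdf[sites, , drop = FALSE]
  }
  genotype_matrix(geno, sdf, ids, contigs = gm$contigs,
                  n_excluded = gm$n_excluded)
}

info_meta_line <- function(k) {
  sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">", k, k)
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF (plain or gzipped) via \pkg{vcfR}, keeps biallelic SNP
#' records only (single-base REF and ALT, no comma in ALT), converts GT
#' fields to diploid dosage codes, and pulls QUAL plus every numeric INFO
#' annotation into the site table. Multiallelic and non-SNP records are
#' dropped and counted in `$n_excluded`.
#'
#' @param vcf_path path to a VCF file.
#' @param sample_subset optional character vector of sample ids to keep.
#' @return a [genotype_matrix].
#' @export
read_genotypes <- function(vcf_path, sample_subset = NULL) {
  if (!file.exists(vcf_path)) stop("cannot read VCF: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- v@fix
  all_samples <- colnames(v@gt)[-1]
  if (!is.null(sample_subset)) {
    missing_ids <- setdiff(sample_subset, all_samples)
    if (length(missing_ids))
      stop("unknown sample id: ", paste(missing_ids, collapse = ", "))
  }
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  ok <- !is.na(alt) & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  n_excluded <- sum(!ok)
  if (!any(ok)) stop_empty("no biallelic SNP records retained from VCF")
  v <- v[ok, ]
  fix <- v@fix
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  code[gt %in% c("0/0")] <- 0L
  code[gt %in% c("0/1", "1/0")] <- 1L
  code[gt %in% c("1/1")] <- 2L
  geno <- t(code)
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
                      stringsAsFactors = FALSE)
  ## numeric INFO tags declared in the header
  tags <- regmatches(v@meta, regexec("^##INFO=<ID=([^,]+)", v@meta))
  tags <- vapply(tags[lengths(tags) == 2], `[`, "", 2)
  for (k in tags) {
    val <- suppressWarnings(
      vcfR::extract.info(v, element = k, as.numeric = TRUE))
    if (!all(is.na(val))) sites[[tolower(k)]] <- val
  }
  if (!is.null(sites$dp)) sites$dp <- as.numeric(sites$dp)
  contigs <- parse_contigs(v@meta)
  gm <- genotype_matrix(geno, sites, all_samples, contigs = contigs,
                        n_excluded = n_excluded)
  if (!is.null(sample_subset)) gm <- subset_gm(gm, samples = sample_subset)
  gm
}

parse_contigs <- function(meta) {
  m <- regmatches(meta,
                  regexec("^##contig=<ID=([^,>]+),length=([0-9]+)", meta))
  m <- m[lengths(m) == 3]
  if (!length(m)) return(NULL)
  setNames(as.numeric(vapply(m, `[`, "", 3)), vapply(m, `[`, "", 2))
}

#' Write a genotype matrix to VCF (4.2, gzipped)
#'
#' Emits GT-only genotype records plus the numeric site annotations as INFO
#' fields; contig lengths, when known, go into the header. Round-trips
#' genotype codes exactly through [read_genotypes()].
#'
#' @param gm a [genotype_matrix].
#' @param path output path; \pkg{vcfR} writes gzip, so use `.vcf.gz`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  n_sites <- nrow(gm$sites)
  meta <- c("##fileformat=VCFv4.2",
            "##source=erosionscope")
  if (!is.null(gm$contigs))
    meta <- c(meta, sprintf("##contig=<ID=%s,length=%d>",
                            names(gm$contigs), as.integer(gm$contigs)))
  ann_cols <- setdiff(names(gm$sites), c("chrom", "pos", "ref", "alt", "qual"))
  meta <- c(meta, vapply(toupper(ann_cols), info_meta_line, ""),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  info <- rep(".", n_sites)
  if (length(ann_cols)) {
    parts <- lapply(ann_cols, function(k) {
      val <- gm$sites[[k]]
      ifelse(is.na(val), NA_character_,
             paste0(toupper(k), "=", format(val, trim = TRUE,
                                            scientific = FALSE)))
    })
    info <- apply(do.call(cbind, parts), 1, function(r)
      if (all(is.na(r))) "." else paste(r[!is.na(r)], collapse = ";"))
  }
  qual <- if (is.null(gm$sites$qual)) rep(".", n_sites) else
    ifelse(is.na(gm$sites$qual), ".",
           format(gm$sites$qual, trim = TRUE, scientific = FALSE))
  fix <- cbind(CHROM = gm$sites$chrom, POS = as.character(gm$sites$pos),
               ID = rep(".", n_sites), REF = gm$sites$ref,
               ALT = gm$sites$alt, QUAL = qual,
               FILTER = rep("PASS", n_sites), INFO = info)
  gt_chr <- matrix("./.", nrow = n_sites, ncol = length(gm$sample_ids))
  g <- t(gm$geno)
  gt_chr[!is.na(g) & g == 0L] <- "0/0"
  gt_chr[!is.na(g) & g == 1L] <- "0/1"
  gt_chr[!is.na(g) & g == 2L] <- "1/1"
  colnames(gt_chr) <- gm$sample_ids
  gt <- cbind(FORMAT = rep("GT", n_sites), gt_chr)
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}
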