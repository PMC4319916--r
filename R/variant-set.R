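#' Construct a variant set
#'
#' Container for a table of biallelic variant calls: a site table plus
#' per-sample genotype and quality-passing read-depth matrices, matching
#' the information content of a VCF with GT and AD fields. An `"unknown"`
#' genotype (no supporting reads in a sample) is coded `NA`.
#'
#' @param sites data frame with columns `chrom`, `pos` (1-based, indels
#'   left-anchored with the anchor base in `ref`), `ref`, `alt`, `class`
#'   (`"SNP"` or `"indel"`).
#' @param gt integer matrix (variants x samples) of alt-allele counts
#'   0/1/2, `NA` = unknown.
#' @param ad_ref,ad_alt integer matrices of quality-passing reads
#'   supporting the reference / alternate allele.
#' @return a `variant_set` object.
#' @export
variant_set <- function(sites, gt, ad_ref, ad_alt) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "class") %in% names(sites)),
            all(sites$ref != sites$alt),
            all(sites$class %in% c("SNP", "indel")),
            nrow(gt) == nrow(sites), all(dim(ad_ref) == dim(gt)),
            all(dim(ad_alt) == dim(gt)), !is.null(colnames(gt)))
  is_indel <- nchar(sites$ref) != nchar(sites$alt)
  if (!all(is_indel == (sites$class == "indel")))
    stop("variant class must be 'indel' exactly when allele lengths differ")
  if (length(ad_ref) && min(ad_ref, ad_alt) < 0)
    stop("read counts must be >= 0")
  dimnames(ad_ref) <- dimnames(ad_alt) <- dimnames(gt)
  if (is.null(sites$gene)) sites$gene <- NA_character_
  structure(list(sites = sites, gt = gt, ad_ref = ad_ref, ad_alt = ad_alt),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("Variant set:", nrow(x$sites), "variants (",
      sum(x$sites$class == "SNP"), "SNPs,",
      sum(x$sites$class == "indel"), "indels ) x",
      ncol(x$gt), "samples\n")
  invisible(x)
}

#' Number of variants in a variant set
#' @param vs a [variant_set()].
#' @return integer count.
#' @export
n_variants <- function(vs) nrow(vs$sites)

# Row subset preserving all slots
subset_variants <- function(vs, keep) {
  variant_set(vs$sites[keep, , drop = FALSE],
              vs$gt[keep, , drop = FALSE],
              vs$ad_ref[keep, , drop = FALSE],
              vs$ad_alt[keep, , drop = FALSE])
}

variant_key <- function(sites) paste(sites$chrom, sites$pos, sites$ref,
                                     sites$alt, sep = ":")

#' Write a variant set as VCF
#'
#' Emits a minimal VCF v4.2 with per-sample `GT:AD` fields (AD =
#' quality-passing reads supporting ref,alt), suitable for downstream
#' consumption by standard VCF tooling.
#'
#' @param vs a [variant_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path) {
  stopifnot(inherits(vs, "variant_set"))
  samples <- colnames(vs$gt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=scdmap",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0('##FORMAT=<ID=AD,Number=R,Type=Integer,Description=',
           '"Quality-passing read depths for the ref and alt alleles">'),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[vs$gt + 1L], nrow = nrow(vs$gt))
  gt_str[is.na(vs$gt)] <- "./."
  cells <- matrix(paste0(gt_str, ":", vs$ad_ref, ",", vs$ad_alt),
                  nrow = nrow(vs$gt))
  body <- vapply(seq_len(nrow(vs$sites)), function(i) {
    paste(c(vs$sites$chrom[i], vs$sites$pos[i], ".", vs$sites$ref[i],
            vs$sites$alt[i], ".", "PASS", ".", "GT:AD", cells[i, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write exon intervals as BED
#'
#' Converts 1-based inclusive exon intervals to BED's 0-based half-open
#' convention; the name column is `<gene_id>_exon<n>`.
#'
#' @param gene_models gene-model data frame (one row per exon) as produced
#'   by [simulate_gene_models()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gene_models, path) {
  df <- data.frame(gene_models$chrom, gene_models$exon_start - 1L,
                   gene_models$exon_end,
                   paste0(gene_models$gene_id, "_exon", gene_models$exon))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
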