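#' Drop variants with no quality-passing read support
#'
#' Upstream variant calling admits only reads and bases of Phred quality
#' >= 20, so the read-depth matrices already count quality-passing
#' evidence only. A per-sample call with zero supporting reads overall is
#' marked unknown (`NA` genotype); records with no evidence in any sample
#' are dropped. An audit count is attached as `attr(, "audit")`.
#'
#' @param vs a [variant_set()].
#' @param min_quality documented Phred threshold applied upstream (kept as
#'   metadata; counts are assumed pre-thresholded).
#' @return the filtered [variant_set()].
#' @export
filter_by_quality <- function(vs, min_quality = 20) {
  stopifnot(inherits(vs, "variant_set"))
  total <- vs$ad_ref + vs$ad_alt
  vs$gt[total == 0L] <- NA_integer_
  keep <- rowSums(total) > 0L
  out <- subset_variants(vs, keep)
  attr(out, "audit") <- list(filter = "quality", min_quality = min_quality,
                             n_input = length(keep), n_retained = sum(keep),
                             n_removed = sum(!keep))
  out
}

#' Keep variants homozygous-alt in every genotyped affected sample
#'
#' A fully penetrant recessive causal variant must be homozygous for the
#' non-reference allele in every affected individual. Unknown genotypes
#' (no supporting reads) do not disqualify a variant, but at least one
#' affected sample must have a known genotype.
#'
#' @param vs a [variant_set()].
#' @param affected character vector of affected sample ids (must be
#'   columns of `vs`).
#' @return the filtered [variant_set()] with an `attr(, "audit")` count.
#' @export
homozygous_alt_in_affecteds <- function(vs, affected) {
  stopifnot(inherits(vs, "variant_set"))
  if (!length(affected)) stop("no affected sample ids supplied")
  if (!all(affected %in% colnames(vs$gt)))
    stop("affected ids absent from the variant table: ",
         paste(setdiff(affected, colnames(vs$gt)), collapse = ", "))
  g <- vs$gt[, affected, drop = FALSE]
  # zero-read calls are unknown whether or not the quality filter ran first
  g[(vs$ad_ref + vs$ad_alt)[, affected, drop = FALSE] == 0L] <- NA_integer_
  known <- rowSums(!is.na(g)) > 0L
  all_hom <- rowSums(g != 2L, na.rm = TRUE) == 0L
  keep <- known & all_hom
  out <- subset_variants(vs, keep)
  attr(out, "audit") <- list(filter = "hom_alt_affected",
                             n_input = length(keep),
                             n_retained = sum(keep), n_removed = sum(!keep))
  out
}

# 1-based inclusive interval of reference bases a variant changes.
# VCF-style left anchor: SNP = its own base; deletion = the deleted bases
# after the anchor; insertion = the two bases flanking the insertion point.
affected_interval <- function(sites) {
  nref <- nchar(sites$ref); nalt <- nchar(sites$alt)
  start <- ifelse(nref > nalt, sites$pos + 1,        # deletion: past anchor
           ifelse(nalt > nref, sites$pos, sites$pos))
  end <- ifelse(nref > nalt, sites$pos + nref - 1,
         ifelse(nalt > nref, sites$pos + 1, sites$pos))
  data.frame(start = start, end = end)
}

#' Retain exonic variants and attach gene ids
#'
#' Keeps variants whose affected reference bases (for indels, the changed
#' bases excluding the left anchor) overlap an exon; interval arithmetic
#' is 1-based inclusive, so a variant on an exon boundary base is
#' retained. The overlapped gene id is written to the `gene` column of the
#' site table.
#'
#' @param vs a [variant_set()].
#' @param gene_models exon table from [simulate_gene_models()] (or any
#'   data frame with `gene_id`, `chrom`, `exon_start`, `exon_end`).
#' @return the filtered, gene-annotated [variant_set()].
#' @export
intersect_exons <- function(vs, gene_models) {
  stopifnot(inherits(vs, "variant_set"))
  iv <- affected_interval(vs$sites)
  hits <- rep(NA_character_, nrow(iv))
  for (chr in unique(vs$sites$chrom)) {
    vi <- which(vs$sites$chrom == chr)
    gm <- gene_models[gene_models$chrom == chr, ]
    if (!length(vi) || !nrow(gm)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(iv$start[vi], iv$end[vi]),
      IRanges::IRanges(gm$exon_start, gm$exon_end))
    first <- !duplicated(S4Vectors::queryHits(ov))
    hits[vi[S4Vectors::queryHits(ov)[first]]] <-
      gm$gene_id[S4Vectors::subjectHits(ov)[first]]
  }
  keep <- !is.na(hits)
  vs$sites$gene <- hits
  out <- subset_variants(vs, keep)
  attr(out, "audit") <- list(filter = "exonic", n_input = length(keep),
                             n_retained = sum(keep), n_removed = sum(!keep))
  out
}

#' Map a candidate region through synteny blocks
#'
#' Projects the region onto the target genome: every block overlapping the
#' region contributes the linearly interpolated image of the overlap,
#' respecting block orientation (a `-` block reverses the direction of the
#' interpolation within the target interval).
#'
#' @param region a [candidate_region()].
#' @param blocks synteny-block data frame (`source_chrom`, `source_start`,
#'   `source_end`, `target_chrom`, `target_start`, `target_end`,
#'   `orientation`).
#' @return data frame of target intervals (`target_chrom`, `start`, `end`)
#'   with the originating block index in `block`.
#' @export
map_synteny <- function(region, blocks) {
  stopifnot(inherits(region, "candidate_region"), !region$empty)
  if (any(blocks$source_end <= blocks$source_start))
    stop("malformed synteny block: zero-length source interval")
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    if (b$source_chrom != region$chrom) next
    lo <- max(region$start, b$source_start)
    hi <- min(region$end, b$source_end)
    if (lo > hi) next
    f1 <- (lo - b$source_start) / (b$source_end - b$source_start)
    f2 <- (hi - b$source_start) / (b$source_end - b$source_start)
    tw <- b$target_end - b$target_start
    t12 <- if (b$orientation == "+") {
      b$target_start + c(f1, f2) * tw
    } else {
      b$target_end - c(f2, f1) * tw
    }
    out[[length(out) + 1L]] <- data.frame(
      target_chrom = b$target_chrom, start = round(t12[1]),
      end = round(t12[2]), block = i)
  }
  if (!length(out))
    return(data.frame(target_chrom = character(), start = numeric(),
                      end = numeric(), block = integer()))
  do.call(rbind, out)
}

#' Restrict genes by model-organism phenotype annotation
#'
#' Case-insensitive substring matching of the query terms over free-text
#' phenotype annotations (mirroring a manual genome-browser phenotype
#' query); genes with at least one matching term are returned.
#'
#' @param genes candidate gene ids.
#' @param annotations data frame with `gene_id`, `phenotype_term`.
#' @param terms character vector of query substrings (non-empty).
#' @return character vector of retained gene ids.
#' @export
phenotype_restrict <- function(genes, annotations, terms) {
  if (!length(terms)) stop("empty phenotype term set")
  ann <- annotations[annotations$gene_id %in% genes, ]
  hit <- Reduce(`|`, lapply(tolower(terms), function(tm)
    grepl(tm, tolower(ann$phenotype_term), fixed = TRUE)))
  unique(ann$gene_id[hit])
}

#' Exclude candidates observed homozygous in other cohorts
#'
#' Drops variants seen in the homozygous-alt state in any sample of an
#' exclusion cohort (e.g. whole-genome datasets of unaffected dogs of
#' other breeds), keyed by `(chrom, pos, ref, alt)`.
#'
#' @param vs a [variant_set()].
#' @param exclusion data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   and optionally `genotype` (rows with anything other than `"hom_mut"`
#'   are ignored; missing column means all rows are homozygous
#'   observations).
#' @return the filtered [variant_set()] with an `attr(, "audit")` count.
#' @export
exclude_cross_cohort <- function(vs, exclusion) {
  stopifnot(inherits(vs, "variant_set"))
  if (is.null(exclusion) || !nrow(exclusion)) {
    attr(vs, "audit") <- list(filter = "cross_cohort",
                              n_input = nrow(vs$sites),
                              n_retained = nrow(vs$sites), n_removed = 0L)
    return(vs)
  }
  if (!is.null(exclusion$genotype))
    exclusion <- exclusion[exclusion$genotype == "hom_mut", ]
  drop <- variant_key(vs$sites) %in% variant_key(exclusion)
  out <- subset_variants(vs, !drop)
  attr(out, "audit") <- list(filter = "cross_cohort", n_input = length(drop),
                             n_retained = sum(!drop), n_removed = sum(drop))
  out
}

#' Run the full candidate-variant filter cascade
#'
#' Applies, in order: quality-evidence filter, homozygous-alt-in-affecteds
#' filter, exon intersection, restriction to genes with a matching
#' model-organism phenotype annotation, and cross-cohort exclusion. The
#' per-stage audit (input = retained + removed at every stage) is
#' returned alongside the surviving variants.
#'
#' @param vs a [variant_set()].
#' @param affected affected sample ids.
#' @param gene_models exon table.
#' @param annotations phenotype annotation table.
#' @param terms phenotype query substrings.
#' @param exclusion optional cross-cohort exclusion table.
#' @return list with `variants` (surviving [variant_set()]), `genes`
#'   (phenotype-restricted gene ids) and `audit` (data frame of per-stage
#'   counts).
#' @export
filter_cascade <- function(vs, affected, gene_models, annotations,
                           terms, exclusion = NULL) {
  stages <- list()
  note <- function(x) {
    a <- attr(x, "audit")
    stages[[length(stages) + 1L]] <<- as.data.frame(
      a[c("filter", "n_input", "n_retained", "n_removed")])
    x
  }
  v1 <- note(filter_by_quality(vs))
  v2 <- note(homozygous_alt_in_affecteds(v1, affected))
  v3 <- note(intersect_exons(v2, gene_models))
  genes <- phenotype_restrict(unique(v3$sites$gene), annotations, terms)
  v4 <- subset_variants(v3, v3$sites$gene %in% genes)
  stages[[length(stages) + 1L]] <- data.frame(
    filter = "phenotype_gene", n_input = nrow(v3$sites),
    n_retained = nrow(v4$sites), n_removed = nrow(v3$sites) - nrow(v4$sites))
  v5 <- note(exclude_cross_cohort(v4, exclusion))
  list(variants = v5, genes = genes, audit = do.call(rbind, stages))
}
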