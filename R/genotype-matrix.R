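#' Construct a genotype matrix
#'
#' Markers x samples matrix of alternate-allele counts (0/1/2, `NA` =
#' missing call) with a marker map and optional case/control labels.
#'
#' @param geno integer matrix, markers in rows (rownames = marker ids),
#'   samples in columns (colnames = sample ids).
#' @param map data frame with columns `marker`, `chrom`, `pos` (1-based bp),
#'   one row per marker, sorted by `(chrom, pos)`.
#' @param status optional named character vector (`"case"` / `"control"`)
#'   covering all samples.
#' @return a `genotype_matrix` object.
#' @export
genotype_matrix <- function(geno, map, status = NULL) {
  stopifnot(is.matrix(geno), !is.null(rownames(geno)), !is.null(colnames(geno)),
            all(c("marker", "chrom", "pos") %in% names(map)),
            nrow(map) == nrow(geno), all(map$marker == rownames(geno)))
  o <- order(map$chrom, map$pos)
  if (!all(o == seq_len(nrow(map)))) stop("marker map must be sorted by (chrom, pos)")
  rng <- range(geno, na.rm = TRUE)
  stopifnot(rng[1] >= 0, rng[2] <= 2)
  if (!is.null(status)) {
    stopifnot(all(colnames(geno) %in% names(status)),
              all(status %in% c("case", "control")))
    status <- status[colnames(geno)]
  }
  structure(list(geno = geno, map = map, status = status),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$geno), "markers x", ncol(x$geno), "samples\n")
  if (!is.null(x$status))
    cat("  cases:", sum(x$status == "case"),
        " controls:", sum(x$status == "control"), "\n")
  cat("  chromosomes:", paste(unique(x$map$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a genotype matrix by sample
#'
#' @param g a [genotype_matrix()].
#' @param ids sample ids to keep, in order.
#' @param status optional replacement case/control labels for the subset.
#' @return a [genotype_matrix()].
#' @export
subset_samples <- function(g, ids, status = NULL) {
  stopifnot(inherits(g, "genotype_matrix"), all(ids %in% colnames(g$geno)))
  genotype_matrix(g$geno[, ids, drop = FALSE], g$map,
                  status = status %||% g$status[ids])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a PED/MAP file pair
#'
#' Standard two-file genotype exchange format: `<prefix>.map` holds the
#' marker map (chrom, marker id, genetic position 0, bp) and
#' `<prefix>.ped` one row per sample (family, id, sire, dam, sex,
#' phenotype, then two allele columns per marker; allele 1 = reference,
#' allele 2 = alternate, 0 0 = missing).
#'
#' @param g a [genotype_matrix()].
#' @param ped a [pedigree()] covering the samples of `g`.
#' @param prefix path prefix for the `.ped`/`.map` pair.
#' @return `write_ped_map()` returns `prefix` invisibly; `read_ped_map()`
#'   returns a list with elements `genotypes` (a [genotype_matrix()] whose
#'   status labels affected samples as cases) and `pedigree`.
#' @export
write_ped_map <- function(g, ped, prefix) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(ped, "pedigree"))
  map <- data.frame(g$map$chrom, g$map$marker, 0L, g$map$pos)
  write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  samples <- colnames(g$geno)
  pd <- ped[match(samples, ped$id), ]
  sex_code <- c(male = 1L, female = 2L)[pd$sex]
  sex_code[is.na(sex_code)] <- 0L
  ph_code <- c(unaffected = 1L, affected = 2L, unknown = 0L)[pd$phenotype]
  allele_strings <- c("1\t1", "1\t2", "2\t2")
  lines <- vapply(seq_along(samples), function(j) {
    a <- allele_strings[g$geno[, j] + 1L]
    a[is.na(a)] <- "0\t0"
    paste(c("FAM1", samples[j],
            ifelse(is.na(pd$sire[j]), "0", pd$sire[j]),
            ifelse(is.na(pd$dam[j]), "0", pd$dam[j]),
            sex_code[j], ph_code[j], a), collapse = "\t")
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' @rdname write_ped_map
#' @export
read_ped_map <- function(prefix) {
  map <- read.table(paste0(prefix, ".map"), sep = "\t",
                    col.names = c("chrom", "marker", "cm", "pos"))
  pedtab <- read.table(paste0(prefix, ".ped"), sep = "\t",
                       stringsAsFactors = FALSE)
  m <- nrow(map)
  stopifnot(ncol(pedtab) == 6 + 2 * m)
  a1 <- as.matrix(pedtab[, 6 + seq(1, 2 * m, 2), drop = FALSE])
  a2 <- as.matrix(pedtab[, 6 + seq(2, 2 * m, 2), drop = FALSE])
  geno <- t((a1 == 2) + (a2 == 2))
  geno[t(a1 == 0 | a2 == 0)] <- NA
  storage.mode(geno) <- "integer"
  rownames(geno) <- map$marker
  colnames(geno) <- pedtab[[2]]
  ped <- pedigree(data.frame(
    id = pedtab[[2]],
    sire = ifelse(pedtab[[3]] == "0", NA_character_, as.character(pedtab[[3]])),
    dam = ifelse(pedtab[[4]] == "0", NA_character_, as.character(pedtab[[4]])),
    sex = c("male", "female")[match(pedtab[[5]], 1:2)],
    phenotype = c("unknown", "unaffected", "affected")[pedtab[[6]] + 1L],
    stringsAsFactors = FALSE))
  status <- setNames(ifelse(ped$phenotype == "affected", "case", "control"),
                     ped$id)
  list(genotypes = genotype_matrix(geno, map[c("marker", "chrom", "pos")],
                                   status = status),
       pedigree = ped)
}
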