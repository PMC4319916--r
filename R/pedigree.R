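#' Construct a pedigree
#'
#' A pedigree is a data frame with one row per individual and columns
#' `id`, `sire`, `dam` (`NA` for founders), `sex` (`"male"`, `"female"` or
#' `NA`), `phenotype` (`"affected"`, `"unaffected"`, `"unknown"`) and
#' `genotype` (assay genotype at the candidate locus: `"hom_wt"`, `"het"`,
#' `"hom_mut"` or `"untyped"`).
#'
#' @param df data frame with at least `id`, `sire`, `dam`; missing
#'   `sex`/`phenotype`/`genotype` columns are filled with
#'   `NA`/`"unknown"`/`"untyped"`.
#' @return a `pedigree` object (a validated data frame).
#' @examples
#' ped <- pedigree(data.frame(
#'   id = c("s", "d", "p"), sire = c(NA, NA, "s"), dam = c(NA, NA, "d"),
#'   sex = c("male", "female", "male"),
#'   phenotype = c("unaffected", "unaffected", "affected")))
#' @export
pedigree <- function(df) {
  stopifnot(is.data.frame(df), all(c("id", "sire", "dam") %in% names(df)))
  df$id <- as.character(df$id)
  df$sire <- as.character(df$sire)
  df$dam <- as.character(df$dam)
  if (anyDuplicated(df$id)) stop("duplicate individual ids")
  if (is.null(df$sex)) df$sex <- NA_character_
  if (is.null(df$phenotype)) df$phenotype <- "unknown"
  if (is.null(df$genotype)) df$genotype <- "untyped"
  stopifnot(all(df$phenotype %in% c("affected", "unaffected", "unknown")),
            all(df$genotype %in% c(GENO_LABELS, "untyped")),
            all(is.na(df$sex) | df$sex %in% c("male", "female")))
  for (col in c("sire", "dam")) {
    known <- !is.na(df[[col]])
    if (!all(df[[col]][known] %in% df$id))
      stop("parent id not present in pedigree: ",
           paste(setdiff(df[[col]][known], df$id), collapse = ", "))
  }
  sx <- df$sex[match(df$sire, df$id)]
  dx <- df$sex[match(df$dam, df$id)]
  if (any(sx %in% "female")) stop("a sire is recorded as female")
  if (any(dx %in% "male")) stop("a dam is recorded as male")
  # no individual may be its own ancestor
  anc <- function(i, seen = character()) {
    if (i %in% seen) stop("pedigree cycle: ", i, " is its own ancestor")
    row <- df[df$id == i, ]
    for (p in c(row$sire, row$dam)) if (!is.na(p)) anc(p, c(seen, i))
    invisible(NULL)
  }
  for (i in df$id) anc(i)
  class(df) <- c("pedigree", "data.frame")
  df
}

founders <- function(ped) ped$id[is.na(ped$sire) & is.na(ped$dam)]

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree with", nrow(x), "individuals (",
      sum(is.na(x$sire) & is.na(x$dam)), "founders,",
      sum(x$phenotype == "affected"), "affected )\n")
  print.data.frame(x, ...)
  invisible(x)
}

# Allele sets transmissible by a parent with alt-allele count g
transmissible <- function(g) switch(as.character(g), `0` = 0L, `1` = c(0L, 1L), `2` = 1L)

# Genotypes a child may have given both parental genotypes
child_genotypes <- function(gs, gd) {
  unique(as.vector(outer(transmissible(gs), transmissible(gd), `+`)))
}

#' Find Mendelian-inconsistent trios
#'
#' Flags every child whose assay genotype is impossible given the genotypes
#' of both of its typed parents at a biallelic locus. Trios in which the
#' child or either parent is untyped are skipped.
#'
#' @param ped a [pedigree()].
#' @param genotypes optional named integer vector (alt-allele counts 0/1/2,
#'   names = individual ids) used in place of the pedigree's assay genotype
#'   column, e.g. one marker of a genotype matrix.
#' @return data frame with columns `id`, `sire`, `dam`, `child_g`,
#'   `sire_g`, `dam_g`; zero rows when the pedigree is consistent.
#' @export
check_mendelian <- function(ped, genotypes = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  g <- if (is.null(genotypes)) {
    setNames(geno_code(ped$genotype), ped$id)
  } else {
    stopifnot(!is.null(names(genotypes)))
    genotypes[ped$id]
  }
  bad <- list()
  for (k in seq_len(nrow(ped))) {
    id <- ped$id[k]; s <- ped$sire[k]; d <- ped$dam[k]
    if (is.na(s) || is.na(d)) next
    gc <- g[[id]]; gs <- g[[s]]; gd <- g[[d]]
    if (anyNA(c(gc, gs, gd))) next
    if (!(gc %in% child_genotypes(gs, gd)))
      bad[[length(bad) + 1L]] <- data.frame(
        id = id, sire = s, dam = d, child_g = gc, sire_g = gs, dam_g = gd,
        stringsAsFactors = FALSE)
  }
  if (!length(bad))
    return(data.frame(id = character(), sire = character(), dam = character(),
                      child_g = integer(), sire_g = integer(), dam_g = integer()))
  do.call(rbind, bad)
}

# Per-individual candidate genotype sets under a fully penetrant AR model:
# affected <=> hom-mut; unaffected therefore 0 or 1; typed assay genotypes
# constrain further.
ar_candidate_sets <- function(ped) {
  sets <- lapply(seq_len(nrow(ped)), function(k) {
    s <- switch(ped$phenotype[k],
                affected = 2L, unaffected = c(0L, 1L), unknown = 0:2)
    if (ped$genotype[k] != "untyped") s <- intersect(s, geno_code(ped$genotype[k]))
    s
  })
  setNames(sets, ped$id)
}

# Depth-first existence search: is there a full genotype assignment
# consistent with Mendelian transmission and the candidate sets, optionally
# with individual `fix_id` pinned to `fix_g`? Individuals are visited in
# pedigree (parents-first) order so each child is pruned against assigned
# parents immediately.
ar_assignment_exists <- function(ped, sets, fix_id = NULL, fix_g = NULL) {
  ids <- ped$id
  sire <- ped$sire; dam <- ped$dam
  idx <- setNames(seq_along(ids), ids)
  if (!is.null(fix_id)) {
    sets[[fix_id]] <- intersect(sets[[fix_id]], fix_g)
    if (!length(sets[[fix_id]])) return(FALSE)
  }
  assign_g <- integer(length(ids))
  recurse <- function(k) {
    if (k > length(ids)) return(TRUE)
    cand <- sets[[k]]
    s <- sire[k]; d <- dam[k]
    if (!is.na(s) && !is.na(d))
      cand <- intersect(cand, child_genotypes(assign_g[idx[[s]]], assign_g[idx[[d]]]))
    for (g in cand) {
      assign_g[k] <<- g
      if (recurse(k + 1L)) return(TRUE)
    }
    FALSE
  }
  recurse(1L)
}

#' Test autosomal recessive segregation and infer obligate carriers
#'
#' Checks whether the pedigree's phenotypes (and any assay genotypes) are
#' jointly consistent with a fully penetrant autosomal recessive model:
#' every affected individual homozygous for the risk allele, every parent of
#' an affected carrying at least one copy, and no unaffected individual
#' forced to be homozygous. Carrier status is inferred by exhaustive
#' enumeration of Mendelian-consistent genotype assignments, so obligate
#' carriers include not only parents of affecteds but any ancestor required
#' on every consistent assignment to supply the allele.
#'
#' @param ped a [pedigree()] with at least one affected individual. The
#'   pedigree must be ordered parents-before-offspring (as produced by
#'   [simulate_pedigree()] and [read_pedfile()]).
#' @return list with `verdict` (`"consistent"` / `"inconsistent"`),
#'   `obligate_carriers` (unaffected individuals heterozygous in every
#'   consistent assignment) and `possible_sources` (founders that carry the
#'   allele in at least one consistent assignment).
#' @export
test_ar_segregation <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  if (!any(ped$phenotype == "affected"))
    stop("autosomal recessive segregation test needs >= 1 affected individual")
  if (all(ped$phenotype == "unknown"))
    stop("pedigree has no phenotype data")
  sets <- ar_candidate_sets(ped)
  # parents must precede offspring for the DFS ordering
  pos <- setNames(seq_len(nrow(ped)), ped$id)
  for (k in seq_len(nrow(ped)))
    for (p in c(ped$sire[k], ped$dam[k]))
      if (!is.na(p) && pos[[p]] > k)
        stop("pedigree rows must be ordered parents before offspring")
  if (!ar_assignment_exists(ped, sets))
    return(list(verdict = "inconsistent", obligate_carriers = character(),
                possible_sources = character()))
  can_be <- function(id, g) ar_assignment_exists(ped, sets, id, g)
  unaff <- ped$id[ped$phenotype == "unaffected"]
  obligate <- unaff[vapply(unaff, function(i)
    !can_be(i, 0L) && can_be(i, 1L), logical(1))]
  fnd <- founders(ped)
  sources <- fnd[vapply(fnd, function(i) can_be(i, 1L) || can_be(i, 2L), logical(1))]
  list(verdict = "consistent", obligate_carriers = obligate,
       possible_sources = sources)
}

#' Summarise genotype-phenotype concordance and penetrance
#'
#' Cross-tabulates assay genotype against phenotype among typed individuals
#' with known phenotype, estimates penetrance as the fraction of hom-mut
#' individuals that are affected, and flags discordant individuals
#' (affected non-hom-mut or unaffected hom-mut). Unknown-phenotype
#' individuals are excluded.
#'
#' @param ped a [pedigree()] with at least one typed individual.
#' @return list with `table` (phenotype x genotype counts), `penetrance`
#'   (`NA` when no hom-mut individual is typed) and `discordant` (ids).
#' @export
genotype_phenotype_concordance <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  typed <- ped[ped$genotype != "untyped" & ped$phenotype != "unknown", ]
  if (!nrow(typed))
    return(list(table = table(factor(), factor()), penetrance = NA_real_,
                discordant = character()))
  tab <- table(factor(typed$phenotype, c("affected", "unaffected")),
               factor(typed$genotype, GENO_LABELS))
  n_hom <- sum(typed$genotype == "hom_mut")
  pen <- if (n_hom) sum(typed$genotype == "hom_mut" &
                        typed$phenotype == "affected") / n_hom else NA_real_
  disc <- typed$id[(typed$phenotype == "affected" & typed$genotype != "hom_mut") |
                   (typed$phenotype == "unaffected" & typed$genotype == "hom_mut")]
  list(table = tab, penetrance = pen, discordant = disc)
}

#' Read / write extended PED pedigree files
#'
#' The on-disk format is the conventional 6-column PED (family, individual,
#' sire, dam, sex, phenotype) extended with two columns: phenotype detail
#' (`affected`/`unaffected`/`unknown`) and assay genotype. `0` encodes a
#' missing parent; sex is 1 = male, 2 = female, 0 = unknown.
#'
#' @param ped a [pedigree()].
#' @param path file path.
#' @param family family id written to column 1.
#' @return `read_pedfile()` returns a [pedigree()]; `write_pedfile()`
#'   returns `path` invisibly.
#' @export
write_pedfile <- function(ped, path, family = "FAM1") {
  stopifnot(inherits(ped, "pedigree"))
  sex_code <- c(male = 1L, female = 2L)[ped$sex]
  sex_code[is.na(sex_code)] <- 0L
  ph_code <- c(unaffected = 1L, affected = 2L, unknown = 0L)[ped$phenotype]
  df <- data.frame(family, ped$id,
                   ifelse(is.na(ped$sire), "0", ped$sire),
                   ifelse(is.na(ped$dam), "0", ped$dam),
                   sex_code, ph_code, ped$phenotype, ped$genotype)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pedfile
#' @export
read_pedfile <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 8)
  pedigree(data.frame(
    id = as.character(df[[2]]),
    sire = ifelse(df[[3]] == "0", NA_character_, as.character(df[[3]])),
    dam = ifelse(df[[4]] == "0", NA_character_, as.character(df[[4]])),
    sex = c("male", "female")[match(df[[5]], 1:2)],
    phenotype = df[[7]], genotype = df[[8]],
    stringsAsFactors = FALSE))
}
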