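#' Construct a restriction enzyme
#'
#' @param name enzyme name.
#' @param site recognition sequence (IUPAC codes allowed, length >= 4).
#' @param offset cut position within the site on the top strand (bases
#'   from the site's 5' end to the cut point); defaults to the site
#'   midpoint when an enzyme table carries no offsets, since fragment
#'   lengths rather than cut chemistry drive a gel-based assay.
#' @return an `enzyme` object.
#' @export
enzyme <- function(name, site, offset = NULL) {
  site <- toupper(site)
  if (nchar(site) < 4) stop("recognition sequence must be >= 4 bases")
  if (is.null(offset) || is.na(offset)) offset <- nchar(site) %/% 2
  if (offset < 0 || offset > nchar(site)) stop("cut offset outside the site")
  structure(list(name = name, site = site, offset = as.integer(offset)),
            class = "enzyme")
}

#' Read an enzyme table from TSV
#'
#' Columns `name`, `site`, `offset` (offset may be `NA`). The bundled
#' table is at `system.file("extdata", "enzymes.tsv", package = "scdmap")`.
#'
#' @param path TSV path.
#' @return list of [enzyme()] objects, named by enzyme.
#' @export
read_enzyme_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    enzyme(df$name[i], df$site[i], df$offset[i]))
  setNames(out, df$name)
}

#' In-silico restriction digestion
#'
#' Scans both strands for the recognition site (IUPAC-aware), cuts at the
#' enzyme's offset (mirrored for sites on the bottom strand) and returns
#' the fragment lengths. Overlapping sites each produce a cut; fragments
#' always sum to the input length.
#'
#' @param seq DNA sequence (character, IUPAC alphabet).
#' @param enz an [enzyme()], or `NULL` for no digestion.
#' @return a `band_pattern`: integer vector of fragment lengths, sorted
#'   decreasing.
#' @export
digest <- function(seq, enz = NULL) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (is.null(enz)) return(band_pattern(n))
  stopifnot(inherits(enz, "enzyme"))
  subject <- Biostrings::DNAString(seq)
  pat <- Biostrings::DNAString(enz$site)
  fwd <- Biostrings::start(Biostrings::matchPattern(pat, subject,
                                                    fixed = FALSE))
  rcp <- Biostrings::reverseComplement(pat)
  rev <- Biostrings::start(Biostrings::matchPattern(rcp, subject,
                                                    fixed = FALSE))
  len <- nchar(enz$site)
  cuts <- sort(unique(c(fwd - 1L + enz$offset,
                        rev - 1L + (len - enz$offset))))
  cuts <- cuts[cuts > 0 & cuts < n]
  band_pattern(diff(c(0L, cuts, n)))
}

#' Band pattern
#'
#' Multiset of gel fragment lengths, stored sorted decreasing.
#'
#' @param lengths fragment lengths (bp, all > 0).
#' @return a `band_pattern` object.
#' @export
band_pattern <- function(lengths) {
  lengths <- as.integer(lengths)
  if (any(lengths <= 0)) stop("fragment lengths must be positive")
  structure(sort(lengths, decreasing = TRUE), class = "band_pattern")
}

#' @export
print.band_pattern <- function(x, ...) {
  cat("Bands:", paste(unclass(x), collapse = " / "), "bp\n")
  invisible(x)
}

#' Construct a PCR-RFLP amplicon pair
#'
#' The wild-type and mutant allele sequences of one amplicon; primers are
#' identical between alleles, so for a 1-bp deletion the mutant amplicon
#' is exactly one base shorter.
#'
#' @param wt,mut allele sequences (character).
#' @param primer_fwd,primer_rev primer coordinates within the wild-type
#'   amplicon, as `c(start, end)` (defaults: first/last 18 bases).
#' @return an `amplicon` object.
#' @export
amplicon <- function(wt, mut, primer_fwd = NULL, primer_rev = NULL) {
  wt <- toupper(wt); mut <- toupper(mut)
  nf <- primer_fwd %||% c(1L, 18L)
  nr <- primer_rev %||% c(nchar(wt) - 17L, nchar(wt))
  if (substr(wt, nf[1], nf[2]) != substr(mut, nf[1], nf[2]))
    stop("forward primer region differs between alleles")
  off <- nchar(wt) - nchar(mut)
  if (substr(wt, nr[1], nr[2]) != substr(mut, nr[1] - off, nr[2] - off))
    stop("reverse primer region differs between alleles")
  structure(list(wt = wt, mut = mut, primer_fwd = nf, primer_rev = nr,
                 wt_length = nchar(wt), mut_length = nchar(mut)),
            class = "amplicon")
}

#' Find enzymes that discriminate the two alleles
#'
#' Digests both allele sequences with every enzyme in the table and
#' returns those whose band patterns are distinguishable on a gel:
#' patterns whose fragments all co-migrate within the resolution
#' tolerance (e.g. an uncut 579 bp vs 578 bp product) do not
#' discriminate.
#'
#' @param amp an [amplicon()].
#' @param enzymes list of [enzyme()] objects (non-empty).
#' @param tolerance relative gel resolution (see [call_genotype()]).
#' @return data frame `name`, `wt_pattern`, `mut_pattern` (patterns as
#'   `/`-separated strings), with the corresponding [band_pattern()]s in
#'   `attr(, "patterns")`.
#' @export
find_discriminating_enzymes <- function(amp, enzymes, tolerance = 0.05) {
  stopifnot(inherits(amp, "amplicon"))
  if (!length(enzymes)) stop("empty enzyme table")
  pats <- lapply(enzymes, function(e)
    list(wt = digest(amp$wt, e), mut = digest(amp$mut, e)))
  differs <- vapply(pats, function(p)
    !patterns_match(p$wt, p$mut, tolerance), logical(1))
  keep <- pats[differs]
  out <- data.frame(
    name = vapply(enzymes[differs], `[[`, character(1), "name"),
    wt_pattern = vapply(keep, function(p)
      paste(unclass(p$wt), collapse = "/"), character(1)),
    mut_pattern = vapply(keep, function(p)
      paste(unclass(p$mut), collapse = "/"), character(1)),
    row.names = NULL)
  attr(out, "patterns") <- keep
  out
}

# Merge fragments whose lengths are within `tolerance` (relative) of each
# other into a single gel band; 578 vs 579 co-migrate on 1% agarose.
merge_bands <- function(lengths, tolerance) {
  lengths <- sort(as.integer(lengths), decreasing = TRUE)
  out <- integer(0)
  for (l in lengths) {
    if (length(out) && abs(out[length(out)] - l) <= tolerance * out[length(out)])
      next
    out <- c(out, l)
  }
  band_pattern(out)
}

#' Expected band patterns for the three assay genotypes
#'
#' @param amp an [amplicon()].
#' @param enz the discriminating [enzyme()].
#' @param tolerance relative gel resolution below which near-equal
#'   fragments merge into one band (default 5%).
#' @return list of [band_pattern()]s: `hom_wt`, `het`, `hom_mut`.
#' @export
expected_band_patterns <- function(amp, enz, tolerance = 0.05) {
  wt <- digest(amp$wt, enz)
  mut <- digest(amp$mut, enz)
  list(hom_wt = wt, het = merge_bands(c(wt, mut), tolerance), hom_mut = mut)
}

patterns_match <- function(observed, expected, tolerance) {
  o <- sort(as.integer(observed)); e <- sort(as.integer(expected))
  length(o) == length(e) && all(abs(o - e) <= tolerance * e)
}

#' Call a genotype from an observed band pattern
#'
#' Matches the observed fragment multiset against the expected pattern of
#' each genotype within the gel resolution tolerance; a pattern matching
#' none of the three is `"uninterpretable"`.
#'
#' @param observed a [band_pattern()] (or integer vector of lengths).
#' @param expected output of [expected_band_patterns()].
#' @param tolerance relative length tolerance.
#' @return one of `"hom_wt"`, `"het"`, `"hom_mut"`, `"uninterpretable"`.
#' @export
call_genotype <- function(observed, expected, tolerance = 0.05) {
  for (g in c("hom_wt", "hom_mut", "het"))
    if (patterns_match(observed, expected[[g]], tolerance)) return(g)
  "uninterpretable"
}

#' Genotype a cohort from band patterns and build association inputs
#'
#' Calls every sample's genotype and, using the pedigree's phenotypes,
#' assembles the case/control genotype-count triples consumed by
#' [allelic_chi2()] (affected = case, unaffected = control; samples with
#' unknown phenotype or an uninterpretable pattern are excluded from the
#' counts but listed in the call table).
#'
#' @param patterns named list of [band_pattern()]s, one per sample.
#' @param ped a [pedigree()] covering the samples.
#' @param expected output of [expected_band_patterns()].
#' @param tolerance relative length tolerance.
#' @return list with `calls` (data frame `id`, `phenotype`, `genotype`),
#'   `case_counts`, `control_counts` (each `(hom-wt, het, hom-mut)`).
#' @export
genotype_cohort <- function(patterns, ped, expected, tolerance = 0.05) {
  stopifnot(inherits(ped, "pedigree"))
  if (!length(patterns))
    return(list(calls = data.frame(id = character(), phenotype = character(),
                                   genotype = character()),
                case_counts = c(0L, 0L, 0L), control_counts = c(0L, 0L, 0L)))
  if (is.null(names(patterns)) || any(!nzchar(names(patterns))))
    stop("band patterns must be named by sample")
  empty <- vapply(patterns, function(p) length(p) == 0L, logical(1))
  if (any(empty))
    stop("sample with no band pattern: ",
         paste(names(patterns)[empty], collapse = ", "))
  calls <- data.frame(
    id = names(patterns),
    phenotype = ped$phenotype[match(names(patterns), ped$id)],
    genotype = vapply(patterns, call_genotype, character(1),
                      expected = expected, tolerance = tolerance),
    row.names = NULL)
  cnt <- function(ph) {
    g <- calls$genotype[calls$phenotype %in% ph & calls$genotype %in% GENO_LABELS]
    as.integer(table(factor(g, GENO_LABELS)))
  }
  list(calls = calls, case_counts = cnt("affected"),
       control_counts = cnt("unaffected"))
}

#' Synthetic worked-example RFLP amplicon
#'
#' Builds a synthetic 579-bp wild-type amplicon carrying a single
#' restriction site whose digestion yields 472-bp and 107-bp fragments,
#' and its 578-bp counterpart in which a 1-bp deletion inside the site
#' abolishes cutting — reproducing the geometry of the diagnostic
#' carrier-detection assay (three bands for a heterozygote). The mutant
#' allele is checked to be site-free on both strands.
#'
#' @param enz discriminating [enzyme()] (default the bundled BsrBI,
#'   CCGCTC cut after base 3).
#' @param seed deterministic construction seed.
#' @return an [amplicon()] with the deleted-base index in
#'   `attr(, "deleted_at")`.
#' @export
synthetic_rflp_amplicon <- function(enz = enzyme("BsrBI", "CCGCTC", 3), seed = 1) {
  set.seed(stage_seed(seed, "rflp_amplicon"))
  site <- enz$site
  site_start <- 107L - enz$offset + 1L  # cut after base 107
  for (try in 1:1000) {
    wt <- paste(sample(c("A", "C", "G", "T"), 579, replace = TRUE),
                collapse = "")
    wt <- paste0(substr(wt, 1, site_start - 1), site,
                 substr(wt, site_start + nchar(site), 579))
    # delete the G at site offset (destroys the site)
    del_at <- site_start + 2L
    mut <- paste0(substr(wt, 1, del_at - 1), substr(wt, del_at + 1, 579))
    ok <- identical(unclass(digest(wt, enz)), c(472L, 107L)) &&
      identical(unclass(digest(mut, enz)), 578L)
    if (ok) {
      amp <- amplicon(wt, mut)
      attr(amp, "deleted_at") <- del_at
      return(amp)
    }
  }
  stop("could not construct a clean single-site amplicon")
}
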