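#' Construct a transcript
#'
#' An mRNA with its coding span and exon structure in transcript
#' coordinates. Coding (c.) positions are 1-based with c.1 = the A of the
#' ATG, following standard HGVS convention.
#'
#' @param id transcript identifier.
#' @param mrna mRNA sequence (character, ACGT).
#' @param cds_start,cds_end CDS span in mRNA coordinates (1-based
#'   inclusive); the CDS must start with ATG, have length divisible by 3,
#'   translate without internal stops and end with a stop codon.
#' @param exon_lengths exon lengths in transcript order, summing to the
#'   mRNA length.
#' @return a `transcript` object.
#' @export
transcript <- function(id, mrna, cds_start, cds_end, exon_lengths) {
  mrna <- toupper(mrna)
  if (grepl("[^ACGT]", mrna)) stop("mRNA contains non-ACGT characters")
  stopifnot(cds_start >= 1, cds_end <= nchar(mrna), cds_start < cds_end)
  cds <- substr(mrna, cds_start, cds_end)
  if (nchar(cds) %% 3 != 0) stop("CDS length must be divisible by 3")
  if (substr(cds, 1, 3) != "ATG") stop("CDS must start with ATG")
  tr <- translate_cds(cds)
  if (!tr$terminated || 3 * (nchar(tr$protein) + 1) != nchar(cds))
    stop("wild-type CDS must translate to a single ORF ending in a stop codon")
  if (sum(exon_lengths) != nchar(mrna))
    stop("exon lengths must sum to the mRNA length")
  structure(list(id = id, mrna = mrna, cds_start = cds_start,
                 cds_end = cds_end, exon_lengths = as.integer(exon_lengths)),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat("Transcript", x$id, ":", nchar(x$mrna), "nt mRNA,",
      length(x$exon_lengths), "exons, CDS", x$cds_start, "-", x$cds_end,
      "(", (x$cds_end - x$cds_start + 1) / 3 - 1, "codons )\n")
  invisible(x)
}

#' Extract the coding sequence of a transcript
#' @param t a [transcript()].
#' @return the CDS as a character string.
#' @export
cds_sequence <- function(t) substr(t$mrna, t$cds_start, t$cds_end)

#' Translate a coding sequence
#'
#' Standard genetic code; translation stops at (and excludes) the first
#' in-frame stop codon. A sequence with no in-frame stop returns the full
#' translation flagged as non-terminated; trailing partial codons (as
#' arise after a frameshift) are ignored.
#'
#' @param cds coding sequence starting with ATG.
#' @return list with `protein` (one-letter string, stop excluded),
#'   `terminated` (logical) and `stop_codon` (codon index of the stop, or
#'   `NA`).
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds)) stop("CDS contains non-ACGT characters")
  if (substr(cds, 1, 3) != "ATG") stop("CDS must start with ATG")
  n3 <- nchar(cds) %/% 3
  codons <- substring(cds, 3 * seq_len(n3) - 2, 3 * seq_len(n3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stop_at <- which(aa == "*")[1]
  if (is.na(stop_at))
    return(list(protein = paste(aa, collapse = ""), terminated = FALSE,
                stop_codon = NA_integer_))
  list(protein = paste(aa[seq_len(stop_at - 1)], collapse = ""),
       terminated = TRUE, stop_codon = stop_at)
}

# HGVS c. edit parser: substitution c.126A>G, deletion c.126delG /
# c.124_126del(TGA), duplication c.124_126dup(TGA) / c.126dup, insertion
# c.126_127insA.
parse_hgvs_c <- function(hgvs_c) {
  x <- sub("^c\\.", "", hgvs_c)
  m <- regmatches(x, regexec("^(\\d+)([ACGT])>([ACGT])$", x))[[1]]
  if (length(m))
    return(list(type = "sub", start = as.integer(m[2]),
                end = as.integer(m[2]), ref = m[3], alt = m[4]))
  m <- regmatches(x, regexec("^(\\d+)(?:_(\\d+))?del([ACGT]*)$", x))[[1]]
  if (length(m)) {
    s <- as.integer(m[2]); e <- if (nzchar(m[3])) as.integer(m[3]) else s
    return(list(type = "del", start = s, end = e, seq = m[4]))
  }
  m <- regmatches(x, regexec("^(\\d+)(?:_(\\d+))?dup([ACGT]*)$", x))[[1]]
  if (length(m)) {
    s <- as.integer(m[2]); e <- if (nzchar(m[3])) as.integer(m[3]) else s
    return(list(type = "dup", start = s, end = e, seq = m[4]))
  }
  m <- regmatches(x, regexec("^(\\d+)_(\\d+)ins([ACGT]+)$", x))[[1]]
  if (length(m))
    return(list(type = "ins", start = as.integer(m[2]),
                end = as.integer(m[3]), seq = m[4]))
  stop("cannot parse HGVS c. description: ", hgvs_c)
}

# Right-shift a deleted/duplicated segment [s, e] to its 3'-most
# equivalent position (HGVS reporting rule).
normalize_3prime <- function(cds, s, e) {
  n <- nchar(cds)
  while (e < n && substr(cds, e + 1, e + 1) == substr(cds, s, s)) {
    s <- s + 1; e <- e + 1
  }
  c(s, e)
}

#' Apply an HGVS coding-DNA edit to a transcript
#'
#' Supports substitutions, deletions, duplications and insertions in c.
#' coordinates. Stated reference bases are verified against the CDS (a
#' mismatch signals a stale transcript). Deletions and duplications are
#' right-shifted to their 3'-most equivalent representation for
#' *reporting*; editing accepts any equivalent position.
#'
#' @param t a [transcript()].
#' @param hgvs_c edit description, e.g. `"c.126delG"`.
#' @return list with `cds` (the edited coding sequence), `hgvs_c` (the
#'   3'-normalized description) and `edit` (parsed fields incl. the length
#'   change `delta`).
#' @export
apply_cdna_variant <- function(t, hgvs_c) {
  stopifnot(inherits(t, "transcript"))
  cds <- cds_sequence(t)
  ed <- parse_hgvs_c(hgvs_c)
  n <- nchar(cds)
  if (ed$start < 1 || ed$end > n || ed$start > ed$end)
    stop("edit position outside the CDS")
  seg <- substr(cds, ed$start, ed$end)
  if (ed$type == "sub") {
    if (seg != ed$ref)
      stop("reference base mismatch at c.", ed$start, ": CDS has ", seg,
           ", description says ", ed$ref, " (stale transcript?)")
    if (ed$ref == ed$alt) {
      warning("substitution to the identical base; CDS unchanged")
      return(list(cds = cds, hgvs_c = hgvs_c,
                  edit = c(ed, list(delta = 0L))))
    }
    mut <- paste0(substr(cds, 1, ed$start - 1), ed$alt,
                  substr(cds, ed$end + 1, n))
    return(list(cds = mut, hgvs_c = hgvs_c, edit = c(ed, list(delta = 0L))))
  }
  if (ed$type %in% c("del", "dup") && nzchar(ed$seq) && seg != ed$seq)
    stop("reference sequence mismatch at c.", ed$start, "_", ed$end,
         ": CDS has ", seg, ", description says ", ed$seq,
         " (stale transcript?)")
  if (ed$type == "del") {
    mut <- paste0(substr(cds, 1, ed$start - 1), substr(cds, ed$end + 1, n))
    norm <- normalize_3prime(cds, ed$start, ed$end)
    lab <- if (norm[1] == norm[2])
      sprintf("c.%ddel%s", norm[1], substr(cds, norm[1], norm[2]))
    else sprintf("c.%d_%ddel%s", norm[1], norm[2],
                 substr(cds, norm[1], norm[2]))
    return(list(cds = mut, hgvs_c = lab,
                edit = c(ed, list(delta = -(ed$end - ed$start + 1L)))))
  }
  if (ed$type == "dup") {
    mut <- paste0(substr(cds, 1, ed$end), seg, substr(cds, ed$end + 1, n))
    norm <- normalize_3prime(cds, ed$start, ed$end)
    lab <- if (norm[1] == norm[2])
      sprintf("c.%ddup%s", norm[1], substr(cds, norm[1], norm[2]))
    else sprintf("c.%d_%ddup%s", norm[1], norm[2],
                 substr(cds, norm[1], norm[2]))
    return(list(cds = mut, hgvs_c = lab,
                edit = c(ed, list(delta = ed$end - ed$start + 1L))))
  }
  # insertion between start and end (must be adjacent positions)
  if (ed$end != ed$start + 1L)
    stop("insertion coordinates must flank adjacent bases")
  mut <- paste0(substr(cds, 1, ed$start), ed$seq, substr(cds, ed$start + 1, n))
  list(cds = mut, hgvs_c = hgvs_c,
       edit = c(ed, list(delta = nchar(ed$seq))))
}

aa3 <- function(a) {
  out <- unname(Biostrings::AMINO_ACID_CODE[strsplit(a, "")[[1]]])
  paste(out, collapse = "")
}

strip_stop <- function(p) sub("\\*+$", "", p)

#' Name the protein consequence of a coding edit
#'
#' Compares wild-type and mutant translations and emits an HGVS-style
#' protein description: `p.(=)` for identical proteins, a simple
#' substitution `p.(Arg25Trp)`, a nonsense change `p.(Gln39Ter)`, or the
#' frameshift form `p.(Thr43ProfsTer24)` where the Ter offset counts
#' codons from the first altered residue to the new stop inclusive. A
#' non-terminated mutant translation reports its Ter offset as `"?"`.
#' Trailing stop characters in either input are ignored.
#'
#' @param wt_protein,mut_protein one-letter protein strings.
#' @return list with `hgvs_p`, `first_altered`, `new_stop_index` (residue
#'   position occupied by the new stop, `NA` if none), `mutant_length`,
#'   `frameshift`.
#' @export
describe_consequence <- function(wt_protein, mut_protein) {
  wt <- strip_stop(wt_protein); mut <- strip_stop(mut_protein)
  if (identical(wt, mut))
    return(list(hgvs_p = "p.(=)", first_altered = NA_integer_,
                new_stop_index = NA_integer_, mutant_length = nchar(mut),
                frameshift = FALSE))
  wtv <- strsplit(wt, "")[[1]]; mv <- strsplit(mut, "")[[1]]
  k <- min(length(wtv), length(mv))
  diffs <- which(wtv[seq_len(k)] != mv[seq_len(k)])
  i <- if (length(diffs)) diffs[1] else k + 1L
  if (i > length(mv)) {
    # mutant is a strict prefix: premature stop with no altered residue
    return(list(hgvs_p = sprintf("p.(%s%dTer)", aa3(wtv[i]), i),
                first_altered = i, new_stop_index = i,
                mutant_length = length(mv), frameshift = FALSE))
  }
  same_tail <- length(wtv) == length(mv) &&
    (i == length(mv) || all(wtv[(i + 1):length(wtv)] == mv[(i + 1):length(mv)]))
  if (same_tail && length(diffs) == 1)
    return(list(hgvs_p = sprintf("p.(%s%d%s)", aa3(wtv[i]), i, aa3(mv[i])),
                first_altered = i, new_stop_index = NA_integer_,
                mutant_length = length(mv), frameshift = FALSE))
  # divergent downstream: frameshift-style description
  stop_idx <- length(mv) + 1L
  ter <- stop_idx - i + 1L
  list(hgvs_p = sprintf("p.(%s%d%sfsTer%s)", aa3(wtv[i]), i, aa3(mv[i]), ter),
       first_altered = i, new_stop_index = stop_idx,
       mutant_length = length(mv), frameshift = TRUE)
}

#' Apply the 50-nt rule for nonsense-mediated decay
#'
#' A premature termination codon escapes NMD when it lies in the last exon
#' or within 50 nt upstream of the final exon-exon junction; otherwise the
#' transcript is predicted to be targeted for decay. Single-exon
#' transcripts always escape.
#'
#' @param exon_lengths exon lengths (nt, transcript order) of the mRNA in
#'   which the stop is expressed — for an indel, the harbouring exon's
#'   length already adjusted ([consequence_report()] does this).
#' @param ptc_pos position of the first base of the termination codon in
#'   that mRNA (1-based).
#' @return list with `verdict` (`"escapes"` / `"targeted"`) and
#'   `distance` (nt from the PTC to the final junction, `NA` for
#'   single-exon transcripts).
#' @export
predict_nmd <- function(exon_lengths, ptc_pos) {
  total <- sum(exon_lengths)
  if (ptc_pos > total) stop("stop position beyond the mRNA length")
  if (length(exon_lengths) == 1)
    return(list(verdict = "escapes", distance = NA_real_))
  final_junction <- sum(exon_lengths[-length(exon_lengths)])
  d <- final_junction - ptc_pos
  list(verdict = if (d <= 50) "escapes" else "targeted", distance = d)
}

#' Classify protein-domain disruption by a truncating consequence
#'
#' A domain lying entirely before the first altered residue is `intact`;
#' one lying entirely at or beyond the new stop is `lost`; anything
#' overlapping the altered interval is `altered`.
#'
#' @param consequence output of [describe_consequence()].
#' @param domains data frame with `name`, `start`, `end` (1-based residue
#'   coordinates in the wild-type protein).
#' @return data frame `name`, `start`, `end`, `status`.
#' @export
domain_disruption <- function(consequence, domains) {
  stopifnot(all(domains$start <= domains$end))
  first <- consequence$first_altered
  stop_idx <- consequence$new_stop_index
  if (is.na(first)) {
    status <- rep("intact", nrow(domains))
  } else {
    if (is.na(stop_idx)) stop_idx <- Inf
    status <- ifelse(domains$end < first, "intact",
              ifelse(domains$start >= stop_idx, "lost", "altered"))
  }
  cbind(domains, status = status)
}

#' Full consequence report for a coding edit
#'
#' Applies the edit, translates wild-type and mutant, names the protein
#' consequence, evaluates the NMD 50-nt rule on the mutant mRNA (the
#' harbouring exon's length adjusted by the edit's length change) and
#' classifies domain disruption.
#'
#' @param t a [transcript()].
#' @param hgvs_c coding edit description.
#' @param domains optional domain table (see [domain_disruption()]).
#' @return list with `hgvs_c`, `wt_protein`, `mut_protein`, `consequence`,
#'   `nmd`, `domains`.
#' @export
consequence_report <- function(t, hgvs_c, domains = NULL) {
  ed <- apply_cdna_variant(t, hgvs_c)
  wt <- translate_cds(cds_sequence(t))
  mut <- translate_cds(ed$cds)
  cons <- describe_consequence(wt$protein, mut$protein)
  if (!mut$terminated && cons$frameshift) {
    # no stop before the end of the mutant sequence: Ter offset unknown
    cons$hgvs_p <- sub("fsTer\\d+", "fsTer?", cons$hgvs_p)
    cons$new_stop_index <- NA_integer_
  }
  nmd <- NULL
  if (mut$terminated) {
    exl <- t$exon_lengths
    edit_mrna_pos <- t$cds_start - 1L + ed$edit$start
    exon_of <- findInterval(edit_mrna_pos - 1, cumsum(exl)) + 1L
    exl[exon_of] <- exl[exon_of] + ed$edit$delta
    ptc_pos <- t$cds_start - 1L + 3L * nchar(mut$protein) + 1L
    nmd <- predict_nmd(exl, ptc_pos)
  }
  list(hgvs_c = ed$hgvs_c, wt_protein = wt$protein,
       mut_protein = mut$protein, consequence = cons, nmd = nmd,
       domains = if (!is.null(domains)) domain_disruption(cons, domains))
}

#' Read a transcript from FASTA plus a TSV sidecar
#'
#' The FASTA holds the mRNA; the sidecar TSV has one row with columns
#' `id`, `cds_start`, `cds_end`, `exon_lengths` (comma-separated).
#'
#' @param fasta path to the mRNA FASTA.
#' @param sidecar path to the TSV sidecar.
#' @return a [transcript()].
#' @export
read_transcript <- function(fasta, sidecar) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  meta <- read.table(sidecar, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  stopifnot(nrow(meta) == 1)
  transcript(meta$id, as.character(seqs[[1]]), meta$cds_start, meta$cds_end,
             as.integer(strsplit(meta$exon_lengths, ",")[[1]]))
}

#' Synthetic HES7-like example transcript
#'
#' A synthetic reconstruction of the canine HES7 mRNA used throughout the
#' worked examples. The true corrected mRNA is not bundled; this stand-in
#' is constructed to satisfy the published constraints exactly — a 224-
#' residue wild-type protein whose c.126delG frameshift leaves residues
#' 1-42 intact, substitutes Thr43Pro, and terminates at codon 66
#' (p.(Thr43ProfsTer24), mutant length 65) — embedded in a 4-exon,
#' 1075-nt mRNA with the deletion in exon 2.
#'
#' @return a [transcript()].
#' @export
synthetic_hes7_transcript <- function() {
  read_transcript(
    system.file("extdata", "hes7_synthetic_mrna.fasta", package = "scdmap"),
    system.file("extdata", "hes7_synthetic_transcript.tsv", package = "scdmap"))
}

#' Domain annotation for the HES7 worked example
#'
#' The two functional regions of HES7 reported from a conserved-domain
#' search of the wild-type protein: the helix-loop-helix DNA-binding
#' domain (residues 14-68) and the Hairy Orange domain (residues 91-128).
#'
#' @return data frame with `name`, `start`, `end`.
#' @export
hes7_domains <- function() {
  data.frame(name = c("HLH", "Orange"), start = c(14L, 91L),
             end = c(68L, 128L))
}
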