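toy_tx <- function(cds = "ATGCAAATAACCTGA")
  transcript("toy", cds, 1, nchar(cds), nchar(cds))

test_that("transcript construction enforces ORF invariants", {
  expect_s3_class(toy_tx(), "transcript")
  expect_error(transcript("x", "ATGAAA", 1, 6, 6), "stop codon")
  expect_error(transcript("x", "AAATGA", 1, 6, 6), "ATG")
  expect_error(transcript("x", "ATGTGAA", 1, 7, 7), "divisible")
  expect_error(transcript("x", "ATGTAA", 1, 6, 12), "sum")
})

test_that("translation stops at the first stop codon", {
  expect_equal(translate_cds("ATGTAA")$protein, "M")
  expect_equal(nchar(translate_cds("ATGTAA")$protein), 1)
  tr <- translate_cds("ATGAAATAACCTGA")  # frameshifted tail ignored
  expect_equal(tr$protein, "MK")
  expect_equal(tr$stop_codon, 3)
  open <- translate_cds("ATGAAAGGG")
  expect_false(open$terminated)
  expect_equal(open$protein, "MKG")
  expect_error(translate_cds("ATGNNN"), "non-ACGT")
})

test_that("cDNA edits apply and 3'-normalize correctly", {
  t <- toy_tx()
  # c.4delC on ATG CAA ATA ACC TGA
  ed <- apply_cdna_variant(t, "c.4delC")
  expect_equal(ed$cds, "ATGAAATAACCTGA")
  expect_equal(ed$hgvs_c, "c.4delC")
  # a deletion in a repeat run is reported at its 3'-most position
  t2 <- transcript("r", "ATGAAACCCTGA", 1, 12, 12)
  expect_equal(apply_cdna_variant(t2, "c.4delA")$hgvs_c, "c.6delA")
  # substitution, duplication, insertion
  expect_equal(apply_cdna_variant(t, "c.5A>T")$cds, "ATGCTAATAACCTGA")
  expect_equal(apply_cdna_variant(t2, "c.7dupC")$hgvs_c, "c.9dupC")
  expect_equal(nchar(apply_cdna_variant(t, "c.3_4insGG")$cds), 17)
  # reference mismatch signals a stale transcript
  expect_error(apply_cdna_variant(t, "c.4delG"), "mismatch")
  expect_error(apply_cdna_variant(t, "c.5C>T"), "mismatch")
  expect_error(apply_cdna_variant(t, "c.99delA"), "outside")
  expect_warning(apply_cdna_variant(t, "c.5A>A"), "identical")
  expect_error(apply_cdna_variant(t, "c.whatever"), "cannot parse")
})

test_that("substitution edits round-trip", {
  t <- toy_tx()
  set.seed(5)
  for (i in 1:20) {
    pos <- sample(nchar(cds_sequence(t)), 1)
    ref <- substr(cds_sequence(t), pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    fwd <- apply_cdna_variant(t, sprintf("c.%d%s>%s", pos, ref, alt))
    # reverse edit restores the original CDS
    back <- paste0(substr(fwd$cds, 1, pos - 1), ref,
                   substr(fwd$cds, pos + 1, nchar(fwd$cds)))
    expect_equal(back, cds_sequence(t))
  }
})

test_that("protein consequences are named in HGVS style", {
  # toy frameshift: MQIT vs MK
  cons <- describe_consequence("MQIT", "MK")
  expect_equal(cons$hgvs_p, "p.(Gln2LysfsTer2)")
  expect_equal(cons$first_altered, 2)
  expect_equal(cons$new_stop_index, 3)
  # identical proteins, including trailing-stop representation
  expect_equal(describe_consequence("MQIT", "MQIT")$hgvs_p, "p.(=)")
  expect_equal(describe_consequence("MQIT*", "MQIT")$hgvs_p, "p.(=)")
  # simple substitution and nonsense
  expect_equal(describe_consequence("MRA", "MKA")$hgvs_p, "p.(Arg2Lys)")
  expect_equal(describe_consequence("MRAW", "MR")$hgvs_p, "p.(Ala3Ter)")
})

test_that("fsTer arithmetic holds against a re-translation oracle", {
  set.seed(11)
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste0, collapse = "")
  nonstop <- setdiff(codons, stops)
  for (i in 1:60) {
    n_cod <- sample(10:40, 1)
    cds <- paste0("ATG", paste(sample(nonstop, n_cod, TRUE), collapse = ""),
                  "TGA")
    t <- transcript("rand", cds, 1, nchar(cds), nchar(cds))
    pos <- sample(4:(nchar(cds) - 3), 1)
    hgvs <- sprintf("c.%ddel%s", pos, substr(cds, pos, pos))
    mut <- apply_cdna_variant(t, hgvs)$cds
    # independent oracle: Biostrings translation of the trimmed frame
    n3 <- 3 * (nchar(mut) %/% 3)
    aa <- suppressWarnings(as.character(Biostrings::translate(
      Biostrings::DNAString(substr(mut, 1, n3)))))
    mut_prot <- sub("\\*.*$", "", aa)
    terminated <- grepl("\\*", aa)
    wt_prot <- translate_cds(cds_sequence(t))$protein
    cons <- describe_consequence(wt_prot, mut_prot)
    if (cons$frameshift && terminated) {
      ter <- as.integer(sub(".*fsTer(\\d+)\\)", "\\1", cons$hgvs_p))
      expect_equal(cons$new_stop_index, cons$first_altered + ter - 1)
      expect_equal(cons$new_stop_index, nchar(mut_prot) + 1)
    }
  }
})

test_that("the 50-nt rule separates NMD-targeted from escaping stops", {
  exl <- c(100, 200, 100)  # final junction at 300
  expect_equal(predict_nmd(exl, 260)$verdict, "escapes")   # 40 nt upstream
  expect_equal(predict_nmd(exl, 260)$distance, 40)
  expect_equal(predict_nmd(exl, 200)$verdict, "targeted")  # 100 nt upstream
  expect_equal(predict_nmd(exl, 350)$verdict, "escapes")   # in last exon
  expect_equal(predict_nmd(400, 100)$verdict, "escapes")   # single exon
  expect_error(predict_nmd(exl, 500), "beyond")
})

test_that("domain disruption classifies intact / altered / lost", {
  doms <- data.frame(name = c("HLH", "Orange"), start = c(14, 91),
                     end = c(68, 128))
  cons <- list(first_altered = 43, new_stop_index = 66, frameshift = TRUE)
  d <- domain_disruption(cons, doms)
  expect_equal(d$status, c("altered", "lost"))
  # frameshift starting after all domains leaves them intact
  late <- list(first_altered = 200, new_stop_index = 220, frameshift = TRUE)
  expect_equal(domain_disruption(late, doms)$status, c("intact", "intact"))
  # frameshift at 100 with a distant stop: HLH intact, Orange altered
  mid <- list(first_altered = 100, new_stop_index = 140, frameshift = TRUE)
  expect_equal(domain_disruption(mid, doms)$status, c("intact", "altered"))
})

test_that("the synthetic HES7 transcript reproduces the published consequence", {
  t <- synthetic_hes7_transcript()
  expect_equal(nchar(translate_cds(cds_sequence(t))$protein), 224)
  rep <- consequence_report(t, "c.126delG", hes7_domains())
  expect_equal(rep$consequence$hgvs_p, "p.(Thr43ProfsTer24)")
  expect_equal(rep$consequence$first_altered, 43)
  expect_equal(rep$consequence$new_stop_index, 66)
  expect_equal(rep$consequence$mutant_length, 65)
  expect_equal(substr(rep$wt_protein, 43, 43), "T")
  expect_equal(substr(rep$mut_protein, 43, 43), "P")
  expect_equal(rep$domains$status, c("altered", "lost"))
  # a PTC at codon 66 of a 4-exon transcript sits far upstream of the
  # final junction, so the rule predicts decay
  expect_equal(rep$nmd$verdict, "targeted")
  expect_gt(rep$nmd$distance, 50)
})

test_that("transcripts read from FASTA + sidecar equal the bundled object", {
  t <- read_transcript(
    system.file("extdata", "hes7_synthetic_mrna.fasta", package = "scdmap"),
    system.file("extdata", "hes7_synthetic_transcript.tsv",
                package = "scdmap"))
  expect_equal(t$exon_lengths, c(180L, 330L, 220L, 345L))
  expect_equal(nchar(t$mrna), 1075)
})
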