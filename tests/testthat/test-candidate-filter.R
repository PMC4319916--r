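test_that("variant_set validates its invariants", {
  expect_error(variant_set(data.frame(chrom = 1, pos = 1, ref = "A",
                                      alt = "A", class = "SNP"),
                           matrix(0L, 1, 1, dimnames = list(NULL, "s")),
                           matrix(1L, 1), matrix(1L, 1)))
  expect_error(variant_set(data.frame(chrom = 1, pos = 1, ref = "AG",
                                      alt = "A", class = "SNP"),
                           matrix(0L, 1, 1, dimnames = list(NULL, "s")),
                           matrix(1L, 1), matrix(1L, 1)),
               "indel")
})

test_that("quality filter drops evidence-free records and marks unknowns", {
  vs <- toy_variants()
  # variant 2: sample A1 has (0,3), sample A2 has (0,0) -> retained,
  # A2 genotype marked unknown
  out <- filter_by_quality(vs)
  i <- which(out$sites$pos == 200)
  expect_length(i, 1)
  expect_true(is.na(out$gt[i, "A2"]))
  expect_equal(unname(out$gt[i, "A1"]), 2L)

  # a record with (0,0) everywhere is dropped
  vs$ad_ref[1, ] <- 0L; vs$ad_alt[1, ] <- 0L
  out2 <- filter_by_quality(vs)
  expect_equal(n_variants(out2), 3)
  a <- attr(out2, "audit")
  expect_equal(a$n_input, a$n_retained + a$n_removed)
})

test_that("homozygous-alt filter keeps unknown-genotype affecteds as candidates", {
  vs <- filter_by_quality(toy_variants())
  out <- homozygous_alt_in_affecteds(vs, c("A1", "A2"))
  # pos 100: hom in both; pos 200: hom in A1, unknown in A2 -> both kept;
  # pos 300 het in A1 and pos 400 hom-wt in A2 -> excluded
  expect_setequal(out$sites$pos, c(100, 200))
  expect_error(homozygous_alt_in_affecteds(vs, character(0)), "no affected")
  expect_error(homozygous_alt_in_affecteds(vs, "nope"), "absent")
})

test_that("hom-alt recount matches a brute-force scan on simulated tables", {
  co <- simulate_cohort(sim_config(seed = 23, ascertain = "affected"))
  vs <- filter_by_quality(co$variants)
  aff <- co$truth$affected
  out <- homozygous_alt_in_affecteds(vs, aff)
  brute <- vapply(seq_len(n_variants(vs)), function(i) {
    g <- vs$gt[i, aff]
    any(!is.na(g)) && all(g[!is.na(g)] == 2L)
  }, logical(1))
  expect_equal(n_variants(out), sum(brute))
})

test_that("exon intersection uses 1-based inclusive affected-base arithmetic", {
  gm <- data.frame(gene_id = "G1", chrom = 1, strand = "+", exon = 1:2,
                   exon_start = c(100, 300), exon_end = c(199, 399),
                   cds_start = 100, cds_end = 399)
  mk <- function(pos, ref, alt)
    variant_set(data.frame(chrom = 1, pos = pos, ref = ref, alt = alt,
                           class = ifelse(nchar(ref) != nchar(alt),
                                          "indel", "SNP")),
                matrix(2L, 1, 1, dimnames = list(NULL, "s")),
                matrix(0L, 1), matrix(5L, 1))
  # SNP on the exon boundary base
  expect_equal(n_variants(intersect_exons(mk(199, "A", "G"), gm)), 1)
  # 1-bp deletion whose deleted base is the exon's last base
  expect_equal(n_variants(intersect_exons(mk(198, "AG", "A"), gm)), 1)
  # same deletion anchored on the last base deletes base 200: intronic
  expect_equal(n_variants(intersect_exons(mk(199, "GT", "G"), gm)), 0)
  # intronic SNP
  expect_equal(n_variants(intersect_exons(mk(250, "A", "G"), gm)), 0)
  # gene id annotation
  out <- intersect_exons(mk(350, "T", "C"), gm)
  expect_equal(out$sites$gene, "G1")
})

test_that("synteny mapping interpolates within blocks and respects orientation", {
  blocks <- data.frame(
    source_chrom = 5, source_start = c(100, 1100),
    source_end = c(1100, 2100),
    target_chrom = c("mmu9", "mmu11"),
    target_start = c(5000, 8000), target_end = c(6000, 9000),
    orientation = c("+", "-"))
  # region exactly one block
  m1 <- map_synteny(candidate_region(5, 100, 1100), blocks[1, ])
  expect_equal(c(m1$start, m1$end), c(5000, 6000))
  # half a forward block scales proportionally
  m2 <- map_synteny(candidate_region(5, 100, 600), blocks[1, ])
  expect_equal(c(m2$start, m2$end), c(5000, 5500))
  # a region spanning both blocks yields two target intervals,
  # the reverse-orientation one counted from the target end
  m3 <- map_synteny(candidate_region(5, 600, 1600), blocks)
  expect_equal(nrow(m3), 2)
  expect_equal(c(m3$start[1], m3$end[1]), c(5500, 6000))
  expect_equal(c(m3$start[2], m3$end[2]), c(8500, 9000))
  expect_error(map_synteny(candidate_region(5, 1, 10),
                           transform(blocks, source_end = source_start)),
               "zero-length")
})

test_that("phenotype restriction is case-insensitive substring matching", {
  ann <- data.frame(
    gene_id = c("HES7", "PER1", "ZZZ"),
    phenotype_term = c("Abnormal rib and vertebrae morphology",
                       "increased bone mass", "abnormal gait"))
  expect_equal(phenotype_restrict(c("HES7", "PER1", "ZZZ"), ann, "rib"),
               "HES7")
  expect_setequal(phenotype_restrict(c("HES7", "PER1", "ZZZ"), ann,
                                     c("RIB", "bone")), c("HES7", "PER1"))
  # genes with no annotation are dropped
  expect_length(phenotype_restrict("NOPE", ann, "rib"), 0)
  expect_error(phenotype_restrict("HES7", ann, character(0)), "empty")
})

test_that("cross-cohort exclusion drops homozygous hits and nothing else", {
  vs <- toy_variants()
  excl <- data.frame(chrom = 5, pos = 300, ref = "T", alt = "C",
                     genotype = "hom_mut")
  out <- exclude_cross_cohort(vs, excl)
  expect_equal(n_variants(out), 3)
  expect_false(300 %in% out$sites$pos)
  # het observations in other cohorts do not exclude
  excl$genotype <- "het"
  expect_equal(n_variants(exclude_cross_cohort(vs, excl)), 4)
  # empty exclusion set is the identity
  expect_equal(n_variants(exclude_cross_cohort(vs, NULL)), 4)
})

test_that("independent filters commute", {
  co <- simulate_cohort(sim_config(seed = 37, ascertain = "affected"))
  vs <- co$variants
  aff <- co$truth$affected
  gm <- co$gene_models
  key <- function(v) sort(scdmap:::variant_key(v$sites))
  o1 <- intersect_exons(homozygous_alt_in_affecteds(filter_by_quality(vs),
                                                    aff), gm)
  o2 <- homozygous_alt_in_affecteds(intersect_exons(filter_by_quality(vs),
                                                    gm), aff)
  o3 <- filter_by_quality(homozygous_alt_in_affecteds(
    intersect_exons(vs, gm), aff))
  expect_equal(key(o1), key(o2))
  expect_equal(key(o1), key(o3))
})

test_that("the cascade audit balances and always retains the causal deletion", {
  co <- simulate_cohort(sim_config(seed = 41, ascertain = "affected"))
  fc <- filter_cascade(co$variants, co$truth$affected, co$gene_models,
                       co$phenotypes, terms = c("rib", "vertebra"))
  expect_true(all(fc$audit$n_input == fc$audit$n_retained +
                    fc$audit$n_removed))
  expect_true(scdmap:::variant_key(co$truth$causal_variant$sites) %in%
                scdmap:::variant_key(fc$variants$sites))
  expect_true(attr(co$gene_models, "causal_gene") %in% fc$genes)
})
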