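test_that("config validation rejects impossible study conditions", {
  expect_error(sim_config(litter_size = 0), "litter_size")
  expect_error(sim_config(missing_rate = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(causal_pos = 9e9), "outside")
  expect_error(sim_config(causal_chrom = 99), "outside")
})

test_that("Mendelian transmission drives the simulated litter", {
  # carrier x carrier: each pup affected with probability 1/4
  set.seed(101)
  off <- mendelian_offspring(1L, 1L, 10000)
  frac <- mean(off$genotype == 2L)
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(frac - 0.25), 3 * se)
  # carrier x hom-wt: no affected, about half carriers
  off2 <- mendelian_offspring(1L, 0L, 10000)
  expect_equal(sum(off2$genotype == 2L), 0)
  expect_lt(abs(mean(off2$genotype == 1L) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("simulated pedigrees have the family's structure and full penetrance", {
  ped <- simulate_pedigree(sim_config(seed = 2))
  expect_s3_class(ped, "pedigree")
  # carrier x carrier proband mating and a carrier maternal grandsire
  expect_equal(ped$genotype[match(c("SIRE", "DAM", "GS_M"), ped$id)],
               rep("het", 3))
  expect_equal(ped$phenotype == "affected", ped$genotype == "hom_mut")
  expect_equal(sum(is.na(ped$sire) & is.na(ped$dam)), 5)  # founders
  # litter ascertainment
  ped3 <- simulate_pedigree(sim_config(seed = 2, ascertain = "affected",
                                       min_affected = 3))
  expect_gte(sum(ped3$phenotype == "affected"), 3)
})

test_that("truth record invariants hold", {
  ped <- simulate_pedigree(sim_config(seed = 8, ascertain = "affected"))
  tr <- truth_record(ped, sim_config(seed = 8))
  expect_true(all(ped$genotype[match(tr$affected, ped$id)] == "hom_mut"))
  parents <- unique(unlist(ped[ped$id %in% tr$affected, c("sire", "dam")]))
  expect_true(all(parents %in% c(tr$carriers, tr$affected)))
})

test_that("identical configs give byte-identical cohorts", {
  cfg <- sim_config(seed = 77, n_chromosomes = 2, n_markers_per_chrom = 80, causal_chrom = 2)
  a <- simulate_cohort(cfg, n_snps = 20, n_indels = 3)
  b <- simulate_cohort(cfg, n_snps = 20, n_indels = 3)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$genotypes$geno, b$genotypes$geno)
  expect_identical(a$variants$sites, b$variants$sites)
  expect_identical(a$variants$gt, b$variants$gt)
})

test_that("missing_rate zero gives complete genotype calls", {
  cfg <- sim_config(seed = 4, n_chromosomes = 2, n_markers_per_chrom = 50,
                    causal_chrom = 1, missing_rate = 0)
  gm <- simulate_genotypes(simulate_pedigree(cfg), cfg)
  expect_false(anyNA(gm$geno))
})

test_that("homozygous-causal individuals are homozygous at disease-haplotype tags", {
  cfg <- sim_config(seed = 9, ascertain = "affected", min_affected = 3,
                    missing_rate = 0)
  ped <- simulate_pedigree(cfg)
  gm <- simulate_genotypes(ped, cfg)
  tpl <- attr(gm, "templates")[[cfg$causal_chrom]]
  on_chrom <- gm$map$chrom == cfg$causal_chrom
  private_t1 <- tpl[1, ] == 1L & colSums(tpl[-1, , drop = FALSE]) == 0L
  near <- abs(gm$map$pos[on_chrom] - cfg$causal_pos) < 3e5
  idx <- which(on_chrom)[private_t1 & near]
  affected <- ped$id[ped$phenotype == "affected"]
  expect_gt(length(idx), 0)
  expect_true(all(gm$geno[idx, affected] == 2L))
})

test_that("simulated genotypes contain no Mendelian-inconsistent trios", {
  cfg <- sim_config(seed = 13, n_chromosomes = 3, n_markers_per_chrom = 60, causal_chrom = 2)
  ped <- simulate_pedigree(cfg)
  gm <- simulate_genotypes(ped, cfg)
  for (m in seq_len(nrow(gm$geno))) {
    v <- check_mendelian(ped, genotypes = gm$geno[m, ])
    expect_equal(nrow(v), 0)
  }
})

test_that("founder heterozygosity matches enumeration over the haplotype pool", {
  cfg <- sim_config(seed = 21, missing_rate = 0)
  ped <- simulate_pedigree(cfg)
  gm <- simulate_genotypes(ped, cfg)
  H <- cfg$founder_haplotype_count
  fnd <- ped$id[is.na(ped$sire)]
  bg <- gm$map$chrom != cfg$causal_chrom
  # background copies are uniform draws from templates 2..H, so
  # P(het) at a marker with k alt alleles among them is 2k(H-1-k)/(H-1)^2
  expected <- mean(vapply(which(unique(gm$map$chrom) != cfg$causal_chrom),
    function(cc) {
      tpl <- attr(gm, "templates")[[cc]][-1, , drop = FALSE]
      k <- colSums(tpl)
      mean(2 * k * (H - 1 - k) / (H - 1)^2)
    }, numeric(1)))
  obs <- gm$geno[bg, fnd] == 1L
  p_obs <- mean(obs)
  se <- sqrt(p_obs * (1 - p_obs) / length(obs))  # ignores block correlation
  expect_lt(abs(p_obs - expected), 3 * se + 0.02)
})

test_that("region variants include the causal deletion with the Del/Del read pattern", {
  cfg <- sim_config(seed = 31, ascertain = "affected", min_affected = 3)
  co <- simulate_cohort(cfg)
  cv <- co$truth$causal_variant
  expect_equal(cv$sites$class, "indel")
  expect_equal(nchar(cv$sites$ref) - nchar(cv$sites$alt), 1)
  # all affected samples hom-alt with zero reference-supporting reads
  expect_true(all(cv$gt == 2L))
  expect_true(all(cv$ad_ref == 0L))
  expect_true(all(cv$ad_alt > 0L))
})

test_that("only the causal deletion is emitted when no other variants requested", {
  cfg <- sim_config(seed = 15)
  genes <- simulate_gene_models(cfg)
  tr <- truth_record(simulate_pedigree(
    sim_config(seed = 15, ascertain = "affected")), cfg,
    causal_gene = attr(genes, "causal_gene"))
  vs <- simulate_region_variants(cfg, tr, genes, n_snps = 0, n_indels = 1)
  expect_equal(n_variants(vs), 1)
  expect_equal(vs$sites$pos, cfg$causal_pos - 1)
  expect_error(simulate_region_variants(cfg, tr, genes, n_snps = 1,
                                        n_indels = 0), "n_indels")
})

test_that("exonic placement matches a brute-force recount", {
  cfg <- sim_config(seed = 61)
  genes <- simulate_gene_models(cfg)
  tr <- truth_record(simulate_pedigree(
    sim_config(seed = 61, ascertain = "affected")), cfg,
    causal_gene = attr(genes, "causal_gene"))
  vs <- simulate_region_variants(cfg, tr, genes, n_snps = 980, n_indels = 20,
                                 exonic_fraction = 0.01)
  # brute-force recount of emitted records against the exon table
  iv <- vapply(seq_len(n_variants(vs)), function(i) {
    s <- vs$sites[i, ]
    del <- nchar(s$ref) > nchar(s$alt)
    lo <- if (del) s$pos + 1 else s$pos
    hi <- if (del) s$pos + nchar(s$ref) - 1 else s$pos
    any(genes$exon_start <= hi & genes$exon_end >= lo)
  }, logical(1))
  expect_equal(sum(iv), round(0.01 * 1000))
})

test_that("gene models satisfy their own invariants", {
  genes <- simulate_gene_models(sim_config(seed = 5))
  expect_equal(length(unique(genes$gene_id)), 30)
  causal <- genes[genes$gene_id == attr(genes, "causal_gene"), ]
  cfg <- sim_config(seed = 5)
  hit <- causal$exon_start <= cfg$causal_pos & causal$exon_end >= cfg$causal_pos
  expect_equal(causal$exon[hit], 2)  # causal deletion sits in exon 2
})

test_that("phenotype annotations mark the requested number of skeletal genes", {
  cfg <- sim_config(seed = 5)
  genes <- simulate_gene_models(cfg)
  ann <- simulate_phenotype_annotations(genes, cfg, n_skeletal = 19)
  skel <- phenotype_restrict(unique(genes$gene_id), ann,
                             c("rib", "vertebra", "skeletal", "kyphosis",
                               "cranium", "sternum"))
  expect_equal(length(skel), 19)
  expect_true(attr(genes, "causal_gene") %in% skel)
})

test_that("PED/MAP and VCF exports round-trip", {
  cfg <- sim_config(seed = 19, n_chromosomes = 2, n_markers_per_chrom = 40, causal_chrom = 1)
  co <- simulate_cohort(cfg, n_snps = 15, n_indels = 2)
  prefix <- file.path(withr::local_tempdir(), "cohort")
  write_ped_map(co$genotypes, co$pedigree, prefix)
  back <- read_ped_map(prefix)
  expect_identical(back$genotypes$geno, co$genotypes$geno)
  expect_equal(back$genotypes$map$pos, co$genotypes$map$pos)
  expect_equal(back$pedigree$phenotype, co$pedigree$phenotype)

  skip_if_not_installed("vcfR")
  vcf_path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(co$variants, vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  expect_equal(as.integer(v@fix[, "POS"]), as.integer(co$variants$sites$pos))
  expect_equal(v@fix[, "REF"], co$variants$sites$ref)
  expect_equal(v@fix[, "ALT"], co$variants$sites$alt)
  gt <- vcfR::extract.gt(v, element = "GT")
  coded <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)[gt]
  dim(coded) <- dim(gt)
  expect_equal(unname(coded), unname(co$variants$gt))
  ad <- vcfR::extract.gt(v, element = "AD")
  expect_equal(unname(ad[1, ]),
               unname(paste0(co$variants$ad_ref[1, ], ",",
                             co$variants$ad_alt[1, ])))
})

test_that("exported BED uses 0-based half-open coordinates", {
  genes <- simulate_gene_models(sim_config(seed = 5), n_genes = 3)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(genes, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed[[2]], genes$exon_start - 1)
  expect_equal(bed[[3]], genes$exon_end)
})
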