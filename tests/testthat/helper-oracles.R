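# Shared fixtures and independent oracles used across the suite.

# Brute-force Mendelian trio oracle: enumerate the four possible
# transmissions from the parental genotypes.
allowed_child_genotypes <- function(gs, gd) {
  halves <- function(g) if (g == 1) c(0L, 1L) else c(g %/% 2L, g %/% 2L)
  unique(as.vector(outer(halves(gs), halves(gd), `+`)))
}

# Random pedigree of <= n_max individuals with random (possibly
# inconsistent) assay genotypes; rows ordered parents before offspring.
random_pedigree <- function(n_max = 12) {
  n <- sample(4:n_max, 1)
  n_founders <- sample(2:3, 1)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  sex[1:2] <- c("male", "female")
  id <- sprintf("I%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (k in (n_founders + 1):n) {
    males <- which(sex[1:(k - 1)] == "male")
    females <- which(sex[1:(k - 1)] == "female")
    if (!length(males) || !length(females)) next
    sire[k] <- id[males[sample.int(length(males), 1)]]
    dam[k] <- id[females[sample.int(length(females), 1)]]
  }
  pedigree(data.frame(
    id = id, sire = sire, dam = dam, sex = sex,
    phenotype = "unknown",
    genotype = sample(c("hom_wt", "het", "hom_mut", "untyped"), n,
                      replace = TRUE, prob = c(.3, .3, .2, .2))))
}

# Small hand-built variant table: 4 variants x 2 affected samples.
toy_variants <- function() {
  sites <- data.frame(
    chrom = 5, pos = c(100, 200, 300, 400),
    ref = c("A", "CG", "T", "G"), alt = c("G", "C", "C", "T"),
    class = c("SNP", "indel", "SNP", "SNP"))
  gt <- matrix(c(2L, 2L, 1L, 2L, 2L, NA, 2L, 0L), nrow = 4,
               dimnames = list(NULL, c("A1", "A2")))
  ad_ref <- matrix(c(0L, 0L, 3L, 0L, 0L, 0L, 0L, 5L), nrow = 4)
  ad_alt <- matrix(c(5L, 3L, 4L, 6L, 4L, 0L, 7L, 0L), nrow = 4)
  variant_set(sites, gt, ad_ref, ad_alt)
}

# Fig-3-style family: carrier parents, carrier maternal grandsire and
# aunt, three genotyped affected pups, wild-type relatives.
family_pedigree <- function() {
  pedigree(data.frame(
    id   = c("SIRE", "GS_M", "GD_M", "DAM", "AUNT", "P1", "P2", "P3", "P4"),
    sire = c(NA, NA, NA, "GS_M", "GS_M", "SIRE", "SIRE", "SIRE", "SIRE"),
    dam  = c(NA, NA, NA, "GD_M", "GD_M", "DAM", "DAM", "DAM", "DAM"),
    sex  = c("male", "male", "female", "female", "female",
             "male", "female", "male", "female"),
    phenotype = c(rep("unaffected", 5), rep("affected", 3), "unaffected"),
    genotype = c("het", "het", "hom_wt", "het", "het",
                 rep("hom_mut", 3), "het")))
}
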