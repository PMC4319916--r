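#' Simulation configuration for a synthetic mapping cohort
#'
#' Defines the study conditions emulated by the cohort simulator: a small
#' outbred dog-like family segregating a fully penetrant recessive lethal
#' allele, genotyped on a SNP array with megabase-scale within-breed LD.
#' Defaults mirror the mapped family: a litter of eight from a carrier x
#' carrier mating, ten chromosomes with the causal locus mid-chromosome 5,
#' and array density scaled down to desk size.
#'
#' @param n_chromosomes number of autosomes simulated.
#' @param chrom_length_bp length of each chromosome (bp).
#' @param n_markers_per_chrom array markers per chromosome.
#' @param causal_chrom chromosome carrying the causal locus.
#' @param causal_pos causal position (bp, 1-based).
#' @param founder_haplotype_count size of the founder haplotype pool;
#'   haplotype 1 is the disease haplotype (private to carrier founders),
#'   the rest form the breed background each chromosome copy is
#'   mosaicked from.
#' @param ld_block_length_bp mean length of founder-haplotype copying
#'   blocks; within-breed canine LD extends over megabases and the mapped
#'   family showed a dispersed but contiguous signal tens of Mb wide,
#'   hence the multi-Mb default.
#' @param tag_marker_fraction fraction of array markers whose minor
#'   allele is private to a single founder haplotype, emulating array
#'   content selected to tag breed haplotypes; the remainder segregate
#'   independently of haplotype identity.
#' @param missing_rate per-call missing-genotype probability.
#' @param litter_size pups in the proband litter.
#' @param candidate_halfwidth_bp half-width of the candidate window around
#'   `causal_pos` used for gene models and region variants.
#' @param ascertain `"none"` (unconditional litter, the default) or
#'   `"affected"` (redraw the litter until at least `min_affected`
#'   affected pups, emulating families sampled because they produced
#'   affected offspring).
#' @param min_affected minimum affected pups under `ascertain = "affected"`.
#' @param seed integer seed; one seed drives every stage.
#' @return a validated `sim_config` list.
#' @examples
#' cfg <- sim_config(seed = 7)
#' ped <- simulate_pedigree(cfg)
#' @export
sim_config <- function(n_chromosomes = 10, chrom_length_bp = 8e6,
                       n_markers_per_chrom = 500, causal_chrom = 5,
                       causal_pos = 4.1e6, founder_haplotype_count = 6,
                       ld_block_length_bp = 4e6, tag_marker_fraction = 0.9,
                       missing_rate = 0.02,
                       litter_size = 8, candidate_halfwidth_bp = 2.5e6,
                       ascertain = c("none", "affected"), min_affected = 1,
                       seed = 1) {
  ascertain <- match.arg(ascertain)
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.double(chrom_length_bp),
              n_markers_per_chrom = as.integer(n_markers_per_chrom),
              causal_chrom = as.integer(causal_chrom),
              causal_pos = as.double(causal_pos),
              founder_haplotype_count = as.integer(founder_haplotype_count),
              ld_block_length_bp = as.double(ld_block_length_bp),
              tag_marker_fraction = as.double(tag_marker_fraction),
              missing_rate = as.double(missing_rate),
              litter_size = as.integer(litter_size),
              candidate_halfwidth_bp = as.double(candidate_halfwidth_bp),
              ascertain = ascertain, min_affected = as.integer(min_affected),
              seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_chromosomes, n_markers_per_chrom, litter_size) < 1))
      stop("all counts must be >= 1 (litter_size of 0 is rejected)")
    if (founder_haplotype_count < 2)
      stop("founder pool needs the disease haplotype plus >= 1 background")
    if (missing_rate < 0 || missing_rate > 1 ||
        tag_marker_fraction < 0 || tag_marker_fraction > 1)
      stop("proportions must lie in [0, 1]")
    if (causal_chrom < 1 || causal_chrom > n_chromosomes)
      stop("causal_chrom outside the simulated genome")
    if (causal_pos < 1 || causal_pos > chrom_length_bp)
      stop("causal_pos outside the causal chromosome")
  })
  structure(cfg, class = "sim_config")
}

candidate_window <- function(config) {
  c(max(1, config$causal_pos - config$candidate_halfwidth_bp),
    min(config$chrom_length_bp, config$causal_pos + config$candidate_halfwidth_bp))
}

#' Mendelian offspring genotypes from a single mating
#'
#' Draws transmitted-allele pairs for `n` offspring of parents with the
#' given causal-allele counts.
#'
#' @param g_sire,g_dam parental alt-allele counts (0/1/2).
#' @param n number of offspring.
#' @return data frame with `allele_sire`, `allele_dam`, `genotype`
#'   (alt-allele count) per offspring.
#' @export
mendelian_offspring <- function(g_sire, g_dam, n) {
  a_s <- sample(rep(transmissible(g_sire), 2), n, replace = TRUE)
  a_d <- sample(rep(transmissible(g_dam), 2), n, replace = TRUE)
  data.frame(allele_sire = a_s, allele_dam = a_d, genotype = a_s + a_d)
}

#' Simulate a three-generation pedigree segregating a recessive lethal
#'
#' The family structure emulates the mapped household: two unrelated
#' carrier lineages converge on the proband litter — an imported carrier
#' sire (a founder; his parents were never sampled) and a carrier dam who
#' inherits the allele from the carrier maternal grandsire. The
#' grandsire's other typed female offspring is likewise a carrier, and two
#' unrelated non-carrier kennel members complete the typed family. The
#' proband litter's genotypes at the causal locus are drawn by Mendelian
#' transmission from the carrier x carrier mating; phenotype is affected
#' if and only if homozygous for the causal allele (full penetrance). The
#' assay genotype column records the true causal genotype.
#'
#' @param config a [sim_config()].
#' @return a [pedigree()] with extra truth columns `allele_sire`,
#'   `allele_dam` (transmitted causal-allele counts; `NA` for founders).
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "pedigree"))
  founder <- function(id, sex, g)
    data.frame(id = id, sire = NA_character_, dam = NA_character_, sex = sex,
               phenotype = "unaffected", genotype = geno_label(g),
               allele_sire = NA_integer_, allele_dam = NA_integer_)
  child <- function(id, sire, dam, sex, a_s, a_d) {
    g <- a_s + a_d
    data.frame(id = id, sire = sire, dam = dam, sex = sex,
               phenotype = if (g == 2L) "affected" else "unaffected",
               genotype = geno_label(g),
               allele_sire = a_s, allele_dam = a_d)
  }
  gen1 <- rbind(founder("SIRE", "male", 1L),   # imported carrier founder
                founder("GS_M", "male", 1L), founder("GD_M", "female", 0L),
                founder("REL_A", "female", 0L), founder("REL_B", "male", 0L))
  # the carrier grandsire transmits the allele to both typed daughters
  gen2 <- rbind(child("DAM", "GS_M", "GD_M", "female", 1L, 0L),
                child("AUNT", "GS_M", "GD_M", "female", 1L, 0L))
  litter <- function() {
    tr <- mendelian_offspring(1L, 1L, config$litter_size)
    do.call(rbind, lapply(seq_len(config$litter_size), function(i)
      child(sprintf("P%02d", i), "SIRE", "DAM",
            c("male", "female")[i %% 2 + 1],
            tr$allele_sire[i], tr$allele_dam[i])))
  }
  gen3 <- litter()
  if (config$ascertain == "affected") {
    tries <- 0L
    while (sum(gen3$phenotype == "affected") < config$min_affected) {
      gen3 <- litter()
      tries <- tries + 1L
      if (tries > 1e5) stop("ascertainment condition not reached")
    }
  }
  pedigree(rbind(gen1, gen2, gen3))
}

#' Extract the simulation truth record
#'
#' @param ped a pedigree from [simulate_pedigree()].
#' @param config the [sim_config()] used.
#' @param causal_gene optional causal gene id (filled by
#'   [simulate_cohort()]).
#' @param causal_variant optional single-row causal [variant_set()].
#' @return list with `causal_chrom`, `causal_pos`, `carriers`, `affected`,
#'   `causal_gene`, `causal_variant`.
#' @export
truth_record <- function(ped, config, causal_gene = NA_character_,
                         causal_variant = NULL) {
  rec <- list(causal_chrom = config$causal_chrom,
              causal_pos = config$causal_pos,
              carriers = ped$id[ped$genotype == "het"],
              affected = ped$id[ped$phenotype == "affected"],
              causal_gene = causal_gene, causal_variant = causal_variant)
  stopifnot(all(ped$genotype[ped$phenotype == "affected"] == "hom_mut"))
  parents <- unique(c(ped$sire[ped$phenotype == "affected"],
                      ped$dam[ped$phenotype == "affected"]))
  parents <- parents[!is.na(parents)]
  stopifnot(all(ped$genotype[match(parents, ped$id)] %in% c("het", "hom_mut")))
  rec
}

# Founder haplotype templates for one chromosome. Template 1 is the
# disease haplotype; templates 2..H are the breed background pool. At
# tag-informative markers (a `tag_marker_fraction` of the array) the
# minor allele is private to one template; the rest segregate
# independently with a uniform frequency spectrum over the background.
make_templates <- function(m, config) {
  H <- config$founder_haplotype_count
  tagging <- runif(m) < config$tag_marker_fraction
  tmpl <- matrix(0L, nrow = H, ncol = m)
  p <- runif(m, 0.05, 0.95)
  tmpl[, !tagging] <- rbinom(H * sum(!tagging), 1L,
                             rep(p[!tagging], each = H))
  owner <- sample.int(H, sum(tagging), replace = TRUE)
  tmpl[cbind(owner, which(tagging))] <- 1L
  tmpl
}

# One founder chromosome copy: a mosaic of the background templates
# (2..H) in blocks of mean ld_block_length_bp. A carrier founder's copy of
# the causal chromosome is an intact disease haplotype (template 1): the
# mutation is recent relative to haplotype decay, so at the scale of one
# small chromosome the carriers' IBD segment spans it, creating LD between
# the causal allele and the disease haplotype's private tag alleles.
founder_copy <- function(pos, templates, config, causal_here, carry) {
  if (causal_here && carry)
    return(list(alleles = templates[1L, ], carries = TRUE))
  L <- config$chrom_length_bp
  H <- nrow(templates)
  n_draw <- max(8L, ceiling(L / config$ld_block_length_bp * 3))
  breaks <- cumsum(rexp(n_draw, 1 / config$ld_block_length_bp))
  breaks <- breaks[breaks < L]
  tmpl <- sample.int(H - 1L, length(breaks) + 1L, replace = TRUE) + 1L
  block_of <- function(p) findInterval(p, breaks) + 1L
  list(alleles = templates[cbind(tmpl[block_of(pos)], seq_along(pos))],
       carries = FALSE)
}

# One recombinant gamete from `parent` (list of per-copy allele vectors and
# causal flags). When a required causal-allele state is given, the mosaic
# is flipped wholesale if the copy active at the causal position does not
# carry the required state; flipping preserves the crossover structure.
gamete <- function(parent_alleles, parent_carries, pos, config, causal_here,
                   required = NA) {
  L <- config$chrom_length_bp
  n_xo <- rpois(1, L / 1e8)  # ~1 crossover per 100 Mb (1 cM/Mb map)
  # crossover placement is telomere-biased (linear density rising from the
  # chromosome centre), as observed in canid genetic maps
  u <- sqrt(runif(n_xo)) * sample(c(-1, 1), n_xo, replace = TRUE)
  xo <- sort(L / 2 + u * L / 2)
  first <- sample.int(2L, 1)
  copy_at <- function(p) (first + findInterval(p, xo) - 1L) %% 2L + 1L
  copy_idx <- copy_at(pos)
  carries <- FALSE
  if (causal_here) {
    active <- copy_at(config$causal_pos)
    if (!is.na(required)) {
      if (parent_carries[active] != as.logical(required)) {
        other <- 3L - active
        if (parent_carries[other] != as.logical(required))
          stop("pedigree transmission inconsistent with parental haplotypes")
        copy_idx <- 3L - copy_idx
        active <- other
      }
    }
    carries <- parent_carries[active]
  }
  list(alleles = parent_alleles[cbind(pos_idx = seq_along(pos), copy_idx)],
       carries = carries)
}

#' Simulate SNP-array genotypes over a pedigree
#'
#' Founders receive mosaics of a founder haplotype pool in blocks of mean
#' `ld_block_length_bp`; non-founders inherit recombinant parental
#' haplotypes (about one crossover per 100 Mb). Haplotype transmission at
#' the causal locus is made consistent with the pedigree's recorded causal
#' genotypes, so markers in the block containing the causal position tag
#' the causal allele. Missing calls are introduced at `missing_rate`.
#'
#' @param ped a pedigree from [simulate_pedigree()].
#' @param config the same [sim_config()].
#' @return a [genotype_matrix()] whose status labels affected individuals
#'   as cases and all others as controls. The founder template pool is
#'   attached as `attr(, "templates")` for enumeration-based checks.
#' @export
simulate_genotypes <- function(ped, config) {
  stopifnot(inherits(ped, "pedigree"), inherits(config, "sim_config"))
  if (is.null(ped$allele_sire))
    stop("pedigree must come from simulate_pedigree()")
  set.seed(stage_seed(config$seed, "genotypes"))
  nC <- config$n_chromosomes; m <- config$n_markers_per_chrom
  H <- config$founder_haplotype_count
  pos <- lapply(seq_len(nC), function(cc)
    sort(sample.int(config$chrom_length_bp, m)))
  templates <- lapply(seq_len(nC), function(cc) make_templates(m, config))
  fnd <- founders(ped)
  hap <- list()   # per individual: $alleles (list/chrom of m x 2), $carries (len 2)
  for (k in seq_len(nrow(ped))) {
    id <- ped$id[k]
    causal_count <- geno_code(ped$genotype[k])
    if (id %in% fnd) {
      carry_copy <- c(causal_count >= 1L, causal_count == 2L)
      al <- vector("list", nC); carries <- c(FALSE, FALSE)
      for (cc in seq_len(nC)) {
        ch <- cc == config$causal_chrom
        c1 <- founder_copy(pos[[cc]], templates[[cc]], config, ch, carry_copy[1])
        c2 <- founder_copy(pos[[cc]], templates[[cc]], config, ch, carry_copy[2])
        al[[cc]] <- cbind(c1$alleles, c2$alleles)
        if (ch) carries <- c(c1$carries, c2$carries)
      }
      hap[[id]] <- list(alleles = al, carries = carries)
    } else {
      sire <- hap[[ped$sire[k]]]; dam <- hap[[ped$dam[k]]]
      al <- vector("list", nC); carries <- c(FALSE, FALSE)
      for (cc in seq_len(nC)) {
        ch <- cc == config$causal_chrom
        gs <- gamete(sire$alleles[[cc]], sire$carries, pos[[cc]], config, ch,
                     if (ch) ped$allele_sire[k] else NA)
        gd <- gamete(dam$alleles[[cc]], dam$carries, pos[[cc]], config, ch,
                     if (ch) ped$allele_dam[k] else NA)
        al[[cc]] <- cbind(gs$alleles, gd$alleles)
        if (ch) carries <- c(gs$carries, gd$carries)
      }
      hap[[id]] <- list(alleles = al, carries = carries)
    }
  }
  geno <- do.call(rbind, lapply(seq_len(nC), function(cc)
    vapply(ped$id, function(id) as.integer(rowSums(hap[[id]]$alleles[[cc]])),
           integer(m))))
  if (config$missing_rate > 0) {
    miss <- matrix(rbinom(length(geno), 1L, config$missing_rate) == 1L,
                   nrow = nrow(geno))
    geno[miss] <- NA_integer_
  }
  map <- data.frame(
    marker = sprintf("M%02d_%04d", rep(seq_len(nC), each = m),
                     rep(seq_len(m), nC)),
    chrom = rep(seq_len(nC), each = m),
    pos = unlist(pos))
  rownames(geno) <- map$marker
  status <- setNames(ifelse(ped$phenotype == "affected", "case", "control"),
                     ped$id)
  out <- genotype_matrix(geno, map, status = status)
  attr(out, "templates") <- templates
  out
}

#' Simulate gene models in the candidate window
#'
#' Lays `n_genes` non-overlapping genes across the candidate window around
#' the causal position, each with 3-6 exons; the gene whose span contains
#' the causal position is built so that its second exon covers it
#' (mirroring an exon-2 coding deletion).
#'
#' @param config a [sim_config()].
#' @param n_genes number of genes.
#' @return data frame, one row per exon: `gene_id`, `chrom`, `strand`,
#'   `exon`, `exon_start`, `exon_end`, `cds_start`, `cds_end` (1-based
#'   inclusive). The causal gene id is attached as
#'   `attr(, "causal_gene")`.
#' @export
simulate_gene_models <- function(config, n_genes = 30) {
  stopifnot(inherits(config, "sim_config"), n_genes >= 1)
  set.seed(stage_seed(config$seed, "genes"))
  win <- candidate_window(config)
  slot <- (win[2] - win[1]) / n_genes
  causal_slot <- min(n_genes,
                     max(1, floor((config$causal_pos - win[1]) / slot) + 1))
  rows <- list()
  for (g in seq_len(n_genes)) {
    n_ex <- sample(3:6, 1)
    if (g == causal_slot) {
      # causal gene built around the causal position: exon 2 covers it
      gene_start <- round(config$causal_pos - min(0.3 * slot, 5e4))
      gene_end <- round(config$causal_pos + min(0.3 * slot, 5e4))
      ex_start <- ex_end <- integer(n_ex)
      ex_start[1] <- gene_start; ex_end[1] <- gene_start + 600L
      ex_start[2] <- round(config$causal_pos) - 300L
      ex_end[2] <- round(config$causal_pos) + 300L
      tail_bounds <- round(seq(ex_end[2] + 200, gene_end,
                               length.out = n_ex - 1))
      for (e in 3:n_ex) {
        ex_start[e] <- tail_bounds[e - 2]
        ex_end[e] <- ex_start[e] + sample(200:600, 1)
      }
    } else {
      s0 <- win[1] + (g - 1) * slot
      gene_start <- round(s0 + 0.15 * slot)
      gene_end <- round(s0 + 0.85 * slot)
      bounds <- round(seq(gene_start, gene_end, length.out = n_ex + 1))
      ex_start <- ex_end <- integer(n_ex)
      for (e in seq_len(n_ex)) {
        lo <- bounds[e]; hi <- bounds[e + 1] - 1
        len <- sample(200:2000, 1)
        st <- lo + sample.int(max(1, hi - lo - len), 1) - 1L
        ex_start[e] <- st; ex_end[e] <- min(hi, st + len - 1)
      }
    }
    rows[[g]] <- data.frame(
      gene_id = sprintf("GENE%02d", g), chrom = config$causal_chrom,
      strand = sample(c("+", "-"), 1), exon = seq_len(n_ex),
      exon_start = ex_start, exon_end = ex_end,
      cds_start = ex_start[1], cds_end = ex_end[n_ex])
  }
  out <- do.call(rbind, rows)
  stopifnot(all(out$exon_start <= out$exon_end))
  for (rr in split(out, out$gene_id))  # exons sorted, non-overlapping
    stopifnot(all(diff(rr$exon_start) > 0), all(rr$exon_start[-1] > rr$exon_end[-nrow(rr)]))
  attr(out, "causal_gene") <- sprintf("GENE%02d", causal_slot)
  out
}

#' Simulate a synteny-block table for the candidate window
#'
#' Splits the candidate window at the causal position into two blocks
#' mapped to two target-genome chromosomes (one inverted), mirroring a
#' dog-to-mouse synteny break within the associated region, plus one
#' distractor block outside the window.
#'
#' @param config a [sim_config()].
#' @return data frame with columns `source_chrom`, `source_start`,
#'   `source_end`, `target_chrom`, `target_start`, `target_end`,
#'   `orientation`.
#' @export
simulate_synteny_blocks <- function(config) {
  win <- candidate_window(config)
  split <- round(config$causal_pos)
  data.frame(
    source_chrom = config$causal_chrom,
    source_start = c(win[1], split + 1, 1),
    source_end = c(split, win[2], win[1] - 1),
    target_chrom = c("mmu9", "mmu11", "mmu4"),
    target_start = c(5.29e6, 59.6e6, 1e6),
    target_end = c(5.29e6 + (split - win[1]), 59.6e6 + (win[2] - split - 1),
                   1e6 + (win[1] - 2)),
    orientation = c("+", "-", "+"))
}

skeletal_terms <- c(
  "abnormal rib and vertebrae morphology", "decreased rib number",
  "rib fusion", "kyphosis", "abnormal cranium morphology",
  "hemivertebrae", "abnormal sternum morphology")
other_terms <- c(
  "abnormal gait", "cardiac hypertrophy", "increased circulating glucose",
  "retinal degeneration", "abnormal coat colour", "reduced fertility")

#' Simulate gene-to-phenotype annotations
#'
#' Assigns free-text model-organism phenotype terms to the simulated genes:
#' `n_skeletal` genes (always including the causal gene, which receives an
#' abnormal rib/vertebrae term) get a skeletal term; the remainder get
#' non-skeletal terms.
#'
#' @param gene_models output of [simulate_gene_models()].
#' @param config a [sim_config()].
#' @param n_skeletal number of genes annotated with a skeletal phenotype.
#' @return data frame with columns `gene_id`, `phenotype_term`, one row
#'   per (gene, term).
#' @export
simulate_phenotype_annotations <- function(gene_models, config,
                                           n_skeletal = 19) {
  set.seed(stage_seed(config$seed, "phenotypes"))
  genes <- unique(gene_models$gene_id)
  stopifnot(n_skeletal >= 1, n_skeletal <= length(genes))
  causal <- attr(gene_models, "causal_gene")
  skel <- unique(c(causal, sample(setdiff(genes, causal), n_skeletal - 1)))
  term_of <- function(g) {
    if (g == causal) return("abnormal rib and vertebrae morphology")
    if (g %in% skel) return(sample(skeletal_terms, 1))
    sample(other_terms, 1)
  }
  data.frame(gene_id = genes,
             phenotype_term = vapply(genes, term_of, character(1)),
             row.names = NULL)
}

#' Simulate candidate-region variants carried by the affected samples
#'
#' Emits `n_snps` SNPs and `n_indels` indels (the causal exonic 1-bp
#' deletion is always one of the indels) across the candidate window, with
#' simulated quality-passing ref/alt read depths. All affected samples are
#' homozygous for the causal deletion with zero reference-supporting
#' reads; other variants receive random genotypes, and a small fraction of
#' sample calls have no supporting reads (unknown genotype).
#'
#' @param config a [sim_config()].
#' @param truth a [truth_record()]; its `affected` ids become the samples.
#' @param gene_models output of [simulate_gene_models()].
#' @param n_snps,n_indels counts (`n_indels >= 1` for the causal deletion).
#' @param exonic_fraction fraction of variants placed inside exons (the
#'   causal deletion counts toward it).
#' @param mean_depth mean quality-passing read depth per sample.
#' @param empty_rate probability a non-causal sample call has no
#'   supporting reads.
#' @return a [variant_set()]; the causal row index is attached as
#'   `attr(, "causal_index")`.
#' @export
simulate_region_variants <- function(config, truth, gene_models,
                                     n_snps = 180, n_indels = 20,
                                     exonic_fraction = 0.05, mean_depth = 8,
                                     empty_rate = 0.03) {
  stopifnot(inherits(config, "sim_config"), n_snps >= 0, n_indels >= 1,
            exonic_fraction >= 0, exonic_fraction <= 1)
  set.seed(stage_seed(config$seed, "variants"))
  win <- candidate_window(config)
  causal_gene <- attr(gene_models, "causal_gene")
  cg <- gene_models[gene_models$gene_id == causal_gene, ]
  if (!any(cg$exon_start <= config$causal_pos & cg$exon_end >= config$causal_pos))
    stop("causal variant lies outside every exon of the causal gene")
  samples <- truth$affected
  n <- n_snps + n_indels
  n_exonic <- max(1L, round(exonic_fraction * n))  # causal is exonic
  exon_pool <- unlist(mapply(seq, gene_models$exon_start, gene_models$exon_end,
                             SIMPLIFY = FALSE))
  pos_ex <- sample(exon_pool, n_exonic - 1L)
  width <- win[2] - win[1] + 1
  pos_rest <- integer(0)
  while (length(pos_rest) < n - n_exonic) {
    cand <- sample.int(width, min(width, (n - n_exonic) * 2)) + win[1] - 1
    cand <- cand[!(cand %in% exon_pool)]
    pos_rest <- unique(c(pos_rest, cand))
  }
  pos_rest <- pos_rest[seq_len(n - n_exonic)]
  pos <- c(pos_ex, pos_rest)
  is_indel <- c(rep(TRUE, n_indels - 1L), rep(FALSE, n - n_indels))
  is_indel <- sample(is_indel)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n - 1, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  # indels are 1-bp deletions left-anchored one base before the sampled
  # (affected) position, so exonic placement refers to the deleted base
  ref[is_indel] <- paste0(sample(bases, sum(is_indel), TRUE), ref[is_indel])
  alt[is_indel] <- substr(ref[is_indel], 1, 1)
  pos[is_indel] <- pos[is_indel] - 1
  causal_site <- data.frame(chrom = config$causal_chrom,
                            pos = config$causal_pos - 1,
                            ref = "AG", alt = "A", class = "indel")
  sites <- if (n > 1) {
    rbind(causal_site,
          data.frame(chrom = config$causal_chrom, pos = pos, ref = ref,
                     alt = alt, class = ifelse(is_indel, "indel", "SNP")))
  } else causal_site
  ns <- length(samples)
  n_other <- n - 1L
  q <- runif(n_other)
  gt <- matrix(rep(2L, ns), nrow = 1)
  if (n_other > 0)
    gt <- rbind(gt, matrix(rbinom(n_other * ns, 2L, rep(q, ns)),
                           nrow = n_other))
  depth <- matrix(rpois(n * ns, mean_depth) + 1L, nrow = n)
  empty <- matrix(rbinom(n * ns, 1L, empty_rate) == 1L, nrow = n)
  empty[1, ] <- FALSE  # causal site always has evidence in the affecteds
  het_prob <- c(0, .5, 1)[gt + 1L]
  het_prob[is.na(het_prob)] <- 0
  alt_reads <- matrix(rbinom(length(depth), depth, het_prob), nrow = n)
  alt_reads[gt == 2L] <- depth[gt == 2L]
  alt_reads[gt == 0L] <- 0L
  ad_alt <- ifelse(empty, 0L, alt_reads)
  ad_ref <- ifelse(empty, 0L, depth - alt_reads)
  gt[empty] <- NA_integer_
  dimnames(gt) <- dimnames(ad_ref) <- dimnames(ad_alt) <-
    list(NULL, samples)
  o <- order(sites$pos)
  out <- variant_set(sites[o, ], gt[o, , drop = FALSE],
                     ad_ref[o, , drop = FALSE], ad_alt[o, , drop = FALSE])
  attr(out, "causal_index") <- which(o == 1L)
  out
}

#' Simulate a complete mapping cohort
#'
#' Convenience wrapper running every simulator stage off the single config
#' seed: pedigree, genotype matrix, gene models, synteny blocks, phenotype
#' annotations, candidate-region variants and the truth record.
#'
#' @param config a [sim_config()].
#' @param n_genes,n_skeletal,n_snps,n_indels stage sizes (see the
#'   individual simulators).
#' @return list with elements `pedigree`, `genotypes`, `gene_models`,
#'   `synteny`, `phenotypes`, `variants`, `truth`, `config`.
#' @export
simulate_cohort <- function(config = sim_config(), n_genes = 30,
                            n_skeletal = 19, n_snps = 180, n_indels = 20) {
  ped <- simulate_pedigree(config)
  gm <- simulate_genotypes(ped, config)
  genes <- simulate_gene_models(config, n_genes)
  truth <- truth_record(ped, config, causal_gene = attr(genes, "causal_gene"))
  vs <- simulate_region_variants(config, truth, genes,
                                 n_snps = n_snps, n_indels = n_indels)
  truth$causal_variant <- subset_variants(vs, attr(vs, "causal_index"))
  list(pedigree = ped, genotypes = gm, gene_models = genes,
       synteny = simulate_synteny_blocks(config),
       phenotypes = simulate_phenotype_annotations(genes, config, n_skeletal),
       variants = vs, truth = truth, config = config)
}

#' Select the genotyped case/control subset of a simulated cohort
#'
#' Mirrors the array study design: the affected pups as cases plus the
#' seven typed unaffected relatives (sire, dam, maternal grandparents,
#' aunt, the two non-carrier kennel members) as controls.
#'
#' @param cohort output of [simulate_cohort()].
#' @param n_cases,n_controls cohort sizes (default 3 + 7).
#' @return a [genotype_matrix()] restricted to the selected samples.
#' @export
gwas_cohort <- function(cohort, n_cases = 3, n_controls = 7) {
  ped <- cohort$pedigree
  affected <- ped$id[ped$phenotype == "affected"]
  if (length(affected) < n_cases)
    stop("cohort has fewer affected individuals than requested cases; ",
         "simulate with ascertain = \"affected\"")
  cases <- affected[seq_len(n_cases)]
  core <- c("SIRE", "DAM", "GS_M", "GD_M", "AUNT", "REL_A", "REL_B")
  ctrl_order <- c(core, setdiff(ped$id[ped$phenotype == "unaffected"], core))
  controls <- ctrl_order[seq_len(n_controls)]
  status <- setNames(c(rep("case", n_cases), rep("control", n_controls)),
                     c(cases, controls))
  subset_samples(cohort$genotypes, c(cases, controls), status = status)
}
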