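#' Prune markers on minor allele frequency and missingness
#'
#' Retains markers with pooled (cases + controls) minor allele frequency
#' of at least `maf_min` and a missing-call proportion of at most
#' `max_missing` — the conventional array-QC step of removing markers with
#' MAF below 0.1 or missingness above 0.2. The operation is idempotent;
#' per-filter removal counts are attached as `attr(, "prune_audit")`.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (in `[0, 1]`).
#' @param max_missing maximum missing-call proportion (in `[0, 1]`).
#' @return the pruned [genotype_matrix()].
#' @export
prune_markers <- function(g, maf_min = 0.1, max_missing = 0.2) {
  stopifnot(inherits(g, "genotype_matrix"), nrow(g$geno) > 0)
  if (maf_min < 0 || maf_min > 1 || max_missing < 0 || max_missing > 1)
    stop("thresholds must lie in [0, 1]")
  n <- ncol(g$geno)
  n_called <- rowSums(!is.na(g$geno))
  miss <- 1 - n_called / n
  alt <- rowSums(g$geno, na.rm = TRUE)
  f <- ifelse(n_called > 0, alt / (2 * n_called), 0)
  maf <- pmin(f, 1 - f)
  fail_maf <- maf < maf_min
  fail_miss <- miss > max_missing
  keep <- !fail_maf & !fail_miss
  out <- genotype_matrix(g$geno[keep, , drop = FALSE],
                         g$map[keep, , drop = FALSE], status = g$status)
  attr(out, "prune_audit") <- list(
    n_input = nrow(g$geno), n_retained = sum(keep),
    removed_maf = sum(fail_maf), removed_missing = sum(fail_miss))
  out
}

# Pearson chi-squared on a 2x2 table by the closed form
# N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)); log-space upper tail so that
# 1e-36-scale p-values keep full relative precision. Vectorised.
chi2_2x2 <- function(a, b, c, d) {
  N <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(denom > 0, N * (a * d - b * c)^2 / denom, NA_real_)
  log_p <- pchisq(chi2, df = 1, lower.tail = FALSE, log.p = TRUE)
  list(chi2 = chi2, p = exp(log_p), log10_p = log_p / log(10))
}

#' Allelic chi-squared association test
#'
#' Collapses case and control genotype counts to allele counts (each
#' individual contributes two alleles), forms the 2x2 allele table and
#' computes the Pearson chi-squared statistic without continuity
#' correction (df = 1). The tail probability is evaluated in log space so
#' extreme statistics report accurate p-values.
#'
#' @param case_counts,control_counts length-3 vectors of genotype counts
#'   `(hom-wt, het, hom-mut)`.
#' @return list with `chi2`, `df`, `p`, `log10_p` and the allele `table`.
#' @examples
#' allelic_chi2(c(0, 0, 3), c(126, 4, 0))  # chi2 ~ 157.1, p ~ 4.76e-36
#' @export
allelic_chi2 <- function(case_counts, control_counts) {
  stopifnot(length(case_counts) == 3, length(control_counts) == 3,
            all(c(case_counts, control_counts) >= 0))
  a <- 2 * case_counts[1] + case_counts[2]     # case ref alleles
  b <- case_counts[2] + 2 * case_counts[3]     # case alt alleles
  c_ <- 2 * control_counts[1] + control_counts[2]
  d <- control_counts[2] + 2 * control_counts[3]
  if (a + b == 0 || c_ + d == 0)
    stop("zero total alleles in one of the groups")
  r <- chi2_2x2(a, b, c_, d)
  tab <- matrix(c(a, c_, b, d), 2, 2,
                dimnames = list(c("case", "control"), c("ref", "alt")))
  list(chi2 = unname(r$chi2), df = 1L, p = unname(r$p),
       log10_p = unname(r$log10_p), table = tab)
}

#' Genotypic chi-squared association test
#'
#' Pearson chi-squared on the 2x3 case/control genotype table with
#' expected counts from the margins. All-zero genotype columns are dropped
#' first; with fewer than two remaining columns the test is undefined and
#' `NA` statistics are returned.
#'
#' @inheritParams allelic_chi2
#' @return list with `chi2`, `df`, `p` (all `NA` when undefined).
#' @export
genotypic_chi2 <- function(case_counts, control_counts) {
  stopifnot(length(case_counts) == 3, length(control_counts) == 3,
            all(c(case_counts, control_counts) >= 0))
  m <- rbind(case = case_counts, control = control_counts)
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (any(rowSums(m) == 0)) stop("empty row margin in genotype table")
  if (ncol(m) < 2)
    return(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_))
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  chi2 <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  list(chi2 = chi2, df = df,
       p = exp(pchisq(chi2, df, lower.tail = FALSE, log.p = TRUE)))
}

#' Per-marker association scan
#'
#' Runs the allelic chi-squared test at every marker of a labelled
#' genotype matrix. Markers with no called alleles in either group get
#' `NA` statistics.
#'
#' @param g a [genotype_matrix()] with case/control status labels.
#' @return data frame with columns `marker`, `chrom`, `bp`, `maf`, `chi2`,
#'   `df`, `p`.
#' @export
association_scan <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"), !is.null(g$status))
  cases <- g$geno[, g$status == "case", drop = FALSE]
  ctrls <- g$geno[, g$status == "control", drop = FALSE]
  alt_case <- rowSums(cases, na.rm = TRUE)
  n_case <- 2 * rowSums(!is.na(cases))
  alt_ctrl <- rowSums(ctrls, na.rm = TRUE)
  n_ctrl <- 2 * rowSums(!is.na(ctrls))
  a <- n_case - alt_case; b <- alt_case
  c_ <- n_ctrl - alt_ctrl; d <- alt_ctrl
  r <- chi2_2x2(a, b, c_, d)
  r$chi2[n_case == 0 | n_ctrl == 0] <- NA_real_
  r$p[is.na(r$chi2)] <- NA_real_
  f <- ifelse(n_case + n_ctrl > 0, (b + d) / (n_case + n_ctrl), NA_real_)
  data.frame(marker = g$map$marker, chrom = g$map$chrom, bp = g$map$pos,
             maf = pmin(f, 1 - f), chi2 = r$chi2, df = 1L, p = r$p,
             row.names = NULL)
}

#' Chromosomal over-representation among the top-K markers
#'
#' The small-family rescue heuristic for an underpowered scan: rank all
#' tested markers by ascending p-value, take the `k` most significant, and
#' tabulate which chromosomes are over-represented. Ties at the k-th
#' p-value are broken by `(chrom, bp)` order so the output is invariant to
#' input permutation. The arg-max chromosome is flagged as the candidate.
#'
#' @param results association results from [association_scan()].
#' @param k number of top markers (default 100).
#' @return data frame `chrom`, `n`, `proportion` (descending, summing to
#'   1) with the candidate chromosome in `attr(, "candidate_chrom")`.
#' @export
top_k_chromosome_enrichment <- function(results, k = 100) {
  ok <- !is.na(results$p)
  if (k > sum(ok))
    stop("k exceeds the number of markers with a defined p-value")
  r <- results[ok, ]
  r <- r[order(r$p, r$chrom, r$bp), ][seq_len(k), ]
  tab <- sort(table(r$chrom), decreasing = TRUE)
  out <- data.frame(chrom = names(tab), n = as.integer(tab),
                    proportion = as.numeric(tab) / k, row.names = NULL)
  attr(out, "candidate_chrom") <- out$chrom[1]
  out
}

#' Candidate region
#'
#' A 1-based inclusive chromosomal interval; `candidate_region(chrom)`
#' with no coordinates is the distinct empty-region signal returned when
#' no marker passes the refinement threshold.
#'
#' @param chrom chromosome id.
#' @param start,end interval bounds (bp, 1-based inclusive).
#' @return a `candidate_region` object.
#' @export
candidate_region <- function(chrom, start = NA_real_, end = NA_real_) {
  if (!is.na(start) && !is.na(end) && start > end)
    stop("region start must not exceed end")
  structure(list(chrom = chrom, start = start, end = end,
                 empty = is.na(start)),
            class = "candidate_region")
}

#' @export
print.candidate_region <- function(x, ...) {
  if (x$empty) cat("Candidate region: chrom", x$chrom, "(empty)\n")
  else cat(sprintf("Candidate region: chrom %s, %.0f-%.0f bp (%.2f Mb)\n",
                   x$chrom, x$start, x$end, (x$end - x$start + 1) / 1e6))
  invisible(x)
}

#' Refine the associated region on a chromosome
#'
#' Returns the interval spanning the smallest to the largest position
#' among markers with unadjusted p-value strictly below `p_threshold`
#' (default 0.005). When no marker passes, the distinct empty region is
#' returned.
#'
#' @param results association results restricted to one chromosome.
#' @param p_threshold refinement threshold on the raw p-value.
#' @return a [candidate_region()].
#' @export
refine_region <- function(results, p_threshold = 0.005) {
  if (length(unique(results$chrom)) != 1)
    stop("refine_region() expects results from a single chromosome")
  pass <- !is.na(results$p) & results$p < p_threshold
  if (!any(pass)) return(candidate_region(results$chrom[1]))
  candidate_region(results$chrom[1],
                   min(results$bp[pass]), max(results$bp[pass]))
}

#' Membership test for a candidate region
#' @param region a [candidate_region()].
#' @param pos position (bp).
#' @return logical.
#' @export
region_contains <- function(region, pos) {
  !region$empty && pos >= region$start && pos <= region$end
}

#' Parameter-recovery experiment over replicate synthetic cohorts
#'
#' Simulates `n_cohorts` independent families under `base_config`
#' (re-seeded per replicate and ascertained to yield at least the
#' requested number of affected pups), runs the full mapping pipeline on
#' each — marker pruning, allelic scan, top-K chromosomal enrichment,
#' region refinement and the candidate-variant filter cascade — and
#' records whether the causal chromosome, position and deletion were
#' recovered.
#'
#' @param n_cohorts number of replicate cohorts.
#' @param base_config a [sim_config()]; each replicate derives its own
#'   seed from `base_config$seed`.
#' @param k top-K size for the enrichment heuristic.
#' @param p_threshold refinement threshold.
#' @param n_cases,n_controls genotyped subset sizes.
#' @param ... sizes passed to [simulate_cohort()].
#' @return data frame with one row per replicate: `selected_chrom`,
#'   `causal_selected`, `region_contains_causal`, `causal_retained`,
#'   `top_k_causal_proportion`, `n_markers_tested`.
#' @export
recovery_experiment <- function(n_cohorts = 50, base_config = sim_config(),
                                k = 100, p_threshold = 0.005,
                                n_cases = 3, n_controls = 7, ...) {
  reps <- lapply(seq_len(n_cohorts), function(r) {
    cfg <- base_config
    cfg$seed <- as.integer(stage_seed(base_config$seed, sprintf("rep%04d", r)) %%
                             2147483647)
    cfg$ascertain <- "affected"; cfg$min_affected <- n_cases
    cohort <- simulate_cohort(cfg, ...)
    g <- prune_markers(gwas_cohort(cohort, n_cases, n_controls))
    res <- association_scan(g)
    enr <- top_k_chromosome_enrichment(res, k = min(k, sum(!is.na(res$p))))
    sel <- attr(enr, "candidate_chrom")
    hit <- sel == as.character(cfg$causal_chrom)
    reg <- refine_region(res[res$chrom == sel, ], p_threshold)
    cascade <- filter_cascade(cohort$variants, cohort$truth$affected,
                              cohort$gene_models, cohort$phenotypes,
                              terms = c("rib", "vertebra", "skeletal"))
    causal_key <- variant_key(cohort$truth$causal_variant$sites)
    data.frame(
      selected_chrom = sel, causal_selected = hit,
      region_contains_causal = region_contains(reg, cfg$causal_pos),
      causal_retained = causal_key %in% variant_key(cascade$variants$sites),
      top_k_causal_proportion = {
        pp <- enr$proportion[match(as.character(cfg$causal_chrom), enr$chrom)]
        if (is.na(pp)) 0 else pp
      },
      n_markers_tested = sum(!is.na(res$p)))
  })
  do.call(rbind, reps)
}
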