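# Synthetic-cohort generator.  Emulates the inputs the pipeline consumes:
# per-sample breakpoint discovery VCFs with probability-distribution
# annotations, per-sample re-genotyped VCFs with allele balance and
# sample quality, a read-depth copy-number table, a mobile-element BED,
# a pedigree, and the underlying truth table.
#
# The population model is deliberately simple: allele frequencies are
# Beta-distributed, unrelated genotypes follow Hardy-Weinberg
# equilibrium, trio children receive one allele from each parent, and
# per-sample breakpoint positions are perturbed by rounded Gaussian
# jitter (reflecting the ~10-100 bp per-sample mapping resolution of
# read-pair/split-read breakpoint detection).

#' Simulation configuration
#'
#' Defaults describe a desk-scale study cohort: 30 samples including 3
#' parent-offspring trios and ~500 structural variants across the five
#' types.
#'
#' @param n_samples total number of samples.
#' @param n_trios number of parent-offspring trios (3 samples each,
#'   leading the sample list).
#' @param n_variants named integer vector of truth variant counts per
#'   type.
#' @param af_beta shape parameters of the Beta allele-frequency
#'   distribution.
#' @param af_range allele frequencies are clipped to this range after
#'   drawing (degenerate ranges force a fixed frequency).
#' @param jitter_sd per-sample breakpoint jitter SD in bases.
#' @param ci_halfwidth half-width of the reported confidence interval.
#' @param pr_sd SD in bases of the Gaussian probability distribution laid
#'   over the confidence interval.
#' @param miss_rate per-sample, per-variant probability that a carried
#'   variant is missed at discovery.
#' @param ab_noise_sd allele-balance noise SD.
#' @param cn_noise_sd copy-number noise SD.
#' @param gt_error_rate residual per-sample probability that a
#'   re-genotyped call is flipped to a wrong genotype at an ordinary
#'   site.
#' @param bad_variant_rate fraction of variants that are systematically
#'   hard to genotype ("difficult" sites): their calls flip at
#'   `bad_gt_error` and all their carrier qualities are drawn from the
#'   low-SQ range.
#' @param bad_gt_error per-sample genotype flip rate at difficult sites.
#' @param sq_correct,sq_error uniform ranges of sample quality for
#'   confident and unreliable carrier calls.
#' @param su_mean mean supporting-read count per copy of the alternate
#'   allele.
#' @param contigs named integer vector of contig lengths.
#' @param seed RNG seed; fixed seed gives byte-identical outputs.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 30L, n_trios = 3L,
                       n_variants = c(DEL = 150L, DUP = 100L, INV = 75L,
                                      MEI = 100L, BND = 75L),
                       af_beta = c(0.2, 2), af_range = c(0.01, 0.95),
                       jitter_sd = 10,
                       ci_halfwidth = 50L, pr_sd = 20,
                       miss_rate = 0.03, ab_noise_sd = 0.05,
                       cn_noise_sd = 0.25, gt_error_rate = 0.005,
                       bad_variant_rate = 0.05, bad_gt_error = 0.25,
                       sq_correct = c(150, 300), sq_error = c(5, 40),
                       su_mean = 8,
                       contigs = c(chr1 = 12e6, chr2 = 12e6),
                       seed = 42L) {
  stopifnot(n_trios * 3 <= n_samples, miss_rate >= 0, miss_rate <= 1,
            gt_error_rate >= 0, gt_error_rate <= 1, jitter_sd >= 0,
            ab_noise_sd >= 0, cn_noise_sd >= 0, ci_halfwidth >= 1)
  structure(as.list(environment()), class = "sim_config")
}

sim_sample_names <- function(config) {
  trio <- unlist(lapply(seq_len(config$n_trios), function(t)
    paste0("TRIO", t, c("_C", "_F", "_M"))))
  n_extra <- config$n_samples - length(trio)
  c(trio, sprintf("SAMPLE%02d", seq_len(n_extra)))
}

.type_delta <- c(DEL = -1, DUP = 1, INV = 0, MEI = 0, BND = 0)

# strands by type; MEI/BND share the direct (+,-) orientation
.sim_strands <- list(DEL = c("+", "-"), MEI = c("+", "-"),
                     BND = c("+", "-"), DUP = c("-", "+"),
                     INV = c("+", "+"))

#' Simulate the cohort truth table
#'
#' Draws variant positions (laid out with generous spacing so distinct
#' variants never collide), allele frequencies from the configured Beta
#' distribution, unrelated genotypes under Hardy-Weinberg equilibrium
#' and trio children by Mendelian transmission of one parental allele
#' each.
#'
#' @param config a `sim_config`.
#' @return a list of class `sv_truth`: `variants` (an `sv_callset` with
#'   true coordinates and types), `gt` (character matrix variants x
#'   samples), `af`, `me_bed` (mobile-element annotation), `pedigree`
#'   and `samples`.
#' @export
simulate_truth <- function(config) {
  set.seed(config$seed)
  samples <- sim_sample_names(config)
  types <- rep(names(config$n_variants), config$n_variants)
  n <- length(types)
  # interleave types deterministically, then lay out on contigs
  types <- types[order(rep_len(seq_along(config$n_variants), n))]
  types <- sample(types)
  stride <- 9000L
  margin <- 50000L
  per_contig <- ceiling(n / length(config$contigs))
  need <- margin * 2 + per_contig * stride
  if (any(config$contigs < need)) {
    stop("contigs too short for requested variant count")
  }
  contig_of <- rep(names(config$contigs), each = per_contig)[seq_len(n)]
  slot <- unlist(lapply(table(factor(contig_of, names(config$contigs))),
                        seq_len))
  posA <- margin + (slot - 1L) * stride +
    sample(0:1000, n, replace = TRUE)
  len <- ifelse(types == "MEI", 300L, sample(500:5000, n, replace = TRUE))
  posB <- posA + len
  ids <- sprintf("%s_%04d", types, stats::ave(seq_len(n), types,
                                              FUN = seq_along))
  strA <- vapply(types, function(t) .sim_strands[[t]][1], "")
  strB <- vapply(types, function(t) .sim_strands[[t]][2], "")
  variants <- sv_callset(id = ids, chromA = contig_of, posA = posA,
                         strandA = strA, chromB = contig_of, posB = posB,
                         strandB = strB, svtype = types, su = 0L)
  af <- stats::rbeta(n, config$af_beta[1], config$af_beta[2])
  af <- pmin(pmax(af, config$af_range[1]), config$af_range[2])
  gt <- matrix("0/0", n, length(samples), dimnames = list(ids, samples))
  draw_gt <- function(p, k) {
    probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    c("0/0", "0/1", "1/1")[sample.int(3, k, replace = TRUE, prob = probs)]
  }
  transmit <- function(g) {
    # one allele from a parental genotype string
    al <- as.integer(strsplit(g, "/", fixed = TRUE)[[1]])
    al[sample.int(2, 1)]
  }
  trio_cols <- lapply(seq_len(config$n_trios), function(t)
    match(paste0("TRIO", t, c("_C", "_F", "_M")), samples))
  unrelated <- setdiff(seq_along(samples),
                       unlist(lapply(trio_cols, `[`, 1L)))
  for (v in seq_len(n)) {
    gt[v, unrelated] <- draw_gt(af[v], length(unrelated))
    for (tc in trio_cols) {
      a <- sort(c(transmit(gt[v, tc[2]]), transmit(gt[v, tc[3]])))
      gt[v, tc[1]] <- paste(a, collapse = "/")
    }
  }
  # mobile-element annotation: one element under each MEI plus decoys
  mei <- which(types == "MEI")
  decoy_at <- posA + stride - 800L
  decoys <- sample(seq_len(n), min(50L, n))
  me_bed <- rbind(
    if (length(mei)) data.frame(chrom = contig_of[mei],
                                start = posA[mei] - 1L, end = posB[mei],
                                class = "ALU", stringsAsFactors = FALSE),
    data.frame(chrom = contig_of[decoys], start = decoy_at[decoys],
               end = decoy_at[decoys] + 300L, class = "L1",
               stringsAsFactors = FALSE)
  )
  me_bed <- me_bed[order(chrom_rank(me_bed$chrom, names(config$contigs)),
                         me_bed$start), ]
  rownames(me_bed) <- NULL
  ped <- if (config$n_trios > 0) {
    sv_pedigree(paste0("TRIO", seq_len(config$n_trios), "_C"),
                paste0("TRIO", seq_len(config$n_trios), "_F"),
                paste0("TRIO", seq_len(config$n_trios), "_M"))
  } else sv_pedigree(character(0), character(0), character(0))
  difficult <- stats::runif(n) < config$bad_variant_rate
  structure(list(config = config, samples = samples, variants = variants,
                 gt = gt, af = af, me_bed = me_bed, pedigree = ped,
                 difficult = difficult),
            class = "sv_truth")
}

#' @export
print.sv_truth <- function(x, ...) {
  cat(sprintf("<sv_truth: %d variants x %d samples, %d trios>\n",
              nrow(x$variants), length(x$samples), nrow(x$pedigree)))
  invisible(x)
}

# discretized Gaussian probability vector over the CI around pos
gaussian_dist <- function(chrom, pos, halfwidth, sd) {
  lo <- max(0L, pos - 1L - halfwidth)
  hi <- pos - 1L + halfwidth
  p <- stats::dnorm(lo:hi, mean = pos - 1L, sd = max(sd, 0.5))
  make_distribution(lo, p, chrom)
}

# discovery call rows for one truth variant in one carrier sample.
# MEI presents as a direct-orientation deletion-like breakpoint; an
# inversion emits its two inverted breakpoints as separate records.
discovery_rows <- function(truth, v, sample, dosage, config) {
  tv <- truth$variants[v, ]
  jit <- function(p) max(1L, p + as.integer(round(stats::rnorm(1, 0,
                                                   config$jitter_sd))))
  su <- max(1L, stats::rpois(1, config$su_mean * dosage / 2 +
                               config$su_mean / 2))
  mk <- function(id, pA, sA, pB, sB, svtype) {
    if (pB < pA) { tmp <- pA; pA <- pB; pB <- tmp }
    sv_callset(id = id, chromA = tv$chromA, posA = pA, strandA = sA,
               chromB = tv$chromB, posB = pB, strandB = sB,
               svtype = svtype, su = su, sample = sample,
               distA = list(gaussian_dist(tv$chromA, pA,
                                          config$ci_halfwidth,
                                          config$pr_sd)),
               distB = list(gaussian_dist(tv$chromB, pB,
                                          config$ci_halfwidth,
                                          config$pr_sd)))
  }
  if (tv$svtype == "INV") {
    bind_callsets(list(
      mk(paste0(tv$id, "_bp1"), jit(tv$posA), "+", jit(tv$posB), "+", "INV"),
      mk(paste0(tv$id, "_bp2"), jit(tv$posA + 1L), "-", jit(tv$posB + 1L),
         "-", "INV")
    ))
  } else {
    svtype <- switch(tv$svtype, MEI = "DEL", BND = "BND", tv$svtype)
    mk(tv$id, jit(tv$posA), tv$strandA, jit(tv$posB), tv$strandB, svtype)
  }
}

#' Emit per-sample discovery VCFs
#'
#' Each carrier sample receives one record per carried variant (two for
#' inversions: the `(+,+)` and `(-,-)` breakpoints) unless the variant is
#' missed at the configured rate.  Breakpoint positions are perturbed by
#' rounded Gaussian jitter and the PRPOS/PREND annotations carry a
#' discretized Gaussian over the confidence interval centered on the
#' perturbed position.  Mobile-element insertions present with the
#' deletion-like direct orientation, as a breakpoint caller would report
#' them.
#'
#' @param truth an `sv_truth`.
#' @param dir optional output directory; when given, one
#'   `discovery/<sample>.vcf` per sample is written.
#' @return named list of per-sample `sv_vcf` objects.
#' @export
emit_discovery_vcfs <- function(truth, dir = NULL) {
  config <- truth$config
  set.seed(config$seed + 1L)
  out <- list()
  for (s in truth$samples) {
    dos <- gt_dosage(truth$gt[, s, drop = FALSE])[, 1]
    rows <- list()
    for (v in which(dos > 0)) {
      if (stats::runif(1) < config$miss_rate) next
      rows[[length(rows) + 1L]] <- discovery_rows(truth, v, s, dos[v],
                                                  config)
    }
    calls <- sort_callset(bind_callsets(rows), names(config$contigs))
    gtcol <- matrix(c("0/0", "0/1", "1/1")[dos[match(
      sub("_bp[12]$", "", calls$id), truth$variants$id)] + 1L],
      nrow(calls), 1)
    vcf <- callset_to_svvcf(calls, config$contigs, samples = s,
                            format = "GT", geno = gtcol)
    out[[s]] <- vcfsort(vcf)
  }
  if (!is.null(dir)) {
    dir.create(file.path(dir, "discovery"), recursive = TRUE,
               showWarnings = FALSE)
    for (s in names(out)) {
      write_svvcf(out[[s]], file.path(dir, "discovery", paste0(s, ".vcf")))
    }
  }
  out
}

# map site ids back to truth rows (site ids inherit the truth id through
# merging; inversion breakpoints carry a _bp1/_bp2 suffix and duplicated
# merged ids a .k suffix)
site_truth_rows <- function(site_ids, truth) {
  base <- sub("_bp[12]$", "", sub("\\.[0-9]+$", "", site_ids))
  match(base, truth$variants$id)
}

#' Emit re-genotyped per-sample VCFs and a copy-number table
#'
#' Emulates breakpoint re-genotyping and read-depth copy-number
#' estimation at a fixed site list (every sample is genotyped at every
#' site).  Allele balance is drawn around 0, 0.5 or 1 according to the
#' emitted genotype; copy number is `2 + dosage * delta` (delta -1 for
#' DEL, +1 for DUP, 0 otherwise) from the true dosage plus Gaussian
#' noise; genotypes are flipped to a wrong value at the configured error
#' rate, with erroneous carrier calls drawing low sample qualities.
#'
#' @param truth an `sv_truth`.
#' @param sites an `sv_callset` of sites to genotype (typically the
#'   merged callset); default: the truth variants.
#' @param dir optional output directory (`genotyped/<sample>.vcf` plus
#'   `cn_table.tsv`).
#' @return list with `vcfs` (named list of single-sample `sv_vcf`),
#'   `cn_table` (samples x sites data.frame) and `sites`.
#' @export
emit_genotyped <- function(truth, sites = NULL, dir = NULL) {
  config <- truth$config
  set.seed(config$seed + 2L)
  if (is.null(sites)) sites <- truth$variants
  trow <- site_truth_rows(sites$id, truth)
  if (anyNA(trow)) {
    stop("sites contain ids not traceable to truth variants: ",
         paste(utils::head(sites$id[is.na(trow)], 3), collapse = ", "))
  }
  nsite <- nrow(sites)
  ns <- length(truth$samples)
  delta <- .type_delta[truth$variants$svtype[trow]]
  gts <- c("0/0", "0/1", "1/1")
  cn_table <- matrix(NA_real_, ns, nsite,
                     dimnames = list(truth$samples, sites$id))
  vcfs <- list()
  difficult <- truth$difficult[trow]
  flip_rate <- ifelse(difficult, config$bad_gt_error, config$gt_error_rate)
  for (k in seq_len(ns)) {
    s <- truth$samples[k]
    true_gt <- truth$gt[trow, s]
    true_dos <- gt_dosage(matrix(true_gt, ncol = 1))[, 1]
    obs_gt <- true_gt
    flip <- stats::runif(nsite) < flip_rate
    for (i in which(flip)) {
      obs_gt[i] <- sample(setdiff(gts, true_gt[i]), 1)
    }
    obs_dos <- gt_dosage(matrix(obs_gt, ncol = 1))[, 1]
    ab <- pmin(pmax(obs_dos / 2 +
                      stats::rnorm(nsite, 0, config$ab_noise_sd), 0), 1)
    cn <- pmax(2 + true_dos * delta +
                 stats::rnorm(nsite, 0, config$cn_noise_sd), 0)
    sq <- ifelse(obs_dos > 0,
                 ifelse(flip | difficult,
                        stats::runif(nsite, config$sq_error[1],
                                     config$sq_error[2]),
                        stats::runif(nsite, config$sq_correct[1],
                                     config$sq_correct[2])),
                 0)
    cn_table[k, ] <- cn
    geno <- matrix(paste(obs_gt, fmt_num(sq), as.integer(round(sq)),
                         fmt_num(ab), sep = ":"), nsite, 1)
    vcfs[[s]] <- callset_to_svvcf(sites, config$contigs, samples = s,
                                  format = "GT:SQ:GQ:AB", geno = geno)
  }
  cn_df <- as.data.frame(cn_table)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "genotyped"), recursive = TRUE,
               showWarnings = FALSE)
    for (s in names(vcfs)) {
      write_svvcf(vcfs[[s]], file.path(dir, "genotyped", paste0(s, ".vcf")))
    }
    write_cn_table(cn_df, file.path(dir, "cn_table.tsv"))
  }
  list(vcfs = vcfs, cn_table = cn_df, sites = sites)
}

#' Write the fixture corpus for a simulated cohort
#'
#' Convenience wrapper producing, under `dir`: per-sample discovery VCFs,
#' the mobile-element BED, the pedigree file and the truth table
#' (`truth.tsv` with variant coordinates and types, `truth_gt.tsv` with
#' per-sample genotypes).  Re-genotyped VCFs are emitted separately with
#' [emit_genotyped()] once a merged site list exists.
#'
#' @param config a `sim_config`.
#' @param dir output directory.
#' @return the `sv_truth`, invisibly.
#' @export
simulate_cohort <- function(config, dir) {
  truth <- simulate_truth(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  emit_discovery_vcfs(truth, dir = dir)
  utils::write.table(
    data.frame(id = truth$variants$id, svtype = truth$variants$svtype,
               chromA = truth$variants$chromA, posA = truth$variants$posA,
               chromB = truth$variants$chromB, posB = truth$variants$posB,
               af = truth$af),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(data.frame(id = rownames(truth$gt), truth$gt,
                                check.names = FALSE),
                     file.path(dir, "truth_gt.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$me_bed, file.path(dir, "mobile_elements.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_pedigree(truth$pedigree, file.path(dir, "pedigree.ped"))
  invisible(truth)
}
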