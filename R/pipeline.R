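# End-to-end cohort pipeline on a simulated study: discovery -> lsort ->
# lmerge -> re-genotyping -> vcfpaste -> copy number -> allele frequency
# -> classification -> confidence scoring -> QC.  Mirrors how the
# individual tools chain on real data, with the simulator standing in for
# the per-sample discovery, genotyping and read-depth steps.

#' Run the full cohort pipeline on a simulated study
#'
#' Simulates a cohort, merges the per-sample discovery calls, assembles
#' and annotates the cohort callset, re-classifies it and computes the QC
#' reports.  The classifier defaults to naive Bayes, the appropriate
#' choice at small cohort sizes; the model is trained on the generator's
#' labels (in practice one would train on a previously classified
#' callset), with mobile-element insertions contributing to the balanced
#' class since they leave copy number unchanged.
#'
#' @param config a [sim_config()].
#' @param classify_method `"naive-bayes"` or `"regression"`.
#' @param slop merge slop in bases (default 0: the probability supports
#'   already carry the positional uncertainty).
#' @param msq_min per-type MSQ thresholds for the high-confidence subset.
#' @return a list: `truth`, `merged` (callset), `cohort` (classified and
#'   scored `sv_cohort`), `high_conf` cohort, data.frames `sensitivity`,
#'   `me_all`, `me_high_conf`, and `accuracy` (fraction of callset
#'   variants whose classified type equals the generator label).
#' @export
run_cohort_pipeline <- function(config,
                                classify_method = c("naive-bayes",
                                                    "regression"),
                                slop = 0L,
                                msq_min = c(DEL = 100, DUP = 100,
                                            INV = 100, MEI = 100,
                                            BND = 250)) {
  classify_method <- match.arg(classify_method)
  truth <- simulate_truth(config)
  disc <- emit_discovery_vcfs(truth)
  sorted <- lsort(vcfs = disc)
  calls <- svvcf_to_callset(sorted)
  merged <- lmerge(calls, slop = slop, contigs = names(config$contigs))
  merged$id <- make.unique(merged$id, sep = ".")
  geno <- emit_genotyped(truth, sites = merged)
  site_vcf <- callset_to_svvcf(merged, config$contigs)
  cohort <- as_cohort(vcfpaste(site_vcf, geno$vcfs))
  cohort <- afreq(attach_copynumber(cohort, geno$cn_table))
  trow <- site_truth_rows(cohort$calls$id, truth)
  nbm <- NULL
  if (classify_method == "naive-bayes") {
    labels <- truth$variants$svtype[trow]
    labels[labels == "MEI"] <- "BND"  # copy-number-balanced class
    nbm <- train_nb(cohort, labels)
  }
  cohort <- sv_classify(cohort, classify_method, me_bed = truth$me_bed,
                        nb_model = nbm)
  cohort <- score_confidence(cohort)
  high_conf <- filter_high_confidence(cohort, msq_min)
  trow2 <- site_truth_rows(cohort$calls$id, truth)
  list(
    truth = truth,
    merged = merged,
    cohort = cohort,
    high_conf = high_conf,
    sensitivity = sensitivity_vs_truth(cohort, truth$variants, truth$gt),
    me_all = mendelian_error_rate(cohort, truth$pedigree),
    me_high_conf = mendelian_error_rate(high_conf, truth$pedigree),
    accuracy = mean(cohort$calls$svtype == truth$variants$svtype[trow2])
  )
}
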