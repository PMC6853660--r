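test_that("identical seeds give byte-identical fixture corpora", {
  cfg <- sim_config(n_samples = 6, n_trios = 1,
                    n_variants = c(DEL = 10L, DUP = 5L, INV = 3L, MEI = 5L,
                                   BND = 3L), seed = 12)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_cohort(cfg, d1)
  simulate_cohort(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("unrelated genotype frequencies follow Hardy-Weinberg", {
  cfg <- sim_config(n_samples = 2000L, n_trios = 0L,
                    n_variants = c(DEL = 20L, DUP = 0L, INV = 0L, MEI = 0L,
                                   BND = 0L),
                    af_beta = c(2, 4), af_range = c(0.05, 0.95), seed = 3)
  truth <- simulate_truth(cfg)
  within3 <- 0
  for (v in seq_len(20)) {
    p <- truth$af[v]
    exp_het <- 2 * p * (1 - p)
    obs_het <- mean(truth$gt[v, ] == "0/1")
    se <- sqrt(exp_het * (1 - exp_het) / 2000)
    expect_lt(abs(obs_het - exp_het), 4.5 * se)
    if (abs(obs_het - exp_het) < 3 * se) within3 <- within3 + 1
  }
  expect_gte(within3, 17)
})

test_that("degenerate allele frequencies produce monomorphic genotypes", {
  cfg0 <- sim_config(n_samples = 20L, n_trios = 2L,
                     n_variants = c(DEL = 5L, DUP = 0L, INV = 0L, MEI = 0L,
                                    BND = 0L),
                     af_range = c(0, 0), seed = 2)
  expect_true(all(simulate_truth(cfg0)$gt == "0/0"))
  cfg1 <- cfg0; cfg1$af_range <- c(1, 1)
  expect_true(all(simulate_truth(cfg1)$gt == "1/1"))
})

test_that("trio children inherit one allele from each parent", {
  cfg <- sim_config(n_samples = 12L, n_trios = 4L,
                    n_variants = c(DEL = 40L, DUP = 0L, INV = 0L, MEI = 0L,
                                   BND = 0L),
                    af_range = c(0.2, 0.8), seed = 44)
  truth <- simulate_truth(cfg)
  for (t in seq_len(4)) {
    gc <- truth$gt[, paste0("TRIO", t, "_C")]
    gf <- truth$gt[, paste0("TRIO", t, "_F")]
    gm <- truth$gt[, paste0("TRIO", t, "_M")]
    for (v in seq_along(gc)) {
      expect_true(svcohort:::mendelian_consistent(gc[v], gf[v], gm[v]))
    }
  }
})

test_that("breakpoint jitter has the half-normal mean deviation", {
  cfg <- sim_config(n_samples = 40L, n_trios = 0L,
                    n_variants = c(DEL = 60L, DUP = 0L, INV = 0L, MEI = 0L,
                                   BND = 0L),
                    af_range = c(0.4, 0.8), miss_rate = 0, jitter_sd = 10,
                    seed = 6)
  truth <- simulate_truth(cfg)
  calls <- svvcf_to_callset(lsort(vcfs = emit_discovery_vcfs(truth)))
  dev <- abs(calls$posA - truth$variants$posA[match(calls$id,
                                                   truth$variants$id)])
  expected <- 10 * sqrt(2 / pi)
  se <- 10 * sqrt(1 - 2 / pi) / sqrt(length(dev))
  expect_lt(abs(mean(dev) - expected), 3 * se + 0.3)  # + rounding slack
})

test_that("zero jitter reproduces truth positions and miss rate one empties", {
  cfg <- sim_config(n_samples = 6L, n_trios = 0L,
                    n_variants = c(DEL = 10L, DUP = 5L, INV = 0L, MEI = 5L,
                                   BND = 0L),
                    af_range = c(0.4, 0.8), miss_rate = 0, jitter_sd = 0,
                    seed = 15)
  truth <- simulate_truth(cfg)
  calls <- svvcf_to_callset(lsort(vcfs = emit_discovery_vcfs(truth)))
  tmatch <- match(calls$id, truth$variants$id)
  expect_equal(calls$posA, truth$variants$posA[tmatch])
  expect_equal(calls$posB, truth$variants$posB[tmatch])

  cfg$miss_rate <- 1
  vcfs <- emit_discovery_vcfs(simulate_truth(cfg))
  expect_true(all(vapply(vcfs, function(v) nrow(v$records), 1L) == 0))
})

test_that("noise-free genotyped emissions hit the textbook values", {
  cfg <- sim_config(n_samples = 10L, n_trios = 0L,
                    n_variants = c(DEL = 10L, DUP = 5L, INV = 0L, MEI = 0L,
                                   BND = 5L),
                    af_range = c(0.3, 0.8), ab_noise_sd = 0,
                    cn_noise_sd = 0, gt_error_rate = 0,
                    bad_variant_rate = 0, seed = 25)
  truth <- simulate_truth(cfg)
  geno <- emit_genotyped(truth)
  coh <- as_cohort(vcfpaste(callset_to_svvcf(truth$variants, cfg$contigs),
                            geno$vcfs))
  coh <- attach_copynumber(coh, geno$cn_table)
  types <- truth$variants$svtype
  homalt <- coh$gt == "1/1"
  del <- types == "DEL"
  expect_true(all(coh$ab[del, ][homalt[del, ]] == 1))
  expect_true(all(coh$cn[del, ][homalt[del, ]] == 0))
  # balanced break-ends keep copy number 2 whatever the genotype
  expect_true(all(coh$cn[types == "BND", ] == 2))
  # duplications gain one copy per allele
  expect_true(all(coh$cn[types == "DUP", ][homalt[types == "DUP", ]] == 4))
})

test_that("regression on emitted deletions recovers the expected slope", {
  cfg <- sim_config(n_samples = 150L, n_trios = 0L,
                    n_variants = c(DEL = 12L, DUP = 0L, INV = 0L, MEI = 0L,
                                   BND = 0L),
                    af_range = c(0.3, 0.7), seed = 35)
  truth <- simulate_truth(cfg)
  geno <- emit_genotyped(truth)
  coh <- as_cohort(vcfpaste(callset_to_svvcf(truth$variants, cfg$contigs),
                            geno$vcfs))
  coh <- attach_copynumber(coh, geno$cn_table)
  for (i in seq_len(6)) {
    fit <- fit_ab_cn_regression(coh$ab[i, ], coh$cn[i, ], coh$gt[i, ])
    se <- sqrt(sum(stats::residuals(stats::lm(coh$cn[i, ] ~ coh$ab[i, ]))^2) /
                 (fit$n - 2) / sum((coh$ab[i, ] - mean(coh$ab[i, ]))^2))
    expect_lt(abs(fit$slope - (-2)), 3 * se + 0.05)
  }
})

test_that("fixture VCFs parse cleanly through the io layer", {
  cfg <- sim_config(n_samples = 5L, n_trios = 0L,
                    n_variants = c(DEL = 8L, DUP = 4L, INV = 3L, MEI = 4L,
                                   BND = 3L), seed = 61)
  truth <- simulate_truth(cfg)
  vcfs <- emit_discovery_vcfs(truth)
  expect_no_warning({
    for (v in vcfs) svvcf_to_callset(v)
  })
})
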