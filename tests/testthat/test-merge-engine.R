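test_that("distribution overlap follows widened support intersection", {
  d <- function(start, n) make_distribution(start, rep(1, n), "chr1")
  expect_true(distributions_overlap(d(100, 5), d(103, 5)))
  expect_false(distributions_overlap(d(100, 5), d(106, 5)))
  expect_true(distributions_overlap(d(100, 5), d(106, 5), slop = 1))
  # different chromosomes never overlap
  expect_false(distributions_overlap(make_distribution(100, 1, "chr1"),
                                     make_distribution(100, 1, "chr2")))
})

test_that("overlap verdicts match a set-intersection oracle", {
  set.seed(3)
  for (rep in 1:200) {
    a <- make_distribution(sample(0:50, 1), stats::runif(sample(1:20, 1)))
    b <- make_distribution(sample(0:50, 1), stats::runif(sample(1:20, 1)))
    slop <- sample(0:3, 1)
    sa <- dist_support(a, slop); sb <- dist_support(b, slop)
    oracle <- length(intersect(seq(sa[1], sa[2]), seq(sb[1], sb[2]))) > 0
    expect_identical(distributions_overlap(a, b, slop), oracle)
  }
})

test_that("clustering links calls overlapping at both breakends", {
  a <- make_call("a", 100, 5100, probsA = rep(1, 11), startA = 94,
                 probsB = rep(1, 11), startB = 5094)
  b <- make_call("b", 105, 5105, probsA = rep(1, 11), startA = 99,
                 probsB = rep(1, 11), startB = 5099, sample = "S2")
  # same A support, disjoint B support
  c2 <- make_call("c", 102, 9000, probsA = rep(1, 11), startA = 96,
                  probsB = rep(1, 11), startB = 8994, sample = "S3")
  cl <- cluster_calls(sort_callset(bind_rows_callset(list(a, b, c2))))
  expect_length(cl, 2)
  expect_setequal(cl[[1]]$id, c("a", "b"))
  expect_equal(cl[[2]]$id, "c")
})

test_that("single linkage is transitive through a chain", {
  mk <- function(id, pA) make_call(id, pA, 5000, probsA = rep(1, 21),
                                   startA = pA - 11, probsB = rep(1, 200),
                                   startB = 4899, sample = id)
  # a-b overlap, b-c overlap, a-c disjoint at breakend A
  calls <- sort_callset(bind_rows_callset(list(mk("a", 100), mk("b", 118),
                                               mk("c", 136))))
  cl <- cluster_calls(calls)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$id, c("a", "b", "c"))
})

test_that("clustering equals brute-force union-find on random inputs", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(5:60, 1)
    calls <- random_callset(n)
    got <- canon_clusters(lapply(cluster_calls(calls), function(s) s$id))
    want <- canon_clusters(oracle_clusters(calls))
    expect_identical(got, want)
  }
  # one larger case
  calls <- random_callset(200, span = 20000L)
  expect_identical(canon_clusters(lapply(cluster_calls(calls),
                                         function(s) s$id)),
                   canon_clusters(oracle_clusters(calls)))
})

test_that("unsorted input is rejected with the offending call named", {
  a <- make_call("a", 500, 5000)
  b <- make_call("b", 100, 5000)
  calls <- bind_rows_callset(list(a, b))  # deliberately unsorted
  expect_error(cluster_calls(calls), "not sorted.*\\bb\\b")
})

test_that("combining a singleton cluster is the identity", {
  a <- make_call("a", 100, 5100, probsA = c(0.2, 0.6, 0.2), startA = 98,
                 probsB = c(0.4, 0.6), startB = 5098)
  out <- combine_cluster(a)
  expect_equal(out$posA, a$posA)
  expect_equal(out$posB, a$posB)
  expect_equal(out$distA[[1]]$start, a$distA[[1]]$start)
  expect_equal(out$distA[[1]]$probs, a$distA[[1]]$probs)
  expect_equal(out$su, a$su)
  expect_equal(out$snames[[1]], a$snames[[1]])
})

test_that("combined distributions are the weighted per-base sum", {
  a <- make_call("a", 101, 5100, probsA = c(0.2, 0.8), startA = 99,
                 probsB = 1, startB = 5099)
  b <- make_call("b", 100, 5100, probsA = c(0.6, 0.4), startA = 99,
                 probsB = 1, startB = 5099, sample = "S2")
  cl <- bind_rows_callset(list(a, b))
  out <- combine_cluster(cl, weighting = "uniform")
  expect_equal(out$distA[[1]]$probs, c(0.4, 0.6))
  expect_equal(out$posA, 101)
  # evidence weighting: SU 9 at mode 100 dominates SU 1 at mode 110
  hi <- make_call("hi", 100, 5100, su = 9L,
                  probsA = c(rep(0.5 / 10, 5), 0.5, rep(0.5 / 10, 5)),
                  startA = 94, probsB = 1, startB = 5099)
  lo <- make_call("lo", 110, 5100, su = 1L,
                  probsA = c(rep(0.5 / 10, 5), 0.5, rep(0.5 / 10, 5)),
                  startA = 104, probsB = 1, startB = 5099, sample = "S2")
  out2 <- combine_cluster(bind_rows_callset(list(hi, lo)),
                          weighting = "evidence")
  expect_equal(out2$posA, 100)
  expect_equal(out2$su, 10L)
})

test_that("lmerge recovers the truth count and refines within member CIs", {
  cfg <- sim_config(n_samples = 10, n_trios = 0,
                    n_variants = c(DEL = 30L, DUP = 20L, INV = 0L, MEI = 0L,
                                   BND = 0L),
                    af_range = c(0.5, 0.9),  # every variant carried somewhere
                    miss_rate = 0, seed = 13)
  truth <- simulate_truth(cfg)
  calls <- svvcf_to_callset(lsort(vcfs = emit_discovery_vcfs(truth)))
  merged <- lmerge(calls, contigs = names(cfg$contigs))
  expect_equal(nrow(merged), 50)
  # partition property: every input call contributes exactly once
  expect_equal(sum(lengths(merged$snames)), nrow(calls))
  expect_equal(sum(merged$su), sum(calls$su))
  # refined positions stay within the union of member supports
  for (i in seq_len(nrow(merged))) {
    members <- match(sub("^[^:]+:", "", merged$snames[[i]]), calls$id)
    sups <- vapply(calls$distA[members], dist_support, integer(2))
    expect_gte(merged$posA[i] - 1, min(sups))
    expect_lte(merged$posA[i] - 1, max(sups))
  }
  # merging sharpens localization relative to per-sample calls
  tmatch <- match(merged$id, truth$variants$id)
  merged_err <- stats::median(abs(merged$posA - truth$variants$posA[tmatch]))
  input_err <- stats::median(abs(calls$posA -
    truth$variants$posA[match(calls$id, truth$variants$id)]))
  expect_lte(merged_err, input_err)
})

test_that("lmerge is idempotent and self-merge preserves counts", {
  cfg <- sim_config(n_samples = 6, n_trios = 0,
                    n_variants = c(DEL = 20L, DUP = 10L, INV = 5L, MEI = 5L,
                                   BND = 5L),
                    af_range = c(0.4, 0.9), seed = 21)
  calls <- svvcf_to_callset(lsort(vcfs =
    emit_discovery_vcfs(simulate_truth(cfg))))
  merged <- lmerge(calls, contigs = names(cfg$contigs))
  # fixed point: re-merging the merged output changes nothing
  again <- lmerge(merged, contigs = names(cfg$contigs))
  expect_equal(again$posA, merged$posA)
  expect_equal(again$posB, merged$posB)
  expect_equal(nrow(again), nrow(merged))
  # merging a callset with itself yields the same variant count
  doubled <- sort_callset(bind_rows_callset(list(calls, calls)))
  expect_equal(nrow(lmerge(doubled, contigs = names(cfg$contigs))),
               nrow(merged))
})

test_that("tiered merging matches bulk merging on low-jitter cohorts", {
  cfg <- sim_config(n_samples = 12, n_trios = 0,
                    n_variants = c(DEL = 25L, DUP = 15L, INV = 5L, MEI = 10L,
                                   BND = 5L),
                    af_range = c(0.4, 0.9), jitter_sd = 2, seed = 31)
  truth <- simulate_truth(cfg)
  vcfs <- emit_discovery_vcfs(truth)
  bulk <- lmerge(svvcf_to_callset(lsort(vcfs = vcfs)),
                 contigs = names(cfg$contigs))
  batches <- lapply(split(seq_along(vcfs), rep(1:3, length.out = length(vcfs))),
                    function(ix) svvcf_to_callset(lsort(vcfs = vcfs[ix])))
  tiered <- tiered_merge(batches, contigs = names(cfg$contigs))
  expect_equal(nrow(tiered), nrow(bulk))
  expect_equal(sum(lengths(tiered$snames)), sum(lengths(bulk$snames)))
  # single batch degenerates to plain lmerge
  one <- tiered_merge(list(svvcf_to_callset(lsort(vcfs = vcfs))),
                      contigs = names(cfg$contigs))
  expect_equal(one$posA, bulk$posA)
  expect_equal(nrow(one), nrow(bulk))
})
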