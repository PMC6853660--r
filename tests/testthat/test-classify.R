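test_that("regression fits exact lines to closed form", {
  fit_del <- fit_ab_cn_regression(ab = c(0, 0.5, 1), cn = c(2, 1, 0),
                                  gt = c("0/0", "0/1", "1/1"),
                                  min_informative = 3)
  expect_equal(fit_del$slope, -2, tolerance = 1e-9)
  expect_equal(fit_del$intercept, 2, tolerance = 1e-9)
  expect_equal(fit_del$r2, 1, tolerance = 1e-9)
  fit_dup <- fit_ab_cn_regression(ab = c(0, 0.5, 1), cn = c(2, 3, 4),
                                  gt = c("0/0", "0/1", "1/1"),
                                  min_informative = 3)
  expect_equal(fit_dup$slope, 2, tolerance = 1e-9)
})

test_that("regression matches the textbook OLS closed form on noisy data", {
  set.seed(19)
  for (rep in 1:10) {
    n <- 40
    ab <- stats::runif(n)
    cn <- 2 - 2 * ab + stats::rnorm(n, 0, 0.3)
    fit <- fit_ab_cn_regression(ab, cn, gt = rep("0/1", n))
    slope_cf <- stats::cov(ab, cn) / stats::var(ab)
    expect_equal(fit$slope, slope_cf, tolerance = 1e-9)
    expect_equal(fit$intercept, mean(cn) - slope_cf * mean(ab),
                 tolerance = 1e-9)
    expect_equal(fit$r2, stats::cor(ab, cn)^2, tolerance = 1e-9)
  }
})

test_that("under-informative input yields an undefined fit", {
  expect_null(fit_ab_cn_regression(ab = c(0, 0.5), cn = c(2, 1),
                                   gt = c("0/0", "0/1")))  # too few
  expect_null(fit_ab_cn_regression(ab = rep(0.5, 10), cn = stats::runif(10),
                                   gt = rep("0/1", 10),
                                   min_informative = 8))  # zero AB variance
  expect_null(fit_ab_cn_regression(ab = stats::runif(10), cn = stats::runif(10),
                                   gt = rep("0/0", 10)))  # no carrier
})

test_that("regression thresholds map slopes to types", {
  mkfit <- function(slope, r2) structure(list(slope = slope, intercept = 2,
                                              n = 30, r2 = r2),
                                         class = "ab_cn_fit")
  expect_equal(classify_by_regression("BND", "+", "-", mkfit(-2, 1)), "DEL")
  expect_equal(classify_by_regression("BND", "-", "+", mkfit(2, 1)), "DUP")
  expect_equal(classify_by_regression("BND", "+", "-", mkfit(0.05, 0.01)),
               "BND")
  # strand compatibility: a (-,+) call can never become DEL
  expect_equal(classify_by_regression("BND", "-", "+", mkfit(-2, 1)), "BND")
  expect_equal(classify_by_regression("BND", "+", "-", mkfit(2, 1)), "BND")
  # confident slope but poor fit stays balanced
  expect_equal(classify_by_regression("BND", "+", "-", mkfit(-2, 0.05)),
               "BND")
  # undefined fit retains the original type
  expect_equal(classify_by_regression("DEL", "+", "-", NULL), "DEL")
})

test_that("regression recovers classes at low noise, degrading with noise", {
  set.seed(33)
  # 100 variants per class, >= 100 carriers each
  acc1 <- panel_accuracy(simulate_class_panel(100, 250, 0.5, 0.05, 0.25))
  expect_gte(acc1, 0.99)
  acc2 <- panel_accuracy(simulate_class_panel(100, 250, 0.5, 0.10, 0.60))
  acc3 <- panel_accuracy(simulate_class_panel(100, 250, 0.5, 0.20, 1.20))
  expect_gte(acc1, acc2)
  expect_gte(acc2, acc3)
})

test_that("naive Bayes picks the nearest copy-number class", {
  # training panel with canonical means: DEL het 1, DUP het 3, BND het 2
  set.seed(4)
  panel <- simulate_class_panel(25, 40, 0.5, 0.05, 0.2)
  coh <- list(gt = panel$gt, cn = panel$cn)
  model <- train_nb(coh, panel$classes)
  expect_equal(unname(model$params["DEL", "0/1", "mean"]), 1, tolerance = 0.1)
  expect_equal(unname(model$params["DUP", "0/1", "mean"]), 3, tolerance = 0.1)
  expect_equal(unname(model$params["BND", "0/1", "mean"]), 2, tolerance = 0.1)

  one <- function(cn_val, gt_val = "0/1", strands = c("+", "-"))
    classify_by_nb("BND", strands[1], strands[2],
                   gt = c(gt_val, "0/0"), cn = c(cn_val, 2), model = model)
  expect_equal(one(1.0), "DEL")
  expect_equal(one(2.0), "BND")
  expect_equal(one(3.0, strands = c("-", "+")), "DUP")
  # no carrier: type retained
  expect_equal(classify_by_nb("DEL", "+", "-", gt = c("0/0", "0/0"),
                              cn = c(2, 2), model = model), "DEL")
  # strand incompatibility: CN says DUP but orientation forbids it
  expect_equal(one(3.0, strands = c("+", "-")), "BND")
})

test_that("training requires every class", {
  panel <- simulate_class_panel(25, 40, 0.5, 0.05, 0.2)
  labels <- panel$classes
  labels[labels == "DUP"] <- "DEL"
  expect_error(train_nb(list(gt = panel$gt, cn = panel$cn), labels),
               "class absent")
})

test_that("naive Bayes recovers labels in a 12-sample cohort", {
  pipe <- small_pipeline()
  expect_gte(pipe$accuracy, 0.90)
})

test_that("mobile-element overlap relabels CN-neutral direct breakpoints", {
  me <- data.frame(chrom = "chr1", start = 980, end = 1280, class = "ALU")
  dA <- make_distribution(995, rep(1, 11), "chr1")
  dB <- make_distribution(1295, rep(1, 11), "chr1")
  flat <- structure(list(slope = 0.02, intercept = 2, n = 30, r2 = 0.001),
                    class = "ab_cn_fit")
  steep <- structure(list(slope = -2, intercept = 2, n = 30, r2 = 0.9),
                     class = "ab_cn_fit")
  expect_equal(classify_mei("BND", "+", "-", dA, dB, flat, me), "MEI")
  expect_equal(classify_mei("BND", "+", "-", dA, dB, NULL, me), "MEI")
  # a real deletion inside a repeat keeps its copy-number class
  expect_equal(classify_mei("DEL", "+", "-", dA, dB, steep, me), "DEL")
  # inverted orientation is never an MEI
  expect_equal(classify_mei("BND", "+", "+", dA, dB, flat, me), "BND")
  # far from any element: unchanged
  far <- data.frame(chrom = "chr1", start = 50000, end = 50300,
                    class = "L1")
  expect_equal(classify_mei("BND", "+", "-", dA, dB, flat, far), "BND")
})

# build a cohort holding only inverted-orientation breakpoint rows
inv_cohort <- function(rows) {
  calls <- sort_callset(bind_rows_callset(rows))
  n <- nrow(calls)
  structure(list(
    calls = calls, samples = "S1",
    gt = matrix("0/1", n, 1, dimnames = list(NULL, "S1")),
    sq = matrix(99, n, 1), ab = matrix(0.5, n, 1), cn = matrix(2, n, 1),
    info = data.frame(af = rep(NA_real_, n), nsamp = NA_integer_,
                      msq = NA_real_),
    contigs = "chr1", contig_lengths = c(chr1 = 1e6)
  ), class = "sv_cohort")
}

inv_bp <- function(id, posA, posB, strand) {
  make_call(id, posA, posB, svtype = "BND", strandA = strand,
            strandB = strand, probsA = rep(1, 21), startA = posA - 11,
            probsB = rep(1, 21), startB = posB - 11)
}

test_that("inverted breakpoint pairs fuse into one INV call", {
  coh <- inv_cohort(list(inv_bp("p", 1000, 2000, "+"),
                         inv_bp("m", 1005, 2005, "-")))
  out <- pair_inversions(coh)
  expect_equal(nrow(out$calls), 1)
  expect_equal(out$calls$svtype, "INV")
  expect_equal(out$calls$posA, 1000)
  expect_equal(out$calls$posB, 2005)
  expect_equal(out$calls$su, 10L)
  expect_setequal(out$calls$snames[[1]], c("S1:p", "S1:m"))
})

test_that("unpaired inverted breakpoints fall back to BND", {
  coh <- inv_cohort(list(inv_bp("lonely", 1000, 2000, "+")))
  out <- pair_inversions(coh)
  expect_equal(out$calls$svtype, "BND")
  # distant (+,+)/(-,-) calls do not pair
  coh2 <- inv_cohort(list(inv_bp("p", 1000, 2000, "+"),
                          inv_bp("m", 50000, 60000, "-")))
  out2 <- pair_inversions(coh2)
  expect_equal(sort(out2$calls$svtype), c("BND", "BND"))
})

test_that("greedy inversion pairing matches exhaustive matching on small sets", {
  # exhaustive maximum-cardinality matching over candidate pairs; among
  # those, the minimum total breakpoint distance
  best_matching <- function(npp, nmm, ok, d) {
    best_n <- 0; best_d <- Inf
    recurse <- function(i, free_mm, n, acc) {
      if (i > npp) {
        if (n > best_n || (n == best_n && acc < best_d)) {
          best_n <<- n; best_d <<- if (n > 0) acc else Inf
        }
        return()
      }
      recurse(i + 1L, free_mm, n, acc)  # leave i unmatched
      for (j in free_mm) if (ok[i, j]) {
        recurse(i + 1L, setdiff(free_mm, j), n + 1L, acc + d[i, j])
      }
    }
    recurse(1L, seq_len(nmm), 0L, 0)
    list(n = best_n, d = best_d)
  }
  set.seed(55)
  for (rep in 1:12) {
    k <- sample(2:4, 1)
    rows <- list()
    for (t in seq_len(k)) {
      # inversions 80 bp apart: cross-pairings are within the 100 bp slop,
      # so the matching is genuinely ambiguous
      base <- 10000 + t * 80
      rows <- c(rows, list(
        inv_bp(sprintf("p%d", t), base, base + 5000, "+"),
        inv_bp(sprintf("m%d", t), base + sample(0:20, 1),
               base + 5000 + sample(0:20, 1), "-")))
    }
    coh <- inv_cohort(rows)
    out <- pair_inversions(coh, inv_slop = 100L)
    # recover the greedy matching and its total distance from provenance
    inv_rows <- which(out$calls$svtype == "INV")
    ids <- lapply(out$calls$snames[inv_rows],
                  function(s) sub("^S1:", "", s))
    calls0 <- coh$calls
    greedy_d <- sum(vapply(ids, function(pr) {
      i <- match(grep("^p", pr, value = TRUE), calls0$id)
      j <- match(grep("^m", pr, value = TRUE), calls0$id)
      abs(calls0$posA[i] - calls0$posA[j]) +
        abs(calls0$posB[i] - calls0$posB[j])
    }, numeric(1)))
    pp <- which(calls0$strandA == "+")
    mm <- which(calls0$strandA == "-")
    ok <- matrix(FALSE, length(pp), length(mm))
    d <- matrix(0, length(pp), length(mm))
    for (a in seq_along(pp)) for (b in seq_along(mm)) {
      ok[a, b] <- svcohort:::inv_mutual_overlap(calls0, pp[a], mm[b], 100L)
      d[a, b] <- abs(calls0$posA[pp[a]] - calls0$posA[mm[b]]) +
        abs(calls0$posB[pp[a]] - calls0$posB[mm[b]])
    }
    oracle <- best_matching(length(pp), length(mm), ok, d)
    expect_equal(length(inv_rows), oracle$n)
    expect_equal(greedy_d, oracle$d)
  }
})
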