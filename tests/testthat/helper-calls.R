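# shared fixture builders

# one-row callset with explicit distributions (point masses by default)
make_call <- function(id, posA, posB, svtype = "DEL", chromA = "chr1",
                      chromB = chromA, su = 5L, sample = "S1",
                      strandA = NULL, strandB = NULL,
                      probsA = 1, startA = posA - 1L,
                      probsB = 1, startB = posB - 1L) {
  strands <- switch(svtype, DEL = , MEI = c("+", "-"), DUP = c("-", "+"),
                    INV = c("+", "+"), c("+", "-"))
  sv_callset(
    id = id, chromA = chromA, posA = posA,
    strandA = strandA %||% strands[1],
    chromB = chromB, posB = posB, strandB = strandB %||% strands[2],
    svtype = svtype, su = su, sample = sample,
    distA = list(make_distribution(startA, probsA, chromA)),
    distB = list(make_distribution(startB, probsB, chromB))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random callset on one chromosome for property tests: uniform-support
# distributions of random width, all in the same merge stratum
random_callset <- function(n, span = 5000L, max_width = 60L,
                           svtype = "DEL") {
  posA <- sort(sample.int(span, n, replace = TRUE)) + 200L
  posB <- posA + 10000L + sample.int(span, n, replace = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    wa <- sample.int(max_width, 1); wb <- sample.int(max_width, 1)
    make_call(sprintf("C%03d", i), posA[i], posB[i], svtype,
              su = sample.int(20, 1), sample = sprintf("S%d", i %% 5),
              probsA = rep(1, wa), startA = posA[i] - 1L - sample.int(wa, 1) + 1L,
              probsB = rep(1, wb), startB = posB[i] - 1L - sample.int(wb, 1) + 1L)
  })
  sort_callset(bind_rows_callset(rows))
}

bind_rows_callset <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(s) {
    class(s) <- "data.frame"
    s
  }))
  rownames(df) <- NULL
  class(df) <- c("sv_callset", "data.frame")
  df
}

# independent brute-force single-linkage clustering: all pairwise overlap
# tests (vectorized), then union-find over the resulting edges
oracle_clusters <- function(calls, slop = 0L) {
  n <- nrow(calls)
  key <- paste(calls$chromA, calls$chromB, calls$strandA, calls$strandB)
  sa <- t(vapply(calls$distA, dist_support, integer(2), slop = slop))
  sb <- t(vapply(calls$distB, dist_support, integer(2), slop = slop))
  ovA <- outer(sa[, 1], sa[, 2], "<=") & t(outer(sa[, 1], sa[, 2], "<="))
  ovB <- outer(sb[, 1], sb[, 2], "<=") & t(outer(sb[, 1], sb[, 2], "<="))
  link <- ovA & ovB & outer(key, key, "==")
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  edges <- which(link & upper.tri(link), arr.ind = TRUE)
  for (e in seq_len(nrow(edges))) {
    ri <- find(edges[e, 1]); rj <- find(edges[e, 2])
    if (ri != rj) comp[ri] <- rj
  }
  roots <- vapply(seq_len(n), find, 1L)
  split(calls$id, roots)
}

# canonical form of a clustering: sorted list of sorted id vectors
canon_clusters <- function(cl) {
  cl <- lapply(unname(cl), sort)
  cl[order(vapply(cl, `[`, "", 1L))]
}

# small simulated pipeline run shared across tests (cached per session)
small_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_samples = 12L, n_trios = 1L,
                        n_variants = c(DEL = 40L, DUP = 25L, INV = 10L,
                                       MEI = 20L, BND = 15L),
                        seed = 101L)
      cache <<- run_cohort_pipeline(cfg)
    }
    cache
  }
})
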