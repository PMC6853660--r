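# Resolution-aware cross-sample merging.  Calls are clustered by
# single-linkage within strata of (chromA, chromB, strand pair); two calls
# are linked when their breakend probability distributions overlap at BOTH
# breakends.  Cluster evidence is then combined per base, weighted by
# supporting-read counts, to refine the breakpoint coordinates.
#
# Because the strand pair determines the candidate type class
# (DEL/MEI and BND share (+,-); DUP and BND share (-,+); the two inversion
# orientations are (+,+) and (-,-)), stratifying by strand pair merges
# DEL with MEI candidates of identical breakpoint configuration, leaving
# their separation to the downstream classifier.

#' Do two breakend distributions overlap?
#'
#' Overlap is defined on the supports (bases with positive probability),
#' each widened by `slop` bases on both sides.
#'
#' @param a,b `breakend_distribution` objects on the same chromosome.
#' @param slop non-negative widening in bases (default 0).
#' @return logical.
#' @export
distributions_overlap <- function(a, b, slop = 0L) {
  if (!is.na(a$chrom) && !is.na(b$chrom) && a$chrom != b$chrom) return(FALSE)
  sa <- dist_support(a, slop)
  sb <- dist_support(b, slop)
  sa[1] <= sb[2] && sb[1] <= sa[2]
}

merge_stratum_key <- function(calls) {
  paste(calls$chromA, calls$chromB, calls$strandA, calls$strandB, sep = "\1")
}

check_sorted_calls <- function(calls) {
  if (nrow(calls) < 2) return(invisible(TRUE))
  ch <- calls$chromA
  new_chrom <- c(TRUE, ch[-1] != ch[-length(ch)])
  seen <- character(0)
  for (i in which(new_chrom)) {
    if (ch[i] %in% seen) {
      stop(sprintf("input not sorted: chromosome %s revisited at call %s",
                   ch[i], calls$id[i]))
    }
    seen <- c(seen, ch[i])
  }
  bad <- which(ch[-1] == ch[-length(ch)] &
                 calls$posA[-1] < calls$posA[-length(ch)]) + 1L
  if (length(bad)) {
    stop(sprintf("input not sorted: call %s at %s:%d precedes position %d",
                 calls$id[bad[1]], ch[bad[1]], calls$posA[bad[1]],
                 calls$posA[bad[1] - 1L]))
  }
  invisible(TRUE)
}

# union-find with path compression
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Cluster breakpoint calls by mutual distribution overlap
#'
#' Single-linkage clustering within each (chromA, chromB, strand-pair)
#' stratum: two calls are linked iff [distributions_overlap()] holds at
#' both breakends.  Within a stratum, calls are swept in order of breakend
#' A support start so each call is only tested against members whose
#' A-support can still reach it; linkage verdicts are identical to
#' exhaustive pairwise union-find.
#'
#' @param calls an `sv_callset`, sorted as produced by [lsort()]
#'   (grouped by chromA, non-decreasing posA).
#' @param slop widening in bases applied to every support (default 0).
#' @return a list of `sv_callset` clusters, in order of their leftmost
#'   member.
#' @export
cluster_calls <- function(calls, slop = 0L) {
  check_sorted_calls(calls)
  n <- nrow(calls)
  if (n == 0) return(list())
  keys <- merge_stratum_key(calls)
  parent <- seq_len(n)
  suppA <- t(vapply(calls$distA, dist_support, integer(2), slop = slop))
  suppB <- t(vapply(calls$distB, dist_support, integer(2), slop = slop))
  for (key in unique(keys)) {
    idx <- which(keys == key)
    idx <- idx[order(suppA[idx, 1], method = "radix")]
    active <- integer(0)
    for (i in idx) {
      active <- active[suppA[active, 2] >= suppA[i, 1]]
      for (j in active) {
        if (suppB[i, 1] <= suppB[j, 2] && suppB[j, 1] <= suppB[i, 2]) {
          ri <- uf_find(parent, i); rj <- uf_find(parent, j)
          if (ri != rj) parent[ri] <- rj
        }
      }
      active <- c(active, i)
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), 1L)
  comp <- split(seq_len(n), roots)
  comp <- comp[order(vapply(comp, min, 1L))]
  lapply(comp, function(ix) {
    cl <- calls[sort(ix), , drop = FALSE]
    rownames(cl) <- NULL
    class(cl) <- c("sv_callset", "data.frame")
    cl
  })
}

# element-wise weighted sum of distributions laid onto their union span,
# trimmed to the minimal mass-`ci_mass` interval containing the mode
combine_distributions <- function(dists, weights, ci_mass = 0.95) {
  starts <- vapply(dists, function(d) d$start, 1L)
  ends <- vapply(dists, function(d) d$start + length(d$probs) - 1L, 1L)
  span0 <- min(starts); span1 <- max(ends)
  acc <- numeric(span1 - span0 + 1L)
  for (k in seq_along(dists)) {
    d <- dists[[k]]
    off <- d$start - span0
    ix <- (off + 1L):(off + length(d$probs))
    acc[ix] <- acc[ix] + weights[k] * d$probs
  }
  full <- make_distribution(span0, acc, dists[[1]]$chrom)
  ci <- dist_ci(full, ci_mass)
  keep <- (ci[1] - span0 + 1L):(ci[2] - span0 + 1L)
  make_distribution(ci[1], full$probs[keep], dists[[1]]$chrom)
}

#' Combine a cluster of concordant calls into one merged variant
#'
#' For each breakend the member distributions are laid onto the union of
#' their spans and summed per base, each member weighted 1 (`uniform`) or
#' by its supporting-read count SU (`evidence`, the default).  The
#' refined position is the mode of the combined distribution (leftmost on
#' ties) and the reported interval is the smallest interval containing
#' the mode and at least 95% of the combined mass.  SU is summed and
#' sample provenance (`snames`) is the union over members.
#'
#' @param cluster an `sv_callset` of mutually consistent calls.
#' @param weighting `"evidence"` (weight = SU) or `"uniform"`.
#' @param ci_mass probability mass of the reported interval (default 0.95).
#' @return a one-row `sv_callset`.
#' @export
combine_cluster <- function(cluster, weighting = c("evidence", "uniform"),
                            ci_mass = 0.95) {
  weighting <- match.arg(weighting)
  stopifnot(nrow(cluster) >= 1)
  w <- if (weighting == "evidence") pmax(cluster$su, 1L) else
    rep(1, nrow(cluster))
  dA <- combine_distributions(cluster$distA, w, ci_mass)
  dB <- combine_distributions(cluster$distB, w, ci_mass)
  svtab <- table(cluster$svtype)
  prio <- c("DEL", "DUP", "INV", "MEI", "BND")
  best <- names(svtab)[svtab == max(svtab)]
  svtype <- prio[prio %in% best][1]
  snames <- unique(unlist(cluster$snames))
  posA <- point_estimate(dA); posB <- point_estimate(dB)
  if (dA$chrom == dB$chrom && posA > posB) {
    # degenerate refinement (heavily overlapping breakends): keep order
    posB <- posA
  }
  sv_callset(
    id = min(cluster$id), chromA = cluster$chromA[1], posA = posA,
    strandA = cluster$strandA[1], chromB = cluster$chromB[1], posB = posB,
    strandB = cluster$strandB[1], svtype = svtype,
    su = sum(cluster$su), sample = NA_character_,
    distA = list(dA), distB = list(dB), snames = list(snames)
  )
}

#' Merge a sorted callset into a non-redundant variant set
#'
#' The composition of [cluster_calls()] and [combine_cluster()]: every
#' input call contributes to exactly one output variant.  Output is
#' sorted by (contig order, position A, position B, id).
#'
#' @param calls a sorted `sv_callset` (as from [lsort()] +
#'   [svvcf_to_callset()]).
#' @param slop support widening in bases (default 0).
#' @param weighting `"evidence"` or `"uniform"`.
#' @param contigs optional character vector giving the contig sort order
#'   (default: order of first appearance in `calls`).
#' @return an `sv_callset` of merged variants.
#' @export
lmerge <- function(calls, slop = 0L, weighting = c("evidence", "uniform"),
                   contigs = NULL) {
  weighting <- match.arg(weighting)
  clusters <- cluster_calls(calls, slop)
  merged <- bind_callsets(lapply(clusters, combine_cluster,
                                 weighting = weighting))
  sort_callset(merged, contigs %||% unique(calls$chromA))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sort a callset by genomic position
#' @param calls an `sv_callset`.
#' @param contigs character vector giving the contig order (default:
#'   order of first appearance).
#' @return the sorted `sv_callset`.
#' @export
sort_callset <- function(calls, contigs = NULL) {
  if (nrow(calls) < 2) return(calls)
  contigs <- contigs %||% unique(calls$chromA)
  o <- order(chrom_rank(calls$chromA, contigs), calls$posA,
             chrom_rank(calls$chromB, contigs), calls$posB, calls$id,
             method = "radix")
  out <- calls[o, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sv_callset", "data.frame")
  out
}

#' Tiered (batch-then-cohort) merging
#'
#' For cohorts too large to merge in one pass, calls are merged within
#' batches of samples first and the batch-level variants are then merged
#' together.  Sample provenance accumulates through both tiers.
#'
#' @param batches list of sorted `sv_callset` objects, one per batch.
#' @param slop,weighting,contigs as in [lmerge()].
#' @return an `sv_callset` of merged variants.
#' @export
tiered_merge <- function(batches, slop = 0L,
                         weighting = c("evidence", "uniform"),
                         contigs = NULL) {
  weighting <- match.arg(weighting)
  tier1 <- lapply(batches, lmerge, slop = slop, weighting = weighting,
                  contigs = contigs)
  pooled <- sort_callset(bind_callsets(tier1),
                         contigs %||% unique(batches[[1]]$chromA))
  lmerge(pooled, slop = slop, weighting = weighting, contigs = contigs)
}
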