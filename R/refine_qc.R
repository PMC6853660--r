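# Callset refinement and QC: redundancy pruning, mean-sample-quality
# confidence scoring and filtering, trio Mendelian-error rates,
# sensitivity against a truth set, and cross-callset lookups.

# strand-pair type class, consistent with the merge strata: direct
# orientation (DEL/MEI/BND +-), duplication orientation (-+), inverted
type_class <- function(svtype, strandA, strandB) {
  pair <- paste0(strandA, strandB)
  ifelse(svtype == "INV" | pair %in% c("++", "--"), "INV",
         ifelse(pair == "-+", "DUPLIKE", "DIRECT"))
}

#' Prune redundant calls from a sorted callset
#'
#' Two same-type calls conflict when both breakend point estimates are
#' within `eval_dist` of each other (same chromosomes).  While any
#' conflict remains, the worst conflicting record — lowest SU, ties
#' resolved against the rightmost and then the lexicographically larger
#' id — is removed, so among mutually redundant records the highest-SU
#' (then leftmost) one survives.  The output is a subset of the input and
#' pruning is idempotent.
#'
#' @param x an `sv_callset` or `sv_cohort`, sorted by position.
#' @param eval_dist maximum breakend distance for redundancy (default
#'   100).
#' @return the pruned object, same class as `x`.
#' @export
prune <- function(x, eval_dist = 100L) {
  calls <- if (inherits(x, "sv_cohort")) x$calls else x
  check_sorted_calls(calls)
  keep <- prune_survivors(calls, eval_dist)
  if (inherits(x, "sv_cohort")) {
    subset_cohort(x, keep)
  } else {
    out <- calls[keep, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("sv_callset", "data.frame")
    out
  }
}

prune_conflicts <- function(calls, eval_dist) {
  n <- nrow(calls)
  pairs <- list()
  if (n < 2) return(pairs)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (calls$chromA[j] != calls$chromA[i] ||
          calls$posA[j] - calls$posA[i] > eval_dist) break
      if (calls$svtype[j] == calls$svtype[i] &&
          calls$chromB[j] == calls$chromB[i] &&
          abs(calls$posB[j] - calls$posB[i]) <= eval_dist) {
        pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
  }
  pairs
}

prune_survivors <- function(calls, eval_dist) {
  n <- nrow(calls)
  alive <- rep(TRUE, n)
  edges <- prune_conflicts(calls, eval_dist)
  if (length(edges)) {
    em <- do.call(rbind, edges)
    repeat {
      act <- alive[em[, 1]] & alive[em[, 2]]
      if (!any(act)) break
      involved <- unique(as.vector(em[act, , drop = FALSE]))
      # lowest SU; among ties the rightmost, then lexicographically last id
      worst <- involved[order(calls$su[involved], -calls$posA[involved],
                              calls$id[involved], method = "radix",
                              decreasing = c(FALSE, FALSE, TRUE))][1]
      alive[worst] <- FALSE
    }
  }
  which(alive)
}

#' Annotate mean carrier sample quality (MSQ)
#'
#' MSQ is the mean SQ over samples with a called non-reference genotype;
#' variants with no carriers get missing MSQ.
#'
#' @param cohort an `sv_cohort`.
#' @return the cohort with `info$msq` populated.
#' @export
score_confidence <- function(cohort) {
  carrier <- cohort$gt %in% c("0/1", "1/1")
  dim(carrier) <- dim(cohort$gt)
  sq <- cohort$sq
  sq[!carrier] <- NA_real_
  ncarr <- rowSums(carrier & !is.na(cohort$sq))
  msq <- rowMeans(sq, na.rm = TRUE)
  msq[ncarr == 0] <- NA_real_
  cohort$info$msq <- msq
  cohort
}

#' Filter a cohort to high-confidence variants
#'
#' Keeps variants whose MSQ meets a per-type threshold; variants without
#' MSQ (no carriers) are excluded.
#'
#' @param cohort an `sv_cohort` scored with [score_confidence()].
#' @param msq_min named numeric vector of per-type MSQ thresholds.
#' @return the filtered cohort.
#' @export
filter_high_confidence <- function(cohort,
                                   msq_min = c(DEL = 100, DUP = 100,
                                               INV = 100, MEI = 100,
                                               BND = 250)) {
  if (is.null(cohort$info$msq)) stop("run score_confidence() first")
  thr <- msq_min[cohort$calls$svtype]
  keep <- which(!is.na(cohort$info$msq) & cohort$info$msq >= thr)
  subset_cohort(cohort, keep)
}

# can the child genotype arise from one allele of each parent?
mendelian_consistent <- function(child, father, mother) {
  al <- function(g) as.integer(strsplit(g, "/", fixed = TRUE)[[1]])
  ca <- al(child); fa <- al(father); ma <- al(mother)
  for (f in fa) for (m in ma) {
    if ((f == ca[1] && m == ca[2]) || (f == ca[2] && m == ca[1])) return(TRUE)
  }
  FALSE
}

is_autosome <- function(chrom) {
  !toupper(sub("^chr", "", chrom)) %in% c("X", "Y", "M", "MT")
}

#' Trio Mendelian-error rates
#'
#' For each trio, an autosomal variant is informative when all three
#' members have called genotypes and at least one is non-reference; it is
#' a Mendelian error (ME) when the child genotype is impossible under
#' biallelic transmission of one allele from each parent.  The rate is
#' `100 * ME / informative`.
#'
#' @param cohort an `sv_cohort`.
#' @param pedigree an `sv_pedigree`.
#' @return data.frame with one row per trio: `child`, `informative`,
#'   `errors`, `me_rate` (percent).
#' @export
mendelian_error_rate <- function(cohort, pedigree) {
  missing_s <- setdiff(unlist(pedigree[c("child", "father", "mother")]),
                       cohort$samples)
  if (length(missing_s)) {
    stop("trio sample(s) absent from cohort: ",
         paste(missing_s, collapse = ", "))
  }
  auto <- is_autosome(cohort$calls$chromA) & is_autosome(cohort$calls$chromB)
  out <- data.frame(child = pedigree$child, informative = 0L, errors = 0L,
                    me_rate = NA_real_)
  for (t in seq_len(nrow(pedigree))) {
    gc <- cohort$gt[, pedigree$child[t]]
    gf <- cohort$gt[, pedigree$father[t]]
    gm <- cohort$gt[, pedigree$mother[t]]
    called <- gc != "./." & gf != "./." & gm != "./."
    nonref <- gc %in% c("0/1", "1/1") | gf %in% c("0/1", "1/1") |
      gm %in% c("0/1", "1/1")
    inf <- which(auto & called & nonref)
    err <- sum(!vapply(inf, function(i)
      mendelian_consistent(gc[i], gf[i], gm[i]), logical(1)))
    out$informative[t] <- length(inf)
    out$errors[t] <- err
    out$me_rate[t] <- if (length(inf)) 100 * err / length(inf) else NA_real_
  }
  out
}

match_breakpoints <- function(qcalls, tcalls, slop) {
  # returns a logical matrix: query x target, TRUE where type class and
  # both breakend point estimates agree within slop
  qc <- type_class(qcalls$svtype, qcalls$strandA, qcalls$strandB)
  tc <- type_class(tcalls$svtype, tcalls$strandA, tcalls$strandB)
  m <- matrix(FALSE, nrow(qcalls), nrow(tcalls))
  for (i in seq_len(nrow(qcalls))) {
    m[i, ] <- qc[i] == tc &
      qcalls$chromA[i] == tcalls$chromA &
      qcalls$chromB[i] == tcalls$chromB &
      abs(qcalls$posA[i] - tcalls$posA) <= slop &
      abs(qcalls$posB[i] - tcalls$posB) <= slop
  }
  m
}

#' Per-sample sensitivity against a truth set
#'
#' A truth variant is detected for a sample when some callset variant of
#' the same type class has both breakends within `match_slop` of the
#' truth breakends and a called non-reference genotype in that sample.
#' Sensitivity is `100 * detected / detectable` where detectable counts
#' truth variants the sample carries.
#'
#' @param cohort an `sv_cohort`.
#' @param truth_calls an `sv_callset` of truth variants.
#' @param truth_gt character genotype matrix (truth variants x samples).
#' @param match_slop breakend matching distance in bases (default 100).
#' @return data.frame with one row per sample: `sample`, `detectable`,
#'   `detected`, `sensitivity` (percent).
#' @export
sensitivity_vs_truth <- function(cohort, truth_calls, truth_gt,
                                 match_slop = 100L) {
  mm <- match_breakpoints(cohort$calls, truth_calls, match_slop)
  samples <- intersect(cohort$samples, colnames(truth_gt))
  out <- data.frame(sample = samples, detectable = 0L, detected = 0L,
                    sensitivity = NA_real_)
  carrier_call <- cohort$gt %in% c("0/1", "1/1")
  dim(carrier_call) <- dim(cohort$gt)
  colnames(carrier_call) <- cohort$samples
  for (k in seq_along(samples)) {
    s <- samples[k]
    detectable <- which(truth_gt[, s] %in% c("0/1", "1/1"))
    det <- vapply(detectable, function(v) {
      hits <- which(mm[, v])
      length(hits) > 0 && any(carrier_call[hits, s])
    }, logical(1))
    out$detectable[k] <- length(detectable)
    out$detected[k] <- sum(det)
    out$sensitivity[k] <- if (length(detectable))
      100 * mean(det) else NA_real_
  }
  out
}

#' Cross-callset variant lookup
#'
#' Annotates each query variant with the ids of target variants of the
#' same type class whose breakend point estimates both lie within `slop`.
#'
#' @param query,target `sv_callset` objects.
#' @param slop matching distance in bases (default 100).
#' @return `query` with an added list-column `matches`.
#' @export
sv_lookup <- function(query, target, slop = 100L) {
  mm <- match_breakpoints(query, target, slop)
  query$matches <- lapply(seq_len(nrow(query)),
                          function(i) target$id[mm[i, ]])
  query
}
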