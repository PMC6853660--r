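# Core domain types: breakend probability distributions, strand-oriented
# breakpoint calls, per-sample observations.  All downstream stages build
# on these.

#' Create a breakend probability distribution
#'
#' A breakend's position is uncertain; the uncertainty is represented as a
#' discretized per-base probability vector anchored at a 0-based leftmost
#' coordinate.  This is the in-memory form of the `CIPOS`/`PRPOS` (and
#' `CIEND`/`PREND`) annotations carried in per-sample discovery VCFs: the
#' confidence interval gives the extent and the probability vector gives
#' the per-base mass.
#'
#' @param start 0-based coordinate of the leftmost base of the interval.
#' @param probs numeric vector of non-negative weights, one per base.
#'   Normalized to sum to 1 on construction.
#' @param chrom optional chromosome name.
#' @return an object of class `breakend_distribution` with fields
#'   `chrom`, `start` and `probs` (normalized).
#' @examples
#' d <- make_distribution(100, c(1, 2, 1))
#' d$probs            # 0.25 0.50 0.25
#' point_estimate(d)  # 102 (1-based position of the mode)
#' @export
make_distribution <- function(start, probs, chrom = NA_character_) {
  if (length(probs) == 0L) {
    stop("breakend distribution requires a non-empty probability vector")
  }
  if (anyNA(probs) || any(probs < 0)) {
    stop("breakend distribution probabilities must be non-negative and non-missing")
  }
  s <- sum(probs)
  if (s <= 0) {
    stop("breakend distribution probabilities must have positive total mass")
  }
  structure(
    list(chrom = chrom, start = as.integer(start), probs = probs / s),
    class = "breakend_distribution"
  )
}

#' @export
print.breakend_distribution <- function(x, ...) {
  cat(sprintf(
    "<breakend_distribution %s:%d-%d (%d bp), mode at %d>\n",
    x$chrom, x$start, x$start + length(x$probs) - 1L, length(x$probs),
    point_estimate(x)
  ))
  invisible(x)
}

#' Maximum-probability position of a breakend distribution
#'
#' Returns the 1-based coordinate of the base with highest probability.
#' Ties are broken leftmost so the result is deterministic and invariant
#' under rescaling of the probability vector.
#'
#' @param d a `breakend_distribution`.
#' @return integer 1-based genomic position.
#' @export
point_estimate <- function(d) {
  stopifnot(inherits(d, "breakend_distribution"))
  d$start + which.max(d$probs)  # which.max is leftmost on ties; +1 then -1 cancel
}

#' Support of a breakend distribution
#'
#' The support is the range of bases with strictly positive probability,
#' optionally widened by `slop` bases on each side.
#'
#' @param d a `breakend_distribution`.
#' @param slop non-negative integer widening in bases.
#' @return integer vector `c(first, last)` of 0-based inclusive bounds.
#' @export
dist_support <- function(d, slop = 0L) {
  pos <- which(d$probs > 0)
  c(d$start + pos[1L] - 1L - as.integer(slop),
    d$start + pos[length(pos)] - 1L + as.integer(slop))
}

#' Minimal high-mass interval of a breakend distribution
#'
#' The reported confidence interval of a (merged) breakend is the smallest
#' contiguous interval that contains the mode and at least `mass` of the
#' probability; among equally small intervals the leftmost is chosen.
#'
#' @param d a `breakend_distribution`.
#' @param mass required probability mass (default 0.95).
#' @return integer vector `c(first, last)` of 0-based inclusive bounds.
#' @export
dist_ci <- function(d, mass = 0.95) {
  p <- d$probs
  n <- length(p)
  m <- which.max(p)
  cs <- cumsum(p)
  best <- c(1L, n)
  best_w <- n
  for (i in seq_len(m)) {
    # smallest j >= m with mass(i..j) >= mass
    lo <- cs[i] - p[i]
    j <- m
    while (j <= n && cs[j] - lo < mass - 1e-12) j <- j + 1L
    if (j > n) next
    w <- j - i + 1L
    if (w < best_w) {
      best <- c(i, j)
      best_w <- w
    }
  }
  c(d$start + best[1L] - 1L, d$start + best[2L] - 1L)
}

# strand pair conventions per SV type; BND is unconstrained
.type_strands <- list(
  DEL = list(c("+", "-")),
  MEI = list(c("+", "-")),
  DUP = list(c("-", "+")),
  INV = list(c("+", "+"), c("-", "-"))
)

check_svtype_strands <- function(svtype, strandA, strandB) {
  allowed <- .type_strands[[svtype]]
  if (is.null(allowed)) return(TRUE)  # BND
  for (a in allowed) if (a[1] == strandA && a[2] == strandB) return(TRUE)
  stop(sprintf(
    "strand pair (%s,%s) inconsistent with SVTYPE %s", strandA, strandB, svtype
  ))
}

#' Construct a callset of strand-oriented SV breakpoint calls
#'
#' A breakpoint is a pair of strand-oriented breakends (A and B), each with
#' a probability distribution over its position.  A callset is a
#' data.frame with one row per call and list-columns for the per-breakend
#' distributions and for sample provenance.
#'
#' @param id character vector of call identifiers.
#' @param chromA,posA,strandA breakend A: chromosome, 1-based point
#'   estimate, strand ("+"/"-").
#' @param chromB,posB,strandB breakend B likewise.  `(chromA, posA)` must
#'   not sort after `(chromB, posB)`.
#' @param svtype one of DEL, DUP, INV, MEI, BND.  Strand pairs must match
#'   the type convention: DEL/MEI `(+,-)`, DUP `(-,+)`, INV `(+,+)` or
#'   `(-,-)`; BND is unconstrained.
#' @param su integer evidence-read counts.
#' @param sample originating sample name (NA after merging).
#' @param distA,distB lists of `breakend_distribution` (default: point
#'   mass at `posA`/`posB`).
#' @param snames list of contributing `sample:call` identifier vectors.
#' @return a data.frame of class `sv_callset`.
#' @export
sv_callset <- function(id, chromA, posA, strandA, chromB, posB, strandB,
                       svtype, su = 0L, sample = NA_character_,
                       distA = NULL, distB = NULL, snames = NULL) {
  n <- length(id)
  chromA <- as.character(chromA); chromB <- as.character(chromB)
  posA <- as.integer(posA); posB <- as.integer(posB)
  svtype <- as.character(svtype)
  su <- rep_len(as.integer(su), n)
  sample <- rep_len(as.character(sample), n)
  strandA <- rep_len(as.character(strandA), n)
  strandB <- rep_len(as.character(strandB), n)
  for (i in seq_len(n)) {
    check_svtype_strands(svtype[i], strandA[i], strandB[i])
    if (chromA[i] == chromB[i] && posA[i] > posB[i]) {
      stop(sprintf("call %s: breakend A sorts after breakend B", id[i]))
    }
  }
  if (is.null(distA)) {
    distA <- lapply(seq_len(n), function(i)
      make_distribution(posA[i] - 1L, 1, chromA[i]))
  }
  if (is.null(distB)) {
    distB <- lapply(seq_len(n), function(i)
      make_distribution(posB[i] - 1L, 1, chromB[i]))
  }
  if (is.null(snames)) {
    snames <- lapply(seq_len(n), function(i)
      if (is.na(sample[i])) character(0) else paste0(sample[i], ":", id[i]))
  }
  df <- data.frame(
    id = as.character(id), chromA = chromA, posA = posA, strandA = strandA,
    chromB = chromB, posB = posB, strandB = strandB, svtype = svtype,
    su = su, sample = sample, stringsAsFactors = FALSE
  )
  df$distA <- distA
  df$distB <- distB
  df$snames <- snames
  class(df) <- c("sv_callset", "data.frame")
  df
}

#' @export
print.sv_callset <- function(x, ...) {
  cat(sprintf("<sv_callset: %d calls (%s)>\n", nrow(x),
              paste(names(table(x$svtype)), table(x$svtype),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# rbind that preserves the sv_callset class and list-columns
bind_callsets <- function(sets) {
  sets <- Filter(function(s) nrow(s) > 0, sets)
  if (length(sets) == 0) {
    return(sv_callset(character(0), character(0), integer(0), character(0),
                      character(0), integer(0), character(0), character(0)))
  }
  out <- do.call(rbind, lapply(sets, function(s) { class(s) <- "data.frame"; s }))
  rownames(out) <- NULL
  class(out) <- c("sv_callset", "data.frame")
  out
}

#' Per-sample observations at SV variants
#'
#' Validates a set of per-sample genotype observations: genotype `GT`
#' (one of `0/0`, `0/1`, `1/1`, `./.`), phred-like sample quality `SQ`,
#' allele balance `AB` in `[0,1]` (alternate / total breakpoint evidence)
#' and read-depth copy number `CN` (diploid baseline 2).
#'
#' @param sample character sample names.
#' @param gt genotype strings.
#' @param sq non-negative sample qualities (NA when `gt` is missing).
#' @param ab allele balances in `[0,1]` or NA.
#' @param cn non-negative copy numbers or NA.
#' @return a data.frame of class `sample_observation`.
#' @export
sample_observation <- function(sample, gt, sq = NA_real_, ab = NA_real_,
                               cn = NA_real_) {
  n <- length(sample)
  gt <- rep_len(as.character(gt), n)
  sq <- rep_len(as.numeric(sq), n)
  ab <- rep_len(as.numeric(ab), n)
  cn <- rep_len(as.numeric(cn), n)
  ok <- gt %in% c("0/0", "0/1", "1/1", "./.")
  if (!all(ok)) stop("invalid genotype: ", paste(unique(gt[!ok]), collapse = ", "))
  if (any(gt == "./." & !is.na(sq))) {
    stop("missing genotype must have missing sample quality")
  }
  if (any(!is.na(ab) & (ab < 0 | ab > 1))) stop("allele balance outside [0,1]")
  if (any(!is.na(cn) & cn < 0)) stop("negative copy number")
  if (any(!is.na(sq) & sq < 0)) stop("negative sample quality")
  structure(
    data.frame(sample = as.character(sample), gt = gt, sq = sq, ab = ab,
               cn = cn, stringsAsFactors = FALSE),
    class = c("sample_observation", "data.frame")
  )
}

#' Pedigree of parent-offspring trios
#'
#' @param child,father,mother character vectors of sample names; the three
#'   members of each trio must be distinct.
#' @return a data.frame of class `sv_pedigree`.
#' @export
sv_pedigree <- function(child, father, mother) {
  n <- length(child)
  stopifnot(length(father) == n, length(mother) == n)
  for (i in seq_len(n)) {
    if (anyDuplicated(c(child[i], father[i], mother[i]))) {
      stop("trio members must be distinct: ", child[i])
    }
  }
  structure(
    data.frame(child = as.character(child), father = as.character(father),
               mother = as.character(mother), stringsAsFactors = FALSE),
    class = c("sv_pedigree", "data.frame")
  )
}

#' Read a pedigree file
#'
#' Expects a whitespace-separated file with one trio per line:
#' `child father mother` (comment lines starting with `#` are ignored).
#'
#' @param path file path.
#' @return an `sv_pedigree`.
#' @export
read_pedigree <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) stop("pedigree line needs child, father, mother fields")
  sv_pedigree(vapply(parts, `[[`, "", 1L),
              vapply(parts, `[[`, "", 2L),
              vapply(parts, `[[`, "", 3L))
}

#' Write a pedigree file
#' @param ped an `sv_pedigree`.
#' @param path output file path.
#' @export
write_pedigree <- function(ped, path) {
  writeLines(c("#child\tfather\tmother",
               paste(ped$child, ped$father, ped$mother, sep = "\t")), path)
}
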