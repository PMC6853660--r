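# Variant re-classification.  Breakpoint detection sees novel adjacencies
# only, so copy-number-changing SVs (DEL, DUP), mobile-element insertions
# (whose breakpoints mimic deletions of the reference element) and
# balanced rearrangements must be separated afterwards using per-sample
# allele balance, read-depth copy number and genome annotation:
#   - large cohorts: per-variant OLS of copy number on allele balance
#     (expected slope -2 for DEL, +2 for DUP, ~0 for balanced events);
#   - small cohorts: a naive-Bayes classifier on carrier copy number,
#     stratified by genotype;
#   - MEI: direct-orientation breakpoints at annotated mobile elements
#     with no copy-number effect;
#   - INV: pairing of co-detected (+,+) and (-,-) breakpoints.

#' Per-variant regression of copy number on allele balance
#'
#' Ordinary least squares with copy number as the response and allele
#' balance as the predictor, over samples where both are observed.  A
#' hemizygous deletion halves copy number per unit of allele balance
#' dosage (slope -2 at diploid baseline); a tandem duplication adds one
#' copy (slope +2); balanced variants show no trend.
#'
#' @param ab,cn numeric vectors of per-sample allele balance and copy
#'   number.
#' @param gt character vector of genotypes (used to require a carrier).
#' @param min_informative minimum number of samples with both AB and CN
#'   observed (default 8).
#' @return a list with `slope`, `intercept`, `n`, `r2` (class
#'   `ab_cn_fit`), or `NULL` when the input is under-informative (too few
#'   observations, no carrier, or zero AB variance).
#' @export
fit_ab_cn_regression <- function(ab, cn, gt, min_informative = 8L) {
  ok <- !is.na(ab) & !is.na(cn)
  carrier <- gt %in% c("0/1", "1/1")
  if (sum(ok) < min_informative || !any(ok & carrier)) return(NULL)
  x <- ab[ok]; y <- cn[ok]
  if (stats::var(x) == 0) return(NULL)
  fit <- stats::lm(y ~ x)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n = sum(ok),
    r2 = if (sst > 0) 1 - ssr / sst else 0
  ), class = "ab_cn_fit")
}

#' Classify a variant from its AB~CN regression
#'
#' A confidently negative slope makes a DEL, a confidently positive slope
#' a DUP, anything else a balanced break-end (BND).  Calls whose strand
#' pair is incompatible with a copy-number class (DEL requires `(+,-)`,
#' DUP `(-,+)`) can only fall to BND.  An undefined fit retains the
#' original type.
#'
#' @param svtype current variant type.
#' @param strandA,strandB breakend strands.
#' @param fit an `ab_cn_fit` or `NULL`.
#' @param slope_min minimum |slope| for a copy-number class (default 1.0,
#'   the midpoint between 0 and the expected |slope| of 2).
#' @param r2_min minimum coefficient of determination (default 0.2).
#' @return the re-classified svtype.
#' @export
classify_by_regression <- function(svtype, strandA, strandB, fit,
                                   slope_min = 1.0, r2_min = 0.2) {
  if (is.null(fit)) return(svtype)
  pair <- paste0(strandA, strandB)
  if (fit$slope <= -slope_min && fit$r2 >= r2_min && pair == "+-") return("DEL")
  if (fit$slope >= slope_min && fit$r2 >= r2_min && pair == "-+") return("DUP")
  "BND"
}

#' Train the small-cohort naive-Bayes classifier
#'
#' Class-conditional Gaussians of carrier copy number, stratified by
#' genotype (`0/1`, `1/1`), for the classes DEL, DUP and balanced BND,
#' with empirical class priors.  Variances are floored at 1e-3.
#'
#' @param cohort an `sv_cohort` with CN attached.
#' @param labels character vector of known types per variant; variants
#'   labeled outside DEL/DUP/BND are ignored.
#' @param min_per_class minimum training variants per class (default 20).
#' @return an `nb_model`: `priors` and a `params` array
#'   (class x stratum x {mean, var}).
#' @export
train_nb <- function(cohort, labels, min_per_class = 20L) {
  classes <- c("DEL", "DUP", "BND")
  use <- labels %in% classes
  counts <- table(factor(labels[use], levels = classes))
  if (any(counts == 0)) {
    stop("class absent from training data: ",
         paste(classes[counts == 0], collapse = ", "))
  }
  if (any(counts < min_per_class)) {
    warning("fewer than ", min_per_class, " training variants for: ",
            paste(classes[counts < min_per_class], collapse = ", "))
  }
  strata <- c("0/1", "1/1")
  params <- array(NA_real_, dim = c(3, 2, 2),
                  dimnames = list(classes, strata, c("mean", "var")))
  for (cl in classes) {
    rows <- which(use & labels == cl)
    for (g in strata) {
      vals <- unlist(lapply(rows, function(i) {
        sel <- cohort$gt[i, ] == g & !is.na(cohort$cn[i, ])
        cohort$cn[i, sel]
      }))
      if (length(vals) == 0) {
        stop(sprintf("no training observations for class %s at GT %s", cl, g))
      }
      params[cl, g, "mean"] <- mean(vals)
      params[cl, g, "var"] <- max(stats::var(vals), 1e-3, na.rm = TRUE)
    }
  }
  structure(list(priors = as.numeric(counts) / sum(counts),
                 classes = classes, params = params),
            class = "nb_model")
}

#' Classify a variant with the naive-Bayes model
#'
#' Log-posterior = log prior + sum over carrier samples of the log
#' Gaussian likelihood of the observed copy number given class and
#' genotype stratum; the maximum-posterior class is returned, with ties
#' (and posteriors tied within 1e-9) resolved to BND.  Classes
#' incompatible with the call's strand pair are excluded.  A variant with
#' no carrier retains its type.
#'
#' @param svtype,strandA,strandB the call's current type and strands.
#' @param gt,cn per-sample genotype and copy-number vectors.
#' @param model an `nb_model` from [train_nb()].
#' @return the re-classified svtype.
#' @export
classify_by_nb <- function(svtype, strandA, strandB, gt, cn, model) {
  carrier <- gt %in% c("0/1", "1/1") & !is.na(cn)
  if (!any(carrier)) return(svtype)
  pair <- paste0(strandA, strandB)
  allowed <- switch(pair, "+-" = c("DEL", "BND"), "-+" = c("DUP", "BND"),
                    "BND")
  lp <- vapply(model$classes, function(cl) {
    if (!(cl %in% allowed)) return(-Inf)
    mu <- model$params[cl, gt[carrier], "mean"]
    v <- model$params[cl, gt[carrier], "var"]
    log(model$priors[match(cl, model$classes)]) +
      sum(stats::dnorm(cn[carrier], mu, sqrt(v), log = TRUE))
  }, numeric(1))
  best <- max(lp)
  winners <- model$classes[lp >= best - 1e-9]
  if (length(winners) > 1) "BND" else winners
}

#' Read a mobile-element annotation (BED4)
#'
#' Columns: chrom, start (0-based), end (half-open), element class.
#'
#' @param path file path.
#' @return a data.frame with columns `chrom`, `start`, `end`, `class`.
#' @export
read_me_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "class"))
  df
}

breakend_overlaps_bed <- function(d, bed, slop = 0L) {
  supp <- dist_support(d)  # 0-based inclusive
  any(bed$chrom == d$chrom &
        bed$start <= supp[2] + slop &
        bed$end - 1L >= supp[1] - slop)
}

#' Mobile-element insertion call-up
#'
#' A direct-orientation `(+,-)` breakpoint whose confidence interval
#' (widened by `mei_slop`) touches an annotated mobile element, and whose
#' regression shows no copy-number effect (undefined fit or
#' |slope| < `slope_min`), is re-labeled MEI.  A genuine copy-number
#' signal takes precedence: a deletion inside a repeat stays DEL.
#'
#' @param svtype current type (after regression/NB classification).
#' @param strandA,strandB breakend strands.
#' @param distA,distB breakend distributions.
#' @param fit the variant's `ab_cn_fit` (or `NULL`).
#' @param me_bed mobile-element annotation from [read_me_bed()].
#' @param mei_slop widening in bases for the overlap test (default 100).
#' @param slope_min slope magnitude that counts as a copy-number effect
#'   (default 1.0).
#' @return the (possibly re-labeled) svtype.
#' @export
classify_mei <- function(svtype, strandA, strandB, distA, distB, fit,
                         me_bed, mei_slop = 100L, slope_min = 1.0) {
  if (paste0(strandA, strandB) != "+-") return(svtype)
  no_cn_effect <- is.null(fit) || abs(fit$slope) < slope_min
  if (!no_cn_effect) return(svtype)
  if (breakend_overlaps_bed(distA, me_bed, mei_slop) ||
      breakend_overlaps_bed(distB, me_bed, mei_slop)) "MEI" else svtype
}

# mutual both-end CI overlap within slop for two calls
inv_mutual_overlap <- function(calls, i, j, slop) {
  sa_i <- dist_support(calls$distA[[i]]); sa_j <- dist_support(calls$distA[[j]])
  sb_i <- dist_support(calls$distB[[i]]); sb_j <- dist_support(calls$distB[[j]])
  calls$chromA[i] == calls$chromA[j] && calls$chromB[i] == calls$chromB[j] &&
    sa_i[1] - slop <= sa_j[2] && sa_j[1] - slop <= sa_i[2] &&
    sb_i[1] - slop <= sb_j[2] && sb_j[1] - slop <= sb_i[2]
}

#' Pair inverted breakpoints into inversions
#'
#' An inversion produces two breakpoints with inverted orientation:
#' one `(+,+)` and one `(-,-)`.  Candidate pairs whose confidence
#' intervals mutually overlap at both breakends (within `inv_slop`) are
#' matched greedily by distance between point estimates (deterministic
#' leftmost tie-break) and emitted as a single INV call spanning the
#' outer coordinates, with provenance and evidence pooled.  Unpaired
#' inverted calls remain BND.
#'
#' @param cohort an `sv_cohort` (variant rows with genotype matrices).
#' @param inv_slop pairing slop in bases (default 100).
#' @return the cohort with paired rows fused into INV calls and unpaired
#'   `(+,+)`/`(-,-)` calls labeled BND.
#' @export
pair_inversions <- function(cohort, inv_slop = 100L) {
  calls <- cohort$calls
  pair_key <- paste0(calls$strandA, calls$strandB)
  pp <- which(pair_key == "++")
  mm <- which(pair_key == "--")
  # candidate pairs with mutual both-end overlap
  cand <- list()
  for (i in pp) for (j in mm) {
    if (inv_mutual_overlap(calls, i, j, inv_slop)) {
      d <- abs(calls$posA[i] - calls$posA[j]) +
        abs(calls$posB[i] - calls$posB[j])
      cand[[length(cand) + 1L]] <- c(i = i, j = j, d = d)
    }
  }
  drop <- integer(0)
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    # greedy nearest pair; ties to the leftmost (smallest posA, then id)
    cm <- cm[order(cm[, "d"], calls$posA[cm[, "i"]], calls$id[cm[, "i"]],
                   calls$posA[cm[, "j"]]), , drop = FALSE]
    used <- logical(nrow(calls))
    for (k in seq_len(nrow(cm))) {
      i <- cm[k, "i"]; j <- cm[k, "j"]
      if (used[i] || used[j]) next
      used[i] <- used[j] <- TRUE
      keep <- if (calls$posA[i] <= calls$posA[j]) i else j
      other <- if (keep == i) j else i
      lo <- if (calls$posA[i] <= calls$posA[j]) i else j
      hi <- if (calls$posB[i] >= calls$posB[j]) i else j
      calls$svtype[keep] <- "INV"
      calls$posA[keep] <- calls$posA[lo]
      calls$distA[[keep]] <- calls$distA[[lo]]
      calls$strandA[keep] <- calls$strandA[lo]
      calls$posB[keep] <- calls$posB[hi]
      calls$distB[[keep]] <- calls$distB[[hi]]
      calls$strandB[keep] <- calls$strandA[lo]  # keep a valid INV pair
      calls$su[keep] <- calls$su[i] + calls$su[j]
      calls$snames[[keep]] <- unique(c(calls$snames[[i]], calls$snames[[j]]))
      drop <- c(drop, other)
    }
  }
  unpaired <- setdiff(c(pp, mm), c(drop, which(calls$svtype == "INV")))
  calls$svtype[unpaired] <- "BND"
  cohort$calls <- calls
  if (length(drop)) {
    keep_rows <- setdiff(seq_len(nrow(calls)), drop)
    cohort <- subset_cohort(cohort, keep_rows)
  }
  cohort
}

# row-subset every per-variant structure of a cohort
subset_cohort <- function(cohort, rows) {
  cohort$calls <- cohort$calls[rows, , drop = FALSE]
  rownames(cohort$calls) <- NULL
  class(cohort$calls) <- c("sv_callset", "data.frame")
  for (f in c("gt", "sq", "ab", "cn")) {
    cohort[[f]] <- cohort[[f]][rows, , drop = FALSE]
  }
  cohort$info <- cohort$info[rows, , drop = FALSE]
  rownames(cohort$info) <- NULL
  cohort
}

#' Re-classify a cohort callset
#'
#' Applies the full classification stack: per-variant regression (large
#' cohorts) or naive Bayes (small cohorts) to separate DEL/DUP from
#' balanced variants, the mobile-element rule for MEI, and inverted
#' breakpoint pairing for INV.  Interchromosomal calls keep their BND
#' type.
#'
#' @param cohort an `sv_cohort` with AB and CN populated.
#' @param method `"regression"` or `"naive-bayes"`.
#' @param me_bed optional mobile-element annotation ([read_me_bed()]).
#' @param nb_model an `nb_model`, required for `method = "naive-bayes"`.
#' @param slope_min,r2_min regression decision thresholds.
#' @param min_informative minimum informative samples for a defined fit.
#' @param mei_slop,inv_slop annotation-overlap and inversion-pairing slop.
#' @return the cohort with `calls$svtype` re-assigned and inversions
#'   paired.
#' @export
sv_classify <- function(cohort, method = c("regression", "naive-bayes"),
                        me_bed = NULL, nb_model = NULL, slope_min = 1.0,
                        r2_min = 0.2, min_informative = 8L,
                        mei_slop = 100L, inv_slop = 100L) {
  method <- match.arg(method)
  calls <- cohort$calls
  for (i in seq_len(nrow(calls))) {
    if (calls$chromA[i] != calls$chromB[i]) next
    pair <- paste0(calls$strandA[i], calls$strandB[i])
    if (!pair %in% c("+-", "-+")) next
    fit <- fit_ab_cn_regression(cohort$ab[i, ], cohort$cn[i, ],
                                cohort$gt[i, ], min_informative)
    new_type <- if (method == "regression") {
      classify_by_regression(calls$svtype[i], calls$strandA[i],
                             calls$strandB[i], fit, slope_min, r2_min)
    } else {
      if (is.null(nb_model)) stop("naive-bayes method requires nb_model")
      classify_by_nb(calls$svtype[i], calls$strandA[i], calls$strandB[i],
                     cohort$gt[i, ], cohort$cn[i, ], nb_model)
    }
    if (!is.null(me_bed)) {
      new_type <- classify_mei(new_type, calls$strandA[i], calls$strandB[i],
                               calls$distA[[i]], calls$distB[[i]], fit,
                               me_bed, mei_slop, slope_min)
    }
    calls$svtype[i] <- new_type
  }
  cohort$calls <- calls
  pair_inversions(cohort, inv_slop)
}
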