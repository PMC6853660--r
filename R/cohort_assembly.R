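# Cohort-level callset assembly: column-wise pasting of per-sample
# genotyped VCFs onto a merged site list, copy-number attachment and
# allele-frequency annotation.  The working container is an `sv_cohort`:
# a mate-collapsed callset plus per-sample GT/SQ/AB/CN matrices.

#' Paste per-sample genotyped VCFs onto a merged site VCF
#'
#' Each per-sample VCF must contain exactly the site list of `site_vcf`,
#' in the same order and with the same variant ids; any mismatch is an
#' error (never a silent misalignment).  Fixed columns and INFO come from
#' `site_vcf`; one genotype column per sample is appended in input order.
#'
#' @param site_vcf an `sv_vcf` holding the cohort site list.
#' @param sample_vcfs list of single-sample `sv_vcf` objects (or file
#'   paths).
#' @return a multi-sample `sv_vcf`.
#' @export
vcfpaste <- function(site_vcf, sample_vcfs) {
  sample_vcfs <- lapply(sample_vcfs, function(v)
    if (is.character(v)) read_svvcf(v) else v)
  nrec <- nrow(site_vcf$records)
  samples <- character(0)
  geno <- NULL
  fmt <- NULL
  for (k in seq_along(sample_vcfs)) {
    v <- sample_vcfs[[k]]
    if (length(v$samples) != 1) {
      stop(sprintf("input %d: expected exactly one sample column", k))
    }
    if (nrow(v$records) != nrec) {
      stop(sprintf("input %d (%s): %d records, site VCF has %d",
                   k, v$samples, nrow(v$records), nrec))
    }
    mism <- which(v$records$id != site_vcf$records$id)
    if (length(mism)) {
      stop(sprintf(
        "input %d (%s): variant id mismatch at record %d (%s vs site %s)",
        k, v$samples, mism[1], v$records$id[mism[1]],
        site_vcf$records$id[mism[1]]))
    }
    if (is.null(fmt)) fmt <- v$records$format
    else if (nrec && any(v$records$format != fmt)) {
      stop(sprintf("input %d (%s): FORMAT differs from first sample",
                   k, v$samples))
    }
    samples <- c(samples, v$samples)
    geno <- cbind(geno, v$geno)
  }
  rec <- site_vcf$records
  rec$format <- fmt %||% NA_character_
  if (is.null(geno)) geno <- matrix(character(0), nrec, 0)
  colnames(geno) <- samples
  hdr <- site_vcf$header[!startsWith(site_vcf$header, "##sample=")]
  new_svvcf(hdr, samples, rec, geno)
}

# extract one FORMAT sub-field across a genotype matrix
format_field <- function(format, geno, key) {
  out <- matrix(NA_character_, nrow(geno), ncol(geno),
                dimnames = dimnames(geno))
  if (nrow(geno) == 0) return(out)
  keys <- strsplit(format, ":", fixed = TRUE)
  for (i in seq_len(nrow(geno))) {
    k <- match(key, keys[[i]])
    if (is.na(k)) next
    parts <- strsplit(geno[i, ], ":", fixed = TRUE)
    out[i, ] <- vapply(parts, function(p)
      if (length(p) >= k) p[k] else NA_character_, character(1))
  }
  out
}

num_or_na <- function(x) {
  d <- dim(x); dn <- dimnames(x)
  x[x == "." | x == ""] <- NA_character_
  y <- suppressWarnings(as.numeric(x))
  dim(y) <- d
  dimnames(y) <- dn
  y
}

#' Build an `sv_cohort` from a multi-sample SV VCF
#'
#' Collapses BND mate pairs into two-breakend calls and parses the
#' per-sample GT/SQ/AB/CN FORMAT fields into matrices (BND calls take the
#' genotype columns of their primary mate line).
#'
#' @param vcf a multi-sample `sv_vcf`.
#' @return an `sv_cohort`: list with `calls` (an `sv_callset`), `samples`,
#'   character matrix `gt` and numeric matrices `sq`, `ab`, `cn`
#'   (calls x samples), an `info` data.frame (`af`, `nsamp`, `msq`) and
#'   the contig order.
#' @export
as_cohort <- function(vcf) {
  calls <- svvcf_to_callset(vcf)
  r <- vcf$records
  svtype <- info_get(r$info, "SVTYPE")
  secondary <- grepl("(^|;)SECONDARY(;|$)", r$info)
  primary <- which(svtype != "BND" | !secondary)
  # primary rows in record order: non-BND by id, BND by EVENT id
  prim_id <- ifelse(svtype[primary] == "BND",
                    info_get(r$info[primary], "EVENT"), r$id[primary])
  rows <- match(calls$id, prim_id)
  if (anyNA(rows)) stop("internal: call ids not recoverable from records")
  ridx <- primary[rows]
  gt_raw <- format_field(r$format[ridx], vcf$geno[ridx, , drop = FALSE], "GT")
  dn <- list(calls$id, vcf$samples)
  dimnames(gt_raw) <- dn
  info <- data.frame(
    af = num_or_na(info_get(r$info[ridx], "AF")),
    nsamp = suppressWarnings(as.integer(info_get(r$info[ridx], "NSAMP"))),
    msq = num_or_na(info_get(r$info[ridx], "MSQ"))
  )
  cohort <- structure(list(
    calls = calls,
    samples = vcf$samples,
    gt = gt_raw,
    sq = structure(num_or_na(format_field(
      r$format[ridx], vcf$geno[ridx, , drop = FALSE], "SQ")), dimnames = dn),
    ab = structure(num_or_na(format_field(
      r$format[ridx], vcf$geno[ridx, , drop = FALSE], "AB")), dimnames = dn),
    cn = structure(num_or_na(format_field(
      r$format[ridx], vcf$geno[ridx, , drop = FALSE], "CN")), dimnames = dn),
    info = info,
    contigs = vcf_contigs(vcf),
    contig_lengths = contig_lengths(vcf$header)
  ), class = "sv_cohort")
  cohort
}

contig_lengths <- function(header) {
  lines <- grep("^##contig=", header, value = TRUE)
  len <- as.integer(sub(".*length=([0-9]+).*", "\\1", lines))
  names(len) <- sub(".*ID=([^,>]+).*", "\\1", lines)
  len
}

#' @export
print.sv_cohort <- function(x, ...) {
  cat(sprintf("<sv_cohort: %d variants x %d samples>\n", nrow(x$calls),
              length(x$samples)))
  invisible(x)
}

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), ".", sprintf(paste0("%.", digits, "g"), x))
}

#' Serialize an `sv_cohort` as a multi-sample `sv_vcf`
#'
#' FORMAT is `GT:SQ:GQ:AB:CN` (GQ is the rounded SQ); AF/NSAMP/MSQ are
#' written to INFO where annotated.
#'
#' @param cohort an `sv_cohort`.
#' @return an `sv_vcf`.
#' @export
cohort_to_svvcf <- function(cohort) {
  n <- nrow(cohort$calls)
  ns <- length(cohort$samples)
  geno <- matrix("", n, ns)
  for (j in seq_len(ns)) {
    gq <- ifelse(is.na(cohort$sq[, j]), ".",
                 as.character(as.integer(round(cohort$sq[, j]))))
    geno[, j] <- paste(cohort$gt[, j], fmt_num(cohort$sq[, j]), gq,
                       fmt_num(cohort$ab[, j]), fmt_num(cohort$cn[, j]),
                       sep = ":")
  }
  info <- lapply(seq_len(n), function(i) {
    out <- character(0)
    if (!is.na(cohort$info$af[i])) {
      out <- c(out, AF = fmt_num(cohort$info$af[i]),
               NSAMP = as.character(cohort$info$nsamp[i]))
    }
    if (!is.na(cohort$info$msq[i])) out <- c(out, MSQ = fmt_num(cohort$info$msq[i]))
    out
  })
  callset_to_svvcf(cohort$calls, cohort$contig_lengths,
                   samples = cohort$samples, format = "GT:SQ:GQ:AB:CN",
                   geno = geno, info = info)
}

#' Read / write a copy-number table
#'
#' The table is a TSV with a header row of variant ids and one row per
#' sample (first column `sample`).
#'
#' @param path file path.
#' @return a data.frame with rownames = samples, columns = variant ids.
#' @export
read_cn_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.data.frame(df)
}

#' @rdname read_cn_table
#' @param cn data.frame of copy numbers (samples x variants).
#' @export
write_cn_table <- function(cn, path) {
  df <- data.frame(sample = rownames(cn), cn, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Attach per-sample copy-number estimates to a cohort
#'
#' @param cohort an `sv_cohort`.
#' @param cn_table data.frame (samples x variant ids) of read-depth copy
#'   numbers; `NA` cells stay missing.  Every cohort sample and variant id
#'   must be present.
#' @return the cohort with its `cn` matrix populated.
#' @export
attach_copynumber <- function(cohort, cn_table) {
  miss_s <- setdiff(cohort$samples, rownames(cn_table))
  if (length(miss_s)) stop("copy-number table lacks sample(s): ",
                           paste(miss_s, collapse = ", "))
  miss_v <- setdiff(cohort$calls$id, colnames(cn_table))
  if (length(miss_v)) stop("copy-number table lacks variant(s): ",
                           paste(utils::head(miss_v, 5), collapse = ", "))
  m <- as.matrix(cn_table[cohort$samples, cohort$calls$id, drop = FALSE])
  cohort$cn <- t(m)
  dimnames(cohort$cn) <- dimnames(cohort$gt)
  cohort
}

gt_dosage <- function(gt) {
  d <- c("0/0" = 0, "0/1" = 1, "1/1" = 2, "./." = NA_real_)[gt]
  dim(d) <- dim(gt)
  d
}

#' Annotate allele frequency and carrier count
#'
#' AF = alternate-allele count / called-allele count over non-missing
#' diploid genotypes; NSAMP = number of samples with a called
#' non-reference genotype.  Variants with no called alleles get missing
#' AF.
#'
#' @param cohort an `sv_cohort`.
#' @return the cohort with `info$af` and `info$nsamp` populated.
#' @export
afreq <- function(cohort) {
  dos <- gt_dosage(cohort$gt)
  called <- 2 * rowSums(!is.na(dos))
  alt <- rowSums(dos, na.rm = TRUE)
  cohort$info$af <- ifelse(called > 0, alt / called, NA_real_)
  cohort$info$nsamp <- as.integer(rowSums(dos > 0, na.rm = TRUE))
  cohort
}
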