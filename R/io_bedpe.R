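# BEDPE reader/writer and VCF<->BEDPE conversion.  BEDPE intervals are
# 0-based half-open and equal to the VCF breakend confidence intervals;
# the original VCF INFO strings are carried in INFO_A/INFO_B columns so
# the conversion round-trips exactly.  BND mate pairs occupy a single
# BEDPE line and are re-emitted as two mated VCF lines.

new_svbedpe <- function(header, samples, records, geno = NULL) {
  structure(list(header = header, samples = samples, records = records,
                 geno = geno),
            class = "sv_bedpe")
}

#' @export
print.sv_bedpe <- function(x, ...) {
  cat(sprintf("<sv_bedpe: %d records, %d samples>\n", nrow(x$records),
              length(x$samples)))
  invisible(x)
}

bedpe_cols <- c("chromA", "startA", "endA", "chromB", "startB", "endB",
                "name", "score", "strandA", "strandB", "svtype", "filter",
                "info_a", "info_b")

# shift a breakend's CI/PR annotation right by `by` bases (dropping the
# leading probability entries) when clamping a negative BEDPE start
clamp_info <- function(info, cikey, prkey, by) {
  ci <- parse_pair(info_get(info, cikey))
  info <- info_set(info, cikey, sprintf("%d,%d", ci[1] + by, ci[2]))
  pr <- info_get(info, prkey)
  if (!is.na(pr)) {
    p <- parse_probs(pr)
    info <- info_set(info, prkey, format_probs(p[-seq_len(by)]))
  }
  info
}

#' Convert a VCF of SV records to BEDPE
#'
#' Each breakend confidence interval becomes a 0-based half-open BEDPE
#' interval: `[POS + CIPOS[1] - 1, POS + CIPOS[2])` on side A and likewise
#' for END/CIEND on side B.  BND mate pairs collapse to one line whose
#' INFO_A/INFO_B columns keep both mates' INFO strings.  Intervals that
#' would start before the chromosome are clamped to 0 and the probability
#' vector shortened accordingly (with a warning).
#'
#' @param vcf an `sv_vcf`.
#' @return an `sv_bedpe`.
#' @export
vcf_to_bedpe <- function(vcf) {
  r <- vcf$records
  svtype <- info_get(r$info, "SVTYPE")
  secondary <- grepl("(^|;)SECONDARY(;|$)", r$info)
  is_bnd <- svtype == "BND"
  rows <- list(); grows <- list()
  add_row <- function(row, g) {
    rows[[length(rows) + 1L]] <<- row
    grows[[length(grows) + 1L]] <<- g
  }
  breakend_interval <- function(pos, ci) c(pos - 1L + ci[1], pos + ci[2])
  for (i in which(!is_bnd)) {
    info <- r$info[i]
    endp <- as.integer(info_get(info, "END"))
    iva <- breakend_interval(r$pos[i], parse_pair(info_get(info, "CIPOS")))
    ivb <- breakend_interval(endp, parse_pair(info_get(info, "CIEND")))
    if (iva[1] < 0) {
      warning(sprintf("%s: breakend A interval clamped at chromosome start",
                      r$id[i]))
      info <- clamp_info(info, "CIPOS", "PRPOS", -iva[1]); iva[1] <- 0L
    }
    if (ivb[1] < 0) {
      warning(sprintf("%s: breakend B interval clamped at chromosome start",
                      r$id[i]))
      info <- clamp_info(info, "CIEND", "PREND", -ivb[1]); ivb[1] <- 0L
    }
    strands <- sub(":.*$", "", info_get(info, "STRANDS"))
    add_row(data.frame(
      chromA = r$chrom[i], startA = iva[1], endA = iva[2],
      chromB = r$chrom[i], startB = ivb[1], endB = ivb[2],
      name = r$id[i], score = r$qual[i],
      strandA = substr(strands, 1, 1), strandB = substr(strands, 2, 2),
      svtype = svtype[i], filter = r$filter[i],
      info_a = info, info_b = ".", stringsAsFactors = FALSE),
      if (length(vcf$samples)) c(r$format[i], vcf$geno[i, ]) else NULL)
  }
  for (i in which(is_bnd & !secondary)) {
    j <- find_mate(r, i, is_bnd)
    ia <- r$info[i]; ib <- r$info[j]
    iva <- breakend_interval(r$pos[i], parse_pair(info_get(ia, "CIPOS")))
    ivb <- breakend_interval(r$pos[j], parse_pair(info_get(ib, "CIPOS")))
    if (iva[1] < 0) {
      warning(sprintf("%s: breakend A interval clamped at chromosome start",
                      r$id[i]))
      ia <- clamp_info(ia, "CIPOS", "PRPOS", -iva[1]); iva[1] <- 0L
    }
    if (ivb[1] < 0) {
      warning(sprintf("%s: breakend B interval clamped at chromosome start",
                      r$id[j]))
      ib <- clamp_info(ib, "CIPOS", "PRPOS", -ivb[1]); ivb[1] <- 0L
    }
    ev <- info_get(ia, "EVENT")
    strands <- sub(":.*$", "", info_get(ia, "STRANDS"))
    add_row(data.frame(
      chromA = r$chrom[i], startA = iva[1], endA = iva[2],
      chromB = r$chrom[j], startB = ivb[1], endB = ivb[2],
      name = if (is.na(ev)) r$id[i] else ev, score = r$qual[i],
      strandA = substr(strands, 1, 1), strandB = substr(strands, 2, 2),
      svtype = "BND", filter = r$filter[i],
      info_a = ia, info_b = ib, stringsAsFactors = FALSE),
      if (length(vcf$samples)) c(r$format[i], vcf$geno[i, ]) else NULL)
  }
  rec <- if (length(rows)) do.call(rbind, rows) else
    do.call(data.frame, c(stats::setNames(
      rep(list(character(0)), length(bedpe_cols)), bedpe_cols),
      stringsAsFactors = FALSE))
  rownames(rec) <- NULL
  gm <- if (length(vcf$samples)) {
    m <- do.call(rbind, grows)
    if (is.null(m)) m <- matrix(character(0), 0, 1 + length(vcf$samples))
    colnames(m) <- c("format", vcf$samples)
    m
  } else matrix(character(0), nrow(rec), 0)
  new_svbedpe(vcf$header, vcf$samples, rec, gm)
}

#' Convert a BEDPE of SV records back to VCF
#'
#' The inverse of [vcf_to_bedpe()]: POS is recovered from the interval
#' start and the CIPOS stored in INFO_A (`POS = START_A + 1 - CIPOS[1]`),
#' and BND lines are re-expanded into reciprocal mate pairs using the
#' MATEID keys stored in INFO_A/INFO_B.
#'
#' @param bedpe an `sv_bedpe`.
#' @return an `sv_vcf` (unsorted; apply [vcfsort()] for positional order).
#' @export
bedpe_to_vcf <- function(bedpe) {
  r <- bedpe$records
  rows <- list(); grows <- list()
  has_geno <- length(bedpe$samples) > 0
  add_row <- function(row, g) {
    rows[[length(rows) + 1L]] <<- row
    grows[[length(grows) + 1L]] <<- g
  }
  for (i in seq_len(nrow(r))) {
    g <- if (has_geno) bedpe$geno[i, -1] else NULL
    fmt <- if (has_geno) bedpe$geno[i, 1] else NA_character_
    cipA <- parse_pair(info_get(r$info_a[i], "CIPOS"))
    posA <- r$startA[i] + 1L - cipA[1]
    if (r$svtype[i] != "BND") {
      add_row(data.frame(
        chrom = r$chromA[i], pos = posA, id = r$name[i], ref = "N",
        alt = sprintf("<%s>", r$svtype[i]), qual = r$score[i],
        filter = r$filter[i], info = r$info_a[i], format = fmt,
        stringsAsFactors = FALSE), g)
    } else {
      cipB <- parse_pair(info_get(r$info_b[i], "CIPOS"))
      posB <- r$startB[i] + 1L - cipB[1]
      id1 <- info_get(r$info_b[i], "MATEID")
      id2 <- info_get(r$info_a[i], "MATEID")
      add_row(data.frame(
        chrom = r$chromA[i], pos = posA, id = id1, ref = "N",
        alt = bnd_alt("N", r$strandA[i], r$strandB[i], r$chromB[i], posB),
        qual = r$score[i], filter = r$filter[i], info = r$info_a[i],
        format = fmt, stringsAsFactors = FALSE), g)
      add_row(data.frame(
        chrom = r$chromB[i], pos = posB, id = id2, ref = "N",
        alt = bnd_alt("N", r$strandB[i], r$strandA[i], r$chromA[i], posA),
        qual = r$score[i], filter = r$filter[i], info = r$info_b[i],
        format = fmt, stringsAsFactors = FALSE), g)
    }
  }
  rec <- if (length(rows)) do.call(rbind, rows) else empty_records()
  rownames(rec) <- NULL
  gm <- if (has_geno) {
    m <- do.call(rbind, grows)
    if (is.null(m)) m <- matrix(character(0), 0, length(bedpe$samples))
    colnames(m) <- bedpe$samples
    m
  } else matrix(character(0), nrow(rec), 0)
  new_svvcf(bedpe$header, bedpe$samples, rec, gm)
}

#' Sort a BEDPE by position
#'
#' Stable order by (contig order, START_A, END_A, contig order of B,
#' START_B, name).
#'
#' @param bedpe an `sv_bedpe`.
#' @return the sorted `sv_bedpe`.
#' @export
bedpesort <- function(bedpe) {
  if (nrow(bedpe$records) == 0) return(bedpe)
  contigs <- sub(".*ID=([^,>]+).*", "\\1",
                 grep("^##contig=", bedpe$header, value = TRUE))
  r <- bedpe$records
  o <- order(chrom_rank(r$chromA, contigs), r$startA, r$endA,
             chrom_rank(r$chromB, contigs), r$startB, r$name,
             method = "radix")
  bedpe$records <- r[o, , drop = FALSE]
  rownames(bedpe$records) <- NULL
  bedpe$geno <- bedpe$geno[o, , drop = FALSE]
  bedpe
}

#' Read a BEDPE file written by [write_svbedpe()]
#'
#' @param path file path, or lines via `text`.
#' @param text optional character vector of lines.
#' @return an `sv_bedpe`.
#' @export
read_svbedpe <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  hdr <- lines[startsWith(lines, "##")]
  colline <- lines[startsWith(lines, "#CHROM_A")]
  if (length(colline) != 1) stop("BEDPE missing #CHROM_A column header line")
  cols <- strsplit(colline, "\t", fixed = TRUE)[[1]]
  samples <- if (length(cols) > 15) cols[16:length(cols)] else character(0)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  f <- function(i) vapply(parts, `[[`, "", i)
  rec <- if (length(body)) data.frame(
    chromA = f(1), startA = as.integer(f(2)), endA = as.integer(f(3)),
    chromB = f(4), startB = as.integer(f(5)), endB = as.integer(f(6)),
    name = f(7), score = f(8), strandA = f(9), strandB = f(10),
    svtype = f(11), filter = f(12), info_a = f(13), info_b = f(14),
    stringsAsFactors = FALSE
  ) else do.call(data.frame, c(stats::setNames(
    rep(list(character(0)), length(bedpe_cols)), bedpe_cols),
    stringsAsFactors = FALSE))
  gm <- if (length(samples)) {
    m <- matrix("", nrow(rec), 1L + length(samples),
                dimnames = list(NULL, c("format", samples)))
    if (nrow(rec)) for (j in seq_len(ncol(m))) m[, j] <- f(14L + j)
    m
  } else matrix(character(0), nrow(rec), 0)
  new_svbedpe(hdr, samples, rec, gm)
}

#' Write an `sv_bedpe` to a file
#' @param bedpe an `sv_bedpe`.
#' @param path output path ("" writes to stdout).
#' @return invisibly, the lines written.
#' @export
write_svbedpe <- function(bedpe, path = "") {
  colline <- paste(c("#CHROM_A", "START_A", "END_A", "CHROM_B", "START_B",
                     "END_B", "ID", "QUAL", "STRAND_A", "STRAND_B", "TYPE",
                     "FILTER", "INFO_A", "INFO_B",
                     if (length(bedpe$samples)) c("FORMAT", bedpe$samples)),
                   collapse = "\t")
  r <- bedpe$records
  body <- if (nrow(r) == 0) character(0) else {
    fixed <- do.call(paste, c(unname(r[bedpe_cols]), sep = "\t"))
    if (length(bedpe$samples)) {
      paste(fixed, apply(bedpe$geno, 1, paste, collapse = "\t"), sep = "\t")
    } else fixed
  }
  lines <- c(bedpe$header, colline, body)
  if (nzchar(path)) writeLines(lines, path) else writeLines(lines)
  invisible(lines)
}
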