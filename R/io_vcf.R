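# VCF reader/writer for SV records carrying LUMPY-style breakpoint
# annotations (SVTYPE, STRANDS, CIPOS/CIEND, PRPOS/PREND, SU, SNAME) and
# per-sample FORMAT fields (GT, SQ, GQ, AB, CN).  Parsing is line-oriented
# and field-preserving so that format conversions round-trip exactly.

# ---- INFO string helpers ------------------------------------------------

#' Extract a key's value from VCF INFO strings
#'
#' @param info character vector of semicolon-separated INFO strings.
#' @param key INFO key.
#' @return character vector of values, `NA` where absent; flag keys
#'   present without `=` return `""`.
#' @export
info_get <- function(info, key) {
  vapply(strsplit(info, ";", fixed = TRUE), function(kv) {
    hit <- grep(paste0("^", key, "(=|$)"), kv, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    sub(paste0("^", key, "=?"), "", hit[1])
  }, character(1))
}

#' Set or replace a key in VCF INFO strings
#'
#' @param info character vector of INFO strings.
#' @param key INFO key.
#' @param value replacement values (recycled); use `NULL` value semantics
#'   via [info_drop()] to remove a key.
#' @return updated INFO strings.
#' @export
info_set <- function(info, key, value) {
  value <- rep_len(as.character(value), length(info))
  mapply(function(one, val) {
    kv <- strsplit(one, ";", fixed = TRUE)[[1]]
    kv <- kv[!grepl(paste0("^", key, "(=|$)"), kv)]
    kv <- kv[nzchar(kv) & kv != "."]
    paste(c(kv, paste0(key, "=", val)), collapse = ";")
  }, info, value, USE.NAMES = FALSE)
}

#' Remove a key from VCF INFO strings
#' @param info character vector of INFO strings.
#' @param key INFO key to drop.
#' @return updated INFO strings (`"."` if nothing remains).
#' @export
info_drop <- function(info, key) {
  vapply(strsplit(info, ";", fixed = TRUE), function(kv) {
    kv <- kv[!grepl(paste0("^", key, "(=|$)"), kv)]
    if (length(kv) == 0) "." else paste(kv, collapse = ";")
  }, character(1))
}

# format a probability vector for PRPOS/PREND: 6 significant digits
format_probs <- function(p) {
  paste(sprintf("%.6g", p), collapse = ",")
}

parse_probs <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])

parse_pair <- function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1]])

# ---- sv_vcf object ------------------------------------------------------

new_svvcf <- function(header, samples, records, geno = NULL) {
  structure(list(header = header, samples = samples, records = records,
                 geno = geno),
            class = "sv_vcf")
}

#' @export
print.sv_vcf <- function(x, ...) {
  cat(sprintf("<sv_vcf: %d records, %d samples>\n", nrow(x$records),
              length(x$samples)))
  invisible(x)
}

empty_records <- function() {
  data.frame(chrom = character(0), pos = integer(0), id = character(0),
             ref = character(0), alt = character(0), qual = character(0),
             filter = character(0), info = character(0),
             format = character(0), stringsAsFactors = FALSE)
}

#' Standard VCF header for SV callsets
#'
#' @param contigs named integer vector of contig lengths (names are
#'   contig ids), in the order they should sort.
#' @param samples character vector of sample column names.
#' @param extra additional `##` header lines.
#' @return character vector of header lines (without the `#CHROM` line).
#' @export
svvcf_header <- function(contigs, samples = character(0), extra = character(0)) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=STRANDS,Number=.,Type=String,Description="Strand orientation of the adjacency with supporting read count">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of the variant">',
    '##INFO=<ID=CIPOS,Number=2,Type=Integer,Description="Confidence interval around POS">',
    '##INFO=<ID=CIEND,Number=2,Type=Integer,Description="Confidence interval around END">',
    '##INFO=<ID=PRPOS,Number=.,Type=Float,Description="Breakpoint probability distribution over CIPOS">',
    '##INFO=<ID=PREND,Number=.,Type=Float,Description="Breakpoint probability distribution over CIEND">',
    '##INFO=<ID=SU,Number=1,Type=Integer,Description="Number of pieces of evidence supporting the variant">',
    '##INFO=<ID=SNAME,Number=.,Type=String,Description="Source sample name and original call id">',
    '##INFO=<ID=EVENT,Number=1,Type=String,Description="Id of the event associated with this breakend">',
    '##INFO=<ID=MATEID,Number=1,Type=String,Description="Id of mate breakend">',
    '##INFO=<ID=SECONDARY,Number=0,Type=Flag,Description="Secondary breakend in a multi-line variant">',
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Allele frequency">',
    '##INFO=<ID=NSAMP,Number=1,Type=Integer,Description="Number of samples with non-reference genotype">',
    '##INFO=<ID=MSQ,Number=1,Type=Float,Description="Mean sample quality of non-reference samples">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=SQ,Number=1,Type=Float,Description="Phred-scaled probability that this site is variant in this sample">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=AB,Number=1,Type=Float,Description="Allele balance of the alternate allele">',
    '##FORMAT=<ID=CN,Number=1,Type=Float,Description="Copy number of the structural variant interval">',
    extra)
}

#' Contig order declared in a VCF header
#' @param vcf an `sv_vcf`.
#' @return character vector of contig ids in header order.
#' @export
vcf_contigs <- function(vcf) {
  lines <- grep("^##contig=", vcf$header, value = TRUE)
  sub(".*ID=([^,>]+).*", "\\1", lines)
}

#' Read a VCF file of SV records
#'
#' Accepts plain or gzip-compressed VCF 4.2 text.
#'
#' @param path file path, or a character vector of VCF lines via `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @return an `sv_vcf` object: header lines, sample names, a records
#'   data.frame (chrom, pos, id, ref, alt, qual, filter, info, format) and
#'   a character genotype matrix (records x samples).
#' @export
read_svvcf <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  hdr <- lines[startsWith(lines, "##")]
  chromline <- lines[startsWith(lines, "#CHROM")]
  if (length(chromline) != 1) stop("VCF missing #CHROM header line")
  cols <- strsplit(chromline, "\t", fixed = TRUE)[[1]]
  samples <- if (length(cols) > 9) cols[10:length(cols)] else character(0)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(new_svvcf(hdr, samples, empty_records(),
                     matrix(character(0), 0, length(samples),
                            dimnames = list(NULL, samples))))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nfield <- vapply(parts, length, 1L)
  want <- if (length(samples)) 9L + length(samples) else 8L
  bad <- which(nfield < want)
  if (length(bad)) {
    stop(sprintf("malformed VCF record at data line %d: %d fields, expected %d",
                 bad[1], nfield[bad[1]], want))
  }
  f <- function(i) vapply(parts, `[[`, "", i)
  rec <- data.frame(
    chrom = f(1), pos = as.integer(f(2)), id = f(3), ref = f(4), alt = f(5),
    qual = f(6), filter = f(7), info = f(8),
    format = if (length(samples)) f(9) else NA_character_,
    stringsAsFactors = FALSE
  )
  geno <- if (length(samples)) {
    m <- matrix("", nrow(rec), length(samples), dimnames = list(NULL, samples))
    for (j in seq_along(samples)) m[, j] <- f(9L + j)
    m
  } else {
    matrix(character(0), nrow(rec), 0)
  }
  new_svvcf(hdr, samples, rec, geno)
}

#' Write an `sv_vcf` to a file
#' @param vcf an `sv_vcf`.
#' @param path output path ("" writes to stdout).
#' @return invisibly, the lines written.
#' @export
write_svvcf <- function(vcf, path = "") {
  lines <- svvcf_lines(vcf)
  if (nzchar(path)) writeLines(lines, path) else writeLines(lines)
  invisible(lines)
}

svvcf_lines <- function(vcf) {
  chromline <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO",
                       if (length(vcf$samples)) c("FORMAT", vcf$samples)),
                     collapse = "\t")
  r <- vcf$records
  body <- if (nrow(r) == 0) character(0) else {
    fixed <- paste(r$chrom, r$pos, r$id, r$ref, r$alt, r$qual, r$filter,
                   r$info, sep = "\t")
    if (length(vcf$samples)) {
      gcols <- apply(vcf$geno, 1, paste, collapse = "\t")
      paste(fixed, r$format, gcols, sep = "\t")
    } else fixed
  }
  c(vcf$header, chromline, body)
}

# rank of chromosomes under a declared contig order; unknown contigs sort
# after known ones, alphabetically
chrom_rank <- function(chrom, contigs) {
  r <- match(chrom, contigs)
  unknown <- is.na(r)
  if (any(unknown)) {
    extra <- sort(unique(chrom[unknown]))
    r[unknown] <- length(contigs) + match(chrom[unknown], extra)
  }
  r
}

# sort key END: INFO END if present, else POS
record_end <- function(rec) {
  e <- suppressWarnings(as.integer(info_get(rec$info, "END")))
  ifelse(is.na(e), rec$pos, e)
}

#' Sort a VCF by position
#'
#' Records are ordered by (contig order from the header, POS, END, ID);
#' the sort is stable so records with equal keys keep their input order.
#'
#' @param vcf an `sv_vcf`.
#' @return the sorted `sv_vcf`.
#' @export
vcfsort <- function(vcf) {
  if (nrow(vcf$records) == 0) return(vcf)
  contigs <- vcf_contigs(vcf)
  o <- order(chrom_rank(vcf$records$chrom, contigs), vcf$records$pos,
             record_end(vcf$records), vcf$records$id, method = "radix")
  vcf$records <- vcf$records[o, , drop = FALSE]
  rownames(vcf$records) <- NULL
  vcf$geno <- vcf$geno[o, , drop = FALSE]
  vcf
}

#' Merge and sort per-sample VCFs into a single stream
#'
#' The first step of cohort assembly: per-sample discovery VCFs are
#' concatenated, each record is tagged with its origin via the INFO key
#' `SNAME=sample:original_id`, genotype columns are dropped, and the
#' combined stream is sorted by (contig order, POS, END, ID).
#'
#' The sample name is taken from the VCF's single genotype column, or from
#' a `##sample=` header line when the file has no genotype columns.
#' All inputs must declare identical contig dictionaries.
#'
#' @param paths character vector of VCF file paths, or a list of `sv_vcf`
#'   objects via `vcfs`.
#' @param vcfs optional list of already-read `sv_vcf` objects.
#' @return a sorted site-level `sv_vcf` with `SNAME` provenance.
#' @export
lsort <- function(paths = NULL, vcfs = NULL) {
  if (is.null(vcfs)) vcfs <- lapply(paths, read_svvcf)
  if (length(vcfs) == 0) stop("lsort requires at least one input VCF")
  contigs <- vcf_contigs(vcfs[[1]])
  recs <- vector("list", length(vcfs))
  for (k in seq_along(vcfs)) {
    v <- vcfs[[k]]
    ck <- vcf_contigs(v)
    if (!identical(ck, contigs)) {
      stop(sprintf(
        "inconsistent contig dictionaries: input %d declares [%s], input 1 declares [%s]",
        k, paste(ck, collapse = ","), paste(contigs, collapse = ",")))
    }
    smp <- vcf_sample_name(v)
    r <- v$records
    if (nrow(r)) {
      sname <- info_get(r$info, "SNAME")
      r$info <- info_set(r$info, "SNAME",
                         ifelse(is.na(sname), paste0(smp, ":", r$id), sname))
    }
    recs[[k]] <- r
  }
  rec <- do.call(rbind, recs)
  rownames(rec) <- NULL
  rec$format <- NA_character_
  out <- new_svvcf(vcfs[[1]]$header, character(0), rec,
                   matrix(character(0), nrow(rec), 0))
  vcfsort(out)
}

vcf_sample_name <- function(vcf) {
  if (length(vcf$samples) == 1) return(vcf$samples)
  hs <- grep("^##sample=", vcf$header, value = TRUE)
  if (length(hs)) return(sub("^##sample=", "", hs[1]))
  NA_character_
}

# ---- sv_vcf <-> sv_callset ---------------------------------------------

# breakend distribution from POS (1-based), CI offsets and PR string
.dist_from_fields <- function(chrom, pos, ci, pr, fallback, what, id) {
  if (is.na(ci[1])) ci <- c(0L, 0L)
  span <- ci[2] - ci[1] + 1L
  if (is.na(pr)) {
    warning(sprintf("%s: %s missing; synthesizing %s distribution over CI",
                    id, what, fallback))
    probs <- if (fallback == "uniform") rep(1 / span, span) else {
      p <- rep(0, span); p[1L - ci[1]] <- 1; p
    }
  } else {
    probs <- parse_probs(pr)
    if (length(probs) != span) {
      stop(sprintf("%s: %s length %d does not match CI span %d",
                   id, what, length(probs), span))
    }
  }
  make_distribution(pos - 1L + ci[1], probs, chrom)
}

#' Parse an `sv_vcf` into a callset of breakpoint calls
#'
#' One `SVBreakpointCall` per variant: intrachromosomal DEL/DUP/INV/MEI
#' records map POS/END to the two breakends; BND mate-pair records
#' (linked by MATEID) are collapsed into a single two-breakend call whose
#' B-side distribution comes from the mate's CIPOS/PRPOS.
#'
#' @param vcf an `sv_vcf`.
#' @param fallback distribution synthesized when PRPOS/PREND is absent:
#'   `"uniform"` over the confidence interval or `"point"` mass at the
#'   point estimate (with a warning either way).
#' @return an `sv_callset`.
#' @export
svvcf_to_callset <- function(vcf, fallback = c("uniform", "point")) {
  fallback <- match.arg(fallback)
  r <- vcf$records
  if (nrow(r) == 0) return(bind_callsets(list()))
  svtype <- info_get(r$info, "SVTYPE")
  strands_raw <- info_get(r$info, "STRANDS")
  strands <- sub(":.*$", "", strands_raw)
  su <- suppressWarnings(as.integer(info_get(r$info, "SU")))
  su[is.na(su)] <- 0L
  sname <- info_get(r$info, "SNAME")
  smp <- vcf_sample_name(vcf)
  is_bnd <- svtype == "BND"
  secondary <- grepl("(^|;)SECONDARY(;|$)", r$info)

  calls <- list()
  # intrachromosomal symbolic records
  for (i in which(!is_bnd)) {
    endp <- as.integer(info_get(r$info[i], "END"))
    dA <- .dist_from_fields(r$chrom[i], r$pos[i],
                            parse_pair(info_get(r$info[i], "CIPOS")),
                            info_get(r$info[i], "PRPOS"), fallback, "PRPOS",
                            r$id[i])
    dB <- .dist_from_fields(r$chrom[i], endp,
                            parse_pair(info_get(r$info[i], "CIEND")),
                            info_get(r$info[i], "PREND"), fallback, "PREND",
                            r$id[i])
    calls[[length(calls) + 1L]] <- sv_callset(
      id = r$id[i], chromA = r$chrom[i], posA = r$pos[i],
      strandA = substr(strands[i], 1, 1),
      chromB = r$chrom[i], posB = endp, strandB = substr(strands[i], 2, 2),
      svtype = svtype[i], su = su[i], sample = smp,
      distA = list(dA), distB = list(dB),
      snames = if (is.na(sname[i])) NULL else
        list(strsplit(sname[i], ",", fixed = TRUE)[[1]])
    )
  }
  # BND mate pairs: primary line + SECONDARY mate
  prim <- which(is_bnd & !secondary)
  for (i in prim) {
    j <- find_mate(r, i, is_bnd)
    dA <- .dist_from_fields(r$chrom[i], r$pos[i],
                            parse_pair(info_get(r$info[i], "CIPOS")),
                            info_get(r$info[i], "PRPOS"), fallback, "PRPOS",
                            r$id[i])
    dB <- .dist_from_fields(r$chrom[j], r$pos[j],
                            parse_pair(info_get(r$info[j], "CIPOS")),
                            info_get(r$info[j], "PRPOS"), fallback, "PRPOS",
                            r$id[j])
    ev <- info_get(r$info[i], "EVENT")
    calls[[length(calls) + 1L]] <- sv_callset(
      id = if (is.na(ev)) r$id[i] else ev,
      chromA = r$chrom[i], posA = r$pos[i], strandA = substr(strands[i], 1, 1),
      chromB = r$chrom[j], posB = r$pos[j], strandB = substr(strands[i], 2, 2),
      svtype = "BND", su = su[i], sample = smp,
      distA = list(dA), distB = list(dB),
      snames = if (is.na(sname[i])) NULL else
        list(strsplit(sname[i], ",", fixed = TRUE)[[1]])
    )
  }
  # mate collapsing interleaves record order; restore positional order
  sort_callset(bind_callsets(calls), vcf_contigs(vcf))
}

# locate the mate line of a BND record; after lsort several samples can
# carry the same record ids, so mates are disambiguated by SNAME
find_mate <- function(r, i, is_bnd) {
  mate <- info_get(r$info[i], "MATEID")
  j <- which(r$id == mate & is_bnd)
  if (length(j) > 1) {
    sname <- info_get(r$info[c(i, j)], "SNAME")
    j <- j[!is.na(sname[-1]) & sname[-1] == sname[1]]
  }
  if (length(j) != 1) {
    stop(sprintf("BND %s: mate %s not found", r$id[i], mate))
  }
  j
}

# bracketed ALT notation for a BND breakend: strand pair -> join geometry
bnd_alt <- function(ref, strandA, strandB, chrom, pos) {
  key <- paste0(strandA, strandB)
  switch(key,
         "+-" = sprintf("%s[%s:%d[", ref, chrom, pos),
         "++" = sprintf("%s]%s:%d]", ref, chrom, pos),
         "-+" = sprintf("]%s:%d]%s", chrom, pos, ref),
         "--" = sprintf("[%s:%d[%s", chrom, pos, ref),
         stop("invalid strand pair ", key))
}

# CI offsets of a distribution relative to a 1-based anchor position
ci_offsets <- function(d, pos) {
  c(d$start - (pos - 1L), d$start + length(d$probs) - 1L - (pos - 1L))
}

#' Serialize a callset as an `sv_vcf`
#'
#' Intrachromosomal DEL/DUP/INV/MEI calls become one symbolic-ALT record;
#' BND calls become a reciprocal mate pair (`<id>_1`, `<id>_2`, linked by
#' MATEID/EVENT, the second flagged SECONDARY) sharing any genotype
#' columns.  CIPOS/CIEND span the full extent of each breakend
#' distribution and PRPOS/PREND carry its per-base probabilities.
#'
#' @param calls an `sv_callset`.
#' @param contigs named integer vector of contig lengths for the header.
#' @param samples optional sample names for genotype columns.
#' @param format,geno optional FORMAT string and genotype matrix
#'   (rows = calls, columns = samples).
#' @param info optional list of named character vectors of extra INFO
#'   fields per call (e.g. AF, NSAMP, MSQ).
#' @param extra_header additional `##` header lines.
#' @return an `sv_vcf`.
#' @export
callset_to_svvcf <- function(calls, contigs, samples = character(0),
                             format = "GT", geno = NULL, info = NULL,
                             extra_header = character(0)) {
  n <- nrow(calls)
  rec <- vector("list", n)
  grows <- vector("list", n)
  for (i in seq_len(n)) {
    dA <- calls$distA[[i]]; dB <- calls$distB[[i]]
    ciA <- ci_offsets(dA, calls$posA[i])
    ciB <- ci_offsets(dB, calls$posB[i])
    strands <- sprintf("%s%s:%d", calls$strandA[i], calls$strandB[i],
                       calls$su[i])
    base_info <- function(extra) {
      fields <- c(
        sprintf("SVTYPE=%s", extra$svtype),
        sprintf("STRANDS=%s", extra$strands),
        if (!is.null(extra$end)) sprintf("END=%d", extra$end),
        sprintf("CIPOS=%d,%d", extra$cipos[1], extra$cipos[2]),
        if (!is.null(extra$ciend)) sprintf("CIEND=%d,%d", extra$ciend[1],
                                           extra$ciend[2]),
        sprintf("PRPOS=%s", extra$prpos),
        if (!is.null(extra$prend)) sprintf("PREND=%s", extra$prend),
        sprintf("SU=%d", calls$su[i]),
        if (length(calls$snames[[i]]))
          sprintf("SNAME=%s", paste(calls$snames[[i]], collapse = ",")),
        extra$more
      )
      paste(fields, collapse = ";")
    }
    user_info <- if (!is.null(info) && !is.null(info[[i]]) &&
                     length(info[[i]])) {
      paste0(names(info[[i]]), "=", info[[i]])
    } else character(0)
    gi <- if (!is.null(geno)) geno[i, , drop = TRUE] else NULL
    if (calls$svtype[i] != "BND") {
      rec[[i]] <- data.frame(
        chrom = calls$chromA[i], pos = calls$posA[i], id = calls$id[i],
        ref = "N", alt = sprintf("<%s>", calls$svtype[i]), qual = ".",
        filter = ".",
        info = base_info(list(
          svtype = calls$svtype[i], strands = strands, end = calls$posB[i],
          cipos = ciA, ciend = ciB, prpos = format_probs(dA$probs),
          prend = format_probs(dB$probs), more = user_info)),
        format = if (length(samples)) format else NA_character_,
        stringsAsFactors = FALSE)
      grows[[i]] <- rbind(gi)
    } else {
      id1 <- paste0(calls$id[i], "_1"); id2 <- paste0(calls$id[i], "_2")
      strands2 <- sprintf("%s%s:%d", calls$strandB[i], calls$strandA[i],
                          calls$su[i])
      l1 <- data.frame(
        chrom = calls$chromA[i], pos = calls$posA[i], id = id1, ref = "N",
        alt = bnd_alt("N", calls$strandA[i], calls$strandB[i],
                      calls$chromB[i], calls$posB[i]),
        qual = ".", filter = ".",
        info = base_info(list(
          svtype = "BND", strands = strands, cipos = ciA,
          prpos = format_probs(dA$probs),
          more = c(sprintf("MATEID=%s", id2),
                   sprintf("EVENT=%s", calls$id[i]), user_info))),
        format = if (length(samples)) format else NA_character_,
        stringsAsFactors = FALSE)
      l2 <- l1
      l2$chrom <- calls$chromB[i]; l2$pos <- calls$posB[i]; l2$id <- id2
      l2$alt <- bnd_alt("N", calls$strandB[i], calls$strandA[i],
                        calls$chromA[i], calls$posA[i])
      l2$info <- base_info(list(
        svtype = "BND", strands = strands2, cipos = ciB,
        prpos = format_probs(dB$probs),
        more = c(sprintf("MATEID=%s", id1),
                 sprintf("EVENT=%s", calls$id[i]), "SECONDARY", user_info)))
      rec[[i]] <- rbind(l1, l2)
      grows[[i]] <- rbind(gi, gi)
    }
  }
  rec <- if (n) do.call(rbind, rec) else empty_records()
  rownames(rec) <- NULL
  gm <- if (length(samples)) {
    m <- do.call(rbind, grows)
    if (is.null(m)) m <- matrix(character(0), 0, length(samples))
    colnames(m) <- samples
    m
  } else matrix(character(0), nrow(rec), 0)
  new_svvcf(svvcf_header(contigs, samples, extra_header), samples, rec, gm)
}
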