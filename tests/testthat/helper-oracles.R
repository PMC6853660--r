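# independent oracles and panel builders shared across test files

# enumerate every parental allele transmission; TRUE when the child
# genotype is impossible
oracle_me <- function(child, father, mother) {
  al <- function(g) as.integer(strsplit(g, "/")[[1]])
  poss <- expand.grid(f = al(father), m = al(mother))
  consistent <- apply(poss, 1, function(p)
    identical(sort(unname(p)), sort(al(child))))
  !any(consistent)
}

# repeatedly delete the worst record involved in any remaining conflict,
# recomputing conflicts from scratch each time
oracle_prune <- function(calls, eval_dist) {
  alive <- rep(TRUE, nrow(calls))
  conflicted <- function() {
    idx <- which(alive)
    out <- integer(0)
    for (i in idx) for (j in idx) {
      if (i < j && calls$svtype[i] == calls$svtype[j] &&
          calls$chromA[i] == calls$chromA[j] &&
          calls$chromB[i] == calls$chromB[j] &&
          abs(calls$posA[i] - calls$posA[j]) <= eval_dist &&
          abs(calls$posB[i] - calls$posB[j]) <= eval_dist) {
        out <- union(out, c(i, j))
      }
    }
    out
  }
  repeat {
    bad <- conflicted()
    if (length(bad) == 0) break
    o <- bad[order(calls$su[bad], -calls$posA[bad], calls$id[bad],
                   method = "radix", decreasing = c(FALSE, FALSE, TRUE))]
    alive[o[1]] <- FALSE
  }
  calls$id[alive]
}

# labeled per-variant AB/CN matrices without the full pipeline:
# n_var variants per class over nsamp samples
simulate_class_panel <- function(n_var, nsamp, frac_carrier, ab_sd, cn_sd) {
  classes <- rep(c("DEL", "DUP", "BND"), each = n_var)
  delta <- c(DEL = -1, DUP = 1, BND = 0)
  gt <- matrix("0/0", length(classes), nsamp)
  ab <- matrix(0, length(classes), nsamp)
  cn <- matrix(2, length(classes), nsamp)
  for (i in seq_along(classes)) {
    carriers <- sample.int(nsamp, round(frac_carrier * nsamp))
    hom <- carriers[seq_len(floor(length(carriers) / 4))]
    het <- setdiff(carriers, hom)
    gt[i, het] <- "0/1"; gt[i, hom] <- "1/1"
    dos <- ifelse(gt[i, ] == "0/1", 1, ifelse(gt[i, ] == "1/1", 2, 0))
    ab[i, ] <- pmin(pmax(dos / 2 + stats::rnorm(nsamp, 0, ab_sd), 0), 1)
    cn[i, ] <- pmax(2 + dos * delta[classes[i]] +
                      stats::rnorm(nsamp, 0, cn_sd), 0)
  }
  list(classes = classes, gt = gt, ab = ab, cn = cn)
}

panel_accuracy <- function(panel) {
  strands <- list(DEL = c("+", "-"), DUP = c("-", "+"), BND = c("+", "-"))
  got <- vapply(seq_along(panel$classes), function(i) {
    s <- strands[[panel$classes[i]]]
    # balanced truth can have either CNV-compatible orientation
    if (panel$classes[i] == "BND" && i %% 2 == 0) s <- c("-", "+")
    fit <- fit_ab_cn_regression(panel$ab[i, ], panel$cn[i, ], panel$gt[i, ])
    classify_by_regression("BND", s[1], s[2], fit)
  }, character(1))
  mean(got == panel$classes)
}
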