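#' Quartet specification for ABBA-BABA tests
#'
#' The four taxa of a `(((P1, P2), P3), P4)` test. Each slot is either a
#' population label from the population map or an explicit vector of sample
#' ids; the four resolved sample sets must be non-empty and disjoint. P4 is
#' the outgroup used for polarization.
#'
#' @param p1,p2,p3,p4 population label or character vector of sample ids.
#' @return A `quartet_spec` object.
#' @export
quartet_spec <- function(p1, p2, p3, p4) {
  structure(list(p1 = p1, p2 = p2, p3 = p3, p4 = p4), class = "quartet_spec")
}

resolve_quartet <- function(popmap, quartet) {
  sets <- lapply(quartet[c("p1", "p2", "p3", "p4")],
                 function(s) resolve_samples(popmap, s))
  if (any(lengths(sets) == 0L)) stopf("empty quartet population")
  all <- unlist(sets)
  if (anyDuplicated(all)) stopf("quartet sample sets must be disjoint")
  sets
}

#' Per-block ABBA/BABA site-pattern sums
#'
#' For each biallelic site, alleles are polarized against the P4 outgroup
#' consensus: the majority allele among non-missing P4 calls is ancestral
#' and the other allele derived; sites where P4 is polymorphic, missing, or
#' exactly tied are skipped, as are sites where any of P1-P3 has no
#' non-missing call. With `p_i` the derived-allele frequency in population
#' `i`, each used site contributes `(1-p1) p2 p3 (1-p4)` to the ABBA sum and
#' `p1 (1-p2) p3 (1-p4)` to the BABA sum of its genomic block. Blocks tile
#' each chromosome in `block_bp` steps and are the jackknife units.
#'
#' @param cohort a [new_cohort()].
#' @param popmap a [population_map()].
#' @param quartet a [quartet_spec()].
#' @param block_bp jackknife block length in bp (default 5 Mb).
#' @return A `pattern_sums` data frame: `chrom`, `start`, `end`, `abba`,
#'   `baba`, `n_sites_used`.
#' @export
site_pattern_sums <- function(cohort, popmap, quartet, block_bp = 5e6) {
  stopifnot(inherits(cohort, "cohort"), inherits(quartet, "quartet_spec"))
  if (block_bp <= 0) stopf("block_bp must be positive")
  sets <- resolve_quartet(popmap, quartet)

  f <- lapply(sets, function(s) alt_freq(cohort, s))
  p4_alt <- f[[4]]
  # P4 must be monomorphic among non-missing calls; ties and all-missing skip
  usable <- !is.na(p4_alt) & (p4_alt == 0 | p4_alt == 1) &
    !is.na(f[[1]]) & !is.na(f[[2]]) & !is.na(f[[3]])
  # derived = allele absent from the P4 consensus
  p <- lapply(f[1:3], function(fi) ifelse(p4_alt == 1, 1 - fi, fi))
  abba <- ifelse(usable, (1 - p[[1]]) * p[[2]] * p[[3]], 0)
  baba <- ifelse(usable, p[[1]] * (1 - p[[2]]) * p[[3]], 0)

  block <- floor(cohort$pos / block_bp)
  key <- paste(cohort$chrom, block, sep = ":")
  # tile every chromosome from 0 through its last occupied block
  chroms <- unique(cohort$chrom)
  tiles <- do.call(rbind, lapply(chroms, function(ch) {
    mx <- max(block[cohort$chrom == ch])
    data.frame(chrom = ch, block = 0:mx, stringsAsFactors = FALSE)
  }))
  tkey <- paste(tiles$chrom, tiles$block, sep = ":")
  agg <- function(v) {
    s <- tapply(v, key, sum)
    out <- setNames(rep(0, length(tkey)), tkey)
    out[names(s)] <- s
    out
  }
  res <- data.frame(chrom = tiles$chrom,
                    start = tiles$block * block_bp,
                    end = (tiles$block + 1) * block_bp,
                    abba = agg(abba), baba = agg(baba),
                    n_sites_used = agg(as.numeric(usable)),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, class = c("pattern_sums", "data.frame"),
            quartet = quartet, block_bp = block_bp)
}

#' D statistic with weighted block-jackknife standard error
#'
#' `D = (sum BABA - sum ABBA) / (sum BABA + sum ABBA)`: an excess of ABBA
#' (derived-allele sharing between P2 and P3) gives a *negative* D. The
#' standard error is a delete-one-block jackknife over the pattern-sum
#' blocks, weighted by the number of sites used per block (Busing-style
#' unequal block sizes); `Z = D / SE`.
#'
#' @param pattern_sums a [site_pattern_sums()] result.
#' @return A `dstat_result` with fields `D`, `se`, `Z`, `abba`, `baba`,
#'   `n_blocks`, `n_sites`.
#' @export
d_statistic <- function(pattern_sums) {
  ps <- pattern_sums[pattern_sums$n_sites_used > 0, ]
  A <- sum(ps$abba); B <- sum(ps$baba)
  if (A + B <= 0) stopf("undefined D statistic: no informative sites")
  D <- (B - A) / (A + B)
  g <- nrow(ps)
  if (g < 2) stopf("need at least 2 non-empty blocks for the jackknife")
  m <- ps$n_sites_used
  n <- sum(m)
  loo <- vapply(seq_len(g), function(j) {
    Aj <- A - ps$abba[j]; Bj <- B - ps$baba[j]
    (Bj - Aj) / (Aj + Bj)
  }, numeric(1))
  h <- n / m
  theta_J <- g * D - sum((1 - m / n) * loo)
  var_J <- sum((h * D - (h - 1) * loo - theta_J)^2 / (h - 1)) / g
  se <- sqrt(var_J)
  structure(list(D = D, se = se, Z = if (se > 0) D / se else NA_real_,
                 abba = A, baba = B, n_blocks = g, n_sites = n),
            class = "dstat_result")
}

#' @exportS3Method base::print
print.dstat_result <- function(x, ...) {
  cat(sprintf("D = %.4f  SE = %.4f  Z = %.2f  (ABBA %.1f, BABA %.1f, %d blocks, %g sites)\n",
              x$D, x$se, x$Z, x$abba, x$baba, x$n_blocks, x$n_sites))
  invisible(x)
}

#' One-call ABBA-BABA test
#'
#' Convenience wrapper: [site_pattern_sums()] followed by [d_statistic()].
#' A Z below -3 is the conventional threshold for significant derived-allele
#' sharing between P2 and P3.
#'
#' @inheritParams site_pattern_sums
#' @return A `dstat_result`.
#' @export
d_test <- function(cohort, popmap, quartet, block_bp = 5e6) {
  d_statistic(site_pattern_sums(cohort, popmap, quartet, block_bp))
}
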