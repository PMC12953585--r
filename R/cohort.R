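#' Genotyped cohort container
#'
#' A `cohort` holds a filtered set of biallelic SNPs for a fixed panel of
#' diploid samples: one row per site (chromosome, 0-based position, reference
#' and alternate allele, site quality) and two allele matrices giving each
#' sample's diploid call. Alleles are coded 0 (reference) and 1 (alternate);
#' a missing genotype has both alleles `NA`. Positions are strictly
#' increasing within each chromosome and every site is a biallelic SNP.
#'
#' Internally all coordinates are 0-based half-open; VCF input/output
#' converts to and from the 1-based POS convention.
#'
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 0-based positions, strictly increasing
#'   within each chromosome.
#' @param ref,alt single-base reference/alternate alleles per site.
#' @param a1,a2 integer matrices (sites x samples) of first/second alleles,
#'   each entry 0, 1 or `NA`.
#' @param phased logical matrix (sites x samples) marking phased calls, or a
#'   single logical recycled to all calls.
#' @param samples character vector of sample names (column order of `a1`).
#' @param qual numeric vector of per-site quality scores (`NA` = unknown).
#' @return An object of class `cohort`.
#' @export
new_cohort <- function(chrom, pos, ref, alt, a1, a2, phased = FALSE,
                       samples = colnames(a1), qual = NULL) {
  n_sites <- length(pos)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(a1)))
  if (length(phased) == 1L)
    phased <- matrix(phased, n_sites, ncol(a1))
  qual <- qual %||% rep(NA_real_, n_sites)
  obj <- structure(list(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    a1 = a1, a2 = a2, phased = phased,
    samples = as.character(samples), qual = as.numeric(qual)
  ), class = "cohort")
  validate_cohort(obj)
  obj
}

validate_cohort <- function(x) {
  ns <- length(x$pos)
  if (length(x$chrom) != ns || length(x$ref) != ns || length(x$alt) != ns ||
      length(x$qual) != ns)
    stopf("cohort site vectors have inconsistent lengths")
  if (nrow(x$a1) != ns || !identical(dim(x$a1), dim(x$a2)))
    stopf("genotype matrices must be n_sites x n_samples")
  if (ncol(x$a1) != length(x$samples))
    stopf("sample names do not match genotype columns")
  if (anyDuplicated(x$samples)) stopf("duplicated sample names")
  bad <- x$ref == x$alt | nchar(x$ref) != 1L | nchar(x$alt) != 1L
  if (any(bad)) stopf("all sites must be biallelic SNPs (ref != alt, single bases)")
  for (ch in unique(x$chrom)) {
    p <- x$pos[x$chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0L))
      stopf("positions not strictly increasing on chromosome %s", ch)
  }
  ok <- function(m) all(m %in% c(0L, 1L) | is.na(m))
  if (!ok(x$a1) || !ok(x$a2)) stopf("alleles must be coded 0/1/NA")
  if (!identical(is.na(x$a1), is.na(x$a2)))
    stopf("half-missing genotypes are not supported")
  invisible(x)
}

#' @exportS3Method base::print
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d biallelic SNPs x %d samples on %d chromosome(s)\n",
              n_sites(x), n_samples(x), length(unique(x$chrom))))
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing calls: %.2f%%; phased: %.1f%%\n",
              100 * miss, 100 * mean(x$phased)))
  invisible(x)
}

#' @exportS3Method base::summary
summary.cohort <- function(object, ...) {
  tab <- table(object$chrom)
  cat(sprintf("cohort of %d samples\n", n_samples(object)))
  for (ch in names(tab))
    cat(sprintf("  %s: %d sites, span %d bp\n", ch, tab[[ch]],
                diff(range(object$pos[object$chrom == ch])) + 1L))
  invisible(object)
}

#' Number of sites / samples in a cohort
#' @param x a [new_cohort()] object.
#' @return integer count.
#' @export
n_sites <- function(x) length(x$pos)

#' @rdname n_sites
#' @export
n_samples <- function(x) length(x$samples)

#' Subset a cohort by site index or sample name
#' @param x a cohort.
#' @param sites integer/logical site index.
#' @param samples character vector of sample names or column index.
#' @return a new `cohort`; site and sample order is preserved.
#' @export
cohort_subset <- function(x, sites = NULL, samples = NULL) {
  s <- sites %||% seq_len(n_sites(x))
  if (is.logical(s)) s <- which(s)
  j <- if (is.null(samples)) seq_len(n_samples(x))
       else if (is.character(samples)) {
         miss <- setdiff(samples, x$samples)
         if (length(miss)) stopf("unknown sample(s): %s", paste(miss, collapse = ", "))
         match(samples, x$samples)
       } else samples
  new_cohort(x$chrom[s], x$pos[s], x$ref[s], x$alt[s],
             x$a1[s, j, drop = FALSE], x$a2[s, j, drop = FALSE],
             x$phased[s, j, drop = FALSE], x$samples[j], x$qual[s])
}

# sites x samples matrix of alternate-allele dosage (0/1/2, NA = missing)
geno_dosage <- function(x, samples = NULL) {
  j <- if (is.null(samples)) seq_len(n_samples(x)) else match(samples, x$samples)
  x$a1[, j, drop = FALSE] + x$a2[, j, drop = FALSE]
}

# per-site alternate-allele frequency over a sample subset; NA where no calls.
# Missing genotypes are excluded from the denominator.
alt_freq <- function(x, samples = NULL) {
  d <- geno_dosage(x, samples)
  nn <- 2L * rowSums(!is.na(d))
  ifelse(nn > 0, rowSums(d, na.rm = TRUE) / nn, NA_real_)
}

#' Sample-to-population map
#'
#' Associates each sample with exactly one population label and a role,
#' either `"ingroup"` or `"outgroup"` (outgroups anchor polarization and are
#' excluded from ingroup summaries).
#'
#' @param sample character vector of sample names.
#' @param population character vector of population labels.
#' @param role `"ingroup"` or `"outgroup"` per sample (recycled).
#' @return A `population_map` data frame.
#' @export
population_map <- function(sample, population, role = "ingroup") {
  pm <- data.frame(sample = as.character(sample),
                   population = as.character(population),
                   role = rep_len(as.character(role), length(sample)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(pm$sample)) stopf("duplicated sample in population map")
  if (!all(pm$role %in% c("ingroup", "outgroup")))
    stopf("role must be 'ingroup' or 'outgroup'")
  both <- intersect(pm$population[pm$role == "ingroup"],
                    pm$population[pm$role == "outgroup"])
  if (length(both))
    stopf("population label(s) used as both ingroup and outgroup: %s",
          paste(both, collapse = ", "))
  class(pm) <- c("population_map", "data.frame")
  pm
}

#' Read a population map from TSV
#'
#' Expected columns: `sample<TAB>population[<TAB>role]` with role in
#' `{ingroup, outgroup}` (defaults to ingroup).
#' @param path path to a TSV file without header.
#' @return A [population_map()].
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) stopf("population map not found: %s", path)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2) stopf("population map needs at least 2 columns")
  role <- if (ncol(tab) >= 3) tab[[3]] else "ingroup"
  population_map(tab[[1]], tab[[2]], role)
}

#' Write a population map to TSV
#' @param popmap a [population_map()].
#' @param path output path.
#' @export
write_popmap <- function(popmap, path) {
  write.table(popmap, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# samples belonging to `spec`: a population label, or explicit sample names
resolve_samples <- function(popmap, spec) {
  if (all(spec %in% popmap$population))
    return(popmap$sample[popmap$population %in% spec])
  unknown <- setdiff(spec, popmap$sample)
  if (length(unknown))
    stopf("not a population label or sample id: %s", paste(unknown, collapse = ", "))
  spec
}

#' Recombination map
#'
#' Non-overlapping half-open genomic windows, each with a local recombination
#' rate in cM/Mb; the genome-wide mean is the length-weighted mean of window
#' rates.
#'
#' @param chrom,start,end window coordinates (0-based half-open).
#' @param rate window recombination rate, cM/Mb, non-negative.
#' @return A `recomb_map` data frame with attribute `genome_mean_rate`.
#' @export
recomb_map <- function(chrom, start, end, rate) {
  rm <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), rate = as.numeric(rate),
                   stringsAsFactors = FALSE)
  if (any(rm$end <= rm$start)) stopf("recombination windows must have end > start")
  if (any(rm$rate < 0)) stopf("negative recombination rate")
  rm <- rm[order(rm$chrom, rm$start), ]
  for (ch in unique(rm$chrom)) {
    w <- rm[rm$chrom == ch, ]
    if (nrow(w) > 1L && any(w$start[-1] < w$end[-nrow(w)]))
      stopf("overlapping recombination windows on chromosome %s", ch)
  }
  len <- rm$end - rm$start
  attr(rm, "genome_mean_rate") <- sum(rm$rate * len) / sum(len)
  class(rm) <- c("recomb_map", "data.frame")
  rm
}

#' Read a recombination map (BED4: chrom, start, end, cM/Mb)
#' @param path BED-like TSV, 0-based half-open.
#' @return A [recomb_map()].
#' @export
read_recomb_map <- function(path) {
  if (!file.exists(path)) stopf("recombination map not found: %s", path)
  tab <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(tab) < 4) stopf("recombination map needs 4 columns: chrom start end cM_per_Mb")
  recomb_map(tab[[1]], tab[[2]], tab[[3]], tab[[4]])
}

#' Genome-wide mean recombination rate of a map
#' @param map a [recomb_map()].
#' @return length-weighted mean rate in cM/Mb.
#' @export
genome_mean_rate <- function(map) attr(map, "genome_mean_rate")

#' Site filter specification
#'
#' Genotype-level filters applied jointly by [filter_sites()]. Read-depth
#' style filters of variant-calling pipelines are represented here by the
#' site-quality and missingness knobs.
#'
#' @param min_site_quality minimum site quality (sites with unknown quality
#'   pass).
#' @param max_missing_fraction maximum fraction of samples with a missing
#'   call (0 = no missing data allowed).
#' @param min_minor_allele_count minimum count of the rarer allele among
#'   non-missing calls.
#' @param biallelic_only kept for interface symmetry; cohorts are biallelic
#'   by construction.
#' @param hwe_het_excess_p optional p-value threshold for a one-sided exact
#'   Hardy-Weinberg test against heterozygote excess; sites with
#'   p < threshold are removed. `NA` disables the test.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(min_site_quality = 0, max_missing_fraction = 1,
                        min_minor_allele_count = 0, biallelic_only = TRUE,
                        hwe_het_excess_p = NA) {
  if (max_missing_fraction < 0 || max_missing_fraction > 1)
    stopf("max_missing_fraction must be in [0, 1]")
  if (min_minor_allele_count < 0 || min_site_quality < 0)
    stopf("filter thresholds must be non-negative")
  structure(list(min_site_quality = min_site_quality,
                 max_missing_fraction = max_missing_fraction,
                 min_minor_allele_count = min_minor_allele_count,
                 biallelic_only = isTRUE(biallelic_only),
                 hwe_het_excess_p = hwe_het_excess_p),
            class = "filter_spec")
}

# one-sided exact HWE test for heterozygote excess at a single site
hwe_het_excess_pval <- function(n_het, n_hom_alt, n_hom_ref) {
  n <- n_het + n_hom_alt + n_hom_ref
  n_alt <- n_het + 2L * n_hom_alt
  if (n == 0L || n_alt == 0L || n_alt == 2L * n) return(1)
  hets <- seq.int(n_alt %% 2L, min(n_alt, 2L * n - n_alt), by = 2L)
  logp <- vapply(hets, function(h) {
    ha <- (n_alt - h) / 2
    lchoose(n, h) + lchoose(n - h, ha) + h * log(2) -
      lchoose(2 * n, n_alt)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  sum(p[hets >= n_het])
}

#' Filter cohort sites
#'
#' Returns a new cohort containing exactly the sites that pass every
#' criterion of `spec`; the input is unchanged and site/sample order is
#' preserved. The number of sites removed by each criterion (applied
#' site-wise, not sequentially) is attached as attribute `"filter_log"`.
#'
#' @param cohort a [new_cohort()].
#' @param spec a [filter_spec()].
#' @return The filtered `cohort` (possibly empty, with a warning).
#' @export
filter_sites <- function(cohort, spec = filter_spec()) {
  stopifnot(inherits(cohort, "cohort"), inherits(spec, "filter_spec"))
  d <- geno_dosage(cohort)
  miss_frac <- rowMeans(is.na(d))
  nn <- 2L * rowSums(!is.na(d))
  n_alt <- rowSums(d, na.rm = TRUE)
  mac <- pmin(n_alt, nn - n_alt)

  fail_qual <- !is.na(cohort$qual) & cohort$qual < spec$min_site_quality
  fail_miss <- miss_frac > spec$max_missing_fraction + 1e-12
  fail_mac <- mac < spec$min_minor_allele_count
  fail_hwe <- rep(FALSE, n_sites(cohort))
  if (!is.na(spec$hwe_het_excess_p)) {
    n_het <- rowSums(d == 1L, na.rm = TRUE)
    n_ha <- rowSums(d == 2L, na.rm = TRUE)
    n_hr <- rowSums(d == 0L, na.rm = TRUE)
    pv <- mapply(hwe_het_excess_pval, n_het, n_ha, n_hr)
    fail_hwe <- pv < spec$hwe_het_excess_p
  }
  keep <- !(fail_qual | fail_miss | fail_mac | fail_hwe)
  out <- cohort_subset(cohort, sites = keep)
  attr(out, "filter_log") <- c(site_quality = sum(fail_qual),
                               missingness = sum(fail_miss),
                               minor_allele_count = sum(fail_mac),
                               hwe_het_excess = sum(fail_hwe))
  if (!any(keep)) warnf("no sites pass the filter specification")
  out
}
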