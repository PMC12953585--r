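#' HMM parameters for ROH detection
#'
#' Two-state hidden Markov model over an individual's genotype calls:
#' state AZ (autozygous) emits heterozygotes only at the error rate
#' `het_emission_in_roh`; state HW (Hardy-Weinberg) emits heterozygotes at
#' `2 f (1 - f)` with `f = default_alt_freq` (the fixed alternate-allele
#' frequency of bcftools/RoH's default setting).
#'
#' @param default_alt_freq fixed alternate-allele frequency for the HW
#'   state (default 0.4).
#' @param het_emission_in_roh heterozygote emission probability inside an
#'   autozygous tract (genotyping-error rate).
#' @param transition per-site probability of switching state. The default
#'   1e-5 keeps the posterior phred ceiling well above the quality-80
#'   segment filter, so clean autozygous tracts are not rejected by their
#'   own transition noise.
#' @param min_length minimum reported segment length in bp (default 100 kb).
#' @param min_quality minimum segment quality (default 80).
#' @return An `hmm_params` object.
#' @export
hmm_params <- function(default_alt_freq = 0.4, het_emission_in_roh = 1e-4,
                       transition = 1e-5, min_length = 1e5,
                       min_quality = 80) {
  probs <- c(default_alt_freq, het_emission_in_roh, transition)
  if (any(probs <= 0 | probs >= 1)) stopf("probabilities must be in (0, 1)")
  structure(list(default_alt_freq = default_alt_freq,
                 het_emission_in_roh = het_emission_in_roh,
                 transition = transition, min_length = min_length,
                 min_quality = min_quality), class = "hmm_params")
}

# scaled forward-backward posterior of state AZ given het/hom observations
roh_posterior <- function(het, p_az, p_hw, trans) {
  n <- length(het)
  e_az <- ifelse(het, p_az, 1 - p_az)
  e_hw <- ifelse(het, p_hw, 1 - p_hw)
  fa <- numeric(n); fh <- numeric(n); scale <- numeric(n)
  fa[1] <- 0.5 * e_az[1]; fh[1] <- 0.5 * e_hw[1]
  scale[1] <- fa[1] + fh[1]; fa[1] <- fa[1] / scale[1]; fh[1] <- fh[1] / scale[1]
  for (i in 2:n) {
    t1 <- trans[i - 1]
    fa[i] <- (fa[i - 1] * (1 - t1) + fh[i - 1] * t1) * e_az[i]
    fh[i] <- (fh[i - 1] * (1 - t1) + fa[i - 1] * t1) * e_hw[i]
    scale[i] <- fa[i] + fh[i]
    fa[i] <- fa[i] / scale[i]; fh[i] <- fh[i] / scale[i]
  }
  ba <- numeric(n); bh <- numeric(n)
  ba[n] <- 1; bh[n] <- 1
  for (i in (n - 1):1) {
    t1 <- trans[i]
    ba[i] <- ((1 - t1) * e_az[i + 1] * ba[i + 1] + t1 * e_hw[i + 1] * bh[i + 1]) /
      scale[i + 1]
    bh[i] <- ((1 - t1) * e_hw[i + 1] * bh[i + 1] + t1 * e_az[i + 1] * ba[i + 1]) /
      scale[i + 1]
  }
  pa <- fa * ba; ph <- fh * bh
  pa / (pa + ph)
}

#' Detect runs of homozygosity in one individual
#'
#' Runs the two-state AZ/HW hidden Markov model over the individual's
#' non-missing biallelic calls per chromosome, computes forward-backward
#' posteriors, and reports maximal runs of sites with AZ posterior > 0.5.
#' Segment boundaries are extended to the midpoint between the run's end
#' sites and their flanking sites (or to the chromosome's terminal sites).
#' Segment quality is the mean per-site phred score of the AZ posterior
#' (capped at 99 per site); segments shorter than `min_length` or below
#' `min_quality` are removed.
#'
#' When a recombination map is supplied, the per-site transition probability
#' is scaled by the genetic distance between adjacent sites relative to the
#' genome-wide mean, honouring recombination-rate variation.
#'
#' @param cohort a [new_cohort()].
#' @param individual sample name.
#' @param params an [hmm_params()].
#' @param map optional [recomb_map()].
#' @return A `roh_segments` data frame: `chrom`, `start`, `end`, `length`,
#'   `n_sites`, `quality`.
#' @export
detect_roh <- function(cohort, individual, params = hmm_params(),
                       map = NULL) {
  j <- match(individual, cohort$samples)
  if (is.na(j)) stopf("individual not found: %s", individual)
  f <- params$default_alt_freq
  p_hw <- 2 * f * (1 - f)
  p_az <- params$het_emission_in_roh
  segs <- list()
  any_sites <- FALSE
  for (ch in unique(cohort$chrom)) {
    sel <- which(cohort$chrom == ch & !is.na(cohort$a1[, j]))
    if (length(sel) < 2L) next
    any_sites <- TRUE
    pos <- cohort$pos[sel]
    het <- cohort$a1[sel, j] != cohort$a2[sel, j]
    trans <- rep(params$transition, length(sel) - 1L)
    if (!is.null(map)) {
      d_bp <- diff(pos)
      mid <- floor((pos[-1] + pos[-length(pos)]) / 2)
      w <- map[map$chrom == ch, , drop = FALSE]
      idx <- findInterval(mid, w$start)
      rate <- ifelse(idx >= 1L & mid < w$end[pmax(idx, 1L)],
                     w$rate[pmax(idx, 1L)], 0)
      d_cm <- rate * d_bp / 1e6
      mean_cm <- mean(d_cm)
      if (mean_cm > 0)
        trans <- pmin(0.49, params$transition * d_cm / mean_cm)
    }
    post <- roh_posterior(het, p_az, p_hw, trans)
    az <- post > 0.5
    r <- rle(az)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      s_bp <- if (i0 == 1L) pos[1L] else (pos[i0 - 1L] + pos[i0]) %/% 2L + 1L
      e_bp <- if (i1 == length(pos)) pos[i1] + 1L
              else (pos[i1] + pos[i1 + 1L]) %/% 2L + 1L
      phred <- pmin(99, -10 * log10(pmax(1 - post[i0:i1], 1e-10)))
      segs[[length(segs) + 1L]] <-
        data.frame(chrom = ch, start = s_bp, end = e_bp,
                   length = e_bp - s_bp, n_sites = i1 - i0 + 1L,
                   quality = mean(phred), stringsAsFactors = FALSE)
    }
  }
  if (!any_sites) stopf("all sites missing for %s", individual)
  out <- do.call(rbind, segs) %||%
    data.frame(chrom = character(), start = integer(), end = integer(),
               length = integer(), n_sites = integer(), quality = numeric())
  out <- out[out$length >= params$min_length &
               out$quality >= params$min_quality, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("roh_segments", "data.frame")
  out
}

#' Bin ROH segments into the four canonical length classes
#'
#' Length bins: 0.1-1 Mb (short), 1-5 Mb (short-medium), 5-10 Mb
#' (medium-long) and 10-100 Mb (long). `F_ROH` is the summed segment length
#' divided by the genome length; segments over 100 Mb are excluded from the
#' bins (with a warning) but still count towards `F_ROH`.
#'
#' @param segments a [detect_roh()] result.
#' @param genome_length total genome length in bp.
#' @return A `roh_profile`: per-bin counts and total lengths, plus `F_ROH`.
#' @export
bin_roh <- function(segments, genome_length) {
  breaks_mb <- c(0.1, 1, 5, 10, 100)
  labels <- c("short", "short_medium", "medium_long", "long")
  len_mb <- segments$length / 1e6
  over <- len_mb > 100
  if (any(over))
    warnf("%d segment(s) over 100 Mb excluded from bins", sum(over))
  keep <- len_mb[!over & len_mb >= 0.1]
  bin <- cut(keep, breaks = breaks_mb, labels = labels, right = FALSE,
             include.lowest = TRUE)
  counts <- table(bin)
  totals <- tapply(keep, bin, sum, default = 0)
  structure(list(counts = setNames(as.integer(counts), labels),
                 total_mb = setNames(as.numeric(totals), labels),
                 n_segments = nrow(segments),
                 total_length = sum(as.numeric(segments$length)),
                 F_ROH = sum(as.numeric(segments$length)) / genome_length,
                 genome_length = genome_length),
            class = "roh_profile")
}

#' @exportS3Method base::print
print.roh_profile <- function(x, ...) {
  cat(sprintf("ROH profile: %d segments, F_ROH = %.4f\n", x$n_segments, x$F_ROH))
  for (b in names(x$counts))
    cat(sprintf("  %-13s %3d segments, %8.2f Mb\n", b, x$counts[b],
                x$total_mb[b]))
  invisible(x)
}

#' Timing of inbreeding from ROH length
#'
#' Expected number of generations back to the inbreeding loop that produced
#' a run of homozygosity of length `L` Mb at recombination rate `r` cM/Mb:
#' `g = 100 / (2 r L)`. A 5 Mb ROH at the genome-wide wolf average of
#' 1.34 cM/Mb dates the inbreeding to ~7 generations ago. Assumes a uniform
#' recombination rate, so results are estimates.
#'
#' @param length_mb ROH length(s) in Mb (> 0).
#' @param rate_cM_per_Mb recombination rate (default 1.34 cM/Mb).
#' @param generation_time optional generation time in years; when given the
#'   result also carries the timing in years.
#' @return Numeric vector of generations; if `generation_time` is supplied,
#'   a data frame with columns `generations` and `years`.
#' @export
inbreeding_time <- function(length_mb, rate_cM_per_Mb = 1.34,
                            generation_time = NULL) {
  if (any(length_mb <= 0) || any(rate_cM_per_Mb <= 0))
    stopf("length and rate must be positive")
  g <- 100 / (2 * rate_cM_per_Mb * length_mb)
  if (is.null(generation_time)) return(g)
  data.frame(generations = g, years = g * generation_time)
}
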