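#' Per-individual heterozygosity
#'
#' `H = n_het / n_callable`, where `n_callable` counts sites with a
#' non-missing diploid call for the individual.
#'
#' @param cohort a [new_cohort()].
#' @param individual sample name.
#' @return list with `H`, `n_het`, `n_callable`.
#' @export
heterozygosity <- function(cohort, individual) {
  j <- match(individual, cohort$samples)
  if (is.na(j)) stopf("individual not found: %s", individual)
  callable <- !is.na(cohort$a1[, j])
  n_callable <- sum(callable)
  if (n_callable == 0L) stopf("no callable sites for %s", individual)
  n_het <- sum(cohort$a1[callable, j] != cohort$a2[callable, j])
  list(H = n_het / n_callable, n_het = n_het, n_callable = n_callable)
}

#' Per-individual inbreeding coefficient
#'
#' Moment estimator of the probability of identity by descent:
#' `F = 1 - observed heterozygous sites / expected heterozygous sites`,
#' where the expectation sums the unbiased estimator `2 p (1 - p) n/(n-1)`
#' over the individual's callable sites, with `p` the alternate-allele
#' frequency estimated from the `n` alleles of the *other* members of its
#' population (the focal individual is excluded to avoid self-bias at small
#' sample sizes; the `n/(n-1)` factor removes the downward bias of the
#' plug-in heterozygosity at small panels).
#'
#' @param cohort a [new_cohort()].
#' @param popmap a [population_map()].
#' @param individual sample name; its population needs at least 2 other
#'   members.
#' @return list with `F`, `observed_het`, `expected_het`.
#' @export
inbreeding_coefficient <- function(cohort, popmap, individual) {
  j <- match(individual, cohort$samples)
  if (is.na(j)) stopf("individual not found: %s", individual)
  pop <- popmap$population[match(individual, popmap$sample)]
  others <- setdiff(popmap$sample[popmap$population == pop], individual)
  others <- intersect(others, cohort$samples)
  if (length(others) < 2L)
    stopf("population %s needs at least 2 members besides %s", pop, individual)
  d <- geno_dosage(cohort, others)
  nn <- 2 * rowSums(!is.na(d))
  p <- ifelse(nn > 0, rowSums(d, na.rm = TRUE) / nn, NA_real_)
  callable <- !is.na(cohort$a1[, j]) & !is.na(p) & nn >= 2
  obs <- sum(cohort$a1[callable, j] != cohort$a2[callable, j])
  expd <- sum(2 * p[callable] * (1 - p[callable]) *
                nn[callable] / (nn[callable] - 1))
  if (expd == 0) stopf("expected heterozygosity is zero")
  list(F = 1 - obs / expd, observed_het = obs, expected_het = expd)
}

#' Genome-wide diversity report for every sample
#'
#' One row per sample with heterozygosity and, where the population has
#' enough members, the inbreeding coefficient (`NA` otherwise).
#'
#' @param cohort a [new_cohort()].
#' @param popmap a [population_map()].
#' @return A `diversity_report` data frame: `sample`, `population`,
#'   `n_het`, `n_callable`, `H`, `F`.
#' @export
diversity_report <- function(cohort, popmap) {
  rows <- lapply(cohort$samples, function(s) {
    h <- heterozygosity(cohort, s)
    pop <- popmap$population[match(s, popmap$sample)]
    Fv <- tryCatch(inbreeding_coefficient(cohort, popmap, s)$F,
                   error = function(e) NA_real_)
    data.frame(sample = s, population = pop, n_het = h$n_het,
               n_callable = h$n_callable, H = h$H, F = Fv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diversity_report", "data.frame")
  out
}
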