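#' Two-outgroup polarization of cohort sites
#'
#' Each outgroup is reduced to a single pseudo-haploid allele per site: one
#' allele drawn uniformly (seeded) from the outgroup's pooled non-missing
#' calls (a homozygous single-sample outgroup simply contributes that
#' allele); sites where either outgroup has no call are dropped. A site is
#' retained only when the two pseudo-haploid alleles agree; the agreed
#' allele is ancestral and the other cohort allele derived, assumed to be
#' the deleterious one at annotated sites. Retained sites are joined with
#' their impact annotation and per-sample derived-allele dosages.
#'
#' @param cohort a [new_cohort()].
#' @param outgroup1,outgroup2 population label (or sample vector) of each
#'   outgroup.
#' @param annotation an [assign_impact_annotations()] table covering the
#'   retained sites.
#' @param popmap a [population_map()] used to resolve outgroup labels.
#' @param seed integer seed for the pseudo-haploid draws.
#' @return A `polarized_sites` object: data frame `sites` (`chrom`, `pos`,
#'   `ancestral`, `derived`, `impact`), matrix `dosage` (sites x ingroup
#'   samples, entries 0/1/2/NA), and a `drop_log`.
#' @export
polarize_sites <- function(cohort, outgroup1, outgroup2, annotation, popmap,
                           seed = 1L) {
  og1 <- resolve_samples(popmap, outgroup1)
  og2 <- resolve_samples(popmap, outgroup2)
  for (s in list(og1, og2))
    if (!length(intersect(s, cohort$samples))) stopf("outgroup absent from cohort")
  og1 <- intersect(og1, cohort$samples); og2 <- intersect(og2, cohort$samples)
  ingroup <- setdiff(cohort$samples, c(og1, og2))

  pseudo_haploid <- function(samples) {
    d <- geno_dosage(cohort, samples)
    n_alt <- rowSums(d, na.rm = TRUE)
    nn <- 2L * rowSums(!is.na(d))
    # one allele drawn uniformly from the pooled non-missing alleles
    draw <- runif(length(nn))
    ifelse(nn == 0L, NA_integer_, as.integer(draw < n_alt / nn))
  }
  ph <- with_seed(seed, list(pseudo_haploid(og1), pseudo_haploid(og2)))
  missing_og <- is.na(ph[[1]]) | is.na(ph[[2]])
  disagree <- !missing_og & ph[[1]] != ph[[2]]
  keep <- which(!missing_og & !disagree)

  key <- paste(cohort$chrom[keep], cohort$pos[keep])
  akey <- paste(annotation$chrom, annotation$pos)
  hit <- match(key, akey)
  if (anyNA(hit))
    stopf("%d retained site(s) lack an impact annotation", sum(is.na(hit)))

  anc_is_alt <- ph[[1]][keep] == 1L
  d <- geno_dosage(cohort, ingroup)[keep, , drop = FALSE]
  dosage <- d
  dosage[anc_is_alt, ] <- 2L - d[anc_is_alt, , drop = FALSE]
  dimnames(dosage) <- list(NULL, ingroup)
  sites <- data.frame(chrom = cohort$chrom[keep], pos = cohort$pos[keep],
                      ancestral = ifelse(anc_is_alt, cohort$alt[keep],
                                         cohort$ref[keep]),
                      derived = ifelse(anc_is_alt, cohort$ref[keep],
                                       cohort$alt[keep]),
                      impact = annotation$impact[hit],
                      stringsAsFactors = FALSE)
  structure(list(sites = sites, dosage = dosage,
                 drop_log = c(outgroup_missing = sum(missing_og),
                              outgroup_disagree = sum(disagree))),
            class = "polarized_sites")
}

#' @exportS3Method base::print
print.polarized_sites <- function(x, ...) {
  cat(sprintf("polarized sites: %d retained, %d samples (dropped: %d missing-outgroup, %d disagreeing)\n",
              nrow(x$sites), ncol(x$dosage),
              x$drop_log["outgroup_missing"], x$drop_log["outgroup_disagree"]))
  invisible(x)
}

#' Genetic-load accounting for one individual
#'
#' Counts derived alleles by impact category and derives the three load
#' summaries over HIGH + MODERATE sites: total load (all derived alleles),
#' realized load (derived alleles in homozygous state) and masked load
#' (derived alleles in heterozygous state), so that
#' `total = realized + masked` holds exactly. Missing genotypes contribute
#' nothing. Normalized rates divide each category's derived-allele count by
#' the MODIFIER (putatively neutral) count and multiply by 100,000; they are
#' `NA` (flagged) when the individual carries no derived MODIFIER alleles.
#'
#' With `units = "alleles"` (default) a homozygous-derived site contributes
#' 2 and a heterozygous site 1; with `units = "sites"` each qualifying site
#' contributes 1 (total = sites carrying any derived allele).
#'
#' @param polarized a [polarize_sites()] result.
#' @param individual sample name.
#' @param units `"alleles"` or `"sites"`.
#' @return A `load_report` list.
#' @export
count_load <- function(polarized, individual, units = c("alleles", "sites")) {
  units <- match.arg(units)
  j <- match(individual, colnames(polarized$dosage))
  if (is.na(j)) stopf("individual not found: %s", individual)
  dos <- polarized$dosage[, j]
  imp <- polarized$sites$impact
  cats <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
  derived_count <- vapply(cats, function(cc)
    sum(dos[imp == cc], na.rm = TRUE), numeric(1))
  del <- imp %in% c("HIGH", "MODERATE")
  if (units == "alleles") {
    realized <- 2 * sum(dos[del] == 2L, na.rm = TRUE)
    masked <- sum(dos[del] == 1L, na.rm = TRUE)
  } else {
    realized <- sum(dos[del] == 2L, na.rm = TRUE)
    masked <- sum(dos[del] == 1L, na.rm = TRUE)
  }
  total <- realized + masked
  modifier <- derived_count[["MODIFIER"]]
  normalized <- if (modifier > 0) derived_count / modifier * 1e5
                else setNames(rep(NA_real_, 4L), cats)
  structure(list(individual = individual, units = units,
                 total_load = total, realized_load = realized,
                 masked_load = masked, derived_count = derived_count,
                 normalized_per_1e5_neutral = normalized,
                 modifier_undefined = modifier == 0),
            class = "load_report")
}

#' @exportS3Method base::print
print.load_report <- function(x, ...) {
  cat(sprintf("genetic load for %s (%s): total %g = realized %g + masked %g\n",
              x$individual, x$units, x$total_load, x$realized_load,
              x$masked_load))
  cat(sprintf("  derived counts: HIGH %g, MODERATE %g, LOW %g, MODIFIER %g\n",
              x$derived_count[["HIGH"]], x$derived_count[["MODERATE"]],
              x$derived_count[["LOW"]], x$derived_count[["MODIFIER"]]))
  invisible(x)
}

#' Load table for all individuals
#'
#' @param polarized a [polarize_sites()] result.
#' @param units see [count_load()].
#' @return data frame with one row per individual.
#' @export
load_table <- function(polarized, units = "alleles") {
  rows <- lapply(colnames(polarized$dosage), function(s) {
    r <- count_load(polarized, s, units)
    data.frame(sample = s, total_load = r$total_load,
               realized_load = r$realized_load, masked_load = r$masked_load,
               high = r$derived_count[["HIGH"]],
               moderate = r$derived_count[["MODERATE"]],
               low = r$derived_count[["LOW"]],
               modifier = r$derived_count[["MODIFIER"]],
               norm_load = r$normalized_per_1e5_neutral[["HIGH"]] +
                 r$normalized_per_1e5_neutral[["MODERATE"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare load metrics between populations
#'
#' Per-population mean and standard deviation of each load metric, with the
#' populations ranked by mean (1 = highest). Populations without any
#' individual in the table are excluded with a warning.
#'
#' @param loads a [load_table()] data frame.
#' @param popmap a [population_map()].
#' @return A `load_comparison` object.
#' @export
compare_populations <- function(loads, popmap) {
  pop <- popmap$population[match(loads$sample, popmap$sample)]
  pops <- unique(popmap$population[popmap$role == "ingroup"])
  empty <- setdiff(pops, pop)
  if (length(empty))
    warnf("population(s) with no individuals excluded: %s",
          paste(empty, collapse = ", "))
  pops <- intersect(pops, pop)
  if (length(pops) < 2L) stopf("need at least 2 populations with individuals")
  metrics <- c("total_load", "realized_load", "masked_load")
  stats <- lapply(metrics, function(m) {
    mu <- vapply(pops, function(p) mean(loads[[m]][pop == p]), numeric(1))
    dv <- vapply(pops, function(p) sd(loads[[m]][pop == p]), numeric(1))
    data.frame(population = pops, mean = mu, sd = dv,
               rank = rank(-mu, ties.method = "min"), metric = m,
               stringsAsFactors = FALSE)
  })
  structure(list(summary = do.call(rbind, stats), populations = pops),
            class = "load_comparison")
}

#' @exportS3Method base::print
print.load_comparison <- function(x, ...) {
  cat("population genetic-load comparison\n")
  for (m in unique(x$summary$metric)) {
    s <- x$summary[x$summary$metric == m, ]
    s <- s[order(s$rank), ]
    cat(sprintf("  %s: %s\n", m,
                paste(sprintf("%s %.1f", s$population, s$mean),
                      collapse = " > ")))
  }
  invisible(x)
}
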