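#' Simulate a phased diploid cohort under a demographic model
#'
#' Draws coalescent genealogies and infinite-sites mutations for a genome of
#' `chromosome_count` equal chromosomes. Recombination is approximated by
#' partitioning each chromosome into fixed-length blocks with free
#' recombination between blocks and none within, so each block carries a
#' single genealogy — the same independence structure the downstream
#' window-based analyses assume. The reference allele is the ancestral
#' state, the alternate allele the derived one.
#'
#' @param model a [demographic_model()].
#' @param samples_per_pop named integer vector: diploid samples per
#'   population (0 omits a population); unnamed scalar = same count for all.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @param missing_rate fraction of genotype calls set to missing at random.
#' @param block_bp length of the non-recombining blocks (bp).
#' @return A list with elements `cohort`, `popmap` and `truth` (a
#'   `truth_record` holding the model, seed, per-individual admixture
#'   expectations and planted ROH tracts).
#' @export
simulate_cohort <- function(model, samples_per_pop = 4L, seed = 1L,
                            missing_rate = 0, block_bp = 25000) {
  stopifnot(inherits(model, "demographic_model"))
  if (model$sequence_length <= 0) stopf("zero-length sequence")
  pops <- model$populations$name
  if (is.null(names(samples_per_pop))) {
    if (length(samples_per_pop) != 1L)
      stopf("samples_per_pop must be named or a single count")
    samples_per_pop <- setNames(rep(as.integer(samples_per_pop),
                                    length(pops)), pops)
  }
  unknown <- setdiff(names(samples_per_pop), pops)
  if (length(unknown))
    stopf("unknown population: %s", paste(unknown, collapse = ", "))
  nd <- setNames(rep(0L, length(pops)), pops)
  nd[names(samples_per_pop)] <- as.integer(samples_per_pop)
  if (sum(nd) < 1L) stopf("at least one sample is required")

  events <- compile_events(model)
  nhap <- 2L * nd
  sample_ids <- unlist(lapply(pops[nd > 0], function(p)
    paste0(p, "_", seq_len(nd[[p]]))), use.names = FALSE)
  sample_pop <- rep(pops[nd > 0], nd[nd > 0])

  with_seed(seed, {
    chroms <- paste0("chr", seq_len(model$chromosome_count))
    per_chr <- lapply(chroms, function(ch) {
      n_full <- floor(model$sequence_length / block_bp)
      rem <- model$sequence_length - n_full * block_bp
      loci <- .sim_haplotypes_cpp(nhap, model$populations$size, events,
                                  model$mutation_rate, block_bp, n_full)
      if (rem > 0)
        loci <- c(loci, .sim_haplotypes_cpp(nhap, model$populations$size,
                                            events, model$mutation_rate,
                                            rem, 1L))
      pos <- integer(0); hap <- NULL
      for (b in seq_along(loci)) {
        p <- as.integer(floor(loci[[b]]$pos)) + (b - 1L) * as.integer(block_bp)
        g <- loci[[b]]$geno
        if (length(p)) { pos <- c(pos, p); hap <- rbind(hap, g) }
      }
      # enforce strictly increasing integer positions after flooring
      if (length(pos) > 1L) {
        for (i in 2:length(pos)) if (pos[i] <= pos[i - 1L])
          pos[i] <- pos[i - 1L] + 1L
      }
      list(chrom = rep(ch, length(pos)), pos = pos, hap = hap)
    })
    pos <- unlist(lapply(per_chr, `[[`, "pos"))
    chrom <- unlist(lapply(per_chr, `[[`, "chrom"))
    hap <- do.call(rbind, lapply(per_chr, `[[`, "hap"))
    ns <- length(pos)
    if (ns == 0L) stopf("simulation produced no segregating sites")

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, ns, replace = TRUE)
    alt <- bases[(match(ref, bases) + sample(1:3, ns, replace = TRUE) - 1L) %% 4L + 1L]
    a1 <- hap[, seq(1L, ncol(hap), by = 2L), drop = FALSE]
    a2 <- hap[, seq(2L, ncol(hap), by = 2L), drop = FALSE]
    if (missing_rate > 0) {
      mk <- matrix(runif(ns * ncol(a1)) < missing_rate, ns, ncol(a1))
      a1[mk] <- NA_integer_; a2[mk] <- NA_integer_
    }
    cohort <- new_cohort(chrom, pos, ref, alt, a1, a2, phased = TRUE,
                         samples = sample_ids,
                         qual = rep(100, ns))
  })

  role <- ifelse(sample_pop %in% model$outgroups, "outgroup", "ingroup")
  popmap <- population_map(sample_ids, sample_pop, role)

  admix_frac <- setNames(rep(0, length(sample_ids)), sample_ids)
  if (!is.null(model$admixture) && nrow(model$admixture))
    for (i in seq_len(nrow(model$admixture)))
      admix_frac[sample_pop == model$admixture$dest[i]] <-
        admix_frac[sample_pop == model$admixture$dest[i]] + model$admixture$prop[i]
  truth <- structure(list(model = model, seed = seed,
                          samples_per_pop = nd,
                          admixture_fraction = admix_frac,
                          roh_tracts = data.frame(individual = character(),
                                                  chrom = character(),
                                                  start = integer(),
                                                  end = integer())),
                     class = "truth_record")
  list(cohort = cohort, popmap = popmap, truth = truth)
}

#' @exportS3Method base::print
print.truth_record <- function(x, ...) {
  cat(sprintf("truth record: seed %s, %d samples, %d planted ROH tract(s)\n",
              format(x$seed), sum(x$samples_per_pop), nrow(x$roh_tracts)))
  invisible(x)
}

#' Simulate method for demographic models
#'
#' Thin wrapper so a model can be used with the standard [stats::simulate()]
#' generic; each replicate is one [simulate_cohort()] result.
#'
#' @param object a [demographic_model()].
#' @param nsim number of cohorts.
#' @param seed integer seed for the first replicate (incremented per
#'   replicate).
#' @param ... passed to [simulate_cohort()].
#' @return A list of `nsim` simulation results.
#' @export
simulate.demographic_model <- function(object, nsim = 1, seed = 1L, ...) {
  lapply(seq_len(nsim), function(i)
    simulate_cohort(object, seed = derive_seed(seed, i - 1L), ...))
}

#' Plant autozygous tracts into an individual
#'
#' Within each tract every heterozygous call of the individual is forced
#' homozygous, picking one of its two alleles uniformly at random (seeded);
#' genotypes outside the tracts, missing calls, and all other individuals
#' are untouched. Used as ground truth for the ROH caller.
#'
#' @param cohort a [new_cohort()].
#' @param individual sample name.
#' @param tracts data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open, non-overlapping).
#' @param truth optional `truth_record` to append the tracts to.
#' @param seed integer seed.
#' @return list with elements `cohort` and `truth`.
#' @export
plant_roh <- function(cohort, individual, tracts, truth = NULL, seed = 1L) {
  j <- match(individual, cohort$samples)
  if (is.na(j)) stopf("individual not found: %s", individual)
  if (nrow(tracts)) {
    if (any(tracts$end <= tracts$start)) stopf("tracts must have end > start")
    o <- order(tracts$chrom, tracts$start)
    tt <- tracts[o, ]
    same <- tt$chrom[-1] == tt$chrom[-nrow(tt)]
    if (nrow(tt) > 1 && any(same & tt$start[-1] < tt$end[-nrow(tt)]))
      stopf("overlapping tracts")
  }
  with_seed(seed, {
    for (i in seq_len(nrow(tracts))) {
      inside <- cohort$chrom == tracts$chrom[i] &
        cohort$pos >= tracts$start[i] & cohort$pos < tracts$end[i]
      het <- inside & !is.na(cohort$a1[, j]) & cohort$a1[, j] != cohort$a2[, j]
      if (any(het)) {
        pick <- runif(sum(het)) < 0.5
        chosen <- ifelse(pick, cohort$a1[het, j], cohort$a2[het, j])
        cohort$a1[het, j] <- chosen
        cohort$a2[het, j] <- chosen
      }
    }
  })
  if (is.null(truth))
    truth <- structure(list(model = NULL, seed = seed, samples_per_pop = NULL,
                            admixture_fraction = NULL,
                            roh_tracts = data.frame(individual = character(),
                                                    chrom = character(),
                                                    start = integer(),
                                                    end = integer())),
                       class = "truth_record")
  if (nrow(tracts))
    truth$roh_tracts <- rbind(truth$roh_tracts,
                              data.frame(individual = individual,
                                         chrom = tracts$chrom,
                                         start = tracts$start,
                                         end = tracts$end))
  list(cohort = cohort, truth = truth)
}

#' Assign variant-impact annotations to cohort sites
#'
#' Stands in for a variant-effect predictor: each site receives one impact
#' category (`HIGH` = loss-of-function, `MODERATE` = missense, `LOW` =
#' synonymous, `MODIFIER` = non-coding, assumed neutral) by a seeded
#' multinomial draw at the given proportions.
#'
#' @param cohort a [new_cohort()].
#' @param proportions named numeric vector over
#'   `c("HIGH","MODERATE","LOW","MODIFIER")`, summing to 1 (tolerance 1e-9).
#' @param seed integer seed.
#' @return An `annotation_table` data frame with columns `chrom`, `pos`,
#'   `impact`.
#' @export
assign_impact_annotations <- function(cohort,
                                      proportions = c(HIGH = 0.001,
                                                      MODERATE = 0.01,
                                                      LOW = 0.05,
                                                      MODIFIER = 0.939),
                                      seed = 1L) {
  cats <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
  if (!setequal(names(proportions), cats))
    stopf("proportions must be named HIGH, MODERATE, LOW, MODIFIER")
  proportions <- proportions[cats]
  if (abs(sum(proportions) - 1) > 1e-9)
    stopf("proportions must sum to 1 (got %.12f)", sum(proportions))
  impact <- with_seed(seed,
    sample(cats, n_sites(cohort), replace = TRUE, prob = proportions))
  structure(data.frame(chrom = cohort$chrom, pos = cohort$pos,
                       impact = impact, stringsAsFactors = FALSE),
            class = c("annotation_table", "data.frame"))
}

#' Write / read an annotation table (TSV: chrom pos impact)
#' @param annotation an `annotation_table`.
#' @param path file path.
#' @return the table (read) or the path (write), invisibly.
#' @export
write_annotations <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "pos", "impact"))
  if (!all(tab$impact %in% c("HIGH", "MODERATE", "LOW", "MODIFIER")))
    stopf("invalid impact category in %s", path)
  structure(tab, class = c("annotation_table", "data.frame"))
}
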