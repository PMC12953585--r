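#' Demographic model for coalescent cohort simulation
#'
#' Describes a set of populations with diploid effective sizes, population
#' splits, pulse admixture events and optional size changes, together with
#' the mutation and recombination rates, a generation time and the genome
#' layout (equal-length chromosomes). Times are in generations before
#' present.
#'
#' Forward-in-time semantics: a split `(time, derived, ancestral)` means the
#' derived population originated from the ancestral one at `time`; an
#' admixture event `(time, source, dest, prop)` means a fraction `prop` of
#' the destination population's ancestry was replaced by source-population
#' migrants at `time`.
#'
#' @param populations data frame with columns `name` and `size` (diploid
#'   effective size).
#' @param splits data frame with columns `time`, `derived`, `ancestral`.
#' @param admixture data frame with columns `time`, `source`, `dest`,
#'   `prop`, or `NULL`.
#' @param size_changes data frame with columns `time`, `pop`, `size`
#'   (the population's diploid size *earlier* than `time`), or `NULL`.
#' @param mutation_rate per-bp per-generation mutation rate.
#' @param recombination_rate per-bp per-generation recombination rate.
#' @param generation_time generation time in years.
#' @param sequence_length chromosome length in bp.
#' @param chromosome_count number of chromosomes.
#' @param outgroups character vector of population names acting as
#'   polarization outgroups.
#' @return A `demographic_model` object.
#' @seealso [default_wolf_model()], [simulate_cohort()]
#' @export
demographic_model <- function(populations, splits, admixture = NULL,
                              size_changes = NULL,
                              mutation_rate = 4.5e-9,
                              recombination_rate = 1.34e-8,
                              generation_time = 4.4,
                              sequence_length = 5e6,
                              chromosome_count = 10L,
                              outgroups = character()) {
  m <- structure(list(populations = populations, splits = splits,
                      admixture = admixture, size_changes = size_changes,
                      mutation_rate = mutation_rate,
                      recombination_rate = recombination_rate,
                      generation_time = generation_time,
                      sequence_length = sequence_length,
                      chromosome_count = as.integer(chromosome_count),
                      outgroups = outgroups),
                 class = "demographic_model")
  validate_model(m)
  m
}

validate_model <- function(m) {
  pops <- m$populations
  if (anyDuplicated(pops$name)) stopf("duplicated population name")
  if (any(pops$size <= 0)) stopf("population sizes must be positive")
  if (m$mutation_rate <= 0) stopf("mutation rate must be positive")
  known <- function(x) {
    bad <- setdiff(x, pops$name)
    if (length(bad)) stopf("unknown population: %s", paste(bad, collapse = ", "))
  }
  origin <- setNames(rep(Inf, nrow(pops)), pops$name)
  if (!is.null(m$splits) && nrow(m$splits)) {
    known(c(m$splits$derived, m$splits$ancestral))
    if (any(m$splits$time <= 0)) stopf("split times must be positive")
    if (anyDuplicated(m$splits$derived))
      stopf("a population can be derived in at most one split")
    origin[m$splits$derived] <- m$splits$time
    # ancestral population must still exist (not yet originated) at the split
    bad <- m$splits$time > origin[m$splits$ancestral]
    if (any(bad))
      stopf("split of %s predates origin of its ancestral population",
            paste(m$splits$derived[bad], collapse = ", "))
  }
  if (!is.null(m$admixture) && nrow(m$admixture)) {
    known(c(m$admixture$source, m$admixture$dest))
    if (any(m$admixture$prop <= 0 | m$admixture$prop >= 1))
      stopf("admixture proportion must be in (0, 1)")
    bad <- m$admixture$time >= pmin(origin[m$admixture$source],
                                    origin[m$admixture$dest])
    if (any(bad))
      stopf("admixture event predates the origin of an involved population")
  }
  if (!is.null(m$size_changes) && nrow(m$size_changes)) {
    known(m$size_changes$pop)
    if (any(m$size_changes$size <= 0)) stopf("sizes must be positive")
  }
  if (length(m$outgroups)) known(m$outgroups)
  invisible(m)
}

#' @exportS3Method base::print
print.demographic_model <- function(x, ...) {
  cat(sprintf("demographic model: %d populations, %d chromosomes x %g bp\n",
              nrow(x$populations), x$chromosome_count, x$sequence_length))
  cat(sprintf("  mu = %g /bp/gen, r = %g /bp/gen, generation = %g y\n",
              x$mutation_rate, x$recombination_rate, x$generation_time))
  for (i in seq_len(nrow(x$populations)))
    cat(sprintf("  %s: N = %g\n", x$populations$name[i], x$populations$size[i]))
  if (!is.null(x$splits))
    for (i in seq_len(nrow(x$splits)))
      cat(sprintf("  split: %s from %s at %.0f gen\n", x$splits$derived[i],
                  x$splits$ancestral[i], x$splits$time[i]))
  if (!is.null(x$admixture) && nrow(x$admixture))
    for (i in seq_len(nrow(x$admixture)))
      cat(sprintf("  admixture: %s -> %s, prop %.3f at %.0f gen\n",
                  x$admixture$source[i], x$admixture$dest[i],
                  x$admixture$prop[i], x$admixture$time[i]))
  invisible(x)
}

#' Default three-lineage wolf model
#'
#' The study system: three deeply diverged grey-wolf lineages (Indian,
#' Tibetan, Holarctic), a southwest-Asian population splitting recently from
#' the Holarctic/central-Asian stock, a pulse of Indian ancestry into
#' southwest Asia, and two long-diverged canid outgroups anchoring
#' polarization. Calibrations: Indian divergence ~100 kya, Tibetan ~80 kya,
#' SWAsia-Central split ~10.3 kya, introgression pulse of proportion 0.11 at
#' ~6 kya, mu = 4.5e-9 per bp per generation, generation time 4.4 years,
#' mean recombination 1.34 cM/Mb. Effective sizes are order-of-magnitude
#' defaults (small India/SWAsia, large Holarctic), exposed for overriding.
#'
#' @param sequence_length,chromosome_count genome layout (default 10 x 5 Mb,
#'   a desk-scale stand-in for a full genome).
#' @return A [demographic_model()].
#' @export
default_wolf_model <- function(sequence_length = 5e6, chromosome_count = 10L) {
  gen <- 4.4
  pops <- data.frame(
    name = c("Indian", "Tibetan", "Holarctic", "SWAsia", "Outgroup1", "Outgroup2"),
    size = c(3000, 3000, 20000, 5000, 20000, 20000),
    stringsAsFactors = FALSE)
  splits <- data.frame(
    time = c(10300 / gen, 80000 / gen, 100000 / gen, 2.5e6 / gen, 3e6 / gen),
    derived = c("SWAsia", "Tibetan", "Indian", "Outgroup1", "Outgroup2"),
    ancestral = c("Holarctic", "Holarctic", "Holarctic", "Holarctic", "Holarctic"),
    stringsAsFactors = FALSE)
  admix <- data.frame(time = 6000 / gen, source = "Indian", dest = "SWAsia",
                      prop = 0.11, stringsAsFactors = FALSE)
  demographic_model(pops, splits, admix,
                    mutation_rate = 4.5e-9, recombination_rate = 1.34e-8,
                    generation_time = gen,
                    sequence_length = sequence_length,
                    chromosome_count = chromosome_count,
                    outgroups = c("Outgroup1", "Outgroup2"))
}

# Compile a model into the event matrix consumed by the C++ engine.
# Backward in time: a split moves all lineages of the derived population into
# the ancestral one; an admixture pulse moves lineages of the destination
# into the source with probability prop; a size change resets a diploid size.
compile_events <- function(model) {
  idx <- setNames(seq_len(nrow(model$populations)) - 1L,
                  model$populations$name)
  ev <- matrix(numeric(0), ncol = 5)
  if (!is.null(model$admixture) && nrow(model$admixture))
    ev <- rbind(ev, cbind(model$admixture$time, 1,
                          idx[model$admixture$dest],
                          idx[model$admixture$source],
                          model$admixture$prop))
  if (!is.null(model$splits) && nrow(model$splits))
    ev <- rbind(ev, cbind(model$splits$time, 1,
                          idx[model$splits$derived],
                          idx[model$splits$ancestral], 1))
  if (!is.null(model$size_changes) && nrow(model$size_changes))
    ev <- rbind(ev, cbind(model$size_changes$time, 2,
                          idx[model$size_changes$pop], 0,
                          model$size_changes$size))
  ev[order(ev[, 1]), , drop = FALSE]
}
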