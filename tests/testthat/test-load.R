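# cohort with two single-sample outgroups and controllable outgroup calls
load_fixture <- function(n_ing = 3L, n_sites = 20L, seed = 1) {
  set.seed(seed)
  dos <- cbind(matrix(rbinom(n_sites * n_ing, 2, 0.4), n_sites, n_ing),
               O1 = rbinom(n_sites, 2, 0.1), O2 = rbinom(n_sites, 2, 0.1))
  colnames(dos)[seq_len(n_ing)] <- paste0("W", seq_len(n_ing))
  co <- make_toy_cohort(dos, ref = rep("C", n_sites), alt = rep("T", n_sites))
  pm <- population_map(co$samples,
                       c(rep("Wolves", n_ing), "Og1", "Og2"),
                       c(rep("ingroup", n_ing), "outgroup", "outgroup"))
  list(cohort = co, popmap = pm)
}

uniform_annotation <- function(cohort, impact = "MODIFIER") {
  structure(data.frame(chrom = cohort$chrom, pos = cohort$pos,
                       impact = impact, stringsAsFactors = FALSE),
            class = c("annotation_table", "data.frame"))
}

test_that("polarization keeps agreeing outgroup sites and orients alleles", {
  dos <- cbind(W1 = c(1L, 1L, 1L), O1 = c(0L, 0L, 2L), O2 = c(0L, 2L, 2L))
  co <- make_toy_cohort(dos, ref = rep("C", 3), alt = rep("T", 3))
  pm <- population_map(co$samples, c("W", "Og1", "Og2"),
                       c("ingroup", "outgroup", "outgroup"))
  pol <- polarize_sites(co, "Og1", "Og2", uniform_annotation(co), pm)
  # site 1: both outgroups C/C -> ancestral C, derived T
  # site 2: C/C vs T/T -> dropped; site 3: both T/T -> ancestral T, derived C
  expect_equal(nrow(pol$sites), 2L)
  expect_equal(pol$sites$ancestral, c("C", "T"))
  expect_equal(pol$sites$derived, c("T", "C"))
  expect_equal(unname(pol$drop_log["outgroup_disagree"]), 1L)
  # dosage is counted on the derived allele: W1 het at both sites
  expect_equal(unname(pol$dosage[, "W1"]), c(1L, 1L))
  expect_error(polarize_sites(co, "Nowhere", "Og2", uniform_annotation(co), pm),
               "Nowhere")
})

test_that("polarization matches a per-site oracle on 500 planted sites", {
  set.seed(8)
  n <- 500L
  o1 <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE, prob = c(.4, .1, .4, .1))
  o2 <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE, prob = c(.4, .1, .4, .1))
  dos <- cbind(W1 = rbinom(n, 2, 0.3), W2 = rbinom(n, 2, 0.3),
               O1 = o1, O2 = o2)
  co <- make_toy_cohort(dos)
  pm <- population_map(co$samples, c("W", "W", "Og1", "Og2"),
                       c("ingroup", "ingroup", "outgroup", "outgroup"))
  seed <- 33
  pol <- polarize_sites(co, "Og1", "Og2", uniform_annotation(co), pm, seed)
  # oracle: replay the pseudo-haploid draws with the same seeded stream,
  # then apply the retention rule site by site
  draws <- lupuspg:::with_seed(seed, list(runif(n), runif(n)))
  ph <- function(dosage, u) ifelse(is.na(dosage), NA_integer_,
                                   as.integer(u < dosage / 2))
  h1 <- ph(o1, draws[[1]]); h2 <- ph(o2, draws[[2]])
  keep_oracle <- !is.na(h1) & !is.na(h2) & h1 == h2
  expect_equal(nrow(pol$sites), sum(keep_oracle))
  expect_equal(pol$sites$pos, co$pos[keep_oracle])
  # retention monotone under added outgroup missingness
  o1b <- o1; o1b[sample.int(n, 100)] <- NA
  dos2 <- dos; dos2[, "O1"] <- o1b
  co2 <- make_toy_cohort(dos2)
  pol2 <- polarize_sites(co2, "Og1", "Og2", uniform_annotation(co2), pm, seed)
  expect_lte(nrow(pol2$sites), nrow(pol$sites))
})

test_that("load accounting follows the category definitions", {
  pol <- structure(list(
    sites = data.frame(chrom = "chr1", pos = 1:4,
                       ancestral = "C", derived = "T",
                       impact = c("HIGH", "MODERATE", "LOW", "MODIFIER")),
    dosage = matrix(c(2L, 1L, 2L, 1L), 4, 1,
                    dimnames = list(NULL, "W1")),
    drop_log = c(outgroup_missing = 0, outgroup_disagree = 0)),
    class = "polarized_sites")
  r <- count_load(pol, "W1")
  expect_equal(r$total_load, 3)
  expect_equal(r$realized_load, 2)
  expect_equal(r$masked_load, 1)
  expect_equal(unname(r$derived_count), c(2, 1, 2, 1))
  # normalized rate: (HIGH + MODERATE) / MODIFIER * 1e5
  expect_equal(unname(r$normalized_per_1e5_neutral[["HIGH"]] +
                        r$normalized_per_1e5_neutral[["MODERATE"]]), 3e5)
  # per-site units
  rs <- count_load(pol, "W1", units = "sites")
  expect_equal(rs$total_load, 2)
  expect_equal(rs$realized_load, 1)
  expect_equal(rs$masked_load, 1)
  # all-ancestral individual
  pol0 <- pol; pol0$dosage[] <- 0L
  r0 <- count_load(pol0, "W1")
  expect_equal(r0$total_load + r0$realized_load + r0$masked_load, 0)
  expect_true(r0$modifier_undefined)
  expect_true(all(is.na(r0$normalized_per_1e5_neutral)))
})

test_that("the printed normalization formula gives 50 per 100,000", {
  expect_equal(500 / 1e6 * 1e5, 50)
  pol <- structure(list(
    sites = data.frame(chrom = "chr1", pos = 1:2, ancestral = "C",
                       derived = "T", impact = c("HIGH", "MODIFIER")),
    dosage = matrix(c(1L, 2L), 2, 1, dimnames = list(NULL, "W1")),
    drop_log = c(outgroup_missing = 0, outgroup_disagree = 0)),
    class = "polarized_sites")
  r <- count_load(pol, "W1")
  expect_equal(unname(r$normalized_per_1e5_neutral[["HIGH"]]), 1 / 2 * 1e5)
})

test_that("total = realized + masked for every simulated individual", {
  fix <- load_fixture(n_ing = 4L, n_sites = 300L, seed = 3)
  ann <- assign_impact_annotations(fix$cohort,
    c(HIGH = 0.1, MODERATE = 0.2, LOW = 0.2, MODIFIER = 0.5), seed = 2)
  pol <- polarize_sites(fix$cohort, "Og1", "Og2", ann, fix$popmap, seed = 5)
  lt <- load_table(pol)
  expect_true(all(lt$total_load == lt$realized_load + lt$masked_load))
  lt2 <- load_table(pol, units = "sites")
  expect_true(all(lt2$total_load == lt2$realized_load + lt2$masked_load))
  # normalized rates invariant to duplicating the whole site set
  pol2 <- pol
  pol2$sites <- rbind(pol$sites, pol$sites)
  pol2$dosage <- rbind(pol$dosage, pol$dosage)
  r1 <- count_load(pol, "W1"); r2 <- count_load(pol2, "W1")
  expect_equal(r1$normalized_per_1e5_neutral, r2$normalized_per_1e5_neutral)
})

test_that("bottlenecked populations shift load from masked to realized", {
  reps <- 20L
  hits_realized <- 0L; hits_masked <- 0L
  for (i in seq_len(reps)) {
    m <- demographic_model(
      data.frame(name = c("Big", "Small", "Og1", "Og2"),
                 size = c(10000, 200, 10000, 10000)),
      splits = data.frame(time = c(4000, 150000, 200000),
                          derived = c("Small", "Og1", "Og2"),
                          ancestral = c("Big", "Big", "Big")),
      size_changes = data.frame(time = 100, pop = "Small", size = 10000),
      sequence_length = 2e6, chromosome_count = 2)
    s <- simulate_cohort(m, c(Big = 5, Small = 5, Og1 = 1, Og2 = 1),
                         seed = 900 + i)
    ann <- assign_impact_annotations(s$cohort,
      c(HIGH = 0.05, MODERATE = 0.15, LOW = 0.1, MODIFIER = 0.7),
      seed = i)
    pm <- population_map(s$popmap$sample, s$popmap$population,
                         ifelse(s$popmap$population %in% c("Og1", "Og2"),
                                "outgroup", "ingroup"))
    pol <- polarize_sites(s$cohort, "Og1", "Og2", ann, pm, seed = i)
    cmp <- compare_populations(load_table(pol), pm)
    sm <- cmp$summary
    mr <- function(metric, pop) sm$mean[sm$metric == metric & sm$population == pop]
    if (mr("realized_load", "Small") > mr("realized_load", "Big"))
      hits_realized <- hits_realized + 1L
    if (mr("masked_load", "Small") < mr("masked_load", "Big"))
      hits_masked <- hits_masked + 1L
  }
  expect_gte(hits_realized, ceiling(0.8 * reps))
  expect_gte(hits_masked, ceiling(0.8 * reps))
})

test_that("population comparison needs data and warns on empty populations", {
  fix <- load_fixture(n_ing = 2L)
  ann <- uniform_annotation(fix$cohort, "MODERATE")
  pol <- polarize_sites(fix$cohort, "Og1", "Og2", ann, fix$popmap)
  lt <- load_table(pol)
  # two populations with data plus one ingroup population with none
  pm2 <- population_map(c(fix$popmap$sample, "ghost"),
                        c("X", "Y", "Og1", "Og2", "Empty"),
                        c(fix$popmap$role, "ingroup"))
  # two identical individuals in two populations -> equal means
  pm3 <- population_map(fix$popmap$sample, c("X", "Y", "Og1", "Og2"),
                        fix$popmap$role)
  lt_dup <- lt; lt_dup$total_load <- rep(lt$total_load[1], 2)
  lt_dup$realized_load <- rep(lt$realized_load[1], 2)
  lt_dup$masked_load <- rep(lt$masked_load[1], 2)
  cmp <- compare_populations(lt_dup, pm3)
  tot <- cmp$summary[cmp$summary$metric == "total_load", ]
  expect_equal(tot$mean[1], tot$mean[2])
  expect_warning(compare_populations(lt, pm2), "Empty")
})
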