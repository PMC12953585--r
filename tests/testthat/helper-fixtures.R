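# Shared fixtures. Everything is generated in code; expensive simulation
# sets are memoised so several test files can reuse them within a session.

`%||%` <- function(a, b) if (is.null(a)) b else a

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# deterministic hand-built cohort: n sites, n samples, explicit dosages
# (0/1/2/NA); one chromosome unless chrom given
make_toy_cohort <- function(dosage, pos = NULL, chrom = NULL,
                            ref = NULL, alt = NULL, qual = NULL,
                            phased = TRUE) {
  dosage <- as.matrix(dosage)
  ns <- nrow(dosage)
  pos <- pos %||% (seq_len(ns) * 1000L)
  chrom <- chrom %||% rep("chr1", ns)
  a1 <- ifelse(is.na(dosage), NA_integer_, as.integer(dosage >= 1L))
  a2 <- ifelse(is.na(dosage), NA_integer_, as.integer(dosage == 2L))
  samples <- colnames(dosage) %||% paste0("S", seq_len(ncol(dosage)))
  blank <- is.na(samples) | samples == ""
  samples[blank] <- paste0("S", which(blank))
  new_cohort(chrom, pos, ref %||% rep("A", ns), alt %||% rep("G", ns),
             a1, a2, phased = phased, samples = samples, qual = qual)
}

toy_popmap <- function(cohort, population, role = "ingroup") {
  population_map(cohort$samples, population, role)
}

# single panmictic population, N = 10000, 2 x 5 Mb
panmictic_model <- function(n_chrom = 2L, seq_len_bp = 5e6, N = 10000) {
  demographic_model(data.frame(name = "P", size = N), splits = NULL,
                    mutation_rate = 4.5e-9, sequence_length = seq_len_bp,
                    chromosome_count = n_chrom)
}

sim_panmictic <- function(seed = 11, n = 6L, n_chrom = 2L) {
  simulate_cohort(panmictic_model(n_chrom), c(P = n), seed = seed)
}

# wolf model without the admixture pulse (null for D statistics)
null_wolf_model <- function(...) {
  m <- default_wolf_model(...)
  m$admixture <- NULL
  m
}

dstat_quartet <- function() quartet_spec("Holarctic", "SWAsia", "Indian", "Outgroup1")

dstat_samples <- c(Indian = 4L, Holarctic = 4L, SWAsia = 4L, Outgroup1 = 2L)

# Z scores (and D, SE) for replicate simulations under a model
dstat_replicates <- function(model, n_rep, seed0) {
  t(vapply(seq_len(n_rep), function(i) {
    s <- simulate_cohort(model, dstat_samples, seed = seed0 + i)
    d <- d_test(s$cohort, s$popmap, dstat_quartet())
    c(D = d$D, se = d$se, Z = d$Z)
  }, numeric(3)))
}

# 100 null-model D replicates, shared by the calibration and jackknife checks
null_dstat_replicates <- function() {
  cached("null_dstat", dstat_replicates(null_wolf_model(), 100L, 5000L))
}

# independent brute-force topology weights: prune with ape::keep.tip and
# match against the catalog by Robinson-Foulds distance
brute_force_weights <- function(tree, groups, catalog) {
  gnames <- catalog$groups
  combos <- expand.grid(lapply(groups[gnames], seq_along),
                        KEEP.OUT.ATTRS = FALSE)
  w <- numeric(length(catalog$trees))
  for (r in seq_len(nrow(combos))) {
    sel <- vapply(gnames, function(g) groups[[g]][combos[[g]][r]], character(1))
    sub <- ape::keep.tip(tree, sel)
    sub$tip.label <- gnames[match(sub$tip.label, sel)]
    sub <- ape::unroot(sub)
    if (!is.null(sub$edge.length)) sub <- ape::di2multi(sub, tol = 1e-12)
    d <- vapply(catalog$trees, function(ct)
      suppressWarnings(ape::dist.topo(sub, ct)), numeric(1))
    hit <- which(d == 0)
    if (length(hit) == 1L) w[hit] <- w[hit] + 1
    else {
      # unresolved subtree: every catalog tree compatible with its splits
      comp <- which(vapply(catalog$trees, function(ct)
        all(lupuspg:::tree_splits(sub) %in% lupuspg:::tree_splits(ct)),
        logical(1)))
      w[comp] <- w[comp] + 1 / length(comp)
    }
  }
  w / nrow(combos)
}

# base-pair overlap of two half-open interval sets on the same chromosome set
interval_overlap_bp <- function(a, b) {
  tot <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    tot <- tot + max(0, min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]))
  }
  tot
}
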