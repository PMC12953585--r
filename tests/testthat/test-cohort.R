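test_that("VCF round trip preserves genotypes, positions, alleles and phase", {
  s <- cached("rt_sim", {
    m <- panmictic_model(1L, 2e5, 5000)
    simulate_cohort(m, c(P = 4), seed = 3, missing_rate = 0.05)
  })
  co <- cohort_subset(s$cohort, sites = seq_len(min(100, n_sites(s$cohort))))
  path <- withr::local_tempfile(fileext = ".vcf")
  pmpath <- withr::local_tempfile(fileext = ".tsv")
  write_vcf_cohort(co, s$popmap, path)
  write_popmap(s$popmap, pmpath)
  back <- read_vcf_cohort(path, pmpath)
  expect_identical(back$cohort$pos, co$pos)
  expect_identical(back$cohort$chrom, co$chrom)
  expect_identical(back$cohort$ref, co$ref)
  expect_identical(back$cohort$alt, co$alt)
  expect_identical(back$cohort$a1, unname(co$a1))
  expect_identical(back$cohort$a2, unname(co$a2))
  expect_identical(back$cohort$samples, co$samples)
  # phase flag survives except at missing calls (written ./.)
  expect_identical(back$cohort$phased[!is.na(co$a1)], co$phased[!is.na(co$a1)])
  expect_identical(back$popmap$population, s$popmap$population)
})

test_that("VCF output uses 1-based POS and ./. for missing genotypes", {
  co <- make_toy_cohort(matrix(c(0L, NA, 2L, 1L), 2, 2), pos = c(0L, 999L))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_cohort(co, NULL, path)
  lines <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  expect_equal(sapply(strsplit(lines, "\t"), `[`, 2), c("1", "1000"))
  expect_match(lines[2], "\\./\\.")
})

test_that("VCF reader keeps only biallelic SNPs and logs dropped records", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "W1", "W2", "W3", sep = "\t"),
    "chr1\t10\t.\tA\tG\t50\tPASS\t.\tGT\t0/0\t0|1\t1/1",
    "chr1\t20\t.\tA\tAT\t50\tPASS\t.\tGT\t0/0\t0/0\t0/0",   # indel
    "chr1\t30\t.\tC\tT\t50\tPASS\t.\tGT\t0/1\t./.\t1/1",
    "chr1\t40\t.\tC\tG,T\t50\tPASS\t.\tGT\t0/0\t0/1\t0/2",  # multiallelic
    "chr1\t50\t.\tG\tA\t50\tPASS\t.\tGT\t0/0\t0/0\t0/1",
    "chr1\t60\t.\tT\tC\t50\tPASS\t.\tGT\t1/1\t0/0\t0/0",
    "chr1\t70\t.\tT\tG\t50\tPASS\t.\tGT\t0/0\t1|1\t0/0"),
    path)
  out <- read_vcf_cohort(path)
  expect_equal(n_sites(out$cohort), 5L)
  expect_equal(attr(out$cohort, "drop_log")[["indel_or_other"]], 1L)
  expect_equal(attr(out$cohort, "drop_log")[["multiallelic"]], 1L)
  # phased 0|1 is het with the phase flag set
  expect_true(out$cohort$phased[1, 2])
  expect_false(out$cohort$phased[1, 3])
  expect_equal(out$cohort$a1[1, 2] + out$cohort$a2[1, 2], 1L)
  # sample present in VCF but absent from popmap is an error naming it
  pmpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("W2\tPopA", "W3\tPopA"), pmpath)
  expect_error(read_vcf_cohort(path, pmpath), "W1")
})

test_that("recombination map computes length-weighted means and rejects overlap", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t1000000\t1.0", "chr1\t1000000\t3000000\t2.0"), path)
  map <- read_recomb_map(path)
  expect_equal(genome_mean_rate(map), 5 / 3)
  one <- recomb_map("chr1", 0, 5e5, 0.7)
  expect_equal(genome_mean_rate(one), 0.7)
  writeLines(c("chr1\t0\t1000\t1.0", "chr1\t500\t2000\t2.0"), path)
  expect_error(read_recomb_map(path), "verlap")
  writeLines("chr1\t0\t1000\t-1.0", path)
  expect_error(read_recomb_map(path), "egative")
})

test_that("site filters match a site-by-site oracle and are idempotent", {
  # 12 sites with planted violations of each rule
  dos <- matrix(0L, 12, 6)
  dos[, 1] <- 1L                      # keep some polymorphism everywhere
  dos[1, ] <- c(NA, NA, 0L, 1L, 0L, 0L)   # 2/6 missing
  dos[2, 2] <- NA                         # 1/6 missing
  dos[3, ] <- c(1L, 1L, 0L, 0L, 0L, 0L)   # mac 2
  dos[4, ] <- c(1L, 1L, 1L, 0L, 0L, 0L)   # mac 3
  dos[5, ] <- c(2L, 2L, 2L, 2L, 2L, 1L)   # mac 1 (ref side)
  qual <- c(rep(100, 6), 20, 35, rep(100, 4))
  co <- make_toy_cohort(dos, qual = qual)
  spec <- filter_spec(min_site_quality = 30, max_missing_fraction = 0.2,
                      min_minor_allele_count = 3)
  out <- filter_sites(co, spec)

  # independent per-site re-application of each rule
  keep_oracle <- vapply(seq_len(12), function(i) {
    d <- dos[i, ]
    miss <- mean(is.na(d))
    nalt <- sum(d, na.rm = TRUE); nn <- 2 * sum(!is.na(d))
    mac <- min(nalt, nn - nalt)
    qual[i] >= 30 && miss <= 0.2 && mac >= 3
  }, logical(1))
  expect_equal(n_sites(out), sum(keep_oracle))
  expect_equal(out$pos, co$pos[keep_oracle])
  # idempotence
  again <- filter_sites(out, spec)
  expect_equal(again$pos, out$pos)
  expect_identical(again$a1, out$a1)
  # input unchanged, order preserved
  expect_equal(n_sites(co), 12L)
  expect_true(all(diff(match(out$pos, co$pos)) > 0))
})

test_that("missingness and minor-allele-count filters follow their definitions", {
  dos <- matrix(1L, 10, 4)
  dos[3, 1] <- NA; dos[7, c(2, 4)] <- NA
  co <- make_toy_cohort(dos)
  out <- filter_sites(co, filter_spec(max_missing_fraction = 0))
  expect_equal(n_sites(out), 8L)
  # site with alt count 2 removed at mac 3
  dos2 <- rbind(c(1L, 1L, 0L, 0L), c(1L, 1L, 1L, 0L))
  co2 <- make_toy_cohort(dos2)
  out2 <- filter_sites(co2, filter_spec(min_minor_allele_count = 3))
  expect_equal(out2$pos, co2$pos[2])
  expect_warning(filter_sites(co2, filter_spec(min_minor_allele_count = 5)),
                 "no sites")
})

test_that("cohort invariants are enforced", {
  expect_error(make_toy_cohort(matrix(0L, 2, 2), pos = c(5L, 5L)),
               "increasing")
  expect_error(new_cohort("chr1", 1L, "A", "A", matrix(0L, 1, 1),
                          matrix(0L, 1, 1)), "biallelic")
  expect_error(population_map(c("a", "a"), c("X", "X")), "duplicated")
  expect_error(population_map(c("a", "b"), c("X", "X"),
                              c("ingroup", "outgroup")), "both")
})
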