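test_that("joint folding merges complement cells with lexicographic ties", {
  # 2 populations, 2 haploids each: cell (2,0) folds onto (0,2)'s complement
  counts <- array(0, c(3, 3))
  counts[3, 1] <- 4   # d = (2, 0), total 2 = half of 4 -> tie
  counts[1, 3] <- 2   # d = (0, 2), complement of (2, 0)
  counts[2, 1] <- 5   # d = (1, 0), minor side already
  counts[3, 3] <- 7   # d = (2, 2), monomorphic-derived -> folds to (0, 0)
  sfs <- folded_sfs(counts, c(2L, 2L))
  # tie cells keyed by the lexicographically smaller index (0, 2)... (2,0) vs
  # complement (0,2): (0,2) is smaller, so both land there
  expect_equal(sfs$counts[1, 3], 6)
  expect_equal(sfs$counts[3, 1], 0)
  expect_equal(sfs$counts[2, 1], 5)
  expect_equal(sfs$monomorphic, 7)
  expect_equal(sum(sfs$counts) + sfs$monomorphic, sum(counts))
})

test_that("block downsampling matches a brute-force per-block oracle", {
  set.seed(12)
  n <- 60L
  dos <- matrix(rbinom(n * 8, 2, 0.3), n, 8)
  dos[sample.int(length(dos), 60)] <- NA
  colnames(dos) <- c(paste0("A", 1:3), paste0("B", 1:5))
  co <- make_toy_cohort(dos, pos = as.integer(seq(0, 3e6, length.out = n)))
  pm <- population_map(colnames(dos), rep(c("A", "B"), c(3, 5)))
  res <- build_folded_3dsfs(co, pm, c("A", "B"), block_bp = 1e6,
                            subsample = c(2L, 3L), seed = 4)
  # oracle: per block, re-select the least-missing individuals and count
  # complete polymorphic SNPs
  blk <- floor(co$pos / 1e6)
  n_poly <- 0; n_mono <- 0
  for (b in unique(blk)) {
    rows <- which(blk == b)
    pick <- function(members, k) {
      miss <- colSums(is.na(dos[rows, members, drop = FALSE]))
      members[order(miss, seq_along(miss))[seq_len(k)]]
    }
    sel <- c(pick(paste0("A", 1:3), 2), pick(paste0("B", 1:5), 3))
    d <- dos[rows, sel, drop = FALSE]
    complete <- rowSums(is.na(d)) == 0
    tot <- rowSums(d[complete, , drop = FALSE])
    n_poly <- n_poly + sum(tot > 0 & tot < 10)
    n_mono <- n_mono + sum(tot == 0 | tot == 10)
  }
  expect_equal(sum(res$all$counts), n_poly)
  expect_equal(res$all$monomorphic, n_mono)
  # unlinked: at most one SNP per block
  expect_lte(sum(res$unlinked$counts), length(unique(blk)))
  expect_error(build_folded_3dsfs(co, pm, c("A", "B"), subsample = c(4L, 3L)),
               "fewer")
})

test_that("no-op downsampling reproduces the direct folded spectrum", {
  set.seed(3)
  dos <- matrix(rbinom(40 * 4, 2, 0.4), 40, 4)
  colnames(dos) <- c("A1", "A2", "B1", "B2")
  co <- make_toy_cohort(dos, pos = as.integer(seq(0, 2e6, length.out = 40)))
  pm <- population_map(colnames(dos), c("A", "A", "B", "B"))
  res <- build_folded_3dsfs(co, pm, c("A", "B"), block_bp = 1e7,
                            subsample = c(2L, 2L))
  # direct: fold joint derived counts of the full panel
  dA <- rowSums(dos[, 1:2]); dB <- rowSums(dos[, 3:4])
  direct <- array(0, c(5, 5))
  for (i in seq_len(40)) direct[dA[i] + 1, dB[i] + 1] <-
      direct[dA[i] + 1, dB[i] + 1] + 1
  ref <- folded_sfs(direct, c(4L, 4L))
  expect_equal(res$all$counts, ref$counts)
  expect_equal(res$all$monomorphic, ref$monomorphic)
})

test_that("composite log-likelihood follows the cell formula", {
  nhap <- c(2L, 2L)
  p <- array(0, c(3, 3)); m <- array(0, c(3, 3))
  m[2, 1] <- 1; p[2, 1] <- 1
  expect_equal(composite_loglik(m, p), 0)
  m2 <- array(0, c(3, 3)); m2[2, 1] <- 2; m2[1, 2] <- 1
  p2 <- array(0, c(3, 3)); p2[2, 1] <- 0.5; p2[1, 2] <- 0.5
  expect_equal(composite_loglik(m2, p2), 3 * log(0.5))
  # random SFS: equals brute-force per-cell accumulation, and is additive
  # over disjoint cell partitions
  set.seed(9)
  mr <- array(rpois(9, 3), c(3, 3)); mr[1, 1] <- 0
  pr <- array(runif(9), c(3, 3)); pr <- pr / sum(pr)
  by_hand <- sum(as.vector(mr)[-1] * log(as.vector(pr))[-1])
  expect_equal(composite_loglik(mr, pr), by_hand)
  mA <- mr; mA[, 2:3] <- 0
  mB <- mr; mB[, 1] <- 0
  expect_equal(composite_loglik(mA, pr) + composite_loglik(mB, pr),
               composite_loglik(mr, pr))
  # occupied cell with zero expectation is an error
  pz <- pr; pz[2, 1] <- 0
  mz <- array(0, c(3, 3)); mz[2, 1] <- 1
  expect_error(composite_loglik(mz, pz), "probability 0")
  expect_error(composite_loglik(array(0, c(2, 2)), pr), "differ")
})

test_that("SFS text round trip preserves counts and metadata", {
  set.seed(4)
  sfs <- folded_sfs(array(rpois(60, 2), c(3, 4, 5)), c(2L, 3L, 4L), 11)
  path <- withr::local_tempfile(fileext = ".sfs")
  write_sfs(sfs, path)
  back <- read_sfs(path)
  expect_equal(back$counts, sfs$counts)
  expect_equal(back$nhap, sfs$nhap)
  expect_equal(back$monomorphic, sfs$monomorphic)
})

test_that("expected spectra are seeded and nested in the model hierarchy", {
  specB <- sfs_model_spec("B", subsample = c(2L, 2L, 2L),
                          ranges = list(alpha = c(1e-9, 0.5)))
  pars <- c(T_sw = 2000, alpha = 0.3, T_intro = 1000)
  e1 <- expected_sfs(specB, pars, n_loci = 1000, seed = 5)
  e2 <- expected_sfs(specB, pars, n_loci = 1000, seed = 5)
  expect_identical(e1$counts, e2$counts)
  expect_equal(sum(e1$counts), 1, tolerance = 1e-12)
  # alpha ~ 0 under model B is statistically indistinguishable from model A
  specA <- sfs_model_spec("A", subsample = c(2L, 2L, 2L))
  eA <- expected_sfs(specA, c(T_sw = 2000), n_loci = 1e5, seed = 7)
  eB0 <- expected_sfs(specB, c(T_sw = 2000, alpha = 1e-9, T_intro = 1000),
                      n_loci = 1e5, seed = 8)
  tv <- 0.5 * sum(abs(eA$counts - eB0$counts))
  expect_lt(tv, 0.02)
  # invalid parameter combination
  expect_error(expected_sfs(specB, c(T_sw = 1000, alpha = 0.3,
                                     T_intro = 2000), n_loci = 1000),
               "invalid parameter combination")
  expect_error(expected_sfs(specA, c(T_sw = 2000), n_loci = 10), "1000")
})

test_that("fitting is deterministic and a 1-point grid is returned as-is", {
  obs <- cached("sfs_obs_small", {
    specB <- sfs_model_spec("B")
    m <- lupuspg:::build_sfs_model(specB, c(T_sw = 10300 / 4.4, alpha = 0.11,
                                            T_intro = 6000 / 4.4))
    m$sequence_length <- 2e6; m$chromosome_count <- 4L
    s <- simulate_cohort(m, c(Indian = 3, SWAsia = 6, Central = 9), seed = 19)
    build_folded_3dsfs(s$cohort, s$popmap, c("Indian", "SWAsia", "Central"),
                       seed = 2)
  })
  specA <- sfs_model_spec("A")
  f1 <- fit_model(obs, specA, n_loci = 1000, seed = 4,
                  search = search_config(grid_points = 2, refine_iter = 5))
  f2 <- fit_model(obs, specA, n_loci = 1000, seed = 4,
                  search = search_config(grid_points = 2, refine_iter = 5))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$AIC, f2$AIC)
  # degenerate search: single grid point, no refinement
  spec1 <- sfs_model_spec("A", ranges = list(T_sw = c(1999.9, 2000.1)))
  f0 <- fit_model(obs, spec1, n_loci = 1000, seed = 4,
                  search = search_config(grid_points = 1, refine_iter = 0))
  r <- spec1$ranges$T_sw
  expect_equal(unname(coef(f0)), exp(mean(log(r))), tolerance = 1e-6)
  expect_equal(f0$AIC, 2 * 1 - 2 * f0$lnL_unlinked)
  expect_error(search_config(grid_points = 0), "budget")
  # logLik carries the unlinked likelihood and parameter count
  ll <- logLik(f0)
  expect_equal(as.numeric(ll), f0$lnL_unlinked)
  expect_equal(attr(ll, "df"), 1)
})

test_that("AIC comparison follows the Akaike-weight closed form", {
  fake <- function(model, aic) structure(
    list(model = model, id = model, k = 1, lnL_unlinked = -aic / 2 + 1,
         AIC = aic, data_digest = "x"), class = "sfs_fit")
  cmp <- compare_models(fake("A", 10), fake("B", 10))
  expect_equal(cmp$akaike_weight, c(0.5, 0.5))
  cmp2 <- compare_models(fake("A", 10), fake("B", 12))
  expect_equal(cmp2$dAIC, c(0, 2))
  expect_equal(cmp2$akaike_weight,
               c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(cmp2$model[cmp2$best], "A")
  cmp3 <- compare_models(fake("A", 3), fake("B", 4), fake("C", 9))
  expect_equal(sum(cmp3$akaike_weight), 1)
  expect_true(all(cmp3$dAIC >= 0) && min(cmp3$dAIC) == 0)
  bad <- fake("B", 5); bad$data_digest <- "y"
  expect_error(compare_models(fake("A", 3), bad), "different observed data")
})
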