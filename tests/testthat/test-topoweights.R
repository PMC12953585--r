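test_that("SNP windows tile chromosomes and carry overlap-weighted rates", {
  dos <- matrix(rep(c(0L, 1L), 125 * 2), 250, 2)
  co <- make_toy_cohort(dos, pos = seq(0L, by = 8000L, length.out = 250))
  w <- make_snp_windows(co, window_snps = 100L)
  expect_equal(nrow(w), 2L)   # terminal 50-SNP remainder dropped
  expect_equal(attr(w, "n_dropped_windows"), 1L)
  expect_equal(w$n_snps, c(100L, 100L))

  # window spanning two map windows equally: 1 Mb @ 0.1 + 1 Mb @ 3.0
  map <- recomb_map(c("chr1", "chr1"), c(0, 1e6), c(1e6, 2e6), c(0.1, 3.0))
  co2 <- make_toy_cohort(matrix(0:1, 100, 2),
                         pos = as.integer(seq(0, 2e6 - 1, length.out = 100)))
  w2 <- suppressWarnings(make_snp_windows(co2, map, 100L))
  expect_equal(w2$mean_rate, 1.55, tolerance = 1e-3)

  # random windows: rate equals brute-force bp-by-bp average
  set.seed(5)
  map3 <- recomb_map("chr1", seq(0, 9e5, 1e5), seq(1e5, 1e6, 1e5),
                     round(runif(10, 0, 4), 2))
  co3 <- make_toy_cohort(matrix(0:1, 200, 2),
                         pos = sort(sample(0:999999, 200)))
  w3 <- make_snp_windows(co3, map3, 100L)
  for (i in seq_len(nrow(w3))) {
    bp <- w3$start[i]:(w3$end[i] - 1)
    rate_at <- vapply(bp, function(x) {
      hit <- map3$rate[map3$start <= x & map3$end > x]
      if (length(hit)) hit else 0
    }, numeric(1))
    expect_equal(w3$mean_rate[i], mean(rate_at), tolerance = 1e-9)
  }
  expect_error(make_snp_windows(co3, NULL, 1L), "at least 2")
})

test_that("window trees recover clean topologies and degenerate cases", {
  # two identical pairs: haplotypes of S1 = haplotypes of S2, S3 = S4
  h <- rbind(c(0, 0, 1, 1), c(0, 0, 1, 1), c(1, 1, 0, 0), c(0, 0, 1, 1))
  a1 <- h[, c(1, 3)]; a2 <- h[, c(2, 4)]
  co <- new_cohort(rep("chr1", 4), (1:4) * 100L, rep("A", 4), rep("C", 4),
                   a1, a2, phased = TRUE, samples = c("S1", "S2"))
  w <- make_snp_windows(co, window_snps = 4L)
  tr <- infer_window_tree(co, w[1, ], c("S1", "S2"))
  expect_setequal(tr$tip.label, c("S1.h1", "S1.h2", "S2.h1", "S2.h2"))
  sig <- lupuspg:::split_signature(tr)
  expect_equal(sig, "S2.h1,S2.h2")

  # all haplotypes identical -> star tree with zero branch lengths
  co0 <- new_cohort(rep("chr1", 4), (1:4) * 100L, rep("A", 4), rep("C", 4),
                    matrix(0L, 4, 3), matrix(0L, 4, 3), phased = TRUE,
                    samples = c("S1", "S2", "S3"))
  w0 <- make_snp_windows(co0, window_snps = 4L)
  tr0 <- infer_window_tree(co0, w0[1, ], c("S1", "S2", "S3"))
  expect_equal(tr0$Nnode, 1L)
  expect_equal(sum(tr0$edge.length), 0)

  # NJ recovers quartets of an additive distance matrix
  set.seed(42)
  for (rep in 1:3) {
    ref <- ape::rtree(6, tip.label = paste0("S", 1:6, ".h1"))
    dm <- ape::cophenetic.phylo(ref)
    nj <- ape::nj(as.dist(dm))
    expect_equal(suppressWarnings(
      ape::dist.topo(ape::unroot(nj), ape::unroot(ref))), 0,
      ignore_attr = TRUE)
  }
})

test_that("topology catalogs have (2k-5)!! members, all distinct", {
  dfact <- function(k) prod(seq(2 * k - 5, 1, by = -2))
  for (k in 3:6) {
    cat <- enumerate_topologies(LETTERS[1:k])
    expect_equal(length(cat$trees), dfact(k))
    expect_equal(anyDuplicated(cat$signatures), 0L)
    expect_equal(anyDuplicated(cat$newick), 0L)
  }
  expect_equal(length(enumerate_topologies(LETTERS[1:5])$trees), 15L)
  expect_equal(length(enumerate_topologies(LETTERS[1:6])$trees), 105L)
  expect_error(enumerate_topologies(LETTERS[1:8]), "3 and 7")
})

test_that("weights are exact: single combination and concordant trees", {
  cat4 <- enumerate_topologies(c("A", "B", "C", "D"))
  tr <- ape::read.tree(text = "((a1:1,b1:1):1,(c1:1,d1:1):1);")
  w <- weight_topologies(tr, list(A = "a1", B = "b1", C = "c1", D = "d1"), cat4)
  expect_equal(sum(w), 1)
  expect_equal(sum(w == 1), 1L)
  hit <- which(w == 1)
  expect_equal(lupuspg:::tree_splits(cat4$trees[[hit]]), "C,D")
  # concordant: groups monophyletic, 3 tips each -> weight 1 on that topology
  txt <- "(((a1:1,a2:1):1,a3:1):2,((b1:1,b2:1,b3:1):2,((c1:1,c2:1,c3:1):2,(d1:1,d2:1,d3:1):2):1):1);"
  trc <- ape::read.tree(text = txt)
  groups <- list(A = paste0("a", 1:3), B = paste0("b", 1:3),
                 C = paste0("c", 1:3), D = paste0("d", 1:3))
  wc <- weight_topologies(trc, groups, cat4)
  expect_equal(max(wc), 1)
})

test_that("weights match exhaustive brute force on random trees", {
  set.seed(77)
  tips <- paste0(rep(letters[1:4], each = 3), rep(1:3, 4))
  groups <- split(tips, rep(c("A", "B", "C", "D"), each = 3))
  cat4 <- enumerate_topologies(c("A", "B", "C", "D"))
  for (rep in 1:5) {
    tr <- ape::unroot(ape::rtree(12, tip.label = sample(tips)))
    w <- weight_topologies(tr, groups, cat4)
    wb <- brute_force_weights(tr, groups, cat4)
    expect_equal(w, wb, tolerance = 1e-12)
    expect_equal(sum(w), 1, tolerance = 1e-9)
  }
})

test_that("weights are invariant under group-preserving tip relabeling", {
  set.seed(3)
  tips <- paste0(rep(letters[1:4], each = 2), rep(1:2, 4))
  tr <- ape::unroot(ape::rtree(8, tip.label = tips))
  groups <- split(tips, rep(c("A", "B", "C", "D"), each = 2))
  cat4 <- enumerate_topologies(c("A", "B", "C", "D"))
  w1 <- weight_topologies(tr, groups, cat4)
  # swap the names of the two tips within each group
  tr2 <- tr
  for (g in groups) {
    i <- match(g, tr2$tip.label)
    tr2$tip.label[i] <- g[2:1]
  }
  expect_equal(weight_topologies(tr2, groups, cat4), w1)
})

test_that("stratification partitions windows at 0.2 and 2 cM/Mb", {
  wdf <- data.frame(mean_rate = c(0.1, 1.0, 3.0))
  class(wdf) <- c("snp_windows", "data.frame")
  W <- diag(3)
  st <- stratify_weights(W, wdf)
  expect_equal(unname(st$means["low", ]), c(1, 0, 0))
  expect_equal(unname(st$means["medium", ]), c(0, 1, 0))
  expect_equal(unname(st$means["high", ]), c(0, 0, 1))
  # boundary values 0.2 and 2.0 both belong to the medium stratum
  wb <- data.frame(mean_rate = c(0.2, 2.0))
  st2 <- stratify_weights(matrix(1, 2, 1), wb)
  expect_equal(unname(st2$counts), c(0L, 2L, 0L))
  # all windows medium -> single non-empty stratum
  st3 <- stratify_weights(matrix(1, 3, 1), data.frame(mean_rate = rep(1, 3)))
  expect_equal(unname(st3$counts), c(0L, 3L, 0L))
  expect_true(all(is.na(st3$means["low", ])))
  # 30 random windows: stratum means equal a brute-force group-by
  set.seed(10)
  rates <- runif(30, 0, 4)
  W30 <- matrix(runif(90), 30, 3); W30 <- W30 / rowSums(W30)
  st4 <- stratify_weights(W30, data.frame(mean_rate = rates))
  lab <- ifelse(rates < 0.2, "low", ifelse(rates <= 2, "medium", "high"))
  for (s in c("low", "medium", "high"))
    if (sum(lab == s))
      expect_equal(unname(st4$means[s, ]),
                   unname(colMeans(W30[lab == s, , drop = FALSE])))
})

test_that("per-window weights sum to one on simulated data", {
  s <- cached("topo_sim", {
    m <- default_wolf_model(1e6, 2L)
    simulate_cohort(m, c(Indian = 2, SWAsia = 2, Holarctic = 2, Outgroup1 = 1),
                    seed = 5)
  })
  tw <- window_topology_weights(s$cohort, s$popmap,
                                c("Indian", "SWAsia", "Holarctic", "Outgroup1"),
                                max_windows = 25)
  expect_true(all(abs(rowSums(tw$weights) - 1) < 1e-9))
  expect_true(all(tw$weights >= 0))
})
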