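#' Consecutive 100-SNP windows with recombination rates
#'
#' Splits each chromosome's sites into consecutive disjoint windows of
#' `window_snps` SNPs; a terminal remainder of fewer SNPs is dropped (count
#' attached as attribute `"n_dropped_windows"`). Each window's
#' `mean_rate` is the bp-overlap-weighted mean recombination rate of the map
#' windows it spans; uncovered bp contribute rate 0 (with a warning).
#'
#' @param cohort a [new_cohort()].
#' @param map a [recomb_map()] or `NULL` (all rates `NA`).
#' @param window_snps SNPs per window (>= 2).
#' @return A `snp_windows` data frame: `chrom`, `first`, `last` (global site
#'   indices), `start`, `end` (bp, half-open), `n_snps`, `mean_rate`.
#' @export
make_snp_windows <- function(cohort, map = NULL, window_snps = 100L) {
  if (window_snps < 2L) stopf("window_snps must be at least 2")
  rows <- list(); dropped <- 0L; uncovered <- FALSE
  for (ch in unique(cohort$chrom)) {
    idx <- which(cohort$chrom == ch)
    nw <- length(idx) %/% window_snps
    if (length(idx) %% window_snps > 0L) dropped <- dropped + 1L
    if (nw == 0L) next
    for (w in seq_len(nw)) {
      sel <- idx[((w - 1L) * window_snps + 1L):(w * window_snps)]
      start <- cohort$pos[sel[1L]]
      end <- cohort$pos[sel[length(sel)]] + 1L
      rate <- NA_real_
      if (!is.null(map)) {
        r <- interval_mean_rate(map, ch, start, end)
        rate <- r$rate
        if (r$uncovered > 0) uncovered <- TRUE
      }
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = ch, first = sel[1L], last = sel[length(sel)],
                   start = start, end = end, n_snps = length(sel),
                   mean_rate = rate, stringsAsFactors = FALSE)
    }
  }
  if (uncovered)
    warnf("some window bp are not covered by the recombination map; rate 0 assumed there")
  out <- do.call(rbind, rows) %||%
    data.frame(chrom = character(), first = integer(), last = integer(),
               start = integer(), end = integer(), n_snps = integer(),
               mean_rate = numeric())
  attr(out, "n_dropped_windows") <- dropped
  class(out) <- c("snp_windows", "data.frame")
  out
}

# bp-overlap-weighted mean rate over [start, end); uncovered bp count as 0
interval_mean_rate <- function(map, chrom, start, end) {
  w <- map[map$chrom == chrom & map$end > start & map$start < end, ]
  ov <- pmin(w$end, end) - pmax(w$start, start)
  covered <- sum(ov)
  list(rate = sum(w$rate * ov) / (end - start),
       uncovered = (end - start) - covered)
}

# haplotype matrix for a window: sites x (2 * samples), columns named
# <sample>.h1 / <sample>.h2
window_haplotypes <- function(cohort, window, samples) {
  idx <- window$first:window$last
  j <- match(samples, cohort$samples)
  if (anyNA(j)) stopf("unknown sample in haplotype selection")
  h <- cbind(cohort$a1[idx, j, drop = FALSE], cohort$a2[idx, j, drop = FALSE])
  ord <- as.vector(rbind(seq_along(j), seq_along(j) + length(j)))
  h <- h[, ord, drop = FALSE]
  colnames(h) <- as.vector(rbind(paste0(samples, ".h1"), paste0(samples, ".h2")))
  h
}

#' Neighbor-joining gene tree for one SNP window
#'
#' Pairwise haplotype p-distances (proportion of differing calls among
#' pairwise-complete sites) followed by neighbor joining. Tips are entered
#' in lexicographic order so ties resolve deterministically; zero-length
#' internal branches are collapsed, so a window of identical haplotypes
#' yields a star tree.
#'
#' @param cohort a phased [new_cohort()].
#' @param window one row of [make_snp_windows()].
#' @param samples diploid samples whose two haplotypes become tips.
#' @return An `ape::phylo` gene tree.
#' @export
infer_window_tree <- function(cohort, window, samples) {
  h <- window_haplotypes(cohort, window, samples)
  h <- h[, order(colnames(h)), drop = FALSE]
  n <- ncol(h)
  if (n < 3L) stopf("need at least 3 haplotypes")
  all_missing <- colSums(!is.na(h)) == 0L
  if (any(all_missing))
    stopf("haplotype with all-missing window sites: %s",
          paste(colnames(h)[all_missing], collapse = ", "))
  d <- matrix(0, n, n, dimnames = list(colnames(h), colnames(h)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(h[, i]) & !is.na(h[, j])
    d[i, j] <- d[j, i] <- if (any(ok)) mean(h[ok, i] != h[ok, j]) else 0
  }
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::di2multi(tr, tol = 1e-12)
}

# --- topology catalog ------------------------------------------------------

# canonical side of a bipartition: the side not containing the reference
# (alphabetically first) tip, sorted and comma-joined
canon_side <- function(side, all_tips) {
  if (min(all_tips) %in% side) side <- setdiff(all_tips, side)
  paste(sort(side), collapse = ",")
}

# sorted non-trivial bipartitions of an (unrooted) tree with unique tip labels
tree_splits <- function(tree) {
  nt <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", nt + tr$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  splits <- character(0)
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2L]
    if (ch > nt) {
      side <- desc[[ch]]
      if (length(side) >= 2L && length(side) <= nt - 2L)
        splits <- c(splits, canon_side(side, tr$tip.label))
    }
  }
  sort(unique(splits))
}

split_signature <- function(tree) paste(tree_splits(tree), collapse = ";")

# deterministic newick serialization: rooted at the alphabetically first tip,
# children sorted by their serialized form
canonical_newick <- function(tree) {
  tr <- ape::root(tree, outgroup = sort(tree$tip.label)[1L],
                  resolve.root = TRUE)
  nt <- length(tr$tip.label)
  rec <- function(node) {
    if (node <= nt) return(tr$tip.label[node])
    kids <- tr$edge[tr$edge[, 1L] == node, 2L]
    paste0("(", paste(sort(vapply(kids, rec, character(1))), collapse = ","),
           ")")
  }
  paste0(rec(nt + 1L), ";")
}

#' Enumerate all unrooted leaf-labeled topologies over groups
#'
#' All `(2k-5)!!` distinct unrooted binary topologies with one leaf per
#' group (3 for k = 4, 15 for k = 5, 105 for k = 6), each stored with a
#' canonical split signature and sorted newick string.
#'
#' @param groups character vector of 3 to 7 group names.
#' @return A `topology_catalog`: list with `groups`, `trees` (multiPhylo),
#'   `signatures`, `newick`.
#' @export
enumerate_topologies <- function(groups) {
  k <- length(groups)
  if (k < 3L || k > 7L) stopf("between 3 and 7 groups are supported")
  if (anyDuplicated(groups)) stopf("duplicated group name")
  trees <- phangorn::allTrees(k, rooted = FALSE, tip.label = sort(groups))
  sig <- vapply(trees, split_signature, character(1))
  if (anyDuplicated(sig)) stopf("internal error: duplicated topology")
  structure(list(groups = sort(groups), trees = trees, signatures = sig,
                 newick = vapply(trees, canonical_newick, character(1))),
            class = "topology_catalog")
}

#' @exportS3Method base::print
print.topology_catalog <- function(x, ...) {
  cat(sprintf("topology catalog: %d unrooted topologies over %d groups (%s)\n",
              length(x$trees), length(x$groups),
              paste(x$groups, collapse = ", ")))
  invisible(x)
}

#' Exact topology weights of one gene tree
#'
#' Iterates the full Cartesian product of one tip per group, prunes the gene
#' tree to the chosen tips, and matches the induced unrooted topology
#' against the catalog; weights are counts divided by the number of
#' combinations (no subsampling). A combination whose induced topology is
#' unresolved (multifurcation from zero-length branches) is distributed
#' equally over all compatible catalog topologies.
#'
#' @param tree an `ape::phylo` gene tree.
#' @param groups named list: group name -> tip labels in `tree`.
#' @param catalog an [enumerate_topologies()] catalog over the group names.
#' @return Numeric weight vector over the catalog (sums to 1).
#' @export
weight_topologies <- function(tree, groups, catalog) {
  gnames <- catalog$groups
  if (!setequal(names(groups), gnames))
    stopf("group names do not match the catalog")
  groups <- groups[gnames]
  for (g in gnames) {
    if (length(groups[[g]]) == 0L) stopf("group %s has no tips", g)
    miss <- setdiff(groups[[g]], tree$tip.label)
    if (length(miss)) stopf("tips not in tree: %s", paste(miss, collapse = ", "))
  }
  n_comb <- prod(lengths(groups))
  if (n_comb > 1e6) stopf("combination count %g exceeds the 1e6 cap", n_comb)
  cat_splits <- lapply(catalog$trees, tree_splits)
  sigmap <- setNames(seq_along(catalog$signatures), catalog$signatures)
  k <- length(gnames)

  # the induced topology of a tip choice is read off the gene tree's
  # bipartitions restricted to the chosen tips; zero-length branches were
  # already collapsed, so unresolved choices simply induce fewer splits
  masks <- edge_tip_masks(tree)
  tip_idx <- lapply(groups, function(tp) match(tp, tree$tip.label))
  combos <- as.matrix(expand.grid(tip_idx, KEEP.OUT.ATTRS = FALSE))
  w <- numeric(length(catalog$trees))
  for (r in seq_len(nrow(combos))) {
    chosen <- combos[r, ]
    sp <- character(0)
    for (m in masks) {
      s <- m[chosen]
      cnt <- sum(s)
      if (cnt >= 2L && cnt <= k - 2L) {
        side <- gnames[if (s[1L]) !s else s]  # side without the first group
        sp <- c(sp, paste(sort(side), collapse = ","))
      }
    }
    sp <- sort(unique(sp))
    idx <- sigmap[paste(sp, collapse = ";")]
    if (!is.na(idx)) {
      w[idx] <- w[idx] + 1
    } else {
      comp <- which(vapply(cat_splits, function(cs) all(sp %in% cs), logical(1)))
      w[comp] <- w[comp] + 1 / length(comp)
    }
  }
  w / n_comb
}

# descendant-tip masks of every internal non-root node (= the tree's
# non-trivial edge bipartitions, one logical vector over tips each)
edge_tip_masks <- function(tree) {
  nt <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  M <- matrix(FALSE, nt + tr$Nnode, nt)
  M[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]
    M[p, ] <- M[p, ] | M[tr$edge[e, 2L], ]
  }
  internal <- unique(tr$edge[tr$edge[, 2L] > nt, 2L])
  lapply(internal, function(v) M[v, ])
}

#' Per-window topology weights for a cohort
#'
#' Builds 100-SNP windows, infers a neighbor-joining gene tree on phased
#' haplotypes per window, and computes exact topology weights over the
#' population groups. Tips are the two haplotypes of each diploid sample;
#' a sample's group is its population.
#'
#' @param cohort a phased [new_cohort()].
#' @param popmap a [population_map()].
#' @param groups character vector of population labels (one of which is
#'   typically the outgroup).
#' @param map optional [recomb_map()] for window rates.
#' @param window_snps SNPs per window.
#' @param max_per_group optional cap on diploid samples used per group
#'   (first samples in popmap order), to bound the combination count.
#' @param max_windows optional cap on the number of windows analysed
#'   (evenly thinned across the genome), for quick-look runs.
#' @return List with `windows` (a `snp_windows` frame), `weights` (windows x
#'   topologies matrix), `trees` (list of `phylo`), `catalog`.
#' @export
window_topology_weights <- function(cohort, popmap, groups, map = NULL,
                                    window_snps = 100L,
                                    max_per_group = Inf,
                                    max_windows = Inf) {
  catalog <- enumerate_topologies(groups)
  samples <- lapply(setNames(groups, groups), function(g) {
    s <- popmap$sample[popmap$population == g]
    s <- s[s %in% cohort$samples]
    if (!length(s)) stopf("no cohort samples in group %s", g)
    head(s, max_per_group)
  })
  tip_groups <- lapply(samples, function(s)
    as.vector(rbind(paste0(s, ".h1"), paste0(s, ".h2"))))
  windows <- make_snp_windows(cohort, map, window_snps)
  if (is.finite(max_windows) && nrow(windows) > max_windows) {
    sel <- unique(round(seq(1L, nrow(windows), length.out = max_windows)))
    windows <- windows[sel, ]
  }
  all_samp <- unlist(samples, use.names = FALSE)
  trees <- vector("list", nrow(windows))
  weights <- matrix(0, nrow(windows), length(catalog$trees))
  for (i in seq_len(nrow(windows))) {
    trees[[i]] <- infer_window_tree(cohort, windows[i, ], all_samp)
    weights[i, ] <- weight_topologies(trees[[i]], tip_groups, catalog)
  }
  list(windows = windows, weights = weights, trees = trees, catalog = catalog)
}

#' Recombination-rate stratification boundaries
#'
#' Default boundaries split the genome into low (< 0.2 cM/Mb), medium
#' (0.2-2 cM/Mb, closed) and high (> 2 cM/Mb) recombination strata.
#'
#' @param low low/medium boundary in cM/Mb.
#' @param high medium/high boundary in cM/Mb.
#' @return A `strat_config` object.
#' @export
strat_config <- function(low = 0.2, high = 2) {
  if (!(0 < low && low < high)) stopf("need 0 < low < high")
  structure(list(low = low, high = high), class = "strat_config")
}

#' Mean topology weights per recombination stratum
#'
#' Partitions windows into low `[0, low)`, medium `[low, high]` and high
#' `(high, Inf)` strata by their mean recombination rate and averages the
#' weight vectors per stratum (unweighted mean over windows).
#'
#' @param weights windows x topologies weight matrix.
#' @param windows the matching `snp_windows` frame (with `mean_rate`).
#' @param config a [strat_config()].
#' @return A `stratified_weights` object: `means` (3 x topologies, `NA` rows
#'   for empty strata), `counts` per stratum.
#' @export
stratify_weights <- function(weights, windows, config = strat_config()) {
  if (nrow(windows) != nrow(weights))
    stopf("weights and windows disagree in length")
  if (all(is.na(windows$mean_rate)))
    stopf("windows carry no recombination rates")
  r <- windows$mean_rate
  stratum <- ifelse(r < config$low, "low",
                    ifelse(r <= config$high, "medium", "high"))
  lv <- c("low", "medium", "high")
  means <- matrix(NA_real_, 3L, ncol(weights), dimnames = list(lv, NULL))
  counts <- setNames(integer(3L), lv)
  for (s in lv) {
    sel <- which(stratum == s)
    counts[s] <- length(sel)
    if (length(sel))
      means[s, ] <- colMeans(weights[sel, , drop = FALSE])
  }
  structure(list(means = means, counts = counts, config = config),
            class = "stratified_weights")
}

#' @exportS3Method base::print
print.stratified_weights <- function(x, ...) {
  cat("mean topology weights per recombination stratum\n")
  for (s in rownames(x$means)) {
    cat(sprintf("  %s (%d windows):", s, x$counts[s]))
    if (x$counts[s] == 0) cat(" (empty)\n")
    else cat(sprintf(" %s\n", paste(formatC(x$means[s, ], digits = 3,
                                            format = "f"), collapse = " ")))
  }
  invisible(x)
}
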