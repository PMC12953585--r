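#' Folded joint site-frequency spectrum
#'
#' Counts over folded minor-allele-frequency cells for one or more
#' populations. Folding merges each joint cell with its complement
#' (swapping derived and ancestral in all populations simultaneously); when
#' the total derived count equals exactly half the total alleles, the cell
#' with the lexicographically smaller index keys the merged cell. The
#' all-zero cell is the monomorphic class, stored separately.
#'
#' @param counts numeric array with `dim = nhap + 1` of per-cell site
#'   counts (unfolded or already folded).
#' @param nhap integer vector of haploid sample sizes per population.
#' @param monomorphic count of retained monomorphic sites.
#' @param provenance free-text provenance tag (e.g. `"all_snps"`).
#' @return A `folded_sfs` object.
#' @export
folded_sfs <- function(counts, nhap, monomorphic = 0, provenance = "") {
  dims <- nhap + 1L
  counts <- array(as.numeric(counts), dims)
  tgt <- fold_map(nhap)
  folded <- numeric(prod(dims))
  agg <- tapply(as.vector(counts), tgt, sum)
  folded[as.integer(names(agg))] <- agg
  monomorphic <- monomorphic + folded[1L]
  folded[1L] <- 0
  structure(list(counts = array(folded, dims), nhap = as.integer(nhap),
                 monomorphic = as.numeric(monomorphic),
                 provenance = provenance),
            class = "folded_sfs")
}

# linear (1-based) folded target index for every cell of the unfolded array
fold_map <- function(nhap) {
  dims <- nhap + 1L
  idx <- arrayInd(seq_len(prod(dims)), dims) - 1L
  comp <- matrix(rep(nhap, each = nrow(idx)), nrow(idx)) - idx
  tot <- rowSums(idx)
  half <- sum(nhap) / 2
  usecomp <- tot > half
  for (r in which(tot == half)) {
    dlt <- idx[r, ] - comp[r, ]
    nz <- which(dlt != 0)
    if (length(nz) && dlt[nz[1L]] > 0) usecomp[r] <- TRUE
  }
  target <- idx
  target[usecomp, ] <- comp[usecomp, ]
  stride <- cumprod(c(1, dims[-length(dims)]))
  as.integer(target %*% stride) + 1L
}

# indices of folded cells that can carry polymorphic mass
polymorphic_cells <- function(nhap) setdiff(unique(fold_map(nhap)), 1L)

#' @exportS3Method base::print
print.folded_sfs <- function(x, ...) {
  cat(sprintf("folded SFS (%s): haploid sizes (%s), %g polymorphic sites, %g monomorphic\n",
              x$provenance, paste(x$nhap, collapse = ", "), sum(x$counts),
              x$monomorphic))
  invisible(x)
}

#' Build the folded 3D SFS with per-block complete-data downsampling
#'
#' Divides the genome into unlinked blocks (default 2 Mb). Within each
#' block, each target population is represented by the requested number of
#' individuals chosen to minimize within-block missingness (ties broken by
#' sample order), and only SNPs with complete data in the chosen set are
#' retained. Retained sites monomorphic in the subsample feed the
#' monomorphic count. A companion spectrum holding one SNP per block
#' (uniform seeded choice) supports likelihood recomputation on unlinked
#' sites.
#'
#' @param cohort a [new_cohort()].
#' @param popmap a [population_map()].
#' @param pops character vector of population labels (order fixes the SFS
#'   axes).
#' @param block_bp block length in bp (default 2 Mb).
#' @param subsample diploid individuals per population (default 3, 6, 9).
#' @param seed integer seed for the unlinked SNP choice.
#' @return list with elements `all` and `unlinked`, both [folded_sfs()].
#' @export
build_folded_3dsfs <- function(cohort, popmap, pops, block_bp = 2e6,
                               subsample = c(3L, 6L, 9L), seed = 1L) {
  if (block_bp <= 0) stopf("block_bp must be positive")
  stopifnot(length(pops) == length(subsample))
  members <- lapply(pops, function(p) {
    s <- intersect(popmap$sample[popmap$population == p], cohort$samples)
    s
  })
  short <- lengths(members) < subsample
  if (any(short))
    stopf("population %s has fewer than %d members",
          paste(pops[short], collapse = ", "), subsample[which(short)[1]])
  nhap <- 2L * as.integer(subsample)
  dims <- nhap + 1L
  stride <- cumprod(c(1, dims[-length(dims)]))
  counts <- numeric(prod(dims))
  unlinked <- numeric(prod(dims))
  mono_all <- 0; mono_un <- 0

  with_seed(seed, {
    for (ch in unique(cohort$chrom)) {
      on_ch <- which(cohort$chrom == ch)
      blk <- floor(cohort$pos[on_ch] / block_bp)
      for (b in unique(blk)) {
        sel <- on_ch[blk == b]
        # per population: individuals with least missingness in this block
        chosen <- lapply(seq_along(pops), function(k) {
          cols <- match(members[[k]], cohort$samples)
          miss <- colSums(is.na(cohort$a1[sel, cols, drop = FALSE]))
          members[[k]][order(miss, seq_along(miss))[seq_len(subsample[k])]]
        })
        dos <- lapply(chosen, function(s) geno_dosage(cohort, s)[sel, , drop = FALSE])
        complete <- Reduce(`&`, lapply(dos, function(d) rowSums(is.na(d)) == 0L))
        if (!any(complete)) next
        dcount <- vapply(dos, function(d)
          rowSums(d[complete, , drop = FALSE]), numeric(sum(complete)))
        dcount <- matrix(dcount, ncol = length(pops))
        cell <- as.integer(dcount %*% stride) + 1L
        poly <- rowSums(dcount) > 0L & rowSums(dcount) < sum(nhap)
        tab <- table(cell[poly])
        counts[as.integer(names(tab))] <-
          counts[as.integer(names(tab))] + as.integer(tab)
        mono_all <- mono_all + sum(!poly)
        if (any(poly)) {
          pick <- sample(which(poly), 1L)
          unlinked[cell[pick]] <- unlinked[cell[pick]] + 1
        } else mono_un <- mono_un + 1
      }
    }
  })
  list(all = folded_sfs(counts, nhap, mono_all, "all_snps"),
       unlinked = folded_sfs(unlinked, nhap, mono_un, "unlinked_one_per_block"))
}

#' Composite log-likelihood of an observed folded SFS
#'
#' `lnL = sum over polymorphic cells of m_cell * log(p_cell)`, treating
#' sites as independent.
#'
#' @param observed a [folded_sfs()] (or plain count array).
#' @param expected probability array of matching dimensions (from
#'   [expected_sfs()]).
#' @return the composite log-likelihood (scalar).
#' @export
composite_loglik <- function(observed, expected) {
  m <- if (inherits(observed, "folded_sfs")) observed$counts else observed
  p <- if (inherits(expected, "folded_sfs")) expected$counts else expected
  if (!identical(dim(m), dim(p)))
    stopf("observed and expected cell structures differ")
  m <- as.vector(m); p <- as.vector(p)
  m[1L] <- 0  # monomorphic class is carried separately
  use <- m > 0
  if (any(p[use] == 0))
    stopf("expected probability 0 at an occupied cell")
  sum(m[use] * log(p[use]))
}

#' Write / read a folded SFS as plain text
#'
#' Format: a header `#n1 n2 ...` with the haploid sample sizes, a
#' `#monomorphic N` line, then `index count` lines (0-based row-major index
#' over the cell array).
#'
#' @param sfs a [folded_sfs()].
#' @param path file path.
#' @return the path (write) / a `folded_sfs` (read).
#' @export
write_sfs <- function(sfs, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("#", paste(sfs$nhap, collapse = " ")),
               paste0("#monomorphic ", format(sfs$monomorphic))), con)
  v <- as.vector(sfs$counts)
  writeLines(sprintf("%d %s", seq_along(v) - 1L, format(v)), con)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  nhap <- as.integer(strsplit(sub("^#", "", lines[1L]), " ")[[1L]])
  mono <- as.numeric(sub("^#monomorphic ", "", lines[2L]))
  body <- read.table(text = lines[-(1:2)], col.names = c("index", "count"))
  v <- numeric(prod(nhap + 1L))
  v[body$index + 1L] <- body$count
  out <- folded_sfs(v, nhap, 0, "file")
  out$monomorphic <- mono
  out
}
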