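#' Read a VCF into a cohort
#'
#' Parses a VCF (plain or gzipped) through vcfR and keeps only biallelic SNP
#' records; indels, multi-allelic records and records with non-SNP alleles
#' are dropped and counted in the `"drop_log"` attribute. Sample order
#' follows the VCF header; phase is taken from the `|` separator of the GT
#' field. VCF 1-based POS is converted to the 0-based internal convention.
#'
#' @param path path to a VCF file with a GT FORMAT field.
#' @param popmap_path optional path to a population map TSV
#'   (`sample<TAB>population[<TAB>role]`); every VCF sample must appear.
#' @return A list with elements `cohort` and (if `popmap_path` is given)
#'   `popmap`.
#' @export
read_vcf_cohort <- function(path, popmap_path = NULL) {
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0L) stopf("VCF contains no records")
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  is_snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  multi <- grepl(",", alt %||% "")
  drop_log <- c(multiallelic = sum(multi, na.rm = TRUE),
                indel_or_other = sum(!is_snp & !multi, na.rm = TRUE))
  keep <- which(is_snp & !multi)

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stopf("VCF has no GT field")
  gt <- gt[keep, , drop = FALSE]
  samples <- colnames(gt)
  gt[is.na(gt)] <- "./."
  phased <- matrix(grepl("|", gt, fixed = TRUE), nrow(gt), ncol(gt))
  a1c <- substr(gt, 1L, 1L)
  a2c <- substr(gt, 3L, 3L)
  bad <- !(a1c %in% c("0", "1", ".")) | !(a2c %in% c("0", "1", ".")) |
    nchar(gt) < 3L
  if (any(bad))
    stopf("malformed or non-diploid GT value (e.g. '%s')", gt[which(bad)[1]])
  a1 <- matrix(as.integer(replace(a1c, a1c == ".", NA)), nrow(gt), ncol(gt))
  a2 <- matrix(as.integer(replace(a2c, a2c == ".", NA)), nrow(gt), ncol(gt))
  half <- xor(is.na(a1), is.na(a2))
  a1[half] <- NA_integer_; a2[half] <- NA_integer_

  qual <- suppressWarnings(as.numeric(fix[keep, "QUAL"]))
  co <- new_cohort(chrom = fix[keep, "CHROM"],
                   pos = as.integer(fix[keep, "POS"]) - 1L,
                   ref = ref[keep], alt = alt[keep],
                   a1 = a1, a2 = a2, phased = phased,
                   samples = samples, qual = qual)
  attr(co, "drop_log") <- drop_log

  out <- list(cohort = co)
  if (!is.null(popmap_path)) {
    pm <- read_popmap(popmap_path)
    missing <- setdiff(samples, pm$sample)
    if (length(missing))
      stopf("sample(s) in VCF absent from population map: %s",
            paste(missing, collapse = ", "))
    out$popmap <- pm
  }
  out
}

#' Write a cohort as VCF 4.2
#'
#' Emits a plain-text VCF with 1-based POS; reading the file back with
#' [read_vcf_cohort()] returns identical genotypes, positions, alleles and
#' phase. Missing genotypes are written `./.`, phased calls use `|`.
#'
#' @param cohort a [new_cohort()].
#' @param popmap optional [population_map()] (recorded as header metadata).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf_cohort <- function(cohort, popmap = NULL, path) {
  stopifnot(inherits(cohort, "cohort"))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stopf("cannot write to %s", path)
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=lupuspg",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  for (ch in unique(cohort$chrom)) {
    len <- max(cohort$pos[cohort$chrom == ch]) + 1L
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ch, len), con)
  }
  if (!is.null(popmap))
    writeLines(sprintf("##population=<sample=%s,population=%s,role=%s>",
                       popmap$sample, popmap$population, popmap$role), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", cohort$samples), collapse = "\t"), con)
  sep <- ifelse(cohort$phased, "|", "/")
  gt <- matrix(paste0(ifelse(is.na(cohort$a1), ".", cohort$a1),
                      sep,
                      ifelse(is.na(cohort$a2), ".", cohort$a2)),
               n_sites(cohort), n_samples(cohort))
  gt[is.na(cohort$a1)] <- "./."
  lines <- paste(cohort$chrom, cohort$pos + 1L, ".", cohort$ref, cohort$alt,
                 ifelse(is.na(cohort$qual), ".",
                        formatC(cohort$qual, format = "g", digits = 8)),
                 "PASS", ".", "GT",
                 apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
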