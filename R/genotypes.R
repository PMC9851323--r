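#' Genotype matrix for biallelic SNPs
#'
#' The substrate of all population statistics: biallelic SNP genotypes for a
#' cohort, stored as a sites x individuals integer matrix with codes
#' 0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate and
#' `NA` = missing. Positions are 1-based (as in VCF) and strictly increasing
#' within each chromosome; all window arithmetic in this package is done on
#' 0-based half-open intervals, converting at the I/O boundary.
#'
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 1-based positions, strictly increasing within
#'   each chromosome.
#' @param ref,alt single-character reference/alternate alleles per site.
#' @param gt integer matrix (sites x individuals) of genotype codes.
#' @param samples character vector of unique individual ids (columns of `gt`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, gt, samples) {
  gt <- as.matrix(gt)
  n <- length(pos)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n,
            nrow(gt) == n, ncol(gt) == length(samples))
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  ord <- order(chrom, pos)
  if (is.unsorted(ord)) {
    chrom <- chrom[ord]; pos <- pos[ord]; ref <- ref[ord]; alt <- alt[ord]
    gt <- gt[ord, , drop = FALSE]
  }
  if (any(vapply(split(pos, chrom), function(p) anyDuplicated(p) > 0, logical(1))))
    stop("duplicated positions within a chromosome")
  dimnames(gt) <- list(NULL, samples)
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 gt = gt, samples = as.character(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d individuals on %d chromosome(s)\n",
              n_sites(x), length(x$samples), length(unique(x$chrom))))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm a `genotype_matrix`.
#' @export
n_sites <- function(gm) length(gm$pos)

#' Subset a genotype matrix by site index and/or individuals
#'
#' @param gm a `genotype_matrix`.
#' @param sites logical or integer index over sites.
#' @param samples character vector of individual ids to keep.
#' @return A `genotype_matrix`.
#' @export
subset_sites <- function(gm, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(gm))
  keep <- gm$samples
  if (!is.null(samples)) {
    missing <- setdiff(samples, gm$samples)
    if (length(missing)) stop("unknown individuals: ", paste(missing, collapse = ", "))
    keep <- samples
  }
  genotype_matrix(gm$chrom[sites], gm$pos[sites], gm$ref[sites], gm$alt[sites],
                  gm$gt[sites, keep, drop = FALSE], keep)
}

#' Combine genotype matrices (e.g. a sex chromosome plus autosomes)
#'
#' @param ... `genotype_matrix` objects sharing the same individuals.
#' @return A single `genotype_matrix`.
#' @export
combine_genotypes <- function(...) {
  gms <- list(...)
  stopifnot(length(gms) >= 1)
  samples <- gms[[1]]$samples
  for (g in gms) stopifnot(identical(g$samples, samples))
  genotype_matrix(
    unlist(lapply(gms, `[[`, "chrom")),
    unlist(lapply(gms, `[[`, "pos")),
    unlist(lapply(gms, `[[`, "ref")),
    unlist(lapply(gms, `[[`, "alt")),
    do.call(rbind, lapply(gms, `[[`, "gt")),
    samples)
}

.gt_code_from_string <- function(g) {
  # "0/1", "1|0", "./." etc -> 0/1/2/NA; anything non-biallelic handled upstream
  g <- sub(":.*", "", g)
  out <- rep(NA_integer_, length(g))
  out[g %in% c("0/0", "0|0")] <- 0L
  out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  out[g %in% c("1/1", "1|1")] <- 2L
  out
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Reads a VCF (v4.2) through VariantAnnotation, drops multiallelic and
#' non-SNP records (counts are reported via `message()`), and maps GT fields
#' to the four genotype codes; phased (`0|1`) and unphased (`0/1`) calls are
#' treated identically.
#'
#' @param path path to a VCF file.
#' @param region optional `"chrom"` or `"chrom:start-end"` string; records
#'   outside it are dropped after reading (plain-text VCFs carry no index).
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path, region = NULL) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  is_snp <- S4Vectors::elementNROWS(altl) == 1L & nchar(ref) == 1L
  alt <- rep(NA_character_, length(ref))
  alt[is_snp] <- as.character(unlist(altl[is_snp]))
  is_snp <- is_snp & !is.na(alt) & nchar(alt) == 1L & alt %in% c("A", "C", "G", "T")
  n_drop <- sum(!is_snp)
  if (n_drop > 0)
    message(sprintf("read_vcf: dropped %d multiallelic/non-SNP record(s)", n_drop))
  gtc <- VariantAnnotation::geno(vcf)$GT[is_snp, , drop = FALSE]
  gt <- matrix(.gt_code_from_string(gtc), nrow = nrow(gtc),
               dimnames = dimnames(gtc))
  gm <- genotype_matrix(as.character(GenomicRanges::seqnames(rr))[is_snp],
                        GenomicRanges::start(rr)[is_snp],
                        ref[is_snp], alt[is_snp], gt, colnames(gtc))
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
    if (length(m) == 0) stop("malformed region: ", region)
    keep <- gm$chrom == m[2]
    if (m[3] != "")
      keep <- keep & gm$pos >= as.integer(m[4]) & gm$pos <= as.integer(m[5])
    gm <- subset_sites(gm, keep)
  }
  gm
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits a minimal GT-only VCF (1-based positions) that round-trips losslessly
#' through [read_vcf()].
#'
#' @param gm a `genotype_matrix`.
#' @param path output file path.
#' @param contig_lengths optional named vector of chromosome lengths for the
#'   header `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=sexscan",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", gm$samples), collapse = "\t"))
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gts <- matrix("./.", nrow = n_sites(gm), ncol = length(gm$samples))
  ok <- !is.na(gm$gt)
  gts[ok] <- code[as.character(gm$gt[ok])]
  body <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", "PASS", ".", "GT",
                apply(gts, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Sex phenotype labels
#'
#' @param id character vector of individual ids.
#' @param sex character vector, `"M"` or `"F"` per individual.
#' @param excluded logical: individuals flagged as likely sex-reversed and
#'   excluded from sex-aware statistics.
#' @return A data frame of class `sex_labels` with columns id, sex, excluded.
#' @export
sex_labels <- function(id, sex, excluded = FALSE) {
  sex <- toupper(as.character(sex))
  sex[sex %in% c("MALE")] <- "M"
  sex[sex %in% c("FEMALE")] <- "F"
  stopifnot(all(sex %in% c("M", "F")), !anyDuplicated(id))
  out <- data.frame(id = as.character(id), sex = sex,
                    excluded = rep_len(as.logical(excluded), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("sex_labels", class(out))
  out
}

#' @rdname sex_labels
#' @param path two-column TSV (id, M|F), no header required.
#' @export
read_sex_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (tolower(df[1, 1]) %in% c("id", "individual")) df <- df[-1, , drop = FALSE]
  sex_labels(df[[1]], df[[2]])
}

#' @rdname sex_labels
#' @param sexes a `sex_labels` data frame.
#' @export
write_sex_table <- function(sexes, path) {
  utils::write.table(sexes[, c("id", "sex")], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ids of included individuals of one sex, checked against the matrix
included_ids <- function(gm, sexes, sex) {
  ids <- sexes$id[sexes$sex == sex & !sexes$excluded]
  missing <- setdiff(ids, gm$samples)
  if (length(missing))
    stop("sex labels refer to unknown individuals: ", paste(missing, collapse = ", "))
  ids
}

#' Filter sites on minor allele frequency
#'
#' Retains biallelic sites whose sample minor allele frequency, computed over
#' non-missing alleles, exceeds `maf_min` (default 0.05, so a MAF of exactly
#' 0.05 is removed). Monomorphic sites are always removed.
#'
#' @param gm a `genotype_matrix`.
#' @param maf_min minor-allele-frequency threshold.
#' @return The filtered `genotype_matrix`.
#' @export
filter_sites <- function(gm, maf_min = 0.05) {
  alt <- rowSums(gm$gt, na.rm = TRUE)
  tot <- 2L * rowSums(!is.na(gm$gt))
  p <- ifelse(tot > 0, alt / tot, NA_real_)
  maf <- pmin(p, 1 - p)
  subset_sites(gm, !is.na(maf) & maf > maf_min)
}
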