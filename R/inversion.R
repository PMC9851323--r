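#' Genotype candidate inversions from read-pair orientation fractions
#'
#' Classifies each candidate region from the fraction f = n_support/n_total
#' of informative read pairs (same-orientation, long-distance pairs) that
#' support an inversion: f below (or exactly at) 0.25 is homozygous for the
#' reference arrangement, 0.25 < f < 1 is a candidate heterozygote, and
#' f = 1 is called homozygous inverted (the two boundary conventions are
#' package choices; the source rule defines only the open intervals).
#' Regions with no informative pairs are uninformative. Classification is
#' monotone in f.
#'
#' @param n_support read pairs supporting the inversion (vectorized).
#' @param n_total informative read pairs.
#' @param het_lo lower bound of the heterozygote band (default 0.25).
#' @return Data frame (n_support, n_total, fraction, genotype) with genotype
#'   in {"homRef", "het", "homInv", "uninformative"}.
#' @export
genotype_inversion <- function(n_support, n_total, het_lo = 0.25) {
  stopifnot(length(n_support) == length(n_total),
            all(n_support >= 0), all(n_total >= 0),
            all(n_support <= n_total))
  f <- ifelse(n_total > 0, n_support / n_total, NA_real_)
  geno <- rep("uninformative", length(f))
  geno[!is.na(f) & f <= het_lo] <- "homRef"
  geno[!is.na(f) & f > het_lo & f < 1] <- "het"
  geno[!is.na(f) & f == 1] <- "homInv"
  data.frame(n_support = n_support, n_total = n_total, fraction = f,
             genotype = geno, stringsAsFactors = FALSE)
}

#' Read a read-pair inversion evidence table and genotype it
#'
#' @param path TSV with columns chrom, start, end, n_support, n_total.
#' @param het_lo passed to [genotype_inversion()].
#' @return The evidence table with added fraction and genotype columns.
#' @export
read_inversion_evidence <- function(path, het_lo = 0.25) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "n_support", "n_total") %in% names(ev)))
  cbind(ev[c("chrom", "start", "end")],
        genotype_inversion(ev$n_support, ev$n_total, het_lo))
}
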