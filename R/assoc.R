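#' Genome-wide Bonferroni significance threshold
#'
#' The genome-wide threshold is alpha divided by the number of SNPs tested;
#' with the SNP counts of a whole-genome resequencing panel this lands around
#' 1e-8 (e.g. 0.05 / 6,115,914 = 8.18e-9).
#'
#' @param n_snps number of SNPs tested (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @return The per-test threshold alpha / n_snps.
#' @export
bonferroni_threshold <- function(n_snps, alpha = 0.05) {
  stopifnot(length(n_snps) == 1, n_snps >= 1)
  alpha / n_snps
}

# two-sided Fisher P for 2x2 tables given as rows of (a,b,c,d); memoized over
# unique tables since allele-count tables repeat heavily across sites
fisher_p_2x2 <- function(tab) {
  key <- paste(tab[, 1], tab[, 2], tab[, 3], tab[, 4])
  uk <- !duplicated(key)
  pu <- apply(tab[uk, , drop = FALSE], 1, function(x)
    stats::fisher.test(matrix(x, 2, byrow = TRUE))$p.value)
  names(pu) <- key[uk]
  unname(pu[key])
}

# genotypic chi-square on the 2 x k table of genotype-class counts by sex
# (classes with zero total dropped); P is NA when < 2 classes remain
chisq_p_genotypic <- function(gm, males, females) {
  gm_m <- gm$gt[, males, drop = FALSE]
  gm_f <- gm$gt[, females, drop = FALSE]
  cnt <- function(g, v) rowSums(g == v, na.rm = TRUE)
  m <- cbind(cnt(gm_m, 0L), cnt(gm_m, 1L), cnt(gm_m, 2L))
  f <- cbind(cnt(gm_f, 0L), cnt(gm_f, 1L), cnt(gm_f, 2L))
  vapply(seq_len(nrow(m)), function(i) {
    tab <- rbind(m[i, ], f[i, ])
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2 || any(rowSums(tab) == 0)) return(NA_real_)
    exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - exp)^2 / exp)
    stats::pchisq(stat, df = (nrow(tab) - 1) * (ncol(tab) - 1),
                  lower.tail = FALSE)
  }, numeric(1))
}

#' Per-site sex-association scan
#'
#' Tests each SNP for association with phenotypic sex. The default is a
#' two-sided Fisher exact test on the 2 x 2 allele-count table (sex x
#' ref/alt); a genotypic chi-square on the 2 x 3 genotype table is available
#' as an alternative. Significance uses the genome-wide Bonferroni threshold
#' over all tested SNPs. The paper-scale alternative -- a kinship-corrected
#' mixed model on imputed, phased genotypes -- is deliberately out of scope
#' here; see the methods vignette.
#'
#' @param gm a `genotype_matrix` (filtered).
#' @param sexes a [sex_labels()] data frame (>= 2 individuals per sex).
#' @param test `"fisher_allelic"` (default), `"chisq_genotypic"`, or
#'   `"chisq_allelic"` (the same 2 x 2 allele table as the default, tested
#'   asymptotically; the exact test is conservative at finite sample sizes
#'   while this variant is calibrated under label permutation).
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @return An object of class `assoc_result`: data frame (chrom, pos, p,
#'   significant) with attributes `threshold`, `test`, `n_tested`.
#' @export
assoc_scan <- function(gm, sexes, test = c("fisher_allelic", "chisq_genotypic",
                                           "chisq_allelic"),
                       alpha = 0.05) {
  test <- match.arg(test)
  males <- included_ids(gm, sexes, "M")
  females <- included_ids(gm, sexes, "F")
  if (length(males) < 2 || length(females) < 2)
    stop("need >= 2 included individuals per sex")
  if (test %in% c("fisher_allelic", "chisq_allelic")) {
    gm_m <- gm$gt[, males, drop = FALSE]
    gm_f <- gm$gt[, females, drop = FALSE]
    alt_m <- rowSums(gm_m, na.rm = TRUE)
    tot_m <- 2L * rowSums(!is.na(gm_m))
    alt_f <- rowSums(gm_f, na.rm = TRUE)
    tot_f <- 2L * rowSums(!is.na(gm_f))
    p <- rep(NA_real_, n_sites(gm))
    ok <- tot_m > 0 & tot_f > 0
    tab <- cbind(tot_m - alt_m, alt_m, tot_f - alt_f, alt_f)[ok, , drop = FALSE]
    p[ok] <- if (test == "fisher_allelic") fisher_p_2x2(tab) else {
      e <- cbind((tab[, 1] + tab[, 2]) * (tab[, 1] + tab[, 3]),
                 (tab[, 1] + tab[, 2]) * (tab[, 2] + tab[, 4]),
                 (tab[, 3] + tab[, 4]) * (tab[, 1] + tab[, 3]),
                 (tab[, 3] + tab[, 4]) * (tab[, 2] + tab[, 4])) / rowSums(tab)
      stat <- rowSums((tab - e)^2 / e)
      stats::pchisq(stat, df = 1, lower.tail = FALSE)
    }
  } else {
    p <- chisq_p_genotypic(gm, males, females)
  }
  thr <- bonferroni_threshold(sum(!is.na(p)), alpha)
  out <- data.frame(chrom = gm$chrom, pos = gm$pos, p = p,
                    significant = !is.na(p) & p < thr,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  attr(out, "test") <- test
  attr(out, "n_tested") <- sum(!is.na(p))
  class(out) <- c("assoc_result", class(out))
  out
}

#' Heterogamety call from counts of male- vs female-heterozygous sites
#'
#' XY is called when the male-het share m/(m+f) reaches `min_fraction` and an
#' exact binomial test rejects 0.5 at `alpha`; ZW is the mirror call; any
#' other outcome (e.g. 248 male-het vs 171 female-het sites, a 59% share) is
#' `undetermined`.
#'
#' @param n_male_het,n_female_het counts of significant sites classified as
#'   heterozygous-in-males resp. heterozygous-in-females.
#' @param min_fraction minimum share for a call (default 0.8).
#' @param alpha binomial test level (default 0.01).
#' @return A list of class `heterogamety_call`: counts, fraction, binomial P
#'   and call in {"XY","ZW","undetermined"}.
#' @export
heterogamety_from_counts <- function(n_male_het, n_female_het,
                                     min_fraction = 0.8, alpha = 0.01) {
  m <- n_male_het; f <- n_female_het
  if (m + f == 0) {
    warning("zero classified significant sites; heterogamety undetermined")
    out <- list(n_male_het = 0L, n_female_het = 0L, fraction = NA_real_,
                p = NA_real_, call = "undetermined")
  } else {
    frac <- m / (m + f)
    p_xy <- stats::pbinom(m - 1, m + f, 0.5, lower.tail = FALSE)  # P(>= m)
    p_zw <- stats::pbinom(f - 1, m + f, 0.5, lower.tail = FALSE)
    call <- "undetermined"
    if (frac >= min_fraction && p_xy < alpha) call <- "XY"
    else if ((1 - frac) >= min_fraction && p_zw < alpha) call <- "ZW"
    out <- list(n_male_het = as.integer(m), n_female_het = as.integer(f),
                fraction = frac, p = if (frac >= 0.5) p_xy else p_zw,
                call = call)
  }
  class(out) <- "heterogamety_call"
  out
}

#' @export
print.heterogamety_call <- function(x, ...) {
  cat(sprintf("heterogamety: %s (male-het %d, female-het %d, fraction %.3f, P %.3g)\n",
              x$call, x$n_male_het, x$n_female_het,
              ifelse(is.na(x$fraction), NA, x$fraction), x$p))
  invisible(x)
}

#' Infer heterogamety from significant sites of an association scan
#'
#' Significant sites are classified by which sex is predominantly
#' heterozygous (at least `frac` of one sex het and `frac` of the other hom;
#' the default 0.5 encodes "most individuals") and the counts are passed to
#' [heterogamety_from_counts()].
#'
#' @inheritParams assoc_scan
#' @param assoc an `assoc_result` from [assoc_scan()].
#' @param frac per-site class fraction (default 0.5 = "most").
#' @param p_max optional suggestive P cutoff; when set, sites with
#'   `p < p_max` are classified instead of only Bonferroni-significant ones
#'   (useful before sex-reversal exclusion, when mislabeled individuals
#'   depress the exact-test P-values).
#' @param top_k optional count; when set, the `top_k` most strongly
#'   associated sites (ties broken by (P, chrom, position)) are classified,
#'   regardless of their significance. This is the most robust pre-exclusion
#'   selection: with no sex-linked region the top sites are association
#'   noise, their classes balance, and the call comes back undetermined.
#'   `top_k` takes precedence over `p_max`.
#' @inheritParams heterogamety_from_counts
#' @return A `heterogamety_call`.
#' @export
heterogamety_call <- function(gm, sexes, assoc, frac = 0.5,
                              min_fraction = 0.8, alpha = 0.01,
                              p_max = NULL, top_k = NULL) {
  sig <- if (!is.null(top_k)) {
    ok <- which(!is.na(assoc$p))
    ok[order(assoc$p[ok], assoc$chrom[ok], assoc$pos[ok])][
      seq_len(min(top_k, length(ok)))]
  } else if (is.null(p_max)) which(assoc$significant)
  else which(!is.na(assoc$p) & assoc$p < p_max)
  if (length(sig) == 0) return(heterogamety_from_counts(0L, 0L,
                                                        min_fraction, alpha))
  cls <- site_het_class(subset_sites(gm, sig), sexes, frac)
  heterogamety_from_counts(sum(cls == "male_het"), sum(cls == "female_het"),
                           min_fraction, alpha)
}

#' Detect likely sex-reversed individuals
#'
#' Takes the `top_k` most strongly sex-associated SNPs (ties broken by
#' (P, chrom, position) for determinism) and flags any individual whose
#' non-missing genotypes at those sites match the opposite sex's expected
#' pattern in at least `match_frac` of sites. Under XY heterogamety the
#' expected pattern is heterozygous for males and homozygous for females, so
#' a phenotypic male is flagged when it is homozygous at nearly all top
#' sites; under ZW the patterns mirror. Detection runs once (single
#' exclusion pass, no iteration).
#'
#' @inheritParams heterogamety_call
#' @param call a `heterogamety_call`; must not be `"undetermined"`.
#' @param top_k number of top-associated SNPs to genotype (default 100).
#' @param match_frac fraction of opposite-pattern sites needed to flag.
#' @return Data frame of class `reversal_report` (id, sex, n_sites,
#'   frac_opposite, flagged).
#' @export
detect_sex_reversals <- function(gm, sexes, assoc, call, top_k = 100,
                                 match_frac = 0.9) {
  if (call$call == "undetermined")
    stop("heterogamety undetermined; cannot define expected genotype patterns")
  ok <- which(!is.na(assoc$p))
  if (length(ok) < 1) stop("no tested sites")
  ord <- ok[order(assoc$p[ok], assoc$chrom[ok], assoc$pos[ok])]
  top <- ord[seq_len(min(top_k, length(ord)))]
  g <- gm$gt[top, sexes$id, drop = FALSE]
  het_frac <- colSums(g == 1L, na.rm = TRUE) / colSums(!is.na(g))
  # under XY: het-sex = male; under ZW: het-sex = female
  het_sex <- if (call$call == "XY") "M" else "F"
  frac_opp <- ifelse(sexes$sex == het_sex, 1 - het_frac, het_frac)
  out <- data.frame(id = sexes$id, sex = sexes$sex,
                    n_sites = colSums(!is.na(g)),
                    frac_opposite = frac_opp,
                    flagged = !is.na(frac_opp) & frac_opp >= match_frac,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("reversal_report", class(out))
  out
}

#' Mark flagged sex-reversed individuals as excluded
#'
#' @param sexes a [sex_labels()] data frame.
#' @param report a `reversal_report` from [detect_sex_reversals()].
#' @return `sexes` with `excluded = TRUE` for flagged individuals.
#' @export
apply_reversals <- function(sexes, report) {
  sexes$excluded <- sexes$excluded | sexes$id %in% report$id[report$flagged]
  sexes
}

#' RAD-marker presence/absence sex association
#'
#' A marker is scored present in an individual when its depth reaches
#' `min_depth` (default 5, the radsex `-d 5` convention). Markers absent in
#' all individuals are dropped. Each remaining marker is tested on the 2 x 2
#' presence x sex table -- chi-square, falling back to the Fisher exact test
#' for small samples (any expected count < 5 or total n < 40) -- and declared
#' significant under Bonferroni correction over the tested markers.
#' Significant markers are classified `male_linked` or `female_linked` by
#' which sex carries them more often.
#'
#' @param depth integer matrix or data frame, markers x individuals; column
#'   names are individual ids.
#' @param sexes a [sex_labels()] data frame.
#' @param min_depth presence threshold (default 5).
#' @param alpha family-wise error rate (default 0.05).
#' @return Data frame (marker, n_male_present, n_female_present, p,
#'   significant, class) with attribute `threshold`.
#' @export
rad_marker_assoc <- function(depth, sexes, min_depth = 5, alpha = 0.05) {
  depth <- as.matrix(depth)
  if (any(depth < 0) || any(depth != floor(depth)))
    stop("depths must be non-negative integers")
  males <- sexes$id[sexes$sex == "M" & !sexes$excluded]
  females <- sexes$id[sexes$sex == "F" & !sexes$excluded]
  pres <- depth >= min_depth
  keep <- rowSums(pres) > 0
  pres <- pres[keep, , drop = FALSE]
  pm <- rowSums(pres[, males, drop = FALSE])
  pf <- rowSums(pres[, females, drop = FALSE])
  nm <- length(males); nf <- length(females)
  n_tot <- nm + nf
  p <- vapply(seq_along(pm), function(i) {
    tab <- matrix(c(pm[i], nm - pm[i], pf[i], nf - pf[i]), 2, byrow = TRUE)
    exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp < 5) || n_tot < 40) {
      stats::fisher.test(tab)$p.value
    } else {
      stats::chisq.test(tab, correct = FALSE)$p.value
    }
  }, numeric(1))
  thr <- bonferroni_threshold(length(p), alpha)
  sig <- p < thr
  cls <- rep(NA_character_, length(p))
  cls[sig] <- ifelse(pm[sig] / nm >= pf[sig] / nf, "male_linked", "female_linked")
  out <- data.frame(marker = rownames(pres) %||% as.character(which(keep)),
                    n_male_present = pm, n_female_present = pf, p = p,
                    significant = sig, class = cls,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "threshold") <- thr
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
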