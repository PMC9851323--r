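#' Per-site observed/expected heterozygosity and F_IS
#'
#' F_IS = 1 - Ho/He with He = 2*p*(1-p) from the sample allele frequency
#' (no small-sample correction, matching the classical Nei definition).
#' Strongly negative values flag systematic heterozygote excess, the
#' signature of Y-linked sites in males. Monomorphic sites (He = 0) and
#' all-missing sites yield `NA`.
#'
#' @param gm a `genotype_matrix`.
#' @param subset optional character vector of individual ids (e.g. males
#'   only); defaults to all individuals.
#' @return A data frame (chrom, pos, n, p, ho, he, fis), one row per site.
#' @export
fis_per_site <- function(gm, subset = NULL) {
  g <- if (is.null(subset)) gm$gt else {
    missing <- setdiff(subset, gm$samples)
    if (length(missing)) stop("unknown individuals: ", paste(missing, collapse = ", "))
    gm$gt[, subset, drop = FALSE]
  }
  n <- rowSums(!is.na(g))
  alt <- rowSums(g, na.rm = TRUE)
  p <- ifelse(n > 0, alt / (2 * n), NA_real_)
  ho <- ifelse(n > 0, rowSums(g == 1L, na.rm = TRUE) / n, NA_real_)
  he <- 2 * p * (1 - p)
  fis <- ifelse(!is.na(he) & he > 0, 1 - ho / he, NA_real_)
  data.frame(chrom = gm$chrom, pos = gm$pos, n = n, p = p,
             ho = ho, he = he, fis = fis, stringsAsFactors = FALSE)
}

# Weir & Cockerham (1984) per-site variance components for two populations
# (here: the sexes). Returns a, b, c and theta = a/(a+b+c); sites where any
# population has < 2 non-missing genotypes, or where a+b+c == 0, give NA.
wc_fst_components <- function(gm, sexes) {
  males <- included_ids(gm, sexes, "M")
  females <- included_ids(gm, sexes, "F")
  pops <- list(gm$gt[, males, drop = FALSE], gm$gt[, females, drop = FALSE])
  r <- 2
  ns <- n_sites(gm)
  ni <- vapply(pops, function(g) rowSums(!is.na(g)), numeric(ns))
  dim(ni) <- c(ns, r)
  pi <- vapply(pops, function(g) rowSums(g, na.rm = TRUE), numeric(ns))
  dim(pi) <- c(ns, r); pi <- pi / (2 * ni)
  hi <- vapply(pops, function(g) rowSums(g == 1L, na.rm = TRUE), numeric(ns))
  dim(hi) <- c(ns, r); hi <- hi / ni
  usable <- ni[, 1] >= 2 & ni[, 2] >= 2
  nbar <- rowMeans(ni)
  nc <- (r * nbar - rowSums(ni^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(ni * pi) / (r * nbar)
  s2 <- rowSums(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(ni * hi) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  theta <- ifelse(usable & (a + b + cc) != 0, a / (a + b + cc), NA_real_)
  a[!usable] <- NA_real_; b[!usable] <- NA_real_; cc[!usable] <- NA_real_
  data.frame(chrom = gm$chrom, pos = gm$pos, a = a, b = b, c = cc,
             fst = theta, stringsAsFactors = FALSE)
}

#' Per-site Weir-Cockerham F_ST between the sexes
#'
#' @param gm a `genotype_matrix`.
#' @param sexes a [sex_labels()] data frame; excluded individuals are left
#'   out of both populations.
#' @return Data frame (chrom, pos, a, b, c, fst) of WC84 variance components
#'   and the per-site estimate a/(a+b+c); negative estimates are retained.
#' @export
site_fst <- function(gm, sexes) wc_fst_components(gm, sexes)

#' Windowed F_ST between the sexes
#'
#' Window value is the arithmetic mean of per-site Weir-Cockerham estimates
#' (`mode = "mean"`, the default, matching "mean F_ST" scans) or the
#' ratio-of-sums of variance components sum(a)/sum(a+b+c)
#' (`mode = "weighted"`, the vcftools weighted variant) for sensitivity
#' checks. Windows with zero usable sites are missing.
#'
#' @inheritParams site_fst
#' @param windows window data frame from [make_windows()].
#' @param mode `"mean"` or `"weighted"`.
#' @return `windows` with an added `fst_mean` (or `fst_weighted`) column.
#' @export
fst_windowed <- function(gm, sexes, windows, mode = c("mean", "weighted")) {
  mode <- match.arg(mode)
  comp <- wc_fst_components(gm, sexes)
  idx <- sites_in_windows(gm$chrom, gm$pos, windows)
  if (mode == "mean") {
    windows$fst_mean <- vapply(idx, function(i) {
      v <- comp$fst[i]; v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else mean(v)
    }, numeric(1))
  } else {
    windows$fst_weighted <- vapply(idx, function(i) {
      a <- comp$a[i]; d <- comp$a[i] + comp$b[i] + comp$c[i]
      ok <- !is.na(d)
      if (!any(ok) || sum(d[ok]) == 0) NA_real_ else sum(a[ok]) / sum(d[ok])
    }, numeric(1))
  }
  windows
}

# per-site sex-heterozygosity classification: class (a) sites het in >= frac
# of included, non-missing males AND hom in >= frac of included females;
# class (b) is the mirror. Returns a factor-free character vector.
site_het_class <- function(gm, sexes, frac = 0.9) {
  males <- included_ids(gm, sexes, "M")
  females <- included_ids(gm, sexes, "F")
  if (length(males) == 0 || length(females) == 0)
    stop("no included individuals of one sex")
  gm_m <- gm$gt[, males, drop = FALSE]
  gm_f <- gm$gt[, females, drop = FALSE]
  nm <- rowSums(!is.na(gm_m)); nf <- rowSums(!is.na(gm_f))
  het_m <- rowSums(gm_m == 1L, na.rm = TRUE) / nm
  het_f <- rowSums(gm_f == 1L, na.rm = TRUE) / nf
  cls <- rep("none", n_sites(gm))
  ok <- nm > 0 & nf > 0
  cls[ok & het_m >= frac & (1 - het_f) >= frac] <- "male_het"
  cls[ok & het_f >= frac & (1 - het_m) >= frac] <- "female_het"
  cls
}

#' Windowed densities of sex-specific heterozygous sites
#'
#' Counts, per window, the sites that are heterozygous in at least `frac`
#' of included males and homozygous in at least `frac` of included females
#' (`het_density_mf`), and the mirror class (`het_density_fm`). `frac = 1`
#' reproduces the strict all-males-het / all-females-hom criterion used to
#' select genes for X-Y divergence. Sex-reversed individuals must already be
#' flagged `excluded` in `sexes` (see [detect_sex_reversals()]).
#'
#' @inheritParams fst_windowed
#' @param frac fraction of individuals of each sex required to show the
#'   class-defining genotype.
#' @return `windows` with added `het_density_mf` / `het_density_fm` counts.
#' @export
sex_het_site_classes <- function(gm, sexes, windows, frac = 0.9) {
  cls <- site_het_class(gm, sexes, frac)
  idx <- sites_in_windows(gm$chrom, gm$pos, windows)
  windows$het_density_mf <- vapply(idx, function(i) sum(cls[i] == "male_het"), integer(1))
  windows$het_density_fm <- vapply(idx, function(i) sum(cls[i] == "female_het"), integer(1))
  windows
}

#' Between-sex normalized coverage ratio per window
#'
#' Each sex's per-window mean depth is normalized by that sex's genome-wide
#' median, and the ratio male/female is reported. A fully degenerate Y gives
#' a ratio near 0.5 (coverage twice as high in the homogametic sex); windows
#' with zero female depth are missing.
#'
#' @param depth data frame with columns chrom, start, end plus one numeric
#'   depth column per individual (the simulator's depth-track format).
#' @param sexes a [sex_labels()] data frame.
#' @return Data frame (chrom, start, end, cov_ratio).
#' @export
coverage_ratio <- function(depth, sexes) {
  males <- sexes$id[sexes$sex == "M" & !sexes$excluded]
  females <- sexes$id[sexes$sex == "F" & !sexes$excluded]
  missing <- setdiff(c(males, females), names(depth))
  if (length(missing)) stop("depth track lacks individuals: ",
                            paste(missing, collapse = ", "))
  dm <- rowMeans(depth[, males, drop = FALSE])
  df <- rowMeans(depth[, females, drop = FALSE])
  norm_m <- dm / stats::median(dm)
  norm_f <- df / stats::median(df)
  ratio <- ifelse(df > 0, norm_m / norm_f, NA_real_)
  if (anyNA(ratio))
    message(sprintf("coverage_ratio: %d window(s) with zero female depth set to NA",
                    sum(is.na(ratio))))
  data.frame(chrom = depth$chrom, start = depth$start, end = depth$end,
             cov_ratio = ratio, stringsAsFactors = FALSE)
}
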