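#' Configuration for the sex-chromosome population simulator
#'
#' Defaults describe a captive-population resequencing design of the kind
#' the scan is built for: 30 males + 29 females at ~15x depth on a 26.1 Mb
#' chromosome whose first 1.28 Mb are pseudoautosomal and whose remainder is
#' sex-linked, with 15% sex-reversed individuals and occasional X-Y
#' exchange. `theta` is the per-bp expected heterozygosity of background
#' polymorphism; with allele frequencies uniform on [0.05, 0.95] (mean
#' per-SNP heterozygosity 0.365) the default theta of 3.65e-4 places
#' background SNPs at 1 per kb, keeping 50 kb windows well populated.
#' `xy_divergence` is the per-bp probability that an SLR site carries a
#' fixed X/Y difference.
#'
#' @param n_males,n_females cohort sizes (>= 1).
#' @param chrom_length chromosome length in bp.
#' @param par_intervals list of `c(start, end)` 0-based half-open PAR
#'   intervals.
#' @param slr_interval `c(start, end)` sex-linked region, disjoint from the
#'   PARs.
#' @param theta per-bp expected background heterozygosity.
#' @param xy_divergence per-bp fixed X/Y difference probability in the SLR.
#' @param reversal_rate probability an individual's genotypic sex is
#'   opposite to its phenotypic label.
#' @param leak_rate per-genotypic-male probability that a terminal SLR block
#'   has recombined onto the X (single crossover, uniform breakpoint).
#' @param mean_depth mean sequencing depth (reads).
#' @param degenerate_interval optional `c(start, end)` sub-interval of the
#'   SLR in which the Y is fully degenerate (male depth halved).
#' @param chrom chromosome name.
#' @param seed integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_males = 30, n_females = 29, chrom_length = 26.1e6,
                       par_intervals = list(c(0, 1.28e6)),
                       slr_interval = c(1.28e6, 26.1e6),
                       theta = 3.65e-4, xy_divergence = 0.002,
                       reversal_rate = 0.15, leak_rate = 0.05,
                       mean_depth = 15, degenerate_interval = NULL,
                       chrom = "chrSex", seed = 1L) {
  stopifnot(n_males >= 1, n_females >= 1, chrom_length > 0,
            theta >= 0, xy_divergence >= 0 && xy_divergence <= 1,
            reversal_rate >= 0 && reversal_rate <= 1,
            leak_rate >= 0 && leak_rate <= 1, mean_depth > 0)
  ivs <- c(par_intervals, list(slr_interval))
  for (iv in ivs)
    if (length(iv) != 2 || iv[1] < 0 || iv[2] > chrom_length || iv[1] >= iv[2])
      stop("intervals must be non-empty [start, end) within [0, chrom_length)")
  ivs <- ivs[order(vapply(ivs, `[`, numeric(1), 1))]
  for (i in seq_len(length(ivs) - 1))
    if (ivs[[i]][2] > ivs[[i + 1]][1]) stop("PAR and SLR intervals overlap")
  if (!is.null(degenerate_interval))
    stopifnot(degenerate_interval[1] >= slr_interval[1],
              degenerate_interval[2] <= slr_interval[2])
  structure(list(n_males = n_males, n_females = n_females,
                 chrom_length = chrom_length, par_intervals = par_intervals,
                 slr_interval = slr_interval, theta = theta,
                 xy_divergence = xy_divergence, reversal_rate = reversal_rate,
                 leak_rate = leak_rate, mean_depth = mean_depth,
                 degenerate_interval = degenerate_interval,
                 chrom = chrom, seed = as.integer(seed)),
            class = "sim_config")
}

# mean per-SNP heterozygosity of the Uniform(0.05, 0.95) frequency model
.MEAN_HE_UNIF <- 0.365

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  force(expr)
}

#' Simulate a diploid population with a planted sex-linked region
#'
#' Generates biallelic SNP genotypes for `n_males + n_females` individuals
#' on one chromosome carrying pseudoautosomal region(s) and a sex-linked
#' region (SLR). Background SNPs are placed by a Poisson process and drawn
#' in Hardy-Weinberg proportions at allele frequencies uniform on
#' [0.05, 0.95] (so the MAF > 0.05 filter is non-trivially exercised).
#' Inside the SLR, fixed X/Y difference sites are heterozygous in every
#' genotypic male and homozygous reference in every genotypic female;
#' sex-reversed individuals carry the opposite sex's genotypic pattern, and
#' "leaked" genotypic males revert to X/X over a contiguous terminal block
#' of the SLR (one crossover, uniform breakpoint). Per-individual depth per
#' 50 kb window is Poisson(mean_depth), halved for males over any declared
#' degenerate-Y interval. Identical seeds give identical output.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_result`: `gm` (genotype_matrix), `sexes`
#'   (phenotypic [sex_labels()]), `depth` (window x individual data frame),
#'   and `truth` (boundaries, reversed/leaked individuals, per-site class,
#'   xy_divergence used).
#' @export
simulate_sexchrom_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    L <- config$chrom_length
    slr <- config$slr_interval
    n <- config$n_males + config$n_females
    ids <- c(sprintf("M%02d", seq_len(config$n_males)),
             sprintf("F%02d", seq_len(config$n_females)))
    pheno <- rep(c("M", "F"), c(config$n_males, config$n_females))
    reversed <- stats::runif(n) < config$reversal_rate
    geno_male <- (pheno == "M") != reversed   # genotypic sex
    # site positions: background Poisson process + fixed X/Y differences
    n_bg <- stats::rpois(1, L * config$theta / .MEAN_HE_UNIF)
    pos_bg <- sort(sample.int(L, min(n_bg, L)))
    n_fix <- stats::rpois(1, (slr[2] - slr[1]) * config$xy_divergence)
    pos_fix <- slr[1] + sort(sample.int(slr[2] - slr[1], min(n_fix, slr[2] - slr[1])))
    pos_fix <- setdiff(pos_fix, pos_bg)
    pos <- sort(c(pos_bg, pos_fix))
    is_fix <- pos %in% pos_fix
    ns <- length(pos)
    gt <- matrix(NA_integer_, ns, n, dimnames = list(NULL, ids))
    # background sites: HWE at p ~ U(0.05, 0.95)
    p_bg <- stats::runif(sum(!is_fix), 0.05, 0.95)
    gt[!is_fix, ] <- stats::rbinom(sum(!is_fix) * n, 2,
                                   rep(p_bg, times = n))
    # fixed X/Y differences: genotypic males X/Y het, genotypic females X/X
    gt[is_fix, ] <- rep(ifelse(geno_male, 1L, 0L), each = sum(is_fix))
    # X-Y exchange: terminal SLR block of a leaked genotypic male reverts to X/X
    leaked <- geno_male & stats::runif(n) < config$leak_rate
    leak_from <- rep(NA_real_, n)
    for (j in which(leaked)) {
      b <- stats::runif(1, slr[1], slr[2])
      leak_from[j] <- b
      gt[is_fix & pos > b, j] <- 0L
    }
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, ns, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))
    gm <- genotype_matrix(rep(config$chrom, ns), pos, ref, alt, gt, ids)
    sexes <- sex_labels(ids, pheno)
    # depth: Poisson(mean_depth) per individual per non-overlapping 50 kb window
    dw <- make_windows(stats::setNames(L, config$chrom),
                       window_spec(50000L, 50000L))
    mu <- matrix(config$mean_depth, nrow(dw), n)
    if (!is.null(config$degenerate_interval)) {
      di <- config$degenerate_interval
      ov <- pmax(0, pmin(dw$end, di[2]) - pmax(dw$start, di[1])) /
        (dw$end - dw$start)
      mu[, geno_male] <- config$mean_depth * (1 - 0.5 * ov)
    }
    depth <- cbind(dw, matrix(stats::rpois(length(mu), mu), nrow(dw), n,
                              dimnames = list(NULL, ids)))
    boundaries <- sort(unique(c(unlist(config$par_intervals), slr)))
    boundaries <- boundaries[boundaries > 0 & boundaries < L]
    truth <- list(chrom = config$chrom, chrom_length = L,
                  par_intervals = config$par_intervals, slr_interval = slr,
                  boundaries = boundaries,
                  reversed_individuals = ids[reversed],
                  leaked_individuals = ids[leaked],
                  leak_from = leak_from[leaked],
                  site_class = ifelse(is_fix, "SLR_fixed_difference",
                                      "background"),
                  positions = pos,
                  xy_divergence_used = config$xy_divergence)
    structure(list(gm = gm, sexes = sexes, depth = depth, truth = truth,
                   config = config), class = "sim_result")
  })
}

#' Write simulator outputs to disk
#'
#' Emits VCF v4.2, a sex table TSV, a depth TSV, a truth BED (0-based
#' half-open region classes) and a truth JSON.
#'
#' @param sim a `sim_result`.
#' @param dir output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim$config
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             sex = file.path(dir, "sex.tsv"),
             depth = file.path(dir, "depth.tsv"),
             bed = file.path(dir, "truth.bed"),
             json = file.path(dir, "truth.json"))
  write_vcf(sim$gm, paths["vcf"],
            stats::setNames(cfg$chrom_length, cfg$chrom))
  write_sex_table(sim$sexes, paths["sex"])
  utils::write.table(sim$depth, paths["depth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bed <- rbind(
    do.call(rbind, lapply(cfg$par_intervals, function(iv)
      data.frame(chrom = cfg$chrom, start = iv[1], end = iv[2],
                 name = "PAR"))),
    data.frame(chrom = cfg$chrom, start = cfg$slr_interval[1],
               end = cfg$slr_interval[2], name = "SLR"))
  utils::write.table(format(bed, scientific = FALSE), paths["bed"],
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  truth <- sim$truth
  truth$site_class <- NULL; truth$positions <- NULL  # bulky; BED covers regions
  jsonlite::write_json(truth, paths["json"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
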