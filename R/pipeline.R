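#' Configuration for the full sex-chromosome scan
#'
#' Bundles input paths (or in-memory objects) and the thresholds of every
#' stage. Defaults mirror the standard scan parameters: 50 kb / 25 kb
#' windows, MAF 0.05, family-wise alpha 0.05, top-100 reversal sites with a
#' 0.9 match fraction, and at most 3 changepoints per track.
#'
#' @param vcf path to a VCF, or a `genotype_matrix`.
#' @param sex path to a sex TSV, or a [sex_labels()] data frame.
#' @param chrom_lengths named vector of chromosome lengths (bp); required
#'   for window tiling.
#' @param fasta,gff optional genome FASTA and GFF3 (enable GC windows and
#'   X-Y divergence).
#' @param depth optional depth-track data frame or TSV path.
#' @param window_size,window_step window geometry in bp.
#' @param maf_min MAF filter threshold.
#' @param alpha family-wise error rate of the scan.
#' @param assoc_test `"fisher_allelic"` or `"chisq_genotypic"`.
#' @param het_frac fraction for the sex-het window classes; the pipeline
#'   default 0.5 counts sites heterozygous in *most* males and homozygous in
#'   most females, which is robust to occasional X-Y exchange (the stricter
#'   0.9 remains the [sex_het_site_classes()] default for stand-alone use).
#' @param suggestive_p suggestive P cutoff retained in the manifest and
#'   available to [heterogamety_call()] users (default 1e-4); the pipeline
#'   itself infers heterogamety from the `top_k` most-associated sites,
#'   which is robust when mislabeled individuals depress exact-test
#'   P-values.
#' @param top_k,match_frac reversal-detection parameters.
#' @param max_cpts,penalty segmentation parameters.
#' @param out_dir optional output directory; when set, tracks, regions,
#'   reports and a run manifest are written there.
#' @param seed integer seed recorded in the manifest (the scan itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, sex, chrom_lengths, fasta = NULL, gff = NULL,
                            depth = NULL, window_size = 50000L,
                            window_step = 25000L, maf_min = 0.05,
                            alpha = 0.05,
                            assoc_test = c("fisher_allelic", "chisq_genotypic"),
                            het_frac = 0.5, suggestive_p = 1e-4,
                            top_k = 100, match_frac = 0.9,
                            max_cpts = 3, penalty = "MBIC", out_dir = NULL,
                            seed = 1L) {
  for (p in c(if (is.character(vcf)) vcf, if (is.character(sex)) sex,
              fasta, gff, if (is.character(depth)) depth))
    if (!file.exists(p)) stop("input file does not exist: ", p)
  stopifnot(maf_min >= 0, maf_min < 0.5, alpha > 0, alpha < 1,
            het_frac > 0, het_frac <= 1, match_frac > 0, match_frac <= 1,
            top_k >= 1, max_cpts >= 0)
  structure(list(vcf = vcf, sex = sex, chrom_lengths = chrom_lengths,
                 fasta = fasta, gff = gff, depth = depth,
                 window = window_spec(window_size, window_step),
                 maf_min = maf_min, alpha = alpha,
                 assoc_test = match.arg(assoc_test), het_frac = het_frac,
                 suggestive_p = suggestive_p,
                 top_k = top_k, match_frac = match_frac,
                 max_cpts = max_cpts, penalty = penalty,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full sex-linked-region scan
#'
#' Executes the stages in order: MAF filter -> sex-association scan ->
#' heterogamety inference -> sex-reversal detection and single-pass
#' exclusion -> recomputation of the F_ST and sex-het window tracks on the
#' pruned cohort -> change-point segmentation and PAR/SLR region calling per
#' chromosome -> region fractions -> (when FASTA + GFF are given) X-Y
#' divergence over fully sex-linked genes. When heterogamety is
#' undetermined (e.g. no significant SNP anywhere) reversal detection is
#' skipped and all segments come back undetermined -- a "no sex-linked
#' region" result, not an error. A manifest with stage parameters and
#' summaries is returned and, with `out_dir` set, written alongside TSV/BED
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `scan_result`: `regions` (a `region_call` per
#'   chromosome, rbound), `fractions`, `heterogamety`, `reversals`,
#'   `assoc`, `tracks`, `sexes` (with exclusions applied), `kaks`
#'   (or `NULL`) and `manifest`.
#' @export
run_full_scan <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "load"
  result <- tryCatch({
    gm <- if (is.character(config$vcf)) read_vcf(config$vcf) else config$vcf
    sexes <- if (is.character(config$sex)) read_sex_table(config$sex)
             else config$sex
    stage <- "filter"
    n_raw <- n_sites(gm)
    gm <- filter_sites(gm, config$maf_min)
    stage <- "assoc"
    assoc <- assoc_scan(gm, sexes, test = config$assoc_test,
                        alpha = config$alpha)
    stage <- "heterogamety"
    het <- heterogamety_call(gm, sexes, assoc, top_k = config$top_k)
    stage <- "reversals"
    reversals <- NULL
    assoc_initial <- assoc
    if (het$call != "undetermined") {
      reversals <- detect_sex_reversals(gm, sexes, assoc, het,
                                        top_k = config$top_k,
                                        match_frac = config$match_frac)
      sexes <- apply_reversals(sexes, reversals)
      if (any(reversals$flagged))  # exclusion-dependent; recompute
        assoc <- assoc_scan(gm, sexes, test = config$assoc_test,
                            alpha = config$alpha)
    }
    stage <- "tracks"
    windows <- make_windows(config$chrom_lengths, config$window)
    tracks <- fst_windowed(gm, sexes, windows)
    tracks <- sex_het_site_classes(gm, sexes, tracks, frac = config$het_frac)
    tracks <- assoc_window_track(assoc, tracks)
    tracks <- snp_density(gm, tracks)
    if (!is.null(config$fasta)) tracks <- gc_windows(config$fasta, tracks)
    stage <- "segment"
    calls <- lapply(names(config$chrom_lengths), function(ch)
      call_regions(tracks, assoc, ch, config$chrom_lengths[[ch]],
                   max_cpts = config$max_cpts, penalty = config$penalty))
    regions <- do.call(rbind, calls)
    class(regions) <- c("region_call", "data.frame")
    fractions <- lapply(stats::setNames(nm = names(config$chrom_lengths)),
                        function(ch)
      region_fractions(regions[regions$chrom == ch, , drop = FALSE],
                       config$chrom_lengths[[ch]]))
    stage <- "xydiv"
    kaks <- NULL
    if (!is.null(config$fasta) && !is.null(config$gff)) {
      genes <- read_gff_genes(config$gff)
      sel <- select_fully_sexlinked_genes(gm, sexes, genes, regions)
      if (length(sel)) {
        xy <- lapply(sel, build_xy_haplotypes, gm = gm, fasta = config$fasta,
                     genes = genes, sexes = sexes)
        kaks <- slr_divergence_summary(xy)
      }
    }
    manifest <- list(
      parameters = config[setdiff(names(config), c("vcf", "sex", "out_dir"))],
      n_sites_raw = n_raw, n_sites_filtered = n_sites(gm),
      n_tested = attr(assoc, "n_tested"),
      bonferroni_threshold = attr(assoc, "threshold"),
      heterogamety = het$call,
      n_reversed = if (is.null(reversals)) 0L else sum(reversals$flagged),
      n_slr_segments = sum(regions$class == "SLR"),
      fractions = fractions,
      mean_ks = if (is.null(kaks)) NA else kaks$mean_ks)
    out <- list(regions = regions, fractions = fractions,
                heterogamety = het, reversals = reversals, assoc = assoc,
                assoc_initial = assoc_initial, tracks = tracks,
                sexes = sexes, kaks = kaks, manifest = manifest)
    class(out) <- "scan_result"
    out
  }, error = function(e)
    stop(sprintf("scan failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE))
  if (!is.null(config$out_dir)) write_scan_outputs(result, config$out_dir)
  result
}

write_scan_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(result$tracks, "tracks.tsv")
  wt(as.data.frame(result$assoc), "assoc.tsv")
  if (!is.null(result$reversals)) wt(result$reversals, "reversals.tsv")
  bed <- data.frame(chrom = result$regions$chrom,
                    start = format(result$regions$start, scientific = FALSE),
                    end = format(result$regions$end, scientific = FALSE),
                    name = result$regions$class)
  utils::write.table(bed, file.path(dir, "regions.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(result$kaks) && nrow(result$kaks$per_gene))
    wt(result$kaks$per_gene, "kaks.tsv")
  jsonlite::write_json(
    list(call = result$heterogamety$call,
         n_male_het = result$heterogamety$n_male_het,
         n_female_het = result$heterogamety$n_female_het,
         fraction = result$heterogamety$fraction),
    file.path(dir, "heterogamety.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' @export
print.scan_result <- function(x, ...) {
  cat("sexscan full scan\n")
  cat(sprintf("  heterogamety: %s\n", x$heterogamety$call))
  cat(sprintf("  SLR segments: %d\n", sum(x$regions$class == "SLR")))
  cat(sprintf("  flagged sex reversals: %d\n",
              if (is.null(x$reversals)) 0L else sum(x$reversals$flagged)))
  if (!is.null(x$kaks)) cat(sprintf("  mean X-Y Ks: %.4g\n", x$kaks$mean_ks))
  invisible(x)
}
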