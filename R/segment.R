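#' Binary segmentation for joint mean and variance changes
#'
#' Greedy binary segmentation of a univariate series under a Gaussian model
#' in which both the mean and the variance may change at a changepoint.
#' At each round the split maximizing the likelihood-ratio statistic
#' `cost(segment) - cost(left) - cost(right)` (with `cost = n * log(sigma2_mle)`,
#' variances floored at `var_floor`) is accepted if the statistic exceeds the
#' penalty, up to `max_cpts` changepoints. Missing values are dropped before
#' segmentation and reported indices are mapped back to the original series.
#'
#' @param x numeric series (e.g. one metric of a window track).
#' @param max_cpts maximum number of changepoints (default 3).
#' @param min_seg minimum segment length in points (default 2, the smallest
#'   length admitting a variance estimate).
#' @param penalty `"MBIC"` (default, `4*log(n)` for the 2-parameter
#'   mean+variance change plus the changepoint location), `"BIC"`
#'   (`3*log(n)`), or a single numeric penalty value.
#' @param var_floor lower bound on segment variance estimates; a series that
#'   is constant below this floor yields zero changepoints.
#' @return A list of class `changepoint_set`: `changepoints` (indices into
#'   the original series of the last point of each left segment, increasing),
#'   `segments` data frame (start, end index, mean, var), and the penalty
#'   value used.
#' @export
binseg_meanvar <- function(x, max_cpts = 3, min_seg = 2, penalty = "MBIC",
                           var_floor = 1e-8) {
  keep <- which(!is.na(x))
  v <- x[keep]
  n <- length(v)
  pen <- if (is.numeric(penalty)) penalty
         else switch(match.arg(penalty, c("MBIC", "BIC")),
                     MBIC = 4 * log(n), BIC = 3 * log(n))
  cs1 <- c(0, cumsum(v)); cs2 <- c(0, cumsum(v^2))
  seg_cost <- function(i, j) {
    m <- j - i + 1
    mu <- (cs1[j + 1] - cs1[i]) / m
    s2 <- pmax((cs2[j + 1] - cs2[i]) / m - mu^2, var_floor)
    m * log(s2)
  }
  cpts <- integer(0)
  if (n >= 2 * min_seg) {
    repeat {
      if (length(cpts) >= max_cpts) break
      bounds <- c(0L, cpts, n)
      best <- NULL
      for (s in seq_len(length(bounds) - 1)) {
        i <- bounds[s] + 1L; j <- bounds[s + 1]
        if (j - i + 1 < 2 * min_seg) next
        taus <- (i + min_seg - 1L):(j - min_seg)
        gains <- seg_cost(i, j) - seg_cost(i, taus) - seg_cost(taus + 1L, j)
        k <- which.max(gains)
        if (is.null(best) || gains[k] > best$gain)
          best <- list(tau = taus[k], gain = gains[k])
      }
      if (is.null(best) || best$gain <= pen) break
      cpts <- sort(c(cpts, best$tau))
    }
  }
  bounds <- c(0L, cpts, n)
  segs <- data.frame(
    start = keep[bounds[-length(bounds)] + 1L],
    end = keep[bounds[-1]],
    mean = vapply(seq_len(length(bounds) - 1), function(s)
      mean(v[(bounds[s] + 1):bounds[s + 1]]), numeric(1)),
    var = vapply(seq_len(length(bounds) - 1), function(s) {
      vv <- v[(bounds[s] + 1):bounds[s + 1]]
      sum((vv - mean(vv))^2) / length(vv)
    }, numeric(1)))
  structure(list(changepoints = keep[cpts], segments = segs, penalty = pen),
            class = "changepoint_set")
}

# changepoint window indices -> boundary bp positions: midpoint between the
# centers of the last window of one segment and the first of the next
# (windows overlap, so a point estimate is needed)
cpt_positions_bp <- function(cpt_idx, windows) {
  centers <- (windows$start + windows$end) / 2
  vapply(cpt_idx, function(i) (centers[i] + centers[i + 1]) / 2, numeric(1))
}

#' Call PAR / sex-linked segments from concordant changepoints
#'
#' Candidate boundaries are the changepoints of the between-sex F_ST track,
#' the max -log10(P) association track and the male-het-density track,
#' merged whenever two candidates lie within `concordance_bp` (default one
#' window step). A resulting segment is classified `SLR` if it contains at
#' least one Bonferroni-significant SNP and both its mean F_ST and its mean
#' male-het density exceed the genome-wide 90th percentile of the respective
#' window track; `PAR` if it abuts an SLR on the same chromosome and fails
#' those criteria; otherwise `undetermined`. With no significant SNP anywhere
#' all segments are `undetermined` (no sex chromosome found), which is a
#' result, not an error.
#'
#' @param tracks window data frame carrying columns `chrom`, `start`, `end`,
#'   `fst_mean`, `het_density_mf` and `neglog10p_max` (see
#'   [assoc_window_track()]), typically restricted to the candidate
#'   chromosome plus autosomal background.
#' @param assoc an `assoc_result` (for per-segment significant-SNP counts).
#' @param chrom chromosome to segment.
#' @param chrom_length its length in bp.
#' @param concordance_bp merge radius for near-coincident changepoints;
#'   default = the window step inferred from the track.
#' @param max_cpts,penalty,min_seg passed to [binseg_meanvar()].
#' @param q probability for the genome-wide support quantile (default 0.9).
#' @return An object of class `region_call`: data frame (chrom, start, end,
#'   class, fst_mean, het_density, n_sig_snps, neglog10p_max); segments tile
#'   `[0, chrom_length)`.
#' @export
call_regions <- function(tracks, assoc, chrom, chrom_length,
                         concordance_bp = NULL, max_cpts = 3,
                         penalty = "MBIC", min_seg = 2, q = 0.9) {
  w <- tracks[tracks$chrom == chrom, , drop = FALSE]
  w <- w[order(w$start), , drop = FALSE]
  stopifnot(nrow(w) >= 1)
  if (is.null(concordance_bp))
    concordance_bp <- if (nrow(w) > 1) w$start[2] - w$start[1] else 25000
  cand <- c()
  for (metric in c("fst_mean", "neglog10p_max", "het_density_mf")) {
    if (!metric %in% names(w)) next
    cs <- binseg_meanvar(w[[metric]], max_cpts = max_cpts, penalty = penalty,
                         min_seg = min_seg)
    cand <- c(cand, cpt_positions_bp(cs$changepoints, w))
  }
  # merge candidates within concordance_bp into their mean position
  bounds <- numeric(0)
  if (length(cand)) {
    cand <- sort(cand)
    grp <- cumsum(c(TRUE, diff(cand) > concordance_bp))
    bounds <- as.numeric(tapply(cand, grp, mean))
  }
  bounds <- bounds[bounds > 0 & bounds < chrom_length]
  edges <- c(0, sort(bounds), chrom_length)
  sig <- assoc[assoc$significant & assoc$chrom == chrom, , drop = FALSE]
  q_fst <- stats::quantile(tracks$fst_mean, q, na.rm = TRUE)
  q_het <- stats::quantile(tracks$het_density_mf, q, na.rm = TRUE)
  seg <- data.frame(chrom = chrom, start = edges[-length(edges)],
                    end = edges[-1], stringsAsFactors = FALSE)
  in_seg <- function(col, s, e) {
    i <- w$start < e & w$end > s
    if (!any(i)) NA_real_ else mean(w[[col]][i], na.rm = TRUE)
  }
  seg$fst_mean <- mapply(in_seg, "fst_mean", seg$start, seg$end)
  seg$het_density <- mapply(in_seg, "het_density_mf", seg$start, seg$end)
  seg$neglog10p_max <- if ("neglog10p_max" %in% names(w))
    mapply(in_seg, "neglog10p_max", seg$start, seg$end) else NA_real_
  seg$n_sig_snps <- mapply(function(s, e) sum(sig$pos > s & sig$pos <= e),
                           seg$start, seg$end)
  is_slr <- seg$n_sig_snps >= 1 &
    !is.na(seg$fst_mean) & seg$fst_mean > q_fst &
    !is.na(seg$het_density) & seg$het_density > q_het
  cls <- rep("undetermined", nrow(seg))
  cls[is_slr] <- "SLR"
  abuts_slr <- vapply(seq_len(nrow(seg)), function(i)
    (i > 1 && is_slr[i - 1]) || (i < nrow(seg) && is_slr[i + 1]), logical(1))
  cls[!is_slr & abuts_slr] <- "PAR"
  seg$class <- cls
  seg <- seg[, c("chrom", "start", "end", "class", "fst_mean", "het_density",
                 "neglog10p_max", "n_sig_snps")]
  structure(seg, class = c("region_call", class(seg)))
}

#' Window track of max -log10 association P-values
#'
#' @param assoc an `assoc_result`.
#' @param windows window data frame.
#' @return `windows` with added `neglog10p_max` (0 for windows without
#'   tested sites, so the association track is defined everywhere).
#' @export
assoc_window_track <- function(assoc, windows) {
  idx <- sites_in_windows(assoc$chrom, assoc$pos, windows)
  windows$neglog10p_max <- vapply(idx, function(i) {
    p <- assoc$p[i]; p <- p[!is.na(p)]
    if (length(p) == 0) 0 else max(-log10(p))
  }, numeric(1))
  windows
}

#' Fractions of a chromosome occupied by each region class
#'
#' @param call a `region_call` (or any data frame with start, end, class).
#' @param chrom_length chromosome length in bp.
#' @return Named numeric vector of percentages per class (summing to 100
#'   when the segments tile the chromosome).
#' @export
region_fractions <- function(call, chrom_length) {
  len <- tapply(call$end - call$start, call$class, sum)
  100 * as.numeric(len) / chrom_length -> pct
  names(pct) <- names(len)
  pct
}

#' Detect high-GC chromosome tip regions
#'
#' Segments each chromosome's GC window track by [binseg_meanvar()] and
#' reports the terminal segments (either chromosome end) whose mean GC
#' exceeds the chromosome mean -- the signature of crossover-localized,
#' GC-biased gene conversion at chromosome tips. Chromosomes with fewer than
#' `2 * min_seg` windows are skipped.
#'
#' @param gc_track window data frame with columns chrom, start, end, gc.
#' @param max_cpts,penalty,min_seg passed to [binseg_meanvar()].
#' @return A list: `regions` data frame (chrom, start, end, mean_gc) of tip
#'   segments, and `genome_fraction` = summed tip length / total tracked
#'   length.
#' @export
tip_gc_regions <- function(gc_track, max_cpts = 3, penalty = "MBIC",
                           min_seg = 2) {
  out <- list()
  total <- 0
  for (ch in unique(gc_track$chrom)) {
    w <- gc_track[gc_track$chrom == ch, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    total <- total + max(w$end) - min(w$start)
    if (nrow(w) < 2 * min_seg) next
    cs <- binseg_meanvar(w$gc, max_cpts = max_cpts, penalty = penalty,
                         min_seg = min_seg)
    if (length(cs$changepoints) == 0) next
    chrom_mean <- mean(w$gc, na.rm = TRUE)
    segs <- cs$segments
    for (i in c(1L, nrow(segs))) {
      if (segs$mean[i] > chrom_mean) {
        out[[length(out) + 1]] <- data.frame(
          chrom = ch,
          start = w$start[segs$start[i]],
          end = w$end[segs$end[i]],
          mean_gc = segs$mean[i], stringsAsFactors = FALSE)
      }
    }
  }
  regions <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               mean_gc = numeric(0))
  list(regions = regions,
       genome_fraction = if (total > 0) sum(regions$end - regions$start) / total
                         else NA_real_)
}
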