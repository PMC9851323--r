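#' Sliding-window specification
#'
#' Default geometry is 50 kb windows advanced in 25 kb steps, the standard
#' overlapping-window layout for between-sex scans of homomorphic sex
#' chromosomes. With `step == size` the windows partition sites exactly once;
#' with `step < size` adjacent windows overlap and sites are counted in every
#' window containing them (by construction).
#'
#' @param size window size in bp (default 50000).
#' @param step step between window starts in bp (default 25000); must be
#'   `<= size`.
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(size = 50000L, step = 25000L) {
  size <- as.integer(size); step <- as.integer(step)
  stopifnot(size > 0L, step > 0L, step <= size)
  structure(list(size = size, step = step), class = "window_spec")
}

#' Tile chromosomes with sliding windows
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param spec a [window_spec()].
#' @return A data frame (chrom, start, end), 0-based half-open; the final
#'   window of each chromosome is truncated at the contig end.
#' @export
make_windows <- function(chrom_lengths, spec = window_spec()) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0))
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- as.integer(chrom_lengths[[ch]])
    starts <- seq.int(0L, max(0L, L - 1L), by = spec$step)
    starts <- starts[starts < L]
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + spec$size, L), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# index of windows (rows of `windows`) containing each (chrom, pos) pair;
# returns a list: per window, the integer site indices. pos is 1-based VCF
# coordinate; window [start, end) is 0-based half-open, so site pos is inside
# iff start < pos <= end. Overlap lookup is delegated to IRanges for speed.
sites_in_windows <- function(chrom, pos, windows) {
  sites <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  win <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start + 1L,
                                                 windows$end))
  hits <- GenomicRanges::findOverlaps(sites, win)
  out <- rep(list(integer(0)), nrow(windows))
  grouped <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  out[as.integer(names(grouped))] <- grouped
  out
}

#' SNP density per window
#'
#' @param gm a (filtered) `genotype_matrix`.
#' @param windows window data frame from [make_windows()].
#' @return `windows` with an added `snp_density` count column.
#' @export
snp_density <- function(gm, windows) {
  idx <- sites_in_windows(gm$chrom, gm$pos, windows)
  windows$snp_density <- vapply(idx, length, integer(1))
  windows
}

#' GC content per window
#'
#' GC is computed as (G+C)/(A+C+G+T), ignoring N and other ambiguity codes;
#' all-N windows are missing. Windows extending beyond the contig end are
#' truncated (as [make_windows()] already guarantees when lengths match the
#' FASTA).
#'
#' @param fasta path to a genome FASTA, or a `Biostrings::DNAStringSet`.
#' @param windows window data frame; `chrom` values must name FASTA contigs.
#' @return `windows` with an added `gc` column.
#' @export
gc_windows <- function(fasta, windows) {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  missing <- setdiff(unique(windows$chrom), names(seqs))
  if (length(missing)) stop("contigs absent from FASTA: ",
                            paste(missing, collapse = ", "))
  gc <- numeric(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    L <- length(seqs[[windows$chrom[i]]])
    s <- windows$start[i] + 1L
    e <- min(windows$end[i], L)
    if (s > L) { gc[i] <- NA_real_; next }
    sub <- Biostrings::subseq(seqs[[windows$chrom[i]]], s, e)
    f <- Biostrings::letterFrequency(sub, c("A", "C", "G", "T"))
    tot <- sum(f)
    gc[i] <- if (tot == 0) NA_real_ else (f[["C"]] + f[["G"]]) / tot
  }
  windows$gc <- gc
  windows
}
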