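#' TPM normalization of a read-count matrix
#'
#' Transcripts per million: per-gene counts are divided by gene length (kb
#' scaling cancels), then each sample's rates are scaled to sum to 1e6.
#'
#' @param counts genes x samples matrix of read counts.
#' @param lengths per-gene effective lengths (bp), all > 0.
#' @return Matrix of TPM values; every column sums to 1e6.
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths) == nrow(counts), all(lengths > 0))
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) stop("sample(s) with zero total rate: ",
                          paste(colnames(counts)[tot == 0], collapse = ", "))
  sweep(rate, 2, tot, "/") * 1e6
}

#' Quantile normalization across samples
#'
#' Replaces each column's sorted values by the cross-column means of the
#' order statistics, averaging over ties, so all columns share one empirical
#' distribution afterwards. Delegates to `limma::normalizeQuantiles`.
#'
#' @param m genes x samples matrix of non-negative expression values.
#' @return The normalized matrix.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("negative expression values")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Tissue-specificity index tau
#'
#' tau = sum_i (1 - x_i / max(x)) / (n - 1) over n >= 2 tissue values:
#' 0 for a uniform profile, 1 for single-tissue expression; invariant to
#' positive scaling. All-zero (or all-NA) profiles are `NA`.
#'
#' @param profile numeric vector of per-tissue expression values (>= 0).
#' @return tau in [0, 1], or `NA`.
#' @export
tau <- function(profile) {
  x <- profile[!is.na(profile)]
  if (length(x) < 2) stop("tau needs >= 2 tissues")
  if (any(x < 0)) stop("negative expression values")
  mx <- max(x)
  if (mx == 0) return(NA_real_)
  sum(1 - x / mx) / (length(x) - 1)
}

#' Mean expression per tissue
#'
#' Collapses a genes x samples matrix to genes x tissues by averaging the
#' samples of each tissue.
#'
#' @param m genes x samples matrix.
#' @param tissue character vector, one tissue label per sample (column).
#' @return genes x tissues matrix.
#' @export
tissue_profiles <- function(m, tissue) {
  m <- as.matrix(m)
  stopifnot(length(tissue) == ncol(m))
  sapply(unique(tissue), function(t)
    rowMeans(m[, tissue == t, drop = FALSE]))
}

#' Classify tissue-specific genes by tau and the top-three rule
#'
#' Works on a quantile-normalized genes x tissues expression matrix. Genes
#' expressed below `expr_min` in every tissue are pre-filtered (not
#' classified). A gene is specific to a tissue iff its tau reaches
#' `tau_threshold` and that tissue is among the gene's top `top_n` tissues
#' by normalized expression; ties at the last rank are all included. The
#' reported `specific_tissue` is the gene's maximally expressing tissue.
#'
#' @param expr genes x tissues matrix (quantile-normalized per-tissue
#'   expression).
#' @param tau_threshold tau cutoff (default 0.8).
#' @param top_n rank cutoff (default 3).
#' @param expr_min pre-filter threshold (default 1, i.e. TPM < 1 everywhere
#'   excludes a gene).
#' @return Data frame (gene, tau, specific_tissue, filtered) plus a logical
#'   genes x tissues attribute `specific_matrix` answering "is gene g
#'   specific to tissue t".
#' @export
classify_tissue_specific <- function(expr, tau_threshold = 0.8, top_n = 3,
                                     expr_min = 1) {
  expr <- as.matrix(expr)
  stopifnot(ncol(expr) >= 2)
  filtered <- apply(expr, 1, function(x) all(x < expr_min, na.rm = TRUE))
  taus <- rep(NA_real_, nrow(expr))
  taus[!filtered] <- apply(expr[!filtered, , drop = FALSE], 1, tau)
  spec_mat <- matrix(FALSE, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  spec_tis <- rep(NA_character_, nrow(expr))
  for (i in which(!filtered & !is.na(taus) & taus >= tau_threshold)) {
    x <- expr[i, ]
    cut <- sort(x, decreasing = TRUE)[min(top_n, length(x))]
    spec_mat[i, ] <- x >= cut  # ties at the last rank included
    spec_tis[i] <- colnames(expr)[which.max(x)]
  }
  out <- data.frame(gene = rownames(expr) %||% as.character(seq_len(nrow(expr))),
                    tau = taus, specific_tissue = spec_tis,
                    filtered = filtered, stringsAsFactors = FALSE)
  attr(out, "specific_matrix") <- spec_mat
  out
}

#' Tissue-biased genes by fold change over other tissues
#'
#' Within one developmental stage, a gene is biased toward tissue T iff its
#' TPM in T is at least `fold` times the mean TPM over the other tissues of
#' that stage (inclusive boundary: exactly `fold`-fold counts).
#'
#' @param tpm_mat genes x samples TPM matrix.
#' @param tissue,stage per-sample tissue and stage labels.
#' @param fold bias threshold (default 2).
#' @param use_stage stage to evaluate (default: the single stage present).
#' @return Logical genes x tissues matrix of bias calls for `use_stage`.
#' @export
tissue_biased <- function(tpm_mat, tissue, stage = NULL, fold = 2,
                          use_stage = NULL) {
  tpm_mat <- as.matrix(tpm_mat)
  if (is.null(stage)) stage <- rep("one", ncol(tpm_mat))
  if (is.null(use_stage)) {
    use_stage <- unique(stage)
    if (length(use_stage) > 1) stop("multiple stages present; set use_stage")
  }
  sel <- stage == use_stage
  prof <- tissue_profiles(tpm_mat[, sel, drop = FALSE], tissue[sel])
  if (ncol(prof) < 2) stop("need >= 2 tissues at stage ", use_stage)
  out <- matrix(FALSE, nrow(prof), ncol(prof), dimnames = dimnames(prof))
  for (j in seq_len(ncol(prof))) {
    other <- rowMeans(prof[, -j, drop = FALSE])
    out[, j] <- prof[, j] >= fold * other
  }
  out
}

#' Chromosomal enrichment of a gene set by Fisher's exact test
#'
#' For each chromosome (or region label), tests over-representation of the
#' gene set among that chromosome's genes against the genome-wide background
#' with a one-sided (greater) Fisher exact test on the 2 x 2 table
#' [[in-set & on-chrom, in-set & off], [out & on, out & off]]. Raw P-values
#' are marked at 0.05 / 0.01; a Benjamini-Hochberg column is provided for
#' sensitivity but is not used for the marks.
#'
#' @param gene_set character vector of gene ids (subset of the universe).
#' @param universe data frame with columns `gene` and `chrom` covering all
#'   annotated genes.
#' @return Data frame (chrom, n_set_on, n_on, n_set, n_universe, p, p_bh,
#'   mark) with one row per chromosome.
#' @export
chrom_enrichment <- function(gene_set, universe) {
  stopifnot(all(c("gene", "chrom") %in% names(universe)))
  extra <- setdiff(gene_set, universe$gene)
  if (length(extra)) stop("gene set not contained in universe: ",
                          paste(utils::head(extra), collapse = ", "))
  in_set <- universe$gene %in% gene_set
  N <- nrow(universe); K <- sum(in_set)
  chroms <- unique(universe$chrom)
  res <- lapply(chroms, function(ch) {
    on <- universe$chrom == ch
    k <- sum(in_set & on); n <- sum(on)
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)  # P(X >= k)
    data.frame(chrom = ch, n_set_on = k, n_on = n, n_set = K, n_universe = N,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bh <- stats::p.adjust(out$p, "BH")
  out$mark <- ifelse(out$p < 0.01, "**", ifelse(out$p < 0.05, "*", ""))
  out
}
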