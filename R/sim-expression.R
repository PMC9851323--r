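#' Simulate an expression matrix with planted tissue-specific genes
#'
#' Background genes express at a log-normal level shared across tissues with
#' mild log-normal sample noise; planted tissue-specific genes are `fold`
#' times higher in one designated tissue (`fold = Inf` makes them strictly
#' one-hot). `n_specific` genes are planted per tissue, cycling through the
#' tissue list. Values are on a TPM-like scale with background medians well
#' above the TPM < 1 expression filter.
#'
#' @param n_genes total genes.
#' @param tissues character vector of >= 2 tissue names.
#' @param n_specific planted specific genes per tissue.
#' @param fold expression fold of a planted gene in its tissue (>= 1; 1 is
#'   the null configuration, `Inf` makes planted genes one-hot).
#' @param n_reps biological replicates per tissue (default 2).
#' @param noise_sdlog log-normal sample noise (default 0.25).
#' @param seed RNG seed.
#' @return A list: `expr` genes x samples matrix, `tissue` per-sample
#'   labels, `truth` data frame (gene, tissue) of planted assignments.
#' @export
simulate_expression_matrix <- function(n_genes, tissues, n_specific,
                                       fold = 20, n_reps = 2,
                                       noise_sdlog = 0.25, seed = 1L) {
  stopifnot(length(tissues) >= 2, fold >= 1,
            n_specific * length(tissues) <= n_genes)
  with_seed(seed, {
    n_t <- length(tissues)
    n_samp <- n_t * n_reps
    tissue <- rep(tissues, each = n_reps)
    base <- stats::rlnorm(n_genes, meanlog = 3, sdlog = 1)
    expr <- matrix(base, n_genes, n_samp) *
      matrix(stats::rlnorm(n_genes * n_samp, 0, noise_sdlog), n_genes, n_samp)
    planted <- data.frame(gene = character(0), tissue = character(0))
    idx <- 1
    for (t in tissues) {
      for (k in seq_len(n_specific)) {
        cols <- which(tissue == t)
        if (is.infinite(fold)) {
          expr[idx, ] <- 0
          expr[idx, cols] <- base[idx]
        } else {
          expr[idx, cols] <- expr[idx, cols] * fold
        }
        planted <- rbind(planted, data.frame(gene = sprintf("g%05d", idx),
                                             tissue = t))
        idx <- idx + 1
      }
    }
    rownames(expr) <- sprintf("g%05d", seq_len(n_genes))
    colnames(expr) <- sprintf("%s_r%d", tissue, rep(seq_len(n_reps), n_t))
    list(expr = expr, tissue = tissue, truth = planted)
  })
}

#' Simulate a RAD marker-depth matrix with planted sex-linked markers
#'
#' The first `n_sex_linked` markers are present (Poisson depth around
#' `mean_depth`) in one sex only (`linked_sex`); background markers are
#' present in each individual independently of sex with a marker-specific
#' presence probability uniform on [0.2, 0.95]. Absent marker/individual
#' cells have depth 0.
#'
#' @param n_markers total markers.
#' @param n_m,n_f numbers of males and females.
#' @param n_sex_linked planted sex-linked markers (<= n_markers).
#' @param mean_depth Poisson mean depth of present markers (default 10).
#' @param linked_sex `"M"` (default) or `"F"`.
#' @param seed RNG seed.
#' @return A list: `depth` markers x individuals integer matrix, `sexes`
#'   a [sex_labels()] data frame, `truth` character vector of planted
#'   sex-linked marker ids.
#' @export
simulate_rad_markers <- function(n_markers, n_m, n_f, n_sex_linked,
                                 mean_depth = 10, linked_sex = "M",
                                 seed = 1L) {
  stopifnot(n_sex_linked <= n_markers, n_m >= 1, n_f >= 1,
            linked_sex %in% c("M", "F"))
  with_seed(seed, {
    ids <- c(sprintf("M%03d", seq_len(n_m)), sprintf("F%03d", seq_len(n_f)))
    sex <- rep(c("M", "F"), c(n_m, n_f))
    n <- n_m + n_f
    depth <- matrix(0L, n_markers, n,
                    dimnames = list(sprintf("mk%05d", seq_len(n_markers)), ids))
    sl <- seq_len(n_sex_linked)
    if (n_sex_linked > 0) {
      carriers <- sex == linked_sex
      depth[sl, carriers] <- stats::rpois(n_sex_linked * sum(carriers),
                                          mean_depth)
    }
    bg <- setdiff(seq_len(n_markers), sl)
    q <- stats::runif(length(bg), 0.2, 0.95)
    pres <- matrix(stats::runif(length(bg) * n) < q, length(bg), n)
    d_bg <- matrix(0L, length(bg), n)
    d_bg[pres] <- stats::rpois(sum(pres), mean_depth)
    depth[bg, ] <- d_bg
    list(depth = depth, sexes = sex_labels(ids, sex),
         truth = rownames(depth)[sl])
  })
}

#' Simulate X/Y coding-sequence pairs with known divergence
#'
#' Draws random stop-free coding sequences (the X haplotype) and derives a Y
#' haplotype by planting synonymous substitutions at per-synonymous-site
#' rate `ks` and nonsynonymous substitutions at per-nonsynonymous-site rate
#' `ka`, using the NG86 site fractions of each codon position, so that NG86
#' estimation recovers `ks`/`ka` up to sampling error (the Jukes-Cantor
#' correction is negligible at these divergences).
#'
#' @param n_genes number of gene pairs.
#' @param n_codons codons per gene (internal stop codons are never drawn).
#' @param ks,ka planted per-site synonymous / nonsynonymous divergence.
#' @param seed RNG seed.
#' @return A list: `genes` list of `xy_gene`-style lists (gene_id, x, y),
#'   `truth` list with planted ks/ka and realized substitution counts.
#' @export
simulate_xy_gene_pairs <- function(n_genes, n_codons = 300, ks = 0.002,
                                   ka = 0, seed = 1L) {
  stopifnot(ks >= 0, ks < 0.5, ka >= 0, ka < 0.5)
  env <- ng86_tables()
  sense <- names(env$code)[env$code != "*"]
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    genes <- vector("list", n_genes)
    n_syn <- 0L; n_nonsyn <- 0L
    for (g in seq_len(n_genes)) {
      cx <- sample(sense, n_codons, replace = TRUE)
      cy <- cx
      for (i in seq_len(n_codons)) {
        cd <- cx[i]
        for (p in 1:3) {
          alts <- vapply(setdiff(bases, substr(cd, p, p)), function(b) {
            a <- cd; substr(a, p, p) <- b; a
          }, character(1))
          aa <- env$code[alts]
          syn_alt <- alts[aa == env$code[[cd]]]
          non_alt <- alts[aa != env$code[[cd]] & aa != "*"]
          tot <- length(syn_alt) + length(non_alt)
          if (tot == 0) next
          f_syn <- length(syn_alt) / tot
          u <- stats::runif(1)
          prev <- cy[i]
          if (u < ks * f_syn && length(syn_alt)) {
            pick <- sample(syn_alt, 1)
            substr(cy[i], p, p) <- substr(pick, p, p)
            if (env$code[[cy[i]]] == "*") cy[i] <- prev else n_syn <- n_syn + 1L
          } else if (u < ks * f_syn + ka * (1 - f_syn) && length(non_alt)) {
            pick <- sample(non_alt, 1)
            substr(cy[i], p, p) <- substr(pick, p, p)
            if (env$code[[cy[i]]] == "*") cy[i] <- prev
            else n_nonsyn <- n_nonsyn + 1L
          }
        }
      }
      genes[[g]] <- structure(list(gene_id = sprintf("xy%04d", g),
                                   x = paste(cx, collapse = ""),
                                   y = paste(cy, collapse = "")),
                              class = "xy_gene")
    }
    list(genes = genes,
         truth = list(ks = ks, ka = ka, n_syn_planted = n_syn,
                      n_nonsyn_planted = n_nonsyn))
  })
}
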