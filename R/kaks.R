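# --- NG86 codon machinery -------------------------------------------------
# Lookup tables are built once per session. Potential sites follow the
# Nei-Gojobori (1986) fractional scheme: at each codon position the three
# single-nucleotide changes are classified synonymous/nonsynonymous; changes
# creating a stop codon are excluded from the denominator, so each position
# still contributes exactly one site and S + N = 3 per codon.

.ng86_env <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(.ng86_env$sites)) return(.ng86_env)
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons <- names(gc)
  sites <- matrix(0, length(codons), 2, dimnames = list(codons, c("S", "N")))
  for (cd in codons) {
    if (gc[[cd]] == "*") next
    s_tot <- 0
    for (p in 1:3) {
      alts <- vapply(setdiff(bases, substr(cd, p, p)), function(b) {
        alt <- cd; substr(alt, p, p) <- b; alt
      }, character(1))
      aa <- gc[alts]
      nonstop <- aa != "*"
      s_tot <- s_tot + if (any(nonstop))
        sum(aa[nonstop] == gc[[cd]]) / sum(nonstop) else 0
    }
    sites[cd, ] <- c(s_tot, 3 - s_tot)
  }
  .ng86_env$sites <- sites
  .ng86_env$code <- gc
  .ng86_env$paths <- new.env(parent = emptyenv())
  .ng86_env
}

# observed synonymous/nonsynonymous differences between two codons, averaged
# over mutational pathways; pathways passing through a stop codon are
# excluded (renormalizing over the valid ones) unless count_stop_paths, or
# unless no pathway avoids a stop.
ng86_codon_diff <- function(c1, c2, count_stop_paths = FALSE) {
  env <- ng86_tables()
  key <- paste(c1, c2, count_stop_paths)
  hit <- env$paths[[key]]
  if (!is.null(hit)) return(hit)
  gc <- env$code
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0) {
    res <- c(sd = 0, nd = 0)
  } else {
    perms <- if (k == 1) list(pos) else {
      p <- list()
      rec <- function(left, acc) {
        if (!length(left)) { p[[length(p) + 1]] <<- acc; return(invisible()) }
        for (i in seq_along(left)) rec(left[-i], c(acc, left[i]))
      }
      rec(pos, integer(0))
      p
    }
    eval_path <- function(ord) {
      cur <- c1; sd <- 0; nd <- 0
      for (p1 in ord) {
        nxt <- cur
        substr(nxt, p1, p1) <- substr(c2, p1, p1)
        if (gc[[nxt]] == "*") return(NULL)  # endpoints are stop-free
        if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    }
    vals <- lapply(perms, eval_path)
    ok <- !vapply(vals, is.null, logical(1))
    if (!any(ok) || count_stop_paths) {
      # fall back to counting every pathway, stops treated as nonsynonymous
      vals <- lapply(perms, function(ord) {
        cur <- c1; sd <- 0; nd <- 0
        for (p1 in ord) {
          nxt <- cur
          substr(nxt, p1, p1) <- substr(c2, p1, p1)
          if (gc[[nxt]] != "*" && gc[[cur]] != "*" && gc[[nxt]] == gc[[cur]])
            sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        c(sd = sd, nd = nd)
      })
      ok <- rep(TRUE, length(vals))
    }
    m <- do.call(rbind, vals[ok])
    res <- colMeans(m)
  }
  env$paths[[key]] <- res
  res
}

jc_correct <- function(p) {
  ifelse(!is.na(p) & (4 / 3) * p < 1, -0.75 * log(1 - (4 / 3) * p), NA_real_)
}

#' Nei-Gojobori (1986) Ka/Ks between two coding sequences
#'
#' Counts potential synonymous (S) and nonsynonymous (N) sites by the NG86
#' per-codon fractional method, averaged over the two sequences; observed
#' differences in multi-difference codons are averaged over all mutational
#' pathways, excluding pathways through stop codons (set
#' `count_stop_paths = TRUE` for the alternative convention). Proportions
#' are Jukes-Cantor corrected: Ka = -(3/4) log(1 - (4/3) pn), Ks likewise;
#' a proportion at or beyond the correction's domain (4/3 p >= 1) yields
#' `NA`. Codons containing any non-ACGT base are excluded entirely.
#'
#' @param x_cds,y_cds equal-length, in-frame, stop-free coding sequences
#'   (character strings or `Biostrings::DNAString`).
#' @param count_stop_paths count pathways through stop codons as
#'   nonsynonymous instead of excluding them.
#' @return A list of class `kaks_result`: S, N, Sd, Nd, ps, pn, ka, ks,
#'   n_codons_used.
#' @export
ng86_ka_ks <- function(x_cds, y_cds, count_stop_paths = FALSE) {
  x <- toupper(as.character(x_cds)); y <- toupper(as.character(y_cds))
  if (nchar(x) != nchar(y)) stop("sequences differ in length")
  if (nchar(x) %% 3 != 0) stop("sequence length not a multiple of 3")
  env <- ng86_tables()
  nc <- nchar(x) / 3
  starts <- 3 * (seq_len(nc) - 1) + 1
  cx <- substring(x, starts, starts + 2)
  cy <- substring(y, starts, starts + 2)
  valid <- grepl("^[ACGT]{3}$", cx) & grepl("^[ACGT]{3}$", cy)
  if (any(env$code[cx[valid]] == "*" & env$code[cy[valid]] == "*") ||
      any(env$code[cx[valid]] == "*") || any(env$code[cy[valid]] == "*"))
    stop("internal stop codon")
  cxv <- cx[valid]; cyv <- cy[valid]
  S <- sum(env$sites[cxv, "S"] + env$sites[cyv, "S"]) / 2
  N <- sum(env$sites[cxv, "N"] + env$sites[cyv, "N"]) / 2
  Sd <- 0; Nd <- 0
  for (i in which(cxv != cyv)) {
    d <- ng86_codon_diff(cxv[i], cyv[i], count_stop_paths)
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                 ks = jc_correct(ps), ka = jc_correct(pn),
                 n_codons_used = sum(valid)),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("NG86: S=%.2f N=%.2f Sd=%.2f Nd=%.2f Ks=%s Ka=%s\n",
              x$S, x$N, x$Sd, x$Nd,
              format(x$ks, digits = 4), format(x$ka, digits = 4)))
  invisible(x)
}

# --- gene models from GFF3 ------------------------------------------------

#' Read CDS gene models from a GFF3 file
#'
#' Extracts `CDS` features and groups them by gene (the first available of
#' the `gene_id`, `Parent` or `ID` attributes). Coordinates stay 1-based
#' inclusive as in GFF3.
#'
#' @param path GFF3 file.
#' @return Data frame (gene_id, chrom, strand, start, end), one row per CDS
#'   segment.
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0) stop("no CDS features in ", path)
  md <- S4Vectors::mcols(cds)
  gid <- NULL
  for (f in c("gene_id", "Parent", "ID")) {
    if (f %in% names(md)) {
      v <- md[[f]]
      if (methods::is(v, "CharacterList")) v <- vapply(v, function(x)
        if (length(x)) x[[1]] else NA_character_, character(1))
      if (!all(is.na(v))) { gid <- as.character(v); break }
    }
  }
  if (is.null(gid)) stop("cannot determine gene ids from GFF attributes")
  data.frame(gene_id = gid,
             chrom = as.character(GenomicRanges::seqnames(cds)),
             strand = as.character(GenomicRanges::strand(cds)),
             start = GenomicRanges::start(cds),
             end = GenomicRanges::end(cds),
             stringsAsFactors = FALSE)
}

# site indices of gm falling in the CDS of one gene (genomic orientation)
gene_cds_sites <- function(gm, gene_rows) {
  hits <- rep(FALSE, n_sites(gm))
  for (i in seq_len(nrow(gene_rows))) {
    hits <- hits | (gm$chrom == gene_rows$chrom[i] &
                      gm$pos >= gene_rows$start[i] &
                      gm$pos <= gene_rows$end[i])
  }
  which(hits)
}

#' Select genes whose CDS variants are fully sex-linked
#'
#' A gene is retained iff it lies within an SLR segment of `regions`, has at
#' least one variable CDS site in `gm`, and every variable CDS site is
#' heterozygous in all included males and homozygous in all included females
#' (missing genotypes are ignored; the criterion is evaluated on observed
#' calls). Genes with zero CDS variants cannot be assessed and are excluded
#' with a message.
#'
#' @param gm a `genotype_matrix` restricted to filtered SNPs.
#' @param sexes a [sex_labels()] data frame with reversals already excluded.
#' @param genes CDS table from [read_gff_genes()].
#' @param regions a `region_call`; only `SLR` segments are used.
#' @return Character vector of retained gene ids.
#' @export
select_fully_sexlinked_genes <- function(gm, sexes, genes, regions) {
  slr <- regions[regions$class == "SLR", , drop = FALSE]
  males <- included_ids(gm, sexes, "M")
  females <- included_ids(gm, sexes, "F")
  kept <- character(0)
  n_novar <- 0
  for (g in unique(genes$gene_id)) {
    rows <- genes[genes$gene_id == g, , drop = FALSE]
    span_in_slr <- any(slr$chrom == rows$chrom[1] &
                         slr$start < min(rows$start) &
                         slr$end >= max(rows$end))
    if (!span_in_slr) next
    sites <- gene_cds_sites(gm, rows)
    if (length(sites) == 0) { n_novar <- n_novar + 1; next }
    gmat_m <- gm$gt[sites, males, drop = FALSE]
    gmat_f <- gm$gt[sites, females, drop = FALSE]
    all_male_het <- all(gmat_m == 1L, na.rm = TRUE) && any(!is.na(gmat_m))
    all_female_hom <- all(gmat_f != 1L, na.rm = TRUE) && any(!is.na(gmat_f))
    if (all_male_het && all_female_hom) kept <- c(kept, g)
  }
  if (n_novar > 0)
    message(sprintf("select_fully_sexlinked_genes: %d SLR gene(s) without CDS variants excluded",
                    n_novar))
  kept
}

#' Reconstruct the X and Y coding haplotypes of a fully sex-linked gene
#'
#' The X CDS is the reference CDS with the female-homozygous allele
#' substituted at every variable site (females homozygous for the alternate
#' allele contribute that allele to X); the Y CDS carries the other allele
#' at every male-specific heterozygous site. Minus-strand genes are
#' reverse-complemented after assembly, so substituted bases appear
#' complemented in the returned CDS.
#'
#' @param gene_id gene to reconstruct.
#' @param gm a `genotype_matrix`.
#' @param fasta genome FASTA path or `DNAStringSet`.
#' @param genes CDS table from [read_gff_genes()].
#' @param sexes a [sex_labels()] data frame (excluded individuals dropped).
#' @return A list of class `xy_gene`: gene_id, x, y (character CDS),
#'   n_var_sites.
#' @export
build_xy_haplotypes <- function(gene_id, gm, fasta, genes, sexes) {
  rows <- genes[genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(rows) == 0) stop("unknown gene: ", gene_id)
  rows <- rows[order(rows$start), , drop = FALSE]
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  chrom <- rows$chrom[1]
  if (!chrom %in% names(seqs)) stop("contig absent from FASTA: ", chrom)
  cds_parts <- lapply(seq_len(nrow(rows)), function(i)
    as.character(Biostrings::subseq(seqs[[chrom]], rows$start[i], rows$end[i])))
  x <- paste(cds_parts, collapse = "")
  y <- x
  # map genomic position -> position in the genomic-orientation concatenation
  offsets <- cumsum(c(0L, rows$end - rows$start + 1L))
  males <- included_ids(gm, sexes, "M")
  females <- included_ids(gm, sexes, "F")
  sites <- gene_cds_sites(gm, rows)
  if (length(sites) == 0) stop("gene has no variable CDS sites: ", gene_id)
  for (s in sites) {
    exon <- which(gm$pos[s] >= rows$start & gm$pos[s] <= rows$end)[1]
    cpos <- offsets[exon] + (gm$pos[s] - rows$start[exon]) + 1L
    gf <- gm$gt[s, females]; gf <- gf[!is.na(gf)]
    if (any(gf == 1L)) stop("females heterozygous at used site ", gm$pos[s],
                            " of gene ", gene_id)
    x_allele <- if (length(gf) && mean(gf == 2L) > 0.5) gm$alt[s] else gm$ref[s]
    y_allele <- if (x_allele == gm$ref[s]) gm$alt[s] else gm$ref[s]
    substr(x, cpos, cpos) <- x_allele
    substr(y, cpos, cpos) <- y_allele
  }
  if (rows$strand[1] == "-") {
    x <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
    y <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(y)))
  }
  if (nchar(x) %% 3 != 0) stop("CDS of ", gene_id, " not a multiple of 3")
  env <- ng86_tables()
  nc <- nchar(x) / 3
  cx <- substring(x, 3 * (seq_len(nc) - 1) + 1, 3 * (seq_len(nc) - 1) + 3)
  internal <- cx[-length(cx)]
  aa_ok <- grepl("^[ACGT]{3}$", internal)
  if (any(env$code[internal[aa_ok]] == "*"))
    stop("internal stop codon in X haplotype of ", gene_id)
  structure(list(gene_id = gene_id, x = x, y = y, n_var_sites = length(sites)),
            class = "xy_gene")
}

#' Average X-Y divergence over a set of reconstructed genes
#'
#' @param xy_genes list of `xy_gene` objects (or of lists with `x`, `y`,
#'   `gene_id`).
#' @param count_stop_paths passed to [ng86_ka_ks()].
#' @return A list: `per_gene` data frame (gene_id, S, N, Sd, Nd, ks, ka) and
#'   unweighted `mean_ks` / `mean_ka` across genes (NA-dropped); both are
#'   `NA` for an empty list.
#' @export
slr_divergence_summary <- function(xy_genes, count_stop_paths = FALSE) {
  if (length(xy_genes) == 0)
    return(list(per_gene = data.frame(), mean_ks = NA_real_, mean_ka = NA_real_))
  rows <- lapply(xy_genes, function(g) {
    k <- ng86_ka_ks(g$x, g$y, count_stop_paths)
    data.frame(gene_id = g$gene_id %||% NA_character_, S = k$S, N = k$N,
               Sd = k$Sd, Nd = k$Nd, ks = k$ks, ka = k$ka,
               stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, rows)
  list(per_gene = per_gene,
       mean_ks = mean(per_gene$ks, na.rm = TRUE),
       mean_ka = mean(per_gene$ka, na.rm = TRUE))
}
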