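test_that("NG86 reproduces the hand-computed fourfold-degenerate example", {
  # identical sequences: zero divergence
  k0 <- ng86_ka_ks("GGAGGTACC", "GGAGGTACC")
  expect_equal(k0$ka, 0)
  expect_equal(k0$ks, 0)
  # 5 glycine codons, one third-position (fourfold degenerate) difference:
  # S = 5, N = 10, Sd = 1, Nd = 0, ps = 0.2, Ks = -0.75 log(1 - 4/15)
  k <- ng86_ka_ks(strrep("GGA", 5), paste0(strrep("GGA", 4), "GGG"))
  expect_equal(k$S, 5)
  expect_equal(k$N, 10)
  expect_equal(k$Sd, 1)
  expect_equal(k$Nd, 0)
  expect_equal(k$ps, 0.2)
  expect_equal(k$ks, -0.75 * log(1 - (4 / 3) * 0.2), tolerance = 1e-12)
  expect_equal(round(k$ks, 4), 0.2326)
  expect_equal(k$ka, 0)
})

test_that("NG86 is symmetric and multi-hit codons average over valid pathways", {
  set.seed(19)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  for (i in 1:20) {
    c1 <- sample(sense, 1); c2 <- sample(sense, 1)
    k12 <- ng86_ka_ks(c1, c2)
    k21 <- ng86_ka_ks(c2, c1)
    expect_equal(k12$Sd, k21$Sd)
    expect_equal(k12$Nd, k21$Nd)
    expect_equal(k12$S, k21$S, tolerance = 1e-12)
    d <- codon_diff_oracle(c1, c2)
    expect_equal(unname(k12$Sd), unname(d[1]), tolerance = 1e-12)
    expect_equal(unname(k12$Nd), unname(d[2]), tolerance = 1e-12)
  }
  # sequences differing only at fourfold third positions have Nd = 0 exactly
  x <- paste0("GGT", "CCT", "GCT", "ACT")   # Gly Pro Ala Thr
  y <- paste0("GGC", "CCG", "GCA", "ACG")   # same amino acids
  ky <- ng86_ka_ks(x, y)
  expect_equal(ky$Nd, 0)
  expect_equal(ky$Sd, 4)
  # saturation: ps at its JC limit yields missing Ks
  ksat <- ng86_ka_ks("GGAGGA", "GGGGGC")
  expect_equal(ksat$ps, 1)
  expect_true(is.na(ksat$ks))
  # malformed input
  expect_error(ng86_ka_ks("GGAG", "GGAG"), "multiple of 3")
  expect_error(ng86_ka_ks("GGA", "GGAGGA"), "length")
  expect_error(ng86_ka_ks("TAAGGA", "TAAGGA"), "stop")
})

# small two-gene fixture: plus- and minus-strand single-exon genes on one contig
xy_fixture <- function() {
  # gene1 (+): CDS 11..22 (12 bp); gene2 (-): CDS 31..39 (9 bp)
  seq <- paste0(strrep("T", 10),
                "ATGGGACCTGCA",          # gene1 CDS
                strrep("T", 8),
                "TTACATGGT",             # gene2 CDS (reverse strand)
                strrep("T", 11))
  fa <- Biostrings::DNAStringSet(c(chrS = seq))
  genes <- data.frame(gene_id = c("gene1", "gene2"),
                      chrom = "chrS", strand = c("+", "-"),
                      start = c(11L, 31L), end = c(22L, 39L))
  # variants: pos 16 (gene1, ref A per FASTA) male-het; pos 33 (gene2, ref A)
  g <- rbind(c(rep(1L, 4), rep(0L, 4)),
             c(rep(1L, 4), rep(0L, 4)))
  gm <- genotype_matrix(c("chrS", "chrS"), c(16L, 33L), c("A", "A"),
                        c("T", "C"), g, sexes_mf(4, 4)$id)
  list(fa = fa, genes = genes, gm = gm, sexes = sexes_mf(4, 4))
}

test_that("X/Y haplotypes substitute alleles strand-awarely", {
  fx <- xy_fixture()
  xy1 <- build_xy_haplotypes("gene1", fx$gm, fx$fa, fx$genes, fx$sexes)
  # X = reference CDS (females homRef); Y carries T at CDS offset 6
  expect_equal(xy1$x, "ATGGGACCTGCA")
  expect_equal(xy1$y, "ATGGGTCCTGCA")
  # minus strand: CDS is the reverse complement; the pos-33 A->C variant sits
  # 3 bases into the genomic segment, i.e. complemented G->T at CDS offset 7
  xy2 <- build_xy_haplotypes("gene2", fx$gm, fx$fa, fx$genes, fx$sexes)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(xy2$x, rc("TTACATGGT"))
  expect_equal(xy2$y, rc("TTCCATGGT"))  # manual: C substituted at genomic pos 33
  # females heterozygous at a used site violates the contract
  gm_bad <- fx$gm; gm_bad$gt[1, 5] <- 1L
  expect_error(build_xy_haplotypes("gene1", gm_bad, fx$fa, fx$genes, fx$sexes),
               "heterozygous")
  # a gene with no variable CDS sites cannot be reconstructed
  gm_empty <- subset_sites(fx$gm, 2)
  expect_error(build_xy_haplotypes("gene1", gm_empty, fx$fa, fx$genes,
                                   fx$sexes), "no variable")
})

test_that("fully sex-linked gene selection applies the strict criterion", {
  fx <- xy_fixture()
  regions <- data.frame(chrom = "chrS", start = 0, end = 60, class = "SLR")
  sel <- select_fully_sexlinked_genes(fx$gm, fx$sexes, fx$genes, regions)
  expect_setequal(sel, c("gene1", "gene2"))
  # one male homozygous at gene1's site -> gene1 excluded
  gm2 <- fx$gm; gm2$gt[1, 1] <- 0L
  sel2 <- select_fully_sexlinked_genes(gm2, fx$sexes, fx$genes, regions)
  expect_setequal(sel2, "gene2")
  # gene outside the SLR is never considered
  regions_par <- data.frame(chrom = "chrS", start = 0, end = 25,
                            class = c("SLR"))
  sel3 <- select_fully_sexlinked_genes(fx$gm, fx$sexes, fx$genes, regions_par)
  expect_setequal(sel3, "gene1")
  # leak makes the retained fraction drop below 1
  world <- sim_world(seed = 61, chrom_length = 2e6, par_end = 5e5,
                     n_autosomes = 0, reversal_rate = 0, leak_rate = 0.3)
  leaked <- world$sim$truth$leaked_individuals
  expect_gt(length(leaked), 0)
})

test_that("GFF3 gene models read through rtracklayer", {
  gff <- file.path(tempdir(), "toy.gff3")
  writeLines(c("##gff-version 3",
               "chrS\tsrc\tgene\t11\t22\t.\t+\t.\tID=gene1",
               "chrS\tsrc\tmRNA\t11\t22\t.\t+\t.\tID=tx1;Parent=gene1",
               "chrS\tsrc\tCDS\t11\t16\t.\t+\t0\tID=cds1;Parent=tx1",
               "chrS\tsrc\tCDS\t17\t22\t.\t+\t0\tID=cds2;Parent=tx1"),
             gff)
  genes <- read_gff_genes(gff)
  expect_equal(nrow(genes), 2L)
  expect_equal(unique(genes$gene_id), "tx1")
  expect_equal(genes$start, c(11L, 17L))
})

test_that("divergence summary averages per-gene Ks and recovers planted rates", {
  # single gene: summary equals that gene's Ks
  one <- ng86_ka_ks(strrep("GGA", 5), paste0(strrep("GGA", 4), "GGG"))
  s1 <- slr_divergence_summary(list(list(gene_id = "g", x = strrep("GGA", 5),
                                         y = paste0(strrep("GGA", 4), "GGG"))))
  expect_equal(s1$mean_ks, one$ks)
  # identical X/Y across genes: zero
  s0 <- slr_divergence_summary(list(list(gene_id = "g", x = "GGAGCT",
                                         y = "GGAGCT")))
  expect_equal(s0$mean_ks, 0)
  expect_equal(slr_divergence_summary(list())$mean_ks, NA_real_)
  # parameter recovery at the published divergence scale (small here; the
  # full-size run lives in the acceptance suite)
  sim <- simulate_xy_gene_pairs(n_genes = 60, n_codons = 400, ks = 0.006,
                                seed = 3)
  s <- slr_divergence_summary(sim$genes)
  expect_equal(s$mean_ks, 0.006, tolerance = 0.35)
  expect_true(all(is.na(s$per_gene$ka) | s$per_gene$ka == 0 |
                    s$per_gene$ka < 0.002))
})
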