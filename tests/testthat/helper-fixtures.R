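# Shared fixture builders. Everything is generated in code; no binary data.

# genotype matrix from a plain sites x individuals code matrix
gm_from_codes <- function(codes, chrom = "chr1", pos = NULL,
                          ref = "A", alt = "G") {
  codes <- as.matrix(codes)
  n <- nrow(codes)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  genotype_matrix(rep(chrom, n), pos,
                  rep_len(ref, n), rep_len(alt, n), codes,
                  colnames(codes) %||% sprintf("i%02d", seq_len(ncol(codes))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sexes_mf <- function(n_m, n_f) {
  sex_labels(c(sprintf("i%02d", seq_len(n_m)),
               sprintf("i%02d", n_m + seq_len(n_f))),
             rep(c("M", "F"), c(n_m, n_f)))
}

# brute-force Weir-Cockerham (1984) two-population theta for one site,
# written independently of the package implementation
wc_theta_oracle <- function(g1, g2) {
  pops <- list(g1[!is.na(g1)], g2[!is.na(g2)])
  r <- 2
  n <- vapply(pops, length, numeric(1))
  p <- vapply(pops, function(g) sum(g) / (2 * length(g)), numeric(1))
  h <- vapply(pops, function(g) mean(g == 1), numeric(1))
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# two-sided Fisher P for a 2x2 table by full hypergeometric enumeration
fisher_oracle_2x2 <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  x_obs <- tab[1, 1]
  lo <- max(0, rs[1] - cs[2]); hi <- min(rs[1], cs[1])
  probs <- vapply(lo:hi, function(x) dhyper(x, cs[1], cs[2], rs[1]), numeric(1))
  p_obs <- dhyper(x_obs, cs[1], cs[2], rs[1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exhaustive optimal single changepoint under the same Gaussian mean+variance
# cost the package uses, implemented naively for cross-checking
best_single_split_oracle <- function(x, min_seg = 2, var_floor = 1e-8) {
  cost <- function(v) {
    s2 <- max(mean((v - mean(v))^2), var_floor)
    length(v) * log(s2)
  }
  n <- length(x)
  taus <- min_seg:(n - min_seg)
  gains <- vapply(taus, function(t)
    cost(x) - cost(x[1:t]) - cost(x[(t + 1):n]), numeric(1))
  list(tau = taus[which.max(gains)], gain = max(gains))
}

# small multi-chromosome simulated world: one sex chromosome plus autosomal
# background, combined into a single genotype matrix
sim_world <- function(seed, chrom_length = 4e6, par_end = 1e6,
                      n_autosomes = 2, n_males = 30, n_females = 29,
                      xy_divergence = 0.002, reversal_rate = 0.15,
                      leak_rate = 0.05) {
  cfg <- sim_config(n_males = n_males, n_females = n_females,
                    chrom_length = chrom_length,
                    par_intervals = list(c(0, par_end)),
                    slr_interval = c(par_end, chrom_length),
                    xy_divergence = xy_divergence,
                    reversal_rate = reversal_rate, leak_rate = leak_rate,
                    seed = seed)
  sim <- simulate_sexchrom_population(cfg)
  autos <- lapply(seq_len(n_autosomes), function(i)
    simulate_sexchrom_population(sim_config(
      n_males = n_males, n_females = n_females, chrom_length = chrom_length,
      par_intervals = list(c(0, chrom_length / 2)),
      slr_interval = c(chrom_length / 2, chrom_length),
      xy_divergence = 0, reversal_rate = 0, leak_rate = 0,
      chrom = sprintf("chrA%02d", i), seed = seed + 1000L + i)))
  gm <- do.call(combine_genotypes,
                c(list(sim$gm), lapply(autos, `[[`, "gm")))
  chrom_lengths <- c(stats::setNames(chrom_length, cfg$chrom),
                     stats::setNames(rep(chrom_length, n_autosomes),
                                     sprintf("chrA%02d", seq_len(n_autosomes))))
  list(gm = gm, sim = sim, chrom_lengths = chrom_lengths)
}

# independent pathway-enumeration oracle for observed NG86 differences
codon_diff_oracle <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- if (length(pos) <= 1) list(pos) else {
    idx <- seq_along(pos)
    do.call(c, lapply(asplit(as.matrix(expand.grid(rep(list(idx), length(pos)))), 1),
                      function(o) if (anyDuplicated(o)) NULL else list(pos[o])))
  }
  res <- list()
  for (ord in perms) {
    cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[[nxt]] == "*") { ok <- FALSE; break }
      if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) res[[length(res) + 1]] <- c(sd, nd)
  }
  colMeans(do.call(rbind, res))
}
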