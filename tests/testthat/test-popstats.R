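test_that("F_IS matches hand computation and hits its boundary cases", {
  # 10 individuals: 8 het, 2 homRef -> p = 0.4, He = 0.48, Ho = 0.8
  g <- rbind(c(rep(1L, 8), rep(0L, 2)),
             rep(1L, 10),                 # all het at p = 0.5 -> F_IS = -1
             c(rep(0L, 5), rep(2L, 5)),   # polymorphic, all hom -> F_IS = 1
             rep(0L, 10))                 # monomorphic -> He = 0 -> NA
  st <- fis_per_site(gm_from_codes(g))
  expect_equal(st$fis[1], 1 - 0.8 / 0.48)   # = -2/3
  expect_equal(st$fis[1], -2 / 3)
  expect_equal(st$fis[2], -1)
  expect_equal(st$fis[3], 1)
  expect_true(is.na(st$fis[4]))
  expect_true(all(st$ho >= 0 & st$ho <= 1))
  expect_true(all(st$he >= 0 & st$he <= 0.5))
})

test_that("per-site WC F_ST agrees with a brute-force oracle to 1e-12", {
  set.seed(401)
  for (rep in 1:20) {
    n_m <- sample(3:12, 1); n_f <- sample(3:12, 1)
    g <- matrix(sample(c(0:2, NA), (n_m + n_f) * 15, replace = TRUE,
                       prob = c(.3, .3, .3, .1)), 15)
    gm <- gm_from_codes(g)
    sx <- sexes_mf(n_m, n_f)
    got <- site_fst(gm, sx)
    for (i in 1:15) {
      g1 <- g[i, 1:n_m]; g2 <- g[i, n_m + 1:n_f]
      if (sum(!is.na(g1)) < 2 || sum(!is.na(g2)) < 2) {
        expect_true(is.na(got$fst[i]))
      } else {
        exp_theta <- wc_theta_oracle(g1, g2)
        if (is.na(exp_theta) || !is.finite(exp_theta)) {
          expect_true(is.na(got$fst[i]))
        } else {
          expect_equal(got$fst[i], exp_theta, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("WC F_ST endpoints: no differentiation vs fixed difference", {
  # identical genotype distributions in the sexes -> estimate <= 0
  g_same <- rbind(rep(c(0L, 1L, 2L), length.out = 20))
  f_same <- site_fst(gm_from_codes(g_same), sexes_mf(10, 10))
  expect_lte(f_same$fst[1], 0)
  # sexes fixed for alternative alleles -> 1
  g_fix <- rbind(c(rep(0L, 10), rep(2L, 10)))
  f_fix <- site_fst(gm_from_codes(g_fix), sexes_mf(10, 10))
  expect_equal(f_fix$fst[1], 1)
  # 10 males all het, 10 females all homRef: value from the WC formula oracle
  g_xy <- rbind(c(rep(1L, 10), rep(0L, 10)))
  f_xy <- site_fst(gm_from_codes(g_xy), sexes_mf(10, 10))
  expect_equal(f_xy$fst[1], wc_theta_oracle(rep(1L, 10), rep(0L, 10)),
               tolerance = 1e-12)
})

test_that("swapping sex labels leaves F_ST unchanged and mirrors het classes", {
  set.seed(77)
  g <- matrix(sample(0:2, 30 * 12, replace = TRUE), 30)
  g[1:5, 1:6] <- 1L; g[1:5, 7:12] <- 0L  # male-het block under labels A
  gm <- gm_from_codes(g)
  sx <- sexes_mf(6, 6)
  swapped <- sx; swapped$sex <- ifelse(sx$sex == "M", "F", "M")
  w <- make_windows(c(chr1 = 3100L), window_spec(3100L, 3100L))
  f1 <- fst_windowed(gm, sx, w)$fst_mean
  f2 <- fst_windowed(gm, swapped, w)$fst_mean
  expect_equal(f1, f2, tolerance = 1e-12)
  h1 <- sex_het_site_classes(gm, sx, w)
  h2 <- sex_het_site_classes(gm, swapped, w)
  expect_equal(h1$het_density_mf, h2$het_density_fm)
  expect_equal(h1$het_density_fm, h2$het_density_mf)
})

test_that("sex-het site classes follow the frac rule and binomial expectation", {
  # an SLR-like fixed-difference site is counted in the male-het class
  g <- rbind(c(rep(1L, 10), rep(0L, 10)))
  w <- make_windows(c(chr1 = 200L), window_spec(200L, 200L))
  h <- sex_het_site_classes(gm_from_codes(g), sexes_mf(10, 10), w)
  expect_equal(h$het_density_mf, 1L)
  expect_equal(h$het_density_fm, 0L)
  # autosomal HWE sites at p = 0.5, n = 30/29: the chance a site passes the
  # frac = 0.9 male-het criterion is the product of two binomial tails
  p_pass <- (1 - pbinom(26, 30, 0.5)) * pbinom(2, 29, 0.5)  # >=27 het males, <=2 het females
  expect_lt(p_pass, 1e-10)  # essentially never
  set.seed(55)
  g_hwe <- matrix(rbinom(2000 * 59, 2, 0.5), 2000)
  w2 <- make_windows(c(chr1 = 200100L), window_spec(200100L, 200100L))
  h2 <- sex_het_site_classes(gm_from_codes(g_hwe), sexes_mf(30, 29), w2)
  expect_equal(h2$het_density_mf, 0L)
  expect_equal(h2$het_density_fm, 0L)
  # all-female cohort is a precondition violation
  expect_error(sex_het_site_classes(gm_from_codes(g), sexes_mf(0, 20), w),
               "no included individuals")
})

test_that("coverage ratio is 1 at equal depth, ~0.5 over a degenerate Y, NA at zero", {
  depth <- data.frame(chrom = "chr1", start = c(0, 100, 200),
                      end = c(100, 200, 300),
                      m1 = c(10, 10, 10), m2 = c(10, 10, 10),
                      f1 = c(10, 10, 0), f2 = c(10, 10, 0))
  sx <- sex_labels(c("m1", "m2", "f1", "f2"), c("M", "M", "F", "F"))
  expect_message(cr <- coverage_ratio(depth, sx), "zero female depth")
  expect_equal(cr$cov_ratio[1:2], c(1, 1))
  expect_true(is.na(cr$cov_ratio[3]))
  # planted degenerate-Y interval halves normalized male coverage
  cfg <- sim_config(n_males = 20, n_females = 20, chrom_length = 2e6,
                    par_intervals = list(c(0, 5e5)),
                    slr_interval = c(5e5, 2e6), mean_depth = 30,
                    reversal_rate = 0, leak_rate = 0,
                    degenerate_interval = c(1e6, 1.5e6), seed = 5)
  sim <- simulate_sexchrom_population(cfg)
  cr2 <- coverage_ratio(sim$depth, sim$sexes)
  inside <- cr2$start >= 1e6 & cr2$end <= 1.5e6
  outside <- cr2$end <= 1e6 | cr2$start >= 1.5e6
  expect_equal(mean(cr2$cov_ratio[inside]), 0.5, tolerance = 0.08)
  expect_equal(mean(cr2$cov_ratio[outside]), 1.0, tolerance = 0.05)
})

test_that("GC windows match manual counts and handle N runs", {
  fa <- Biostrings::DNAStringSet(c(
    chrT = paste0(strrep("ACGT", 25),          # 100 bp, GC 0.5
                  strrep("N", 100),            # all-N window
                  paste0(strrep("G", 30), strrep("A", 70)))))  # GC 0.30
  w <- data.frame(chrom = "chrT", start = c(0, 100, 200),
                  end = c(100, 200, 300))
  g <- gc_windows(fa, w)
  expect_equal(g$gc, c(0.5, NA, 0.30))
  expect_error(gc_windows(fa, data.frame(chrom = "nope", start = 0, end = 10)),
               "absent from FASTA")
})

test_that("non-overlapping windows partition sites; overlapping double-count", {
  gm <- gm_from_codes(matrix(0:2, 40, 3), pos = as.integer(seq(50, 3950, by = 100)))
  w1 <- snp_density(gm, make_windows(c(chr1 = 4000L), window_spec(1000L, 1000L)))
  expect_equal(sum(w1$snp_density), n_sites(gm))
  w2 <- snp_density(gm, make_windows(c(chr1 = 4000L), window_spec(1000L, 500L)))
  # interior sites fall in exactly two step-500 windows
  expect_gt(sum(w2$snp_density), n_sites(gm))
})
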