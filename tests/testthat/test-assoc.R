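test_that("Bonferroni thresholds reproduce the genome-wide values", {
  expect_equal(signif(bonferroni_threshold(6115914), 3), 8.18e-9)
  expect_equal(signif(bonferroni_threshold(5603399), 3), 8.92e-9)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_error(bonferroni_threshold(0))
})

test_that("association scan P-values match exact enumeration", {
  # both sexes all het -> identical allele tables -> P = 1
  g <- rbind(rep(1L, 20))
  a <- assoc_scan(gm_from_codes(g), sexes_mf(10, 10))
  expect_equal(a$p[1], 1)
  # 10 males all het vs 10 females all homRef: allelic table [[10,10],[20,0]]
  g2 <- rbind(c(rep(1L, 10), rep(0L, 10)))
  a2 <- assoc_scan(gm_from_codes(g2), sexes_mf(10, 10))
  oracle <- fisher_oracle_2x2(matrix(c(10, 10, 20, 0), 2, byrow = TRUE))
  expect_equal(a2$p[1], oracle, tolerance = 1e-10)
  expect_equal(a2$p[1], 4.36e-4, tolerance = 1e-2)
  # random tables: package Fisher == enumeration oracle
  set.seed(31)
  for (i in 1:15) {
    gi <- rbind(sample(0:2, 14, replace = TRUE))
    ai <- assoc_scan(gm_from_codes(gi), sexes_mf(7, 7))
    am <- sum(gi[1, 1:7]); af <- sum(gi[1, 8:14])
    tab <- matrix(c(14 - am, am, 14 - af, af), 2, byrow = TRUE)
    expect_equal(ai$p[1], fisher_oracle_2x2(tab), tolerance = 1e-10)
  }
  # genotypic chi-square agrees with stats::chisq.test on the 2x3 table
  g3 <- rbind(c(0L, 0L, 1L, 1L, 2L, 2L, 0L, 1L, 1L, 1L, 2L, 0L))
  a3 <- assoc_scan(gm_from_codes(g3), sexes_mf(6, 6), test = "chisq_genotypic")
  tab3 <- rbind(table(factor(g3[1, 1:6], 0:2)), table(factor(g3[1, 7:12], 0:2)))
  expect_equal(a3$p[1],
               suppressWarnings(chisq.test(tab3, correct = FALSE)$p.value),
               tolerance = 1e-12)
})

test_that("fixed X/Y differences at 30/29 clear the Bonferroni threshold", {
  # closed form: the extreme table [[30,30],[58,0]] has two-sided Fisher P
  # far below 0.05 / n for any realistic simulated SNP count
  p_extreme <- fisher_oracle_2x2(matrix(c(30, 30, 58, 0), 2, byrow = TRUE))
  world <- sim_world(seed = 21, chrom_length = 2e6, par_end = 6e5,
                     n_autosomes = 1, reversal_rate = 0, leak_rate = 0)
  gm <- filter_sites(world$gm)
  expect_lt(p_extreme, bonferroni_threshold(n_sites(gm)))
  a <- assoc_scan(gm, world$sim$sexes)
  fixed_pos <- world$sim$truth$positions[
    world$sim$truth$site_class == "SLR_fixed_difference"]
  on_sex <- a$chrom == "chrSex" & a$pos %in% fixed_pos
  expect_true(all(a$significant[on_sex]))
})

test_that("heterogamety calls reproduce the published contrasts", {
  # 248 male-het vs 171 female-het significant sites: share 59% -> undetermined
  pipefish <- heterogamety_from_counts(248, 171)
  expect_equal(pipefish$call, "undetermined")
  expect_equal(pipefish$fraction, 248 / (248 + 171))
  # 89.3% male-het vs 0.4% female-het (shares of 1000 sites) -> XY
  seahorse <- heterogamety_from_counts(893, 4)
  expect_equal(seahorse$call, "XY")
  expect_equal(heterogamety_from_counts(100, 0)$call, "XY")
  expect_equal(heterogamety_from_counts(0, 100)$call, "ZW")
  expect_warning(undet <- heterogamety_from_counts(0, 0), "zero classified")
  expect_equal(undet$call, "undetermined")
})

test_that("sex-reversal detection recovers planted reversals and is involutive", {
  world <- sim_world(seed = 9, chrom_length = 3e6, par_end = 8e5,
                     n_autosomes = 1, reversal_rate = 0.1)
  gm <- filter_sites(world$gm)
  truth <- world$sim$truth$reversed_individuals
  a <- assoc_scan(gm, world$sim$sexes)
  h <- heterogamety_call(gm, world$sim$sexes, a, p_max = 1e-4)
  expect_equal(h$call, "XY")
  rep1 <- detect_sex_reversals(gm, world$sim$sexes, a, h)
  expect_setequal(rep1$id[rep1$flagged], truth)
  # relabeling a flagged individual's phenotypic sex unflags it
  if (any(rep1$flagged)) {
    flip <- rep1$id[rep1$flagged][1]
    sx2 <- world$sim$sexes
    sx2$sex[sx2$id == flip] <- ifelse(sx2$sex[sx2$id == flip] == "M", "F", "M")
    rep2 <- detect_sex_reversals(gm, sx2, a, h)
    expect_false(rep2$flagged[rep2$id == flip])
  }
  # no reversals planted -> none flagged
  world0 <- sim_world(seed = 10, chrom_length = 3e6, par_end = 8e5,
                      n_autosomes = 1, reversal_rate = 0, leak_rate = 0)
  gm0 <- filter_sites(world0$gm)
  a0 <- assoc_scan(gm0, world0$sim$sexes)
  h0 <- heterogamety_call(gm0, world0$sim$sexes, a0, p_max = 1e-4)
  rep0 <- detect_sex_reversals(gm0, world0$sim$sexes, a0, h0)
  expect_equal(sum(rep0$flagged), 0L)
  # undetermined heterogamety refuses
  expect_error(detect_sex_reversals(gm0, world0$sim$sexes, a0,
                                    heterogamety_from_counts(5, 5)),
               "undetermined")
})

test_that("a reversal stays flagged while leak erodes sites below match_frac", {
  # phenotypic male, genotypically female, but 15% of its top sites carry the
  # male pattern again (leak-like erosion): frac_opposite = 0.85, so the call
  # flips between match_frac 0.8 and 0.9 -- direct count is the oracle
  n_sites <- 100
  g <- matrix(1L, n_sites, 20)          # 10 males het / 10 females... build below
  g[, 11:20] <- 0L                      # females homRef
  g[, 1] <- 0L                          # i01: male with female pattern
  g[1:15, 1] <- 1L                      # ...except 15 leaked-back sites
  gm <- gm_from_codes(g)
  sx <- sexes_mf(10, 10)
  a <- assoc_scan(gm, sx)
  h <- heterogamety_call(gm, sx, a, p_max = 1)
  r90 <- detect_sex_reversals(gm, sx, a, h, top_k = 100, match_frac = 0.9)
  r80 <- detect_sex_reversals(gm, sx, a, h, top_k = 100, match_frac = 0.8)
  expect_equal(r90$frac_opposite[r90$id == "i01"], 0.85)
  expect_false(r90$flagged[r90$id == "i01"])
  expect_true(r80$flagged[r80$id == "i01"])
})

test_that("RAD marker association matches the exact oracle and classifies sexes", {
  sx <- sexes_mf(10, 10)
  depth <- matrix(0L, 3, 20, dimnames = list(c("mA", "mB", "mC"), sx$id))
  depth["mA", 1:10] <- 10L                     # males only
  depth["mB", ] <- 10L                         # everyone
  depth["mC", c(1, 11:20)] <- c(10L, rep(10L, 10))  # one male + all females
  res <- rad_marker_assoc(depth, sx, min_depth = 5)
  # single fully male-linked marker: exact two-sided P = 2 / C(20,10)
  expect_equal(res$p[res$marker == "mA"], 2 / choose(20, 10), tolerance = 1e-9)
  expect_true(res$significant[res$marker == "mA"])
  expect_equal(res$class[res$marker == "mA"], "male_linked")
  expect_false(res$significant[res$marker == "mB"])
  # presence threshold: depth 4 is absent
  depth2 <- depth; depth2["mA", 1:10] <- 4L
  res2 <- rad_marker_assoc(depth2, sx, min_depth = 5)
  expect_false("mA" %in% res2$marker[res2$significant])
  # a singleton marker in 1 male among 224 individuals dies under Bonferroni
  sx224 <- sexes_mf(167, 57)
  d224 <- matrix(0L, 100, 224, dimnames = list(sprintf("k%03d", 1:100), sx224$id))
  d224[, ] <- 10L            # background: everyone carries everything
  d224[1, ] <- 0L; d224[1, 1] <- 10L
  res3 <- rad_marker_assoc(d224, sx224)
  expect_false(res3$significant[res3$marker == "k001"])
})

test_that("RAD recovery: planted sex-linked markers found, background clean", {
  fp <- 0L
  for (seed in 1:10) {
    rad <- simulate_rad_markers(n_markers = 300, n_m = 20, n_f = 20,
                                n_sex_linked = 5, seed = seed)
    res <- rad_marker_assoc(rad$depth, rad$sexes)
    hits <- res$marker[res$significant]
    expect_true(all(rad$truth %in% hits))
    fp <- fp + length(setdiff(hits, rad$truth))
  }
  expect_lte(fp, 1L)
})
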