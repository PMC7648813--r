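test_that("planted fixed-difference fractions are exact at population level", {
  set.seed(101)
  cfg <- sim_config(
    groups = list(A = list(sites = c(SA = 15), he = 0.10),
                  B = list(sites = c(SB = 15), he = 0.10)),
    divergence = c("A:B" = 0.30), n_loci = 1000, hybrids = list(),
    error_rate = 0, missing_rate = 0)
  sim <- simulate_populations(cfg)
  f <- sim$truth$group_freqs
  pop_fixed <- mean(abs(f["A", ] - f["B", ]) == 1)
  expect_equal(pop_fixed, 0.30)
  # sample-level realized fraction stays close for n = 15 without error
  aft <- allele_frequencies(sim$gm)
  fd <- count_fixed_differences(aft, "SA", "SB")
  expect_gte(fd$count / fd$n_compared, 0.28)
})

test_that("three-group divergence targets respect triangle constraints", {
  expect_error(sim_config(divergence = c("Northern:Central" = 0.5,
                                         "Northern:Southern" = 0.01,
                                         "Central:Southern" = 0.01)),
               "infeasible")
  expect_error(sim_config(divergence = c("Northern:Central" = 0.9,
                                         "Northern:Southern" = 0.9,
                                         "Central:Southern" = 0.9)),
               "infeasible")
  # per-pair fractions decompose exactly for the defaults
  cfg <- sim_config()
  set.seed(102)
  sim <- simulate_populations(cfg)
  f <- sim$truth$group_freqs
  expect_equal(mean(abs(f["Northern", ] - f["Central", ]) == 1), 0.25)
  expect_equal(mean(abs(f["Northern", ] - f["Southern", ]) == 1), 0.35)
  expect_equal(mean(abs(f["Central", ] - f["Southern", ]) == 1), 0.15)
})

test_that("hybrid genotype laws follow Mendelian gamete draws", {
  set.seed(103)
  L <- 4000
  p0 <- rep(0, L)
  p1 <- rep(1, L)
  f1 <- simulate_hybrid_genotype("F1", p0, p1)
  expect_true(all(f1 == 1))
  bc <- simulate_hybrid_genotype("F1xP0", p0, p1)
  expect_true(all(bc %in% 0:1))
  expect_lt(abs(mean(bc == 0) - 0.5), 3 * sqrt(0.25 / L))
  f2 <- simulate_hybrid_genotype("F2", p0, p1)
  expect_lt(abs(mean(f2 == 1) - 0.5), 3 * sqrt(0.25 / L))
  expect_error(simulate_hybrid_genotype("nope", p0, p1), "unknown")
})

test_that("planted parent-linked backcross is both backcross and offspring", {
  set.seed(104)
  sim <- simulate_populations(sim_config(error_rate = 0, missing_rate = 0))
  expect_equal(sim$truth$kin_pairs[[1]], c("T1", "T5"))
  expect_equal(opposing_homozygote_count(sim$gm, "T1", "T5")$count, 0)
  # at loci fixed between the parental pools the F1 is always heterozygous
  fixed_nc <- which(abs(sim$truth$group_freqs["Northern", ] -
                          sim$truth$group_freqs["Central", ]) == 1)
  expect_true(all(sim$gm$genotypes["T1", fixed_nc] == 1))
  # and the backcross carries at most one Central allele there
  bc <- sim$gm$genotypes["T5", fixed_nc]
  central_allele <- sim$truth$group_freqs["Central", fixed_nc] * 2
  expect_true(all(bc != central_allele))
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(n_loci = 120)
  set.seed(105)
  a <- simulate_populations(cfg)
  set.seed(105)
  b <- simulate_populations(cfg)
  expect_identical(a$gm, b$gm)
  expect_identical(a$truth$group_freqs, b$truth$group_freqs)
  set.seed(106)
  ma <- simulate_morphology()
  set.seed(106)
  mb <- simulate_morphology()
  expect_identical(ma, mb)
})

test_that("inject_artifacts rejects over-requested violations", {
  set.seed(107)
  base <- random_gm(n = 10, L = 30, missing = 0)
  base$loci$rep_avg <- runif(30, 0.995, 1)
  base$loci$read_depth <- runif(30, 10, 60)
  expect_error(inject_artifacts(base, n_bad_depth = 20, n_low_rep = 20),
               "more planted")
  expect_error(inject_artifacts(base, n_poor_individuals = 99), "more poor")
})

test_that("morphology generator hits configured moments", {
  ref <- morph_reference()
  ref$sds[] <- 0
  set.seed(108)
  m <- simulate_morphology(ref)
  s <- region_summary(m)
  expect_equal(s$mean[s$region == "Southern" & s$trait == "mass"], 1.36)
  expect_equal(s$sd[s$region == "Southern" & s$trait == "mass"], 0)
  # stochastic defaults recover means within 3 s.e.
  set.seed(109)
  m2 <- simulate_morphology()
  s2 <- region_summary(m2)
  ref2 <- morph_reference()
  for (r in rownames(ref2$means)) {
    se <- ref2$sds[r, ] / sqrt(ref2$n[r])
    got <- s2[s2$region == r, ]
    expect_true(all(abs(setNames(got$mean, got$trait) -
                          ref2$means[r, ]) < 3.5 * se))
  }
})
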