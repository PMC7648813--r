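test_that("allele frequencies count alternate alleles over called genotypes", {
  gm <- toy_gm(rbind(c(0L, NA, 2L), c(1L, NA, 2L), c(2L, NA, NA)))
  aft <- allele_frequencies(gm)
  expect_equal(aft$p["pop1", 1], 0.5)   # (0 + 1 + 2) / 6
  expect_equal(aft$n["pop1", 1], 3)
  expect_true(is.na(aft$p["pop1", 2]))  # uncallable locus
  expect_equal(aft$p["pop1", 3], 1)
})

test_that("fixed differences require strict joint fixation at tolerance 0", {
  # per-pop frequencies (A, B): (0,1), (0,0), (1,1), (0.5,1), (1,0)
  gm <- gm_from_freqs(list(A = c(0, 0, 1, 0.5, 1),
                           B = c(1, 0, 1, 1, 0)))
  aft <- allele_frequencies(gm)
  fd <- count_fixed_differences(aft, "A", "B")
  expect_equal(fd$count, 2)            # loci 1 and 5
  expect_equal(fd$n_compared, 5)
  expect_equal(unname(fd$loci), c(1L, 5L))
  # near-fixation only counts with tolerance
  gm2 <- gm_from_freqs(list(A = 0.25, B = 1))
  expect_equal(count_fixed_differences(allele_frequencies(gm2),
                                       "A", "B")$count, 0)
  expect_equal(count_fixed_differences(allele_frequencies(gm2),
                                       "A", "B", tolerance = 0.25)$count, 1)
})

test_that("fixed-difference counting matches an exhaustive oracle", {
  brute_force_fd <- function(gm, a, b) {
    ga <- gm$genotypes[gm$populations == a, , drop = FALSE]
    gb <- gm$genotypes[gm$populations == b, , drop = FALSE]
    n <- 0
    for (l in seq_len(ncol(ga))) {
      xa <- ga[, l][!is.na(ga[, l])]
      xb <- gb[, l][!is.na(gb[, l])]
      if (!length(xa) || !length(xb)) next
      pa <- sum(xa) / (2 * length(xa))
      pb <- sum(xb) / (2 * length(xb))
      if ((pa == 0 && pb == 1) || (pa == 1 && pb == 0)) n <- n + 1
    }
    n
  }
  set.seed(51)
  for (rep in 1:20) {
    gm <- random_gm(n = 6, L = 10, n_pops = 2, missing = 0.15)
    aft <- allele_frequencies(gm)
    expect_equal(count_fixed_differences(aft, "pop1", "pop2")$count,
                 brute_force_fd(gm, "pop1", "pop2"))
  }
})

test_that("false-positive simulation matches the closed-form one-locus case", {
  # pooled p = 0.5, one diploid individual per sample:
  # P(apparent fixed difference) = 2 * 0.25 * 0.25 = 0.125
  g <- matrix(c(0L, 2L), 2, 1)
  rownames(g) <- c("a1", "b1")
  gm <- genotype_matrix(g, populations = c("A", "B"))
  aft <- allele_frequencies(gm)
  set.seed(52)
  fp <- false_positive_rate(aft, "A", "B", n_sim = 10000)
  se <- sqrt(0.125 * 0.875 / 10000)
  expect_lt(abs(fp$expected_fp_count - 0.125), 3 * se)
  # monomorphic pooled frequencies can never fake a fixed difference
  gm0 <- toy_gm(matrix(0L, 4, 6), populations = rep(c("A", "B"), 2))
  fp0 <- false_positive_rate(allele_frequencies(gm0), "A", "B",
                             n_sim = 500)
  expect_equal(fp0$expected_fp_count, 0)
  # an observed zero count is fully consistent with that null ...
  expect_equal(fp0$pvalue, 1)
  # ... while any positive observed count is impossible under it
  fp3 <- false_positive_rate(allele_frequencies(gm0), "A", "B",
                             n_sim = 500, observed = 3)
  expect_equal(fp3$pvalue, 0)
  expect_error(false_positive_rate(aft, "A", "B", n_sim = 0), "n_sim")
})

test_that("false-positive expectation decreases with sample size", {
  set.seed(53)
  make_pair <- function(n_per_pop) {
    p <- rep(0.5, 50)
    g <- matrix(rbinom(2 * n_per_pop * 50, 2, 0.5), 2 * n_per_pop)
    rownames(g) <- paste0("i", seq_len(nrow(g)))
    genotype_matrix(g, populations = rep(c("A", "B"), each = n_per_pop))
  }
  fp_small <- false_positive_rate(allele_frequencies(make_pair(2)),
                                  "A", "B", n_sim = 4000, observed = 0)
  fp_big <- false_positive_rate(allele_frequencies(make_pair(10)),
                                "A", "B", n_sim = 4000, observed = 0)
  expect_gt(fp_small$expected_fp_count,
            fp_big$expected_fp_count - 3 * sqrt(fp_small$expected_fp_count /
                                                  4000))
})

test_that("private alleles include and bound fixed differences", {
  aft <- allele_frequencies(gm_from_freqs(list(A = c(0.5, 1, 0.5),
                                               B = c(0, 0, 0.5))))
  pc <- count_private_alleles(aft, "A", "B")
  # locus 1: alt private to A; locus 2: fixed difference, private both ways
  expect_equal(unname(pc), c(2, 1))
  set.seed(54)
  for (rep in 1:15) {
    gm <- random_gm(n = 8, L = 20, n_pops = 2, missing = 0.1)
    aft <- allele_frequencies(gm)
    fd <- count_fixed_differences(aft, "pop1", "pop2")$count
    pc <- count_private_alleles(aft, "pop1", "pop2")
    expect_gte(pc[["countAB"]], fd)
    expect_gte(pc[["countBA"]], fd)
  }
})

test_that("identical populations amalgamate into one OTU", {
  set.seed(55)
  p <- runif(60)
  g <- matrix(rbinom(12 * 60, 2, rep(p, each = 12)), 12)
  rownames(g) <- paste0("i", 1:12)
  gm <- genotype_matrix(g, populations = rep(c("X", "Y"), each = 6))
  res <- amalgamate_otus(gm, n_sim = 200)
  expect_equal(res$n_otus, 1)
  expect_equal(unname(res$otus["X"]), unname(res$otus["Y"]))
})

test_that("small-sample apparent fixation is merged by the significance test", {
  # two tiny samples (n = 3 and 2) from one panmictic pool show apparent
  # fixed differences that the false-positive test recognises as noise
  set.seed(56)
  gm <- NULL
  for (try in 1:500) {
    p <- runif(800)
    g <- matrix(rbinom(5 * 800, 2, rep(p, each = 5)), 5)
    rownames(g) <- paste0("i", 1:5)
    cand <- genotype_matrix(g, populations = rep(c("Bendoc", "Wombat"),
                                                 c(3, 2)))
    aft <- allele_frequencies(cand)
    if (count_fixed_differences(aft, "Bendoc", "Wombat")$count > 0) {
      gm <- cand
      break
    }
  }
  expect_false(is.null(gm))   # apparent fixation occurs at this sample size
  res <- amalgamate_otus(gm, n_sim = 500)
  expect_equal(res$n_otus, 1)
  expect_equal(res$merges[[1]]$rule, "false_positive")
})

test_that("the planted three-group design yields three OTUs", {
  set.seed(57)
  sim <- simulate_populations(sim_config())
  res <- amalgamate_otus(sim$gm, n_sim = 400, exclude = c("T1", "T5"))
  expect_equal(res$n_otus, 3)
  truth <- sim$truth$individuals
  otu_of_site <- res$otus
  site_group <- unique(truth[truth$role == "member", c("site", "group")])
  # sites of one group share an OTU label; sites of different groups do not
  expect_equal(length(unique(tapply(otu_of_site[site_group$site],
                                    site_group$group, unique))), 3)
})

test_that("amalgamation is invariant to population input order", {
  set.seed(58)
  sim <- simulate_populations(sim_config(n_loci = 400))
  gm <- sim$gm
  set.seed(99)
  res1 <- amalgamate_otus(gm, n_sim = 200, exclude = c("T1", "T5"))
  perm <- sample(n_individuals(gm))
  gm2 <- gm[perm, ]
  set.seed(99)
  res2 <- amalgamate_otus(gm2, n_sim = 200, exclude = c("T1", "T5"))
  expect_equal(res1$otus, res2$otus)
  expect_equal(res1$counts, res2$counts)
})
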