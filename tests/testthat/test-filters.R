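test_that("one SNP per tag keeps the best-quality SNP deterministically", {
  gm <- toy_gm(matrix(0:1, 2, 3),
               loci = data.frame(clone_id = c("c1", "c1", "c2"),
                                 snp_position = c(20L, 5L, 1L),
                                 rep_avg = c(0.99, 1.00, 0.98)))
  out <- select_one_snp_per_tag(gm)
  expect_equal(n_loci(out), 2)
  expect_equal(out$loci$rep_avg[out$loci$clone_id == "c1"], 1.00)
  # tie on rep_avg -> lowest snp_position
  gm2 <- toy_gm(matrix(0:1, 2, 2),
                loci = data.frame(clone_id = c("c1", "c1"),
                                  snp_position = c(30L, 4L),
                                  rep_avg = c(0.99, 0.99)))
  expect_equal(select_one_snp_per_tag(gm2)$loci$snp_position, 4L)
  # all unique: unchanged
  gm3 <- toy_gm(matrix(0:1, 2, 3))
  expect_same_gm(select_one_snp_per_tag(gm3), gm3)
})

test_that("read-depth bounds are inclusive and validated", {
  gm <- toy_gm(matrix(0:1, 2, 4),
               loci = data.frame(read_depth = c(4, 5, 100, 101)))
  out <- filter_by_read_depth(gm)
  expect_equal(out$loci$read_depth, c(5, 100))
  gm2 <- toy_gm(matrix(0:1, 2, 2), loci = data.frame(read_depth = c(50, 50)))
  expect_same_gm(filter_by_read_depth(gm2), gm2)
  expect_error(filter_by_read_depth(gm, min_depth = 100, max_depth = 5),
               "min_depth")
})

test_that("individual call-rate filter is strictly 'less than'", {
  g <- rbind(c(0L, 1L, NA, NA, NA),     # 40% called -> removed
             c(0L, 1L, 2L, NA, NA),     # 60% -> kept
             c(0L, 1L, 2L, 0L, 1L))
  gm <- toy_gm(g)
  out <- filter_individuals_by_callrate(gm, 0.5)
  expect_setequal(individual_ids(out), c("i2", "i3"))
  expect_equal(attr(out, "removed"), "i1")
  # exactly at the threshold is retained
  g2 <- rbind(c(0L, 1L, NA, NA), c(0L, 1L, 2L, 0L))
  expect_equal(n_individuals(filter_individuals_by_callrate(toy_gm(g2))), 2)
  gm3 <- toy_gm(matrix(1L, 3, 4))
  expect_same_gm(filter_individuals_by_callrate(gm3), gm3)
})

test_that("monomorphic removal keeps any segregating locus", {
  g <- cbind(c(0L, 0L, 0L),      # all hom ref -> removed
             c(2L, 2L, 2L),      # all hom alt -> removed
             c(1L, 1L, 1L),      # het implies both alleles -> kept
             c(0L, NA, 2L),      # both homozygotes -> kept
             c(NA, NA, NA))      # all missing -> removed
  out <- remove_monomorphic_loci(toy_gm(g))
  expect_equal(n_loci(out), 2)
})

test_that("repeatability and locus call-rate thresholds are strict", {
  gm <- toy_gm(matrix(0:1, 2, 3),
               loci = data.frame(rep_avg = c(0.98, 0.99, 1)))
  expect_equal(filter_by_repeatability(gm)$loci$rep_avg, c(0.99, 1))
  expect_same_gm(filter_by_repeatability(gm, min_rep = 0), gm)

  g <- matrix(1L, 20, 3)
  g[1, 2] <- NA          # call rate 0.95 -> retained
  g[1:2, 3] <- NA        # call rate 0.90 -> removed
  out <- filter_by_locus_callrate(toy_gm(g))
  expect_equal(n_loci(out), 2)
  expect_same_gm(filter_by_locus_callrate(toy_gm(matrix(1L, 4, 3))),
                 toy_gm(matrix(1L, 4, 3)))
})

test_that("every filter is idempotent", {
  set.seed(31)
  gm <- random_gm(n = 15, L = 60, missing = 0.08)
  gm$loci$clone_id <- paste0("c", sample(1:40, 60, replace = TRUE))
  gm$loci$rep_avg <- runif(60, 0.9, 1)
  gm$loci$read_depth <- runif(60, 1, 120)
  filters <- list(
    select_one_snp_per_tag,
    filter_by_read_depth,
    filter_individuals_by_callrate,
    remove_monomorphic_loci,
    filter_by_repeatability,
    filter_by_locus_callrate)
  for (f in filters) {
    once <- f(gm)
    expect_same_gm(f(once), once)
  }
})

test_that("pipeline reports reconcile with planted violations", {
  set.seed(32)
  base <- random_gm(n = 24, L = 150, missing = 0)
  base$loci$rep_avg <- runif(150, 0.995, 1)
  base$loci$read_depth <- runif(150, 10, 60)
  planted <- inject_artifacts(base, n_secondary = 7, n_bad_depth = 5,
                              n_low_rep = 4, n_monomorphic = 6,
                              n_low_callrate = 3, n_poor_individuals = 2)
  res <- run_filter_pipeline(planted$gm)
  rep <- res$report
  removed <- setNames(rep$loci_removed, rep$stage)
  expect_equal(removed[["secondary_snps"]], 7)
  expect_equal(removed[["read_depth"]], 5)
  expect_equal(removed[["monomorphic"]], 6)
  expect_equal(removed[["repeatability"]], 4)
  expect_equal(removed[["locus_call_rate"]], 3)
  expect_equal(rep$individuals_removed[rep$stage == "individual_call_rate"],
               2)
  # totals reconcile per dimension
  init <- attr(rep, "initial")
  expect_equal(init[["loci"]] - sum(rep$loci_removed),
               rep$loci_remaining[nrow(rep)])
  expect_equal(init[["individuals"]] - sum(rep$individuals_removed),
               rep$individuals_remaining[nrow(rep)])
  # remaining counts never increase
  expect_true(all(diff(rep$loci_remaining) <= 0))
  expect_true(all(diff(rep$individuals_remaining) <= 0))
})

test_that("a clean matrix passes every stage untouched", {
  set.seed(33)
  base <- random_gm(n = 20, L = 80, missing = 0)
  base$loci$rep_avg <- runif(80, 0.995, 1)
  base$loci$read_depth <- runif(80, 10, 60)
  clean <- inject_artifacts(base)$gm   # pre-cleaned, zero artifacts
  res <- run_filter_pipeline(clean)
  expect_true(all(res$report$loci_removed == 0))
  expect_true(all(res$report$individuals_removed == 0))
})
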