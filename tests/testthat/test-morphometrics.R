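toy_morph <- function(values_by_region, sexes = NULL) {
  # one value per individual, copied across all eight traits
  rows <- do.call(rbind, lapply(names(values_by_region), function(r) {
    v <- values_by_region[[r]]
    df <- data.frame(id = paste0(r, seq_along(v)), site = r, region = r,
                     sex = if (is.null(sexes)) rep(c("F", "M"),
                                                   length.out = length(v))
                     else sexes[[r]])
    for (tr in morph_traits()) df[[tr]] <- v
    df
  }))
  morph_table(rows)
}

test_that("region summaries are exact sample statistics", {
  m <- toy_morph(list(Northern = c(1, 3), Central = c(2, 2, 2)))
  s <- region_summary(m)
  expect_equal(s$mean[s$region == "Northern" & s$trait == "mass"], 2)
  expect_equal(s$sd[s$region == "Northern" & s$trait == "mass"], sqrt(2))
  expect_error(region_summary(toy_morph(list(Northern = 1))), "at least two")
})

test_that("the exact reference fixture reproduces its generating moments", {
  set.seed(91)
  m <- simulate_morphology(exact = TRUE)
  s <- region_summary(m)
  ref <- morph_reference()
  for (r in rownames(ref$means)) {
    sub <- s[s$region == r, ]
    expect_equal(setNames(sub$mean, sub$trait), ref$means[r, ],
                 tolerance = 1e-10)
    expect_equal(setNames(sub$sd, sub$trait), ref$sds[r, ],
                 tolerance = 1e-10)
    expect_equal(unique(sub$n), unname(ref$n[r]))
  }
})

test_that("tukey_kramer agrees with TukeyHSD on random data", {
  set.seed(92)
  n <- c(12, 8, 10)
  m <- toy_morph(list(Northern = rnorm(12, 10), Central = rnorm(8, 11),
                      Southern = rnorm(10, 12)))
  tk <- tukey_kramer(m)
  y <- m$mass
  hsd <- TukeyHSD(aov(y ~ region, data = m))$region
  tk_mass <- tk[tk$trait == "mass", ]
  for (i in seq_len(nrow(hsd))) {
    lv <- strsplit(rownames(hsd)[i], "-")[[1]]
    row <- tk_mass[tk_mass$pair %in% paste(c(lv[1], lv[2]),
                                           c(lv[2], lv[1]), sep = "-"), ]
    expect_equal(abs(row$diff), abs(unname(hsd[i, "diff"])),
                 tolerance = 1e-10)
    expect_equal(row$p_adj, unname(hsd[i, "p adj"]), tolerance = 1e-6)
  }
})

test_that("identical groups give zero difference and p near 1", {
  set.seed(93)
  v <- rnorm(10, 5, 0.3)
  m <- toy_morph(list(Northern = v, Central = v))
  tk <- tukey_kramer(m)
  expect_equal(tk$diff, rep(0, nrow(tk)))
  expect_true(all(tk$p_adj > 0.999))
  # singleton groups are excluded with a warning
  m2 <- toy_morph(list(Northern = c(1, 2), Central = c(2, 3),
                       Southern = 5))
  expect_warning(tk2 <- tukey_kramer(m2), "size 1")
  expect_false(any(grepl("Southern", tk2$pair)))
})

test_that("sex screening keeps a planted tail effect and drops the rest", {
  set.seed(94)
  kept_tail <- 0
  kept_other <- 0
  for (r in 1:10) {
    ref <- morph_reference()
    ref$sex_effect["tail_length"] <- 4.5   # ~1.5 SD
    m <- simulate_morphology(ref)
    sx <- sex_effect_screen(m)
    kept <- attr(sx, "sex_retained")
    if (isTRUE(kept[["tail_length"]])) kept_tail <- kept_tail + 1
    kept_other <- kept_other +
      sum(kept[setdiff(names(kept), "tail_length")])
  }
  expect_gte(kept_tail, 8)          # high power at 1.5 SD
  expect_lte(kept_other, 14)        # ~5% type I per trait-run (70 chances)
  # a single sex skips the screen
  m1 <- simulate_morphology()
  m1$sex <- "F"
  expect_warning(expect_null(sex_effect_screen(m1)), "one sex")
})

test_that("CVA separates the reference groups and normalizes percents", {
  set.seed(95)
  m <- simulate_morphology(exact = TRUE)
  cv <- cva(m)
  expect_equal(sum(cv$percent), 100)
  expect_equal(ncol(cv$scores), 2)  # k - 1 axes for 3 groups
  # canonical space has unit within-group variance, so centroid distances
  # are Mahalanobis-scaled; the groups are far apart
  cd <- as.matrix(dist(cv$centroids))
  expect_true(all(cd[upper.tri(cd)] > 2))
  # constant trait makes the within-group scatter singular
  m2 <- m
  m2$ear_width <- 1
  expect_error(cva(m2), "singular|constant")
})

test_that("morphometric PCA uses correlations and reports full variance", {
  set.seed(96)
  m <- simulate_morphology()
  pc <- pca_morph(m)
  expect_equal(sum(pc$percent), 100)
  # a planted one-factor structure dominates PC1
  f <- rnorm(40)
  X <- sapply(1:8, function(j) 3 * f + rnorm(40, sd = 0.8))
  df <- data.frame(id = paste0("i", 1:40), site = "Taravale", sex = "F",
                   region = "Northern")
  for (j in seq_along(morph_traits())) df[[morph_traits()[j]]] <-
    X[, j] + 100
  pc2 <- pca_morph(morph_table(df))
  expect_gt(pc2$percent[1], 70)
  # degenerate input errors
  df0 <- df
  df0[morph_traits()] <- 1
  expect_error(pca_morph(morph_table(df0)), "zero-variance")
})

test_that("statistics are invariant to row order", {
  set.seed(97)
  m <- simulate_morphology()
  perm <- sample(nrow(m))
  m2 <- m[perm, ]
  expect_equal(region_summary(m2), region_summary(m))
  expect_equal(tukey_kramer(m2), tukey_kramer(m))
  expect_equal(cva(m2)$percent, cva(m)$percent)
})
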