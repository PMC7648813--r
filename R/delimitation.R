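#' Per-population allele frequencies
#'
#' Alternate-allele frequency p = (het + 2 x hom_alt) / (2 n) per population
#' per locus, with n the number of called individuals. Loci with n = 0 in a
#' population are uncallable there (p is `NA`).
#'
#' @param gm a [genotype_matrix()]; every individual must carry a population
#'   label.
#' @param grouping optional alternative grouping vector (one label per
#'   individual) overriding the stored populations.
#' @return an object of class `allele_freq_table`: list with matrices `p`
#'   and `n` (populations x loci) and `pop_sizes`.
#' @export
allele_frequencies <- function(gm, grouping = NULL) {
  pops <- grouping %||% gm$populations
  if (length(pops) != n_individuals(gm) || anyNA(pops))
    stop("every individual needs exactly one population label")
  g <- gm$genotypes
  f <- factor(pops)
  called <- !is.na(g)
  n_mat <- rowsum(called + 0L, f)                 # pops x loci called counts
  alt <- rowsum(ifelse(called, g, 0L), f)         # alt allele copies
  p <- alt / (2 * n_mat)
  p[n_mat == 0] <- NA_real_
  structure(list(p = p, n = n_mat,
                 pop_sizes = c(table(f))),
            class = "allele_freq_table")
}

#' Count fixed allelic differences between two populations
#'
#' A locus carries a fixed difference when the two populations share no
#' alleles: one is fixed (or within `tolerance` of fixed) for the reference
#' allele and the other for the alternate. With `tolerance = 0` this is
#' strict fixation. Only loci callable in both populations are compared.
#'
#' @param aft an [allele_frequencies()] table.
#' @param popA,popB population labels.
#' @param tolerance allowed departure from fixation (0 = strict).
#' @return list with `count`, `n_compared` (loci callable in both) and
#'   `loci` (indices of the fixed-difference loci).
#' @export
count_fixed_differences <- function(aft, popA, popB, tolerance = 0) {
  pa <- aft$p[popA, ]
  pb <- aft$p[popB, ]
  shared <- !is.na(pa) & !is.na(pb)
  if (!any(shared)) stop("populations ", popA, " and ", popB,
                         " share no callable loci")
  fd <- shared &
    ((pa <= tolerance & pb >= 1 - tolerance) |
       (pa >= 1 - tolerance & pb <= tolerance))
  fd[is.na(fd)] <- FALSE
  list(count = sum(fd), n_compared = sum(shared), loci = which(fd))
}

#' False-positive test for fixed differences
#'
#' Small samples from a single panmictic population can show apparent fixed
#' differences purely by sampling error. The null model pools the two
#' samples' allele frequencies per locus and, for each of `n_sim`
#' replicates, draws `nA` and `nB` diploid genotypes binomially from the
#' pooled frequency at every shared locus, counting how many loci come out
#' spuriously fixed. Per locus the apparent-fixed-difference indicator is
#' Bernoulli with probability
#' P(pA_hat <= tol) P(pB_hat >= 1 - tol) + P(pA_hat >= 1 - tol) P(pB_hat <= tol)
#' under binomial sampling of the 2nA / 2nB allele copies, which is what is
#' simulated (equivalent in distribution to drawing every genotype, locus by
#' locus). The per-locus sample sizes are the observed called counts, so
#' missingness is respected.
#'
#' @param aft an [allele_frequencies()] table.
#' @param popA,popB population labels.
#' @param n_sim number of simulation replicates (default 1000).
#' @param tolerance as in [count_fixed_differences()].
#' @param observed observed fixed-difference count; computed from `aft` when
#'   omitted.
#' @return list with `expected_fp_count` (null mean), `pvalue` (fraction of
#'   replicates with simulated count >= observed), `observed` and `n_sim`.
#' @export
false_positive_rate <- function(aft, popA, popB, n_sim = 1000,
                                tolerance = 0, observed = NULL) {
  if (n_sim < 1) stop("n_sim must be at least 1")
  if (is.null(observed))
    observed <- count_fixed_differences(aft, popA, popB, tolerance)$count
  pa <- aft$p[popA, ]; na <- aft$n[popA, ]
  pb <- aft$p[popB, ]; nb <- aft$n[popB, ]
  shared <- !is.na(pa) & !is.na(pb)
  pa <- pa[shared]; pb <- pb[shared]
  na <- na[shared]; nb <- nb[shared]
  pooled <- (pa * na + pb * nb) / (na + nb)
  kA <- floor(tolerance * 2 * na)
  kB <- floor(tolerance * 2 * nb)
  pA_low <- stats::pbinom(kA, 2 * na, pooled)        # P(pA_hat <= tol)
  pA_high <- 1 - stats::pbinom(2 * na - kA - 1, 2 * na, pooled)
  pB_low <- stats::pbinom(kB, 2 * nb, pooled)
  pB_high <- 1 - stats::pbinom(2 * nb - kB - 1, 2 * nb, pooled)
  q <- pA_low * pB_high + pA_high * pB_low
  q <- pmin(pmax(q, 0), 1)
  L <- length(q)
  hits <- matrix(stats::runif(L * n_sim) < q, nrow = L)
  counts <- colSums(hits)
  list(expected_fp_count = mean(counts),
       pvalue = mean(counts >= observed),
       observed = observed,
       n_sim = n_sim)
}

#' Fixed-difference analysis with progressive amalgamation into OTUs
#'
#' Populations are progressively merged into diagnosable operational
#' taxonomic units (OTUs): first, pairs with zero fixed differences are
#' amalgamated (smallest pair first; fixed differences are recomputed after
#' every merge, since pooling samples can dissolve apparent fixation); then
#' remaining pairs whose fixed-difference count does not exceed the
#' sampling-error false-positive rate ([false_positive_rate()] p-value >
#' `alpha`) are amalgamated, smallest observed count first, until every
#' remaining pair is diagnosably distinct.
#'
#' @param gm a [genotype_matrix()] with population labels.
#' @param alpha significance level for the false-positive test.
#' @param tolerance fixation tolerance (0 = strict).
#' @param n_sim replicates for the false-positive test.
#' @param exclude individual ids removed before the analysis (e.g. putative
#'   hybrids).
#' @return an object of class `fixed_diff_result`: list with `populations`,
#'   symmetric matrices `counts`, `percents` (of loci callable in both),
#'   `mean_n` (mean summed individuals scored per shared locus), `pvalues`
#'   (NA where the test was not reached), `otus` (OTU label per population)
#'   and `merges` (the amalgamation trace).
#' @export
amalgamate_otus <- function(gm, alpha = 0.05, tolerance = 0, n_sim = 1000,
                            exclude = character()) {
  if (length(exclude)) gm <- drop_individuals(gm, exclude)
  pops <- sort(unique(gm$populations))
  if (length(pops) < 2) stop("need at least two populations")

  # population-pair matrices on the original (unmerged) populations
  aft0 <- allele_frequencies(gm)
  k <- length(pops)
  counts <- matrix(0L, k, k, dimnames = list(pops, pops))
  percents <- matrix(0, k, k, dimnames = list(pops, pops))
  mean_n <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  pvalues <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    fd <- count_fixed_differences(aft0, pops[i], pops[j], tolerance)
    counts[i, j] <- counts[j, i] <- fd$count
    percents[i, j] <- percents[j, i] <- 100 * fd$count / fd$n_compared
    sh <- !is.na(aft0$p[pops[i], ]) & !is.na(aft0$p[pops[j], ])
    mean_n[i, j] <- mean_n[j, i] <-
      mean(aft0$n[pops[i], sh] + aft0$n[pops[j], sh])
  }

  # progressive amalgamation on working clusters
  cluster <- stats::setNames(pops, pops)  # population -> current OTU label
  merges <- list()
  repeat {
    labels <- sort(unique(cluster))
    if (length(labels) < 2) break
    aft <- allele_frequencies(gm, grouping = unname(cluster[gm$populations]))
    pair_count <- function(a, b)
      count_fixed_differences(aft, a, b, tolerance)$count
    prs <- utils::combn(labels, 2)
    cnt <- apply(prs, 2, function(pr) pair_count(pr[1], pr[2]))
    ord <- order(cnt, prs[1, ], prs[2, ])
    merged <- FALSE
    # phase 1: zero fixed differences
    z <- ord[cnt[ord] == 0]
    if (length(z)) {
      pick <- prs[, z[1]]
      merges[[length(merges) + 1]] <-
        list(pair = pick, count = 0L, pvalue = NA_real_, rule = "zero")
      cluster[cluster %in% pick] <- paste(sort(pick), collapse = "+")
      next
    }
    # phase 2: smallest count first, merge if not significant
    for (idx in ord) {
      pr <- prs[, idx]
      fp <- false_positive_rate(aft, pr[1], pr[2], n_sim = n_sim,
                                tolerance = tolerance,
                                observed = cnt[idx])
      # record the p-value on the original-population matrix when the pair
      # is a pair of original populations
      if (all(pr %in% pops))
        pvalues[pr[1], pr[2]] <- pvalues[pr[2], pr[1]] <- fp$pvalue
      if (fp$pvalue > alpha) {
        merges[[length(merges) + 1]] <-
          list(pair = pr, count = cnt[idx], pvalue = fp$pvalue,
               rule = "false_positive")
        cluster[cluster %in% pr] <- paste(sort(pr), collapse = "+")
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  otus <- cluster
  structure(list(populations = pops,
                 counts = counts, percents = percents, mean_n = mean_n,
                 pvalues = pvalues, otus = otus, merges = merges,
                 n_otus = length(unique(otus)),
                 alpha = alpha, tolerance = tolerance),
            class = "fixed_diff_result")
}

#' @exportS3Method base::print
print.fixed_diff_result <- function(x, ...) {
  cat("fixed-difference analysis of", length(x$populations),
      "populations ->", x$n_otus, "OTU(s)\n")
  cat("\npercent fixed differences (lower) / mean individuals scored",
      "(upper):\n")
  m <- round(x$percents, 1)
  m[upper.tri(m)] <- round(x$mean_n, 1)[upper.tri(m)]
  print(m)
  cat("\nOTU assignment:\n")
  print(x$otus)
  invisible(x)
}

#' Count private alleles between two populations
#'
#' An allele is private to population A (with respect to B) when it is
#' present in A and absent in B, evaluated per allele per locus over loci
#' callable in both. Fixed differences necessarily contribute one private
#' allele in each direction, so each directional count is at least the
#' fixed-difference count.
#'
#' @param aft an [allele_frequencies()] table.
#' @param popA,popB population labels.
#' @return named vector `c(countAB, countBA)`: alleles private to A vs B,
#'   and to B vs A.
#' @export
count_private_alleles <- function(aft, popA, popB) {
  pa <- aft$p[popA, ]
  pb <- aft$p[popB, ]
  shared <- !is.na(pa) & !is.na(pb)
  pa <- pa[shared]; pb <- pb[shared]
  countAB <- sum(pa > 0 & pb == 0) + sum(pa < 1 & pb == 1)
  countBA <- sum(pb > 0 & pa == 0) + sum(pb < 1 & pa == 1)
  c(countAB = countAB, countBA = countBA)
}

#' Pairwise private-allele matrix
#'
#' @param aft an [allele_frequencies()] table.
#' @param pops populations to compare (default: all in `aft`).
#' @return square matrix M with M[A, B] = number of alleles private to A
#'   with respect to B (zero diagonal).
#' @export
private_allele_matrix <- function(aft, pops = rownames(aft$p)) {
  k <- length(pops)
  m <- matrix(0L, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    pc <- count_private_alleles(aft, pops[i], pops[j])
    m[i, j] <- pc[["countAB"]]
    m[j, i] <- pc[["countBA"]]
  }
  m
}
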