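#' Expected heterozygosity of a population
#'
#' Mean over callable loci of 2p(1-p), with p the alternate-allele frequency
#' in the population: the standard relative genetic-diversity measure under
#' Hardy-Weinberg expectations. Loci uncallable in the population are
#' excluded. The optional unbiased small-sample correction multiplies each
#' locus by 2n/(2n-1).
#'
#' @param gm a [genotype_matrix()].
#' @param population population label; when `NULL`, all populations are
#'   returned as a named vector.
#' @param unbiased apply the 2n/(2n-1) correction (off by default).
#' @return expected heterozygosity (scalar, or named vector over
#'   populations).
#' @export
expected_heterozygosity <- function(gm, population = NULL,
                                    unbiased = FALSE) {
  aft <- allele_frequencies(gm)
  pops <- population %||% rownames(aft$p)
  he <- vapply(pops, function(pop) {
    p <- aft$p[pop, ]
    n <- aft$n[pop, ]
    ok <- !is.na(p)
    if (!any(ok)) stop("population ", pop, " has no callable loci")
    h <- 2 * p[ok] * (1 - p[ok])
    if (unbiased) h <- h * (2 * n[ok]) / (2 * n[ok] - 1)
    mean(h)
  }, numeric(1))
  if (!is.null(population) && length(population) == 1L) unname(he) else he
}

he_from_genotypes <- function(g) {
  # He of one group from its raw genotype submatrix (internal fast path for
  # the permutation test)
  n <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * n)
  mean(2 * p * (1 - p), na.rm = TRUE)
}

#' Randomization test for a heterozygosity difference
#'
#' Tests whether two populations differ in expected heterozygosity by
#' re-randomization: individuals of the pooled sample are repeatedly
#' reassigned at random to two groups of the original sizes (the individual,
#' not the allele, is the randomization unit, preserving within-individual
#' genotype structure) and |delta He| recomputed each replicate. The p-value
#' uses the add-one rule (1 + #\{null >= observed\}) / (reps + 1), so it is
#' never exactly zero. Two-sided by construction.
#'
#' @param gm a [genotype_matrix()].
#' @param popA,popB population labels.
#' @param reps number of randomization replicates (default 10000).
#' @return object of class `he_test`: list with `he` (both observed values),
#'   `delta_he` (observed |difference|), `pvalue` and `reps`.
#' @export
heterozygosity_randomization_test <- function(gm, popA, popB,
                                              reps = 10000) {
  if (reps < 1) stop("reps must be at least 1")
  idx_a <- which(gm$populations == popA)
  idx_b <- which(gm$populations == popB)
  if (!length(idx_a) || !length(idx_b))
    stop("both populations must be non-empty")
  g <- gm$genotypes[c(idx_a, idx_b), , drop = FALSE]
  na <- length(idx_a)
  n_tot <- nrow(g)
  he_a <- he_from_genotypes(g[seq_len(na), , drop = FALSE])
  he_b <- he_from_genotypes(g[-seq_len(na), , drop = FALSE])
  obs <- abs(he_a - he_b)
  null <- vapply(seq_len(reps), function(r) {
    pick <- sample.int(n_tot, na)
    abs(he_from_genotypes(g[pick, , drop = FALSE]) -
          he_from_genotypes(g[-pick, , drop = FALSE]))
  }, numeric(1))
  structure(list(he = stats::setNames(c(he_a, he_b), c(popA, popB)),
                 delta_he = obs,
                 pvalue = (1 + sum(null >= obs)) / (reps + 1),
                 reps = reps),
            class = "he_test")
}

#' @exportS3Method base::print
print.he_test <- function(x, ...) {
  cat(sprintf("He %s = %.4f, %s = %.4f; |delta| = %.4f\n",
              names(x$he)[1], x$he[1], names(x$he)[2], x$he[2], x$delta_he))
  cat(sprintf("randomization p-value = %.4g (%d replicates)\n",
              x$pvalue, x$reps))
  invisible(x)
}
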