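#' Opposing-homozygote count for a pair of individuals
#'
#' Counts loci at which one individual is homozygous reference and the other
#' homozygous alternate - a pedigree inconsistency that Mendelian
#' transmission forbids in true parent-offspring pairs, so nonzero counts in
#' such pairs can only come from genotyping error. Loci missing in either
#' individual are skipped.
#'
#' @param gm a [genotype_matrix()].
#' @param indA,indB individual ids.
#' @return list with `count` and `loci_compared`.
#' @export
opposing_homozygote_count <- function(gm, indA, indB) {
  ids <- individual_ids(gm)
  if (!(indA %in% ids)) stop("unknown individual id: ", indA)
  if (!(indB %in% ids)) stop("unknown individual id: ", indB)
  a <- gm$genotypes[indA, ]
  b <- gm$genotypes[indB, ]
  ok <- !is.na(a) & !is.na(b)
  list(count = sum((a[ok] == 0 & b[ok] == 2) | (a[ok] == 2 & b[ok] == 0)),
       loci_compared = sum(ok))
}

#' All-pairs opposing-homozygote scan
#'
#' Computes the opposing-homozygote count for every pair of individuals,
#' expressed as a rate per compared locus, and summarizes the all-pairs
#' distribution (median and MAD) as the empirical null expectation for
#' unrelated pairs; true parent-offspring pairs fall far below it.
#'
#' @param gm a [genotype_matrix()] with at least 3 individuals.
#' @return object of class `kinship_scan`: list with `pairs` (data frame:
#'   `idA`, `idB`, `count`, `loci_compared`, `rate`, `score`), `median_rate`
#'   and `mad_rate` (MAD with the usual 1.4826 consistency constant).
#' @export
pairwise_inconsistency_null <- function(gm) {
  if (n_individuals(gm) < 3) stop("need at least three individuals")
  g <- gm$genotypes
  A0 <- (!is.na(g) & g == 0L) + 0
  A2 <- (!is.na(g) & g == 2L) + 0
  called <- (!is.na(g)) + 0
  opp <- A0 %*% t(A2)
  opp <- opp + t(opp)             # symmetric: counts for unordered pairs
  shared <- called %*% t(called)
  ids <- individual_ids(gm)
  idx <- which(upper.tri(opp), arr.ind = TRUE)
  pairs <- data.frame(idA = ids[idx[, 1]],
                      idB = ids[idx[, 2]],
                      count = opp[idx],
                      loci_compared = shared[idx])
  pairs$rate <- pairs$count / pairs$loci_compared
  med <- stats::median(pairs$rate)
  mad <- stats::mad(pairs$rate)
  pairs$score <- if (mad > 0) (pairs$rate - med) / mad else NA_real_
  structure(list(pairs = pairs, median_rate = med, mad_rate = mad),
            class = "kinship_scan")
}

#' @exportS3Method base::print
print.kinship_scan <- function(x, ...) {
  cat("opposing-homozygote scan:", nrow(x$pairs), "pairs\n")
  cat(sprintf("null rate: median %.4g, MAD %.4g\n",
              x$median_rate, x$mad_rate))
  lo <- utils::head(x$pairs[order(x$pairs$rate), ], 3)
  cat("lowest-rate pairs:\n")
  print(lo, row.names = FALSE)
  invisible(x)
}

#' Flag putative parent-offspring pairs
#'
#' Pairs whose opposing-homozygote rate lies below
#' median - `threshold_mads` x MAD of the all-pairs distribution are flagged
#' as parent-offspring-like outliers (one-sided: only the low tail is
#' informative). Full-sib pairs also depress the rate, so a flag means
#' "first-degree-relative-like", not strictly parent-offspring.
#'
#' @param scan a `kinship_scan` from [pairwise_inconsistency_null()].
#' @param threshold_mads outlier cut in MAD units (default 5).
#' @return data frame of flagged pairs (possibly zero rows), ordered by
#'   rate; when the MAD is zero (all rates equal), nothing is flagged and a
#'   warning is issued.
#' @export
detect_parent_offspring <- function(scan, threshold_mads = 5) {
  if (scan$mad_rate == 0) {
    warning("MAD of pair rates is zero; no outliers can be flagged")
    return(scan$pairs[0, ])
  }
  cut <- scan$median_rate - threshold_mads * scan$mad_rate
  flagged <- scan$pairs[scan$pairs$rate < cut, , drop = FALSE]
  flagged[order(flagged$rate), ]
}
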