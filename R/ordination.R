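#' Inter-individual genetic distance
#'
#' Euclidean distance between individuals on the allele-dosage scale
#' (genotypes 0/1/2 divided by 2). Missing genotypes are handled
#' pairwise-complete: the squared-difference sum over the loci called in both
#' individuals is rescaled by L / L_shared before the square root, the
#' standard missing-aware Euclidean metric. After filtering to >= 95% call
#' rate this correction is minor.
#'
#' @param gm a [genotype_matrix()] with at least two individuals.
#' @param method currently only `"euclidean_genotype"`.
#' @return a [stats::dist] object (zero diagonal, symmetric by construction).
#' @export
genetic_distance <- function(gm, method = "euclidean_genotype") {
  method <- match.arg(method)
  if (n_individuals(gm) < 2) stop("need at least two individuals")
  d <- stats::dist(gm$genotypes / 2, method = "euclidean")
  if (anyNA(d)) {
    m <- as.matrix(d)
    bad <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)[1, ]
    stop("individuals ", rownames(m)[bad[1]], " and ", colnames(m)[bad[2]],
         " share no called loci")
  }
  d
}

#' Principal coordinates analysis (classical multidimensional scaling)
#'
#' Double-centres -D^2/2 and eigendecomposes it ([stats::cmdscale]).
#' Negative eigenvalues (possible for non-Euclidean distances) are reported
#' but excluded from the variance denominator, so the per-axis percentages
#' are shares of the positive eigenvalue mass. Axis signs are fixed
#' deterministically: each axis is flipped so its largest-magnitude
#' coordinate is positive.
#'
#' @param d a distance matrix (`dist` or symmetric matrix), e.g. from
#'   [genetic_distance()].
#' @param k number of axes to retain (default: all positive axes).
#' @param populations optional population label per individual, carried
#'   through for plotting.
#' @return an object of class `pcoa_result`: list with `coordinates`
#'   (individuals x k), `eigenvalues` (all axes, non-increasing),
#'   `percent_variance` (per retained axis, of the positive mass) and
#'   `populations`.
#' @export
pcoa <- function(d, k = NULL, populations = NULL) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d)))
      stop("distance matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  # negative/zero trailing eigenvalues are expected; cmdscale warns about
  # them but drops the offending axes itself
  res <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- res$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (is.null(k)) k <- length(pos) else k <- min(k, length(pos))
  k <- min(k, ncol(res$points))
  coords <- res$points[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-magnitude coordinate on each axis positive
  for (j in seq_len(ncol(coords))) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  pct <- 100 * eig[seq_len(k)] / sum(eig[pos])
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 percent_variance = pct,
                 populations = populations),
            class = "pcoa_result")
}

#' @exportS3Method base::print
print.pcoa_result <- function(x, ...) {
  k <- ncol(x$coordinates)
  cat("principal coordinates analysis:", nrow(x$coordinates),
      "individuals,", k, "retained axes\n")
  cat("percent variance (positive eigenvalue mass):\n")
  print(round(stats::setNames(x$percent_variance,
                              colnames(x$coordinates)), 2))
  n_neg <- sum(x$eigenvalues < 0)
  if (n_neg > 0) cat(n_neg, "negative eigenvalues excluded from the",
                     "variance denominator\n")
  invisible(x)
}

#' @exportS3Method graphics::plot
plot.pcoa_result <- function(x, axes = c(1, 2), ...) {
  co <- x$coordinates[, axes, drop = FALSE]
  pops <- x$populations %||% rep("all", nrow(co))
  cols <- as.integer(factor(pops))
  lab <- sprintf("%s (%.1f%%)", colnames(co), x$percent_variance[axes])
  graphics::plot(co, col = cols, pch = 19, xlab = lab[1], ylab = lab[2], ...)
  graphics::legend("topright", legend = levels(factor(pops)),
                   col = seq_along(levels(factor(pops))), pch = 19,
                   cex = 0.8)
  invisible(x)
}

#' Scree table of a PCoA
#'
#' @param ordination a `pcoa_result` from [pcoa()].
#' @return data frame with `axis`, `eigenvalue`, `percent` and `cumulative`
#'   over the positive axes (cumulative reaches 100 at the last one).
#' @export
scree <- function(ordination) {
  eig <- ordination$eigenvalues
  pos <- eig[eig > sqrt(.Machine$double.eps) * max(abs(eig))]
  pct <- 100 * pos / sum(pos)
  data.frame(axis = seq_along(pos),
             eigenvalue = pos,
             percent = pct,
             cumulative = cumsum(pct))
}
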