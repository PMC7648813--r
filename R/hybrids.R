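#' The six hybrid genotype-frequency classes
#'
#' Each class is defined by its gene-pair weights (w00, w01, w11): the
#' probabilities that, at a random locus, an individual carries both gene
#' copies from parental pool 0, one copy from each pool, or both from pool 1.
#' The canonical two-generation set is P0 = (1,0,0), P1 = (0,0,1),
#' F1 = (0,1,0), F2 = (1/4,1/2,1/4), F1xP0 = (1/2,1/2,0),
#' F1xP1 = (0,1/2,1/2).
#'
#' @return data frame with columns `class`, `w00`, `w01`, `w11`.
#' @export
hybrid_classes <- function() {
  data.frame(
    class = c("P0", "P1", "F1", "F2", "F1xP0", "F1xP1"),
    w00 = c(1, 0, 0, 0.25, 0.5, 0),
    w01 = c(0, 0, 1, 0.50, 0.5, 0.5),
    w11 = c(0, 1, 0, 0.25, 0, 0.5)
  )
}

#' Genotype distribution of a hybrid class at one locus
#'
#' With fxy the genotype distribution of one gene copy from pool x and one
#' from pool y (alternate-allele frequencies p0 and p1), a class with
#' gene-pair weights (w00, w01, w11) has
#' P(g) = w00 f00(g) + w01 f01(g) + w11 f11(g).
#'
#' @param hclass class name (one of [hybrid_classes()]`$class`).
#' @param p0,p1 alternate-allele frequencies of the two parental pools
#'   (scalars or equal-length vectors of loci).
#' @return matrix (loci x 3) of P(g = 0), P(g = 1), P(g = 2); a single locus
#'   gives a 1 x 3 matrix.
#' @export
class_genotype_frequencies <- function(hclass, p0, p1) {
  classes <- hybrid_classes()
  row <- classes[classes$class == hclass, ]
  if (nrow(row) != 1) stop("unknown hybrid class: ", hclass)
  if (any(p0 < 0 | p0 > 1) || any(p1 < 0 | p1 > 1))
    stop("allele frequencies must lie in [0, 1]")
  f00 <- cbind((1 - p0)^2, 2 * p0 * (1 - p0), p0^2)
  f01 <- cbind((1 - p0) * (1 - p1),
               p0 * (1 - p1) + p1 * (1 - p0),
               p0 * p1)
  f11 <- cbind((1 - p1)^2, 2 * p1 * (1 - p1), p1^2)
  out <- row$w00 * f00 + row$w01 * f01 + row$w11 * f11
  colnames(out) <- c("g0", "g1", "g2")
  out
}

#' Bayesian assignment to hybrid genotype-frequency classes
#'
#' Classifies every individual into one of the six genotype-frequency
#' classes (parentals P0/P1, F1, F2 and the two first-generation
#' backcrosses) without pre-specifying the parental populations. A Gibbs
#' sampler alternates between latent class labels, the two parental pools'
#' per-locus allele frequencies (Jeffreys Beta(1/2,1/2) priors) and the
#' class mixing proportions (Jeffreys Dirichlet(1/2,...) prior); missing
#' genotypes contribute likelihood 1. Posterior class probabilities are the
#' label frequencies over the post-burn-in sweeps.
#'
#' Mixture pool labels are unidentifiable a priori; they are anchored after
#' sampling so that the first individual's MAP parental pool is pool 0
#' (P0/P1 and F1xP0/F1xP1 are swapped when needed), making reported classes
#' stable across runs. Use `set.seed()` for reproducible chains.
#'
#' @param gm a [genotype_matrix()] with at least 2 individuals and at least
#'   one polymorphic locus.
#' @param burnin,sweeps burn-in and retained Gibbs sweeps (default 10000
#'   each).
#' @return object of class `hybrid_posterior`: list with `posterior`
#'   (individuals x 6 probability matrix), `map` (MAP class per individual,
#'   ties broken by canonical class order), `populations` and
#'   `class_counts`.
#' @export
classify_hybrids <- function(gm, burnin = 10000, sweeps = 10000) {
  if (n_individuals(gm) < 2) stop("need at least two individuals")
  poly <- remove_monomorphic_loci(gm)
  if (n_loci(poly) == 0)
    stop("all loci monomorphic: no information to separate pools")
  classes <- hybrid_classes()
  g <- gm$genotypes
  g[is.na(g)] <- -1L
  res <- hybrid_gibbs_cpp(g, as.matrix(classes[c("w00", "w01", "w11")]),
                          as.integer(burnin), as.integer(sweeps))
  post <- res$posterior
  dimnames(post) <- list(individual_ids(gm), classes$class)
  # pool-label anchoring: pool 0 is the first individual's MAP parental pool
  if (post[1, "P1"] > post[1, "P0"]) {
    post <- post[, c("P1", "P0", "F1", "F2", "F1xP1", "F1xP0"), drop = FALSE]
    colnames(post) <- classes$class
  }
  map <- classes$class[apply(post, 1, which.max)]
  structure(list(posterior = post,
                 map = stats::setNames(map, individual_ids(gm)),
                 populations = gm$populations,
                 class_counts = table(factor(map,
                                             levels = classes$class))),
            class = "hybrid_posterior")
}

#' @exportS3Method base::print
print.hybrid_posterior <- function(x, ...) {
  cat("hybrid classification of", nrow(x$posterior), "individuals\n")
  cat("MAP class counts:\n")
  print(x$class_counts)
  nonpar <- names(x$map)[!(x$map %in% c("P0", "P1"))]
  if (length(nonpar)) {
    cat("non-parental individuals:\n")
    print(round(x$posterior[nonpar, , drop = FALSE], 3))
  }
  invisible(x)
}

#' Assignment table of a hybrid classification
#'
#' Groups individuals by population and MAP class with their posterior
#' probabilities, ordered by canonical class order then id (deterministic).
#'
#' @param posterior a `hybrid_posterior` from [classify_hybrids()].
#' @return data frame with `id`, `population`, `map_class`, `count` (number
#'   of individuals sharing that population x class cell) and the six
#'   posterior columns.
#' @export
assignment_table <- function(posterior) {
  classes <- hybrid_classes()$class
  ids <- rownames(posterior$posterior)
  df <- data.frame(id = ids,
                   population = unname(posterior$populations[ids]),
                   map_class = unname(posterior$map[ids]))
  df <- cbind(df, as.data.frame(posterior$posterior))
  key <- paste(df$population, df$map_class)
  df$count <- as.integer(table(key)[key])
  ord <- order(match(df$map_class, classes), df$id)
  rownames(df) <- NULL
  df[ord, c("id", "population", "map_class", "count", classes)]
}
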