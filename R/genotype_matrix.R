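#' SNP genotype matrix with locus and individual metadata
#'
#' The central container of the package: an individuals x loci matrix of
#' diploid SNP genotypes coded as counts of the alternate allele
#' (0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
#' `NA` = missing call), together with a population label per individual and
#' per-locus metadata of the kind delivered by reduced-representation
#' (DArTseq-style) genotyping: sequence-tag identity, SNP position within the
#' tag, repeatability across technical replicates, call rate and mean read
#' depth.
#'
#' @param genotypes integer matrix, individuals in rows, loci in columns,
#'   values in \{0, 1, 2, NA\}.
#' @param populations character vector of population labels, one per
#'   individual (recycled if length 1).
#' @param individual_ids unique individual identifiers; defaults to the row
#'   names of `genotypes`.
#' @param loci data frame of per-locus metadata with columns `clone_id`,
#'   `snp_position`, `rep_avg`, `call_rate`, `read_depth`; missing columns are
#'   filled with defaults (`clone_id` from column names, `snp_position` 0,
#'   the quality fields `NA` = unknown).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `genotypes`, `populations` (named by individual) and `loci`.
#' @export
#' @examples
#' g <- matrix(c(0L, 1L, 2L, NA), nrow = 2,
#'             dimnames = list(c("a", "b"), c("L1", "L2")))
#' gm <- genotype_matrix(g, populations = c("popA", "popB"))
#' gm
genotype_matrix <- function(genotypes, populations,
                            individual_ids = rownames(genotypes),
                            loci = NULL) {
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  n <- nrow(genotypes)
  L <- ncol(genotypes)
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(n))
  individual_ids <- as.character(individual_ids)
  if (length(individual_ids) != n)
    stop("individual_ids must have one entry per row of genotypes")
  if (anyDuplicated(individual_ids))
    stop("duplicate individual id: ",
         paste(unique(individual_ids[duplicated(individual_ids)]),
               collapse = ", "))
  if (length(populations) == 1L) populations <- rep(populations, n)
  populations <- as.character(populations)
  if (length(populations) != n)
    stop("populations must have one label per individual")
  if (anyNA(populations))
    stop("every individual must have exactly one population label")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotypes must be 0, 1, 2 or NA")
  loci <- complete_locus_meta(loci, L, colnames(genotypes))
  rownames(genotypes) <- individual_ids
  colnames(genotypes) <- loci$clone_id_label
  loci$clone_id_label <- NULL
  names(populations) <- individual_ids
  structure(list(genotypes = genotypes,
                 populations = populations,
                 loci = loci),
            class = "genotype_matrix")
}

complete_locus_meta <- function(loci, L, col_names) {
  if (is.null(loci)) loci <- data.frame(row.names = seq_len(L %||% 0))
  loci <- as.data.frame(loci)
  if (L > 0 && nrow(loci) == 0) loci <- data.frame(row.names = seq_len(L))
  if (nrow(loci) != L)
    stop("loci metadata must have one row per genotype column")
  if (is.null(loci$clone_id)) {
    loci$clone_id <- if (!is.null(col_names)) col_names else
      paste0("L", seq_len(L))
  }
  loci$clone_id <- as.character(loci$clone_id)
  if (is.null(loci$snp_position)) loci$snp_position <- rep(0L, L)
  if (is.null(loci$rep_avg)) loci$rep_avg <- rep(NA_real_, L)
  if (is.null(loci$call_rate)) loci$call_rate <- rep(NA_real_, L)
  if (is.null(loci$read_depth)) loci$read_depth <- rep(NA_real_, L)
  stopifnot(all(loci$snp_position >= 0, na.rm = TRUE))
  frac <- c(loci$rep_avg, loci$call_rate)
  frac <- frac[!is.na(frac)]
  if (length(frac) && (min(frac) < 0 || max(frac) > 1))
    stop("rep_avg and call_rate must lie in [0, 1]")
  if (any(loci$read_depth < 0, na.rm = TRUE))
    stop("read_depth must be non-negative")
  # a locus column name that is unique even when clone_ids repeat
  # (secondary SNPs on one tag)
  loci$clone_id_label <- make.unique(paste0(loci$clone_id, ".",
                                            loci$snp_position))
  rownames(loci) <- NULL
  loci[c("clone_id", "snp_position", "rep_avg", "call_rate", "read_depth",
         "clone_id_label")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_individuals(x), "individuals x",
      n_loci(x), "loci\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("missing calls: %.2f%%\n", 100 * miss))
  cat("populations:\n")
  print(table(x$populations))
  invisible(x)
}

#' @export
summary.genotype_matrix <- function(object, ...) {
  print(object)
  cat("locus metadata:\n")
  print(summary(object$loci[c("rep_avg", "call_rate", "read_depth")]))
  invisible(object)
}

#' Numbers of individuals and loci
#' @param gm a [genotype_matrix()].
#' @return integer count.
#' @export
n_individuals <- function(gm) nrow(gm$genotypes)

#' @rdname n_individuals
#' @export
n_loci <- function(gm) ncol(gm$genotypes)

#' Individual identifiers of a genotype matrix
#' @param gm a [genotype_matrix()].
#' @export
individual_ids <- function(gm) rownames(gm$genotypes)

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param x a [genotype_matrix()].
#' @param i individual selector (indices, logical, or ids).
#' @param j locus selector (indices or logical).
#' @param ... ignored.
#' @return a `genotype_matrix` restricted to the selection.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_individuals(x))
  if (missing(j)) j <- seq_len(n_loci(x))
  if (is.character(i)) {
    idx <- match(i, individual_ids(x))
    if (anyNA(idx)) stop("unknown individual id: ",
                         paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  g <- x$genotypes[i, j, drop = FALSE]
  loci <- x$loci[j, , drop = FALSE]
  rownames(loci) <- NULL
  structure(list(genotypes = g,
                 populations = x$populations[i],
                 loci = loci),
            class = "genotype_matrix")
}

#' Remove individuals by id
#' @param gm a [genotype_matrix()].
#' @param ids character ids to drop; unknown ids are ignored.
#' @export
drop_individuals <- function(gm, ids) {
  keep <- !(individual_ids(gm) %in% ids)
  gm[keep, ]
}
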