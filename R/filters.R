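#' @name filters
#' @title Staged quality filtering of SNP genotype matrices
#'
#' @description Six quality filters in the order a reduced-representation SNP
#' dataset is normally cleaned before population-genetic analysis:
#' one SNP per sequence tag, read-depth bounds, individual call rate,
#' monomorphic-locus removal, repeatability, and locus call rate.
#' [run_filter_pipeline()] chains them and returns a per-stage report.
#'
#' Loci whose quality metadata are unknown (`NA`, e.g. generic VCF input)
#' pass the metadata-based filters (read depth, repeatability) unless
#' `strict = TRUE`, in which case unknown metadata is an error.
NULL

#' Keep a single SNP per sequence tag
#'
#' Reduced-representation tags often carry several SNPs, which are in strong
#' linkage; all downstream analyses assume one independent SNP per tag. For
#' each distinct `clone_id` the locus with the highest repeatability is
#' retained; ties are broken by lowest `snp_position`, then input order.
#'
#' @param gm a [genotype_matrix()].
#' @return filtered `genotype_matrix`.
#' @export
select_one_snp_per_tag <- function(gm) {
  rep_avg <- gm$loci$rep_avg
  rep_key <- ifelse(is.na(rep_avg), -1, rep_avg)
  ord <- order(gm$loci$clone_id, -rep_key, gm$loci$snp_position,
               seq_len(n_loci(gm)))
  first <- !duplicated(gm$loci$clone_id[ord])
  keep <- sort(ord[first])
  gm[, keep]
}

#' Filter loci by mean read depth
#'
#' Removes loci outside the closed interval `[min_depth, max_depth]`.
#' Unknown depth passes unless `strict`.
#'
#' @param gm a [genotype_matrix()].
#' @param min_depth,max_depth inclusive depth bounds.
#' @param strict error on unknown (`NA`) depth instead of passing it.
#' @export
filter_by_read_depth <- function(gm, min_depth = 5, max_depth = 100,
                                 strict = FALSE) {
  if (min_depth > max_depth)
    stop("min_depth must not exceed max_depth")
  d <- gm$loci$read_depth
  if (strict && anyNA(d)) stop("unknown read depth with strict = TRUE")
  keep <- is.na(d) | (d >= min_depth & d <= max_depth)
  gm[, keep]
}

#' Remove individuals with poor call rate
#'
#' Individuals whose fraction of non-missing genotype calls is strictly below
#' `min_ind_callrate` are removed.
#'
#' @param gm a [genotype_matrix()].
#' @param min_ind_callrate threshold on the per-individual call rate.
#' @return filtered `genotype_matrix`; the removed ids are available in
#'   attribute `"removed"`.
#' @export
filter_individuals_by_callrate <- function(gm, min_ind_callrate = 0.5) {
  cr <- rowMeans(!is.na(gm$genotypes))
  keep <- cr >= min_ind_callrate
  out <- gm[keep, ]
  attr(out, "removed") <- individual_ids(gm)[!keep]
  out
}

#' Remove monomorphic loci
#'
#' A locus is monomorphic when its non-missing genotypes show only one
#' allele: all 0 (reference fixed) or all 2 (alternate fixed). Any
#' heterozygote implies both alleles segregate. All-missing loci are also
#' removed.
#'
#' @param gm a [genotype_matrix()].
#' @export
remove_monomorphic_loci <- function(gm) {
  g <- gm$genotypes
  has_het <- colSums(g == 1L, na.rm = TRUE) > 0
  has_ref <- colSums(g == 0L, na.rm = TRUE) > 0
  has_alt <- colSums(g == 2L, na.rm = TRUE) > 0
  keep <- has_het | (has_ref & has_alt)
  gm[, keep]
}

#' Filter loci by repeatability
#'
#' Removes loci whose technical-replicate repeatability (`rep_avg`) is
#' strictly below `min_rep`. Unknown repeatability passes unless `strict`.
#'
#' @param gm a [genotype_matrix()].
#' @param min_rep repeatability threshold.
#' @param strict error on unknown repeatability.
#' @export
filter_by_repeatability <- function(gm, min_rep = 0.99, strict = FALSE) {
  r <- gm$loci$rep_avg
  if (strict && anyNA(r)) stop("unknown repeatability with strict = TRUE")
  keep <- is.na(r) | r >= min_rep
  gm[, keep]
}

#' Filter loci by call rate
#'
#' The per-locus call rate is recomputed on the current set of individuals
#' (the vendor `call_rate` column is kept for provenance only); loci strictly
#' below `min_callrate` are removed.
#'
#' @param gm a [genotype_matrix()].
#' @param min_callrate call-rate threshold.
#' @export
filter_by_locus_callrate <- function(gm, min_callrate = 0.95) {
  cr <- colMeans(!is.na(gm$genotypes))
  gm[, cr >= min_callrate]
}

#' Default thresholds for the filter pipeline
#'
#' @param min_depth,max_depth read-depth bounds (default 5 and 100).
#' @param min_ind_callrate individual call-rate threshold (default 0.5).
#' @param min_rep repeatability threshold (default 0.99).
#' @param min_locus_callrate locus call-rate threshold (default 0.95).
#' @param strict error on unknown locus metadata.
#' @return a list of thresholds for [run_filter_pipeline()].
#' @export
filter_config <- function(min_depth = 5, max_depth = 100,
                          min_ind_callrate = 0.5, min_rep = 0.99,
                          min_locus_callrate = 0.95, strict = FALSE) {
  list(min_depth = min_depth, max_depth = max_depth,
       min_ind_callrate = min_ind_callrate, min_rep = min_rep,
       min_locus_callrate = min_locus_callrate, strict = strict)
}

#' Run the staged filter pipeline
#'
#' Applies, in order: one SNP per tag, read-depth bounds, individual call
#' rate, monomorphic-locus removal, repeatability, locus call rate. The
#' order matters (e.g. removing individuals can render loci monomorphic, and
#' locus call rates are recomputed on the retained individuals).
#'
#' @param gm a [genotype_matrix()].
#' @param config thresholds from [filter_config()].
#' @param verbose print the report.
#' @return list with elements `gm` (the filtered matrix) and `report`
#'   (a `filter_report` data frame: one row per stage with loci/individuals
#'   removed and remaining).
#' @export
run_filter_pipeline <- function(gm, config = filter_config(),
                                verbose = FALSE) {
  stages <- list(
    secondary_snps = function(x) select_one_snp_per_tag(x),
    read_depth = function(x)
      filter_by_read_depth(x, config$min_depth, config$max_depth,
                           strict = isTRUE(config$strict)),
    individual_call_rate = function(x)
      filter_individuals_by_callrate(x, config$min_ind_callrate),
    monomorphic = function(x) remove_monomorphic_loci(x),
    repeatability = function(x)
      filter_by_repeatability(x, config$min_rep,
                              strict = isTRUE(config$strict)),
    locus_call_rate = function(x)
      filter_by_locus_callrate(x, config$min_locus_callrate)
  )
  rows <- vector("list", length(stages))
  cur <- gm
  for (k in seq_along(stages)) {
    before_l <- n_loci(cur)
    before_i <- n_individuals(cur)
    cur <- stages[[k]](cur)
    rows[[k]] <- data.frame(
      stage = names(stages)[k],
      loci_removed = before_l - n_loci(cur),
      individuals_removed = before_i - n_individuals(cur),
      loci_remaining = n_loci(cur),
      individuals_remaining = n_individuals(cur)
    )
  }
  report <- do.call(rbind, rows)
  class(report) <- c("filter_report", "data.frame")
  attr(report, "initial") <- c(loci = n_loci(gm),
                               individuals = n_individuals(gm))
  if (verbose) print(report)
  list(gm = cur, report = report)
}

#' @exportS3Method base::print
print.filter_report <- function(x, ...) {
  init <- attr(x, "initial")
  cat(sprintf("filter report: %d loci x %d individuals in\n",
              init["loci"], init["individuals"]))
  print.data.frame(x, row.names = FALSE)
  last <- x[nrow(x), ]
  cat(sprintf("retained: %d loci x %d individuals\n",
              last$loci_remaining, last$individuals_remaining))
  invisible(x)
}

#' Write a filter report as CSV or JSON
#' @param report a `filter_report` from [run_filter_pipeline()].
#' @param path output path; format chosen by extension (.csv or .json).
#' @export
write_filter_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  }
  invisible(path)
}
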