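#' Read a DArT-style one-row-per-locus SNP CSV
#'
#' Expects one row per locus with per-locus metadata columns followed by one
#' genotype column per individual. Genotype cells are counts of the alternate
#' allele (0/1/2); configured missing tokens and any unparseable cell become
#' `NA` (the latter with a warning giving the count).
#'
#' @param path path to the CSV file.
#' @param populations population label per individual: either a character
#'   vector named by individual id, an unnamed vector in column order, or a
#'   single label. Defaults to `"unknown"`.
#' @param encoding list controlling parsing: `missing_tokens` (cell values
#'   treated as missing, default `c("-", "", "NA")`) and `col_map`, a named
#'   character vector mapping the canonical metadata fields `clone_id`,
#'   `snp_position`, `rep_avg`, `call_rate`, `read_depth` to the file's column
#'   names (default `CloneID`, `SnpPosition`, `RepAvg`, `CallRate`,
#'   `ReadDepth`).
#' @return a [genotype_matrix()].
#' @export
read_dart_csv <- function(path, populations = "unknown",
                          encoding = dart_encoding()) {
  if (!file.exists(path)) stop("file not found: ", path)
  enc <- utils::modifyList(dart_encoding(), encoding)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  col_map <- enc$col_map
  for (field in names(col_map)) {
    if (!col_map[[field]] %in% names(raw))
      stop("missing mandatory metadata column '", col_map[[field]],
           "' (maps to ", field, ")")
  }
  meta_cols <- unname(col_map)
  ind_cols <- names(raw)[!(names(raw) %in% meta_cols)]  # keep duplicates
  if (anyDuplicated(ind_cols))
    stop("duplicate individual id: ",
         paste(unique(ind_cols[duplicated(ind_cols)]), collapse = ", "))
  loci <- data.frame(
    clone_id = raw[[col_map[["clone_id"]]]],
    snp_position = as.integer(raw[[col_map[["snp_position"]]]]),
    rep_avg = suppressWarnings(as.numeric(raw[[col_map[["rep_avg"]]]])),
    call_rate = suppressWarnings(as.numeric(raw[[col_map[["call_rate"]]]])),
    read_depth = suppressWarnings(as.numeric(raw[[col_map[["read_depth"]]]]))
  )
  cells <- as.matrix(raw[ind_cols])
  cells[cells %in% enc$missing_tokens] <- NA
  g <- suppressWarnings(matrix(as.integer(cells), nrow = nrow(cells)))
  g[!(g %in% 0:2)] <- NA_integer_
  n_bad <- sum(!is.na(cells) & is.na(g))
  if (n_bad > 0)
    warning(n_bad, " unparseable genotype cell(s) set to missing")
  g <- t(g) # individuals in rows
  rownames(g) <- ind_cols
  pops <- resolve_populations(populations, ind_cols)
  genotype_matrix(g, populations = pops, individual_ids = ind_cols,
                  loci = loci)
}

#' Default DArT CSV parsing configuration
#' @return list with `missing_tokens` and `col_map` (see [read_dart_csv()]).
#' @export
dart_encoding <- function() {
  list(missing_tokens = c("-", "", "NA"),
       col_map = c(clone_id = "CloneID", snp_position = "SnpPosition",
                   rep_avg = "RepAvg", call_rate = "CallRate",
                   read_depth = "ReadDepth"))
}

resolve_populations <- function(populations, ids) {
  if (!is.null(names(populations))) {
    miss <- setdiff(ids, names(populations))
    if (length(miss))
      stop("no population label for individual(s): ",
           paste(miss, collapse = ", "))
    return(unname(populations[ids]))
  }
  if (length(populations) == 1L) return(rep(populations, length(ids)))
  if (length(populations) != length(ids))
    stop("populations must be length 1, one per individual, or named by id")
  populations
}

#' Write a genotype matrix as a DArT-style one-row-per-locus CSV
#'
#' Inverse of [read_dart_csv()]: genotypes and the five metadata columns
#' round-trip exactly for valid inputs.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param missing_token string written for missing genotype calls.
#' @return `path`, invisibly.
#' @export
write_dart_csv <- function(gm, path, missing_token = "-") {
  g <- t(gm$genotypes)
  cells <- matrix(as.character(g), nrow = nrow(g))
  cells[is.na(cells)] <- missing_token
  colnames(cells) <- individual_ids(gm)
  out <- cbind(
    data.frame(CloneID = gm$loci$clone_id,
               SnpPosition = gm$loci$snp_position,
               RepAvg = gm$loci$rep_avg,
               CallRate = gm$loci$call_rate,
               ReadDepth = gm$loci$read_depth),
    as.data.frame(cells, check.names = FALSE)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a generic genotype CSV
#'
#' A plain table of 0/1/2 genotypes with ids on one margin and locus names on
#' the other; no locus metadata (quality fields are set to unknown, which
#' passes the metadata filters).
#'
#' @param path path to the CSV.
#' @param orientation `"individuals_rows"` (default) or `"loci_rows"`.
#' @param populations as in [read_dart_csv()].
#' @param missing_tokens cell values treated as missing.
#' @return a [genotype_matrix()].
#' @export
read_genotype_csv <- function(path,
                              orientation = c("individuals_rows",
                                              "loci_rows"),
                              populations = "unknown",
                              missing_tokens = c("-", "", "NA")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, row.names = 1,
                         colClasses = "character")
  cells <- as.matrix(raw)
  cells[cells %in% missing_tokens] <- NA
  g <- suppressWarnings(matrix(as.integer(cells), nrow = nrow(cells),
                               dimnames = dimnames(cells)))
  n_bad <- sum(!is.na(cells) & (is.na(g) | !(g %in% c(0:2, NA))))
  g[!(g %in% 0:2)] <- NA_integer_
  if (n_bad > 0)
    warning(n_bad, " unparseable genotype cell(s) set to missing")
  if (orientation == "loci_rows") g <- t(g)
  ids <- rownames(g)
  if (anyDuplicated(ids)) stop("duplicate individual id")
  loci <- data.frame(clone_id = colnames(g))
  genotype_matrix(g, populations = resolve_populations(populations, ids),
                  individual_ids = ids, loci = loci)
}

#' Read genotypes from a VCF file
#'
#' Biallelic records are converted from their GT field (0/0 -> 0, 0/1 -> 1,
#' 1/1 -> 2, missing -> `NA`; phased separators accepted). Multiallelic
#' records are skipped with a warning. `clone_id` defaults to `CHROM:POS`;
#' per-locus mean read depth is taken from FORMAT/DP when present, otherwise
#' left unknown (unknown metadata passes the metadata filters).
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param populations as in [read_dart_csv()].
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, populations = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi))
    warning(sum(multi), " multiallelic record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, names(gt)))
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  if (nrow(fix) == 0) stop("no biallelic records in VCF")
  gsub_gt <- gsub("\\|", "/", gt)
  code <- matrix(NA_integer_, nrow(gsub_gt), ncol(gsub_gt))
  code[gsub_gt %in% c("0/0")] <- 0L
  code[gsub_gt %in% c("0/1", "1/0")] <- 1L
  code[gsub_gt %in% c("1/1")] <- 2L
  depth <- rep(NA_real_, nrow(fix))
  dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  if (!is.null(dp)) {
    if (is.null(dim(dp))) dp <- matrix(dp, nrow = length(multi))
    dp <- dp[!multi, , drop = FALSE]
    depth <- rowMeans(dp, na.rm = TRUE)
    depth[is.nan(depth)] <- NA_real_
  }
  loci <- data.frame(clone_id = paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                     snp_position = 0L,
                     rep_avg = NA_real_,
                     call_rate = NA_real_,
                     read_depth = depth)
  g <- t(code)
  ids <- colnames(gt)
  rownames(g) <- ids
  genotype_matrix(g, populations = resolve_populations(populations, ids),
                  individual_ids = ids, loci = loci)
}
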