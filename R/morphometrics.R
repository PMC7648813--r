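#' Canonical morphometric trait names
#'
#' The eight measured traits: body mass (kg), head length (mm), head width
#' (mm), body length (cm), tail length (cm), knee-to-heel (mm), ear length
#' (mm), ear width (mm).
#' @return character vector of column names.
#' @export
morph_traits <- function() {
  c("mass", "head_length", "head_width", "body_length", "tail_length",
    "knee_to_heel", "ear_length", "ear_width")
}

#' Default site-to-region mapping
#' @return named character vector site -> region.
#' @export
site_regions <- function() {
  c(Taravale = "Northern", Blackbraes = "Northern",
    RedcliffeVale = "Central",
    Bendoc = "Southern", Wombat = "Southern")
}

#' Validate a morphometrics table
#'
#' Checks the schema (id, site, sex, the eight traits), derives the region
#' from the site when absent, and keeps adults only when an `adult` column
#' is present.
#'
#' @param df data frame of per-individual records.
#' @param site_map named vector site -> region used when `region` is absent.
#' @return validated data frame with a `region` factor in canonical order
#'   (Northern, Central, Southern, others appended).
#' @export
morph_table <- function(df, site_map = site_regions()) {
  need <- c("id", "site", "sex", morph_traits())
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing morphometrics column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stop("duplicate individual id")
  if (is.null(df$region)) {
    unknown <- setdiff(unique(df$site), names(site_map))
    if (length(unknown)) stop("no region mapping for site(s): ",
                              paste(unknown, collapse = ", "))
    df$region <- unname(site_map[df$site])
  }
  if (!is.null(df$adult)) df <- df[as.logical(df$adult), , drop = FALSE]
  for (tr in morph_traits()) {
    v <- df[[tr]]
    if (any(v <= 0, na.rm = TRUE)) stop("trait ", tr, " must be positive")
  }
  canonical <- c("Northern", "Central", "Southern")
  lev <- c(intersect(canonical, unique(df$region)),
           setdiff(unique(df$region), canonical))
  df$region <- factor(df$region, levels = lev)
  rownames(df) <- NULL
  df
}

#' Per-region morphometric summary
#'
#' Sample size, mean and standard deviation of each trait per region.
#'
#' @param morph a [morph_table()] data frame.
#' @return data frame with one row per region x trait: `region`, `trait`,
#'   `n`, `mean`, `sd`.
#' @export
region_summary <- function(morph, grouping = "region") {
  g <- factor(morph[[grouping]])
  if (any(table(g) < 2)) stop("every region needs at least two individuals")
  out <- do.call(rbind, lapply(levels(g), function(r) {
    sub <- morph[g == r, morph_traits(), drop = FALSE]
    data.frame(region = r, trait = morph_traits(),
               n = nrow(sub),
               mean = vapply(sub, mean, numeric(1)),
               sd = vapply(sub, stats::sd, numeric(1)))
  }))
  rownames(out) <- NULL
  out
}

#' Screen traits for sex effects by backward elimination
#'
#' Fits `trait ~ region * sex` for each trait on (possibly unbalanced) data
#' and removes the least significant term iteratively (interaction before
#' main effects, respecting marginality) until only terms with p <= `alpha`
#' remain. Degenerate fits (zero residual variance) skip the trait with a
#' warning, as does data containing a single sex.
#'
#' @param morph a [morph_table()] data frame.
#' @param alpha elimination threshold (default 0.05).
#' @return data frame with one row per trait x retained term: `trait`,
#'   `term`, `F`, `df1`, `df2`, `p`; traits whose final model is
#'   intercept-only contribute a single row with `term = "(none)"`. The
#'   logical attribute `"sex_retained"` (named by trait) records whether a
#'   sex term survived.
#' @export
sex_effect_screen <- function(morph, alpha = 0.05) {
  if (length(unique(morph$sex)) < 2) {
    warning("only one sex present; screen skipped")
    return(NULL)
  }
  rows <- list()
  sex_kept <- logical(0)
  for (tr in morph_traits()) {
    dat <- data.frame(y = morph[[tr]], region = morph$region,
                      sex = factor(morph$sex))
    if (stats::var(dat$y) == 0) {
      warning("trait ", tr, " is constant; skipped")
      next
    }
    fit <- stats::lm(y ~ region * sex, data = dat)
    repeat {
      d <- tryCatch(stats::drop1(fit, test = "F"),
                    error = function(e) NULL)
      if (is.null(d) || nrow(d) < 2) break
      terms_d <- rownames(d)[-1]
      pvals <- d[["Pr(>F)"]][-1]
      if (!length(pvals) || all(is.na(pvals))) break
      worst <- which.max(pvals)
      if (is.na(pvals[worst]) || pvals[worst] <= alpha) break
      fit <- stats::update(fit,
                           stats::as.formula(paste(". ~ . -",
                                                   terms_d[worst])))
    }
    d <- stats::drop1(fit, test = "F")
    kept <- rownames(d)[-1]
    if (length(kept)) {
      rows[[tr]] <- data.frame(trait = tr, term = kept,
                               F = d$`F value`[-1],
                               df1 = d$Df[-1],
                               df2 = stats::df.residual(fit),
                               p = d$`Pr(>F)`[-1])
    } else {
      rows[[tr]] <- data.frame(trait = tr, term = "(none)",
                               F = NA_real_, df1 = NA_integer_,
                               df2 = stats::df.residual(fit), p = NA_real_)
    }
    sex_kept[tr] <- any(grepl("sex", kept))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "sex_retained") <- sex_kept
  out
}

#' Tukey-Kramer pairwise comparisons between regions
#'
#' For each trait, compares all region pairs using the pooled within-group
#' variance across all groups and the Tukey-Kramer standard error for
#' unequal sample sizes; p-values come from the studentized-range
#' distribution. The difference sign is first-listed minus second-listed
#' group in canonical order (Northern, Central, Southern).
#'
#' @param morph a [morph_table()] data frame.
#' @param grouping grouping column (default `"region"`).
#' @return data frame with `trait`, `pair`, `diff` (mean difference),
#'   `se` (standard error of the difference), `t` (diff / se) and
#'   `p_adj` (Tukey-adjusted). Groups of size 1 are excluded with a warning.
#' @export
tukey_kramer <- function(morph, grouping = "region") {
  g <- factor(morph[[grouping]])
  small <- names(which(table(g) < 2))
  if (length(small)) {
    warning("group(s) of size 1 excluded: ", paste(small, collapse = ", "))
    keep <- !(g %in% small)
    morph <- morph[keep, , drop = FALSE]
    g <- droplevels(g[keep])
  }
  lev <- levels(g)
  k <- length(lev)
  if (k < 2) stop("need at least two groups of size >= 2")
  out <- list()
  for (tr in morph_traits()) {
    y <- morph[[tr]]
    ni <- tapply(y, g, length)
    mi <- tapply(y, g, mean)
    vi <- tapply(y, g, stats::var)
    df <- sum(ni) - k
    s2 <- sum((ni - 1) * vi) / df
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      diff <- mi[i] - mi[j]
      se <- sqrt(s2 * (1 / ni[i] + 1 / ni[j]))
      tval <- diff / se
      p <- stats::ptukey(sqrt(2) * abs(tval), k, df, lower.tail = FALSE)
      out[[length(out) + 1]] <- data.frame(
        trait = tr, pair = paste(lev[i], lev[j], sep = "-"),
        diff = unname(diff), se = unname(se), t = unname(tval),
        p_adj = unname(p))
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Canonical variate analysis of the morphometric traits
#'
#' Linear axes maximizing between-group relative to within-group variation
#' (linear discriminant axes, computed with [MASS::lda()]), scaled to unit
#' within-group variance. Percent per axis is its share of the
#' between-to-within eigenvalue mass; axis signs are fixed so the
#' largest-magnitude loading is positive.
#'
#' @param morph a [morph_table()] data frame.
#' @param grouping grouping column (default `"region"`).
#' @return object of class `cva_result`: list with `scores` (individuals x
#'   axes), `loadings` (traits x axes), `percent`, `centroids` (group means
#'   in canonical space) and `grouping`.
#' @export
cva <- function(morph, grouping = "region") {
  g <- factor(morph[[grouping]])
  X <- as.matrix(morph[morph_traits()])
  if (nrow(X) <= ncol(X))
    stop("need more individuals than traits")
  fit <- tryCatch(
    MASS::lda(X, grouping = g),
    error = function(e) stop("singular within-group scatter; ",
                             "reduce the trait set (", conditionMessage(e),
                             ")"))
  scores <- scale(X, center = colMeans(X), scale = FALSE) %*% fit$scaling
  loadings <- fit$scaling
  for (j in seq_len(ncol(scores))) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  pct <- 100 * fit$svd^2 / sum(fit$svd^2)
  centroids <- apply(scores, 2, function(col) tapply(col, g, mean))
  structure(list(scores = scores, loadings = loadings, percent = pct,
                 centroids = centroids, grouping = g),
            class = "cva_result")
}

#' @exportS3Method base::print
print.cva_result <- function(x, ...) {
  cat("canonical variate analysis:", nrow(x$scores), "individuals,",
      nlevels(x$grouping), "groups\n")
  cat("percent per axis:",
      paste(sprintf("CV%d = %.1f%%", seq_along(x$percent), x$percent),
            collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method graphics::plot
plot.cva_result <- function(x, axes = c(1, 2), ...) {
  axes <- axes[axes <= ncol(x$scores)]
  if (length(axes) < 2) stop("fewer than two canonical axes available")
  cols <- as.integer(x$grouping)
  lab <- sprintf("CV%d (%.1f%%)", axes, x$percent[axes])
  graphics::plot(x$scores[, axes], col = cols, pch = 19,
                 xlab = lab[1], ylab = lab[2], ...)
  graphics::points(x$centroids[, axes], pch = 21, cex = 2.2,
                   bg = grDevices::grey(0.85),
                   col = seq_len(nrow(x$centroids)))
  graphics::legend("topright", legend = levels(x$grouping),
                   col = seq_len(nlevels(x$grouping)), pch = 19, cex = 0.8)
  invisible(x)
}

#' Principal component analysis of the morphometric traits
#'
#' Correlation-matrix PCA (the traits mix kilograms, centimetres and
#' millimetres, so each is standardized). Rows with any missing trait are
#' dropped and counted; axis signs are fixed so the largest-magnitude
#' loading is positive.
#'
#' @param morph a [morph_table()] data frame.
#' @return list with `scores`, `percent` (summing to 100), `loadings` and
#'   `n_dropped` (incomplete rows removed).
#' @export
pca_morph <- function(morph) {
  X <- as.matrix(morph[morph_traits()])
  complete <- stats::complete.cases(X)
  n_dropped <- sum(!complete)
  X <- X[complete, , drop = FALSE]
  if (nrow(X) < 3) stop("fewer than 3 complete rows")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance trait(s): ",
                          paste(colnames(X)[sds == 0], collapse = ", "))
  fit <- stats::prcomp(X, scale. = TRUE)
  scores <- fit$x
  loadings <- fit$rotation
  for (j in seq_len(ncol(scores))) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores,
       percent = 100 * fit$sdev^2 / sum(fit$sdev^2),
       loadings = loadings,
       n_dropped = n_dropped)
}
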