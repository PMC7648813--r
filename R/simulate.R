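#' Reference morphometric generator parameters
#'
#' Region-level trait means and standard deviations (and sample sizes) used
#' as the default parameters of [simulate_morphology()]: three regions of a
#' wide-ranging arboreal folivore with a strong north-to-south body-size
#' cline. Units: mass kg, body/tail length cm, all other traits mm.
#'
#' @return list with `n` (per region), `sites` (site allocation per region),
#'   `means` and `sds` (region x trait matrices) and `sex_effect` (additive
#'   female offset per trait; all zero by default).
#' @export
morph_reference <- function() {
  traits <- morph_traits()
  means <- rbind(
    Northern = c(0.68, 57.21, 34.19, 27.89, 40.78, 104.19, 35.90, 26.57),
    Central  = c(0.87, 64.17, 37.26, 28.27, 45.02, 112.59, 40.37, 29.88),
    Southern = c(1.36, 67.05, 39.14, 36.11, 51.75, 121.04, 41.62, 31.00))
  sds <- rbind(
    Northern = c(0.06, 2.99, 1.61, 2.47, 3.23, 4.91, 2.06, 3.49),
    Central  = c(0.09, 3.21, 1.51, 3.31, 2.13, 5.02, 4.02, 2.87),
    Southern = c(0.16, 2.34, 2.79, 2.95, 2.82, 3.82, 3.28, 2.46))
  colnames(means) <- colnames(sds) <- traits
  list(n = c(Northern = 27, Central = 15, Southern = 14),
       sites = list(Northern = c(Taravale = 14, Blackbraes = 13),
                    Central = c(RedcliffeVale = 15),
                    Southern = c(Bendoc = 8, Wombat = 6)),
       means = means, sds = sds,
       sex_effect = stats::setNames(rep(0, length(traits)), traits))
}

#' Full parameterization of the synthetic-data generator
#'
#' Defaults emulate the study design every analysis stage assumes: five
#' sampling sites drawn from three divergent groups (Taravale 18 and
#' Blackbraes 15 = Northern, RedcliffeVale 18 = Central, Bendoc 9 and
#' Wombat 6 = Southern), group expected heterozygosities 0.04 / 0.10 / 0.11,
#' planted pairwise fixed-difference fractions Northern-Central 0.25,
#' Northern-Southern 0.35, Central-Southern 0.15, one F1 hybrid (T1,
#' Northern x Central) plus its backcross offspring with a Northern parent
#' (T5, which is thereby also a planted parent-offspring pair with T1),
#' genotyping error 0.2% and missingness 2%.
#'
#' @param groups named list; each entry has `sites` (named integer vector of
#'   site sample sizes) and `he` (target mean expected heterozygosity of the
#'   group's background loci; the per-locus allele-frequency law is a
#'   symmetric beta with shape he/(1-2he), whose mean 2p(1-p) equals the
#'   target).
#' @param divergence named numeric of planted fixed-difference fractions per
#'   group pair, names `"A:B"`. At a planted locus the odd group is fixed
#'   for one allele and the remaining groups for the other, so pairwise
#'   fractions must satisfy the triangle constraints; infeasible targets are
#'   an error. Up to three groups are supported.
#' @param n_loci number of SNP loci.
#' @param drift within-group between-site differentiation (Balding-Nichols
#'   F; sites share group frequencies apart from this drift noise).
#' @param hybrids list of planted hybrid individuals: each a list with `id`,
#'   `class` (one of [hybrid_classes()]), `pools` (two group names, pool 0
#'   first), `site`, and optionally `parent` (an earlier hybrid id whose
#'   genotype contributes one gamete, making the pair parent-offspring).
#' @param kin list of planted parent-offspring pairs: each a list with `ids`
#'   (two new individual ids) and `site`.
#' @param error_rate per-call genotyping error probability (a miscalled
#'   genotype is replaced by one of the two other genotypes at random).
#' @param missing_rate per-call missingness probability.
#' @param meta ranges for simulated locus metadata (`rep_avg_range`,
#'   `read_depth_range`).
#' @param morph morphometric parameters ([morph_reference()] by default).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(
    groups = list(
      Northern = list(sites = c(Taravale = 18, Blackbraes = 15), he = 0.04),
      Central = list(sites = c(RedcliffeVale = 18), he = 0.10),
      Southern = list(sites = c(Bendoc = 9, Wombat = 6), he = 0.11)),
    divergence = c("Northern:Central" = 0.25,
                   "Northern:Southern" = 0.35,
                   "Central:Southern" = 0.15),
    n_loci = 1000,
    drift = 0.002,
    hybrids = list(
      list(id = "T1", class = "F1", pools = c("Northern", "Central"),
           site = "Taravale"),
      list(id = "T5", class = "F1xP0", pools = c("Northern", "Central"),
           site = "Taravale", parent = "T1")),
    kin = list(),
    error_rate = 0.002,
    missing_rate = 0.02,
    meta = list(rep_avg_range = c(0.992, 1), read_depth_range = c(10, 60)),
    morph = morph_reference()) {
  stopifnot(length(groups) >= 1, n_loci >= 1,
            error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            drift >= 0, drift < 1)
  for (g in groups) {
    stopifnot(all(g$sites >= 1), g$he >= 0, g$he < 0.5)
  }
  cfg <- list(groups = groups, divergence = divergence, n_loci = n_loci,
              drift = drift, hybrids = hybrids, kin = kin,
              error_rate = error_rate, missing_rate = missing_rate,
              meta = meta, morph = morph)
  # validate divergence feasibility now so misconfiguration fails early
  resolve_fixed_fractions(cfg)
  class(cfg) <- "sim_config"
  cfg
}

# per-group fraction of loci at which that group is the odd one out
# (fixed for one allele while all other groups are fixed for the other);
# pairwise planted fraction d(a,b) = x_a + x_b
resolve_fixed_fractions <- function(cfg) {
  gnames <- names(cfg$groups)
  K <- length(gnames)
  if (K == 1 || is.null(cfg$divergence) || !length(cfg$divergence))
    return(stats::setNames(rep(0, K), gnames))
  if (K > 3)
    stop("planted divergence supports at most three groups")
  d <- function(a, b) {
    key1 <- paste(a, b, sep = ":"); key2 <- paste(b, a, sep = ":")
    v <- cfg$divergence[key1]
    if (is.na(v)) v <- cfg$divergence[key2]
    if (is.na(v)) stop("no divergence entry for pair ", key1)
    unname(v)
  }
  if (K == 2) {
    dd <- d(gnames[1], gnames[2])
    x <- c(dd / 2, dd / 2)
  } else {
    dab <- d(gnames[1], gnames[2])
    dac <- d(gnames[1], gnames[3])
    dbc <- d(gnames[2], gnames[3])
    x <- c((dab + dac - dbc) / 2,
           (dab + dbc - dac) / 2,
           (dac + dbc - dab) / 2)
  }
  if (any(x < -1e-9) || sum(x) > 1)
    stop("infeasible divergence targets: pairwise fixed-difference ",
         "fractions violate the triangle constraints or exceed 1")
  stats::setNames(pmax(x, 0), gnames)
}

he_beta_shape <- function(he) {
  # symmetric Beta(a, a) has E[2p(1-p)] = a / (2a + 1)
  if (he <= 0) return(1e-3)
  he / (1 - 2 * he)
}

#' Simulate multi-population SNP genotypes with planted truth
#'
#' Per group, background per-locus alternate-allele frequencies are drawn
#' from a symmetric beta calibrated so the mean expected heterozygosity hits
#' the group's target; the configured fraction of loci is planted as fixed
#' differences between groups; sites within a group get Balding-Nichols
#' drift noise around the group frequency; genotypes are drawn binomially
#' (Hardy-Weinberg) per individual; hybrids, parent-offspring pairs,
#' genotyping error and missingness are then layered on; locus metadata
#' (tag ids, SNP position, repeatability, call rate, read depth) emulate a
#' reduced-representation deliverable and pass the default filters.
#'
#' @param config a [sim_config()].
#' @return list with `gm` (a [genotype_matrix()], populations = sites) and
#'   `truth` (a `sim_truth` list: `individuals` data frame with id, site,
#'   group, role and hybrid class; `group_freqs` group x loci matrix of true
#'   frequencies; `locus_type` "background"/"fixed" with the odd group;
#'   `hybrids`; `kin_pairs`; the config).
#' @export
simulate_populations <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  gnames <- names(config$groups)
  K <- length(gnames)
  L <- config$n_loci
  x <- resolve_fixed_fractions(config)
  n_fixed <- round(x * L)
  if (sum(n_fixed) > L)
    stop("infeasible divergence targets: planted fixed loci exceed n_loci")

  # locus allocation
  locus_type <- rep("background", L)
  odd_group <- rep(NA_character_, L)
  pos <- 1
  for (g in gnames) {
    if (n_fixed[[g]] > 0) {
      idx <- seq(pos, pos + n_fixed[[g]] - 1)
      locus_type[idx] <- "fixed"
      odd_group[idx] <- g
      pos <- pos + n_fixed[[g]]
    }
  }

  # group-level true frequencies
  freqs <- matrix(NA_real_, K, L, dimnames = list(gnames, NULL))
  for (g in gnames) {
    a <- he_beta_shape(config$groups[[g]]$he)
    # clamp away from the boundaries: tiny beta shapes can underflow to
    # exactly 0/1, which would plant unintended fixed differences
    freqs[g, ] <- pmin(pmax(stats::rbeta(L, a, a), 1e-6), 1 - 1e-6)
  }
  fixed_idx <- which(locus_type == "fixed")
  if (length(fixed_idx)) {
    side <- stats::rbinom(length(fixed_idx), 1, 0.5) # which allele the odd
    for (k in seq_along(fixed_idx)) {                # group carries
      l <- fixed_idx[k]
      freqs[, l] <- 1 - side[k]
      freqs[odd_group[l], l] <- side[k]
    }
  }

  # site-level frequencies: Balding-Nichols drift around the group value
  site_group <- unlist(lapply(gnames, function(g)
    stats::setNames(rep(g, length(config$groups[[g]]$sites)),
                    names(config$groups[[g]]$sites))))
  site_freqs <- matrix(NA_real_, length(site_group), L,
                       dimnames = list(names(site_group), NULL))
  F <- config$drift
  for (s in names(site_group)) {
    p <- freqs[site_group[[s]], ]
    if (F > 0) {
      shape1 <- p * (1 - F) / F
      shape2 <- (1 - p) * (1 - F) / F
      q <- p
      bg <- which(locus_type == "background")
      q[bg] <- stats::rbeta(length(bg), shape1[bg], shape2[bg])
      site_freqs[s, ] <- q
    } else {
      site_freqs[s, ] <- p
    }
  }

  # genotypes, site by site
  rows <- list()
  ind <- list()
  for (s in names(site_group)) {
    n_s <- config$groups[[site_group[[s]]]]$sites[[s]]
    g_site <- matrix(stats::rbinom(n_s * L, 2, rep(site_freqs[s, ],
                                                   each = n_s)),
                     nrow = n_s)
    ids <- sprintf("%s_%02d", s, seq_len(n_s))
    rownames(g_site) <- ids
    rows[[s]] <- g_site
    ind[[s]] <- data.frame(id = ids, site = s, group = site_group[[s]],
                           role = "member", class = NA_character_)
  }
  g_all <- do.call(rbind, rows)
  ind <- do.call(rbind, ind)

  # planted hybrids
  hybrid_rows <- list()
  for (h in config$hybrids) {
    if (!is.null(h$parent)) {
      parent_g <- if (h$parent %in% rownames(g_all)) {
        g_all[h$parent, ]
      } else stop("hybrid parent ", h$parent,
                  " must be simulated before its offspring")
      gam_parent <- stats::rbinom(L, 1, parent_g / 2)
      gam_pool <- stats::rbinom(L, 1, freqs[h$pools[1], ])
      geno <- gam_parent + gam_pool
    } else {
      geno <- simulate_hybrid_genotype(h$class, freqs[h$pools[1], ],
                                       freqs[h$pools[2], ])
    }
    g_all <- rbind(g_all, matrix(geno, nrow = 1,
                                 dimnames = list(h$id, NULL)))
    ind <- rbind(ind, data.frame(id = h$id, site = h$site,
                                 group = site_group[[h$site]],
                                 role = "hybrid", class = h$class))
    hybrid_rows[[h$id]] <- h
  }

  # planted parent-offspring pairs
  kin_pairs <- lapply(config$hybrids, function(h)
    if (!is.null(h$parent)) c(h$parent, h$id) else NULL)
  for (kp in config$kin) {
    s <- kp$site
    p_site <- site_freqs[s, ]
    parent <- stats::rbinom(L, 2, p_site)
    offspring <- stats::rbinom(L, 1, parent / 2) +
      stats::rbinom(L, 1, p_site)
    g_all <- rbind(g_all,
                   matrix(c(parent, offspring), nrow = 2, byrow = TRUE,
                          dimnames = list(kp$ids, NULL)))
    ind <- rbind(ind,
                 data.frame(id = kp$ids, site = s, group = site_group[[s]],
                            role = c("kin_parent", "kin_offspring"),
                            class = NA_character_))
    kin_pairs[[length(kin_pairs) + 1]] <- kp$ids
  }
  kin_pairs <- Filter(Negate(is.null), kin_pairs)

  # genotyping error: miscalls become one of the two other genotypes
  n_cells <- length(g_all)
  if (config$error_rate > 0) {
    err <- which(stats::runif(n_cells) < config$error_rate)
    if (length(err)) {
      shift <- 1 + (stats::runif(length(err)) < 0.5)
      g_all[err] <- (g_all[err] + shift) %% 3
    }
  }
  if (config$missing_rate > 0) {
    g_all[stats::runif(n_cells) < config$missing_rate] <- NA_integer_
  }

  loci <- data.frame(
    clone_id = sprintf("tag%06d", seq_len(L)),
    snp_position = sample(5:64, L, replace = TRUE),
    rep_avg = stats::runif(L, config$meta$rep_avg_range[1],
                           config$meta$rep_avg_range[2]),
    call_rate = colMeans(!is.na(g_all)),
    read_depth = stats::runif(L, config$meta$read_depth_range[1],
                              config$meta$read_depth_range[2]))

  gm <- genotype_matrix(g_all, populations = ind$site[match(rownames(g_all),
                                                            ind$id)],
                        loci = loci)
  truth <- structure(list(individuals = ind,
                          group_freqs = freqs,
                          site_freqs = site_freqs,
                          locus_type = locus_type,
                          odd_group = odd_group,
                          hybrids = hybrid_rows,
                          kin_pairs = kin_pairs,
                          config = config),
                     class = "sim_truth")
  list(gm = gm, truth = truth)
}

#' Simulate one hybrid genotype row
#'
#' Draws a genotype vector for a hybrid class by Mendelian gamete draws:
#' at each locus the gene-pair source is drawn from the class's
#' (w00, w01, w11) weights and each gene copy is a Bernoulli draw from the
#' corresponding pool's allele frequency. An F1 takes one gamete from each
#' pool; an F2 two F1 gametes; a backcross one F1 gamete and one parental
#' gamete.
#'
#' @param class class name from [hybrid_classes()].
#' @param p0,p1 parental-pool allele-frequency vectors (length = loci).
#' @return integer genotype vector.
#' @export
simulate_hybrid_genotype <- function(class, p0, p1) {
  classes <- hybrid_classes()
  row <- classes[classes$class == class, ]
  if (nrow(row) != 1) stop("unknown hybrid class: ", class)
  L <- length(p0)
  s <- sample.int(3, L, replace = TRUE,
                  prob = c(row$w00, row$w01, row$w11))
  copy0 <- stats::rbinom(L, 1, p0)
  copy1 <- stats::rbinom(L, 1, p1)
  copy0b <- stats::rbinom(L, 1, p0)
  copy1b <- stats::rbinom(L, 1, p1)
  ifelse(s == 1, copy0 + copy0b,
         ifelse(s == 2, copy0 + copy1, copy1 + copy1b))
}

#' Simulate a parent-offspring genotype pair
#'
#' The parent is drawn under Hardy-Weinberg from the population frequency;
#' the offspring receives one allele sampled from the parent's genotype and
#' one from the population. Before error injection the pair has exactly
#' zero opposing homozygotes (Mendelian transmission).
#'
#' @param p allele-frequency vector of the source population.
#' @return 2 x loci integer matrix (parent, offspring).
#' @export
simulate_parent_offspring <- function(p) {
  L <- length(p)
  parent <- stats::rbinom(L, 2, p)
  offspring <- stats::rbinom(L, 1, parent / 2) + stats::rbinom(L, 1, p)
  rbind(parent = parent, offspring = offspring)
}

#' Plant filter-stage violations into a clean genotype matrix
#'
#' Plants known quality violations so the staged filter pipeline can be
#' scored against ground truth: secondary SNPs (duplicate tags with lower
#' repeatability), out-of-range read depths, low repeatability, monomorphic
#' columns, low locus call rate, and poor-call-rate individuals. Violation
#' locus sets are disjoint, so the per-stage removal counts in the
#' [run_filter_pipeline()] report equal the planted counts exactly. By
#' default the input is first passed through the pipeline so the baseline is
#' clean.
#'
#' @param gm a [genotype_matrix()].
#' @param n_secondary,n_bad_depth,n_low_rep,n_monomorphic,n_low_callrate
#'   number of loci to afflict per stage.
#' @param n_poor_individuals individuals whose call rate is forced below
#'   0.5.
#' @param config thresholds ([filter_config()]) used both for the optional
#'   pre-clean and to choose violating metadata values.
#' @param ensure_clean pre-filter the input so planted counts reconcile
#'   exactly.
#' @return list with `gm` (afflicted matrix) and `planted` (named list of
#'   the afflicted loci/ids per stage).
#' @export
inject_artifacts <- function(gm, n_secondary = 0, n_bad_depth = 0,
                             n_low_rep = 0, n_monomorphic = 0,
                             n_low_callrate = 0, n_poor_individuals = 0,
                             config = filter_config(),
                             ensure_clean = TRUE) {
  if (ensure_clean) gm <- run_filter_pipeline(gm, config)$gm
  n_afflict <- n_bad_depth + n_low_rep + n_monomorphic + n_low_callrate
  if (n_afflict > n_loci(gm) || n_secondary > n_loci(gm))
    stop("more planted violations requested than loci available")
  if (n_poor_individuals > n_individuals(gm))
    stop("more poor individuals requested than available")
  pool <- sample.int(n_loci(gm), n_afflict)
  take <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  bad_depth <- take(n_bad_depth)
  low_rep <- take(n_low_rep)
  mono <- take(n_monomorphic)
  low_cr <- take(n_low_callrate)
  poor <- sample(individual_ids(gm), n_poor_individuals)

  g <- gm$genotypes
  loci <- gm$loci
  loci$call_rate <- NULL
  if (length(bad_depth))
    loci$read_depth[bad_depth] <-
      sample(c(config$min_depth - 3, config$max_depth + 50),
             length(bad_depth), replace = TRUE)
  if (length(low_rep))
    loci$rep_avg[low_rep] <- config$min_rep - 0.04
  if (length(mono))
    g[, mono] <- 0L
  ok_ind <- !(individual_ids(gm) %in% poor)
  if (length(low_cr)) {
    n_na <- ceiling((1 - config$min_locus_callrate + 0.05) * sum(ok_ind))
    for (l in low_cr)
      g[sample(which(ok_ind), n_na), l] <- NA_integer_
  }
  if (length(poor)) {
    n_na <- ceiling((1 - config$min_ind_callrate + 0.1) * ncol(g))
    for (id in poor)
      g[id, sample.int(ncol(g), n_na)] <- NA_integer_
  }
  # secondary SNPs: duplicated tags with strictly lower repeatability
  secondary <- integer(0)
  if (n_secondary > 0) {
    # duplicate only clean tags: duplicating a planted-violation locus would
    # tangle the per-stage removal counts
    clean_cols <- setdiff(seq_len(ncol(g)),
                          c(bad_depth, low_rep, mono, low_cr))
    if (n_secondary > length(clean_cols))
      stop("more planted violations requested than loci available")
    src <- sample(clean_cols, n_secondary)
    dup_g <- g[, src, drop = FALSE]
    dup_loci <- loci[src, , drop = FALSE]
    dup_loci$snp_position <- dup_loci$snp_position + 1L
    dup_loci$rep_avg <- pmax(config$min_rep,
                             dup_loci$rep_avg - 1e-4)
    g <- cbind(g, dup_g)
    loci <- rbind(loci, dup_loci)
    secondary <- seq(ncol(g) - n_secondary + 1, ncol(g))
  }
  loci$call_rate <- colMeans(!is.na(g))
  out <- genotype_matrix(g, populations = if (length(gm$populations))
    unname(gm$populations[rownames(g)]) else character(0),
    loci = loci)
  list(gm = out,
       planted = list(secondary = secondary, bad_depth = bad_depth,
                      low_rep = low_rep, monomorphic = mono,
                      low_callrate = low_cr, poor_individuals = poor))
}

#' Simulate a morphometrics table
#'
#' Per-region multivariate-normal (independent traits) draws with the
#' configured means and standard deviations; an optional additive female
#' offset per trait. With `exact = TRUE` the draws are affinely rescaled so
#' every region's sample mean and SD equal the configured parameters
#' exactly (useful as a deterministic reference dataset; the sex effect is
#' then ignored).
#'
#' @param params generator parameters ([morph_reference()] by default).
#' @param exact make sample moments exact.
#' @return a [morph_table()] data frame (all individuals flagged adult).
#' @export
simulate_morphology <- function(params = morph_reference(), exact = FALSE) {
  traits <- morph_traits()
  rows <- list()
  for (r in rownames(params$means)) {
    n <- params$n[[r]]
    sites <- params$sites[[r]]
    site_vec <- rep(names(sites), times = sites)
    if (length(site_vec) != n)
      stop("site allocation for region ", r, " does not sum to its n")
    sex <- rep(c("F", "M"), length.out = n)
    X <- matrix(stats::rnorm(n * length(traits)), n)
    if (exact) X <- apply(X, 2, function(col) (col - mean(col)) / stats::sd(col))
    X <- sweep(X, 2, params$sds[r, ], `*`)
    X <- sweep(X, 2, params$means[r, ], `+`)
    colnames(X) <- traits
    if (!exact && any(params$sex_effect != 0)) {
      fem <- sex == "F"
      X[fem, ] <- sweep(X[fem, , drop = FALSE], 2, params$sex_effect, `+`)
    }
    rows[[r]] <- data.frame(id = sprintf("%s_m%02d", r, seq_len(n)),
                            site = site_vec, region = r, sex = sex,
                            adult = TRUE)
    rows[[r]] <- cbind(rows[[r]], as.data.frame(X))
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  morph_table(df)
}

#' Simulate the full study bundle
#'
#' Convenience wrapper producing the genotype matrix, planted truth and a
#' morphometrics table from one configuration.
#'
#' @param config a [sim_config()].
#' @return list with `gm`, `truth` and `morph`.
#' @export
simulate_study <- function(config = sim_config()) {
  sim <- simulate_populations(config)
  sim$morph <- simulate_morphology(config$morph)
  sim
}
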