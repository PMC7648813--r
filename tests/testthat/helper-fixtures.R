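# shared fixture builders (all fixtures are generated in code)

# quick genotype matrix from a plain matrix; populations default to one pop
toy_gm <- function(g, populations = "pop1", ...) {
  g <- as.matrix(g)
  if (is.null(rownames(g))) rownames(g) <- paste0("i", seq_len(nrow(g)))
  genotype_matrix(g, populations = populations, ...)
}

# genotype matrix realizing given per-population allele frequencies exactly,
# two individuals per population (possible for p in {0, .25, .5, .75, 1})
gm_from_freqs <- function(freqs_by_pop) {
  geno_for_p <- function(p) {
    switch(as.character(p),
           "0" = c(0L, 0L), "0.25" = c(1L, 0L), "0.5" = c(1L, 1L),
           "0.75" = c(1L, 2L), "1" = c(2L, 2L),
           stop("unsupported frequency ", p))
  }
  pops <- names(freqs_by_pop)
  g <- do.call(rbind, lapply(seq_along(pops), function(k) {
    vapply(freqs_by_pop[[k]], geno_for_p, integer(2)) # 2 individuals x loci
  }))
  rownames(g) <- paste0(rep(pops, each = 2), "_", 1:2)
  genotype_matrix(g, populations = rep(pops, each = 2))
}

# random genotype matrix with missingness, for property tests
random_gm <- function(n = 12, L = 40, n_pops = 2, missing = 0.05) {
  p <- stats::runif(L)
  g <- matrix(stats::rbinom(n * L, 2, rep(p, each = n)), nrow = n)
  g[stats::runif(n * L) < missing] <- NA_integer_
  rownames(g) <- paste0("i", seq_len(n))
  genotype_matrix(g, populations = rep(paste0("pop", seq_len(n_pops)),
                                       length.out = n))
}

expect_same_gm <- function(a, b) {
  expect_identical(unname(a$genotypes), unname(b$genotypes))
  expect_identical(a$loci$clone_id, b$loci$clone_id)
  expect_identical(individual_ids(a), individual_ids(b))
}
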