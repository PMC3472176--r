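## shared fixtures, built in code and cached for the duration of the run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

## genotypes object from a raw allele-count matrix (single pseudo-chromosome
## unless chrom/pos supplied)
make_geno <- function(M, chrom = NULL, pos = NULL) {
  if (is.null(colnames(M))) colnames(M) <- paste0("m", seq_len(ncol(M)))
  if (is.null(rownames(M))) rownames(M) <- paste0("i", seq_len(nrow(M)))
  if (is.null(chrom)) chrom <- rep(1L, ncol(M))
  if (is.null(pos)) {
    pos <- integer(ncol(M))
    for (ch in unique(chrom)) pos[chrom == ch] <- seq_len(sum(chrom == ch)) * 1e6
  }
  genotypes(M, data.frame(marker = colnames(M), chrom = chrom, pos = pos))
}

## HWE founder-style genotype matrix at given frequencies
hwe_matrix <- function(n, p) {
  m <- length(p)
  matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m,
         dimnames = list(paste0("i", seq_len(n)), paste0("m", seq_len(m))))
}

## related population genotypes for the split-panel regression tests
beta_pop_geno <- function() {
  cached("beta_geno", {
    cfg <- sim_config(n_founders = 40, n_generations = 2,
                      sires_per_generation = 6, offspring_per_sire = 10,
                      n_chromosomes = 4, markers_per_chromosome = 300,
                      seed = 64)
    simulate_genotypes(simulate_pedigree(cfg), cfg)
  })
}

## medium simulated population shared by several test files
medium_pop <- function() {
  cached("medium_pop", {
    cfg <- sim_config(n_founders = 60, n_generations = 2,
                      sires_per_generation = 10, offspring_per_sire = 12,
                      n_chromosomes = 5, markers_per_chromosome = 120,
                      n_qtl = 100, hidden_qtl_fraction = 0.1,
                      sigma2_g = 100, sigma2_polygenic = 25, sigma2_e = 25,
                      seed = 42)
    pop <- simulate_population(cfg)
    pop$A <- make_A(pop$pedigree, ids = pop$phenotypes$id)
    pop$G <- build_G(pop$genotypes, ids = pop$phenotypes$id)
    pop
  })
}
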