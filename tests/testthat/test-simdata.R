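test_that("pedigree generator produces the configured family structure", {
  ped0 <- simulate_pedigree(sim_config(n_founders = 10, n_generations = 0))
  expect_equal(nrow(ped0), 10)
  expect_true(all(is.na(ped0$sire)) && all(is.na(ped0$dam)))

  cfg <- sim_config(n_founders = 20, n_generations = 2,
                    sires_per_generation = 2, offspring_per_sire = 5,
                    seed = 5)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 20 + 2 * (2 * 5))
  expect_s3_class(ped, "pedigree")
  # sires come from the previous generation's males, dams are founder females
  for (g in 1:2) {
    off <- ped[ped$generation == g, ]
    expect_equal(nrow(off), 10)
    expect_equal(length(unique(off$sire)), 2)
    sire_gen <- ped$generation[match(off$sire, ped$id)]
    expect_true(all(sire_gen == g - 1))
    dam_rows <- ped[match(off$dam, ped$id), ]
    expect_true(all(dam_rows$generation == 0 & dam_rows$sex == "F"))
  }
  # seeded determinism
  expect_identical(ped, simulate_pedigree(cfg))
})

test_that("invalid simulator configurations are rejected", {
  expect_error(sim_config(n_founders = 0), "count")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.05, 0.6)), "maf_range")
  expect_error(sim_config(sigma2_e = -1), "sigma2_e")
  expect_error(sim_config(n_founders = 4, sires_per_generation = 10), "sires")
  expect_error(sim_config(n_chromosomes = 3, qtl_chromosomes = 5),
               "qtl_chromosomes")
})

test_that("gene dropping is Mendelian-consistent and deterministic", {
  cfg <- sim_config(n_founders = 30, n_generations = 2,
                    sires_per_generation = 4, offspring_per_sire = 6,
                    n_chromosomes = 2, markers_per_chromosome = 40, seed = 9)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  expect_identical(geno, simulate_genotypes(ped, cfg))
  M <- geno$geno
  gdam <- attr(ped, "genetic_dam")
  off <- which(!is.na(ped$sire))
  for (i in off) {
    gs <- M[as.character(ped$sire[i]), ]
    gd <- M[as.character(gdam[i]), ]
    go <- M[as.character(ped$id[i]), ]
    # offspring count decomposes into one allele from each parent
    ok <- mapply(function(o, s, d) {
      any(vapply(0:1, function(a)
        ((a == 1 && s >= 1) || (a == 0 && s <= 1)) &&
        {
          b <- o - a
          (b == 1 && d >= 1) || (b == 0 && d <= 1)
        }, logical(1)))
    }, go, gs, gd)
    expect_true(all(ok))
  }
})

test_that("zero recombination transmits intact parental haplotypes and founder alleles explain all descendants", {
  cfg <- sim_config(n_founders = 16, n_generations = 2,
                    sires_per_generation = 3, offspring_per_sire = 4,
                    n_chromosomes = 2, markers_per_chromosome = 25,
                    chromosome_length_morgans = 0, seed = 21)
  ped <- simulate_pedigree(cfg)
  loci <- data.frame(chrom = rep(1:2, each = 25),
                     pos_bp = rep(seq(1e6, 25e6, by = 1e6), 2),
                     gpos = 0, freq = 0.3)
  set.seed(1)
  dropped <- gvpart:::.gene_drop(ped, loci, 0, founder_labels = TRUE)
  founder_rows <- which(rep(is.na(ped$sire) & is.na(ped$dam), each = 2))
  for (H in dropped$haplotypes) {
    # no recombination: every transmitted haplotype is one label throughout
    expect_true(all(apply(H, 1, function(h) length(unique(h)) == 1)))
    # allele conservation: every label traces to a founder haplotype
    expect_true(all(unique(as.vector(H)) %in% founder_rows))
  }
  # with recombination the labels still all trace back to founders
  set.seed(2)
  dropped2 <- gvpart:::.gene_drop(ped, loci, 1, founder_labels = TRUE)
  for (H in dropped2$haplotypes)
    expect_true(all(unique(as.vector(H)) %in% founder_rows))
})

test_that("founder allele frequencies follow binomial sampling around the drawn MAF", {
  cfg <- sim_config(n_founders = 500, n_generations = 0,
                    n_chromosomes = 4, markers_per_chromosome = 2500,
                    maf_range = c(0.05, 0.5), seed = 31)
  geno <- simulate_genotypes(simulate_pedigree(cfg), cfg)
  p_true <- geno$map$founder_freq
  p_hat <- allele_frequencies(geno)[geno$map$marker]
  theo_sd <- sqrt(p_true * (1 - p_true) / (2 * 500))
  # E|p_hat - p| = sqrt(2/pi) * SD for a (near) normal sampling error
  ratio <- mean(abs(p_hat - p_true)) / mean(theo_sd)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 1.2)
  expect_lt(abs(ratio - sqrt(2 / pi)), 3 * 0.2)
})

test_that("QTL assignment rescales components exactly and respects architecture", {
  pop <- medium_pop()
  tv <- pop$true_values
  gen <- attr(tv, "generation")
  final <- tv$id[gen[tv$id] == max(gen)]
  expect_equal(var(tv$tbv_genomic[tv$id %in% final]), 100, tolerance = 1e-10)
  expect_equal(var(tv$tbv_polygenic[tv$id %in% final]), 25, tolerance = 1e-10)
  expect_equal(tv$tbv, tv$tbv_genomic + tv$tbv_polygenic)

  # no hidden loci: TBV is an exact linear function of marker genotypes
  cfg <- sim_config(n_founders = 20, n_generations = 1,
                    sires_per_generation = 3, offspring_per_sire = 5,
                    n_chromosomes = 2, markers_per_chromosome = 30,
                    n_qtl = 10, hidden_qtl_fraction = 0, sigma2_polygenic = 0,
                    seed = 12)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  tv2 <- assign_qtl_and_tbv(geno, cfg)
  q <- attr(tv2, "qtl")
  expect_false(any(q$hidden))
  rebuilt <- as.vector(geno$geno[, q$locus] %*% q$effect)
  expect_equal(tv2$tbv - mean(tv2$tbv), rebuilt - mean(rebuilt),
               tolerance = 1e-10)

  # a single QTL of effect alpha: TBV differences = alpha * allele-count differences
  cfg1 <- sim_config(n_founders = 20, n_generations = 1,
                     sires_per_generation = 3, offspring_per_sire = 5,
                     n_chromosomes = 2, markers_per_chromosome = 30,
                     n_qtl = 1, hidden_qtl_fraction = 0, sigma2_polygenic = 0,
                     sigma2_g = 4, seed = 13)
  geno1 <- simulate_genotypes(simulate_pedigree(cfg1), cfg1)
  tv1 <- assign_qtl_and_tbv(geno1, cfg1)
  q1 <- attr(tv1, "qtl")
  expect_equal(nrow(q1), 1)
  counts <- geno1$geno[, q1$locus]
  expect_equal(diff(tv1$tbv), q1$effect * diff(counts), tolerance = 1e-10,
               ignore_attr = TRUE)

  # configuration errors
  cfg_bad <- sim_config(n_qtl = 0, sigma2_g = 10, hidden_qtl_fraction = 0,
                        sigma2_polygenic = 0)
  expect_error(assign_qtl_and_tbv(geno, cfg_bad), "n_qtl")
})

test_that("DRP simulation has the configured weighted residual structure", {
  n <- 10000
  ids <- as.character(seq_len(n))
  tv <- structure(data.frame(id = ids, tbv = 0, tbv_genomic = 0,
                             tbv_polygenic = 0, stringsAsFactors = FALSE),
                  class = c("true_values", "data.frame"))
  attr(tv, "generation") <- stats::setNames(rep(0L, n), ids)

  cfg <- sim_config(sigma2_e = 100, weight_range = c(4, 4), mu = 50, seed = 77)
  phen <- simulate_drp(tv, cfg)
  expect_equal(nrow(phen), n)
  expect_true(all(phen$weight == 4))
  # sample variance of e within 3 Monte-Carlo SEs of sigma2_e / w = 25
  mc_se <- 25 * sqrt(2 / (n - 1))
  expect_lt(abs(var(phen$y - 50) - 25), 3 * mc_se)
  expect_identical(phen, simulate_drp(tv, cfg))

  # infinite-information limit
  cfg_inf <- sim_config(sigma2_e = 100, weight_range = c(1e9, 1e9), seed = 78)
  phen_inf <- simulate_drp(tv, cfg_inf)
  expect_lt(var(phen_inf$y - cfg_inf$mu), 1e-6 * 100)

  cfg_zero <- cfg
  cfg_zero$sigma2_e <- 0
  expect_error(simulate_drp(tv, cfg_zero), "sigma2_e")
})

test_that("paternal half-sibs approach genomic relationship 0.25 with dense markers", {
  cfg <- sim_config(n_founders = 60, n_generations = 1,
                    sires_per_generation = 6, offspring_per_sire = 20,
                    n_chromosomes = 4, markers_per_chromosome = 400,
                    seed = 55)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  # center at founder (base population) frequencies
  G <- build_G(geno, freqs = stats::setNames(geno$map$founder_freq,
                                             geno$map$marker))
  off <- ped[ped$generation == 1, ]
  pairs <- t(combn(nrow(off), 2))
  same_sire <- off$sire[pairs[, 1]] == off$sire[pairs[, 2]]
  gdam <- attr(ped, "genetic_dam")[match(off$id, ped$id)]
  diff_dam <- gdam[pairs[, 1]] != gdam[pairs[, 2]]
  hs <- which(same_sire & diff_dam)
  vals <- unclass(G)[cbind(as.character(off$id[pairs[hs, 1]]),
                           as.character(off$id[pairs[hs, 2]]))]
  tol <- max(3 * sd(vals) / sqrt(length(vals)), 0.03)
  expect_lt(abs(mean(vals) - 0.25), tol)
  # unrelated pairs (different sire and dam) near zero
  ur <- which(!same_sire & diff_dam)
  vals0 <- unclass(G)[cbind(as.character(off$id[pairs[ur, 1]]),
                            as.character(off$id[pairs[ur, 2]]))]
  expect_lt(abs(mean(vals0)), 0.03)
})
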