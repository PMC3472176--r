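test_that("allele frequencies are mean allele counts over two", {
  expect_equal(unname(allele_frequencies(make_geno(cbind(c(0, 1, 2))))), 0.5)
  expect_equal(unname(allele_frequencies(make_geno(cbind(c(2, 2, 2, 2))))), 1)
  expect_equal(unname(allele_frequencies(make_geno(cbind(c(0, 0, 1, 2))))), 3 / 8)
  # missing calls are excluded from the mean
  M <- cbind(c(0, 2, NA, 2))
  expect_equal(unname(allele_frequencies(make_geno(M))), 4 / 6)
})

test_that("marker QC removes low-MAF and affinely dependent markers", {
  set.seed(4)
  base <- matrix(rbinom(5 * 20, 2, 0.4), 20, 5)
  # ensure markers 1..3 are mutually affinely independent
  base[1:3, 1] <- c(0, 1, 2); base[1:3, 2] <- c(2, 0, 1); base[1:3, 3] <- c(1, 2, 0)
  M <- cbind(base[, 1:3], base[, 2], 2 - base[, 1])
  qc <- qc_markers(make_geno(M))
  expect_equal(qc$report$n_removed_maf, 0)
  expect_equal(qc$report$n_removed_dependence, 2)
  expect_equal(qc$report$n_retained, 3)
  expect_setequal(qc$report$removed$marker, c("m4", "m5"))
  expect_equal(qc$report$n_input,
               with(qc$report, n_removed_maf + n_removed_dependence + n_retained))

  # monomorphic marker removed by the MAF filter
  M2 <- cbind(rep(0, 20), base[, 1:2])
  qc2 <- qc_markers(make_geno(M2))
  expect_equal(qc2$report$n_removed_maf, 1)
  expect_true("m1" %in% qc2$report$removed$marker)

  # MAF exactly at the threshold is retained (strict inequality)
  M3 <- cbind(c(1, rep(0, 49)), rbinom(50, 2, 0.5))
  M3[1:3, 2] <- c(0, 1, 2)
  qc3 <- qc_markers(make_geno(M3), maf_threshold = 0.01)
  expect_equal(qc3$report$n_removed_maf, 0)
  expect_equal(qc3$report$n_retained, 2)

  # constant all-heterozygote marker is non-informative
  M4 <- cbind(rep(1, 20), base[, 1:2])
  qc4 <- qc_markers(make_geno(M4))
  expect_true("m1" %in% qc4$report$removed$marker)
})

test_that("G follows the centered cross-product construction", {
  # two individuals, two markers, hand evaluation
  M <- matrix(c(0, 2, 2, 0), 2, 2)
  G <- build_G(make_geno(M))
  expect_equal(unclass(G), matrix(c(2, -2, -2, 2), 2, 2), ignore_attr = TRUE)

  # duplicating every column leaves G unchanged
  pop <- medium_pop()
  geno <- subset_genotypes(pop$genotypes, ids = pop$phenotypes$id[1:50])
  Mg <- geno$geno[, 1:80]
  dup <- cbind(Mg, Mg)
  colnames(dup) <- paste0("d", seq_len(ncol(dup)))
  Gdup <- build_G(make_geno(dup))
  expect_equal(unclass(Gdup), unclass(build_G(make_geno(Mg))),
               ignore_attr = TRUE)

  # identical individuals give a constant matrix
  Mc <- rbind(c(0, 1, 2, 1), c(0, 1, 2, 1), c(0, 1, 2, 1))
  Gc <- build_G(make_geno(Mc))
  expect_equal(max(Gc) - min(Gc), 0)

  # all-monomorphic panel is degenerate
  expect_error(build_G(make_geno(cbind(rep(2, 4), rep(0, 4)))), "monomorphic")
})

test_that("G is PSD, sample-centered and has mean diagonal near 1 under HWE", {
  set.seed(8)
  p <- runif(20000, 0.05, 0.5)
  M <- hwe_matrix(200, p)
  G <- build_G(make_geno(M))
  expect_lt(abs(mean(diag(unclass(G))) - 1), 0.02)
  # column centering at sample frequencies implies zero row sums
  expect_lt(max(abs(rowSums(unclass(G)))), 1e-8)
  ev <- eigen(unclass(G), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
  # missing calls are mean-imputed before centering
  M2 <- M[1:50, 1:500]
  M2[sample(length(M2), 200)] <- NA
  expect_silent(G2 <- build_G(make_geno(M2)))
  expect_false(anyNA(G2))
})

test_that("chromosome split matrices reassemble the whole-genome numerator", {
  pop <- medium_pop()
  geno <- subset_genotypes(pop$genotypes, ids = pop$phenotypes$id[1:60])
  sp <- split_G_by_chromosome(geno, 2)
  expect_equal(attr(sp$G_c, "kind"), "chromosome")
  expect_equal(attr(sp$G_o, "kind"), "complement")
  # G_c equals build_G restricted to that chromosome's markers
  gc_only <- subset_genotypes(geno, markers = geno$map$marker[geno$map$chrom == 2])
  expect_equal(unclass(sp$G_c), unclass(build_G(gc_only)), ignore_attr = TRUE)
  # numerators (matrix * own denominator) add up to the whole-genome numerator
  denom <- function(g) {
    p <- allele_frequencies(g)
    2 * sum(p * (1 - p))
  }
  go_only <- subset_genotypes(geno, markers = geno$map$marker[geno$map$chrom != 2])
  num_sum <- unclass(sp$G_c) * denom(gc_only) + unclass(sp$G_o) * denom(go_only)
  G <- build_G(geno)
  expect_equal(num_sum, unclass(G) * denom(geno), ignore_attr = TRUE,
               tolerance = 1e-10)
  # shared-denominator variant: matrices add up directly
  sps <- split_G_by_chromosome(geno, 2, shared_denominator = TRUE)
  expect_equal(unclass(sps$G_c) + unclass(sps$G_o), unclass(G),
               ignore_attr = TRUE, tolerance = 1e-10)
  # error paths
  expect_error(split_G_by_chromosome(geno, 99), "no markers")
  one_chr <- subset_genotypes(geno, markers = geno$map$marker[geno$map$chrom == 1])
  expect_error(split_G_by_chromosome(one_chr, 1), "outside")
})
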