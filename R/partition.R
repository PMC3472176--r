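#' Fit one of the four variance-partition models
#'
#' The four models differ only in their random genetic terms:
#' model 1 fits a classical animal model (`a`, pedigree matrix `A`);
#' model 2 a genomic model (`g`, genomic matrix `G`);
#' model 3 both (`g + a`), partitioning total additive variance into a
#' marker-captured and a residual polygenic component;
#' model 4 a chromosome-split genomic model (`g_c + g_o + a`) used for the
#' per-chromosome scan.  All models have a general mean as the only fixed
#' effect and residual variance weighted by the effective-record weights.
#'
#' @param phen phenotype data frame with columns `id`, `y` (or `trait_column`)
#'   and `weight`.
#' @param model integer model id in 1..4.
#' @param A pedigree relationship matrix (models 1, 3, 4).
#' @param G whole-genome genomic relationship matrix (models 2, 3).
#' @param G_c,G_o chromosome and complement matrices (model 4), e.g. from
#'   [split_G_by_chromosome()].
#' @param trait_column,weight_column column names in `phen`.
#' @param trait optional trait label stored with the result.
#' @param ... passed to [greml()].
#' @return object of class `vc_model`: list with the `greml` fit, `model`,
#'   `trait`, `chromosome` (model 4), and the variance ratio `VR`.
#' @export
fit_vc_model <- function(phen, model, A = NULL, G = NULL, G_c = NULL,
                         G_o = NULL, trait_column = "y",
                         weight_column = "weight", trait = NULL, ...) {
  if (!is.numeric(model) || length(model) != 1 || !(model %in% 1:4))
    stop("fit_vc_model: 'model' must be 1, 2, 3 or 4")
  model <- as.integer(model)
  need <- switch(model,
                 `1` = list(a = A),
                 `2` = list(g = G),
                 `3` = list(g = G, a = A),
                 `4` = list(g_c = G_c, g_o = G_o, a = A))
  missing_terms <- names(need)[vapply(need, is.null, logical(1))]
  if (length(missing_terms) > 0)
    stop("fit_vc_model: model ", model, " needs matrix/matrices for term(s): ",
         paste(missing_terms, collapse = ", "))
  if (!all(c("id", trait_column, weight_column) %in% names(phen)))
    stop("fit_vc_model: phenotype table needs columns id, ",
         trait_column, ", ", weight_column)
  dat <- data.frame(id = as.character(phen$id),
                    y = phen[[trait_column]],
                    w = phen[[weight_column]])
  fit <- greml(y ~ 1, dat, random = need, weights = "w", id = "id", ...)
  chrom <- if (model == 4L) attr(G_c, "chromosome") else NULL
  if (is.null(trait) && "trait" %in% names(phen))
    trait <- as.character(phen$trait[1])
  out <- list(model = model, trait = trait, chromosome = chrom,
              fit = fit, VR = variance_ratio(fit))
  class(out) <- "vc_model"
  out
}

#' @export
print.vc_model <- function(x, digits = 4, ...) {
  cat(sprintf("Variance-partition model %d%s%s\n", x$model,
              if (!is.null(x$trait)) paste0(", trait ", x$trait) else "",
              if (!is.null(x$chromosome)) paste0(", chromosome ", x$chromosome) else ""))
  print(x$fit, digits = digits)
  cat(sprintf("  VR = %.4f\n", x$VR))
  invisible(x)
}

#' Proportion of total genetic variance captured by markers
#'
#' For a model fitting genomic and residual polygenic terms jointly, the
#' share `sigma_g^2 / (sigma_g^2 + sigma_a^2)` of total additive genetic
#' variance attributed to genomic relationships.
#'
#' @param sigma2_g genomic variance estimate(s), or a model-3 `vc_model`.
#' @param sigma2_a residual polygenic variance estimate(s) (ignored when a
#'   fitted model is supplied).
#' @return the genomic share(s), vectorized over the inputs.
#' @export
genomic_share <- function(sigma2_g, sigma2_a = NULL) {
  if (inherits(sigma2_g, "vc_model")) {
    m <- sigma2_g
    if (!all(c("g", "a") %in% m$fit$terms))
      stop("genomic_share: model must contain both 'g' and 'a' terms")
    sigma2_a <- m$fit$sigma2[["a"]]
    sigma2_g <- m$fit$sigma2[["g"]]
  }
  if (any(sigma2_g < 0) || any(sigma2_a < 0))
    stop("genomic_share: variances must be >= 0")
  tot <- sigma2_g + sigma2_a
  if (any(tot <= 0)) stop("genomic_share: total genetic variance is zero")
  unname(sigma2_g / tot)
}

#' Total genetic variance of the joint model relative to the animal model
#'
#' The ratio `(sigma_g^2 + sigma_a^2)[model 3] / sigma_a^2[model 1]`
#' comparing the total additive genetic variance recovered by the joint
#' genomic + polygenic model with the classical animal-model estimate
#' (expected to be near 1 when the joint model explains all genetic
#' variance).
#'
#' @param model3 a model-3 `vc_model`, or the numeric total genetic variance
#'   `sigma_g^2 + sigma_a^2` of the joint model (vectorized).
#' @param model1 a model-1 `vc_model`, or the numeric animal-model additive
#'   variance (vectorized).
#' @return the ratio(s).
#' @export
model_total_ratio <- function(model3, model1) {
  if (inherits(model3, "vc_model")) {
    if (model3$model != 3L) stop("model_total_ratio: first fit must be model 3")
    tot3 <- sum(model3$fit$sigma2[c("g", "a")])
  } else tot3 <- as.numeric(model3)
  if (inherits(model1, "vc_model")) {
    if (model1$model != 1L) stop("model_total_ratio: second fit must be model 1")
    if (inherits(model3, "vc_model") && !is.null(model3$trait) &&
        !is.null(model1$trait) && !identical(model3$trait, model1$trait))
      stop("model_total_ratio: fits are for different traits (",
           model3$trait, " vs ", model1$trait, ")")
    tot1 <- model1$fit$sigma2[["a"]]
  } else tot1 <- as.numeric(model1)
  if (any(tot1 <= 0)) stop("model_total_ratio: animal-model variance must be > 0")
  unname(tot3 / tot1)
}

#' Per-chromosome scan of genomic variance
#'
#' For every chromosome `c`, fits model 4 (`g_c + g_o + a`) with the
#' chromosome and complement genomic matrices, collects the chromosome
#' variance estimates, and relates their sum to the whole-genome genomic
#' variance of a reference model-3 fit on the same data.  Chromosome length
#' is the number of megabases between the first and last marker.
#'
#' @param phen phenotype table (`id`, `y`, `weight`).
#' @param geno a QC'd [genotypes] object with at least two chromosomes.
#' @param A pedigree relationship matrix.
#' @param chromosomes chromosomes to scan (default: all in the map).
#' @param shared_denominator passed to [split_G_by_chromosome()].
#' @param reference_fit optional precomputed model-3 `vc_model`; fitted here
#'   otherwise.
#' @param ... passed to [greml()].
#' @return a `chrom_scan` data frame (`chrom`, `length_mb`, `n_markers`,
#'   `sigma2`, `se`, `converged`) with attributes `sum_sigma2`,
#'   `model3_sigma_g`, `sum_ratio` and the reference fit.
#' @export
chromosome_scan <- function(phen, geno, A, chromosomes = NULL,
                            shared_denominator = FALSE,
                            reference_fit = NULL, ...) {
  stopifnot(inherits(geno, "genotypes"))
  chroms <- unique(geno$map$chrom)
  if (length(chroms) < 2)
    stop("chromosome_scan: need at least 2 chromosomes")
  if (!is.null(chromosomes)) {
    miss <- setdiff(chromosomes, chroms)
    if (length(miss) > 0)
      stop("chromosome_scan: chromosome(s) with no markers: ",
           paste(miss, collapse = ", "))
    chroms <- chromosomes
  }
  ids <- as.character(phen$id)
  if (is.null(reference_fit)) {
    G <- build_G(geno, ids = unique(ids))
    reference_fit <- fit_vc_model(phen, 3, A = A, G = G, ...)
  }
  rows <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    sp <- split_G_by_chromosome(subset_genotypes(geno, ids = unique(ids)),
                                ch, shared_denominator = shared_denominator)
    # non-convergence of one chromosome yields a flagged row, not a failure
    f <- suppressWarnings(
      fit_vc_model(phen, 4, A = A, G_c = sp$G_c, G_o = sp$G_o, ...))
    pos <- geno$map$pos[geno$map$chrom == ch]
    rows[[i]] <- data.frame(chrom = ch,
                            length_mb = (max(pos) - min(pos)) / 1e6,
                            n_markers = length(pos),
                            sigma2 = f$fit$sigma2[["g_c"]],
                            se = f$fit$se[["g_c"]],
                            converged = f$fit$converged)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "sum_sigma2") <- sum(out$sigma2)
  attr(out, "model3_sigma_g") <- reference_fit$fit$sigma2[["g"]]
  attr(out, "sum_ratio") <- sum(out$sigma2) / reference_fit$fit$sigma2[["g"]]
  attr(out, "reference_fit") <- reference_fit
  class(out) <- c("chrom_scan", "data.frame")
  out
}

#' @export
print.chrom_scan <- function(x, digits = 4, ...) {
  cat(sprintf("Per-chromosome genomic variance scan (%d chromosomes)\n", nrow(x)))
  print.data.frame(x, digits = digits, row.names = FALSE)
  cat(sprintf("sum of chromosome variances: %.4f (%.1f%% of model-3 genomic variance %.4f)\n",
              attr(x, "sum_sigma2"), 100 * attr(x, "sum_ratio"),
              attr(x, "model3_sigma_g")))
  invisible(x)
}

#' @export
plot.chrom_scan <- function(x, ...) {
  plot(x$length_mb, x$sigma2, pch = 19,
       xlab = "chromosome length (Mb, first to last marker)",
       ylab = expression(hat(sigma)[c]^2),
       main = "chromosomal variance vs length", ...)
  fit <- regress_variance_on_length(x)
  graphics::abline(fit$intercept, fit$slope, lty = 2)
  graphics::mtext(sprintf("R^2 = %.2f", fit$r_squared), side = 3, adj = 1,
                  cex = 0.8)
  invisible(x)
}

#' Regress chromosomal variance on chromosome length
#'
#' Ordinary least squares of the per-chromosome variance estimates on
#' chromosome length in Mb.  A strong relationship is expected when QTL are
#' spread evenly over the genome; a major gene on one chromosome weakens it.
#'
#' @param part a `chrom_scan` result, or any data frame with columns
#'   `sigma2` and `length_mb`.
#' @return list with `intercept`, `slope`, `r_squared` and the underlying
#'   [lm] fit.
#' @export
regress_variance_on_length <- function(part) {
  if (!all(c("sigma2", "length_mb") %in% names(part)))
    stop("regress_variance_on_length: need columns sigma2 and length_mb")
  if (nrow(part) < 3)
    stop("regress_variance_on_length: need at least 3 chromosomes")
  if (stats::var(part$length_mb) <= 0)
    stop("regress_variance_on_length: chromosome lengths are constant")
  fit <- stats::lm(sigma2 ~ length_mb, data = as.data.frame(part))
  # suppressed: summary.lm warns on an exactly proportional (perfect) fit
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       r_squared = r2,
       fit = fit)
}
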