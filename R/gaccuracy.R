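#' Randomly split markers into two disjoint panels
#'
#' Samples `2N` distinct markers genome-wide without replacement and divides
#' them at random into two panels of `N` markers each — the first treated as
#' the observed marker panel, the second as a stand-in for the causal loci.
#'
#' @param geno a [genotypes] object.
#' @param N panel size; `2N` must not exceed the marker count.
#' @param seed optional seed for a reproducible split (when `NULL` the
#'   current RNG stream is used).
#' @return list of two [genotypes] objects, `panel1` and `panel2`.
#' @export
sample_split_markers <- function(geno, N, seed = NULL) {
  stopifnot(inherits(geno, "genotypes"))
  m <- ncol(geno$geno)
  if (N < 1) stop("sample_split_markers: N must be >= 1")
  if (2 * N > m)
    stop("sample_split_markers: 2N = ", 2 * N, " exceeds the ", m,
         " available markers")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(m, 2 * N)
  list(panel1 = subset_genotypes(geno, markers = colnames(geno$geno)[idx[seq_len(N)]]),
       panel2 = subset_genotypes(geno, markers = colnames(geno$geno)[idx[N + seq_len(N)]]))
}

#' Regression slope of one genomic relationship matrix on another
#'
#' Treats `G_t` (built from held-out "causal" markers) as the target and
#' regresses its elements on those of the marker matrix `G_m` over all
#' element pairs `j <= k`.  The diagonal dominance of both matrices is
#' removed by subtracting 1.0 from the diagonal elements before the
#' regression.  The slope `beta` estimates the proportion of additive
#' genetic variance a panel of that size can explain; genomic variance
#' estimated with `G_m` is biased downward by about this factor.
#'
#' @param G_m marker genomic relationship matrix.
#' @param G_t target ("true") genomic relationship matrix over the same
#'   individuals in the same order.
#' @param include_diagonal include the (shifted) diagonal pairs in the
#'   regression (default, as defined); `FALSE` restricts to off-diagonal
#'   pairs for sensitivity analysis.
#' @return named numeric vector `c(alpha, beta)` (intercept and slope).
#' @export
estimate_beta <- function(G_m, G_t, include_diagonal = TRUE) {
  G_m <- unclass(G_m); G_t <- unclass(G_t)
  if (!is.matrix(G_m) || !is.matrix(G_t) || any(dim(G_m) != dim(G_t)))
    stop("estimate_beta: matrices must have identical dimensions")
  if (!is.null(rownames(G_m)) && !is.null(rownames(G_t)) &&
      !identical(rownames(G_m), rownames(G_t)))
    stop("estimate_beta: matrices are over different individuals/orders")
  diag(G_m) <- diag(G_m) - 1
  diag(G_t) <- diag(G_t) - 1
  sel <- upper.tri(G_m, diag = include_diagonal)
  x <- G_m[sel]; y <- G_t[sel]
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0)
    stop("estimate_beta: no variance among the marker-matrix elements")
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(alpha = mean(y) - beta * mean(x), beta = beta)
}

#' Empirical curve of variance captured vs panel size
#'
#' For each panel size `N` and replicate, splits the markers into two
#' disjoint panels of `N`, builds a genomic relationship matrix from each
#' (centering each panel by its own sample allele frequencies), and regresses
#' the second on the first with [estimate_beta()].  The mean slope per `N`
#' traces how the expected proportion of additive variance explained grows
#' with marker density.
#'
#' @param geno a [genotypes] object.
#' @param N_values panel sizes to evaluate.
#' @param n_replicates random splits per panel size.
#' @param seed seed for the whole curve (one RNG stream; the curve is
#'   reproducible bit-for-bit).
#' @param include_diagonal passed to [estimate_beta()].
#' @return a `beta_curve` data frame (`N`, `replicate`, `alpha`, `beta`)
#'   with a per-N aggregate (`N`, `beta_mean`, `beta_sd`) in attribute
#'   `"aggregate"` and the seed in attribute `"seed"`.
#' @export
beta_curve <- function(geno, N_values, n_replicates = 10, seed = 1,
                       include_diagonal = TRUE) {
  stopifnot(inherits(geno, "genotypes"))
  if (n_replicates < 1) stop("beta_curve: n_replicates must be >= 1")
  m <- ncol(geno$geno)
  if (max(N_values) * 2 > m)
    stop("beta_curve: largest 2N = ", 2 * max(N_values), " exceeds the ", m,
         " available markers")
  set.seed(seed)
  rows <- vector("list", length(N_values) * n_replicates)
  k <- 0L
  for (N in N_values) {
    for (rep in seq_len(n_replicates)) {
      sp <- sample_split_markers(geno, N)
      ab <- estimate_beta(build_G(sp$panel1), build_G(sp$panel2),
                          include_diagonal = include_diagonal)
      k <- k + 1L
      rows[[k]] <- data.frame(N = N, replicate = rep,
                              alpha = ab[["alpha"]], beta = ab[["beta"]])
    }
  }
  out <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(out, out$N), function(d)
    data.frame(N = d$N[1], beta_mean = mean(d$beta),
               beta_sd = stats::sd(d$beta))))
  agg <- agg[order(agg$N), ]
  rownames(agg) <- NULL
  attr(out, "aggregate") <- agg
  attr(out, "seed") <- seed
  class(out) <- c("beta_curve", "data.frame")
  out
}

#' @export
summary.beta_curve <- function(object, ...) attr(object, "aggregate")

#' @export
print.beta_curve <- function(x, digits = 4, ...) {
  cat("Variance-captured curve (split-panel regression)\n")
  print(attr(x, "aggregate"), digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
plot.beta_curve <- function(x, ...) {
  agg <- attr(x, "aggregate")
  plot(agg$N, agg$beta_mean, type = "b", pch = 19, ylim = c(0, 1),
       xlab = "number of markers N", ylab = expression(beta),
       main = "expected proportion of additive variance explained", ...)
  graphics::arrows(agg$N, agg$beta_mean - agg$beta_sd,
                   agg$N, agg$beta_mean + agg$beta_sd,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Rescale a genomic relationship matrix towards the causal-locus scale
#'
#' Shrinks the off-diagonal structure of a marker matrix by the estimated
#' accuracy slope: `G* = beta (G_m - I) + I`, so that the rescaled matrix is
#' an unbiased estimate of the causal-locus relationship matrix and the
#' genomic variance estimated with it is corrected for the downward bias of
#' a finite marker panel.
#'
#' @param G_m marker genomic relationship matrix.
#' @param beta the accuracy slope, expected in (0, 1] (values outside give a
#'   warning).
#' @return a [relmat] of kind `"adjusted"` with `beta` recorded as an
#'   attribute.
#' @export
adjust_G <- function(G_m, beta) {
  Gm <- unclass(G_m)
  if (!is.matrix(Gm) || nrow(Gm) != ncol(Gm))
    stop("adjust_G: 'G_m' must be a square matrix")
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta))
    stop("adjust_G: 'beta' must be a finite scalar")
  if (beta <= 0 || beta > 1)
    warning("adjust_G: beta = ", signif(beta, 4),
            " outside the expected (0, 1] range")
  out <- beta * (Gm - diag(nrow(Gm))) + diag(nrow(Gm))
  dimnames(out) <- dimnames(Gm)
  relmat(out, kind = "adjusted", beta = beta,
         markers = attr(G_m, "markers"))
}
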