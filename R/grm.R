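#' Observed second-allele frequencies
#'
#' `p_j` is the mean allele count at marker `j` over non-missing calls,
#' divided by two.
#'
#' @param geno a [genotypes] object.
#' @return named numeric vector of per-marker frequencies in `[0, 1]`.
#' @export
allele_frequencies <- function(geno) {
  stopifnot(inherits(geno, "genotypes"))
  p <- colMeans(geno$geno, na.rm = TRUE) / 2
  if (any(is.nan(p)))
    stop("allele_frequencies: marker(s) with no non-missing calls: ",
         paste(utils::head(names(p)[is.nan(p)], 5), collapse = ", "))
  p
}

#' Marker quality control
#'
#' Removes (i) markers with minor allele frequency strictly below
#' `maf_threshold` and (ii) non-informative markers whose genotype vector is
#' an exact affine function of an earlier retained marker in genome order
#' (covering duplicated markers, allele-flipped copies `2 - m`, and constant
#' vectors).  Affine dependence is detected exactly — by canonicalizing each
#' genotype vector up to shift and scale — not by a correlation threshold.
#'
#' @param geno a [genotypes] object.
#' @param maf_threshold minimum minor allele frequency (strict inequality;
#'   a marker with MAF exactly at the threshold is retained).
#' @return list with elements `genotypes` (the filtered panel) and `report`
#'   (a `qc_report`: counts in, removed by MAF, removed by dependence,
#'   retained, and a per-marker removal log).
#' @export
qc_markers <- function(geno, maf_threshold = 0.01) {
  stopifnot(inherits(geno, "genotypes"))
  if (maf_threshold < 0 || maf_threshold > 0.5)
    stop("qc_markers: 'maf_threshold' must be in [0, 0.5]")
  p <- allele_frequencies(geno)
  maf <- pmin(p, 1 - p)
  fail_maf <- maf < maf_threshold
  removed <- data.frame(marker = character(0), reason = character(0),
                        detail = character(0), stringsAsFactors = FALSE)
  if (any(fail_maf))
    removed <- rbind(removed, data.frame(
      marker = names(p)[fail_maf], reason = "maf",
      detail = sprintf("MAF %.4g < %.4g", maf[fail_maf], maf_threshold),
      stringsAsFactors = FALSE))
  candidates <- colnames(geno$geno)[!fail_maf]
  seen <- new.env(hash = TRUE, parent = emptyenv())
  keep <- character(0)
  for (mk in candidates) {             # genome order: columns already sorted
    v <- geno$geno[, mk]
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    key <- .affine_key(v)
    if (key == "constant") {
      # a constant vector is a degenerate affine function of any marker
      removed <- rbind(removed, data.frame(
        marker = mk, reason = "dependence", detail = "constant vector",
        stringsAsFactors = FALSE))
      next
    }
    prev <- if (!is.null(seen[[key]])) seen[[key]] else NULL
    if (is.null(prev)) {
      seen[[key]] <- mk
      keep <- c(keep, mk)
    } else {
      removed <- rbind(removed, data.frame(
        marker = mk, reason = "dependence",
        detail = paste0("affine function of ", prev),
        stringsAsFactors = FALSE))
    }
  }
  if (length(keep) == 0)
    stop("qc_markers: no markers retained after QC")
  report <- structure(list(n_input = ncol(geno$geno),
                           n_removed_maf = sum(fail_maf),
                           n_removed_dependence = length(candidates) - length(keep),
                           n_retained = length(keep),
                           removed = removed),
                      class = "qc_report")
  list(genotypes = subset_genotypes(geno, markers = keep), report = report)
}

## canonical key of a genotype vector up to affine transformation a*x + b:
## center, then scale so the first nonzero element is 1
.affine_key <- function(v) {
  w <- v - mean(v)
  nz <- which(abs(w) > 1e-9)
  if (length(nz) == 0) return("constant")
  w <- w / w[nz[1]]
  paste(round(w, 9), collapse = ",")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Marker QC: %d in -> %d removed by MAF, %d by linear dependence -> %d retained\n",
              x$n_input, x$n_removed_maf, x$n_removed_dependence, x$n_retained))
  invisible(x)
}

#' Genomic relationship matrix (VanRaden construction)
#'
#' Centers the allele-count matrix `M` column-wise by twice the allele
#' frequency and scales the cross-product by twice the summed marker
#' heterozygosity, `G = (M - P)(M - P)' / (2 * sum_j p_j (1 - p_j))`, so that
#' G is on the same scale as the pedigree relationship matrix.  Missing calls
#' are mean-imputed to `2 p_j` before centering.
#'
#' @param geno a [genotypes] object.
#' @param freqs optional per-marker second-allele frequencies; defaults to
#'   the observed sample frequencies from [allele_frequencies()].
#' @param ids optional individuals to restrict to (frequencies are computed
#'   on the restricted sample unless supplied).
#' @return a [relmat] of kind `"genomic"`; attribute `markers` records the
#'   panel size.
#' @export
build_G <- function(geno, freqs = NULL, ids = NULL) {
  stopifnot(inherits(geno, "genotypes"))
  if (!is.null(ids)) geno <- subset_genotypes(geno, ids = ids)
  m <- ncol(geno$geno)
  if (m < 2) stop("build_G: need at least 2 markers")
  if (is.null(freqs)) {
    p <- allele_frequencies(geno)
  } else {
    if (length(freqs) != m)
      stop("build_G: 'freqs' must have one entry per marker")
    p <- if (!is.null(names(freqs))) freqs[colnames(geno$geno)] else freqs
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
      stop("build_G: invalid frequencies")
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("build_G: all markers monomorphic (sum p(1-p) = 0)")
  W <- geno$geno
  if (anyNA(W)) {
    for (j in which(colSums(is.na(W)) > 0)) W[is.na(W[, j]), j] <- 2 * p[j]
  }
  W <- sweep(W, 2L, 2 * p, "-")
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  relmat(G, kind = "genomic", markers = m)
}

#' Chromosome-split genomic relationship matrices
#'
#' Splits the panel into the markers on one chromosome and the markers on all
#' remaining chromosomes, and builds a genomic relationship matrix from each
#' part.  By default each matrix is normalized by its own summed
#' heterozygosity; `shared_denominator = TRUE` instead divides both
#' cross-products by the whole-genome denominator (this changes only the
#' scale of the per-chromosome variance estimates).
#'
#' @param geno a [genotypes] object spanning at least two chromosomes.
#' @param chrom the chromosome to isolate.
#' @param shared_denominator use the whole-genome `2 sum p(1-p)` for both
#'   matrices.
#' @return list with components `G_c` (kind `"chromosome"`) and `G_o`
#'   (kind `"complement"`).
#' @export
split_G_by_chromosome <- function(geno, chrom, shared_denominator = FALSE) {
  stopifnot(inherits(geno, "genotypes"))
  on_c <- geno$map$chrom == chrom
  if (!any(on_c))
    stop("split_G_by_chromosome: chromosome ", chrom, " has no markers")
  if (sum(on_c) < 2)
    stop("split_G_by_chromosome: chromosome ", chrom, " has fewer than 2 markers")
  if (all(on_c))
    stop("split_G_by_chromosome: no markers left outside chromosome ", chrom)
  gc <- subset_genotypes(geno, markers = geno$map$marker[on_c])
  go <- subset_genotypes(geno, markers = geno$map$marker[!on_c])
  if (shared_denominator) {
    p <- allele_frequencies(geno)
    denom <- 2 * sum(p * (1 - p))
    pc <- p[gc$map$marker]; po <- p[go$map$marker]
    Gc <- build_G(gc, freqs = pc)
    Go <- build_G(go, freqs = po)
    Gc <- unclass(Gc) * (2 * sum(pc * (1 - pc))) / denom
    Go <- unclass(Go) * (2 * sum(po * (1 - po))) / denom
    Gc <- relmat(Gc, kind = "chromosome", markers = sum(on_c), chromosome = chrom)
    Go <- relmat(Go, kind = "complement", markers = sum(!on_c), chromosome = chrom)
  } else {
    Gc <- build_G(gc)
    Go <- build_G(go)
    attr(Gc, "kind") <- "chromosome"; attr(Gc, "chromosome") <- chrom
    attr(Go, "kind") <- "complement"; attr(Go, "chromosome") <- chrom
  }
  list(G_c = Gc, G_o = Go)
}
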