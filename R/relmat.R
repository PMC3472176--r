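#' Relationship matrix objects
#'
#' A `relmat` is a dense symmetric relationship matrix over an ordered set of
#' individuals, tagged by the kind of relationship it encodes: `"pedigree"`
#' (expected additive relationships, identity by descent), `"genomic"`
#' (marker-based realized relationships, identity by state), `"chromosome"` /
#' `"complement"` (a chromosome-split pair), or `"adjusted"` (a genomic matrix
#' rescaled towards the causal-locus scale).  Row and column names carry the
#' individual ids; extra attributes record provenance (marker count,
#' chromosome, adjustment slope).
#'
#' @param x symmetric numeric matrix with identical row/column names.
#' @param kind character tag, see above.
#' @param ... further provenance attributes (e.g. `markers`, `chromosome`,
#'   `beta`) attached to the object.
#' @return `x` with class `relmat`.
#' @export
relmat <- function(x, kind = c("pedigree", "genomic", "chromosome",
                               "complement", "adjusted", "generic"), ...) {
  kind <- match.arg(kind)
  if (!is.matrix(x) || !is.numeric(x)) stop("'x' must be a numeric matrix")
  if (nrow(x) != ncol(x)) stop("relationship matrix must be square")
  if (is.null(rownames(x))) stop("relationship matrix must carry individual ids as dimnames")
  rel <- max(abs(x - t(x))) / max(1, max(abs(x)))
  if (rel > 1e-12) stop("matrix is not symmetric (relative asymmetry ", format(rel), ")")
  colnames(x) <- rownames(x)
  attr(x, "kind") <- kind
  extra <- list(...)
  for (nm in names(extra)) attr(x, nm) <- extra[[nm]]
  class(x) <- c("relmat", class(x))
  x
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("<relmat> %s relationship matrix, %d individuals\n",
              attr(x, "kind"), nrow(x)))
  if (!is.null(attr(x, "markers")))
    cat(sprintf("  markers: %d\n", attr(x, "markers")))
  if (!is.null(attr(x, "chromosome")))
    cat(sprintf("  chromosome: %s\n", attr(x, "chromosome")))
  if (!is.null(attr(x, "beta")))
    cat(sprintf("  adjustment slope beta: %.4f\n", attr(x, "beta")))
  d <- diag(unclass(x))
  cat(sprintf("  diagonal: mean %.4f, range [%.4f, %.4f]\n",
              mean(d), min(d), max(d)))
  invisible(x)
}

#' Principal submatrix of a relationship matrix
#'
#' Restricts a relationship matrix to a subset of its individuals, in the
#' requested order.  Used to align a full-pedigree matrix with the genotyped
#' and phenotyped subset entering the mixed model.
#'
#' @param R a [relmat] (or plain named matrix).
#' @param ids character vector of ids, a subset of `rownames(R)`.
#' @return the principal submatrix as a `relmat` of the same kind.
#' @export
subset_relmat <- function(R, ids) {
  ids <- as.character(ids)
  miss <- setdiff(ids, rownames(R))
  if (length(miss) > 0)
    stop("ids not present in the relationship matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  kind <- attr(R, "kind")
  keep <- attributes(R)
  out <- unclass(R)[ids, ids, drop = FALSE]
  args <- keep[setdiff(names(keep), c("dim", "dimnames", "class", "kind"))]
  do.call(relmat, c(list(x = out, kind = if (is.null(kind)) "generic" else kind), args))
}
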