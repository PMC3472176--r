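#' Genotype matrix with marker map
#'
#' Container for an individuals-by-markers matrix of allele counts (copies of
#' the second allele, coded 0/1/2, `NA` = missing) together with per-marker
#' chromosome and base-pair position.  Markers are kept ordered by
#' (chromosome, position); positions must be strictly increasing within a
#' chromosome.
#'
#' @param geno integer/numeric matrix, rows = individuals (rownames = ids),
#'   columns = markers (colnames = marker ids).
#' @param map data frame with columns `marker`, `chrom`, `pos` covering every
#'   column of `geno`.
#' @return object of class `genotypes`: a list with elements `geno` and `map`.
#' @export
genotypes <- function(geno, map) {
  if (!is.matrix(geno)) stop("'geno' must be a matrix")
  if (is.null(rownames(geno)) || is.null(colnames(geno)))
    stop("'geno' must carry individual ids and marker ids as dimnames")
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(map)))
    stop("'map' must have columns marker, chrom, pos")
  miss_map <- setdiff(colnames(geno), map$marker)
  if (length(miss_map) > 0)
    stop("markers missing from the map: ",
         paste(utils::head(miss_map, 5), collapse = ", "),
         if (length(miss_map) > 5) ", ...")
  extra <- setdiff(map$marker, colnames(geno))
  if (length(extra) > 0)
    stop("map lists markers absent from the genotype matrix: ",
         paste(utils::head(extra, 5), collapse = ", "))
  bad <- !(geno %in% c(0, 1, 2) | is.na(geno))
  if (any(bad))
    stop("genotype codes outside {0, 1, 2, NA}: first offending value ",
         geno[which(bad)[1]])
  map <- map[match(colnames(geno), map$marker), , drop = FALSE]
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  geno <- geno[, map$marker, drop = FALSE]
  for (chr in unique(map$chrom)) {
    p <- map$pos[map$chrom == chr]
    if (any(diff(p) <= 0))
      stop("marker positions must be strictly increasing within chromosome ", chr)
  }
  structure(list(geno = geno, map = map), class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("<genotypes> %d individuals x %d markers on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  nmiss <- sum(is.na(x$geno))
  if (nmiss > 0) cat(sprintf("  missing calls: %d\n", nmiss))
  invisible(x)
}

#' @export
dim.genotypes <- function(x) dim(x$geno)

#' Subset a genotype object by markers and/or individuals
#'
#' @param geno a `genotypes` object.
#' @param markers marker ids or column indices to keep (default all).
#' @param ids individual ids to keep (default all).
#' @return a `genotypes` object; simulator attributes (`hidden`,
#'   `generation`) are carried along.
#' @export
subset_genotypes <- function(geno, markers = NULL, ids = NULL) {
  stopifnot(inherits(geno, "genotypes"))
  g <- geno$geno
  map <- geno$map
  if (!is.null(markers)) {
    if (is.numeric(markers)) markers <- colnames(g)[markers]
    miss <- setdiff(markers, colnames(g))
    if (length(miss) > 0)
      stop("unknown markers: ", paste(utils::head(miss, 5), collapse = ", "))
    keep <- colnames(g) %in% markers   # preserve genome order
    g <- g[, keep, drop = FALSE]
    map <- map[keep, , drop = FALSE]
  }
  if (!is.null(ids)) {
    ids <- as.character(ids)
    miss <- setdiff(ids, rownames(g))
    if (length(miss) > 0)
      stop("unknown individuals: ", paste(utils::head(miss, 5), collapse = ", "))
    g <- g[ids, , drop = FALSE]
  }
  out <- genotypes(g, map)
  hid <- attr(geno, "hidden")
  if (!is.null(hid)) {
    if (!is.null(ids)) hid$geno <- hid$geno[ids, , drop = FALSE]
    attr(out, "hidden") <- hid
  }
  gen <- attr(geno, "generation")
  if (!is.null(gen)) attr(out, "generation") <- gen
  out
}
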