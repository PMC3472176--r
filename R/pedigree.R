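#' Construct and validate a pedigree
#'
#' A pedigree is a data frame of (id, sire, dam) records; missing parents are
#' `NA` (treated as unknown, unrelated, non-inbred founders).  Every
#' non-missing parent must itself appear as an individual.  The records are
#' brought into topological order (parents before offspring); a cycle (an
#' individual among its own ancestors) is an error.
#'
#' @param x data frame with columns `id`, `sire`, `dam` (extra columns are
#'   kept).  Empty strings and `"0"`/`0` parent codes are read as missing.
#' @return a `pedigree` data frame in topological order.
#' @export
as_pedigree <- function(x) {
  if (inherits(x, "pedigree") && isTRUE(attr(x, "topological"))) return(x)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(x)))
    stop("pedigree needs columns id, sire, dam")
  clean <- function(v) {
    v <- as.character(v)
    v[!is.na(v) & (v == "" | v == "0")] <- NA_character_
    v
  }
  x$id <- as.character(x$id)
  x$sire <- clean(x$sire)
  x$dam <- clean(x$dam)
  if (anyNA(x$id) || any(x$id == ""))
    stop("pedigree: missing individual id")
  dup <- x$id[duplicated(x$id)]
  if (length(dup) > 0)
    stop("pedigree: duplicated id(s): ", paste(unique(dup), collapse = ", "))
  for (p in c(x$sire, x$dam)) {
    if (!is.na(p) && !(p %in% x$id))
      stop("pedigree: parent '", p, "' does not appear as an individual")
  }
  sort_pedigree(x)
}

#' Topologically sort a pedigree
#'
#' Orders records so every parent precedes its offspring (Kahn's algorithm);
#' detects cycles.
#'
#' @param ped data frame with columns `id`, `sire`, `dam`.
#' @return the reordered `pedigree` with attribute `topological = TRUE`.
#' @export
sort_pedigree <- function(ped) {
  n <- nrow(ped)
  sire_i <- match(ped$sire, ped$id)
  dam_i <- match(ped$dam, ped$id)
  gdam <- attr(ped, "genetic_dam")
  gdam_i <- if (!is.null(gdam)) match(as.character(gdam), as.character(ped$id)) else NULL
  # already topological: keep the original record order
  ok <- (is.na(sire_i) | sire_i < seq_len(n)) &
        (is.na(dam_i) | dam_i < seq_len(n))
  if (all(ok)) {
    attr(ped, "topological") <- TRUE
    class(ped) <- unique(c("pedigree", class(ped)))
    return(ped)
  }
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire_i[i], dam_i[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  order_out <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    order_out <- c(order_out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order_out) < n)
    stop("pedigree contains a cycle involving id(s): ",
         paste(utils::head(ped$id[indeg > 0], 5), collapse = ", "))
  out <- ped[order_out, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(gdam_i)) attr(out, "genetic_dam") <- ped$id[gdam_i][order_out]
  attr(out, "topological") <- TRUE
  class(out) <- unique(c("pedigree", class(out)))
  out
}

#' Pedigree (numerator) relationship matrix by the tabular method
#'
#' Builds the additive relationship matrix `A` from expected identity by
#' descent: processing individuals in topological order,
#' `a_ii = 1 + a(sire, dam)/2` (missing parents contribute 0, so non-inbred
#' individuals have diagonal exactly 1) and
#' `a_ij = (a(j, sire_i) + a(j, dam_i)) / 2` for earlier `j`.
#'
#' When `ids` is supplied the recursion is restricted to the ancestors of the
#' requested subset and the result is the principal submatrix in the requested
#' order — the phenotyped/genotyped animals aligned against a much larger
#' national-style pedigree.
#'
#' @param ped a pedigree ([as_pedigree()] is applied if needed).
#' @param ids optional ids to restrict the returned matrix to.
#' @return a [relmat] of kind `"pedigree"`; diagonal entries are
#'   `1 + inbreeding coefficient`.
#' @export
make_A <- function(ped, ids = NULL) {
  ped <- as_pedigree(ped)
  if (!is.null(ids)) {
    ids <- as.character(ids)
    miss <- setdiff(ids, ped$id)
    if (length(miss) > 0)
      stop("make_A: unknown id(s): ", paste(utils::head(miss, 5), collapse = ", "))
    keep <- ancestor_closure(ped, ids)
    ped2 <- ped[ped$id %in% keep, , drop = FALSE]
    attr(ped2, "topological") <- TRUE   # subsetting preserves the order
    class(ped2) <- class(ped)
    ped <- ped2
  }
  n <- nrow(ped)
  s <- match(ped$sire, ped$id)
  d <- match(ped$dam, ped$id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    asd <- if (!is.na(s[i]) && !is.na(d[i])) A[s[i], d[i]] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1L) {
      j <- seq_len(i - 1L)
      vs <- if (!is.na(s[i])) A[j, s[i]] else rep(0, i - 1L)
      vd <- if (!is.na(d[i])) A[j, d[i]] else rep(0, i - 1L)
      v <- 0.5 * (vs + vd)
      A[i, j] <- v
      A[j, i] <- v
    }
  }
  dimnames(A) <- list(ped$id, ped$id)
  A <- relmat(A, kind = "pedigree")
  if (!is.null(ids)) A <- subset_relmat(A, ids)
  A
}

## ids plus all their pedigree ancestors
ancestor_closure <- function(ped, ids) {
  sire <- stats::setNames(ped$sire, ped$id)
  dam <- stats::setNames(ped$dam, ped$id)
  seen <- character(0)
  frontier <- ids
  while (length(frontier) > 0) {
    seen <- c(seen, frontier)
    parents <- c(sire[frontier], dam[frontier])
    frontier <- setdiff(unique(parents[!is.na(parents)]), seen)
  }
  unique(seen)
}

#' @export
print.pedigree <- function(x, ...) {
  nf <- sum(is.na(x$sire) & is.na(x$dam))
  cat(sprintf("<pedigree> %d individuals (%d founders)\n", nrow(x), nf))
  invisible(x)
}
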