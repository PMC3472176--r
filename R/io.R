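## Readers and writers for the package's plain-text formats.  Every file the
## package writes starts with a '#' header line carrying the package version
## and the seed of the run; readers skip comment lines.

.stamp <- function(seed = NA) {
  sprintf("# gvpart %s seed=%s",
          as.character(utils::packageVersion("gvpart")), as.character(seed))
}

.sniff_sep <- function(path) {
  l <- readLines(path, n = 10)
  l <- l[!startsWith(l, "#")][1]
  if (grepl("\t", l)) "\t" else if (grepl(",", l)) "," else ""
}

#' Read a pedigree file
#'
#' CSV or TSV with columns `id`, `sire`, `dam`; an empty field or `0` means
#' an unknown parent.  The result is validated (unique ids, parents listed as
#' individuals, no cycles) and topologically sorted, so a file listing an
#' offspring before its parent is handled.
#'
#' @param path file path.
#' @return a `pedigree` data frame; see [as_pedigree()].
#' @export
read_pedigree <- function(path) {
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          colClasses = "character", stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  as_pedigree(df)
}

#' Write a pedigree file
#'
#' @param ped a `pedigree`.
#' @param path output path (CSV; empty field = missing parent).
#' @param seed seed recorded in the header stamp.
#' @export
write_pedigree <- function(ped, path, seed = NA) {
  out <- data.frame(id = ped$id,
                    sire = ifelse(is.na(ped$sire), "", as.character(ped$sire)),
                    dam = ifelse(is.na(ped$dam), "", as.character(ped$dam)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.stamp(seed), con)
  utils::write.table(out, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes with a marker map
#'
#' Two dialects are supported and auto-detected: the package's genotype TSV
#' (first column `id`, remaining columns one marker each) and the PLINK
#' `.raw` allele-dosage dialect (`FID IID PAT MAT SEX PHENOTYPE` then one
#' `SNP_allele` column per marker, space-separated, `NA` = missing).  The
#' companion map TSV must have columns `marker`, `chrom`, `pos`; markers are
#' reordered by (chromosome, position).
#'
#' @param path genotype file.
#' @param map_path marker map file.
#' @return a [genotypes] object (missing calls kept as `NA`; they are
#'   mean-imputed only inside [build_G()]).
#' @export
read_genotypes <- function(path, map_path) {
  header <- readLines(path, n = 20)
  header <- header[!startsWith(header, "#")][1]
  is_raw <- grepl("^FID[ \t]IID", header)
  if (is_raw) {
    df <- utils::read.table(path, header = TRUE, comment.char = "#",
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df$IID)
    gcols <- setdiff(names(df), c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
    M <- as.matrix(df[gcols])
    # strip the _allele suffix PLINK appends to marker names
    colnames(M) <- sub("_[ACGT0-9]+$", "", gcols)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    M <- as.matrix(df[-1])
  }
  storage.mode(M) <- "double"
  rownames(M) <- ids
  map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  names(map) <- tolower(names(map))
  missing_in_map <- setdiff(colnames(M), map$marker)
  extra_in_map <- setdiff(map$marker, colnames(M))
  if (length(missing_in_map) > 0 || length(extra_in_map) > 0)
    stop("read_genotypes: map and genotype markers disagree; ",
         "missing from map: ",
         paste(utils::head(missing_in_map, 5), collapse = ", "),
         "; only in map: ",
         paste(utils::head(extra_in_map, 5), collapse = ", "))
  genotypes(M, map)
}

#' Write genotypes as TSV plus marker map
#'
#' @param geno a [genotypes] object.
#' @param path genotype TSV path.
#' @param map_path marker map TSV path.
#' @param seed seed recorded in the header stamp.
#' @export
write_genotypes <- function(geno, path, map_path, seed = NA) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.stamp(seed), con)
  df <- data.frame(id = rownames(geno$geno), geno$geno, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  con2 <- file(map_path, "w")
  writeLines(.stamp(seed), con2)
  utils::write.table(geno$map, con2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con2)
  invisible(path)
}

#' Write genotypes in the PLINK .raw allele-dosage dialect
#'
#' @inheritParams write_genotypes
#' @export
write_raw <- function(geno, path, seed = NA) {
  M <- geno$geno
  out <- data.frame(FID = rownames(M), IID = rownames(M), PAT = 0, MAT = 0,
                    SEX = 0, PHENOTYPE = -9, check.names = FALSE)
  G <- as.data.frame(M, check.names = FALSE)
  names(G) <- paste0(colnames(M), "_A")
  out <- cbind(out, G)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.stamp(seed), con)
  utils::write.table(out, con, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' TSV with columns `id`, `trait`, `y`, `weight` (one record per row).
#'
#' @param path file path.
#' @param trait optional trait label to filter on.
#' @return a `phenotypes` data frame.
#' @export
read_phenotypes <- function(path, trait = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("id", "y", "weight")
  if (!all(need %in% names(df)))
    stop("read_phenotypes: need columns id, y, weight")
  df$id <- as.character(df$id)
  if (!is.null(trait)) {
    df <- df[df$trait == trait, , drop = FALSE]
    if (nrow(df) == 0) stop("read_phenotypes: no records for trait ", trait)
  }
  if (any(df$weight <= 0)) stop("read_phenotypes: weights must be positive")
  class(df) <- c("phenotypes", "data.frame")
  df
}

#' @rdname read_phenotypes
#' @param phen a `phenotypes` data frame.
#' @param seed seed recorded in the header stamp.
#' @export
write_phenotypes <- function(phen, path, seed = NA) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.stamp(seed), con)
  utils::write.table(phen, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a relationship matrix
#'
#' Either as a symmetric-matrix TSV (header row of ids) or in long format
#' (`id1`, `id2`, `value`; lower triangle including the diagonal).
#'
#' @param R a [relmat].
#' @param path output path.
#' @param format `"wide"` or `"long"`.
#' @param seed seed recorded in the header stamp.
#' @export
write_relmat <- function(R, path, format = c("wide", "long"), seed = NA) {
  format <- match.arg(format)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.stamp(seed), con)
  if (format == "wide") {
    df <- data.frame(id = rownames(R), unclass(R), check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(lower.tri(R, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(id1 = rownames(R)[idx[, 1]],
                     id2 = colnames(R)[idx[, 2]],
                     value = unclass(R)[idx])
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a symmetric-matrix TSV written by [write_relmat()]
#'
#' @param path file path.
#' @param kind relationship kind tag for the result.
#' @return a [relmat].
#' @export
read_relmat <- function(path, kind = "generic") {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (identical(names(df)[1:3], c("id1", "id2", "value"))) {
    ids <- unique(c(df$id1, df$id2))
    M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    M[cbind(df$id1, df$id2)] <- df$value
    M[cbind(df$id2, df$id1)] <- df$value
  } else {
    ids <- as.character(df[[1]])
    M <- as.matrix(df[-1])
    rownames(M) <- ids
  }
  relmat(M, kind = kind)
}

#' Write the true values produced by the simulator
#'
#' @param tv a `true_values` object.
#' @param path output TSV.
#' @param seed seed recorded in the header stamp.
#' @export
write_true_values <- function(tv, path, seed = NA) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.stamp(seed), con)
  utils::write.table(as.data.frame(tv), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
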