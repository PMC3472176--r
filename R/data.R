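#' Published variance components for six dairy traits
#'
#' REML variance-component estimates for three production traits (milk, fat,
#' protein yield) and three fitness traits (female fertility, health,
#' mastitis resistance) of genotyped Nordic Holstein bulls evaluated on
#' deregressed proofs with a 44K SNP panel.  For each trait the table holds
#' the animal-model additive variance (`sigma_a1`) and its variance ratio,
#' the genomic-model variance (`sigma_g2`), the joint model's genomic and
#' residual polygenic variances (`sigma_g3`, `sigma_a3`), and the sum of the
#' per-chromosome genomic variances over the 29 autosomes (`sum_chrom`).
#'
#' These printed estimates serve as inputs for the summary arithmetic of the
#' partition: the genomic share per trait, the joint-model vs animal-model
#' total, and the chromosome-sum ratio.
#'
#' @return data frame with one row per trait.
#' @examples
#' vc <- holstein_vc()
#' # share of total genetic variance attributed to markers, per trait
#' genomic_share(vc$sigma_g3, vc$sigma_a3)
#' @export
holstein_vc <- function() {
  path <- system.file("extdata", "holstein_vc_estimates.tsv",
                      package = "gvpart", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
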