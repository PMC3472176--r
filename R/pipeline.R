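#' Run the end-to-end variance-partitioning pipeline
#'
#' Drives all stages from a single structured configuration: simulate (or
#' load) data, marker QC, relationship matrices, the requested model fits,
#' the per-chromosome scan, and the panel-size accuracy curve.  Every output
#' file is a tidy TSV stamped with the package version and the run seed.
#'
#' The configuration is a YAML file or an equivalent nested list with keys:
#' \describe{
#'   \item{seed}{integer; drives every stochastic stage.}
#'   \item{simulate}{optional list of [sim_config()] arguments; when present
#'     the data are simulated.}
#'   \item{inputs}{otherwise: paths `pedigree`, `genotypes`, `map`,
#'     `phenotypes`, and optionally `trait` to filter on.}
#'   \item{qc}{list, e.g. `maf_threshold: 0.01`.}
#'   \item{models}{vector of model ids among 1, 2, 3 to fit.}
#'   \item{chromosome_scan}{logical; run model 4 per chromosome.}
#'   \item{beta_curve}{optional list `n_values`, `replicates`.}
#'   \item{outdir}{output directory (created).}
#' }
#'
#' @param config path to a YAML file, or a list.
#' @param outdir overrides `config$outdir`.
#' @return (invisibly) a list with the fitted objects, the QC report and the
#'   paths of the written artifacts.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("run_pipeline: config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("run_pipeline: 'config' must be a list or file path")
  seed <- as.integer(config$seed %||% 1L)
  outdir <- outdir %||% config$outdir
  if (is.null(outdir)) stop("run_pipeline: no output directory given")
  # validate everything up front: fail before any artifact is written
  if (is.null(config$simulate)) {
    ins <- config$inputs
    if (is.null(ins)) stop("run_pipeline: need either 'simulate' or 'inputs'")
    for (nm in c("pedigree", "genotypes", "map", "phenotypes")) {
      if (is.null(ins[[nm]])) stop("run_pipeline: inputs$", nm, " missing")
      if (!file.exists(ins[[nm]]))
        stop("run_pipeline: input file not found: ", ins[[nm]])
    }
  }
  models <- as.integer(config$models %||% c(1L, 2L, 3L))
  if (!all(models %in% 1:3))
    stop("run_pipeline: 'models' must be a subset of 1, 2, 3 ",
         "(model 4 runs inside the chromosome scan)")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  log_stage <- function(msg) message("[gvpart] ", msg)

  if (!is.null(config$simulate)) {
    log_stage("simulating population")
    cfg <- do.call(sim_config, c(config$simulate, list(seed = seed)))
    pop <- simulate_population(cfg)
    ped <- pop$pedigree; geno <- pop$genotypes; phen <- pop$phenotypes
    write_pedigree(ped, file.path(outdir, "pedigree.csv"), seed = seed)
    write_genotypes(geno, file.path(outdir, "genotypes.tsv"),
                    file.path(outdir, "marker_map.tsv"), seed = seed)
    write_phenotypes(phen, file.path(outdir, "phenotypes.tsv"), seed = seed)
    write_true_values(pop$true_values,
                      file.path(outdir, "true_values.tsv"), seed = seed)
    artifacts <- c(artifacts, "pedigree.csv", "genotypes.tsv",
                   "marker_map.tsv", "phenotypes.tsv", "true_values.tsv")
  } else {
    log_stage("loading inputs")
    ped <- read_pedigree(config$inputs$pedigree)
    geno <- read_genotypes(config$inputs$genotypes, config$inputs$map)
    phen <- read_phenotypes(config$inputs$phenotypes,
                            trait = config$inputs$trait)
  }

  maf <- config$qc$maf_threshold %||% 0.01
  qc <- qc_markers(geno, maf_threshold = maf)
  log_stage(sprintf("marker QC: %d -> %d retained (%d MAF, %d dependence)",
                    qc$report$n_input, qc$report$n_retained,
                    qc$report$n_removed_maf, qc$report$n_removed_dependence))
  geno <- qc$genotypes
  qc_df <- with(qc$report, data.frame(
    stage = c("input", "removed_maf", "removed_dependence", "retained"),
    markers = c(n_input, n_removed_maf, n_removed_dependence, n_retained)))
  f <- file.path(outdir, "qc_report.tsv")
  con <- file(f, "w"); writeLines(.stamp(seed), con)
  utils::write.table(qc_df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  artifacts <- c(artifacts, "qc_report.tsv")

  ids <- as.character(phen$id)
  log_stage("building relationship matrices")
  A <- make_A(ped, ids = ids)
  G <- build_G(geno, ids = ids)
  write_relmat(A, file.path(outdir, "A_matrix.tsv"), seed = seed)
  write_relmat(G, file.path(outdir, "G_matrix.tsv"), seed = seed)
  artifacts <- c(artifacts, "A_matrix.tsv", "G_matrix.tsv")

  fits <- list()
  rows <- list()
  for (mid in models) {
    log_stage(paste("fitting model", mid))
    fit <- suppressWarnings(fit_vc_model(phen, mid, A = A, G = G))
    fits[[paste0("model", mid)]] <- fit
    est <- fit$fit$sigma2; se <- fit$fit$se
    rows[[length(rows) + 1L]] <- data.frame(
      trait = fit$trait %||% "trait", model = mid,
      component = names(est), estimate = unname(est), se = unname(se),
      VR = fit$VR)
  }
  if (length(rows) > 0) {
    f <- file.path(outdir, "fits.tsv")
    con <- file(f, "w"); writeLines(.stamp(seed), con)
    utils::write.table(do.call(rbind, rows), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    artifacts <- c(artifacts, "fits.tsv")
  }

  scan <- NULL
  if (isTRUE(config$chromosome_scan)) {
    log_stage("chromosome scan (model 4 per chromosome)")
    scan <- chromosome_scan(phen, geno, A,
                            reference_fit = fits$model3)
    f <- file.path(outdir, "chrom_partition.tsv")
    con <- file(f, "w"); writeLines(.stamp(seed), con)
    utils::write.table(as.data.frame(scan), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    artifacts <- c(artifacts, "chrom_partition.tsv")
  }

  bc <- NULL
  if (!is.null(config$beta_curve)) {
    log_stage("panel-size accuracy curve")
    bc <- beta_curve(geno, N_values = config$beta_curve$n_values,
                     n_replicates = config$beta_curve$replicates %||% 10,
                     seed = seed)
    f <- file.path(outdir, "beta_curve.tsv")
    con <- file(f, "w"); writeLines(.stamp(seed), con)
    utils::write.table(as.data.frame(bc), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    f <- file.path(outdir, "beta_curve_aggregate.tsv")
    con <- file(f, "w"); writeLines(.stamp(seed), con)
    utils::write.table(summary(bc), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    artifacts <- c(artifacts, "beta_curve.tsv", "beta_curve_aggregate.tsv")
  }

  manifest <- data.frame(artifact = artifacts, seed = seed)
  con <- file(file.path(outdir, "manifest.tsv"), "w")
  writeLines(.stamp(seed), con)
  utils::write.table(manifest, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(list(fits = fits, qc = qc$report, chromosome_scan = scan,
                 beta_curve = bc, artifacts = file.path(outdir, artifacts),
                 outdir = outdir))
}
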