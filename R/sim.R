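#' Configuration for the population simulator
#'
#' Bundles all parameters of the gene-dropping simulator: a multi-generation
#' sire-heavy pedigree, biallelic SNPs dropped through it with recombination,
#' an additive QTL architecture split between marker-tagged and hidden loci,
#' and deregressed-proof-like phenotypes whose residual variance shrinks with
#' an effective-record weight.
#'
#' The defaults describe the study conditions emulated throughout the package:
#' a progeny-tested dairy-bull-like population with 29 autosomes of 1 Morgan
#' each, founder minor allele frequencies uniform on (0.05, 0.5), 10% of QTL
#' hidden from the marker panel (creating a genuine residual polygenic
#' component), and effective-record weights uniform on (20, 200), i.e. bulls
#' evaluated on large progeny groups of heterogeneous size.
#'
#' @param n_founders number of unrelated founders (first half male, second
#'   half female).
#' @param n_generations number of post-founder generations (0 = founders only).
#' @param sires_per_generation sires sampled from the males of the previous
#'   generation (generation 1 uses founder males).
#' @param offspring_per_sire offspring per selected sire; each offspring's dam
#'   is a founder female sampled with replacement.
#' @param n_chromosomes,markers_per_chromosome genome layout of the marker
#'   panel.
#' @param chromosome_length_morgans genetic length of every chromosome;
#'   physical length is taken as 100 Mb per Morgan.
#' @param maf_range founder allele-frequency bounds, within (0, 0.5].
#' @param n_qtl total number of additive QTL.
#' @param hidden_qtl_fraction fraction of QTL placed on hidden loci that are
#'   gene-dropped like markers but excluded from the panel.
#' @param qtl_chromosomes optional chromosomes to restrict the marker-tagged
#'   QTL to (default: the whole genome); used to plant e.g. a major-gene
#'   architecture on a single chromosome.
#' @param sigma2_g target variance (among final-generation individuals) of the
#'   marker-tagged true-breeding-value component.
#' @param sigma2_polygenic target variance of the hidden-locus component.
#' @param sigma2_e residual variance of a phenotype with unit weight.
#' @param mu general mean of the simulated phenotype.
#' @param weight_range bounds of the uniform effective-record-weight law; a
#'   record with weight w has residual variance `sigma2_e / w`.
#' @param phenotyped which individuals receive phenotypes: all non-founders,
#'   everyone, or the final generation only.
#' @param unknown_dams if `TRUE`, dams are blanked in the recorded pedigree
#'   (the genetic dam is still used for gene dropping), emulating unrecorded
#'   dams in a sire-heavy dairy pedigree.
#' @param seed integer seed; all generator functions derive their RNG state
#'   from it, so a configuration reproduces bit-for-bit.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 100L,
                       n_generations = 4L,
                       sires_per_generation = 20L,
                       offspring_per_sire = 10L,
                       n_chromosomes = 29L,
                       markers_per_chromosome = 50L,
                       chromosome_length_morgans = 1,
                       maf_range = c(0.05, 0.5),
                       n_qtl = 200L,
                       hidden_qtl_fraction = 0.10,
                       qtl_chromosomes = NULL,
                       sigma2_g = 100,
                       sigma2_polygenic = 25,
                       sigma2_e = 25,
                       mu = 100,
                       weight_range = c(20, 200),
                       phenotyped = c("nonfounders", "all", "final"),
                       unknown_dams = FALSE,
                       seed = 1L) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              sires_per_generation = as.integer(sires_per_generation),
              offspring_per_sire = as.integer(offspring_per_sire),
              n_chromosomes = as.integer(n_chromosomes),
              markers_per_chromosome = as.integer(markers_per_chromosome),
              chromosome_length_morgans = chromosome_length_morgans,
              maf_range = maf_range,
              n_qtl = as.integer(n_qtl),
              hidden_qtl_fraction = hidden_qtl_fraction,
              qtl_chromosomes = qtl_chromosomes,
              sigma2_g = sigma2_g,
              sigma2_polygenic = sigma2_polygenic,
              sigma2_e = sigma2_e,
              mu = mu,
              weight_range = weight_range,
              phenotyped = match.arg(phenotyped),
              unknown_dams = isTRUE(unknown_dams),
              seed = as.integer(seed))
  counts <- c("n_founders", "sires_per_generation", "offspring_per_sire",
              "n_chromosomes", "markers_per_chromosome")
  for (nm in counts)
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop("sim_config: '", nm, "' must be a count >= 1")
  if (cfg$n_generations < 0L) stop("sim_config: 'n_generations' must be >= 0")
  if (cfg$n_qtl < 0L) stop("sim_config: 'n_qtl' must be >= 0")
  for (nm in c("sigma2_g", "sigma2_polygenic", "sigma2_e"))
    if (cfg[[nm]] < 0) stop("sim_config: '", nm, "' must be >= 0")
  if (cfg$chromosome_length_morgans < 0)
    stop("sim_config: chromosome length must be >= 0 Morgans")
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stop("sim_config: 'maf_range' bounds must lie within (0, 0.5]")
  if (cfg$hidden_qtl_fraction < 0 || cfg$hidden_qtl_fraction > 1)
    stop("sim_config: 'hidden_qtl_fraction' must be in [0, 1]")
  if (!is.null(cfg$qtl_chromosomes) &&
      any(!(cfg$qtl_chromosomes %in% seq_len(cfg$n_chromosomes))))
    stop("sim_config: 'qtl_chromosomes' outside 1..n_chromosomes")
  if (length(cfg$weight_range) != 2 || any(cfg$weight_range <= 0) ||
      cfg$weight_range[1] > cfg$weight_range[2])
    stop("sim_config: 'weight_range' must be positive and ordered")
  if (cfg$seed >= 2^31 - 16) stop("sim_config: seed too large")
  if (cfg$n_generations >= 1L &&
      cfg$sires_per_generation > ceiling(cfg$n_founders / 2))
    stop("sim_config: not enough founder males to select ",
         cfg$sires_per_generation, " sires")
  if (cfg$n_generations >= 1L && floor(cfg$n_founders / 2) < 1L)
    stop("sim_config: no founder females available as dams")
  class(cfg) <- "sim_config"
  cfg
}

n_hidden_qtl <- function(cfg) round(cfg$n_qtl * cfg$hidden_qtl_fraction)

#' Simulate a sire-heavy multi-generation pedigree
#'
#' Founders are unrelated; in each later generation a fixed number of sires is
#' sampled from the previous generation's males and each sire is mated to
#' founder females (sampled with replacement) to produce its offspring.  Sexes
#' alternate within each sire family so every generation contains males.
#'
#' @param cfg a [sim_config].
#' @return a `pedigree` data frame (columns `id`, `sire`, `dam`, plus
#'   `generation` and `sex`) in topological order.  When `cfg$unknown_dams`
#'   is set the `dam` column is `NA` for non-founders and the true genetic dam
#'   is kept in the `genetic_dam` attribute for gene dropping.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  nf <- cfg$n_founders
  id <- seq_len(nf)
  sex <- rep(c("M", "F"), length.out = nf)
  sire <- rep(NA_integer_, nf)
  dam <- rep(NA_integer_, nf)
  gen <- rep(0L, nf)
  founder_females <- id[sex == "F"]
  next_id <- nf + 1L
  for (g in seq_len(cfg$n_generations)) {
    prev_males <- id[gen == g - 1L & sex == "M"]
    if (length(prev_males) < cfg$sires_per_generation)
      stop("simulate_pedigree: generation ", g, " has only ",
           length(prev_males), " candidate sires")
    sires <- sample(prev_males, cfg$sires_per_generation)
    for (s in sires) {
      k <- cfg$offspring_per_sire
      ids_new <- seq.int(next_id, length.out = k)
      next_id <- next_id + k
      id <- c(id, ids_new)
      sire <- c(sire, rep(s, k))
      dam <- c(dam, sample(founder_females, k, replace = TRUE))
      sex <- c(sex, rep(c("M", "F"), length.out = k))
      gen <- c(gen, rep(g, k))
    }
  }
  ped <- data.frame(id = id, sire = sire, dam = dam,
                    generation = gen, sex = sex,
                    stringsAsFactors = FALSE)
  attr(ped, "genetic_dam") <- ped$dam
  if (cfg$unknown_dams) ped$dam[ped$generation > 0L] <- NA_integer_
  attr(ped, "topological") <- TRUE
  class(ped) <- c("pedigree", "data.frame")
  ped
}

## one meiosis: recombine a parent's two haplotypes at genetic positions gpos
## (Morgans); crossover count Poisson(length), positions uniform (Haldane)
.meiosis <- function(h1, h2, gpos, length_morgans) {
  nxo <- stats::rpois(1L, length_morgans)
  start <- sample.int(2L, 1L) - 1L
  if (nxo == 0L) {
    if (start == 0L) return(h1) else return(h2)
  }
  xo <- sort(stats::runif(nxo, 0, length_morgans))
  phase <- (start + findInterval(gpos, xo)) %% 2L
  ifelse(phase == 0L, h1, h2)
}

## Drop haplotypes for `loci` (data.frame: chrom, pos_bp, gpos, freq) through
## the pedigree.  With founder_labels = TRUE each founder haplotype carries a
## unique integer label instead of a 0/1 allele, and the full haplotype
## matrices are returned — the basis of the allele-conservation check.
.gene_drop <- function(ped, loci, length_morgans, founder_labels = FALSE) {
  n <- nrow(ped)
  sire_row <- match(ped$sire, ped$id)
  dam_row <- match(attr(ped, "genetic_dam") %||% ped$dam, ped$id)
  m <- nrow(loci)
  geno <- matrix(0L, n, m)
  haps <- if (founder_labels) vector("list", length(unique(loci$chrom))) else NULL
  chroms <- unique(loci$chrom)
  for (ci in seq_along(chroms)) {
    jj <- which(loci$chrom == chroms[ci])
    gpos <- loci$gpos[jj]
    p <- loci$freq[jj]
    mc <- length(jj)
    H <- matrix(0L, 2L * n, mc)
    for (i in seq_len(n)) {
      r1 <- 2L * i - 1L; r2 <- 2L * i
      if (is.na(sire_row[i]) && is.na(dam_row[i])) {
        if (founder_labels) {
          H[r1, ] <- r1
          H[r2, ] <- r2
        } else {
          H[r1, ] <- stats::rbinom(mc, 1L, p)
          H[r2, ] <- stats::rbinom(mc, 1L, p)
        }
      } else {
        if (is.na(sire_row[i]) || is.na(dam_row[i]))
          stop("simulate_genotypes: individual ", ped$id[i],
               " has exactly one known genetic parent; gene dropping needs both")
        sr <- sire_row[i]; dr <- dam_row[i]
        if (sr >= i || dr >= i)
          stop("simulate_genotypes: pedigree is not topologically ordered")
        H[r1, ] <- .meiosis(H[2L * sr - 1L, ], H[2L * sr, ], gpos, length_morgans)
        H[r2, ] <- .meiosis(H[2L * dr - 1L, ], H[2L * dr, ], gpos, length_morgans)
      }
    }
    if (founder_labels) haps[[ci]] <- H
    geno[, jj] <- H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
      H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  }
  list(geno = geno, haplotypes = haps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gene-drop genotypes through a simulated pedigree
#'
#' Founders draw haplotypes per marker from the configured founder allele
#' frequencies under Hardy-Weinberg; every non-founder receives one recombined
#' gamete from each genetic parent (crossover count per chromosome Poisson
#' with mean equal to the chromosome length in Morgans, crossover positions
#' uniform).  Marker physical positions are drawn uniformly along each
#' chromosome (100 Mb per Morgan) and genetic positions are proportional to
#' physical ones.  Hidden QTL loci (per `cfg`) are dropped through the same
#' process and attached as an attribute, excluded from the marker panel.
#'
#' @param ped a topologically ordered `pedigree` from [simulate_pedigree()].
#' @param cfg the [sim_config] used to create `ped`.
#' @return a `genotypes` object (see [genotypes()]); attribute `"hidden"`
#'   holds the hidden-locus genotypes and map, attribute `"generation"` the
#'   per-individual generation.
#' @export
simulate_genotypes <- function(ped, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!inherits(ped, "pedigree")) stop("'ped' must be a pedigree object")
  if (!isTRUE(attr(ped, "topological"))) ped <- sort_pedigree(ped)
  set.seed(cfg$seed + 1L)
  L <- cfg$chromosome_length_morgans
  len_bp <- max(1e6, round(L * 1e8))
  maps <- lapply(seq_len(cfg$n_chromosomes), function(chr) {
    pos <- sort(sample.int(len_bp, cfg$markers_per_chromosome))
    while (anyDuplicated(pos))  # strictly increasing positions
      pos <- sort(sample.int(len_bp, cfg$markers_per_chromosome))
    data.frame(chrom = chr, pos_bp = pos, gpos = pos / len_bp * L)
  })
  map <- do.call(rbind, maps)
  map$marker <- sprintf("snp_c%02d_%04d", map$chrom,
                        stats::ave(map$pos_bp, map$chrom, FUN = seq_along))
  map$freq <- stats::runif(nrow(map), cfg$maf_range[1], cfg$maf_range[2])
  nh <- n_hidden_qtl(cfg)
  hidden_map <- NULL
  if (nh > 0L) {
    # hidden loci live on chromosomes carrying no markers: variance they
    # generate is tracked by pedigree, not by realized marker co-segregation
    n_hidden_chrom <- max(2L, round(cfg$n_chromosomes / 10))
    hidden_map <- data.frame(chrom = cfg$n_chromosomes +
                               sample.int(n_hidden_chrom, nh, replace = TRUE),
                             pos_bp = sample.int(len_bp, nh, replace = TRUE))
    hidden_map$gpos <- hidden_map$pos_bp / len_bp * L
    hidden_map$marker <- sprintf("hidden_%03d", seq_len(nh))
    hidden_map$freq <- stats::runif(nh, cfg$maf_range[1], cfg$maf_range[2])
  }
  all_loci <- rbind(map[c("chrom", "pos_bp", "gpos", "marker", "freq")],
                    hidden_map)
  ord <- order(all_loci$chrom, all_loci$pos_bp)
  all_loci <- all_loci[ord, ]
  drop <- .gene_drop(ped, data.frame(chrom = all_loci$chrom,
                                     pos_bp = all_loci$pos_bp,
                                     gpos = all_loci$gpos,
                                     freq = all_loci$freq),
                     L)
  rownames(drop$geno) <- as.character(ped$id)
  colnames(drop$geno) <- all_loci$marker
  is_hidden <- grepl("^hidden_", all_loci$marker)
  g <- genotypes(drop$geno[, !is_hidden, drop = FALSE],
                 data.frame(marker = all_loci$marker[!is_hidden],
                            chrom = all_loci$chrom[!is_hidden],
                            pos = all_loci$pos_bp[!is_hidden],
                            founder_freq = all_loci$freq[!is_hidden]))
  if (nh > 0L)
    attr(g, "hidden") <- list(geno = drop$geno[, is_hidden, drop = FALSE],
                              map = data.frame(marker = all_loci$marker[is_hidden],
                                               chrom = all_loci$chrom[is_hidden],
                                               pos = all_loci$pos_bp[is_hidden]))
  attr(g, "generation") <- stats::setNames(ped$generation, as.character(ped$id))
  g
}

#' Assign QTL effects and compute true breeding values
#'
#' Places `cfg$n_qtl` additive QTL: a fraction on genotyped markers, the
#' remainder on the hidden loci that were gene-dropped alongside the panel.
#' Effects are sampled i.i.d. normal and each component is rescaled so that
#' its realized variance among final-generation individuals equals the target
#' (`sigma2_g` for the marker-tagged component, `sigma2_polygenic` for the
#' hidden one); both components are centered on the founder mean.
#'
#' @param geno a `genotypes` object from [simulate_genotypes()].
#' @param cfg the matching [sim_config].
#' @return a `true_values` data frame (`id`, `tbv`, `tbv_genomic`,
#'   `tbv_polygenic`) with the QTL table in attribute `"qtl"`.
#' @export
assign_qtl_and_tbv <- function(geno, cfg) {
  stopifnot(inherits(cfg, "sim_config"), inherits(geno, "genotypes"))
  set.seed(cfg$seed + 2L)
  nh <- n_hidden_qtl(cfg)
  nm <- cfg$n_qtl - nh
  if (cfg$n_qtl == 0L && (cfg$sigma2_g > 0 || cfg$sigma2_polygenic > 0))
    stop("assign_qtl_and_tbv: n_qtl = 0 with a positive target variance")
  if (nm > ncol(geno$geno))
    stop("assign_qtl_and_tbv: more marker QTL requested than markers available")
  gen <- attr(geno, "generation")
  ids <- rownames(geno$geno)
  if (is.null(gen)) gen <- stats::setNames(rep(0L, length(ids)), ids)
  final <- ids[gen[ids] == max(gen[ids])]
  founders <- ids[gen[ids] == min(gen[ids])]
  scale_component <- function(Q, target, label) {
    if (target == 0 || ncol(Q) == 0L) {
      return(list(values = stats::setNames(rep(0, length(ids)), ids),
                  effects = rep(0, ncol(Q))))
    }
    a <- stats::rnorm(ncol(Q))
    u <- as.vector(Q %*% a)
    names(u) <- ids
    v <- stats::var(u[final])
    if (v <= 0)
      stop("assign_qtl_and_tbv: ", label,
           " component has zero variance in the final generation; ",
           "increase n_qtl or marker diversity")
    s <- sqrt(target / v)
    list(values = (u - mean(u[founders])) * s, effects = a * s)
  }
  eligible <- if (is.null(cfg$qtl_chromosomes)) seq_len(ncol(geno$geno))
  else which(geno$map$chrom %in% cfg$qtl_chromosomes)
  if (nm > length(eligible))
    stop("assign_qtl_and_tbv: more marker QTL requested than eligible markers")
  qtl_idx <- if (nm > 0L) sort(sample(eligible, nm)) else integer(0)
  gm <- scale_component(geno$geno[, qtl_idx, drop = FALSE], cfg$sigma2_g, "marker-QTL")
  hidden <- attr(geno, "hidden")
  if (cfg$sigma2_polygenic > 0 && (nh == 0L || is.null(hidden)))
    stop("assign_qtl_and_tbv: positive sigma2_polygenic but no hidden loci; ",
         "set hidden_qtl_fraction > 0")
  hg <- if (!is.null(hidden))
    scale_component(hidden$geno, cfg$sigma2_polygenic, "hidden-QTL")
  else list(values = stats::setNames(rep(0, length(ids)), ids), effects = numeric(0))
  qtl <- rbind(
    if (nm > 0L) data.frame(locus = colnames(geno$geno)[qtl_idx],
                            chrom = geno$map$chrom[qtl_idx],
                            pos = geno$map$pos[qtl_idx],
                            hidden = FALSE, effect = gm$effects)
    else NULL,
    if (!is.null(hidden) && nh > 0L)
      data.frame(locus = hidden$map$marker, chrom = hidden$map$chrom,
                 pos = hidden$map$pos, hidden = TRUE, effect = hg$effects)
    else NULL)
  tv <- data.frame(id = ids,
                   tbv = gm$values + hg$values,
                   tbv_genomic = gm$values,
                   tbv_polygenic = hg$values,
                   stringsAsFactors = FALSE)
  attr(tv, "qtl") <- qtl
  attr(tv, "generation") <- gen
  class(tv) <- c("true_values", "data.frame")
  tv
}

#' Simulate deregressed-proof-like phenotypes
#'
#' Each phenotyped individual gets an effective-record weight `w` drawn from
#' the configured uniform law and a record `y = mu + TBV + e` with
#' `e ~ N(0, sigma2_e / w)` — the structure of a progeny-group mean corrected
#' for non-genetic effects, whose precision grows with the progeny group size.
#'
#' @param tv a `true_values` object from [assign_qtl_and_tbv()].
#' @param cfg the matching [sim_config]; `cfg$phenotyped` selects which
#'   individuals carry records.
#' @return a `phenotypes` data frame: `id`, `trait`, `y`, `weight`.
#' @export
simulate_drp <- function(tv, cfg) {
  stopifnot(inherits(cfg, "sim_config"), inherits(tv, "true_values"))
  if (cfg$sigma2_e <= 0)
    stop("simulate_drp: sigma2_e must be > 0 for finite-weight records")
  set.seed(cfg$seed + 3L)
  gen <- attr(tv, "generation")
  keep <- switch(cfg$phenotyped,
                 all = rep(TRUE, nrow(tv)),
                 nonfounders = gen[tv$id] > min(gen),
                 final = gen[tv$id] == max(gen))
  if (!any(keep)) keep <- rep(TRUE, nrow(tv))  # founders-only population
  ids <- tv$id[keep]
  w <- stats::runif(length(ids), cfg$weight_range[1], cfg$weight_range[2])
  e <- stats::rnorm(length(ids), 0, sqrt(cfg$sigma2_e / w))
  phen <- data.frame(id = ids, trait = "sim_trait",
                     y = cfg$mu + tv$tbv[keep] + e, weight = w,
                     stringsAsFactors = FALSE)
  class(phen) <- c("phenotypes", "data.frame")
  phen
}

#' Run the whole simulator
#'
#' Convenience wrapper chaining [simulate_pedigree()], [simulate_genotypes()],
#' [assign_qtl_and_tbv()] and [simulate_drp()].
#'
#' @param cfg a [sim_config].
#' @return list with elements `pedigree`, `genotypes`, `true_values`,
#'   `phenotypes`, and the `config` itself.
#' @export
simulate_population <- function(cfg = sim_config()) {
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  tv <- assign_qtl_and_tbv(geno, cfg)
  phen <- simulate_drp(tv, cfg)
  list(pedigree = ped, genotypes = geno, true_values = tv,
       phenotypes = phen, config = cfg)
}
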