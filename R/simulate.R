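#' Configuration for the breeding-population simulator
#'
#' Defaults describe a tilapia-like breeding nucleus: four offspring
#' year-classes produced by a two-dams-per-sire nested mating design
#' (50 sires x 100 dams, 80 full-sib families per year-class), family sizes
#' from a truncated normal with mean 18 and range 5-49, a 22-chromosome
#' genome of about 1 Gb carrying 5,000 SNPs (a desk-scale stand-in for a
#' post-QC 32K chip), 500 additive QTL per trait, and two traits shaped
#' like fillet yield (mean 34.2, SD 2.13, h2 0.21, common-environment
#' ratio c2 0.037) and harvest weight (mean 878 g, SD 254 g, h2 0.36,
#' c2 0.068). Founder linkage disequilibrium comes from a random-mating
#' burn-in (base population 200, 100 generations) at 1 cM/Mb.
#'
#' @param n_generations number of offspring year-classes.
#' @param n_sires,n_dams parents available per generation; the nested
#'   design requires `n_dams = 2 * n_sires`.
#' @param n_families full-sib families per year-class (at most `2 * n_sires`).
#' @param offspring_per_family list with `mean`, `sd`, `min`, `max` of the
#'   truncated-normal family-size distribution.
#' @param n_chromosomes,chromosome_lengths_bp genome layout.
#' @param n_snps,n_qtl marker and causal-locus counts.
#' @param traits trait names.
#' @param h2_target,c2_target per-trait narrow-sense heritability and
#'   common-environment variance ratio (fractions; their sum < 1).
#' @param trait_means,trait_sds phenotype scale per trait.
#' @param cg_levels contemporary groups per year-class; `cg_sd_frac` is the
#'   SD of the group effects as a fraction of the trait SD.
#' @param cov_beta_frac covariate slope as a fraction of trait SD (the
#'   covariate itself is standard normal noise).
#' @param trait_cor genetic correlation between the traits' QTL effects
#'   (0 = independent).
#' @param burnin_generations,base_size random-mating burn-in used to build
#'   founder haplotypes with LD.
#' @param cm_per_mb recombination map density.
#' @param seed integer seed controlling every random draw.
#' @return a validated list of class `aquaGS_config`.
#' @export
simulationConfig <- function(n_generations = 4L,
                             n_sires = 50L,
                             n_dams = 100L,
                             n_families = 80L,
                             offspring_per_family = list(mean = 18, sd = 7,
                                                         min = 5, max = 49),
                             n_chromosomes = 22L,
                             chromosome_lengths_bp =
                               round(seq(70e6, 22e6,
                                         length.out = n_chromosomes)),
                             n_snps = 5000L,
                             n_qtl = 500L,
                             traits = c("fy", "hw"),
                             h2_target = c(fy = 0.21, hw = 0.36),
                             c2_target = c(fy = 0.037, hw = 0.068),
                             trait_means = c(fy = 34.2, hw = 878),
                             trait_sds = c(fy = 2.13, hw = 254),
                             cg_levels = 4L,
                             cg_sd_frac = 0.25,
                             cov_beta_frac = 0.3,
                             trait_cor = 0,
                             burnin_generations = 100L,
                             base_size = 200L,
                             cm_per_mb = 1,
                             seed = 1L) {
  cfg <- list(n_generations = as.integer(n_generations),
              n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
              n_families = as.integer(n_families),
              offspring_per_family = offspring_per_family,
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_lengths_bp = as.numeric(chromosome_lengths_bp),
              n_snps = as.integer(n_snps), n_qtl = as.integer(n_qtl),
              traits = traits,
              h2_target = h2_target, c2_target = c2_target,
              trait_means = trait_means, trait_sds = trait_sds,
              cg_levels = as.integer(cg_levels), cg_sd_frac = cg_sd_frac,
              cov_beta_frac = cov_beta_frac, trait_cor = trait_cor,
              burnin_generations = as.integer(burnin_generations),
              base_size = as.integer(base_size), cm_per_mb = cm_per_mb,
              seed = as.integer(seed))
  o <- cfg$offspring_per_family
  if (cfg$n_dams != 2L * cfg$n_sires)
    stop("the nested mating design requires n_dams = 2 * n_sires")
  if (!(o$min <= o$mean && o$mean <= o$max))
    stop("family size must satisfy min <= mean <= max")
  if (any(cfg$h2_target + cfg$c2_target <= 0) ||
      any(cfg$h2_target + cfg$c2_target >= 1))
    stop("h2_target + c2_target must lie in (0, 1) for every trait")
  if (length(cfg$chromosome_lengths_bp) != cfg$n_chromosomes)
    stop("chromosome_lengths_bp must have n_chromosomes entries")
  if (cfg$n_families > 2L * cfg$n_sires)
    stop("n_families exceeds n_sires * 2: not enough matings")
  if (cfg$n_qtl > cfg$n_snps)
    stop("n_qtl cannot exceed n_snps")
  if (cfg$n_snps < cfg$n_chromosomes)
    stop("need at least one SNP per chromosome")
  for (nm in c("h2_target", "c2_target", "trait_means", "trait_sds"))
    if (length(cfg[[nm]]) != length(cfg$traits))
      stop(nm, " must have one value per trait")
  class(cfg) <- "aquaGS_config"
  cfg
}

## truncated-normal family sizes by rejection
truncNormInt <- function(n, mean, sd, lo, hi) {
  out <- integer(0)
  while (length(out) < n) {
    x <- round(rnorm(2L * n, mean, sd))
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate a multi-generation nested-mating pedigree
#'
#' Founders (generation 0) are `n_sires` males and `n_dams` females. Each
#' year-class nests two dams within each sire; family sizes are drawn from
#' the configured truncated normal. Parents of later year-classes are
#' sampled at random (no selection) from the previous year-class.
#'
#' @param config a [simulationConfig()].
#' @param seed overrides `config$seed` when given.
#' @return a [Pedigree-class]; offspring sexes used internally for parent
#'   sampling are kept in `attr(, "sex")`.
#' @export
simulatePedigree <- function(config, seed = config$seed) {
  set.seed(seed)
  cfg <- config
  id <- c(sprintf("G0_S%03d", seq_len(cfg$n_sires)),
          sprintf("G0_D%03d", seq_len(cfg$n_dams)))
  sex <- c(rep("M", cfg$n_sires), rep("F", cfg$n_dams))
  sire <- rep("0", length(id)); dam <- rep("0", length(id))
  gen <- rep(0L, length(id))
  males <- id[sex == "M"]; females <- id[sex == "F"]
  for (g in seq_len(cfg$n_generations)) {
    if (length(males) < ceiling(cfg$n_families / 2) ||
        length(females) < cfg$n_families)
      stop("not enough candidate parents in generation ", g - 1L)
    n_sires_used <- ceiling(cfg$n_families / 2)
    sires_g <- sample(males, n_sires_used)
    dams_g <- sample(females, cfg$n_families)
    fam_sire <- rep(sires_g, each = 2L)[seq_len(cfg$n_families)]
    sizes <- truncNormInt(cfg$n_families,
                          cfg$offspring_per_family$mean,
                          cfg$offspring_per_family$sd,
                          cfg$offspring_per_family$min,
                          cfg$offspring_per_family$max)
    n_off <- sum(sizes)
    off_id <- sprintf("G%d_%05d", g, seq_len(n_off))
    off_sex <- rep(c("M", "F"), length.out = n_off)[sample.int(n_off)]
    id <- c(id, off_id)
    sire <- c(sire, rep(fam_sire, sizes))
    dam <- c(dam, rep(dams_g, sizes))
    gen <- c(gen, rep(g, n_off))
    sex <- c(sex, off_sex)
    males <- off_id[off_sex == "M"]
    females <- off_id[off_sex == "F"]
  }
  ped <- new("Pedigree", id = id, sire = sire, dam = dam, generation = gen)
  attr(ped, "sex") <- setNames(sex, id)
  ped
}

## One meiosis: recombine the two parental haplotype vectors.
## `gmap` is the precomputed genome map (see snpGenomeMap).
meiosis <- function(hapA, hapB, gmap) {
  nxo <- rpois(gmap$n_chr, gmap$morgans)
  tot <- sum(nxo)
  if (tot > 0L) {
    xo <- runif(tot) * rep(gmap$len_bp, nxo) + rep(gmap$offset, nxo)
    xo <- sort(xo)
    seg <- findInterval(gmap$gpos, xo)
  } else {
    seg <- 0L
  }
  phase <- (seg + gmap$start_phase[gmap$chr_idx] +
              sample(2L, gmap$n_chr, replace = TRUE)[gmap$chr_idx]) %% 2L
  out <- hapA
  swap <- phase == 1L
  out[swap] <- hapB[swap]
  out
}

## Precompute global bp offsets so one findInterval serves all chromosomes.
snpGenomeMap <- function(map, chr_lengths, cm_per_mb) {
  chrs <- unique(map$chr)
  n_chr <- length(chrs)
  len_bp <- chr_lengths[seq_len(n_chr)]
  offset <- c(0, cumsum(len_bp))[seq_len(n_chr)]
  chr_idx <- match(map$chr, chrs)
  list(n_chr = n_chr, len_bp = len_bp, offset = offset,
       chr_idx = chr_idx,
       gpos = map$pos + offset[chr_idx],
       morgans = len_bp / 1e6 * cm_per_mb / 100,
       start_phase = integer(n_chr))
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder haplotypes come from a random-mating burn-in of a small base
#' population (so neighbouring SNPs carry LD that decays with distance);
#' every non-founder receives one recombinant gamete per parent, with
#' crossovers placed by a Poisson/exponential process along each chromosome
#' at `cm_per_mb`. Dosage is the sum of the two inherited haplotypes.
#'
#' @param ped a [Pedigree-class] (founders = animals with two unknown
#'   parents).
#' @param config a [simulationConfig()].
#' @param seed overrides `config$seed` when given.
#' @param keep_haplotypes when `TRUE` the two haplotype matrices are
#'   attached as `attr(, "haplotypes")` (a list of two animal x SNP
#'   matrices), used by tests that need gametic truth.
#' @return a [GenotypeData-class] covering every pedigree animal.
#' @export
simulateGenotypes <- function(ped, config, seed = config$seed,
                              keep_haplotypes = FALSE) {
  cfg <- config
  set.seed(seed + 1L)
  if (cfg$n_snps < cfg$n_chromosomes)
    stop("need at least one SNP per chromosome")
  ## SNP map: counts proportional to chromosome length, >= 1 per chromosome
  lens <- cfg$chromosome_lengths_bp
  quota <- pmax(1L, round(cfg$n_snps * lens / sum(lens)))
  while (sum(quota) != cfg$n_snps) {
    k <- if (sum(quota) > cfg$n_snps) which.max(quota) else which.min(quota)
    quota[k] <- quota[k] + sign(cfg$n_snps - sum(quota))
  }
  map <- do.call(rbind, lapply(seq_len(cfg$n_chromosomes), function(cc) {
    pos <- sort(sample.int(lens[cc] - 2L, quota[cc]))
    data.frame(snp = sprintf("snp_%02d_%05d", cc, seq_len(quota[cc])),
               chr = sprintf("chr%02d", cc), pos = pos,
               a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  }))
  gmap <- snpGenomeMap(map, lens, cfg$cm_per_mb)
  nsnp <- nrow(map)

  ## burn-in: random mating at constant size to build LD
  nb <- cfg$base_size
  p0 <- runif(nsnp, 0.1, 0.9)
  H <- matrix(rbinom(2L * nb * nsnp, 1L, rep(p0, each = 2L * nb)),
              nrow = 2L * nb)
  storage.mode(H) <- "integer"
  for (g in seq_len(cfg$burnin_generations)) {
    Hn <- matrix(0L, 2L * nb, nsnp)
    sires <- sample.int(nb, nb, replace = TRUE)
    dams <- sample.int(nb, nb, replace = TRUE)
    clash <- sires == dams
    dams[clash] <- (dams[clash] %% nb) + 1L
    for (k in seq_len(nb)) {
      Hn[2L * k - 1L, ] <- meiosis(H[2L * sires[k] - 1L, ],
                                   H[2L * sires[k], ], gmap)
      Hn[2L * k, ] <- meiosis(H[2L * dams[k] - 1L, ],
                              H[2L * dams[k], ], gmap)
    }
    H <- Hn
  }

  ## drop through the pedigree
  n <- length(ped@id)
  founder <- ped@sire == "0" & ped@dam == "0"
  if (sum(founder) > nb)
    stop("base_size must be at least the number of pedigree founders")
  pos <- seq_len(n); names(pos) <- ped@id
  hap1 <- matrix(0L, n, nsnp, dimnames = list(ped@id, map$snp))
  hap2 <- matrix(0L, n, nsnp, dimnames = list(ped@id, map$snp))
  base_pick <- sample.int(nb, sum(founder))
  fidx <- which(founder)
  for (k in seq_along(fidx)) {
    hap1[fidx[k], ] <- H[2L * base_pick[k] - 1L, ]
    hap2[fidx[k], ] <- H[2L * base_pick[k], ]
  }
  for (k in which(!founder)) {
    s <- pos[ped@sire[k]]; d <- pos[ped@dam[k]]
    hap1[k, ] <- meiosis(hap1[s, ], hap2[s, ], gmap)
    hap2[k, ] <- meiosis(hap1[d, ], hap2[d, ], gmap)
  }
  geno <- genotypeData(hap1 + hap2, map)
  if (keep_haplotypes)
    attr(geno, "haplotypes") <- list(paternal = hap1, maternal = hap2)
  geno
}

#' Simulate phenotypes on a gene-dropped population
#'
#' True breeding values are sums of QTL dosages times normal effects,
#' rescaled so the additive variance over phenotyped animals matches
#' `h2_target` of the trait variance; a common-environment effect shared by
#' all full sibs of a family matches `c2_target`; the residual takes the
#' remainder. Phenotype = trait mean + contemporary-group effect +
#' covariate term + a + c + e. Founders carry breeding values but no
#' phenotype records.
#'
#' @param ped a [Pedigree-class].
#' @param geno the matching [GenotypeData-class].
#' @param config a [simulationConfig()].
#' @param seed overrides `config$seed` when given.
#' @return a [SimulatedPopulation-class].
#' @export
simulatePhenotypes <- function(ped, geno, config, seed = config$seed) {
  cfg <- config
  set.seed(seed + 2L)
  if (cfg$n_qtl > ncol(geno@dosage))
    stop("n_qtl cannot exceed the number of simulated SNPs")
  traits <- cfg$traits
  n_tr <- length(traits)
  D <- geno@dosage[ped@id, , drop = FALSE]
  phen_idx <- which(ped@generation > 0L)
  poly <- which(apply(D[phen_idx, , drop = FALSE], 2L, var) > 0)
  if (length(poly) < cfg$n_qtl)
    stop("fewer polymorphic SNPs than requested QTL")
  qtl_snps <- sort(sample(poly, cfg$n_qtl))
  ## correlated normal effects across traits
  z <- matrix(rnorm(cfg$n_qtl * n_tr), cfg$n_qtl, n_tr)
  if (n_tr > 1L && cfg$trait_cor != 0) {
    R <- matrix(cfg$trait_cor, n_tr, n_tr); diag(R) <- 1
    z <- z %*% chol(R)
  }
  fam <- fullSibFamily(ped)
  phen <- data.frame(animal = ped@id[phen_idx],
                     generation = ped@generation[phen_idx],
                     family = unname(fam[phen_idx]),
                     stringsAsFactors = FALSE)
  ## contemporary groups nested in year-class
  phen$cg <- paste0("g", phen$generation, "_cg",
                    sample.int(cfg$cg_levels, nrow(phen), replace = TRUE))
  tbv <- matrix(0, length(ped@id), n_tr,
                dimnames = list(ped@id, traits))
  qtl <- data.frame(snp = geno@map$snp[qtl_snps], stringsAsFactors = FALSE)
  params <- list(seed = seed, realized = list())
  fam_levels <- unique(phen$family)
  for (t in seq_len(n_tr)) {
    sd_p <- cfg$trait_sds[[t]]
    s2a <- cfg$h2_target[[t]] * sd_p^2
    s2c <- cfg$c2_target[[t]] * sd_p^2
    s2e <- (1 - cfg$h2_target[[t]] - cfg$c2_target[[t]]) * sd_p^2
    a_raw <- drop(D[, qtl_snps, drop = FALSE] %*% z[, t])
    sda <- sd(a_raw[phen_idx])
    scl <- if (sda > 0) sqrt(s2a) / sda else 0
    a <- (a_raw - mean(a_raw[phen_idx])) * scl
    tbv[, t] <- a
    qtl[[paste0("effect_", traits[t])]] <- z[, t] * scl
    c_fam <- setNames(rnorm(length(fam_levels), 0, sqrt(s2c)), fam_levels)
    cg_lv <- unique(phen$cg)
    cg_eff <- setNames(rnorm(length(cg_lv), 0, cfg$cg_sd_frac * sd_p), cg_lv)
    covar <- rnorm(nrow(phen))
    e <- rnorm(nrow(phen), 0, sqrt(s2e))
    y <- cfg$trait_means[[t]] + cg_eff[phen$cg] + c_fam[phen$family] +
      cfg$cov_beta_frac * sd_p * covar + a[phen_idx] + e
    phen[[traits[t]]] <- unname(y)
    phen[[paste0(traits[t], "_cov")]] <- covar
    tot <- var(a[phen_idx]) + var(c_fam[phen$family]) + var(e)
    params$realized[[traits[t]]] <-
      list(var_a = var(a[phen_idx]), var_c = var(c_fam[phen$family]),
           var_e = var(e), h2 = var(a[phen_idx]) / tot,
           c2 = var(c_fam[phen$family]) / tot,
           sigma2 = c(a = s2a, c = s2c, e = s2e))
  }
  new("SimulatedPopulation", pedigree = ped, genotypes = geno,
      phenotypes = phen, tbv = tbv, qtl = qtl, params = params,
      config = unclass(cfg))
}

#' Simulate a complete breeding population
#'
#' Convenience wrapper: [simulatePedigree()] then [simulateGenotypes()]
#' then [simulatePhenotypes()] under one seed.
#'
#' @inheritParams simulatePhenotypes
#' @param keep_haplotypes passed to [simulateGenotypes()].
#' @return a [SimulatedPopulation-class].
#' @examples
#' cfg <- simulationConfig(n_generations = 1, n_sires = 5, n_dams = 10,
#'                         n_families = 8, n_snps = 120, n_qtl = 30,
#'                         n_chromosomes = 3,
#'                         chromosome_lengths_bp = c(4e7, 3e7, 2e7),
#'                         burnin_generations = 20, base_size = 40,
#'                         seed = 7)
#' pop <- simulatePopulation(cfg)
#' pop
#' @export
simulatePopulation <- function(config, seed = config$seed,
                               keep_haplotypes = FALSE) {
  ped <- simulatePedigree(config, seed = seed)
  geno <- simulateGenotypes(ped, config, seed = seed,
                            keep_haplotypes = keep_haplotypes)
  simulatePhenotypes(ped, geno, config, seed = seed)
}

#' Write a simulated dataset to disk
#'
#' Emits the pedigree CSV, PLINK-style PED/MAP genotypes, the phenotype
#' CSV and a JSON sidecar with the true simulation parameters (for use as
#' test oracles). Every file carries a header with the package version and
#' the seed.
#'
#' @param pop a [SimulatedPopulation-class].
#' @param dir output directory (created if needed).
#' @return character vector of the written paths, invisibly.
#' @export
writeDataset <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(paste("aquaGS", as.character(utils::packageVersion("aquaGS"))),
           paste("seed", pop@params$seed))
  paths <- c(
    writePedigree(pop@pedigree, file.path(dir, "pedigree.csv"), header = hdr),
    writePlink(pop@genotypes, file.path(dir, "genotypes"), header = hdr),
    writePhenotypes(pop@phenotypes, file.path(dir, "phenotypes.csv"),
                    header = hdr))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    sidecar <- file.path(dir, "truth.json")
    jsonlite::write_json(pop@params, sidecar, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, sidecar)
  }
  invisible(paths)
}
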