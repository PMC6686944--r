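#' @import methods
#' @importFrom stats var cor sd rnorm runif rbinom rpois rexp pchisq
#'   pnorm pt qnorm setNames aggregate na.omit optimize model.matrix
#'   complete.cases
#' @importFrom utils read.table write.table head tail
NULL

#' Pedigree of a breeding population
#'
#' Ordered animal records with sire and dam identifiers. Unknown parents are
#' coded `"0"`. Records are stored topologically sorted so that every parent
#' precedes its offspring; [readPedigree()] and [sortPedigree()] enforce
#' this order and reject cyclic pedigrees.
#'
#' @slot id character vector of unique animal identifiers.
#' @slot sire,dam character vectors, same length as `id`; `"0"` = unknown.
#' @slot generation integer vector; founders are generation 0.
#'
#' @seealso [makeA()], [makeAInverse()], [simulatePedigree()]
#' @export
setClass("Pedigree",
  representation(id = "character", sire = "character", dam = "character",
                 generation = "integer"))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  if (length(object@sire) != n || length(object@dam) != n ||
      length(object@generation) != n)
    return("id, sire, dam and generation must have equal length")
  if (anyDuplicated(object@id))
    return("duplicate animal ids")
  if (any(object@id == "0"))
    return("'0' is reserved for unknown parents")
  pos <- seq_len(n)
  names(pos) <- object@id
  for (p in list(object@sire, object@dam)) {
    known <- p != "0"
    if (!all(p[known] %in% object@id))
      return("parent referenced but not present in the pedigree")
    if (any(pos[p[known]] >= pos[known]))
      return("pedigree is not topologically sorted (parent after offspring)")
  }
  TRUE
})

#' SNP genotypes with a physical map
#'
#' Dosage-coded genotypes (0/1/2 copies of the counted allele, `NA` =
#' missing) for a set of animals, together with the SNP map. Rows are
#' animals, columns SNPs. Base-pair positions are strictly increasing
#' within each chromosome.
#'
#' @slot dosage numeric matrix, animals x SNPs, with dimnames.
#' @slot map data.frame with columns `snp`, `chr`, `pos`, `a1`, `a2`;
#'   one row per column of `dosage`. `a2` is the counted allele.
#'
#' @seealso [readPlink()], [qcFilter()], [makeG()]
#' @export
setClass("GenotypeData",
  representation(dosage = "matrix", map = "data.frame"))

setValidity("GenotypeData", function(object) {
  m <- object@map
  need <- c("snp", "chr", "pos")
  if (!all(need %in% names(m)))
    return("map must have columns snp, chr, pos")
  if (nrow(m) != ncol(object@dosage))
    return("map rows must match dosage columns")
  if (!identical(as.character(m$snp), colnames(object@dosage)))
    return("map snp ids must match dosage column names")
  if (is.null(rownames(object@dosage)))
    return("dosage must carry animal ids as rownames")
  bad <- unlist(lapply(split(m$pos, m$chr), function(p) any(diff(p) <= 0)))
  if (any(bad))
    return("bp positions must be strictly increasing within chromosome")
  d <- object@dosage
  if (any(d < 0 | d > 2, na.rm = TRUE))
    return("dosages must lie in [0, 2]")
  TRUE
})

#' Genotype quality-control report
#'
#' Counts of SNPs and samples removed by each filter, in the order the
#' filters were applied (sample call rate, SNP call rate, MAF, HWE), plus
#' the surviving id lists.
#'
#' @slot n_snps_in,n_samples_in input dimensions.
#' @slot removed named integer vector: `samples_callrate`, `snp_callrate`,
#'   `snp_maf`, `snp_hwe`.
#' @slot kept_snps,kept_samples character vectors of survivors.
#' @slot thresholds named numeric vector of the thresholds used.
#' @export
setClass("QCReport",
  representation(n_snps_in = "integer", n_samples_in = "integer",
                 removed = "integer", kept_snps = "character",
                 kept_samples = "character", thresholds = "numeric"))

setValidity("QCReport", function(object) {
  snp_removed <- sum(object@removed[c("snp_callrate", "snp_maf", "snp_hwe")])
  if (snp_removed + length(object@kept_snps) != object@n_snps_in)
    return("removed + surviving SNPs must equal input SNPs")
  if (object@removed[["samples_callrate"]] + length(object@kept_samples) !=
      object@n_samples_in)
    return("removed + surviving samples must equal input samples")
  TRUE
})

#' Variance components of the animal model
#'
#' REML estimates of the additive (`a`), common-environment (`c`) and
#' residual (`e`) variances of the animal model
#' `y = Xb + Za + Wc + e`, their asymptotic standard errors from the
#' average-information matrix, and the derived heritability
#' `h2 = s2a / (s2a + s2c + s2e)` with its delta-method standard error.
#'
#' @slot sigma2 named numeric, components `a`, `c`, `e` (variances >= 0).
#' @slot se named numeric, same names; `NA` when not estimated.
#' @slot h2,h2_se heritability and its standard error.
#' @slot converged logical; `n_iter` iterations used.
#' @slot loglik REML log-likelihood at the final iterate.
#' @slot ai average-information matrix at convergence (3x3, or 0x0).
#' @export
setClass("VarianceComponents",
  representation(sigma2 = "numeric", se = "numeric", h2 = "numeric",
                 h2_se = "numeric", converged = "logical",
                 n_iter = "integer", loglik = "numeric", ai = "matrix"))

setValidity("VarianceComponents", function(object) {
  if (!all(c("a", "c", "e") %in% names(object@sigma2)))
    return("sigma2 must be named a, c, e")
  if (any(object@sigma2 < 0))
    return("variance components must be non-negative")
  TRUE
})

#' Solutions of the mixed-model equations
#'
#' Fixed-effect solutions, (genomic) estimated breeding values and
#' common-environment (full-sib family) solutions from Henderson's
#' mixed-model equations with a pedigree (`A`) or combined (`H`)
#' relationship. The relative residual of the solved system is kept as a
#' solver diagnostic.
#'
#' @slot beta named numeric, fixed-effect solutions.
#' @slot u named numeric, breeding values for every pedigree animal
#'   (EBV under A-inverse, GEBV under H-inverse).
#' @slot cfam named numeric, full-sib family solutions (length 0 when the
#'   common-environment effect is not fitted).
#' @slot kinship character, `"A-inverse"` or `"H-inverse"` (or `"G-inverse"`).
#' @slot vc the [VarianceComponents-class] used to form the variance ratios.
#' @slot residual_norm relative residual of the assembled equations.
#' @export
setClass("MixedModelFit",
  representation(beta = "numeric", u = "numeric", cfam = "numeric",
                 kinship = "character", vc = "VarianceComponents",
                 residual_norm = "numeric"))

#' A simulated breeding population
#'
#' Container returned by [simulatePopulation()]: the pedigree, the
#' gene-dropped genotypes, the phenotype table, the true breeding values
#' and the realized simulation parameters, which downstream tests use as
#' oracles.
#'
#' @slot pedigree a [Pedigree-class].
#' @slot genotypes a [GenotypeData-class] covering every pedigree animal.
#' @slot phenotypes data.frame: `animal`, one column per trait, `cg`
#'   (contemporary group), one covariate column per trait
#'   (`<trait>_cov`), `family` (full-sib family label), `generation`.
#' @slot tbv numeric matrix, animals x traits, true breeding values.
#' @slot qtl data.frame of the causal SNPs and their effects per trait.
#' @slot params list of realized quantities (per-trait realized h2, c2,
#'   variance shares) for use as test oracles.
#' @slot config the [simulationConfig()] list that produced the dataset.
#' @export
setClass("SimulatedPopulation",
  representation(pedigree = "Pedigree", genotypes = "GenotypeData",
                 phenotypes = "data.frame", tbv = "matrix", qtl = "data.frame",
                 params = "list", config = "list"))

setValidity("SimulatedPopulation", function(object) {
  if (!all(object@phenotypes$animal %in% object@pedigree@id))
    return("phenotyped animals must be in the pedigree")
  if (!all(rownames(object@tbv) %in% object@pedigree@id))
    return("tbv rows must be pedigree animals")
  TRUE
})
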