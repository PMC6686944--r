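#' Accessors for aquaGS classes
#'
#' Small accessor generics: `animalIds()` returns the ordered animal ids of
#' a pedigree or genotype set; `sireOf()`/`damOf()` the parent ids;
#' `nAnimals()`/`nSnps()` dimensions; `dosages()` the dosage matrix;
#' `snpMap()` the SNP map; `varComp()` the variance components as a named
#' vector; `breedingValues()` the EBV/GEBV vector of a fit.
#'
#' @param x an aquaGS object.
#' @param object an aquaGS object.
#' @return the slot content described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))
#' @rdname accessors
#' @export
setGeneric("sireOf", function(x) standardGeneric("sireOf"))
#' @rdname accessors
#' @export
setGeneric("damOf", function(x) standardGeneric("damOf"))
#' @rdname accessors
#' @export
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))
#' @rdname accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))
#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))
#' @rdname accessors
#' @export
setGeneric("varComp", function(x) standardGeneric("varComp"))
#' @rdname accessors
#' @export
setGeneric("breedingValues", function(x) standardGeneric("breedingValues"))

#' @rdname accessors
setMethod("animalIds", "Pedigree", function(x) x@id)
#' @rdname accessors
setMethod("sireOf", "Pedigree", function(x) setNames(x@sire, x@id))
#' @rdname accessors
setMethod("damOf", "Pedigree", function(x) setNames(x@dam, x@id))
#' @rdname accessors
setMethod("nAnimals", "Pedigree", function(x) length(x@id))
#' @rdname accessors
setMethod("animalIds", "GenotypeData", function(x) rownames(x@dosage))
#' @rdname accessors
setMethod("nAnimals", "GenotypeData", function(x) nrow(x@dosage))
#' @rdname accessors
setMethod("nSnps", "GenotypeData", function(x) ncol(x@dosage))
#' @rdname accessors
setMethod("dosages", "GenotypeData", function(x) x@dosage)
#' @rdname accessors
setMethod("snpMap", "GenotypeData", function(x) x@map)
#' @rdname accessors
setMethod("varComp", "VarianceComponents", function(x) x@sigma2)
#' @rdname accessors
setMethod("varComp", "MixedModelFit", function(x) x@vc@sigma2)
#' @rdname accessors
setMethod("breedingValues", "MixedModelFit", function(x) x@u)

#' Subset a GenotypeData by animals and/or SNPs
#'
#' @param x a [GenotypeData-class].
#' @param i animal ids (character) or indices.
#' @param j SNP ids (character) or indices.
#' @param ... ignored.
#' @param drop ignored; the result is always a `GenotypeData`.
#' @return a [GenotypeData-class] restricted to the requested animals/SNPs.
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  d <- x@dosage
  m <- x@map
  if (!missing(i)) d <- d[i, , drop = FALSE]
  if (!missing(j)) {
    d <- d[, j, drop = FALSE]
    rownames(m) <- m$snp
    m <- m[colnames(d), , drop = FALSE]
    rownames(m) <- NULL
  }
  new("GenotypeData", dosage = d, map = m)
})

setMethod("show", "Pedigree", function(object) {
  cat("Pedigree with", length(object@id), "animals,",
      sum(object@sire == "0" & object@dam == "0"), "founders,",
      length(unique(object@generation)), "generation(s)\n")
})

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object@dosage), "animals x",
      ncol(object@dosage), "SNPs on",
      length(unique(object@map$chr)), "chromosome(s);",
      sum(is.na(object@dosage)), "missing dosages\n")
})

setMethod("show", "QCReport", function(object) {
  cat("Genotype QC:", object@n_samples_in, "samples,",
      object@n_snps_in, "SNPs in\n")
  cat("  removed samples (call rate):",
      object@removed[["samples_callrate"]], "\n")
  cat("  removed SNPs: call rate", object@removed[["snp_callrate"]],
      "| MAF", object@removed[["snp_maf"]],
      "| HWE", object@removed[["snp_hwe"]], "\n")
  cat("  surviving:", length(object@kept_samples), "samples,",
      length(object@kept_snps), "SNPs\n")
})

setMethod("show", "VarianceComponents", function(object) {
  s <- object@sigma2
  cat("Variance components (REML", if (object@converged) "converged"
      else "NOT converged", "in", object@n_iter, "iterations)\n")
  cat(sprintf("  sigma2_a = %.6g (se %.3g)\n", s[["a"]], object@se[["a"]]))
  cat(sprintf("  sigma2_c = %.6g (se %.3g)\n", s[["c"]], object@se[["c"]]))
  cat(sprintf("  sigma2_e = %.6g (se %.3g)\n", s[["e"]], object@se[["e"]]))
  cat(sprintf("  h2 = %.4f (se %.3g)\n", object@h2, object@h2_se))
})

setMethod("show", "MixedModelFit", function(object) {
  cat("MixedModelFit (", object@kinship, "): ",
      length(object@beta), " fixed effects, ",
      length(object@u), " breeding values, ",
      length(object@cfam), " family effects; rel. residual ",
      format(object@residual_norm, digits = 3), "\n", sep = "")
})

setMethod("show", "SimulatedPopulation", function(object) {
  cat("SimulatedPopulation:", length(object@pedigree@id), "animals,",
      ncol(object@genotypes@dosage), "SNPs,",
      nrow(object@phenotypes), "phenotype records,",
      ncol(object@tbv), "trait(s)\n")
})
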