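test_that("LD panel selection hits its target and lowers adjacent LD", {
  g <- small_geno()
  nsnp <- nSnps(g)
  ## target = HD count: identity panel, thresholds saturate
  all_panel <- selectLDPanel(g, nsnp)
  expect_equal(all_panel$achieved, nsnp)
  expect_setequal(all_panel$snps, snpMap(g)$snp)
  ## reduced targets achieved within 5%
  for (target in c(40, 80)) {
    p <- selectLDPanel(g, target)
    expect_lte(abs(p$achieved - target) / target, 0.05)
    ## per-chromosome allocation roughly proportional to length
    expect_true(all(p$per_chromosome$achieved >= 1))
  }
  ## pruned panel has lower mean adjacent-pair r2 than the HD panel
  p <- selectLDPanel(g, 60)
  adj_r2 <- function(geno) {
    D <- dosages(geno)
    map <- snpMap(geno)
    out <- c()
    for (cc in unique(map$chr)) {
      j <- which(map$chr == cc)
      j <- j[apply(D[, j, drop = FALSE], 2, sd) > 0]
      if (length(j) > 1)
        for (k in seq_len(length(j) - 1))
          out <- c(out, cor(D[, j[k]], D[, j[k + 1]])^2)
    }
    mean(out)
  }
  expect_lte(adj_r2(g[, p$snps]), adj_r2(g))
  ## fewer targets than chromosomes is an error
  expect_error(selectLDPanel(g, 2), "chromosomes")
})

test_that("reference/validation split follows the study arithmetic", {
  parents <- paste0("p", 1:108)
  offspring <- paste0("o", 1:1130)
  sp <- splitReference(parents, offspring, 0.20, seed = 5)
  ## 20% of 1,130 offspring = 226 reference, 904 validation
  expect_length(sp$reference, 108 + 226)
  expect_length(sp$validation, 904)
  expect_length(intersect(sp$reference, sp$validation), 0)
  ## deterministic under the seed
  sp2 <- splitReference(parents, offspring, 0.20, seed = 5)
  expect_identical(sp, sp2)
  ## fraction zero keeps parents only
  sp0 <- splitReference(parents, offspring, 0, seed = 5)
  expect_identical(sp0$reference, parents)
  expect_warning(splitReference(character(0), offspring, 0.2, seed = 1),
                 "population-only")
  expect_error(splitReference(c("x"), c("x", "y"), 0.2, seed = 1),
               "overlap")
})

test_that("homozygous parents force the imputed dosage", {
  ## sire 2/2 and dam 2/2 at an untyped locus force offspring dosage 2
  map <- data.frame(snp = paste0("s", 1:6), chr = "1", pos = 1:6 * 1e6)
  ref <- genotypeData(rbind(sire = c(2, 2, 2, 2, 2, 2),
                            dam = c(2, 0, 2, 2, 0, 2)), map)
  ped <- suppressWarnings(pedigree("kid", "sire", "dam"))
  val <- genotypeData(matrix(c(2, 2), 1, 2,
                             dimnames = list("kid", c("s1", "s6"))),
                      map[c(1, 6), ])
  imp <- imputeGenotypes(ref, val, ped)
  expect_equal(unname(dosages(imp)["kid", c("s1", "s3", "s4", "s6")]),
               c(2, 2, 2, 2))
  expect_equal(unname(dosages(imp)["kid", c("s2", "s5")]), c(1, 1))
})

test_that("an unmasked validation panel is returned unchanged", {
  pop <- small_pop()
  ped <- pop@pedigree
  g <- small_geno()
  off <- intersect(ped@id[ped@generation == 1], animalIds(g))
  par <- intersect(ped@id[ped@generation == 0], animalIds(g))
  sp <- splitReference(par, off, 0.2, seed = 2)
  imp <- imputeGenotypes(g[sp$reference, ], g[sp$validation, ], ped)
  expect_equal(dosages(imp), dosages(g[sp$validation, ]))
  acc <- imputationAccuracy(g[sp$validation, ], imp)
  expect_equal(acc$mean_r, 1)
  expect_equal(acc$concordance, 1)
})

test_that("family matching recovers a non-recombinant segment exactly", {
  ## sire heterozygous everywhere with haplotypes all-1 / all-0; dam 0/0.
  ## The HD reference sib carries the all-1 gamete; a validation sib with
  ## the same gamete and two typed loci must be restored exactly.
  m <- 12
  map <- data.frame(snp = paste0("s", 1:m), chr = "1", pos = 1:m * 1e6)
  ref <- genotypeData(rbind(sire = rep(1, m), dam = rep(0, m),
                            refkid = rep(1, m)), map)
  ped <- pedigree(c("sire", "dam", "refkid", "valkid"),
                  c("0", "0", "sire", "sire"),
                  c("0", "0", "dam", "dam"))
  val <- genotypeData(matrix(c(1, 1), 1, 2,
                             dimnames = list("valkid", c("s1", "s12"))),
                      map[c(1, 12), ])
  imp <- imputeGenotypes(ref, val, ped)
  expect_equal(unname(dosages(imp)["valkid", ]), rep(1, m))
})

test_that("accuracy bookkeeping handles degenerate predictors", {
  set.seed(20)
  truth <- matrix(rbinom(40, 2, 0.5), 8, 5,
                  dimnames = list(paste0("a", 1:8), paste0("s", 1:5)))
  ## perfect imputation: every defined correlation is 1
  acc <- imputationAccuracy(truth, truth)
  expect_equal(as.numeric(na.omit(acc$per_snp$r)),
               rep(1, sum(!is.na(acc$per_snp$r))), tolerance = 1e-12)
  ## constant imputation: correlation undefined, concordance reported
  const <- truth; const[] <- 1
  acc2 <- imputationAccuracy(truth, const)
  expect_true(all(is.na(acc2$per_snp$r)))
  expect_equal(acc2$concordance, mean(truth == 1))
  ## random guessing is uncorrelated on average
  set.seed(21)
  big_truth <- matrix(rbinom(500 * 40, 2, 0.5), 500, 40,
                      dimnames = list(paste0("a", 1:500),
                                      paste0("s", 1:40)))
  guess <- matrix(rbinom(500 * 40, 2, 0.5), 500, 40,
                  dimnames = dimnames(big_truth))
  acc3 <- imputationAccuracy(big_truth, guess)
  expect_lt(abs(acc3$mean_r), 0.03)
  expect_error(imputationAccuracy(truth, truth, character(0)), "masked")
})

test_that("imputation accuracy does not decrease with panel density", {
  pop <- mid_pop()
  ped <- pop@pedigree
  qc <- qcFilter(pop@genotypes)
  last <- max(ped@generation)
  off <- intersect(ped@id[ped@generation == last],
                   animalIds(qc$genotypes))
  par <- intersect(unique(c(sireOf(ped)[off], damOf(ped)[off])),
                   animalIds(qc$genotypes))
  g <- qc$genotypes[c(par, off), ]
  sp <- splitReference(par, off, 0.2, seed = 9)
  acc <- vapply(c(50, 150), function(target) {
    panel <- selectLDPanel(g, target)
    imp <- imputeGenotypes(g[sp$reference, ],
                           g[sp$validation, panel$snps], ped)
    masked <- setdiff(snpMap(g)$snp, panel$snps)
    imputationAccuracy(g[sp$validation, ], imp, masked)$mean_r
  }, numeric(1))
  expect_lte(acc[1], acc[2] + 0.005)
  expect_gt(acc[2], 0.85)
})
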